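---
title: "Phantom epistasis from imperfect LD: model, simulators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom epistasis from imperfect LD: model, simulators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomepi)
```

## The problem

Interaction (epistasis) tests in GWAS regress a phenotype on two marker
genotypes and their product.  When the markers tag an untyped causal
locus imperfectly, the part of the additive causal signal that the
markers' linear span misses is generally *not* orthogonal to the
product contrast, and the population interaction coefficient is nonzero
even though nothing in the generating biology interacts.  This package
makes that mechanism computable: exactly, from a specified multi-locus
haplotype law, and empirically, by Monte Carlo simulation.

## Population model

Let $z$ be the centered genotype of a causal locus with
allele-substitution effect $b$, and $x_1, x_2$ centered marker
genotypes.  The trait is $y = zb + \delta$ with
$\delta \perp (z, x_1, x_2)$.  The instrumental regression
$y = \mu + x_1\beta_1 + x_2\beta_2 + x_1x_2\,\beta_{12} + \varepsilon$
has population coefficients
$$(\beta_1, \beta_2, \beta_{12})^\top = T^{-1}
  \big(E(zx_1),\, E(zx_2),\, E(zx_1x_2)\big)^\top b,$$
where $T$ collects the second-through-fourth genotypic moments of
$(x_1, x_2, x_1x_2)$ with its $(3,3)$ entry equal to
$E(x_1^2x_2^2) - E(x_1x_2)^2$.  Three facts organize everything the
package does:

1. **Moments are LD.**  Every entry above is a genotypic LD measure;
   under random mating each equals twice the corresponding haploid
   central moment (pairwise $D$ for second moments, the three-locus $D$
   for $E(zx_1x_2)$).  The package therefore parameterizes populations
   directly by allele frequencies and haploid $D$ coefficients.
2. **Zero regimes.**  $\beta_{12} = 0$ whenever (i) the causal locus is
   in linkage equilibrium with both markers, or (ii) it is in *perfect*
   LD with the marker pair (its genotype is a linear function of
   theirs), or (iii) any one locus is independent of the pair formed by
   the other two.  Mutual but imperfect LD of the triple is therefore
   necessary (not sufficient) for a phantom interaction, which is what
   `check_necessary_conditions()` reports.
3. **Power, not bias, scales with the study.**  $\beta_{12}$ is a fixed
   population quantity; what grows with sample size and with the
   variance explained by the causal locus is the probability that a
   Wald test detects it.  Hence "bigger data" makes the inferential
   problem worse, which the experiment drivers quantify.

Dominance at the causal locus ($y = az + dz^2 + \delta$) keeps $T$ and
changes only the coupling: the right-hand side becomes
$a\,\mathrm{rhs}_\text{add} + d\,\mathrm{rhs}_\text{dom}$.  Multi-QTL
architectures contribute additively:
$\beta_{12} = \sum_j b_j [T^{-1}\mathrm{rhs}_j]_3$.

### A note on the dominance right-hand side

With a mean-centered phenotype and an intercept in the fitted model,
the dominance signal couples to each regressor through a covariance.
Only the interaction regressor has a nonzero mean, so the package
stores the third dominance entry as
$\mathrm{Cov}(z^2, x_1x_2) = E(z^2x_1x_2) - E(z^2)E(x_1x_2)$.  The raw
moment $E(z^2x_1x_2)$, which is how the emergence criterion
$aE(zx_1x_2) + dE(z^2x_1x_2) \ne 0$ is usually quoted, coincides with
the covariance form exactly when the two markers are in linkage
equilibrium — the setting in which that criterion is normally
discussed (e.g. two flanking markers that are marginally independent).
For markers in LD only the covariance form is the large-sample limit
of the OLS fit, and the package's solver is required (and tested) to
agree with large-$n$ OLS in all regimes.

## Exact computation: enumeration as the canonical path

`exact_moments()` enumerates all $2^L \times 2^L$ ordered diplotypes
(64 for three loci), forms each diplotype's population-centered codes
and accumulates probability-weighted products.  Closed-form shortcuts
(e.g. "genotypic = 2 × haploid") are used as *cross-checks* in the test
suite, never as the primary computation.  Degenerate moment matrices
are detected by SVD at relative tolerance $10^{-10}$ (exposed as an
argument, never hard-coded into comparisons): when the causal genotype
is perfectly spanned by the markers the interaction coefficient is
reported as 0 with a `degenerate` flag; a singular system without that
structure has no well-defined coefficients and they are withheld as
`NA` rather than silently pseudo-inverted.  The solver additionally
recomputes $\beta_{12}$ from the explicit third-row formula and
requires agreement with the dense solve to $10^{-10}$.

## What the synthetic generator emulates

Real-data simulation studies of this problem draw marker triples from
biobank-scale human genotypes, where LD decays with physical distance
along a chromosome.  The package's stand-in is deliberately minimal:

* **Haplotype laws.**  The two-/three-locus constructor uses the
  orthogonal Bernoulli expansion (a Bennett-style parameterization):
  each haplotype frequency is the product of its marginals plus
  D-correction terms, so requested marginals and central moments are
  reproduced exactly, and infeasible $D$ combinations fail loudly with
  the offending haplotype named.
* **Chromosome emulation.**  Allele indicators form a first-order
  Markov chain along loci with adjacent haploid correlation
  $\exp(-\Delta\text{bp}/\lambda)$.  The default decay length
  $\lambda = 0.3$ Mb makes pairwise $R^2$ fall steeply within 0.5 Mb
  and become negligible by 1–2 Mb, qualitatively mimicking the decay
  profile of distantly related human samples.  It is a stand-in, not a
  model of human LD: real LD is blocky, has long-range exceptions, and
  varies along the genome, so distance-axis results on the emulator
  are interpreted qualitatively (shape, limits, orderings), never as
  numeric reproductions of biobank values.
* **Diploids.**  Random union of two independent haplotypes
  (Hardy–Weinberg / random mating, no inbreeding parameter) — the
  assumption under which genotypic LD is twice haploid LD, and which
  the test suite verifies by enumeration across randomly generated
  feasible laws.
* **Phenotypes.**  Total variance is normalized to 1; a QTL "explaining
  fraction $\varphi$" has $b = \sqrt{\varphi/\mathrm{Var}(z)}$ and the
  residual is $N(0, 1-\varphi)$ (effect sign fixed positive; sign is
  immaterial to rejection rates).  The infinitesimal term is either an
  independent normal deviate or an equally weighted sum of standardized
  background-locus codes scaled to its variance share.

What passing tests on these generators show is that the *mechanism* —
inflation governed by mutual imperfect LD, calibration at the LD
extremes, growth with $n$ and $\varphi$ — is implemented correctly;
they do not certify magnitudes for any real population, because those
depend on the empirical LD structure.

## Centering conventions

Analytic (population) work centers genotypes at twice the allele
frequency; empirical pipelines center at observed column means, which
is also the default in the experiment drivers.  Both are supported via
`center_genotypes(G, means = )`, and `empirical_moments()` refuses
uncentered input rather than auto-centering, so the convention in
force is always visible in calling code.  The interaction regressor is
the product of *centered* markers and is not re-centered; the
intercept absorbs its mean.  The centering choice shifts main-effect
estimates slightly in finite samples but not the interaction test at
the sample sizes studied.

## Monte Carlo design

* **Seeding.**  A master seed seeds R's generator once; one sub-seed
  per replicate (or per grid cell) is drawn from it and each replicate
  reseeds with its own sub-seed.  Experiments are therefore pure
  functions of their scenario object, byte-identical on rerun.
* **Replicates.**  Default 1,000 per scenario cell; binomial Monte
  Carlo standard errors $\sqrt{r(1-r)/\text{reps}}$ are always
  reported, and calibration assertions in the test suite use 2–3 SE
  bands.
* **Degenerate replicates** (collinear designs, e.g. a duplicated
  marker draw) are excluded and counted, never imputed.
* **Problem sizes.**  The shipped tests run the null-calibration study
  at $n = 10{,}000$ with 2,000 replicates, the power-monotonicity grid
  at $n \in \{10, 50, 100\} \times 10^3$ with 500 replicates per cell,
  the three-pair study at $n = 50{,}000$ with 400 replicates, and the
  exact-vs-OLS agreement at $n = 10^6$ — sizes at which the analytic
  operating characteristics (computed from the population coefficients
  and the moment matrix before any simulation) put the quantities
  being asserted comfortably inside their Monte Carlo error bands.
* **Pinned scenarios.**  The mutually dependent triple with
  frequencies $(0.5, 0.4, 0.3)$, pairwise $D = (0.05, 0.04, 0.03)$ and
  three-locus $D = 0.01$ is the package's reference nonzero-$\beta_{12}$
  population ($\beta_{12} = 0.0674476\,b$); the three-pair geometry
  uses MAF 0.2, within-pair lag 0.1 Mb and span 0.5 Mb with 5% local
  genetic variance, chosen by analytic power so that the inter-block-LD
  arm is detectable at desk scale while the 6 Mb arm is exactly null to
  numerical precision.

## Known limitations

* No forward simulation of mutation/recombination and no coalescent
  machinery; haplotype laws are specified, not evolved.
* Haploid quantities are only available from exact laws — the package
  does not phase genotypes, so empirical `ld_summary()` reports
  genotype-level covariances and $R^2$ only.
* The closed-form constructor covers two and three loci; larger
  systems use the Markov law or user-supplied frequency vectors
  (enumeration is limited to 12 loci, moments to 10).
* The experiment drivers test one pre-specified marker pair per
  replicate; genome-wide all-pairs scans and multiple-testing control
  are out of scope, as are mixed-model or score tests (classical OLS
  Wald tests with optional HC0 errors are provided).
* Identifying *which* untyped locus generates an observed interaction
  is not addressed; with the causal genotype unobserved, mutual
  three-locus LD cannot be assessed from marker data alone.
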