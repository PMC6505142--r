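Package: phantomepi
Title: Phantom Epistasis from Imperfect Linkage Disequilibrium
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analytical and Monte Carlo tools for studying how imperfect
    linkage disequilibrium (LD) between markers and an untyped causal
    locus generates spurious ("phantom") marker-by-marker interaction
    signals under a purely additive genetic architecture.  Provides exact
    multi-locus haplotype distributions parameterized by allele
    frequencies and two- and three-locus D coefficients, random-mating
    diploid genotype samplers (including a Markov-chain chromosome
    emulator with distance-decaying LD), quantitative-trait phenotype
    simulators (additive, dominance, multi-QTL, polygenic), an exact
    population-coefficient solver for the marker-interaction regression
    built from genotypic moments, Wald tests of the interaction term, and
    experiment drivers that estimate type-I-error inflation of epistasis
    tests as a function of LD, allele frequency, sample size and QTL
    variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
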