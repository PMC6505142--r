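#' Define a Monte Carlo scenario
#'
#' A scenario bundles everything needed to estimate the rejection rate
#' of the interaction Wald test under a known generating model: the
#' haplotype distribution, which locus is causal and which two are the
#' tested markers, the phenotype model and its parameters, the sample
#' size, the significance level, the replicate count and the master
#' seed.  [run_scenario()] is a pure function of this object.
#'
#' @param dist a [haplotype_distribution()] object.
#' @param model one of `"additive"`, `"dominance"`, `"multilocus"`,
#'   `"multilocus+infinitesimal"`.
#' @param n sample size per replicate.
#' @param qtl_index causal locus index (`qtl_indices` for multilocus
#'   models).
#' @param marker_indices indices of the two tested markers.
#' @param qtl_variance_fraction fraction of phenotypic variance
#'   explained by the QTL (additive) or total across QTL (multilocus,
#'   split according to `variance_fractions`).
#' @param variance_fractions per-QTL variance fractions for multilocus
#'   models; defaults to an equal split of `qtl_variance_fraction`.
#' @param a,d,error_variance dominance-model parameters.
#' @param polygenic_fraction variance share of the infinitesimal term
#'   (`"multilocus+infinitesimal"` only).
#' @param alpha significance level.
#' @param replicates Monte Carlo replicates (default 1000).
#' @param master_seed integer master seed; per-replicate seeds are drawn
#'   from it so replicates are independent yet reproducible.
#' @param id optional scenario label.
#' @return An object of class `scenario`.
#' @export
scenario <- function(dist, model = c("additive", "dominance", "multilocus",
                                     "multilocus+infinitesimal"),
                     n, qtl_index = 1, marker_indices = c(2, 3),
                     qtl_variance_fraction = 0.01,
                     variance_fractions = NULL,
                     a = 1, d = 0, error_variance = 1,
                     polygenic_fraction = 0,
                     alpha = 0.05, replicates = 1000, master_seed = 1,
                     id = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(dist, "haplo_dist"), n >= 10, replicates >= 1)
  idx <- c(qtl_index, marker_indices)
  if (any(idx < 1 | idx > dist$n_loci))
    stop("referenced loci do not exist in the distribution", call. = FALSE)
  if (model %in% c("multilocus", "multilocus+infinitesimal")) {
    if (is.null(variance_fractions))
      variance_fractions <- rep(qtl_variance_fraction / length(qtl_index),
                                length(qtl_index))
    if (length(variance_fractions) != length(qtl_index))
      stop("`variance_fractions` must match the number of QTL",
           call. = FALSE)
  }
  if (model != "multilocus+infinitesimal") polygenic_fraction <- 0
  if (is.null(id))
    id <- sprintf("%s_n%d_seed%d", model, n, master_seed)
  structure(list(id = id, dist = dist, model = model, n = as.integer(n),
                 qtl_index = qtl_index, marker_indices = marker_indices,
                 qtl_variance_fraction = qtl_variance_fraction,
                 variance_fractions = variance_fractions,
                 a = a, d = d, error_variance = error_variance,
                 polygenic_fraction = polygenic_fraction,
                 alpha = alpha, replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s model, n = %d, %d replicates, alpha = %g\n",
              x$id, x$model, x$n, x$replicates, x$alpha))
  invisible(x)
}

# Stream-splitting rule: the master seed seeds R's RNG once, and one
# sub-seed per replicate is drawn from it; each replicate then reseeds
# with its own sub-seed.  Experiments are therefore reproducible and
# order-independent across replicates.
replicate_seeds <- function(master_seed, k) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, k)
}

#' Run a Monte Carlo scenario
#'
#' For each replicate: draw `n` random-mating diploid genotypes from the
#' scenario's haplotype distribution, simulate the phenotype under the
#' generating model, fit the marker-interaction regression on the
#' sample-centered marker columns and run the two-sided Wald test of the
#' interaction at the scenario's `alpha`.  Replicates whose design is
#' degenerate (collinear marker columns) are excluded and counted.
#'
#' @param s a [scenario()].
#' @return A one-row data frame of class `rejection_table` with the
#'   empirical rejection rate, its binomial Monte Carlo standard error
#'   `sqrt(r (1 - r) / replicates)`, the mean marker R2 and mean MAF
#'   over replicates, and the excluded-replicate count.  The attribute
#'   `"detail"` holds the per-replicate records (rejection indicator,
#'   observed marker R2, mean marker MAF) used by [bin_results()].
#' @export
run_scenario <- function(s) {
  stopifnot(inherits(s, "scenario"))
  seeds <- replicate_seeds(s$master_seed, s$replicates)
  reject <- r2 <- maf <- rep(NA_real_, s$replicates)
  excluded <- 0L
  for (r in seq_len(s$replicates)) {
    set.seed(seeds[r])
    G <- sample_genotypes(s$dist, s$n)
    pbar <- colMeans(G) / 2
    Gc <- center_genotypes(G)
    x1 <- Gc[, s$marker_indices[1]]
    x2 <- Gc[, s$marker_indices[2]]
    y <- simulate_scenario_phenotype(s, Gc)
    fit <- tryCatch(fit_interaction_model(y, x1, x2), error = function(e) NULL)
    if (is.null(fit)) { excluded <- excluded + 1L; next }
    tst <- wald_interaction_test(fit, s$alpha)
    reject[r] <- as.numeric(tst$reject)
    r2[r] <- stats::cor(x1, x2)^2
    maf[r] <- mean(pmin(pbar[s$marker_indices],
                        1 - pbar[s$marker_indices]))
  }
  used <- !is.na(reject)
  rate <- mean(reject[used])
  out <- data.frame(
    scenario_id = s$id, model = s$model, n = s$n,
    qtl_variance_fraction = s$qtl_variance_fraction,
    alpha = s$alpha,
    rejection_rate = rate,
    mc_standard_error = sqrt(rate * (1 - rate) / sum(used)),
    mean_marker_r2 = mean(r2[used]),
    mean_maf = mean(maf[used]),
    replicates = sum(used), excluded = excluded,
    stringsAsFactors = FALSE)
  class(out) <- c("rejection_table", "data.frame")
  attr(out, "detail") <- data.frame(
    scenario_id = s$id, replicate = seq_len(s$replicates)[used],
    reject = reject[used], marker_r2 = r2[used], mean_maf = maf[used],
    stringsAsFactors = FALSE)
  out
}

simulate_scenario_phenotype <- function(s, Gc) {
  switch(s$model,
    additive = simulate_phenotype_additive(
      Gc[, s$qtl_index], s$qtl_variance_fraction),
    dominance = simulate_phenotype_dominance(
      Gc[, s$qtl_index], s$a, s$d, s$error_variance),
    simulate_phenotype_multilocus(
      Gc[, s$qtl_index, drop = FALSE], s$variance_fractions,
      polygenic_fraction = s$polygenic_fraction))
}

rbind_rejection_tables <- function(rows) {
  details <- lapply(rows, attr, "detail")
  out <- do.call(rbind, lapply(rows, function(r) { attr(r, "detail") <- NULL; r }))
  class(out) <- c("rejection_table", "data.frame")
  attr(out, "detail") <- do.call(rbind, details)
  out
}

#' Rejection-rate profile against marker distance
#'
#' Emulates the design where one marker sits just left of the causal
#' locus and the second marker is placed at increasing base-pair
#' distance to the right: for each lag, the three-locus law (x1, z, x2)
#' is the Markov chromosome distribution with adjacent correlations
#' `exp(-distance / decay_lambda)`, and the scenario is run on the full
#' grid of sample sizes and QTL variance fractions.
#'
#' @param lags base-pair distances between the causal locus and the
#'   distal marker.
#' @param n_grid sample sizes.
#' @param phi_grid QTL variance fractions.
#' @param proximal_lag base-pair distance between the proximal marker
#'   and the causal locus (default 1e4).
#' @param maf allele frequencies for (x1, z, x2) (scalar recycled).
#' @param decay_lambda LD decay length in bp (default 3e5).
#' @param alpha significance level.
#' @param replicates replicates per grid cell.
#' @param master_seed master seed; each grid cell gets an independent
#'   derived seed.
#' @return A `rejection_table` with one row per (lag, n, phi) and an
#'   extra `distance_bp` column.
#' @export
distance_profile_experiment <- function(lags, n_grid, phi_grid,
                                        proximal_lag = 1e4, maf = 0.3,
                                        decay_lambda = 3e5, alpha = 0.05,
                                        replicates = 1000, master_seed = 1) {
  grid <- expand.grid(lag = lags, n = n_grid, phi = phi_grid)
  cell_seeds <- replicate_seeds(master_seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    lag <- grid$lag[k]
    dist <- markov_haplotype_distribution(
      rep_len(maf, 3),
      rho = exp(-c(proximal_lag, lag) / decay_lambda),
      locus_labels = c("x1", "z", "x2"),
      positions = c(0, proximal_lag, proximal_lag + lag))
    s <- scenario(dist, "additive", n = grid$n[k], qtl_index = 2,
                  marker_indices = c(1, 3),
                  qtl_variance_fraction = grid$phi[k], alpha = alpha,
                  replicates = replicates, master_seed = cell_seeds[k],
                  id = sprintf("lag%g_n%d_phi%g", lag, grid$n[k],
                               grid$phi[k]))
    row <- run_scenario(s)
    row$distance_bp <- lag
    rows[[k]] <- row
  }
  rbind_rejection_tables(rows)
}

#' Bin per-replicate rejections by LD or MAF
#'
#' Pools the per-replicate records of one or more scenario runs and
#' recomputes rejection rates within bins of the observed marker R2
#' (`by = "marker_r2"`) or jointly by mean marker MAF and R2
#' (`by = "maf_x_r2"`).  Rates are weighted by replicate count; empty
#' bins are reported as missing, not zero.
#'
#' @param table a `rejection_table` (its `"detail"` attribute is used).
#' @param by `"marker_r2"` or `"maf_x_r2"`.
#' @param edges bin edges for R2 (default `seq(0, 1, 0.1)`).
#' @param maf_edges bin edges for mean MAF (default `seq(0, 0.5, 0.1)`).
#' @return A `rejection_table` with one row per (non-empty) bin.
#' @export
bin_results <- function(table, by = c("marker_r2", "maf_x_r2"),
                        edges = seq(0, 1, 0.1),
                        maf_edges = seq(0, 0.5, 0.1)) {
  by <- match.arg(by)
  det <- attr(table, "detail")
  if (is.null(det))
    stop("table carries no per-replicate detail", call. = FALSE)
  r2bin <- cut(det$marker_r2, edges, include.lowest = TRUE)
  groups <- if (by == "marker_r2") list(r2_bin = r2bin) else
    list(r2_bin = r2bin,
         maf_bin = cut(det$mean_maf, maf_edges, include.lowest = TRUE))
  agg <- stats::aggregate(det$reject, groups,
                          function(v) c(rate = mean(v), k = length(v)))
  out <- data.frame(agg[setdiff(names(agg), "x")],
                    rejection_rate = agg$x[, "rate"],
                    replicates = agg$x[, "k"])
  out$mc_standard_error <- sqrt(out$rejection_rate *
                                  (1 - out$rejection_rate) / out$replicates)
  class(out) <- c("rejection_table", "data.frame")
  out
}

#' Null calibration with an unlinked distal marker
#'
#' The distal marker is simulated independently of the causal locus and
#' proximal marker (the analogue of placing it on another chromosome),
#' so the population interaction coefficient is exactly zero and the
#' empirical rejection rate should match the significance level.
#'
#' @param n_grid sample sizes.
#' @param qtl_variance_fraction QTL variance fraction (default 0.01).
#' @param d_zx1 haploid D between the causal locus and proximal marker.
#' @param freqs allele frequencies of (z, x1, x2).
#' @param alpha significance level.
#' @param replicates replicates per sample size (default 2000).
#' @param master_seed master seed.
#' @return A `rejection_table` with one row per sample size.
#' @export
cross_chromosome_null_experiment <- function(n_grid = 10000,
                                             qtl_variance_fraction = 0.01,
                                             d_zx1 = 0.08,
                                             freqs = c(0.5, 0.5, 0.4),
                                             alpha = 0.05,
                                             replicates = 2000,
                                             master_seed = 1) {
  dist <- make_haplotype_distribution(
    freqs, pairwise_D = c(d_zx1, 0, 0), three_locus_D = 0,
    locus_labels = c("z", "x1", "x2"))
  cell_seeds <- replicate_seeds(master_seed, length(n_grid))
  rows <- vector("list", length(n_grid))
  for (k in seq_along(n_grid)) {
    s <- scenario(dist, "additive", n = n_grid[k], qtl_index = 1,
                  marker_indices = c(2, 3),
                  qtl_variance_fraction = qtl_variance_fraction,
                  alpha = alpha, replicates = replicates,
                  master_seed = cell_seeds[k],
                  id = sprintf("cross_chrom_n%d", n_grid[k]))
    rows[[k]] <- run_scenario(s)
  }
  rbind_rejection_tables(rows)
}

#' Single QTL with and without an infinitesimal background
#'
#' Runs the same mutually-LD scenario twice: once purely additive with
#' the main QTL explaining `phi_qtl` of the variance, and once with an
#' additional strictly additive infinitesimal component bringing the
#' heritability to `phi_qtl + polygenic_fraction` (defaults: 1% QTL,
#' 49% infinitesimal, heritability 0.5).  The infinitesimal term is
#' drawn independently of the three loci, emulating a polygenic
#' background spread over unlinked loci.
#'
#' @param dist three-locus haplotype distribution (default: a pinned
#'   mutually-dependent triple).
#' @param n sample size.
#' @param phi_qtl main-QTL variance fraction.
#' @param polygenic_fraction infinitesimal variance fraction.
#' @param alpha significance level.
#' @param replicates replicates per arm.
#' @param master_seed master seed.
#' @return A two-row `rejection_table` (one row per arm).
#' @export
infinitesimal_experiment <- function(dist = NULL, n = 10000,
                                     phi_qtl = 0.01,
                                     polygenic_fraction = 0.49,
                                     alpha = 0.05, replicates = 1000,
                                     master_seed = 1) {
  if (is.null(dist))
    dist <- make_haplotype_distribution(
      c(0.5, 0.4, 0.3), pairwise_D = c(0.05, 0.04, 0.03),
      three_locus_D = 0.01, locus_labels = c("z", "x1", "x2"))
  seeds <- replicate_seeds(master_seed, 2)
  s1 <- scenario(dist, "additive", n = n, qtl_index = 1,
                 marker_indices = c(2, 3), qtl_variance_fraction = phi_qtl,
                 alpha = alpha, replicates = replicates,
                 master_seed = seeds[1], id = "single_qtl")
  s2 <- scenario(dist, "multilocus+infinitesimal", n = n, qtl_index = 1,
                 marker_indices = c(2, 3), qtl_variance_fraction = phi_qtl,
                 polygenic_fraction = polygenic_fraction, alpha = alpha,
                 replicates = replicates, master_seed = seeds[2],
                 id = "qtl_plus_infinitesimal")
  rbind_rejection_tables(list(run_scenario(s1), run_scenario(s2)))
}

#' Three marker-QTL pairs along a chromosome
#'
#' Simulates three tightly linked marker-QTL pairs placed at the ends
#' and midpoint of a chromosome segment, with a strictly additive trait
#' whose genetic variance is split equally across the three QTL, and
#' tests the interaction between the first and third markers.  When the
#' blocks are in mutual LD the unaccounted middle QTL loads on the
#' interaction contrast of the flanking markers; when the span is much
#' larger than the LD decay length the blocks are independent and the
#' interaction test is calibrated.
#'
#' @param span_bp distance between the first and third pair (pair 2 is
#'   at the midpoint).
#' @param within_bp marker-to-QTL distance inside each pair.
#' @param maf common allele frequency of the six loci.
#' @param decay_lambda LD decay length in bp.
#' @param n sample size.
#' @param phi_total total genetic variance fraction (split equally).
#' @param alpha significance level.
#' @param replicates Monte Carlo replicates.
#' @param master_seed master seed.
#' @return A one-row `rejection_table` with an extra `beta12_analytic`
#'   column: the exact population interaction coefficient implied by the
#'   six-locus law (via [interaction_coefficient_multilocus()]).
#' @export
three_pair_experiment <- function(span_bp = 5e5, within_bp = 1e5,
                                  maf = 0.2, decay_lambda = 3e5,
                                  n = 50000, phi_total = 0.05,
                                  alpha = 0.05, replicates = 400,
                                  master_seed = 1) {
  pos <- c(0, within_bp,
           span_bp / 2, span_bp / 2 + within_bp,
           span_bp, span_bp + within_bp)
  labels <- c("x1", "z1", "x2", "z2", "x3", "z3")
  dist <- markov_haplotype_distribution(
    rep(maf, 6), rho = exp(-diff(pos) / decay_lambda),
    locus_labels = labels, positions = pos)

  qtl <- c(2, 4, 6); markers <- c(1, 5)
  phis <- rep(phi_total / 3, 3)
  mom <- lapply(qtl, function(q) exact_moments(dist, q, markers))
  effects <- vapply(seq_along(qtl), function(k)
    sqrt(phis[k] / mom[[k]]$var_z), 0)
  b12 <- interaction_coefficient_multilocus(mom, effects)

  s <- scenario(dist, "multilocus", n = n, qtl_index = qtl,
                marker_indices = markers, qtl_variance_fraction = phi_total,
                variance_fractions = phis, alpha = alpha,
                replicates = replicates, master_seed = master_seed,
                id = sprintf("three_pair_span%g", span_bp))
  row <- run_scenario(s)
  row$beta12_analytic <- b12
  row$span_bp <- span_bp
  row
}

#' Write a rejection table (and its manifest) to TSV
#'
#' @param table a `rejection_table`.
#' @param path output TSV path; a JSON manifest recording the package
#'   version and timestamp is written alongside as `<path>.manifest.json`.
#' @param master_seed optional seed to record in the manifest.
#' @return `path`, invisibly.
#' @export
write_rejection_table <- function(table, path, master_seed = NULL) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "phantomepi",
    version = as.character(utils::packageVersion("phantomepi")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    master_seed = master_seed,
    rows = nrow(table))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
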