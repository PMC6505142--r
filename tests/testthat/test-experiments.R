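test_that("experiments are pure functions of their scenario", {
  s <- scenario(dist_generic(), "additive", n = 1000, replicates = 30,
                master_seed = 77)
  t1 <- run_scenario(s)
  t2 <- run_scenario(s)
  expect_identical(t1, t2)
  expect_identical(attr(t1, "detail"), attr(t2, "detail"))
})

test_that("rejection tables carry coherent Monte Carlo summaries", {
  s <- scenario(dist_generic(), "additive", n = 2000, replicates = 50,
                master_seed = 5)
  tab <- run_scenario(s)
  expect_true(tab$rejection_rate >= 0 && tab$rejection_rate <= 1)
  expect_equal(tab$mc_standard_error,
               sqrt(tab$rejection_rate * (1 - tab$rejection_rate) /
                      tab$replicates))
  det <- attr(tab, "detail")
  expect_equal(nrow(det), tab$replicates)
  expect_equal(mean(det$reject), tab$rejection_rate)
})

test_that("a linkage-equilibrium scenario is calibrated", {
  s <- scenario(dist_le_qtl(), "additive", n = 2000, replicates = 400,
                master_seed = 19)
  tab <- run_scenario(s)
  expect_lt(abs(tab$rejection_rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("binning by marker R2 reduces to the pooled rate for one bin", {
  s <- scenario(dist_generic(), "additive", n = 1000, replicates = 40,
                master_seed = 3)
  tab <- run_scenario(s)
  binned <- bin_results(tab, "marker_r2", edges = c(0, 1))
  expect_equal(nrow(binned), 1)
  expect_equal(binned$rejection_rate, tab$rejection_rate)
  expect_equal(binned$replicates, tab$replicates)
  # empty bins are absent, not zero
  fine <- bin_results(tab, "marker_r2", edges = seq(0, 1, 0.1))
  expect_lt(nrow(fine), 10)
  expect_true(all(fine$replicates > 0))
  two_way <- bin_results(tab, "maf_x_r2", edges = c(0, 0.5, 1))
  expect_true("maf_bin" %in% names(two_way))
})

test_that("distance profile rows track the lag grid", {
  tab <- distance_profile_experiment(lags = c(5e4, 2e6),
                                     n_grid = 2000, phi_grid = 0.01,
                                     replicates = 40, master_seed = 9)
  expect_equal(nrow(tab), 2)
  expect_equal(sort(tab$distance_bp), c(5e4, 2e6))
  expect_true(all(tab$replicates == 40))
  # LD (hence observed marker R2) decays with the lag
  expect_gt(tab$mean_marker_r2[tab$distance_bp == 5e4],
            tab$mean_marker_r2[tab$distance_bp == 2e6])
})

test_that("cross-chromosome analogue transfers calibration across alpha", {
  tab <- cross_chromosome_null_experiment(n_grid = 2000, alpha = 0.01,
                                          replicates = 1000,
                                          master_seed = 13)
  expect_lt(abs(tab$rejection_rate - 0.01), 3 * sqrt(0.01 * 0.99 / 1000))
  tab2 <- cross_chromosome_null_experiment(n_grid = 2000, alpha = 0.01,
                                           replicates = 1000,
                                           master_seed = 13)
  expect_identical(tab, tab2)
})

test_that("infinitesimal experiment produces both arms", {
  tab <- infinitesimal_experiment(n = 2000, replicates = 30,
                                  master_seed = 21)
  expect_equal(nrow(tab), 2)
  expect_setequal(tab$model, c("additive", "multilocus+infinitesimal"))
})

test_that("three-pair geometry decouples at long range", {
  far <- three_pair_experiment(span_bp = 6e6, n = 2000, replicates = 20,
                               master_seed = 31)
  expect_lt(abs(far$beta12_analytic), 1e-6)
  near <- three_pair_experiment(span_bp = 5e5, n = 2000, replicates = 20,
                                master_seed = 31)
  expect_gt(abs(near$beta12_analytic), 1e-3)
})

test_that("rejection tables serialize with a manifest", {
  s <- scenario(dist_generic(), "additive", n = 1000, replicates = 20,
                master_seed = 2)
  tab <- run_scenario(s)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rejection_table(tab, path, master_seed = 2)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$rejection_rate, tab$rejection_rate)
  expect_true(file.exists(paste0(path, ".manifest.json")))
})
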