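test_that("the generator is deterministic in its seed", {
  cfg <- sim_config(n_snps_total = 100, n_instruments = 10, seed = 5)
  s1 <- simulate_two_sample_study(cfg)
  s2 <- simulate_two_sample_study(cfg)
  expect_identical(s1$exposure, s2$exposure)
  expect_identical(s1$outcome, s2$outcome)
  expect_identical(s1$ld, s2$ld)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_two_sample_study(sim_config(n_snps_total = 100,
    n_instruments = 10, seed = 6))
  expect_false(identical(s1$exposure$beta, s3$exposure$beta))
})

test_that("designed instruments are genome-wide significant with truthful bookkeeping", {
  study <- simulate_two_sample_study(sim_config(seed = 2,
    pleiotropy_frac = 0.2, pleiotropy_mean = 0.1, pleiotropy_sd = 0.02))
  tr <- study$truth
  expect_equal(length(tr$instruments), 30)
  expect_equal(length(tr$invalid_instruments), round(0.2 * 30))
  expect_true(all(tr$invalid_instruments %in% tr$instruments))
  # true effects exceed the significance threshold at their SE
  idx <- match(tr$instruments, study$exposure$snp)
  z_crit <- qnorm(1 - 5e-8 / 2)
  expect_true(all(abs(tr$gamma) > z_crit * study$exposure$se[idx]))
  # invalid instruments carry nonzero direct effects, valid ones zero
  expect_true(all(tr$alpha[tr$invalid_instruments] != 0))
  valid <- setdiff(tr$instruments, tr$invalid_instruments)
  expect_true(all(tr$alpha[valid] == 0))
})

test_that("LD matrix is block-diagonal, symmetric, unit-diagonal", {
  study <- simulate_two_sample_study(sim_config(n_snps_total = 50,
    n_instruments = 5, seed = 3))
  ld <- study$ld
  expect_true(isSymmetric(ld))
  expect_equal(unname(diag(ld)), rep(1, 50))
  expect_true(all(ld >= 0 & ld <= 1))
  # adjacent SNPs in a block correlated, across blocks zero
  expect_equal(unname(ld[1, 2]), 0.7)
  expect_equal(unname(ld[1, 6]), 0)
})

test_that("IVW on the generated truth recovers the causal effect", {
  study <- simulate_two_sample_study(sim_config(seed = 11))
  est <- mr_ivw(instrument_data(study))
  expect_lt(abs(est$beta - 0.72), 3 * est$se)
})

test_that("full heterogeneity is detectable under dispersed pleiotropy", {
  hits <- 0
  for (i in 1:20) {
    dat <- suppressWarnings(quick_instruments(J = 30, seed = 400 + i,
      pleiotropy_frac = 1, pleiotropy_mean = 0, pleiotropy_sd = 0.3))
    if (cochran_q(dat, "ivw")$pvalue < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 16)
})

test_that("outcome SEs scale as 1/sqrt(n)", {
  base <- sim_config(seed = 4)
  doubled <- sim_config(seed = 4, n_outcome = 2 * 214056,
    n_cases_outcome = 2 * 464)
  s1 <- simulate_two_sample_study(base)
  s2 <- simulate_two_sample_study(doubled)
  ratio <- median(s2$outcome$se) / median(s1$outcome$se)
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.05)
})

test_that("pleiotropy is independent of instrument strength unless asked otherwise", {
  dat <- simulate_two_sample_study(quick_config(J = 300, seed = 17,
    pleiotropy_frac = 0.5, pleiotropy_mean = 0.05, pleiotropy_sd = 0.05))
  tr <- dat$truth
  expect_lt(abs(tr$inside_cor), 0.2)

  viol <- simulate_two_sample_study(quick_config(J = 300, seed = 17,
    pleiotropy_frac = 1, pleiotropy_mean = 0.05, pleiotropy_sd = 0.05,
    inside_violation = TRUE))
  r <- cor(abs(viol$truth$gamma), viol$truth$alpha)
  expect_gt(abs(r), 0.8)
})

test_that("IVW confidence intervals are calibrated under the null", {
  cover <- 0
  n_rep <- 1500
  for (i in seq_len(n_rep)) {
    dat <- quick_instruments(J = 30, beta = 0, seed = 20000 + i)
    est <- mr_ivw(dat)
    lo <- est$beta - 1.96 * est$se
    hi <- est$beta + 1.96 * est$se
    if (lo <= 0 && 0 <= hi) cover <- cover + 1
  }
  expect_gte(cover / n_rep, 0.93)
  expect_lte(cover / n_rep, 0.97)
})

test_that("confounder tables cover the requested fraction with known phenotypes", {
  study <- simulate_two_sample_study(sim_config(n_snps_total = 100,
    n_instruments = 10, seed = 9))
  expect_equal(nrow(simulate_confounder_table(study, 0)), 0)
  conf <- simulate_confounder_table(study, 0.2, seed = 1)
  expect_equal(nrow(conf), 2)
  expect_true(all(conf$pvalue < 1e-5))
  expect_true(all(conf$phenotype %in% liver_confounders))
  expect_true(all(conf$snp %in% study$truth$instruments))
  # removable by the confounder filter
  inst <- study$exposure[study$exposure$snp %in% study$truth$instruments, ]
  suppressMessages(kept <- filter_confounders(inst, conf))
  expect_equal(nrow(kept), 8)
})

test_that("fixture bundles round-trip through the IO layer", {
  study <- simulate_two_sample_study(sim_config(n_snps_total = 60,
    n_instruments = 6, seed = 13))
  conf <- simulate_confounder_table(study, 0.5, seed = 2)
  dir <- tempfile()
  paths <- write_fixture_bundle(study, dir, conf)
  expect_equal(read_summary_stats(paths$exposure), study$exposure)
  expect_equal(read_summary_stats(paths$outcome), study$outcome)
  expect_equal(read_ld_matrix(paths$ld), round(study$ld, 6))
  expect_equal(read_confounder_table(paths$confounders)$snp, conf$snp)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_setequal(unlist(truth$instruments), study$truth$instruments)
  expect_equal(
    sort(as.character(unlist(truth$invalid_instruments))),
    sort(study$truth$invalid_instruments)
  )
  # bundle stays desk-sized at the default panel scale
  full <- write_fixture_bundle(
    simulate_two_sample_study(sim_config(seed = 1)), tempfile())
  expect_lt(sum(file.size(unlist(full))), 1e6)
})
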