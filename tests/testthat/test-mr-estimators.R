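test_that("Wald ratios implement the first-order delta method", {
  dat <- make_dat(bx = 0.1, by = 0.05, sx = 0.01, sy = 0.02)
  wr <- wald_ratio(dat)
  expect_equal(wr$beta, 0.5)
  expect_equal(wr$se, 0.2)
  expect_equal(wald_ratio(make_dat(0.1, 0, 0.01, 0.02))$beta, 0)
  expect_error(wald_ratio(make_dat(0, 0.05, 0.01, 0.02)), "zero exposure")
})

test_that("IVW reproduces the hand-worked two-SNP instance", {
  dat <- make_dat(bx = c(0.1, 0.2), by = c(0.1, 0.6), sy = c(0.1, 0.2))
  est <- mr_ivw(dat)
  het <- attr(est, "heterogeneity")
  expect_equal(est$beta, 2.0)
  expect_equal(attr(est, "se_fixed"), 1 / sqrt(2))
  expect_equal(het$Q, 2.0)
  expect_equal(het$df, 1)
  expect_equal(het$pvalue, pchisq(2, 1, lower.tail = FALSE))
  expect_equal(est$model, "fixed") # Q p ~ 0.157 > 0.05
  expect_equal(est$se, 1 / sqrt(2))
})

test_that("IVW handles homogeneous and single-SNP datasets", {
  dat <- make_dat(bx = c(0.1, 0.2), by = c(0.2, 0.4), sy = c(0.1, 0.1))
  est <- mr_ivw(dat)
  expect_equal(est$beta, 2.0)
  expect_equal(attr(est, "heterogeneity")$Q, 0)

  one <- make_dat(0.1, 0.05, 0.01, 0.02)
  est1 <- mr_ivw(one)
  expect_equal(est1$beta, 0.5)
  expect_equal(est1$se, 0.2)
  expect_true(is.na(attr(est1, "heterogeneity")$Q))
  expect_error(mr_ivw(make_dat(numeric(0), numeric(0))), "empty")
})

test_that("IVW matches weighted-least-squares and meta-analysis oracles", {
  skip_if_not_installed("metafor")
  set.seed(101)
  for (i in 1:50) {
    dat <- random_dat(sample(3:50, 1))
    est <- mr_ivw(dat)
    het <- attr(est, "heterogeneity")
    w <- 1 / dat$se_outcome^2
    fit <- lm(beta_outcome ~ 0 + beta_exposure, data = dat, weights = w)
    expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)

    wr <- wald_ratio(dat)
    meta <- metafor::rma(yi = wr$beta, sei = wr$se, method = "FE")
    expect_equal(est$beta, as.numeric(meta$beta), tolerance = 1e-10)
    expect_equal(attr(est, "se_fixed"), meta$se, tolerance = 1e-10)
    expect_equal(het$Q, meta$QE, tolerance = 1e-10)
  }
})

test_that("IVW and Q are invariant to joint re-orientation of a SNP", {
  set.seed(33)
  dat <- random_dat(12)
  base <- mr_ivw(dat)
  flipped <- dat
  flipped$beta_exposure[3] <- -flipped$beta_exposure[3]
  flipped$beta_outcome[3] <- -flipped$beta_outcome[3]
  alt <- mr_ivw(flipped)
  expect_equal(alt$beta, base$beta)
  expect_equal(attr(alt, "heterogeneity")$Q, attr(base, "heterogeneity")$Q)
  # Egger is invariant thanks to its gamma >= 0 orientation rule
  expect_equal(mr_egger(flipped)$slope$beta, mr_egger(dat)$slope$beta)
})

test_that("Egger recovers an exact linear fit with intercept", {
  dat <- make_dat(bx = c(0.1, 0.2, 0.3), by = c(0.25, 0.40, 0.55),
    sy = c(0.1, 0.15, 0.2))
  eg <- mr_egger(dat)
  expect_equal(eg$slope$beta, 1.5, tolerance = 1e-12)
  expect_equal(eg$intercept$estimate, 0.10, tolerance = 1e-12)
  expect_equal(eg$Q, 0, tolerance = 1e-20)

  null <- make_dat(bx = c(0.1, 0.2, 0.3), by = c(0, 0, 0))
  eg0 <- mr_egger(null)
  expect_equal(eg0$slope$beta, 0)
  expect_equal(eg0$intercept$estimate, 0)
  expect_error(mr_egger(make_dat(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("Egger matches a two-parameter WLS oracle on random instances", {
  set.seed(202)
  for (i in 1:50) {
    dat <- random_dat(sample(4:50, 1))
    dat$beta_exposure <- abs(dat$beta_exposure) # already oriented
    eg <- mr_egger(dat)
    w <- 1 / dat$se_outcome^2
    fit <- lm(beta_outcome ~ beta_exposure, data = dat, weights = w)
    expect_equal(eg$intercept$estimate, unname(coef(fit)[1]),
      tolerance = 1e-10)
    expect_equal(eg$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(eg$Q, sum(w * resid(fit)^2), tolerance = 1e-8)
    # SE equals the lm SE with dispersion replaced by max(1, dispersion)
    disp <- sqrt(eg$Q / eg$df)
    lm_se <- summary(fit)$coefficients[, 2]
    expect_equal(eg$slope$se, unname(lm_se[2]) * max(1, disp) / disp,
      tolerance = 1e-8)
  }
})

test_that("Egger recovers slope and directional pleiotropy in simulation", {
  set.seed(77)
  J <- 50
  bx <- abs(rnorm(J, 0.15, 0.05)) + 0.02
  alpha <- rnorm(J, 0.02, 0.01)
  sy <- rep(0.01, J)
  dat <- make_dat(bx, 0.7 * bx + alpha + rnorm(J, 0, sy),
    sx = rep(0.003, J), sy = sy)
  eg <- mr_egger(dat)
  expect_lt(abs(eg$slope$beta - 0.7), 3 * eg$slope$se)
  expect_lt(abs(eg$intercept$estimate - 0.02), 3 * eg$intercept$se)
})

test_that("weighted median interpolates the cumulative weight midpoints", {
  dat <- make_dat(bx = c(1, 1, 1), by = c(1, 2, 3), sy = c(1, 1, 1))
  est <- mr_weighted_median(dat, n_boot = 100, seed = 1)
  expect_equal(est$beta, 2.0)

  # weights (0.25, 0.25, 0.5): interpolate between s2 = 0.375 and s3 = 0.75
  dat2 <- make_dat(bx = c(1, 1, 1), by = c(1, 2, 3),
    sy = c(1, 1, 1 / sqrt(2)))
  est2 <- mr_weighted_median(dat2, n_boot = 100, seed = 1)
  expect_equal(est2$beta, 2 + (0.5 - 0.375) / (0.75 - 0.375), tolerance = 1e-12)

  # degenerate: all ratios equal
  datc <- make_dat(bx = c(0.1, 0.2, 0.4), by = c(0.07, 0.14, 0.28),
    sy = c(0.05, 0.05, 0.05))
  estc <- mr_weighted_median(datc, n_boot = 200, seed = 1)
  expect_equal(estc$beta, 0.7)
  expect_error(mr_weighted_median(make_dat(1, 1)), "at least 3")
})

test_that("weighted median with equal weights equals the sample median", {
  set.seed(9)
  for (J in c(3, 4, 7, 10)) {
    b <- rnorm(J)
    dat <- make_dat(bx = rep(1, J), by = b, sy = rep(1, J))
    est <- mr_weighted_median(dat, n_boot = 50, seed = 1)
    expect_equal(est$beta, median(b))
  }
})

test_that("mode estimators find the majority cluster", {
  dat <- make_dat(bx = rep(1, 4), by = c(1, 1, 1, 5), sy = rep(0.5, 4))
  est <- mr_mode(dat, weighted = FALSE, mode_settings(n_boot = 100), seed = 1)
  expect_lt(abs(est$beta - 1.0), 0.2)

  # all ratios identical: exact point mass
  datc <- make_dat(bx = c(1, 2, 4), by = c(0.7, 1.4, 2.8), sy = rep(0.1, 3))
  estc <- mr_mode(datc, weighted = TRUE, mode_settings(n_boot = 50), seed = 1)
  expect_equal(estc$beta, 0.7)

  # dominant cluster near 0.7 with outliers near 3
  set.seed(12)
  b <- c(rnorm(8, 0.7, 0.03), rnorm(2, 3, 0.03))
  datw <- make_dat(bx = rep(1, 10), by = b, sy = rep(0.3, 10))
  estw <- mr_mode(datw, weighted = TRUE, mode_settings(n_boot = 100), seed = 1)
  expect_lt(abs(estw$beta - 0.7), 0.15)
  expect_error(mr_mode(make_dat(1, 1)), "at least 3")
})

test_that("the method panel runs in reporting order with shared seeding", {
  dat <- quick_instruments(J = 12, seed = 3)
  panel <- mr_all_methods(dat, mode_settings(n_boot = 100), seed = 5)
  expect_equal(panel$method, c(
    "Inverse variance weighted", "Weighted median", "Weighted mode",
    "Simple mode", "MR Egger"
  ))
  expect_true(all(panel$n_snp == 12))
  # bit-identical on re-run with the same seed
  panel2 <- mr_all_methods(dat, mode_settings(n_boot = 100), seed = 5)
  expect_identical(panel, panel2)

  two <- make_dat(bx = c(0.1, 0.2), by = c(0.07, 0.14), sy = c(0.05, 0.05))
  suppressMessages(p2 <- mr_all_methods(two, seed = 1))
  expect_equal(p2$method, "Inverse variance weighted")
  expect_equal(length(attr(p2, "skipped")), 4)
})

test_that("odds-ratio bounds bracket the estimate whenever se > 0", {
  set.seed(4)
  for (i in 1:20) {
    o <- to_odds_ratio(rnorm(1), runif(1, 0.01, 1))
    expect_lt(o$ci_low, o$or)
    expect_gt(o$ci_high, o$or)
    expect_gt(o$ci_low, 0)
  }
  expect_equal(unlist(to_odds_ratio(0, 0)), c(or = 1, ci_low = 1, ci_high = 1))
})

test_that("weighted median resists pleiotropy that breaks IVW", {
  # 40% of weight on directionally pleiotropic instruments, precise outcome
  hits <- 0
  for (i in 1:20) {
    dat <- quick_instruments(J = 25, seed = 1000 + i,
      pleiotropy_frac = 0.4, pleiotropy_mean = 0.3, pleiotropy_sd = 0.02,
      n_cases_outcome = 20000)
    wm <- mr_weighted_median(dat, n_boot = 100, seed = i)
    ivw <- mr_ivw(dat)
    if (abs(wm$beta - 0.72) <= 3 * wm$se &&
      abs(ivw$beta - 0.72) > 3 * ivw$se) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 12) # median robust while IVW biased, most replicates
})
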