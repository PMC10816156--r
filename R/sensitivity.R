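# Sensitivity suite: Cochran's Q (IVW and Egger variants), MR-Egger
# intercept test, MR-PRESSO global/outlier/distortion tests, leave-one-out.

#' Cochran's Q heterogeneity test
#'
#' IVW variant: weighted residual sum about the origin-constrained IVW fit,
#' \eqn{Q = \sum \sigma_{\Gamma j}^{-2} (\Gamma_j - \hat\beta \gamma_j)^2},
#' df = J - 1. Egger variant: weighted residual sum about the two-parameter
#' Egger fit, df = J - 2. p-value from the upper chi-square tail.
#'
#' @param dat Harmonized dataset (J >= 2 for IVW, J >= 3 for Egger).
#' @param method `"ivw"` or `"egger"`.
#' @return One-row `data.frame` with `method, Q, df, pvalue`.
#' @export
cochran_q <- function(dat, method = c("ivw", "egger")) {
  method <- match.arg(method)
  check_harmonized(dat)
  J <- nrow(dat)
  if (method == "ivw") {
    if (J < 2L) stop("Cochran's Q (IVW) requires at least 2 SNPs")
    het <- attr(mr_ivw(dat), "heterogeneity")
    out <- data.frame(method = "IVW", Q = het$Q, df = het$df,
      pvalue = het$pvalue, stringsAsFactors = FALSE)
  } else {
    if (J < 3L) stop("Cochran's Q (Egger) requires at least 3 SNPs")
    eg <- mr_egger(dat)
    out <- data.frame(method = "MR Egger", Q = eg$Q, df = eg$df,
      pvalue = eg$Q_pvalue, stringsAsFactors = FALSE)
  }
  out
}

# Leave-one-out IVW slopes computed from running sums; x, y, w equal-length.
loo_ivw_slopes <- function(x, y, w) {
  num <- sum(w * x * y)
  den <- sum(w * x^2)
  (num - w * x * y) / (den - w * x^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' The observed residual sum of squares is
#' \eqn{RSS = \sum_j w_j (\Gamma_j - \hat\beta_{-j}\gamma_j)^2} with
#' \eqn{w_j = \sigma_{\Gamma j}^{-2}} and \eqn{\hat\beta_{-j}} the IVW slope
#' with SNP j left out. Its null distribution is simulated: in each of
#' `n_sim` replicates, effects are redrawn as
#' \eqn{\gamma^*_j \sim N(\gamma_j, \sigma_{\gamma j})} and
#' \eqn{\Gamma^*_j \sim N(\hat\beta_{-j}\gamma_j, \sigma_{\Gamma j})} and the
#' RSS recomputed (with leave-one-out slopes re-estimated on the simulated
#' effects). The global p-value uses the add-one rule
#' \eqn{(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)}, so it is bounded below by
#' \eqn{1/(n_{sim}+1)}. Per-SNP outlier p-values compare each SNP's observed
#' weighted residual with its simulated distribution (add-one rule), then are
#' Bonferroni-adjusted across J; SNPs below `signif_threshold` are flagged.
#' When outliers exist, the outlier-corrected IVW estimate is recomputed
#' without them and a distortion test compares the raw-vs-corrected slope
#' change against slope changes across random subsets of the same size.
#'
#' @param dat Harmonized dataset, J >= 4.
#' @param n_sim Number of Monte-Carlo replicates (>= 100, default 1000).
#' @param signif_threshold Flagging threshold on the Bonferroni-adjusted
#'   outlier p (default 0.05).
#' @param seed Optional RNG seed.
#' @param n_distortion Random subsets for the distortion test (default 1000).
#' @return A list of class `presso_result`: `rss_obs, global_p, n_sim,
#'   outlier_pvalues` (`data.frame` snp/pvalue/adj_pvalue), `outliers`,
#'   `beta_raw`, `beta_corrected`, `distortion_p` (NA when no outliers),
#'   `ivw_raw`, `ivw_corrected`.
#' @export
mr_presso <- function(dat, n_sim = 1000, signif_threshold = 0.05,
                      seed = NULL, n_distortion = 1000) {
  check_harmonized(dat)
  J <- nrow(dat)
  if (J < 4L) stop("MR-PRESSO requires at least 4 SNPs")
  if (n_sim < 100) stop("n_sim must be at least 100")

  x <- dat$beta_exposure
  y <- dat$beta_outcome
  w <- 1 / dat$se_outcome^2
  b_loo <- loo_ivw_slopes(x, y, w)
  res_obs <- w * (y - b_loo * x)^2
  rss_obs <- sum(res_obs)

  sims <- with_seed(seed, {
    # n_sim x J matrices of redrawn effects under the no-pleiotropy model
    xs <- matrix(stats::rnorm(n_sim * J, mean = rep(x, each = n_sim),
      sd = rep(dat$se_exposure, each = n_sim)), n_sim, J)
    ys <- matrix(stats::rnorm(n_sim * J, mean = rep(b_loo * x, each = n_sim),
      sd = rep(dat$se_outcome, each = n_sim)), n_sim, J)
    wm <- matrix(w, n_sim, J, byrow = TRUE)
    num <- rowSums(wm * xs * ys)
    den <- rowSums(wm * xs^2)
    b_loo_sim <- (num - wm * xs * ys) / (den - wm * xs^2)
    res_sim <- wm * (ys - b_loo_sim * xs)^2
    list(rss = rowSums(res_sim), res = res_sim)
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  p_out <- (1 + colSums(sims$res >= rep(res_obs, each = n_sim))) / (n_sim + 1)
  adj <- pmin(1, J * p_out)
  outliers <- dat$snp[adj < signif_threshold]

  ivw_raw <- mr_ivw(dat)
  beta_raw <- ivw_raw$beta
  ivw_corrected <- NULL
  beta_corrected <- NA_real_
  distortion_p <- NA_real_
  if (length(outliers)) {
    keep <- !(dat$snp %in% outliers)
    if (!any(keep)) stop("every SNP flagged as an outlier; correction degenerate")
    ivw_corrected <- mr_ivw(dat[keep, , drop = FALSE])
    beta_corrected <- ivw_corrected$beta
    n_keep <- sum(keep)
    d_obs <- beta_corrected - beta_raw
    d_sub <- with_seed(
      if (is.null(seed)) NULL else substream_seed(seed, "distortion"),
      vapply(seq_len(n_distortion), function(i) {
        idx <- sample.int(J, n_keep)
        sum(w[idx] * x[idx] * y[idx]) / sum(w[idx] * x[idx]^2) - beta_raw
      }, numeric(1))
    )
    distortion_p <- (1 + sum(abs(d_sub) >= abs(d_obs))) / (n_distortion + 1)
  }

  structure(
    list(
      rss_obs = rss_obs, global_p = global_p, n_sim = n_sim,
      outlier_pvalues = data.frame(snp = dat$snp, pvalue = p_out,
        adj_pvalue = adj, stringsAsFactors = FALSE),
      outliers = outliers,
      beta_raw = beta_raw, beta_corrected = beta_corrected,
      distortion_p = distortion_p,
      ivw_raw = ivw_raw, ivw_corrected = ivw_corrected
    ),
    class = "presso_result"
  )
}

#' Leave-one-out analysis
#'
#' Re-estimates the IVW causal effect J times, each time excluding one SNP,
#' to reveal single-variant dominance.
#'
#' @param dat Harmonized dataset, J >= 3.
#' @return `data.frame` with one row per excluded SNP: `snp, beta, se,
#'   pvalue` (IVW on the remaining J - 1 SNPs, fixed/random rule applied).
#' @export
leave_one_out <- function(dat) {
  check_harmonized(dat)
  J <- nrow(dat)
  if (J < 3L) stop("leave-one-out requires at least 3 SNPs")
  rows <- lapply(seq_len(J), function(j) {
    est <- mr_ivw(dat[-j, , drop = FALSE])
    data.frame(snp = dat$snp[j], beta = est$beta, se = est$se,
      pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Reports the Egger intercept (the average direct pleiotropic effect), its
#' SE and two-sided t-test p-value (J - 2 df); the verdict is
#' "no directional pleiotropy" when p >= 0.05.
#'
#' @param egger An `egger_result` from [mr_egger()], or a harmonized dataset
#'   (in which case the Egger fit is run first).
#' @return A list with `intercept, se, pvalue, df, verdict`.
#' @export
egger_intercept_test <- function(egger) {
  if (inherits(egger, "harmonized_data") || is.data.frame(egger)) {
    egger <- mr_egger(egger)
  }
  stopifnot(inherits(egger, "egger_result"))
  ic <- egger$intercept
  list(
    intercept = ic$estimate, se = ic$se, pvalue = ic$pvalue, df = ic$df,
    verdict = if (ic$pvalue >= 0.05) {
      "no directional pleiotropy"
    } else {
      "directional pleiotropy suspected"
    }
  )
}

#' Assemble the full sensitivity report
#'
#' Convenience wrapper running Cochran's Q (IVW and Egger), the Egger
#' intercept test, MR-PRESSO (when J >= 4) and leave-one-out (when J >= 3).
#'
#' @param dat Harmonized dataset.
#' @param n_sim MR-PRESSO replicates.
#' @param signif_threshold MR-PRESSO outlier threshold.
#' @param seed Optional seed (substreamed for PRESSO).
#' @return A list of class `sensitivity_report` with elements
#'   `heterogeneity` (two-row Q table when J >= 3), `egger_intercept`,
#'   `presso`, `leave_one_out`; unavailable components are `NULL` with the
#'   reason in `skipped`.
#' @export
sensitivity_report <- function(dat, n_sim = 1000, signif_threshold = 0.05,
                               seed = NULL) {
  check_harmonized(dat)
  J <- nrow(dat)
  skipped <- character()
  het <- NULL
  intercept <- NULL
  presso <- NULL
  loo <- NULL

  if (J >= 2L) {
    het <- cochran_q(dat, "ivw")
    if (J >= 3L) het <- rbind(het, cochran_q(dat, "egger"))
  } else {
    skipped <- c(skipped, heterogeneity = "requires at least 2 SNPs")
  }
  if (J >= 3L) {
    intercept <- egger_intercept_test(dat)
    loo <- leave_one_out(dat)
  } else {
    skipped <- c(skipped,
      egger_intercept = "requires at least 3 SNPs",
      leave_one_out = "requires at least 3 SNPs")
  }
  if (J >= 4L) {
    presso <- mr_presso(dat, n_sim = n_sim,
      signif_threshold = signif_threshold,
      seed = if (is.null(seed)) NULL else substream_seed(seed, "presso"))
  } else {
    skipped <- c(skipped, presso = "requires at least 4 SNPs")
  }

  structure(
    list(heterogeneity = het, egger_intercept = intercept, presso = presso,
      leave_one_out = loo, skipped = skipped),
    class = "sensitivity_report"
  )
}
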