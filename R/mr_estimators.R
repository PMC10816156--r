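# The five causal-effect estimators: IVW (fixed/random), MR-Egger,
# weighted median, weighted mode, simple mode.
#
# All estimators consume a harmonized dataset with per-SNP exposure effects
# gamma_j (beta_exposure, se_exposure) and outcome effects Gamma_j
# (beta_outcome, se_outcome), and work on the log-odds scale; odds ratios are
# attached only at reporting via to_odds_ratio().

#' Convert a log-odds estimate to an odds ratio with 95% CI
#'
#' @param beta Causal estimate(s) on the log-odds scale.
#' @param se Standard error(s), >= 0.
#' @return `data.frame` with `or`, `ci_low`, `ci_high` where
#'   `ci = exp(beta -/+ 1.96 se)`.
#' @export
to_odds_ratio <- function(beta, se) {
  if (any(se < 0)) stop("se must be non-negative")
  data.frame(
    or = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se)
  )
}

new_mr_estimate <- function(method, n_snp, beta, se, pvalue,
                            model = NA_character_) {
  ci <- to_odds_ratio(beta, se)
  data.frame(
    method = method, n_snp = n_snp, beta = beta, se = se, pvalue = pvalue,
    or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high, model = model,
    stringsAsFactors = FALSE
  )
}

#' Per-SNP Wald ratio estimates
#'
#' The single-SNP causal estimate beta_j = Gamma_j / gamma_j with first-order
#' (delta-method) standard error se_j = se(Gamma_j) / |gamma_j|.
#'
#' @param dat Harmonized dataset (see [harmonized_data()]).
#' @return `data.frame` with `snp, beta, se`.
#' @export
wald_ratio <- function(dat) {
  check_harmonized(dat)
  if (any(dat$beta_exposure == 0)) {
    stop("Wald ratio undefined for zero exposure effect (SNP(s): ",
      paste(dat$snp[dat$beta_exposure == 0], collapse = ", "), ")"
    )
  }
  data.frame(
    snp = dat$snp,
    beta = dat$beta_outcome / dat$beta_exposure,
    se = dat$se_outcome / abs(dat$beta_exposure),
    stringsAsFactors = FALSE
  )
}

#' Inverse-variance weighted estimator
#'
#' With weights \eqn{w_j = \sigma_{\Gamma j}^{-2}}, the IVW estimate is the
#' weighted regression of outcome on exposure effects through the origin,
#' \eqn{\hat\beta = \sum w_j \gamma_j \Gamma_j / \sum w_j \gamma_j^2}, with
#' fixed-effects SE \eqn{(\sum w_j \gamma_j^2)^{-1/2}}. Cochran's Q about the
#' fit (df = J - 1) drives the model choice: when the Q p-value is below 0.05
#' a multiplicative random-effects SE, the fixed SE scaled by
#' \eqn{\max(1, \sqrt{Q/(J-1)})}, is reported; otherwise fixed effects.
#' The p-value is two-sided normal. With a single SNP the estimate reduces to
#' its Wald ratio and Q is undefined.
#'
#' @param dat Harmonized dataset, J >= 1.
#' @return One-row estimate `data.frame` (`method, n_snp, beta, se, pvalue,
#'   or, ci_low, ci_high, model`) carrying a `"heterogeneity"` attribute
#'   (list `Q, df, pvalue`) and `"se_fixed"`.
#' @export
mr_ivw <- function(dat) {
  check_harmonized(dat)
  J <- nrow(dat)
  bx <- dat$beta_exposure
  by <- dat$beta_outcome
  w <- 1 / dat$se_outcome^2

  if (J == 1L) {
    wr <- wald_ratio(dat)
    est <- new_mr_estimate(
      "Inverse variance weighted", 1L, wr$beta, wr$se,
      2 * stats::pnorm(-abs(wr$beta / wr$se)), "wald"
    )
    attr(est, "heterogeneity") <- list(Q = NA_real_, df = NA_real_,
      pvalue = NA_real_)
    attr(est, "se_fixed") <- wr$se
    return(est)
  }

  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - beta * bx)^2)
  df <- J - 1L
  q_p <- stats::pchisq(Q, df, lower.tail = FALSE)
  model <- if (q_p < 0.05) "random" else "fixed"
  se <- if (model == "random") se_fixed * max(1, sqrt(Q / df)) else se_fixed
  est <- new_mr_estimate(
    "Inverse variance weighted", J, beta, se,
    2 * stats::pnorm(-abs(beta / se)), model
  )
  attr(est, "heterogeneity") <- list(Q = Q, df = df, pvalue = q_p)
  attr(est, "se_fixed") <- se_fixed
  est
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects with a free
#' intercept, weights \eqn{\sigma_{\Gamma j}^{-2}}. Each SNP is first
#' oriented so its exposure effect is non-negative (negating both effects
#' where needed), which makes the fit invariant to arbitrary allele coding.
#' The slope is the causal estimate; the intercept estimates the average
#' directional pleiotropic effect. Standard errors are scaled by
#' \eqn{\max(1, \sqrt{Q_E/(J-2)})} (multiplicative over-dispersion) and
#' p-values use a t-distribution with J - 2 df.
#'
#' @param dat Harmonized dataset, J >= 3.
#' @return A list of class `egger_result`: `slope` (one-row estimate
#'   `data.frame`, method "MR Egger"), `intercept` (list `estimate, se,
#'   pvalue, df`), and heterogeneity `Q, df, pvalue` about the two-parameter
#'   fit.
#' @export
mr_egger <- function(dat) {
  check_harmonized(dat)
  J <- nrow(dat)
  if (J < 3L) stop("MR-Egger requires at least 3 SNPs")
  flip <- dat$beta_exposure < 0
  x <- ifelse(flip, -dat$beta_exposure, dat$beta_exposure)
  y <- ifelse(flip, -dat$beta_outcome, dat$beta_outcome)
  w <- 1 / dat$se_outcome^2

  sw <- sum(w)
  swx <- sum(w * x)
  swy <- sum(w * y)
  swxx <- sum(w * x^2)
  swxy <- sum(w * x * y)
  denom <- sw * swxx - swx^2
  if (denom <= 0) stop("degenerate exposure effects: no spread after weighting")
  slope <- (sw * swxy - swx * swy) / denom
  intercept <- (swxx * swy - swx * swxy) / denom

  resid <- y - intercept - slope * x
  Q <- sum(w * resid^2)
  df <- J - 2L
  scale <- max(1, sqrt(Q / df))
  se_slope <- sqrt(sw / denom) * scale
  se_int <- sqrt(swxx / denom) * scale
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df)

  structure(
    list(
      slope = new_mr_estimate("MR Egger", J, slope, se_slope, p_slope),
      intercept = list(estimate = intercept, se = se_int, pvalue = p_int,
        df = df),
      Q = Q, df = df,
      Q_pvalue = stats::pchisq(Q, df, lower.tail = FALSE)
    ),
    class = "egger_result"
  )
}

# Weighted median of values b with positive weights w: sort, form cumulative
# weight midpoints s_j = cumsum(w')_j - w'_j/2, interpolate linearly at 0.5.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1L]) return(b[1L])
  n <- length(b)
  if (0.5 >= s[n]) return(b[n])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE shared by the median and mode estimators: resample
# effect estimates from their sampling distributions and recompute the point
# estimate (including ratio weights) each time.
bootstrap_se <- function(dat, point_fun, n_boot, seed) {
  with_seed(seed, {
    J <- nrow(dat)
    reps <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, dat$beta_exposure, dat$se_exposure)
      by <- stats::rnorm(J, dat$beta_outcome, dat$se_outcome)
      point_fun(by / bx, dat$se_outcome / abs(bx))
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted median estimator
#'
#' The weighted median of the per-SNP Wald ratios with weights proportional
#' to the inverse variance of each ratio; consistent when at least half the
#' total weight comes from valid instruments. The SE comes from a parametric
#' bootstrap (effects resampled from their reported sampling distributions);
#' the p-value is two-sided normal.
#'
#' @param dat Harmonized dataset, J >= 3.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional RNG seed for the bootstrap.
#' @return One-row estimate `data.frame`.
#' @export
mr_weighted_median <- function(dat, n_boot = 1000, seed = NULL) {
  check_harmonized(dat)
  if (nrow(dat) < 3L) stop("weighted median requires at least 3 SNPs")
  wr <- wald_ratio(dat)
  beta <- weighted_median_point(wr$beta, 1 / wr$se^2)
  se <- bootstrap_se(dat, function(b, s) weighted_median_point(b, 1 / s^2),
    n_boot, seed)
  new_mr_estimate(
    "Weighted median", nrow(dat), beta, se,
    2 * stats::pnorm(-abs(beta / se))
  )
}

#' Mode settings for the mode-based estimators
#'
#' @param phi Bandwidth multiplier (> 0, default 1).
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @return A list of class `mode_settings` (kernel is normal).
#' @export
mode_settings <- function(phi = 1, n_boot = 1000) {
  stopifnot(phi > 0, n_boot >= 1)
  structure(list(phi = phi, n_boot = n_boot, kernel = "normal"),
    class = "mode_settings")
}

# Kernel-smoothed mode of ratio estimates b with weights w. Bandwidth
# h = phi * 0.9 * min(sd, 1.4826 mad) * J^(-1/5) (the smaller of the two
# scale estimates, falling back to the other when one is zero); density is a
# weighted normal-kernel sum evaluated on a 512-point grid spanning
# [min(b) - h, max(b) + h], and the estimate is the grid argmax (first grid
# point on ties).
mode_point <- function(b, w, phi) {
  if (diff(range(b)) == 0) return(b[1L])
  scales <- c(stats::sd(b), stats::mad(b))
  scales <- scales[scales > 0]
  h <- phi * 0.9 * min(scales) * length(b)^(-1 / 5)
  grid <- seq(min(b) - h, max(b) + h, length.out = 512L)
  dens <- (stats::dnorm(outer(grid, b, "-") / h) / h) %*% (w / sum(w))
  grid[which.max(dens)]
}

#' Mode-based estimators (weighted and simple mode)
#'
#' The causal estimate is the mode of the kernel-smoothed distribution of
#' per-SNP Wald ratios: consistent when the largest group of instruments
#' sharing one causal effect is valid, even if they carry under half the
#' weight. The weighted mode weights each ratio by its inverse variance; the
#' simple mode weights all ratios equally. SE by the same parametric
#' bootstrap as [mr_weighted_median()]; two-sided normal p-value.
#'
#' @param dat Harmonized dataset, J >= 3.
#' @param weighted Use inverse-variance weights (`TRUE`, default) or equal
#'   weights.
#' @param settings A [mode_settings()] object.
#' @param seed Optional RNG seed for the bootstrap.
#' @return One-row estimate `data.frame` (method "Weighted mode" or
#'   "Simple mode").
#' @export
mr_mode <- function(dat, weighted = TRUE, settings = mode_settings(),
                    seed = NULL) {
  check_harmonized(dat)
  if (nrow(dat) < 3L) stop("mode estimators require at least 3 SNPs")
  wr <- wald_ratio(dat)
  weight_fun <- if (weighted) function(s) 1 / s^2 else function(s) rep(1, length(s))
  beta <- mode_point(wr$beta, weight_fun(wr$se), settings$phi)
  se <- bootstrap_se(dat, function(b, s) mode_point(b, weight_fun(s), settings$phi),
    settings$n_boot, seed)
  new_mr_estimate(
    if (weighted) "Weighted mode" else "Simple mode", nrow(dat), beta, se,
    2 * stats::pnorm(-abs(beta / se))
  )
}

#' Run the full estimator panel
#'
#' Runs the five methods in reporting order — inverse variance weighted,
#' weighted median, weighted mode, simple mode, MR Egger — sharing one seed
#' (split into named substreams) across the bootstrap-based methods. Methods
#' whose minimum instrument count exceeds J are skipped and listed, with the
#' reason, in the `"skipped"` attribute.
#'
#' @param dat Harmonized dataset.
#' @param settings A [mode_settings()] object (also supplies `n_boot` for the
#'   weighted median).
#' @param seed Optional integer seed governing all bootstrap draws.
#' @return Estimate `data.frame`, one row per method run; attributes
#'   `"heterogeneity"` (IVW Q) and `"egger"` (full `egger_result`) when
#'   available, `"skipped"` (named character vector of reasons).
#' @export
mr_all_methods <- function(dat, settings = mode_settings(), seed = NULL) {
  check_harmonized(dat)
  J <- nrow(dat)
  skipped <- character()
  rows <- list()

  ivw <- mr_ivw(dat)
  rows[["ivw"]] <- ivw

  sub <- function(name) if (is.null(seed)) NULL else substream_seed(seed, name)
  if (J >= 3L) {
    rows[["wmedian"]] <- mr_weighted_median(dat,
      n_boot = settings$n_boot, seed = sub("weighted_median"))
    rows[["wmode"]] <- mr_mode(dat, weighted = TRUE, settings = settings,
      seed = sub("weighted_mode"))
    rows[["smode"]] <- mr_mode(dat, weighted = FALSE, settings = settings,
      seed = sub("simple_mode"))
    egger <- mr_egger(dat)
    rows[["egger"]] <- egger$slope
  } else {
    skipped <- c(
      "Weighted median" = "requires at least 3 SNPs",
      "Weighted mode" = "requires at least 3 SNPs",
      "Simple mode" = "requires at least 3 SNPs",
      "MR Egger" = "requires at least 3 SNPs"
    )
    message("J = ", J, " < 3: only IVW run; ",
      "median/mode/Egger skipped")
    egger <- NULL
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "heterogeneity") <- attr(ivw, "heterogeneity")
  attr(out, "egger") <- egger
  attr(out, "skipped") <- skipped
  out
}
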