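# End-to-end orchestration: select -> harmonize -> estimate -> sensitivity
# -> report, plus plot-ready tables.

default_run_config <- function() {
  list(
    exposure = NULL, outcome = NULL, ld = NULL, confounders = NULL,
    exposure_label = "exposure", outcome_label = "outcome",
    p_threshold = 5e-8, clump_r2 = 0.01, clump_kb = 10000,
    f_min = 10, confounder_p = 1e-5,
    phi = 1, n_boot = 1000, presso_n_sim = 1000, presso_threshold = 0.05,
    seed = 1, out_dir = NULL
  )
}

normalize_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- default_run_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) {
    stop("unknown run-config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(config)] <- config
  for (f in c("exposure", "outcome", "ld")) {
    if (is.null(cfg[[f]])) stop("run config must name the ", f, " file")
  }
  for (f in c("exposure", "outcome", "ld")) {
    if (!file.exists(cfg[[f]])) stop(f, " file not found: ", cfg[[f]])
  }
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  keep <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(keep[order(names(keep))], tmp, auto_unbox = TRUE,
    digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full two-sample MR pipeline
#'
#' Stages, in order: read exposure/outcome summary statistics, LD matrix and
#' optional confounder table; select instruments (significance, clumping,
#' F-statistic, palindrome, confounder filters); harmonize against the
#' outcome; run the five-estimator panel; run the sensitivity suite; write
#' the report. Any stage error aborts the run with the stage named, and no
#' partial report is written. The run is a pure function of (input files,
#' config, seed): re-runs are byte-identical.
#'
#' @param config A named list or a YAML file path. Mandatory fields:
#'   `exposure`, `outcome`, `ld` (file paths). Optional: `confounders`
#'   (path), `exposure_label`, `outcome_label`, selection thresholds
#'   (`p_threshold`, `clump_r2`, `clump_kb`, `f_min`, `confounder_p`),
#'   estimator settings (`phi`, `n_boot`), PRESSO settings
#'   (`presso_n_sim`, `presso_threshold`), `seed`, and `out_dir` (when set,
#'   `report.json`, `estimates.tsv`, `instruments.tsv`, `sensitivity.tsv`
#'   and `plotdata/*.tsv` are written there).
#' @return The analysis report (list), invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  cfg <- normalize_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE)
    })
  }

  exposure <- stage("read_exposure", read_summary_stats(cfg$exposure))
  outcome <- stage("read_outcome", read_summary_stats(cfg$outcome))
  ld <- stage("read_ld", read_ld_matrix(cfg$ld))
  conf <- if (!is.null(cfg$confounders)) {
    stage("read_confounders", read_confounder_table(cfg$confounders))
  } else {
    NULL
  }

  params <- selection_params(cfg$p_threshold, cfg$clump_r2, cfg$clump_kb,
    cfg$f_min, cfg$confounder_p)
  sel <- stage("select_instruments",
    select_instruments(exposure, ld, conf, params))
  if (nrow(sel$instruments) == 0L) {
    counts <- paste(sprintf("%s=%d", sel$audit$stages$stage,
      sel$audit$stages$n), collapse = ", ")
    stop("no instruments survive selection (", counts, ")", call. = FALSE)
  }

  dat <- stage("harmonize", harmonize(sel$instruments, outcome))
  settings <- mode_settings(phi = cfg$phi, n_boot = cfg$n_boot)
  estimates <- stage("estimate",
    mr_all_methods(dat, settings, seed = substream_seed(cfg$seed, "estimators")))
  sens <- stage("sensitivity",
    sensitivity_report(dat, n_sim = cfg$presso_n_sim,
      signif_threshold = cfg$presso_threshold,
      seed = substream_seed(cfg$seed, "sensitivity")))

  strengths <- sel$strengths
  wr <- wald_ratio(dat)
  instruments <- cbind(
    dat[, c("snp", "beta_exposure", "se_exposure", "beta_outcome",
      "se_outcome", "sign_flipped", "strand_complemented")],
    f_stat = strengths$f_stat[match(dat$snp, strengths$snp)],
    ratio_beta = wr$beta, ratio_se = wr$se
  )

  report <- list(
    report_version = "1.0",
    exposure_label = cfg$exposure_label,
    outcome_label = cfg$outcome_label,
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("tsmr")),
    n_instruments = nrow(dat),
    selection_audit = sel$audit,
    harmonization_drops = attr(dat, "drops"),
    instruments = instruments,
    estimates = estimates,
    heterogeneity = sens$heterogeneity,
    egger_intercept = sens$egger_intercept,
    presso = if (is.null(sens$presso)) NULL else {
      p <- sens$presso
      list(rss_obs = p$rss_obs, global_p = p$global_p, n_sim = p$n_sim,
        outliers = p$outliers, n_outliers = length(p$outliers),
        beta_raw = p$beta_raw, beta_corrected = p$beta_corrected,
        distortion_p = p$distortion_p,
        outlier_pvalues = p$outlier_pvalues)
    },
    leave_one_out = sens$leave_one_out,
    skipped = as.list(sens$skipped)
  )
  validate_report(report)

  if (!is.null(cfg$out_dir)) {
    write_report(report, cfg$out_dir)
    return(invisible(report))
  }
  report
}

#' Validate an analysis report against the schema
#'
#' Checks the presence of required sections, cross-section instrument-count
#' consistency, and that every reported p-value lies in (0, 1].
#'
#' @param report A report list from [run_pipeline()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_report <- function(report) {
  required <- c("report_version", "exposure_label", "outcome_label", "seed",
    "config_hash", "n_instruments", "selection_audit", "instruments",
    "estimates")
  absent <- setdiff(required, names(report))
  if (length(absent)) {
    stop("report lacks section(s): ", paste(absent, collapse = ", "))
  }
  J <- report$n_instruments
  if (nrow(report$instruments) != J) stop("instrument table size mismatch")
  if (!all(report$estimates$n_snp == J)) stop("estimate n_snp mismatch")
  if (!is.null(report$leave_one_out) && nrow(report$leave_one_out) != J) {
    stop("leave-one-out table size mismatch")
  }
  ps <- c(report$estimates$pvalue, report$heterogeneity$pvalue,
    report$egger_intercept$pvalue, report$presso$global_p,
    report$leave_one_out$pvalue)
  ps <- ps[!is.na(ps)]
  if (any(ps <= 0 | ps > 1)) stop("p-value outside (0, 1] in report")
  invisible(TRUE)
}

#' Plot-ready tables from an analysis report
#'
#' @param report A report from [run_pipeline()].
#' @return A list of data frames: `scatter` (per-SNP effect sizes and SEs on
#'   both traits), `fit_lines` (per-method slope and intercept for the
#'   scatter plot), `forest_snp` (per-SNP Wald ratios with 95% CIs followed
#'   by the pooled estimates), `leave_one_out`, and `forest_methods` (one
#'   pooled row per method).
#' @export
make_plot_data <- function(report) {
  inst <- report$instruments
  est <- report$estimates
  scatter <- data.frame(
    snp = inst$snp,
    beta_exposure = inst$beta_exposure, se_exposure = inst$se_exposure,
    beta_outcome = inst$beta_outcome, se_outcome = inst$se_outcome,
    stringsAsFactors = FALSE
  )
  intercepts <- ifelse(est$method == "MR Egger",
    report$egger_intercept$intercept %||% 0, 0)
  fit_lines <- data.frame(method = est$method, slope = est$beta,
    intercept = intercepts, stringsAsFactors = FALSE)
  forest_snp <- rbind(
    data.frame(label = inst$snp, beta = inst$ratio_beta,
      ci_low = inst$ratio_beta - 1.96 * inst$ratio_se,
      ci_high = inst$ratio_beta + 1.96 * inst$ratio_se,
      kind = "snp", stringsAsFactors = FALSE),
    data.frame(label = paste("All SNPs -", est$method), beta = est$beta,
      ci_low = est$beta - 1.96 * est$se, ci_high = est$beta + 1.96 * est$se,
      kind = "pooled", stringsAsFactors = FALSE)
  )
  forest_methods <- est[, c("method", "n_snp", "beta", "se", "pvalue",
    "or", "ci_low", "ci_high")]
  list(
    scatter = scatter, fit_lines = fit_lines, forest_snp = forest_snp,
    leave_one_out = report$leave_one_out, forest_methods = forest_methods
  )
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write report files
#'
#' Writes `report.json`, `estimates.tsv`, `instruments.tsv`,
#' `sensitivity.tsv` and `plotdata/*.tsv` under `dir`.
#'
#' @param report A report from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(file.path(dir, "plotdata"), recursive = TRUE,
    showWarnings = FALSE)
  paths <- list(report = file.path(dir, "report.json"))
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null", null = "null")
  write_tsv(report$estimates, file.path(dir, "estimates.tsv"))
  write_tsv(report$instruments, file.path(dir, "instruments.tsv"))
  sens <- report$heterogeneity
  if (!is.null(sens)) {
    sens_tab <- data.frame(
      statistic = paste("Cochran Q", sens$method),
      value = sens$Q, df = sens$df, pvalue = sens$pvalue,
      stringsAsFactors = FALSE
    )
    if (!is.null(report$egger_intercept)) {
      sens_tab <- rbind(sens_tab, data.frame(
        statistic = "Egger intercept",
        value = report$egger_intercept$intercept,
        df = report$egger_intercept$df,
        pvalue = report$egger_intercept$pvalue, stringsAsFactors = FALSE))
    }
    if (!is.null(report$presso)) {
      sens_tab <- rbind(sens_tab, data.frame(
        statistic = "MR-PRESSO global RSS",
        value = report$presso$rss_obs, df = NA_real_,
        pvalue = report$presso$global_p, stringsAsFactors = FALSE))
    }
    write_tsv(sens_tab, file.path(dir, "sensitivity.tsv"))
  }
  pd <- make_plot_data(report)
  for (nm in names(pd)) {
    if (!is.null(pd[[nm]])) {
      write_tsv(pd[[nm]], file.path(dir, "plotdata", paste0(nm, ".tsv")))
    }
  }
  invisible(paths)
}
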