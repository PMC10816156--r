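# Synthetic two-sample GWAS summary statistics with known causal truth.
#
# The generator emulates the structure the analysis assumes: a panel of SNPs
# in LD blocks, a subset of genome-wide significant instruments for the
# exposure, binary-trait standard errors driven by sample size and case
# fraction, optional horizontal pleiotropy (balanced or directional),
# palindromic allele pairs, and an outcome dataset whose allele coding is
# partially scrambled so harmonization has real work to do.

#' Confounder phenotypes for the hepatic-failure analysis
#'
#' Liver-disease risk factors used as the vocabulary for synthetic
#' confounder-association tables: viral hepatitides, alcohol consumption,
#' metabolic disease, autoimmune and cholestatic liver disease, Wilson's
#' disease, rheumatoid arthritis and cholesterol traits.
#'
#' @export
liver_confounders <- c(
  "Hepatitis A", "Hepatitis B", "Hepatitis C", "Hepatitis D", "Hepatitis E",
  "Alcohol consumption", "Diabetes", "Obesity", "Autoimmune hepatitis",
  "Primary biliary cholangitis", "Primary sclerosing cholangitis",
  "Wilson's disease", "Rheumatoid arthritis", "Hypercholesterolemia",
  "Cholesterol-lowering medication"
)

#' Simulation configuration
#'
#' Defaults emulate the unstable-angina exposure GWAS (9481 cases,
#' 446,987 controls, n = 456,468) and the hepatic-failure outcome GWAS
#' (464 cases, 213,592 controls, n = 214,056) at desk scale: 500 panel SNPs
#' rather than millions, 30 true instruments, and a true causal effect of
#' 0.72 on the log-odds scale (odds ratio about 2.05).
#'
#' @param n_snps_total Panel size (default 500).
#' @param n_instruments Number of true instruments J (default 30); must not
#'   exceed the number of LD blocks.
#' @param beta_causal True causal effect on the log-odds scale (default 0.72).
#' @param tau SD of true instrument effects on the exposure (default 0.1,
#'   matching the 0.05-0.22 per-allele log-odds scale of genome-wide
#'   significant angina loci).
#' @param pleiotropy_frac Fraction of instruments with a direct (pleiotropic)
#'   outcome effect (default 0).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the pleiotropic
#'   effects alpha_j (directional when the mean is nonzero).
#' @param n_exposure,n_cases_exposure Exposure GWAS total and case counts.
#' @param n_outcome,n_cases_outcome Outcome GWAS total and case counts.
#' @param maf_range Minor-allele-frequency range (default 0.05-0.5).
#' @param ld_block_size SNPs per LD block (default 5).
#' @param ld_decay Within-block r^2 between adjacent SNPs decays as
#'   `ld_decay^|i-j|` (default 0.7); r^2 = 0 across blocks.
#' @param palindromic_frac Fraction of SNPs assigned palindromic (A/T or
#'   C/G) allele pairs (default 0.1).
#' @param p_threshold Significance level the designed instruments are
#'   guaranteed to reach (default 5e-8).
#' @param inside_violation If `TRUE`, pleiotropic effects are made
#'   proportional to instrument strength, violating the InSIDE assumption
#'   (for negative tests of MR-Egger).
#' @param seed Global seed; all draws run on named substreams derived from
#'   it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_snps_total = 500, n_instruments = 30,
                       beta_causal = 0.72, tau = 0.1,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0,
                       n_exposure = 456468, n_cases_exposure = 9481,
                       n_outcome = 214056, n_cases_outcome = 464,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 5, ld_decay = 0.7,
                       palindromic_frac = 0.1, p_threshold = 5e-8,
                       inside_violation = FALSE, seed = 1) {
  cfg <- list(
    n_snps_total = n_snps_total, n_instruments = n_instruments,
    beta_causal = beta_causal, tau = tau,
    pleiotropy_frac = pleiotropy_frac, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd,
    n_exposure = n_exposure, n_cases_exposure = n_cases_exposure,
    n_outcome = n_outcome, n_cases_outcome = n_cases_outcome,
    maf_range = maf_range, ld_block_size = ld_block_size,
    ld_decay = ld_decay, palindromic_frac = palindromic_frac,
    p_threshold = p_threshold, inside_violation = inside_violation,
    seed = seed
  )
  stopifnot(
    n_snps_total >= 1, n_instruments >= 1, n_instruments <= n_snps_total,
    tau > 0, pleiotropy_frac >= 0, pleiotropy_frac <= 1,
    pleiotropy_sd >= 0,
    n_exposure > 0, n_outcome > 0,
    n_cases_exposure > 0, n_cases_exposure < n_exposure,
    n_cases_outcome > 0, n_cases_outcome < n_outcome,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2],
    ld_block_size >= 1, ld_decay >= 0, ld_decay < 1,
    palindromic_frac >= 0, palindromic_frac <= 1,
    p_threshold > 0, p_threshold < 1
  )
  n_blocks <- ceiling(n_snps_total / ld_block_size)
  if (n_instruments > n_blocks) {
    stop("n_instruments exceeds the number of LD blocks (",
      n_blocks, "); enlarge the panel or shrink the blocks")
  }
  structure(cfg, class = "sim_config")
}

# Per-SNP SE of a log-odds GWAS effect under the case-fraction approximation
# sigma^2 = 1 / (n * v * 2 maf (1 - maf)), v = cf (1 - cf).
binary_trait_se <- function(n, n_cases, maf) {
  cf <- n_cases / n
  sqrt(1 / (n * cf * (1 - cf) * 2 * maf * (1 - maf)))
}

.nonpalindromic_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)
.palindromic_pairs <- rbind(
  c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C")
)

#' Simulate a paired exposure/outcome GWAS summary-statistics study
#'
#' Instruments receive true exposure effects gamma_j drawn from
#' N(0, tau^2) conditioned to exceed genome-wide significance (exact
#' truncated-normal sampling, equivalent to rejection sampling); a
#' `pleiotropy_frac` fraction receive a direct outcome effect
#' alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2), independent of gamma_j
#' (InSIDE) unless `inside_violation` is set. True outcome effects are
#' Gamma_j = beta_causal * gamma_j + alpha_j; non-instrument SNPs are null
#' on both traits. Observed effects add sampling noise with binary-trait
#' SEs set by sample size, case fraction and MAF. The outcome dataset
#' reuses the panel with a randomly swapped effect/other allele coding for
#' ~30% of SNPs and a strand-complemented representation for ~10% of
#' non-palindromic SNPs, so harmonization is exercised. The LD matrix is
#' block-diagonal with `ld_decay^distance` within blocks.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `synthetic_study`: `exposure` and `outcome`
#'   summary-statistic data frames, `ld` matrix, `truth` record (true
#'   effects, instrument and invalid-instrument ids, InSIDE correlation),
#'   `aligned` (observed instrument effects on the exposure allele frame,
#'   as a `harmonized_data` object; see [instrument_data()]), and the
#'   `config`.
#' @export
simulate_two_sample_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_snps_total
  J <- cfg$n_instruments

  # --- panel structure -----------------------------------------------------
  structure_seed <- substream_seed(cfg$seed, "structure")
  block <- rep(seq_len(ceiling(n / cfg$ld_block_size)),
    each = cfg$ld_block_size)[seq_len(n)]
  chr <- as.character((block - 1L) %% 22L + 1L)
  block_on_chr <- stats::ave(block, chr, FUN = function(b) match(b, unique(b)))
  within <- stats::ave(seq_len(n), block, FUN = seq_along)
  pos <- block_on_chr * 2e7 + (within - 1L) * 1e4
  snp <- sprintf("rs%07d", seq_len(n) + 1000000L)

  panel <- with_seed(structure_seed, {
    maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
    pal <- stats::runif(n) < cfg$palindromic_frac
    pair_idx_np <- sample.int(nrow(.nonpalindromic_pairs), n, replace = TRUE)
    pair_idx_p <- sample.int(nrow(.palindromic_pairs), n, replace = TRUE)
    ea <- ifelse(pal, .palindromic_pairs[pair_idx_p, 1],
      .nonpalindromic_pairs[pair_idx_np, 1])
    oa <- ifelse(pal, .palindromic_pairs[pair_idx_p, 2],
      .nonpalindromic_pairs[pair_idx_np, 2])
    list(maf = maf, ea = ea, oa = oa)
  })

  se_exp <- binary_trait_se(cfg$n_exposure, cfg$n_cases_exposure, panel$maf)
  se_out <- binary_trait_se(cfg$n_outcome, cfg$n_cases_outcome, panel$maf)

  # --- true effects --------------------------------------------------------
  inst_idx <- match(unique(block), block)[seq_len(J)] # first SNP of first J blocks
  gamma <- numeric(n)
  alpha <- numeric(n)
  effects_seed <- substream_seed(cfg$seed, "effects")
  truth_draw <- with_seed(effects_seed, {
    # |gamma| > z_crit * se guarantees genome-wide significance of the true
    # effect; sampled by inverse CDF of the truncated normal.
    z_crit <- stats::qnorm(1 - cfg$p_threshold / 2)
    thr <- z_crit * se_exp[inst_idx]
    lo <- stats::pnorm(thr / cfg$tau)
    if (any(lo >= 1)) {
      stop("tau too small: instruments cannot reach significance at this SE")
    }
    mag <- cfg$tau * stats::qnorm(stats::runif(J, lo, 1))
    sgn <- sample(c(-1, 1), J, replace = TRUE)
    g <- sgn * mag

    n_invalid <- round(cfg$pleiotropy_frac * J)
    invalid <- sort(sample.int(J, n_invalid))
    a <- numeric(J)
    if (n_invalid > 0) {
      if (cfg$inside_violation) {
        # direct effects proportional to instrument strength: InSIDE broken
        gs <- abs(g[invalid])
        a[invalid] <- cfg$pleiotropy_mean +
          cfg$pleiotropy_sd * (gs - mean(gs)) / max(stats::sd(gs), 1e-12)
      } else {
        a[invalid] <- stats::rnorm(n_invalid, cfg$pleiotropy_mean,
          cfg$pleiotropy_sd)
      }
    }
    list(gamma = g, alpha = a, invalid = invalid)
  })
  gamma[inst_idx] <- truth_draw$gamma
  # alpha is defined on the exposure-increasing allele orientation, so a
  # nonzero pleiotropy_mean shifts every invalid SNP's ratio the same way
  # (directional pleiotropy) regardless of the panel's allele coding.
  alpha[inst_idx] <- sign(truth_draw$gamma) * truth_draw$alpha
  Gamma <- cfg$beta_causal * gamma + alpha

  inside_cor <- NA_real_
  if (length(truth_draw$invalid) > 0 && stats::sd(truth_draw$alpha) > 0 &&
    !cfg$inside_violation) {
    inside_cor <- stats::cor(abs(truth_draw$gamma), truth_draw$alpha)
    if (J >= 30 && abs(inside_cor) >= 0.2) {
      warning("sample correlation between instrument strength and ",
        "pleiotropy is ", signif(inside_cor, 3),
        "; InSIDE holds only by design, not in this draw")
    }
  }

  # --- observed effects ----------------------------------------------------
  noise_seed <- substream_seed(cfg$seed, "noise")
  obs <- with_seed(noise_seed, {
    list(
      bx = stats::rnorm(n, gamma, se_exp),
      by = stats::rnorm(n, Gamma, se_out)
    )
  })
  p_exp <- 2 * stats::pnorm(-abs(obs$bx / se_exp))
  p_out <- 2 * stats::pnorm(-abs(obs$by / se_out))

  exposure <- data.frame(
    snp = snp, chr = chr, pos = pos,
    effect_allele = panel$ea, other_allele = panel$oa,
    eaf = panel$maf, beta = obs$bx, se = se_exp, pvalue = p_exp,
    n = cfg$n_exposure, n_cases = cfg$n_cases_exposure,
    stringsAsFactors = FALSE
  )

  # outcome allele coding scrambled to exercise harmonization
  coding_seed <- substream_seed(cfg$seed, "coding")
  coding <- with_seed(coding_seed, {
    swap <- stats::runif(n) < 0.3
    flip_strand <- stats::runif(n) < 0.1 &
      !is_palindromic(panel$ea, panel$oa)
    list(swap = swap, flip_strand = flip_strand)
  })
  ea_o <- ifelse(coding$swap, panel$oa, panel$ea)
  oa_o <- ifelse(coding$swap, panel$ea, panel$oa)
  cc <- complement_alleles(ea_o, oa_o)
  ea_o <- ifelse(coding$flip_strand, cc$effect_allele, ea_o)
  oa_o <- ifelse(coding$flip_strand, cc$other_allele, oa_o)
  outcome <- data.frame(
    snp = snp, chr = chr, pos = pos,
    effect_allele = ea_o, other_allele = oa_o,
    eaf = ifelse(coding$swap, 1 - panel$maf, panel$maf),
    beta = ifelse(coding$swap, -obs$by, obs$by),
    se = se_out, pvalue = p_out,
    n = cfg$n_outcome, n_cases = cfg$n_cases_outcome,
    stringsAsFactors = FALSE
  )

  # --- LD matrix -----------------------------------------------------------
  ld <- matrix(0, n, n, dimnames = list(snp, snp))
  for (b in unique(block)) {
    idx <- which(block == b)
    if (length(idx) > 1L) {
      d <- abs(outer(seq_along(idx), seq_along(idx), "-"))
      ld[idx, idx] <- cfg$ld_decay^d
    }
  }
  diag(ld) <- 1

  aligned <- harmonized_data(
    snp = snp[inst_idx],
    beta_exposure = obs$bx[inst_idx], se_exposure = se_exp[inst_idx],
    beta_outcome = obs$by[inst_idx], se_outcome = se_out[inst_idx]
  )

  truth <- list(
    beta_causal = cfg$beta_causal,
    instruments = snp[inst_idx],
    invalid_instruments = snp[inst_idx][truth_draw$invalid],
    gamma = stats::setNames(truth_draw$gamma, snp[inst_idx]),
    alpha = stats::setNames(truth_draw$alpha, snp[inst_idx]),
    inside_cor = inside_cor
  )

  structure(
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth,
      aligned = aligned, config = cfg),
    class = "synthetic_study"
  )
}

#' Observed instrument effects on the exposure allele frame
#'
#' Returns the designed instruments' observed effects as a ready-to-estimate
#' `harmonized_data` object, bypassing selection and harmonization. Useful
#' for validating the estimators against the generator's truth without
#' conflating them with instrument-selection behaviour.
#'
#' @param study A `synthetic_study`.
#' @return A `harmonized_data` data frame with one row per designed
#'   instrument.
#' @export
instrument_data <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  study$aligned
}

#' Simulate a confounder-association table
#'
#' Assigns strong confounder associations (p < 1e-5) to a chosen fraction of
#' the study's instruments, with phenotype labels drawn from
#' [liver_confounders].
#'
#' @param study A `synthetic_study`.
#' @param frac_confounded Fraction of instruments to confound (default 0).
#' @param seed Optional seed (defaults to a substream of the study seed).
#' @return `data.frame` with `snp, phenotype, pvalue` (zero rows when the
#'   fraction is 0).
#' @export
simulate_confounder_table <- function(study, frac_confounded = 0,
                                      seed = NULL) {
  stopifnot(inherits(study, "synthetic_study"),
    frac_confounded >= 0, frac_confounded <= 1)
  inst <- study$truth$instruments
  n_conf <- round(frac_confounded * length(inst))
  if (n_conf == 0L) {
    return(data.frame(snp = character(), phenotype = character(),
      pvalue = numeric(), stringsAsFactors = FALSE))
  }
  seed <- seed %||% substream_seed(study$config$seed, "confounders")
  with_seed(seed, {
    chosen <- sort(sample(inst, n_conf))
    data.frame(
      snp = chosen,
      phenotype = sample(liver_confounders, n_conf, replace = TRUE),
      pvalue = 10^(-stats::runif(n_conf, 5.5, 12)),
      stringsAsFactors = FALSE
    )
  })
}

#' Write a synthetic study as a fixture bundle
#'
#' Emits `exposure.tsv`, `outcome.tsv`, `ld.tsv`, `confounders.tsv` and
#' `truth.json` in the formats the IO and selection modules consume.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @param confounders Optional confounder table (default: empty table).
#' @return Named list of file paths, invisibly.
#' @export
write_fixture_bundle <- function(study, dir, confounders = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    exposure = file.path(dir, "exposure.tsv"),
    outcome = file.path(dir, "outcome.tsv"),
    ld = file.path(dir, "ld.tsv"),
    confounders = file.path(dir, "confounders.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_summary_stats(study$exposure, paths$exposure)
  write_summary_stats(study$outcome, paths$outcome)
  write_ld_matrix(round(study$ld, 6), paths$ld)
  conf <- confounders %||% data.frame(snp = character(),
    phenotype = character(), pvalue = numeric(), stringsAsFactors = FALSE)
  utils::write.table(conf, paths$confounders, sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- study$truth
  truth$schema_version <- "1.0"
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(paths)
}
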