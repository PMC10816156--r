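# Reading, writing and harmonizing GWAS summary statistics.

.default_columns <- c(
  snp = "SNP", chr = "CHR", pos = "POS",
  effect_allele = "EA", other_allele = "OA", eaf = "EAF",
  beta = "BETA", se = "SE", pvalue = "P", n = "N", n_cases = "NCASE"
)

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.check_alleles <- function(...) {
  alleles <- toupper(unlist(list(...)))
  bad <- setdiff(unique(alleles), names(.complement))
  if (length(bad)) {
    stop("allele(s) outside the A/C/G/T alphabet: ", paste(bad, collapse = ", "))
  }
  invisible(alleles)
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads one association record per row. By default columns are tab-delimited
#' with header names `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N` (plus an
#' optional `NCASE`); `column_map` renames any of them, e.g.
#' `list(pvalue = "p_value")`. `EAF` (effect-allele frequency) and `NCASE`
#' are optional and propagated as `NA` when absent. Rows with a missing or
#' non-positive standard error are rejected and their count reported via
#' `message()`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named list/vector overriding default column
#'   names. Names must be among `snp, chr, pos, effect_allele, other_allele,
#'   eaf, beta, se, pvalue, n, n_cases`.
#' @param delim Field delimiter (default tab).
#' @return A `data.frame` with columns `snp, chr, pos, effect_allele,
#'   other_allele, eaf, beta, se, pvalue, n, n_cases`, alleles upper-cased.
#' @export
read_summary_stats <- function(path, column_map = NULL, delim = "\t") {
  cols <- .default_columns
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(cols))
    if (length(unknown)) {
      stop("unknown column_map field(s): ", paste(unknown, collapse = ", "))
    }
    cols[names(column_map)] <- unlist(column_map)
  }
  raw <- utils::read.table(path,
    header = TRUE, sep = delim, colClasses = "character",
    stringsAsFactors = FALSE, check.names = FALSE, quote = "",
    comment.char = ""
  )
  mandatory <- c(
    "snp", "chr", "pos", "effect_allele", "other_allele",
    "beta", "se", "pvalue", "n"
  )
  absent <- setdiff(unname(cols[mandatory]), names(raw))
  if (length(absent)) {
    stop("missing mandatory column(s): ", paste(absent, collapse = ", "))
  }

  numeric_col <- function(field) {
    x <- raw[[cols[[field]]]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !is.na(x) & nzchar(x) & toupper(x) != "NA")
    if (length(bad)) {
      stop(sprintf(
        "unparsable numeric value '%s' in column '%s' at line %d",
        x[bad[1]], cols[[field]], bad[1] + 1L
      ))
    }
    v
  }
  optional_numeric <- function(field) {
    if (cols[[field]] %in% names(raw)) {
      numeric_col(field)
    } else {
      rep(NA_real_, nrow(raw))
    }
  }

  out <- data.frame(
    snp = raw[[cols[["snp"]]]],
    chr = as.character(raw[[cols[["chr"]]]]),
    pos = numeric_col("pos"),
    effect_allele = toupper(raw[[cols[["effect_allele"]]]]),
    other_allele = toupper(raw[[cols[["other_allele"]]]]),
    eaf = optional_numeric("eaf"),
    beta = numeric_col("beta"),
    se = numeric_col("se"),
    pvalue = numeric_col("pvalue"),
    n = numeric_col("n"),
    n_cases = optional_numeric("n_cases"),
    stringsAsFactors = FALSE
  )

  bad_se <- is.na(out$se) | out$se <= 0
  if (any(bad_se)) {
    message(sum(bad_se), " row(s) rejected for missing or non-positive SE")
    out <- out[!bad_se, , drop = FALSE]
  }
  if (nrow(out)) {
    if (any(out$effect_allele == out$other_allele)) {
      stop("effect and other allele identical for SNP(s): ",
        paste(utils::head(out$snp[out$effect_allele == out$other_allele], 5),
          collapse = ", "
        )
      )
    }
    if (any(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1))) {
      stop("effect-allele frequency outside [0, 1]")
    }
    if (any(!is.na(out$pos) & out$pos < 1)) stop("position must be >= 1")
  }
  rownames(out) <- NULL
  out
}

#' Write GWAS summary statistics to delimited text
#'
#' Inverse of [read_summary_stats()] using the default header names.
#'
#' @param records Summary-statistic `data.frame` as returned by
#'   [read_summary_stats()].
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path, delim = "\t") {
  out <- records[, names(.default_columns)[names(.default_columns) %in% names(records)]]
  names(out) <- .default_columns[names(out)]
  utils::write.table(out, path,
    sep = delim, quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Is an allele pair palindromic?
#'
#' A palindromic SNP has complementary alleles ({A,T} or {C,G}), so its strand
#' cannot be resolved from the alleles alone; such SNPs are excluded from
#' instrument sets.
#'
#' @param effect_allele,other_allele Allele vectors (single letters A/C/G/T).
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  .check_alleles(effect_allele, other_allele)
  unname(.complement[toupper(effect_allele)] == toupper(other_allele))
}

#' Complement an allele pair (strand flip)
#'
#' @param effect_allele,other_allele Allele vectors (A/C/G/T).
#' @return A list with components `effect_allele` and `other_allele`, both
#'   complemented (A<->T, C<->G).
#' @export
complement_alleles <- function(effect_allele, other_allele) {
  .check_alleles(effect_allele, other_allele)
  list(
    effect_allele = unname(.complement[toupper(effect_allele)]),
    other_allele = unname(.complement[toupper(other_allele)])
  )
}

#' Construct a harmonized exposure/outcome dataset
#'
#' Low-level constructor used by [harmonize()] and by the synthetic-data
#' generator; validates the invariants every estimator relies on (equal
#' lengths, positive SEs).
#'
#' @param snp SNP identifiers.
#' @param beta_exposure,se_exposure Per-SNP exposure effect and SE.
#' @param beta_outcome,se_outcome Per-SNP outcome effect and SE, on the
#'   exposure's effect-allele frame.
#' @param ... Further equal-length columns (provenance flags etc.).
#' @return A `data.frame` of class `harmonized_data`.
#' @export
harmonized_data <- function(snp, beta_exposure, se_exposure,
                            beta_outcome, se_outcome, ...) {
  dat <- data.frame(
    snp = snp,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    ..., stringsAsFactors = FALSE
  )
  check_harmonized(dat)
  class(dat) <- c("harmonized_data", "data.frame")
  dat
}

check_harmonized <- function(dat) {
  needed <- c("snp", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  absent <- setdiff(needed, names(dat))
  if (length(absent)) {
    stop("harmonized data lacks column(s): ", paste(absent, collapse = ", "))
  }
  if (nrow(dat) < 1L) stop("harmonized dataset is empty")
  if (any(dat$se_exposure <= 0) || any(dat$se_outcome <= 0)) {
    stop("harmonized data requires strictly positive SEs")
  }
  invisible(dat)
}

#' Harmonize outcome effects onto the exposure's effect-allele frame
#'
#' Restricts to SNPs present in both datasets, then aligns each outcome record
#' to the exposure's effect/other allele pair: identical frames are copied;
#' swapped frames (outcome effect allele equals exposure other allele and vice
#' versa) have the outcome beta negated and eaf replaced by 1 - eaf; frames
#' that match only after strand complement are complemented first and then
#' treated the same way. Palindromic SNPs are dropped unconditionally (their
#' strand cannot be resolved), as are allele pairs that match under none of
#' the rules. Every drop is recorded with its reason in the `"drops"`
#' attribute of the result.
#'
#' @param exposure,outcome Summary-statistic data frames (see
#'   [read_summary_stats()]), keyed by `snp`.
#' @return A `harmonized_data` data frame with columns `snp, chr, pos,
#'   effect_allele, other_allele, eaf_exposure, beta_exposure, se_exposure,
#'   pvalue_exposure, n_exposure, beta_outcome, se_outcome, pvalue_outcome,
#'   sign_flipped, strand_complemented`, plus a `"drops"` attribute
#'   (`data.frame` of snp and reason).
#' @export
harmonize <- function(exposure, outcome) {
  shared <- intersect(exposure$snp, outcome$snp)
  if (!length(shared)) stop("no shared SNPs between exposure and outcome")
  e <- exposure[match(shared, exposure$snp), , drop = FALSE]
  o <- outcome[match(shared, outcome$snp), , drop = FALSE]

  n <- length(shared)
  keep <- logical(n)
  reason <- character(n)
  beta_out <- numeric(n)
  eaf_out <- rep(NA_real_, n)
  flipped <- logical(n)
  complemented <- logical(n)

  for (i in seq_len(n)) {
    ea_e <- toupper(e$effect_allele[i])
    oa_e <- toupper(e$other_allele[i])
    ea_o <- toupper(o$effect_allele[i])
    oa_o <- toupper(o$other_allele[i])
    if (is_palindromic(ea_e, oa_e) || is_palindromic(ea_o, oa_o)) {
      reason[i] <- "palindromic"
      next
    }
    o_eaf <- if ("eaf" %in% names(o)) o$eaf[i] else NA_real_
    if (ea_o == ea_e && oa_o == oa_e) {
      keep[i] <- TRUE
      beta_out[i] <- o$beta[i]
      eaf_out[i] <- o_eaf
    } else if (ea_o == oa_e && oa_o == ea_e) {
      keep[i] <- TRUE
      beta_out[i] <- -o$beta[i]
      eaf_out[i] <- if (is.na(o_eaf)) NA_real_ else 1 - o_eaf
      flipped[i] <- TRUE
    } else {
      cc <- complement_alleles(ea_o, oa_o)
      if (cc$effect_allele == ea_e && cc$other_allele == oa_e) {
        keep[i] <- TRUE
        beta_out[i] <- o$beta[i]
        eaf_out[i] <- o_eaf
        complemented[i] <- TRUE
      } else if (cc$effect_allele == oa_e && cc$other_allele == ea_e) {
        keep[i] <- TRUE
        beta_out[i] <- -o$beta[i]
        eaf_out[i] <- if (is.na(o_eaf)) NA_real_ else 1 - o_eaf
        flipped[i] <- TRUE
        complemented[i] <- TRUE
      } else {
        reason[i] <- "incompatible_alleles"
      }
    }
  }

  drops <- data.frame(
    snp = shared[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  if (!any(keep)) {
    stop("no SNPs left after harmonization (",
      paste(sprintf("%s: %s", drops$snp, drops$reason), collapse = "; "), ")"
    )
  }

  idx <- which(keep)
  dat <- data.frame(
    snp = shared[idx],
    chr = if ("chr" %in% names(e)) e$chr[idx] else NA_character_,
    pos = if ("pos" %in% names(e)) e$pos[idx] else NA_real_,
    effect_allele = toupper(e$effect_allele[idx]),
    other_allele = toupper(e$other_allele[idx]),
    eaf_exposure = if ("eaf" %in% names(e)) e$eaf[idx] else NA_real_,
    beta_exposure = e$beta[idx],
    se_exposure = e$se[idx],
    pvalue_exposure = if ("pvalue" %in% names(e)) e$pvalue[idx] else NA_real_,
    n_exposure = if ("n" %in% names(e)) e$n[idx] else NA_real_,
    eaf_outcome = eaf_out[idx],
    beta_outcome = beta_out[idx],
    se_outcome = o$se[idx],
    pvalue_outcome = if ("pvalue" %in% names(o)) o$pvalue[idx] else NA_real_,
    n_outcome = if ("n" %in% names(o)) o$n[idx] else NA_real_,
    sign_flipped = flipped[idx],
    strand_complemented = complemented[idx],
    stringsAsFactors = FALSE
  )
  rownames(dat) <- NULL
  check_harmonized(dat)
  class(dat) <- c("harmonized_data", "data.frame")
  attr(dat, "drops") <- drops
  dat
}
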