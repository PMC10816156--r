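# Instrument selection: significance filtering, LD clumping, F-statistics,
# palindrome and confounder exclusion.

#' Instrument-selection thresholds
#'
#' Defaults follow the conventional genome-wide MR instrument criteria:
#' p < 5e-8 for exposure association, pairwise LD r^2 < 0.01 within a
#' 10,000 kb clumping window, per-SNP F-statistic >= 10, and exclusion of
#' SNPs associated with a known confounder at p < 1e-5.
#'
#' @param p_threshold Genome-wide significance cutoff (strict `<`).
#' @param clump_r2 LD r^2 at or above which a neighbour of an index SNP is
#'   removed; in (0, 1).
#' @param clump_kb Clumping window half-width in kilobases.
#' @param f_min Minimum instrument-strength F (SNPs with F < `f_min` are
#'   excluded).
#' @param confounder_p Confounder-association cutoff (strict `<`).
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(p_threshold = 5e-8, clump_r2 = 0.01,
                             clump_kb = 10000, f_min = 10,
                             confounder_p = 1e-5) {
  stopifnot(
    p_threshold >= 0, clump_r2 > 0, clump_r2 < 1,
    clump_kb > 0, f_min > 0, confounder_p > 0
  )
  structure(
    list(
      p_threshold = p_threshold, clump_r2 = clump_r2, clump_kb = clump_kb,
      f_min = f_min, confounder_p = confounder_p
    ),
    class = "selection_params"
  )
}

#' Retain genome-wide significant SNPs
#'
#' @param records Summary-statistic data frame with a `pvalue` column.
#' @param p_threshold Significance cutoff; rows with `pvalue < p_threshold`
#'   are retained, input order preserved.
#' @return Filtered records.
#' @export
filter_significance <- function(records, p_threshold = 5e-8) {
  stopifnot("pvalue" %in% names(records))
  out <- records[!is.na(records$pvalue) & records$pvalue < p_threshold, ,
    drop = FALSE
  ]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the not-yet-removed SNP with the smallest p-value as an
#' index SNP and removes every other remaining SNP on the same chromosome
#' within `clump_kb` kilobases whose r^2 with the index is at or above
#' `clump_r2`. Ties on p are broken by position, then SNP id, so the result
#' is platform-independent. Index SNPs are returned sorted by p-value under
#' the same tie-break.
#'
#' @param records Summary statistics with `snp`, `chr`, `pos`, `pvalue`.
#' @param ld Square symmetric r^2 matrix with SNP ids as dimnames (see
#'   [read_ld_matrix()]); must cover every record.
#' @param clump_r2 Removal threshold on r^2 (removal when `>=`).
#' @param clump_kb Window half-width in kb; the window applies within a
#'   chromosome as `|position difference| <= clump_kb * 1000`.
#' @return The index-SNP records.
#' @export
ld_clump <- function(records, ld, clump_r2 = 0.01, clump_kb = 10000) {
  if (nrow(records) == 0L) return(records)
  stopifnot(all(c("snp", "chr", "pos", "pvalue") %in% names(records)))
  absent <- setdiff(records$snp, rownames(ld))
  if (length(absent)) {
    stop("SNP(s) missing from LD matrix: ", paste(absent, collapse = ", "))
  }
  ord <- order(records$pvalue, records$pos, records$snp)
  rec <- records[ord, , drop = FALSE]
  n <- nrow(rec)
  active <- rep(TRUE, n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    if (!active[i]) next
    kept[i] <- TRUE
    if (i < n) {
      j <- which(active & !kept)
      if (length(j)) {
        same_chr <- rec$chr[j] == rec$chr[i]
        in_window <- abs(rec$pos[j] - rec$pos[i]) <= clump_kb * 1000
        r2 <- ld[rec$snp[i], rec$snp[j]]
        active[j[same_chr & in_window & r2 >= clump_r2]] <- FALSE
      }
    }
  }
  out <- rec[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-SNP explained variance R^2
#'
#' Two estimators of the exposure variance explained by one SNP:
#' `"zscore"` uses \eqn{R^2 = z^2 / (z^2 + n - 2)} with \eqn{z = \beta/SE}
#' (no allele frequency needed); `"frequency"` uses
#' \eqn{R^2 = 2\,eaf(1-eaf)\beta^2} (standardized-trait approximation).
#'
#' @param beta,se Per-allele effect and its SE.
#' @param n Exposure GWAS sample size (zscore mode).
#' @param eaf Effect-allele frequency (frequency mode).
#' @param mode `"zscore"` (default) or `"frequency"`.
#' @return Numeric vector of R^2 values in \[0, 1).
#' @export
snp_r2 <- function(beta, se, n = NULL, eaf = NULL,
                   mode = c("zscore", "frequency")) {
  mode <- match.arg(mode)
  if (mode == "zscore") {
    if (is.null(n)) stop("zscore mode requires the sample size n")
    z2 <- (beta / se)^2
    r2 <- z2 / (z2 + n - 2)
  } else {
    if (is.null(eaf) || any(is.na(eaf))) {
      stop("frequency mode requires the effect-allele frequency")
    }
    r2 <- 2 * eaf * (1 - eaf) * beta^2
  }
  if (any(r2 >= 1)) stop("per-SNP R^2 reached 1; inputs are implausible")
  r2
}

#' Instrument-strength F-statistic
#'
#' \eqn{F = \frac{N - K - 1}{K}\,\frac{R^2}{1 - R^2}}, where N is the exposure
#' sample size, K the number of SNPs entering the statistic and R^2 the
#' explained variance. Per-SNP strength uses K = 1.
#'
#' @param r_squared Explained variance in \[0, 1).
#' @param n Exposure sample size; must exceed `k + 1`.
#' @param k Number of SNPs in the statistic (default 1).
#' @return F values (>= 0).
#' @export
f_statistic <- function(r_squared, n, k = 1) {
  if (any(r_squared < 0 | r_squared >= 1)) stop("R^2 must lie in [0, 1)")
  if (any(n <= k + 1)) stop("sample size must exceed k + 1")
  (n - k - 1) / k * r_squared / (1 - r_squared)
}

#' Per-SNP instrument strength table
#'
#' @param records Summary statistics with `beta`, `se`, `n` (and `eaf` for
#'   frequency mode).
#' @param mode R^2 estimator passed to [snp_r2()].
#' @param k Number of SNPs per F-statistic (default 1: per-SNP strength).
#' @return `data.frame` with `snp, r_squared, f_stat, n, k`.
#' @export
instrument_strength <- function(records, mode = c("zscore", "frequency"),
                                k = 1) {
  mode <- match.arg(mode)
  r2 <- snp_r2(records$beta, records$se,
    n = records$n,
    eaf = if (mode == "frequency") records$eaf else NULL, mode = mode
  )
  data.frame(
    snp = records$snp, r_squared = r2,
    f_stat = f_statistic(r2, records$n, k = k),
    n = records$n, k = k, stringsAsFactors = FALSE
  )
}

#' Exclude weak instruments
#'
#' SNPs with F below `f_min` are excluded (a SNP at exactly `f_min` is kept).
#'
#' @param records Summary statistics.
#' @param strengths Optional strength table from [instrument_strength()];
#'   computed in zscore mode when `NULL`.
#' @param f_min Minimum F.
#' @return Filtered records.
#' @export
filter_weak_instruments <- function(records, strengths = NULL, f_min = 10) {
  if (nrow(records) == 0L) return(records)
  if (is.null(strengths)) strengths <- instrument_strength(records)
  f <- strengths$f_stat[match(records$snp, strengths$snp)]
  if (any(is.na(f))) stop("strength table does not cover every record")
  out <- records[f >= f_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude palindromic SNPs
#'
#' @param records Summary statistics with allele columns.
#' @return Records whose allele pair is not {A,T} or {C,G}.
#' @export
filter_palindromic <- function(records) {
  if (nrow(records) == 0L) return(records)
  out <- records[!is_palindromic(records$effect_allele, records$other_allele), ,
    drop = FALSE
  ]
  rownames(out) <- NULL
  out
}

#' Exclude SNPs associated with known confounders
#'
#' Removes every record whose SNP has at least one confounder association at
#' `pvalue < confounder_p`. Removals are reported via `message()` with the
#' offending phenotype and recorded in the `"removed"` attribute.
#'
#' @param records Summary statistics.
#' @param confounder_table `data.frame` with columns `snp, phenotype, pvalue`
#'   (exact-id matching; may be empty).
#' @param confounder_p Cutoff (strict `<`).
#' @return Filtered records with a `"removed"` attribute.
#' @export
filter_confounders <- function(records, confounder_table,
                               confounder_p = 1e-5) {
  if (is.null(confounder_table) || nrow(confounder_table) == 0L ||
    nrow(records) == 0L) {
    attr(records, "removed") <- data.frame(
      snp = character(), phenotype = character(), stringsAsFactors = FALSE
    )
    return(records)
  }
  stopifnot(all(c("snp", "phenotype", "pvalue") %in% names(confounder_table)))
  hits <- confounder_table[confounder_table$pvalue < confounder_p, ,
    drop = FALSE
  ]
  drop <- records$snp %in% hits$snp
  removed <- hits[hits$snp %in% records$snp[drop], c("snp", "phenotype"),
    drop = FALSE
  ]
  if (nrow(removed)) {
    message(
      "confounder filter removed ", sum(drop), " SNP(s): ",
      paste(sprintf("%s (%s)", removed$snp, removed$phenotype), collapse = ", ")
    )
  }
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

#' Full instrument-selection pipeline
#'
#' Applies the five selection criteria in order: genome-wide significance,
#' LD clumping, F-statistic, palindrome exclusion, confounder exclusion.
#' Returns the surviving instruments together with a per-stage audit
#' (counts and dropped SNPs with reasons) suitable for JSON serialization.
#'
#' @param exposure Exposure summary statistics.
#' @param ld LD r^2 matrix covering the significant SNPs.
#' @param confounder_table Optional confounder associations
#'   (`snp, phenotype, pvalue`).
#' @param params A [selection_params()] object.
#' @param r2_mode R^2 estimator for the F-statistic stage.
#' @return A list of class `iv_selection` with elements `instruments`
#'   (records), `strengths` (per-SNP F table for the clumped set) and
#'   `audit` (list with `stages` count table and `dropped` reasons).
#' @export
select_instruments <- function(exposure, ld, confounder_table = NULL,
                               params = selection_params(),
                               r2_mode = c("zscore", "frequency")) {
  r2_mode <- match.arg(r2_mode)
  stages <- list()
  dropped <- list()
  note_stage <- function(name, before, after, reason) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, n = nrow(after), stringsAsFactors = FALSE
    )
    gone <- setdiff(before$snp, after$snp)
    if (length(gone)) {
      dropped[[length(dropped) + 1L]] <<- data.frame(
        snp = gone, stage = name, reason = reason, stringsAsFactors = FALSE
      )
    }
    after
  }

  stages[[1L]] <- data.frame(stage = "input", n = nrow(exposure),
    stringsAsFactors = FALSE)
  sig <- note_stage(
    "significance", exposure,
    filter_significance(exposure, params$p_threshold),
    sprintf("p >= %g", params$p_threshold)
  )
  clumped <- note_stage(
    "clump", sig,
    ld_clump(sig, ld, params$clump_r2, params$clump_kb),
    sprintf("in LD (r2 >= %g) with a stronger index SNP", params$clump_r2)
  )
  strengths <- if (nrow(clumped)) {
    instrument_strength(clumped, mode = r2_mode)
  } else {
    data.frame(snp = character(), r_squared = numeric(), f_stat = numeric(),
      n = numeric(), k = numeric(), stringsAsFactors = FALSE)
  }
  strong <- note_stage(
    "f_statistic", clumped,
    filter_weak_instruments(clumped, strengths, params$f_min),
    sprintf("F < %g", params$f_min)
  )
  nonpal <- note_stage(
    "palindrome", strong, filter_palindromic(strong),
    "palindromic allele pair"
  )
  final <- note_stage(
    "confounder", nonpal,
    filter_confounders(nonpal, confounder_table, params$confounder_p),
    sprintf("confounder association p < %g", params$confounder_p)
  )

  audit <- list(
    stages = do.call(rbind, stages),
    dropped = if (length(dropped)) {
      do.call(rbind, dropped)
    } else {
      data.frame(snp = character(), stage = character(), reason = character(),
        stringsAsFactors = FALSE)
    }
  )
  structure(
    list(
      instruments = final,
      strengths = strengths[strengths$snp %in% final$snp, , drop = FALSE],
      audit = audit, params = params
    ),
    class = "iv_selection"
  )
}

#' Read an LD r^2 matrix
#'
#' Accepts either a square tab-delimited matrix whose first column and header
#' row hold SNP ids, or a long-format file with columns `snp_a, snp_b, r2`
#' (symmetrized, unit diagonal, missing pairs set to 0).
#'
#' @param path Path to the LD file.
#' @param delim Field delimiter.
#' @return A symmetric numeric matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path, delim = "\t") {
  header <- strsplit(readLines(path, n = 1L), delim, fixed = TRUE)[[1]]
  if (length(header) == 3L && all(tolower(header) == c("snp_a", "snp_b", "r2"))) {
    long <- utils::read.table(path, header = TRUE, sep = delim,
      stringsAsFactors = FALSE)
    ids <- sort(unique(c(long$snp_a, long$snp_b)))
    m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    m[cbind(long$snp_a, long$snp_b)] <- long$r2
    m[cbind(long$snp_b, long$snp_a)] <- long$r2
    diag(m) <- 1
    return(m)
  }
  tab <- utils::read.table(path, header = TRUE, sep = delim,
    row.names = 1L, check.names = FALSE)
  m <- as.matrix(tab)
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m))) {
    stop("square LD matrix must have matching SNP-id rows and columns")
  }
  m
}

#' Write an LD r^2 matrix (square layout)
#'
#' @param ld Symmetric matrix with SNP-id dimnames.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path, delim = "\t") {
  df <- data.frame(SNP = rownames(ld), ld, check.names = FALSE,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confounder-association table
#'
#' @param path Tab-delimited file with columns `snp, phenotype, pvalue`
#'   (header required; case-insensitive names, `SNP`/`P` accepted).
#' @param delim Field delimiter.
#' @return `data.frame` with `snp, phenotype, pvalue`.
#' @export
read_confounder_table <- function(path, delim = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = delim,
    stringsAsFactors = FALSE, quote = "", comment.char = "")
  names(tab) <- tolower(names(tab))
  if ("p" %in% names(tab) && !"pvalue" %in% names(tab)) {
    names(tab)[names(tab) == "p"] <- "pvalue"
  }
  stopifnot(all(c("snp", "phenotype", "pvalue") %in% names(tab)))
  tab[, c("snp", "phenotype", "pvalue")]
}
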