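# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no binary data.

# Harmonized dataset built directly from effect vectors.
make_dat <- function(bx, by, sx = rep(0.01, length(bx)),
                     sy = rep(0.1, length(bx)),
                     snp = sprintf("snp%02d", seq_along(bx))) {
  harmonized_data(
    snp = snp, beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy
  )
}

# Random harmonized instance for oracle-equivalence checks.
random_dat <- function(J) {
  bx <- stats::rnorm(J, 0.1, 0.05)
  bx[abs(bx) < 0.01] <- 0.05 # keep ratios well defined
  make_dat(
    bx = bx,
    by = 0.5 * bx + stats::rnorm(J, 0, 0.05),
    sx = stats::runif(J, 0.005, 0.02),
    sy = stats::runif(J, 0.02, 0.2)
  )
}

# Brute-force greedy clumping: literal transcription of the rule, used as
# the reference implementation.
brute_clump <- function(records, ld, clump_r2, clump_kb) {
  remaining <- records
  kept <- records[0, ]
  while (nrow(remaining) > 0) {
    o <- order(remaining$pvalue, remaining$pos, remaining$snp)
    idx <- remaining[o[1], , drop = FALSE]
    kept <- rbind(kept, idx)
    drop <- vapply(seq_len(nrow(remaining)), function(i) {
      r <- remaining[i, ]
      if (r$snp == idx$snp) return(TRUE)
      r$chr == idx$chr &&
        abs(r$pos - idx$pos) <= clump_kb * 1000 &&
        ld[idx$snp, r$snp] >= clump_r2
    }, logical(1))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  rownames(kept) <- NULL
  kept
}

# Random clumping instance on <= 20 SNPs spread over two chromosomes.
random_clump_instance <- function(J) {
  snp <- sprintf("s%02d", seq_len(J))
  m <- matrix(stats::runif(J * J), J, J)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(snp, snp)
  records <- data.frame(
    snp = snp,
    chr = as.character(sample(1:2, J, replace = TRUE)),
    pos = sample.int(3e7, J),
    pvalue = 10^(-stats::runif(J, 8, 15)),
    stringsAsFactors = FALSE
  )
  list(records = records, ld = m)
}

# Minimal exposure record table for selection tests.
make_records <- function(n, snp = sprintf("rs%03d", seq_len(n)),
                         chr = rep("1", n), pos = seq_len(n) * 1e6,
                         ea = rep("A", n), oa = rep("G", n),
                         beta = rep(0.1, n), se = rep(0.01, n),
                         pvalue = rep(1e-10, n), nn = rep(1e5, n),
                         eaf = rep(NA_real_, n)) {
  data.frame(
    snp = snp, chr = chr, pos = pos, effect_allele = ea, other_allele = oa,
    eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = nn,
    n_cases = NA_real_, stringsAsFactors = FALSE
  )
}

# 100-SNP fixture engineered so the five filters produce the audit counts
# [100, 20, 12, 12, 10, 9]: 80 non-significant; of the 20 significant SNPs,
# 8 are clumped away against stronger neighbours; the 12 survivors all have
# F >= 10, 2 of them are palindromic, and 1 of the remaining 10 carries a
# confounder association.
selection_fixture <- function() {
  n <- 100
  snp <- sprintf("fx%03d", seq_len(n))
  chr <- rep("1", n)
  pos <- seq_len(n) * 1e6
  pvalue <- rep(1e-4, n) # non-significant bulk
  beta <- rep(0.1, n)
  se <- rep(0.05, n) # F = (0.1/0.05)^2-ish, weak but filtered out earlier
  ea <- rep("A", n)
  oa <- rep("G", n)

  # 12 index SNPs, significant and strong (z = 8 -> F ~ 64)
  index <- seq_len(12)
  pvalue[index] <- 1e-12
  beta[index] <- 0.12
  se[index] <- 0.015
  # 8 satellites in LD with the first 8 index SNPs, significant, weaker p
  sat <- 13:20
  pvalue[sat] <- 1e-9
  beta[sat] <- 0.10
  se[sat] <- 0.016
  pos[sat] <- pos[seq_len(8)] + 5e4 # within the window of their index
  # 2 of the surviving index SNPs palindromic
  ea[11:12] <- "A"
  oa[11:12] <- "T"

  records <- data.frame(
    snp = snp, chr = chr, pos = pos, effect_allele = ea, other_allele = oa,
    eaf = NA_real_, beta = beta, se = se, pvalue = pvalue, n = 456468,
    n_cases = NA_real_, stringsAsFactors = FALSE
  )

  ld <- diag(n)
  dimnames(ld) <- list(snp, snp)
  for (i in seq_len(8)) { # satellite i in LD with index i
    ld[snp[i], snp[12 + i]] <- 0.8
    ld[snp[12 + i], snp[i]] <- 0.8
  }

  confounders <- data.frame(
    snp = snp[10], phenotype = "Alcohol consumption", pvalue = 1e-7,
    stringsAsFactors = FALSE
  )
  list(records = records, ld = ld, confounders = confounders)
}

# Fast instrument-level generator for repeated simulations: J instruments,
# identity LD, panel restricted to the instruments themselves.
quick_config <- function(J = 30, beta = 0.72, seed = 1, ...) {
  sim_config(
    n_snps_total = J, n_instruments = J, ld_block_size = 1,
    beta_causal = beta, seed = seed, ...
  )
}

quick_instruments <- function(J = 30, beta = 0.72, seed = 1, ...) {
  instrument_data(simulate_two_sample_study(quick_config(J, beta, seed, ...)))
}

table2_path <- function() {
  system.file("extdata", "ua_instruments.tsv", package = "tsmr")
}
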