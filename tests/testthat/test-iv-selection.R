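test_that("significance filter keeps rows strictly below the threshold", {
  rec <- read_summary_stats(table2_path())
  expect_equal(nrow(filter_significance(rec, 5e-8)), 11) # max p = 3.35e-8
  expect_equal(nrow(filter_significance(rec, 0)), 0)

  two <- make_records(2, pvalue = c(1e-9, 1e-7))
  expect_equal(filter_significance(two, 5e-8)$snp, two$snp[1])
  # order preserved
  shuffled <- rec[c(5, 1, 9), ]
  expect_equal(filter_significance(shuffled, 5e-8)$snp, shuffled$snp)
})

test_that("greedy clumping keeps index SNPs and respects chromosome windows", {
  rec <- make_records(3,
    snp = c("A", "B", "C"), chr = c("1", "1", "1"),
    pos = c(1e6, 1e6 + 5e4, 2e6), pvalue = c(1e-10, 1e-9, 1e-8)
  )
  ld <- diag(3)
  dimnames(ld) <- list(rec$snp, rec$snp)
  ld["A", "B"] <- ld["B", "A"] <- 0.5
  ld["A", "C"] <- ld["C", "A"] <- 0.001
  expect_equal(ld_clump(rec, ld, 0.01, 10000)$snp, c("A", "C"))

  # independent SNPs are untouched
  ld0 <- diag(3)
  dimnames(ld0) <- list(rec$snp, rec$snp)
  expect_equal(nrow(ld_clump(rec, ld0, 0.01, 10000)), 3)

  # high r2 across chromosomes is ignored (window is per chromosome)
  rec2 <- make_records(2, snp = c("X", "Y"), chr = c("1", "2"),
    pos = c(1e6, 1e6), pvalue = c(1e-10, 1e-9))
  ld2 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(rec2$snp, rec2$snp))
  expect_equal(nrow(ld_clump(rec2, ld2, 0.01, 10000)), 2)

  expect_error(ld_clump(rec, diag(2), 0.01, 10000), "missing from LD")
})

test_that("clumping matches the brute-force greedy reference", {
  set.seed(11)
  for (i in 1:60) {
    inst <- random_clump_instance(sample(2:20, 1))
    r2 <- runif(1, 0.005, 0.5)
    kb <- sample(c(100, 5000, 10000), 1)
    got <- ld_clump(inst$records, inst$ld, r2, kb)
    want <- brute_clump(inst$records, inst$ld, r2, kb)
    expect_equal(got$snp, want$snp)
    # retained pairs on one chromosome within the window are independent
    if (nrow(got) > 1) {
      for (a in 1:(nrow(got) - 1)) {
        for (b in (a + 1):nrow(got)) {
          if (got$chr[a] == got$chr[b] &&
            abs(got$pos[a] - got$pos[b]) <= kb * 1000) {
            expect_lt(inst$ld[got$snp[a], got$snp[b]], r2)
          }
        }
      }
    }
  }
})

test_that("per-SNP R^2 matches its closed forms", {
  # z-score mode at published scale: z = 0.130/0.016 = 8.125
  r2 <- snp_r2(0.130, 0.016, n = 456468)
  expect_equal(r2, 8.125^2 / (8.125^2 + 456466), tolerance = 1e-12)
  expect_equal(r2, 1.446e-4, tolerance = 1e-3)
  expect_equal(snp_r2(0, 0.01, n = 100), 0)
  expect_equal(snp_r2(0.1, 0.01, eaf = 0.5, mode = "frequency"), 0.005)
  expect_equal(snp_r2(0, 0.01, eaf = 0.3, mode = "frequency"), 0)
  expect_error(snp_r2(0.1, 0.01, eaf = NA, mode = "frequency"), "frequency")
})

test_that("F-statistic follows (n-k-1)/k * R2/(1-R2) and is monotone in R2", {
  expect_equal(f_statistic(1.0001e-4, 456468, 1), 45.65, tolerance = 1e-3)
  expect_equal(f_statistic(0, 1000, 1), 0)
  expect_equal(f_statistic(0.5, 4, 1), 2)
  expect_error(f_statistic(0.1, 2, 1), "exceed")
  r2 <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(f_statistic(r2, 1000, 1)) > 0))
})

test_that("weak-instrument filter excludes F < f_min, keeping the boundary", {
  rec <- make_records(3)
  strengths <- data.frame(snp = rec$snp, f_stat = c(9.99, 10.0, 45.6))
  kept <- filter_weak_instruments(rec, strengths, f_min = 10)
  expect_equal(kept$snp, rec$snp[2:3])
  strong <- data.frame(snp = rec$snp, f_stat = c(11, 12, 13))
  expect_equal(filter_weak_instruments(rec, strong, 10), rec)
  expect_equal(nrow(filter_weak_instruments(rec[0, ], strengths, 10)), 0)
})

test_that("confounder filter removes associated SNPs under strict inequality", {
  rec <- make_records(3, snp = c("X", "Y", "Z"))
  conf <- data.frame(
    snp = c("X", "Z"), phenotype = c("Diabetes", "Obesity"),
    pvalue = c(1e-6, 1e-5)
  )
  suppressMessages(kept <- filter_confounders(rec, conf, 1e-5))
  expect_equal(kept$snp, c("Y", "Z")) # Z at exactly 1e-5 retained
  expect_equal(attr(kept, "removed")$phenotype, "Diabetes")
  empty <- data.frame(snp = character(), phenotype = character(),
    pvalue = numeric())
  expect_equal(filter_confounders(rec, empty)$snp, rec$snp)
})

test_that("each selection filter is a contraction and idempotent", {
  set.seed(5)
  rec <- make_records(20,
    pvalue = 10^-runif(20, 4, 12), beta = rnorm(20, 0.1, 0.05),
    se = runif(20, 0.01, 0.05), nn = rep(5e4, 20),
    ea = sample(c("A", "C"), 20, TRUE),
    oa = sample(c("G", "T"), 20, TRUE)
  )
  filters <- list(
    function(r) filter_significance(r, 5e-8),
    function(r) filter_weak_instruments(r, f_min = 10),
    filter_palindromic
  )
  for (f in filters) {
    once <- f(rec)
    expect_true(all(once$snp %in% rec$snp))
    expect_equal(f(once), once)
  }
  ld <- diag(20)
  dimnames(ld) <- list(rec$snp, rec$snp)
  once <- ld_clump(rec, ld, 0.01, 10000)
  expect_equal(ld_clump(once, ld, 0.01, 10000)$snp, once$snp)
})

test_that("the staged pipeline reproduces engineered audit counts", {
  fx <- selection_fixture()
  sel <- suppressMessages(
    select_instruments(fx$records, fx$ld, fx$confounders)
  )
  expect_equal(sel$audit$stages$stage,
    c("input", "significance", "clump", "f_statistic", "palindrome",
      "confounder"))
  expect_equal(sel$audit$stages$n, c(100, 20, 12, 12, 10, 9))
  expect_equal(nrow(sel$instruments), 9)
  # every dropped SNP carries exactly one reason
  expect_equal(anyDuplicated(sel$audit$dropped$snp), 0)
  expect_equal(nrow(sel$audit$dropped), 100 - 9)

  # no significant SNP: empty result, informative audit
  none <- fx$records
  none$pvalue <- 0.5
  sel0 <- select_instruments(none, fx$ld, fx$confounders)
  expect_equal(nrow(sel0$instruments), 0)
  expect_equal(sel0$audit$stages$n[2], 0)
})

test_that("selection parameters round-trip through serialization", {
  p <- selection_params()
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(p), f)
  p2 <- do.call(selection_params, yaml::read_yaml(f))
  expect_equal(p2, p)
  fx <- selection_fixture()
  s1 <- suppressMessages(select_instruments(fx$records, fx$ld,
    fx$confounders, p))
  s2 <- suppressMessages(select_instruments(fx$records, fx$ld,
    fx$confounders, p2))
  expect_equal(s1$instruments, s2$instruments)
})

test_that("LD matrices round-trip in square and long layouts", {
  m <- matrix(c(1, 0.3, 0.3, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  f <- tempfile()
  write_ld_matrix(m, f)
  expect_equal(read_ld_matrix(f), m)

  long <- tempfile()
  writeLines(c("snp_a\tsnp_b\tr2", "a\tb\t0.3"), long)
  expect_equal(read_ld_matrix(long), m)
})
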