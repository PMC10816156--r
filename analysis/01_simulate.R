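#!/usr/bin/env Rscript
# Generate the two synthetic exposure/outcome study bundles the analysis
# runs on: an unstable-angina-like exposure (9481/446,987, 11 instruments)
# and a stable-angina-like exposure (17,894/325,132, 33 instruments), both
# against a hepatic-failure-like outcome (464/213,592). Panel scale is
# desk-sized (500 SNPs); instrument effect sizes sit on the per-allele
# log-odds scale of genome-wide significant angina loci.

suppressMessages(library(tsmr))

seed <- 20240113
out_root <- "results/fixtures"

configs <- list(
  ua = sim_config(
    n_instruments = 11, beta_causal = 0.72,
    n_exposure = 456468, n_cases_exposure = 9481,
    n_outcome = 214056, n_cases_outcome = 464,
    seed = seed
  ),
  sa = sim_config(
    n_instruments = 33, beta_causal = 0.12, # weak effect, OR ~ 1.12
    n_exposure = 343026, n_cases_exposure = 17894,
    n_outcome = 214056, n_cases_outcome = 464,
    seed = seed + 1
  )
)

for (nm in names(configs)) {
  study <- simulate_two_sample_study(configs[[nm]])
  conf <- simulate_confounder_table(study, frac_confounded = 0.1)
  paths <- write_fixture_bundle(study, file.path(out_root, nm), conf)
  cat(sprintf(
    "[%s] %d panel SNPs, %d designed instruments (%d confounded), true OR %.3f\n",
    nm, nrow(study$exposure), length(study$truth$instruments),
    nrow(conf), exp(study$truth$beta_causal)
  ))
}
cat("bundles written under", out_root, "\n")
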