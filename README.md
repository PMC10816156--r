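# tsmr — two-sample Mendelian randomization from GWAS summary statistics

`tsmr` implements a complete two-sample Mendelian randomization (MR)
analysis for epidemiologists asking whether a genetically proxied exposure
(the motivating case: liability to unstable or stable angina) causally
raises the risk of a binary outcome (hepatic failure), using only GWAS
summary statistics from two non-overlapping cohorts.

Given per-SNP exposure associations (γ̂ⱼ, σ_γⱼ) and outcome associations
(Γ̂ⱼ, σ_Γⱼ) on the log-odds scale, the package:

* **selects instruments** — genome-wide significance (p < 5×10⁻⁸), greedy
  LD clumping (r² < 0.01 in a 10,000 kb window), per-SNP F-statistic
  F = (N−K−1)/K · R²/(1−R²) with exclusion of F < 10, palindromic-SNP
  (A/T, C/G) exclusion, and removal of SNPs associated with known
  confounders (p < 1×10⁻⁵) from a local table;
* **harmonizes** outcome effects onto the exposure's effect-allele frame
  (sign flips for swapped alleles, strand complementation, unconditional
  palindrome dropping, every exclusion logged);
* **estimates** the causal effect five ways — inverse-variance weighted
  (IVW) β̂ = Σwⱼγ̂ⱼΓ̂ⱼ / Σwⱼγ̂ⱼ², wⱼ = σ_Γⱼ⁻², with a Cochran's-Q-driven
  fixed/multiplicative-random-effects rule; MR-Egger (free intercept,
  t-based inference on J−2 df); weighted median; weighted mode; simple
  mode (bootstrap SEs for the last three);
* **stress-tests** the result — Cochran's Q (IVW and Egger variants), the
  MR-Egger intercept test for directional pleiotropy, MR-PRESSO
  global/outlier/distortion tests, and leave-one-out analysis;
* **simulates** complete synthetic study bundles with known causal truth
  (LD blocks, palindromic alleles, scrambled outcome allele coding,
  controllable horizontal pleiotropy) so every estimator is validated
  against ground truth rather than against itself.

All estimates are reported as odds ratios with 95% CIs,
exp(β̂ ∓ 1.96·SE), alongside plot-ready scatter, forest and leave-one-out
tables.

## Worked example

```r
library(tsmr)

study <- simulate_two_sample_study(sim_config(seed = 7))   # UA-scale defaults
conf  <- simulate_confounder_table(study, frac_confounded = 0.1)
paths <- write_fixture_bundle(study, tempfile(), conf)

report <- run_pipeline(list(
  exposure = paths$exposure, outcome = paths$outcome,
  ld = paths$ld, confounders = paths$confounders, seed = 7
))
report$estimates[, c("method", "n_snp", "or", "ci_low", "ci_high", "pvalue")]
```

```
                     method n_snp       or   ci_low  ci_high       pvalue
1 Inverse variance weighted    23 2.128411 1.761780 2.571340 4.824537e-15
2           Weighted median    23 2.112810 1.613290 2.766996 5.472583e-08
3             Weighted mode    23 2.079435 1.484836 2.912139 2.039486e-05
4               Simple mode    23 2.114242 1.347600 3.317023 1.120817e-03
5                  MR Egger    23 2.136880 1.181194 3.865799 2.030878e-02
```

The generator's true causal effect is 0.72 log-odds (odds ratio
exp(0.72) ≈ 2.05): all five estimators recover it, and the IVW 95% CI
(1.76–2.57) covers the truth. Of the 30 designed instruments, 23 survive
selection and harmonization (chance non-significance of the observed
effects, palindrome drops and two confounded SNPs account for the rest —
see `report$selection_audit`). The accompanying sensitivity suite
(`report$heterogeneity`, `report$egger_intercept`, `report$presso`,
`report$leave_one_out`) shows no heterogeneity (Q = 18.4, p = 0.68), no
directional pleiotropy (intercept p = 0.99) and no MR-PRESSO outliers, as
expected for a study simulated without pleiotropy.

## Analysis workflow

The `analysis/` scripts run the full study at desk scale and narrate what
they find:

```sh
Rscript analysis/01_simulate.R                # synthetic UA-like and SA-like bundles
Rscript analysis/02_run_mr.R                  # full MR + sensitivity reports
Rscript analysis/03_simulation_experiments.R  # recovery, calibration, robustness, PRESSO
```

Outputs land under `results/`: per-analysis `report.json`,
`estimates.tsv`, `instruments.tsv`, `sensitivity.tsv` and
`plotdata/*.tsv` (scatter, per-SNP and per-method forest, leave-one-out
tables mirroring the standard MR figures).

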