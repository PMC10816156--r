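Package: tsmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomization analysis of GWAS summary
    statistics: instrument selection (genome-wide significance filtering,
    greedy LD clumping, instrument-strength F-statistics, palindromic-SNP
    and confounder exclusion), allele harmonization across exposure and
    outcome datasets, five causal estimators (inverse-variance weighted
    with a Cochran's Q driven fixed/random-effects rule, MR-Egger,
    weighted median, weighted mode, simple mode), and a sensitivity suite
    (Cochran's Q, MR-Egger intercept test, MR-PRESSO global/outlier/
    distortion tests, leave-one-out). Includes a synthetic GWAS
    summary-statistics generator with known causal truth, LD block
    structure, palindromic alleles and controllable horizontal pleiotropy
    for validating the estimators, and an end-to-end pipeline producing
    report tables and plot-ready data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
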