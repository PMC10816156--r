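---
title: "Two-sample Mendelian randomization: models, estimators and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization: models, estimators and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsmr)
```

## The causal model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure (here: liability to unstable or stable angina) on an outcome (here:
hepatic failure) using genetic variants as instrumental variables, with the
variant–exposure and variant–outcome associations taken from two different
GWAS cohorts. For SNP $j$ the inputs are the estimated per-allele exposure
effect $\hat\gamma_j$ with standard error $\sigma_{\gamma j}$ and the outcome
effect $\hat\Gamma_j$ with standard error $\sigma_{\Gamma j}$, both on the
log-odds scale for binary traits. A valid instrument must satisfy three
assumptions: it is associated with the exposure (relevance), it is
independent of confounders of the exposure–outcome relationship
(independence), and it affects the outcome only through the exposure
(exclusion restriction). Under these, each SNP's Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ estimates the same causal effect
$\beta$, and the estimators below pool the ratios with different robustness
trade-offs.

## Instrument selection

`select_instruments()` applies five filters in a fixed order, with an audit
of per-stage counts and per-SNP drop reasons:

1. **Genome-wide significance**: exposure $p < 5\times10^{-8}$ (strict
   inequality).
2. **LD clumping**: greedy pruning at $r^2 < 0.01$ within a 10,000 kb
   window. The SNP with the smallest p-value becomes an index; every
   remaining SNP on the same chromosome within the window with
   $r^2 \ge 0.01$ against it is removed; repeat on the survivors. Ties on
   p-value are broken by position and then SNP id so results are identical
   across platforms.
3. **Instrument strength**: per-SNP
   $F = \frac{N-K-1}{K}\frac{R^2}{1-R^2}$ with $K = 1$; SNPs with $F < 10$
   are excluded. By default $R^2$ is estimated from the z-score,
   $R^2 = z^2/(z^2 + N - 2)$, which needs no allele frequency; a
   frequency-based mode ($R^2 = 2\,\mathrm{eaf}(1-\mathrm{eaf})\beta^2$) is
   available when frequencies are present. Published per-SNP F values
   cannot generally be regenerated from printed $\beta$ and SE columns
   alone (they depend on unreported allele frequencies and covariate
   adjustment), so F agreement with any specific publication is treated as
   an order-of-magnitude statement, not a test target.
4. **Palindrome exclusion**: A/T and C/G SNPs are removed outright, with no
   frequency-based strand inference. Harmonization *also* drops palindromic
   SNPs unconditionally, so the guarantee holds regardless of whether a
   pre-filter ran; the selection-stage filter exists so that the audit
   records the exclusion where the analysis plan places it.
5. **Confounder exclusion**: SNPs with a reported association at
   $p < 1\times10^{-5}$ with a known confounder (viral hepatitides, alcohol
   consumption, diabetes, obesity, autoimmune and cholestatic liver
   disease, Wilson's disease, rheumatoid arthritis, cholesterol traits) are
   removed by exact id match against a local confounder table; no web
   lookup is performed.

## Harmonization

`harmonize()` aligns outcome records onto the exposure's effect-allele
frame: identical allele pairs are copied; swapped pairs have the outcome
beta negated and frequency complemented; pairs matching only after strand
complement are complemented first (attempted only when direct and swapped
matches both fail, to minimize silent mis-alignment); anything else is
dropped with a logged reason. The operation is idempotent, and jointly
flipping a SNP's alleles and effect sign in the input leaves the harmonized
effects unchanged.

## The five estimators

All estimates are carried on the log-odds scale; odds ratios and 95%
confidence intervals $\exp(\hat\beta \mp 1.96\,\mathrm{SE})$ are attached
only at reporting.

**Inverse-variance weighted (IVW).** With weights
$w_j = \sigma_{\Gamma j}^{-2}$,
$\hat\beta = \sum w_j \hat\gamma_j \hat\Gamma_j / \sum w_j \hat\gamma_j^2$
(weighted regression through the origin), fixed-effects
$\mathrm{SE} = (\sum w_j \hat\gamma_j^2)^{-1/2}$. Cochran's
$Q = \sum w_j (\hat\Gamma_j - \hat\beta\hat\gamma_j)^2$ on $J-1$ df decides
the variant: when its p-value is below 0.05 the SE is multiplied by
$\max(1, \sqrt{Q/(J-1)})$ (multiplicative random effects — the SE never
shrinks below the fixed-effects SE); otherwise the fixed-effects SE is
reported. IVW is the primary method; p-values are two-sided normal.

**MR-Egger.** Weighted least squares of $\hat\Gamma_j$ on $\hat\gamma_j$
with a free intercept, after orienting every SNP so $\hat\gamma_j \ge 0$.
The slope estimates $\beta$ under the InSIDE assumption (instrument
strength independent of direct effects); the intercept estimates the mean
directional pleiotropic effect. Standard errors carry the same
$\max(1, \sqrt{Q_E/(J-2)})$ over-dispersion factor and inference uses a
t-distribution with $J-2$ df, reflecting the two-parameter fit at small
$J$.

**Weighted median.** Ratios sorted ascending; normalized inverse-variance
weights $w'_j$; cumulative midpoints $s_j = \sum_{k\le j} w'_k - w'_j/2$;
the estimate interpolates $(s_j, \hat\beta_j)$ linearly at 0.5. With equal
weights this reduces exactly to the sample median. Consistent while valid
instruments carry more than half the total weight.

**Weighted and simple mode.** Kernel-smoothed mode of the ratios with
bandwidth $h = \phi \cdot 0.9\,\min(\mathrm{sd},
1.4826\,\mathrm{mad})\,J^{-1/5}$ (the smaller scale estimate; if one of the
two is zero the other is used, and if all ratios coincide the common value
is returned directly). The density is evaluated on a fixed 512-point grid
spanning $[\min\hat\beta_j - h, \max\hat\beta_j + h]$ and the estimate is
the grid argmax, first point on ties — a deterministic rule independent of
platform optimizers. The weighted mode weights each ratio by
$\mathrm{se}_j^{-2}$, the simple mode equally.

Standard errors for the median and modes come from a parametric bootstrap:
effects are redrawn from
$N(\hat\gamma_j, \sigma_{\gamma j}^2)$ and
$N(\hat\Gamma_j, \sigma_{\Gamma j}^2)$, the point estimate (including
ratio weights and bandwidth) is recomputed, and the SE is the standard
deviation over replicates. The default is 1000 replicates under an
explicit seed; the panel runner derives a named RNG substream per method
from one global seed, so full runs are bit-reproducible. The bootstrap
count, bandwidth multiplier $\phi = 1$ and grid size are configuration
defaults of this package, declared rather than inherited from any
publication.

## Sensitivity suite

* **Cochran's Q** for the IVW fit ($J-1$ df) and the Egger fit ($J-2$ df),
  upper-tail chi-square p-values. Adding a free intercept cannot increase
  the weighted residual sum, so $Q_{Egger} \le Q_{IVW}$ on identically
  oriented data — asserted as a property test.
* **Egger intercept test**: two-sided t-test of the intercept on $J-2$ df;
  "no directional pleiotropy" when $p \ge 0.05$.
* **MR-PRESSO**: the observed residual sum of squares
  $\sum_j w_j(\hat\Gamma_j - \hat\beta_{-j}\hat\gamma_j)^2$ (leave-one-out
  IVW slopes $\hat\beta_{-j}$) is compared against a Monte-Carlo null in
  which effects are redrawn around the no-pleiotropy model; the global
  p-value uses the add-one rule $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$ and
  is therefore bounded below by $1/(n_{sim}+1)$. Per-SNP outlier p-values
  use each SNP's simulated residual distribution with the same add-one
  rule (keeping them in $(0,1]$), Bonferroni-adjusted across $J$; flagged
  SNPs trigger an outlier-corrected IVW estimate and a distortion test
  comparing the raw-vs-corrected slope change against slope changes over
  1000 random subsets of the same size. Defaults ($n_{sim} = 1000$,
  flagging threshold 0.05, Bonferroni) are package configuration with
  documented defaults. The distortion test is reported only when outliers
  exist.
* **Leave-one-out**: the IVW estimate recomputed $J$ times with one SNP
  excluded each time (IVW only, as the primary method).

The pipeline applies the fixed/random IVW rule automatically but reports
both standard errors, and treats $p < 0.05$ as suggestive significance
with no multiple-testing correction across exposures — raw p-values are
reported as such.

## What the synthetic generator emulates — and what it does not

`simulate_two_sample_study()` produces paired exposure/outcome summary
statistics with known truth. Defaults are the study conditions of the
angina–hepatic-failure setting: exposure GWAS of 9481 cases / 446,987
controls, outcome GWAS of 464 cases / 213,592 controls, true causal effect
$\beta = 0.72$ (odds ratio $\approx 2.05$), per-SNP standard errors from
the binary-trait approximation
$\sigma^2 = 1/(n\,v\,2\,\mathrm{maf}(1-\mathrm{maf}))$ with
$v = \mathrm{cf}(1-\mathrm{cf})$ the case-fraction variance factor — this
reproduces the 0.01–0.04 SE scale of genome-wide significant angina loci
without simulating individual-level data. True instrument effects
$\gamma_j \sim N(0, \tau^2)$, $\tau = 0.1$, are conditioned to exceed
genome-wide significance by exact inverse-CDF truncated-normal sampling
(distributionally identical to rejection sampling, with deterministic
runtime). The panel holds 500 SNPs in LD blocks of 5 with
$r^2 = 0.7^{|i-j|}$ within blocks and 0 across; 10% of SNPs receive
palindromic allele pairs; the outcome file's allele coding is swapped for
~30% of SNPs and strand-complemented for ~10%, so harmonization is
genuinely exercised.

Horizontal pleiotropy is injected on a configurable fraction of
instruments as $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ *defined on
the exposure-increasing allele orientation* (the outcome effect is
$\Gamma_j = \beta\gamma_j + \mathrm{sign}(\gamma_j)\,\alpha_j$). This is
the standard simulation convention: a nonzero $\mu_\alpha$ then shifts
every invalid SNP's ratio in the same direction (directional pleiotropy)
regardless of the arbitrary allele coding, while $\mu_\alpha = 0$ gives
balanced pleiotropy. Drawn this way, pleiotropy is independent of
instrument strength (InSIDE holds); the generator records the sample
correlation between $|\gamma_j|$ and $\alpha_j$ in the truth record and
warns when a draw happens to exceed $|r| \ge 0.2$ at $J \ge 30$ — a hard
error would be wrong, since with independent draws at $J = 30$ the
sampling standard deviation of that correlation is about 0.19. An
`inside_violation` switch makes $\alpha_j$ proportional to $|\gamma_j|$
for negative tests of MR-Egger.

Features of real data the generator does **not** emulate, and which
passing tests therefore say nothing about: LD partners of a causal variant
are drawn as nulls rather than showing correlated signal, so clumping is
exercised structurally but not against realistic shared association;
million-SNP panel scale (500 SNPs emulate structure, not cardinality);
imputation quality, covariate adjustment and sample overlap between
cohorts; population stratification. Real per-SNP SEs are matched in order
of magnitude only.

## Numerical and design choices

* **Degenerate inputs**: a single-SNP dataset reduces IVW to the Wald
  ratio with Q undefined and flagged; $\gamma_j = 0$ is a domain error for
  the ratio; methods needing $J \ge 3$ (median, modes, Egger,
  leave-one-out) or $J \ge 4$ (MR-PRESSO) are skipped with logged reasons
  rather than guessed at.
* **Palindrome handling order** is configurable in principle (filter at
  selection, at harmonization, or both); the default runs both, which is
  idempotent.
* **Seeding**: one global seed is split into named substreams (generator
  components, each bootstrap method, PRESSO, distortion test), so
  component-level results are individually reproducible and the full
  pipeline is a pure function of (inputs, config, seed) — reruns are
  byte-identical, which the suite asserts.
* **Validation problem sizes**: the test suite uses 500 replicates for
  parameter recovery (mean IVW estimate within $\pm 0.05$ of the true
  0.72; each estimator within 3 reported SE in $\ge 95\%$), 2000
  replicates for IVW type-I error (measured $\approx 0.040$, band
  0.03–0.07), 500 for Egger-intercept calibration, 200 each for the
  robustness and outlier-detection experiments — sizes chosen so the whole
  suite runs in a few minutes on one CPU while keeping Monte-Carlo error
  well inside the asserted bands.
* **Calibration design**: the Egger-intercept type-I simulation runs at
  $\beta = 0$. At $\beta \ne 0$ the intercept test inherits a small upward
  rejection bias from exposure measurement error (the NOME violation:
  regression dilution of the slope leaks $\beta(1-\lambda)\bar\gamma$ into
  the intercept); at the study's instrument strength this moves the
  empirical rate from 0.05 to roughly 0.06–0.08. That is a known
  limitation of MR-Egger, not of the implementation, and is why the null
  design isolates the intercept.
* **Robustness demonstration design**: 40% of instruments carry
  directional pleiotropy $\mu_\alpha = 0.3$, $\sigma_\alpha = 0.02$, with
  $J = 25$ and a precise outcome GWAS (20,000 cases), chosen from the
  analytic trade-off that the weighted median's quantile-shift bias
  ($\approx z_{0.83}\,\sigma_{ratio}$) must stay inside 3 bootstrap SE
  while the IVW bias $\mu_\alpha E|\gamma|/E[\gamma^2]$ must exceed 3 of
  its (random-effects-inflated) SE. Under these conditions the weighted
  median stays within 3 SE of truth in $\ge 90\%$ of replicates while IVW
  does not.

## Known limitations

No Steiger directionality filtering, multivariable MR, contamination
mixture, Rucker model selection or $I^2$ statistics; no VCF ingestion,
genome-build liftover or proxy-SNP lookup; LD matrices are inputs, never
computed from genotype panels; confounder screening is an exact-id match
against a local table. Reverse-direction analyses (outcome onto exposure)
are out of scope. Headline numbers from any specific published analysis of
real OpenGWAS/FinnGen extracts are not regenerable here, because they
depend on the original data downloads, an unnamed LD reference panel and
unreported Monte-Carlo settings; the validation targets in this package
are therefore property-based and simulation-based, computed entirely from
code in this repository.
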