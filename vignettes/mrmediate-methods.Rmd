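---
title: "Methods: two-sample MR with two-step mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with two-step mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model

`mrmediate` implements summary-statistic Mendelian randomization (MR) as a
two-step mediation pipeline. The motivating design is a study in which a
heritable exposure (for example genetically proxied telomere length) may act
on a binary disease outcome (for example anorexia nervosa) partly through a
panel of intermediate quantitative phenotypes (for example diffusion-MRI
white-matter measures), each available only as GWAS summary statistics.

The causal diagram is

```
G_a ──> X ──(theta1)──> M ──(theta2)──> Y (log-odds)
         └────────────(delta)──────────────┘
```

where `G_a` are the exposure's instruments. Step 1 estimates `b1` (exposure
to mediator) with the exposure's instruments; step 2 estimates `b2` (mediator
to outcome) with the *mediator's own* instruments; the mediated (indirect)
effect is the coefficient product `b1 * b2`, tested with the Sobel statistic

$$S = \sqrt{b_1^2 s_2^2 + b_2^2 s_1^2}, \qquad Z = \frac{b_1 b_2}{S},$$

with a symmetric 95% interval `b1 b2 ± 1.96 S`. A linear "compatibility"
form of `S` (`b1 s2 + b2 s1`) is available behind `se_form = "linear"` for
comparison with older descriptions of the test; it is not a valid standard
error (it does not transform correctly under rescaling of either path) and
is never used by the pipeline.

# Instrument selection

`run_mr()` applies, in order: genome-wide significance (`p < 5e-8`, strict
inequality); greedy LD clumping (r² < 0.001 within 10,000 kb, best p-value
first, ties broken by position then identifier); exclusion of instruments
genome-wide significant for the outcome; exclusion of instruments linked to
listed confounder traits through an offline lookup table (case-insensitive
substring matching — the offline counterpart of interactive variant-trait
catalogue queries); and the weak-instrument filter `F > 10` with

$$F = \frac{R^2 (N - K - 1)}{K (1 - R^2)}, \qquad K = 1.$$

Because public summary statistics rarely report per-SNP variance explained,
`R²` is estimated by the t-statistic approximation `t²/(t² + n − 2)`; an
`r2_snp` column, when supplied, takes precedence. Per-stage counts are
recorded so that `n_in = n_kept + n_dropped` at every filter.

Palindromic (A/T, C/G) variants are dropped by default; under
`infer_by_eaf` they are oriented by allele frequency only when both sides
fall outside `[0.42, 0.58]` (`eaf_window = 0.08`, the common two-sample-MR
convention), and dropped otherwise, including whenever a frequency is
missing — orientation cannot be inferred without it.

# Estimators and sensitivity analyses

The estimator suite follows the conventions of the standard two-sample MR
toolkits:

* **Wald ratio** for a single instrument, first-order delta SE by default
  (second-order available).
* **IVW**: weighted regression through the origin with weights `1/se_out²`;
  the multiplicative random-effects SE multiplies the fixed-effect SE by
  `max(1, sqrt(Q/(nsnp−1)))`. The pipeline reports the random-effects row
  when the Cochran Q p-value is below `alpha` (policy `auto_by_q`,
  configurable), mirroring the practice of recalibrating effect sizes under
  detected heterogeneity.
* **MR-Egger**: weighted regression with free intercept after orienting all
  exposure effects non-negative (the usual InSIDE convention); inference on
  slope and intercept uses t with `nsnp − 2` df and the same multiplicative
  residual scaling, floored at 1. The floor (shared with the widely used R
  implementations of these estimators) makes both Egger tests slightly
  conservative under exact homogeneity — the acceptance suite measures
  their empirical size rather than asserting exact nominality.
* **Weighted median**: interpolated order statistic at standardized
  cumulative weight 0.5; SE by seeded parametric bootstrap (default 1000
  resamples).
* **Simple/weighted mode**: kernel-density mode of the per-SNP ratios with
  a modified Silverman bandwidth `0.9 min(sd, mad) n^{-1/5}` times
  `bandwidth_factor` (default 1); SE by the same bootstrap.

P-values are normal for Wald/IVW/median/mode and t-based for Egger —
conventions, chosen where the analysis practice leaves them unstated.

Sensitivity diagnostics: Cochran's Q (always around the fixed-effect IVW
estimate, the standard definition), the Egger intercept test, leave-one-out
IVW with significance-flip flags, the Steiger directionality test, and
plot-ready funnel/scatter coordinate tables (the package deliberately emits
data, not figures, keeping the core free of plotting dependencies).

For Steiger, per-SNP r² on each side uses the same t-statistic
approximation, summed over instruments; Fisher z-transformed correlations
are compared with a two-sample z-test. For binary traits this r² is an
observed-scale approximation; the report labels it as such
(`r2_scale`) so liability-scale values can be substituted when available.

# Screening cascade

Step 1 passes a mediator only if the IVW *and* 2SLS p-values are below
`alpha` (the dual criterion) and the Egger intercept p-value is at least
`alpha` (pleiotropic mediators are excluded before step 2). Step 2 requires
a significant causal effect (Wald ratio when a single instrument survives,
IVW otherwise), no detected heterogeneity, and a Steiger verdict of
`"true"`. The final table keeps mediators passing both screens with Sobel
`p < alpha`. Reasons record the first failing rule.

Two deliberate choices: (i) screening is at nominal `alpha = 0.05`
throughout, matching the practice the pipeline reproduces; a
Benjamini–Hochberg mode would be a straightforward extension but is not the
default. (ii) The 2SLS clause needs individual-level data; when none is
supplied (`tsls = NULL` in `run_two_step()`), the screen runs with
`require_tsls = FALSE`, since a missing 2SLS would otherwise fail every
mediator as "incomplete". The proportion mediated `indirect/total` is
reported unconstrained — it may exceed 1 or be negative when signs oppose,
as is inherent to the coefficient-product definition.

# Synthetic cohorts

`build_scenario()` / `simulate_cohort()` generate disjoint exposure,
mediator and outcome cohorts (non-overlapping samples, as in a two-sample
design) from

$$X = \textstyle\sum_j a_j G_j + \varepsilon_x,\quad
  M = \theta_1 X + \sum_j (\gamma_j + b_j) G_j + \varepsilon_m,\quad
  \mathrm{logit}\,P(Y{=}1) = \alpha + \theta_2 M + \delta X.$$

Design choices, fixed once:

* **Sizes.** 20,000 individuals per cohort; 50 exposure instruments and 50
  mediator-specific instruments. `exposure_h2 = mediator_h2 = 0.15`, giving
  per-instrument F statistics around 60 — comfortably above the weak-
  instrument cutoff and inside the per-IV F range reported for real
  telomere-length instrument sets (roughly 30 to 1600).
* **Effect-allele coding.** Instrument effects are |N(0, s)|, i.e. effect
  alleles are coded trait-increasing, the usual GWAS reporting convention;
  this is also what makes "directional" pleiotropy directional on the ratio
  scale.
* **Mediator panel.** Each mediator trait carries its own instruments
  (`b_j`), because a step-2 MR instruments the mediator with the mediator's
  genome-wide hits, not the exposure's. Without this panel, step-2
  instruments would have per-SNP F near 10 and regression dilution would
  dominate the mediated-effect estimate.
* **Binary outcome.** Generated through a logistic link (equivalently, a
  liability threshold with logistic errors), so `theta2` and `delta` are
  log-odds effects on the same scale the per-SNP logistic scan estimates.
  Marginal per-SNP fits still attenuate slightly through non-collapsibility
  of the odds ratio (about 4% at `theta2 = 0.5` with unit mediator
  variance); the acceptance suite measures the resulting downward bias of
  the indirect effect rather than hiding it.
* **Prevalence 0.25**, the case fraction typical of large psychiatric
  case-control GWAS.
* **Per-SNP scan.** Continuous traits: closed-form OLS, vectorised. Binary
  traits: a one-iteration score approximation to the logistic fit (exactly
  calibrated under the null; indistinguishable from full IRLS at per-SNP
  GWAS effect sizes — the suite verifies both claims), with `method =
  "glm"` for the full fit. This is what keeps 1000-replicate calibration
  studies tractable on one CPU.
* **Presets.** `mediated` uses `theta1 = 0.4`, `theta2 = 0.5` (true
  indirect 0.2); `direct_only` uses `delta = -0.161`, a protective log-odds
  effect of the size the motivating application reports; `pleiotropic`
  places directional direct-on-mediator effects U(0, 0.04) on every
  instrument (detectable by the Egger intercept while modest relative to
  the instrument effects); `heterogeneous` uses balanced N(0, 0.05)
  effects; `reverse` routes causality outcome-to-exposure with
  `theta_rev = 0.25`, a moderate reverse effect chosen (by power analysis
  at the default sizes) to make the reversed Steiger verdict decisive. The
  robustness comparison of weighted median versus IVW overrides the
  pleiotropic preset to 30% invalid instruments with constant direct effect
  0.1, the classic minority-invalid configuration.
* **LD.** Optional equicorrelated blocks through a Gaussian copula on
  haplotype alleles, with the latent correlation calibrated (tetrachoric
  integral, bisection to 1e-6) to the requested within-block dosage r²;
  calibration tolerance ±0.05. Default is no LD: clumping logic is
  exercised against explicit LD matrices in the tests instead.
* **Seeding.** One integer seed per scenario; the generator restores the
  caller's RNG state. Pipeline bootstraps derive child seeds
  deterministically from the run seed.

The generator emulates the *statistical* structure of the real inputs —
non-overlapping cohorts, a polygenic continuous exposure, continuous
mediators, a binary outcome on the log-odds scale, configurable pleiotropy,
heterogeneity and reverse causation. It does not emulate realistic allele-
frequency spectra, genome maps, population stratification or sample overlap,
so passing tests demonstrate correctness of the estimators and screens under
the stated model, not robustness to those additional features of real data.

# The screening fixture

`build_mediation_fixture()` constructs, at the summary-statistic level, a
complete synthetic input set with known screening truth: 3 true mediators,
2 with designed step-1 directional pleiotropy, 2 with designed step-2
heterogeneity, 3 null. Perturbations are small alternating-sign fractions
of the standard errors, so every verdict is decisive rather than borderline,
and each designed effect is sized to stay clear of the neighbouring
thresholds (for example, the pleiotropy shift 0.03 trips the intercept test
without pushing any single SNP past the outcome-association exclusion).
All numbers are designed; nothing in the fixture derives from real GWAS
data.

# Problem sizes used by the test and acceptance suites

Calibration: 1000 replicates of the null preset (two cohorts of 20,000, 50
instruments). Recovery: 200 replicates of the mediated preset. Robustness,
directionality and 2SLS/IVW concordance: 100–200 replicates each. These
sizes keep the full suite within a few minutes on one CPU while leaving
Monte-Carlo error well below the asserted margins.

# Known limitations

* Mode-estimator bandwidth and bootstrap defaults follow the common
  implementations; mode estimates are sensitive to `bandwidth_factor` on
  small instrument sets.
* Steiger r² for binary traits is an observed-scale approximation.
* The proportion mediated inherits the instability of ratio estimands when
  the total effect is near zero.
* No MR-PRESSO-style outlier correction, multivariable MR, or
  multiple-testing control across mediators (by design, see above).
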