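---
title: "Bayesian profiling of maternal mental health across genetic syndromes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian profiling of maternal mental health across genetic syndromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayeswell)
library(dplyr)
```

## The scientific problem

Mothers of children with rare genetic syndromes report levels of stress and
depression that are poorly characterised relative to the well-studied autism
(ASD) population. `bayeswell` implements a three-stage Bayesian workflow for
comparing maternal well-being across many small syndrome groups against an
ASD reference group, on four questionnaire scales:

* **PGS** — Positive Gain Scale, 7 Likert items (1–5), reverse coded so
  higher totals (7–35) mean more perceived positive gain;
* **PAS5** — 5-item short Positive Affect Scale (totals 5–25);
* **HADS-D** — the 7-item depression subscale of the Hospital Anxiety and
  Depression Scale (items 0–3, totals 0–21; totals above 7 are
  conventionally clinically significant);
* **QRSF** — 7 true/false items from the Questionnaire on Resources and
  Stress short form; the stress score is the count of "true" (0–7).

Small, unbalanced groups (6 to just over 100 mothers per syndrome) make
frequentist per-group contrasts fragile. The Bayesian treatment shares a
common error variance, shrinks syndrome differences toward zero through an
informative prior, and reports whole posterior distributions rather than
point verdicts.

## Stage 1: prior-specified linear regression

For each continuous measure \(y\),

\[
y \sim N(X\beta, \sigma^2), \qquad
X\beta = \beta_{\mathrm{ASD}} + \beta_{\mathrm{diff}[g]},
\]

where the ASD reference level carries a measure-specific informative prior
\(\beta_{\mathrm{ASD}} \sim N(\eta_A, \varepsilon_A^2)\) — depression
\(N(7.6, 0.5^2)\), positive gain \(N(21, 2^2)\), positive affect
\(N(15, 0.5^2)\) — every syndrome-difference coefficient is shrunk by
\(\beta_{\mathrm{diff}} \sim N(0, 2^2)\), and
\(\sigma^2 \sim \mathrm{InvGamma}(0.001, 0.001)\) with shape/scale read
directly as printed (a `halved` switch accepts the halved convention some
software uses). The posterior is simulated by a two-block Gibbs sampler
(`gibbs_linreg()`): a multivariate-normal draw of \(\beta\) given
\(\sigma^2\), then an inverse-gamma draw of \(\sigma^2\) with shape
\(\nu + n/2\) and scale \(\omega + \mathrm{RSS}/2\). With zero data rows the
sampler returns exact prior draws, which is one of the package's
calibration checks.

Derived quantities:

* `prob_difference()` — the **posterior probability of difference** from
  ASD, defined here as the larger one-sided tail probability of the
  difference coefficient. The source analysis never formalises this
  quantity; this definition is chosen because it is 0.5 for a group
  posterior-identical to ASD and approaches 1 for clearly separated groups,
  matching how the published table behaves.
* `prob_clinical()` — the posterior predictive probability that a new
  mother in a group scores above the HADS-D clinical cut-off (default 7,
  the upper end of the conventional "normal" band 0–7). Both a fully
  integrated mode (averaging over \(\sigma^2\) draws) and a plug-in mode
  (posterior-mean predictive sd) are provided because either could stand
  behind a published "risk of being clinically depressed"; they differ
  negligibly at this sample size.
* `group_by_similarity()` — a deterministic greedy agglomeration of groups
  ordered by posterior mean, merging while all pairwise difference
  probabilities stay below 0.9. Published figures shade such groupings
  without formalising them; the threshold matches the convention that a
  difference probability of 0.9 is "credible" and is configurable.

```{r stage1, eval = FALSE}
cohort <- simulate_cohort(cohort_config(), seed = 1)
fit <- fit_stage1(cohort, "hads", iterations = 20000, burn_in = 2000)
summarise_posterior(fit)      # 20/50/80/90% central intervals
prob_clinical(fit, "SMS")     # clinical-depression risk
autoplot(summarise_posterior(fit))
```

## Stage 2: CART covariate factorisation

Continuous covariates (child age, maternal age, Wessex self-help score) are
unlikely to act smoothly; the workflow instead discovers coarse
dichotomies with a regression tree (`fit_tree()`) and hands the resulting
indicators (e.g. child age ≤ 8 vs > 8) to the model-averaging stage.
The tree is deliberately minimal: binary recursive partitioning minimising
within-node sum of squares, splits placed **at observed covariate values**
(so a generating step at age 8 is recovered as exactly 8, not an
interpolated midpoint), ties broken toward the smaller threshold and then
covariate order, no pruning. Defaults — depth 3, minimum leaf 20,
minimum improvement 1% of the parent node's sum of squares — are chosen to
produce the coarse, stable dichotomies the analysis needs rather than a
predictive tree; they are all settable via `tree_params()`.

## Stage 3: Bayesian model averaging

Candidate predictors — syndrome-partition indicators from the stage-1
similarity clusters, CART dichotomies, and their interactions (under strong
heredity) — define a model space that is enumerated exhaustively
(`enumerate_models()`, guarded at 20 candidates; the pipeline falls back to
main effects beyond 12 to keep enumeration tractable). Each model is scored
by a closed-form marginal likelihood under a Zellner g-prior on slopes with
reference priors on intercept and error variance and unit-information
\(g = n\); the model prior is uniform. Posterior model probabilities give
per-predictor **inclusion probabilities** and model-averaged coefficient
means/sds (`bma_fit()`). The original analysis used its software's default
priors, which are not reproducible exactly; with a different prior family
the numeric inclusion probabilities are comparable only qualitatively,
which is why the package's acceptance checks are property-based (exactness
against brute-force enumeration, discrimination between signal and null
predictors, consistency as \(n\) grows) rather than value-matching.

## Stress: ordinal probit by data augmentation

The 0–7 stress count is ordinal, so it is modelled with a latent-variable
probit (`fit_ordinal_probit()`): latent utilities are truncated-normal
given the category, coefficients are drawn under independent \(N(0, 10^2)\)
priors (the concrete quantification of "vague"), and each interior cutpoint
is uniform on its admissible interval. Identification fixes the latent
variance at 1 and the first cutpoint at 0. Two numerical choices matter in
practice:

* cutpoints are **initialised at the empirical quantile positions** of the
  observed category frequencies (shifted so the first is 0). The plain
  cutpoint update is a slow random walk; starting it at its stationary
  region removes the burn-in bias that a naive equally-spaced start shows
  at realistic sample sizes.
* the default schedule (50,000 iterations, thinning 10) is deliberately
  long for the same reason; a collapsed/hybrid cutpoint update is a noted
  extension point.

Empty categories draw their cutpoints from the admissible range between
neighbours, with a warning. `category_probs()` returns the
posterior-averaged category distribution for a covariate profile,
`posterior_median_rating()` its median and central 90% interval by CDF
inversion (an exactly split distribution reports the lower median), and
`age_trend_pvalue()` the smaller one-sided tail probability of a group's
total age slope — the package's concrete reading of the reported "Bayesian
posterior p-value", which the source does not define. Syndrome-by-age
interactions are included by default because opposite age trends across
groups are a finding of interest. A joint model over all groups is the
default; per-group fits can be run by subsetting the cohort.

## The synthetic cohort generator

No raw data are deposited for studies of this design, so the generator
(`generate_cohort()`) is a first-class module that emulates the published
study's structure: 14 groups (ASD reference, 66 dyads, plus 13 syndromes)
totalling 712 mother/child dyads, group-specific truncated-normal ages
(children truncated at 2 years, mothers at 18 — the published table gives
means and sds but no family), gender ratios, and ability profiles expressed
as the probability that the Wessex self-help score is at its maximum of 9.
The Rett syndrome ability entry is not published ("–"); the default of 0.10
at-maximum reflects the profound impairment typical of that syndrome. The
Wessex scale itself is represented as an integer 3–9 because only the
"at maximum vs below" contrast is used analytically; its true item anchors
are not published.

Item-level responses are produced by drawing a continuous latent scale
total (group mean + covariate effects + normal noise), randomised-rounding
it to an integer, and spreading the total uniformly over the scale's
per-item capacity. This construction makes the expected scale score equal
the configured latent mean *exactly* away from the scale bounds — the
property the parameter-recovery and coverage tests rely on — at the cost of
a mildly negative within-scale item correlation, so generated Cronbach
alphas are not calibrated to the published ones (the statistic itself is
implemented and tested against an independent KR-20 computation). Default
group effects are set to the published per-group posterior means (as latent
mean shifts from ASD), residual sds back-calculated from the published
interval widths (3.3/2.1/4.2 scale points for PGS/PAS5/HADS-D, 1.5 for the
latent stress total), and modest covariate effects matching the reported
directions (e.g. higher depression below the Wessex maximum concentrated
in the AS/FXS/PWS/TSC/PMS set; stress rising with child age except Soto,
AS and SMS). Missingness is 2% per item by default.

What passing tests on this generator do **not** show: real questionnaire
data have correlated item errors, floor/ceiling clustering, informative
missingness and family-level clustering, none of which are emulated.
Recovery and coverage results certify the inference machinery, not the
field validity of the instruments.

Scoring (`score_scales()`) reverse-codes the PGS, prorates scales with at
least 75% of items answered (mean of answered × item count, rounded half
up — the standard psychometric convention; the source states only the
exclusion rule), and leaves sparser scales missing. The 75% rule is applied
per scale (configurable), since the source does not say whether it was per
scale or per questionnaire pack. `apply_exclusions()` applies the study's
filters in their reported order — non-mother respondents, children under
2, under-75% completion, and SCQ totals **below** 15 (a total of exactly 15
is retained) wherever an SCQ was collected (the ASD group) — and attaches a
per-rule ledger.

## Orchestration and reproducibility

`run_pipeline()` runs stage 1 → CART → BMA for each continuous measure and
CART → ordinal probit for stress, writing per-measure report CSVs
(posterior means, 90% intervals, difference and clinical probabilities,
similarity cluster), CART split tables, BMA inclusion tables, stress
profile tables over group × Wessex × child age ∈ {8, 16}, and a plain-text
manifest. Every stage seed is derived deterministically from the master
seed by hashing the stage name (`derive_seed()`), so a single stage can be
re-run in isolation and match the full run; reruns are byte-identical.
A failing stage aborts with a stage-named error and the manifest marks the
run incomplete.

```{r pipeline, eval = FALSE}
cfg <- analysis_config(synthesis = cohort_config(), seed = 42)
res <- run_pipeline(cfg, "outputs")
res$reports$hads
```

## Problem sizes and numerical choices

The test-suite and acceptance runs use deliberately scaled problem sizes
chosen to keep every check sharp at desk scale: the sampler-versus-oracle
check uses \(n = 30, p = 2\) against an \(81^3\) dense-grid posterior;
prior recovery uses \(10^5\) draws; interval-coverage calibration uses 200
synthetic cohorts at the full 712-dyad layout with truths drawn from the
fitting prior (positive gain, whose scores stay far from the 7–35 bounds
so clamping cannot bias coverage); BMA exactness enumerates all \(2^5\)
to \(2^6\) models against an independent recomputation; ordinal recovery
uses \(n = 2000\) with known coefficients \((1.0, -0.5)\). Pipeline runs in
tests use shorter chains (1,100–8,000 iterations) than the 20,000/50,000
defaults; determinism and schema properties do not depend on chain length.

Other numerical conventions: credible intervals are equal-tailed sample
quantiles (R type 7); a degenerate posterior predictive exactly at the
clinical cut-off counts ½; `prob_difference` with an empty tail reports
exactly 1; inverse-gamma draws are clamped away from numerical zero and
infinity so prior-only chains remain finite; the collinearity guard inside
BMA drops rank-deficient models and renormalises with a warning.

## Known limitations

* The BMA inclusion probabilities depend on the g-prior choice; only their
  qualitative ordering should be compared with analyses run under other
  default priors.
* The plain single-site cutpoint update mixes slowly for long ordinal
  scales; the long default schedule compensates but a collapsed update
  would be the proper fix.
* Dyads are generated independently — no family clustering or shared-rater
  effects.
* No imputation beyond scale proration; complete-case analysis per
  measure means different measures may use slightly different subsamples.
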