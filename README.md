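# bayeswell

Bayesian modelling of maternal mental health and well-being across rare
genetic syndrome groups, benchmarked against an autism (ASD) reference
group.

Mothers of children with rare genetic syndromes (Angelman, Cornelia de
Lange, Down, Fragile-X, Phelan-McDermid, Prader-Willi, Rett,
Rubinstein-Taybi, Smith-Magenis, Sotos, Tuberous Sclerosis Complex, 1p36
and 8p23 deletion syndromes) complete four questionnaire scales — the
Positive Gain Scale (PGS, 7–35), a 5-item Positive Affect Scale (PAS5,
5–25), the HADS depression subscale (0–21), and a 7-item true/false stress
scale (0–7). Group sizes are small and unbalanced, so the package analyses
each measure with a prior-specified Bayesian workflow rather than per-group
tests:

1. **Stage 1 — Bayesian linear regression** on syndrome group with ASD as
   the base level, fitted by a two-block Gibbs sampler:

   ```
   y ~ N(Xβ, σ²),   Xβ = β_ASD + β_diff[group]
   β_ASD ~ N(η_A, ε_A²)      (depression 7.6/0.5, PGS 21/2, PAS5 15/0.5)
   β_diff ~ N(0, 2²)         σ² ~ InvGamma(0.001, 0.001)
   ```

   with posterior means, nested 20/50/80/90% credible intervals,
   probabilities of difference from ASD, posterior-predictive
   clinical-depression risk P(y_new > 7), and a similarity partition of
   groups.

2. **Stage 2 — CART**: a deterministic regression tree dichotomises child
   age, maternal age and the Wessex self-help ability score at observed
   values (e.g. child age ≤ 8 vs > 8).

3. **Stage 3 — Bayesian model averaging** over syndrome partitions,
   CART-derived dichotomies and their interactions, by exact enumeration
   under a Zellner g-prior (g = n), yielding posterior inclusion
   probabilities and model-averaged coefficients.

The 0–7 stress score is ordinal and is fitted instead by an **ordinal
probit regression** with truncated-normal data augmentation (latent
utilities, vague N(0, 10²) slope priors, uniform cutpoint updates), giving
posterior population stress ratings per group × ability × child-age
profile and Bayesian posterior p-values for age trends.

Because raw questionnaire data of this design are not publicly deposited,
the package ships a first-class **synthetic cohort generator** emulating
the study layout (14 groups, 712 mother/child dyads, per-group age/gender/
ability profiles, item-level responses with configurable effects and
missingness), plus the study's scoring and exclusion rules, so every stage
is verifiable by parameter recovery, interval coverage, and oracle
equivalence.

## Worked example

```r
library(bayeswell)

cohort <- simulate_cohort(cohort_config(), seed = 1)   # 712 dyads, 14 groups
fit <- fit_stage1(cohort, "hads", iterations = 20000, burn_in = 2000,
                  seed = 1)
summarise_posterior(fit)
```

```
   term   mean lower_90 upper_90
 1 ASD    6.92     6.43     7.41
 2 AS     5.75     4.59     6.90
 3 CdLS   6.98     6.05     7.92
 4 DS     4.46     3.34     5.58
 ...
10 SMS    6.58     5.26     7.89
13 1p36   7.42     6.25     8.60
```

Each row is a group's posterior mean depression score with its 90%
credible interval: in this synthetic cohort the ASD, CdLS and 1p36 mothers
sit highest, the Down-syndrome group lowest — the pattern the generator's
defaults encode. Derived quantities:

```r
prob_clinical(fit, "ASD")   # 0.492  P(new ASD mother scores above 7)
prob_clinical(fit, "DS")    # 0.261
prob_difference(fit, "SMS") # 0.661  posterior prob. SMS differs from ASD
group_by_similarity(fit)    # 3 clusters: {DS,FXS,TSC,PWS} < {...} < {ASD,CdLS,1p36}
```

So roughly half of ASD-group mothers are expected above the clinical
depression cut-off versus a quarter of Down-syndrome mothers, and the
groups partition into three posterior-similarity bands.

The full three-stage pipeline (and the ordinal stress stage) with
deterministic per-stage seeding:

```r
cfg <- analysis_config(synthesis = cohort_config(), seed = 42)
res <- run_pipeline(cfg, "outputs")   # report_*.csv, cart_*.csv, bma_*.csv,
res$reports$hads                      # stress_profiles.csv, manifest.txt
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/bayeswell-cli.R` (subcommands `simulate`, `fit-stage1`,
`fit-cart`, `fit-stress`, `run-all`).

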