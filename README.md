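# healthindex3

`healthindex3` computes a **3-item composite health index (HI)** for older
adults and evaluates it against mortality outcomes. The index combines three
objective physiological measurements, one per core system:

- **Cardiovascular** — sample entropy (SampEn) of the resting-state
  beat-to-beat systolic blood pressure series (irregularity of autonomic
  blood-pressure control);
- **Neurocognitive** — the number of bad performances (NBP) in the Sustained
  Attention to Response Task (SART);
- **Locomotor** — usual gait speed (UGS, cm/s).

Each component is min–max normalised against a reference cohort (gait speed
inverted, since slower is worse) and the three normalised values are averaged
with equal weight, giving an index on [0, 1] where higher means worse health.
Risk groups (Low / Medium / High) are read off the index either at fixed
cut-offs (defaults 0.45 and 0.65) or by a data-driven grid search over
univariate Cox proportional-hazards models. The package is aimed at clinical
researchers who have these three measurements per subject plus survival
follow-up, and at methodologists who want to stress-test the pipeline on
synthetic cohorts.

## The statistics at the core

**Sample entropy.** For a series of length *N*, let *B<sup>m</sup>(r)* be the
average fraction of length-*m* template vectors within Chebyshev distance
*r*·SD of each template (self-matches excluded, each count divided by
*N − m − 1*), and *A<sup>m</sup>(r)* the same for length *m + 1*. Then

> SampEn(m, r, N) = −ln( A<sup>m</sup>(r) / B<sup>m</sup>(r) ),

with defaults m = 1, r = 0.4, computed over the final 60 s of supine rest.

**SART scoring.** 23 cycles of the digits 1–9 (207 trials); respond to every
digit except 3. A cycle is a *bad performance* when it contains ≥ 2 mistakes
(commission: press on 3; omission: no press on a GO digit) out of its 9
actions; NBP is the number of bad-performance cycles (0–23).

**Risk stratification.** For each candidate cut-off *c* in {0.2, 0.225, …,
0.65}, a univariate Cox model of the indicator `hi >= c` is fitted; the
selected cut-off minimises the p-value (ties: larger hazard ratio, then
smaller *c*). A second pass above the first cut-off separates Medium from
High risk. Evaluation uses Cox hazard ratios (unadjusted and fully adjusted),
right-censoring at the end of follow-up, cause-specific endpoints
(cardio-respiratory deaths, other causes censored), and the nonparametric
ROC AUC of the index for the binary died-by-end-of-follow-up label.

## Worked example

```r
library(healthindex3)

# A fully synthetic cohort: BP series, SART sessions, gait walks, covariates,
# and survival driven by the true index through a proportional-hazards model.
sim    <- simulate_cohort(cohort_sim_params(n_subjects = 500), seed = 42)
cohort <- sim$cohort

head(cohort[, c("subject_id", "sampen", "nbp", "ugs", "hi", "risk_group")], 4)
#>   subject_id sampen   nbp   ugs    hi risk_group
#> 1 S0001       1.12      5  89.4 0.630 Medium
#> 2 S0002       0.701     1 133.  0.329 Low
#> 3 S0003       0.804     9 133.  0.475 Medium
#> 4 S0004       0.744     2 134.  0.354 Low

fit <- fit_cox(cohort, "risk_group")   # all-cause mortality, unadjusted
tidy(fit)
#>   term             level     hr ci_low ci_high      p
#> 1 risk_groupMedium Medium  2.15  1.16     3.98 0.0152
#> 2 risk_groupHigh   High    2.95  0.901   9.64  0.0738

roc_auc(cohort, "hi")                               # 0.662
roc_auc(cohort, "hi", endpoint = "cardio_respiratory")  # 0.724
```

Subjects in the Medium/High groups die at a substantially higher rate than
Low-risk subjects (hazard ratios above), and the continuous index
discriminates 12-year mortality clearly better than chance, more strongly so
for cardio-respiratory deaths — the qualitative behaviour the index is
designed to show. `autoplot()` methods exist for cut-off scans, ROC curves
and Cox fits; `plot_hi_distribution()` shows the index histogram with group
boundaries.

A command-line interface wrapping the same functions ships in
`inst/cli/healthindex` (subcommands `simulate`, `compute-hi`,
`derive-cutoffs`, `evaluate`; exit codes 0/2/3 for success / validation
failure / fitting failure).

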