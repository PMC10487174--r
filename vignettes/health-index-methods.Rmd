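---
title: "Methods: the 3-item health index pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the 3-item health index pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthindex3)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the design choices made where the procedure was
genuinely open, and what the synthetic-cohort tests do and do not demonstrate.

## The composite index

The 3-item health index aggregates one objective marker per physiological
system: sample entropy of resting-state beat-to-beat systolic blood pressure
(cardiovascular regulation), the number of bad performances in the Sustained
Attention to Response Task (neurocognition), and usual gait speed
(locomotion). Each component is min–max normalised against a reference
cohort's full observed range, with gait speed inverted so that for every
component 0 is the best observed extreme and 1 the worst, and the index is
the unweighted mean of the three normalised values. Equal weighting and
plain min–max scaling are the simplest scheme consistent with a composite on
[0, 1] whose extremes are attained at the cohort's best and worst profiles;
the normalisation is isolated in `normalize_component()` so an alternative
formula is a one-point change. New subjects falling outside the reference
range are clamped to [0, 1] with a warning rather than extrapolated, keeping
the composite in range at the cost of saturating beyond the reference
extremes.

## Sample entropy

`sample_entropy(x, m = 1, r = 0.4)` follows the standard template-matching
estimator: both the length-`m` and length-`m + 1` match fractions average
over template start positions `i = 1..N - m`, each per-template count is
divided by `N - m - 1`, and self-matches are excluded. Numerical choices:

- **Distance metric.** Chebyshev (max-norm) over template components, the
  convention of the reference implementations of this estimator.
- **Tolerance.** `r` multiplies the standard deviation of the analysed
  window, making the statistic invariant under translation and positive
  rescaling of the series. The SD is the *population* SD (divisor `N`) by
  default; the estimator is only weakly sensitive to this, but the choice is
  configurable (`sd_type = "sample"`) and documented because the convention
  differs between implementations.
- **Closed ball.** Similarity is `distance <= tolerance`. A constant series
  (SD 0, tolerance 0) therefore still self-matches exactly and scores 0, the
  natural limit for a perfectly regular signal.
- **Undefined values.** When no template pair matches at either length the
  log-ratio is undefined; the function returns `NA` with a classed warning
  rather than an arbitrary number, and cohort-level wrappers carry a
  `defined` flag so exclusion is explicit and itemised.

The resting-state window is the final 60 s of the recording, selected by
timestamp when beat times are present. The lower boundary is closed
(`time >= t_max - 60`), so a recording spanning exactly 60 s is used whole.
Without timestamps the window is the last `round(60 * beat_rate)` beats with
a configurable expected beat rate (default 1 beat/s); series shorter than
the window raise an insufficient-data error, never a silent truncation. Raw
beat values are used as loaded — no interpolation, artifact rejection or
detrending is applied before entropy computation.

## SART scoring

A session is 23 cycles of the digits 1–9 (207 trials), GO on every digit
except 3. A reaction time of 0 encodes "no key press"; any positive reaction
time is a response, with an optional anticipation filter (`min_rt_ms`,
default off) that reclassifies implausibly fast presses as non-responses.
One *bad performance* is a 9-trial cycle with at least 2 mistakes
(commissions plus omissions) out of its 9 actions — the "2 out of 9" rule
pins the scoring unit to the cycle, which is also what bounds the count at
23. Incomplete sessions are rejected by default; `allow_partial = TRUE`
scores only complete cycles and reports how many were used. A digit stream
that deviates from the repeating 1..9 pattern is flagged but scored from the
recorded digits, which stay authoritative row by row.

## Risk groups and evaluation

`derive_risk_groups()` implements the data-driven cut-off search: univariate
Cox models of the split `hi >= c` over the candidate grid 0.2–0.65 in steps
of 0.025, then a second pass for the Medium/High boundary. Open points and
how they are resolved:

- "Maximise the hazard ratio and minimise the p-value" is not a total order.
  The default rule is **minimal p-value**, ties broken by larger hazard
  ratio, then by smaller cut-off; `rule = "max_hr"` is available, and the
  full scan table is always returned so any other rule can be applied
  downstream.
- The second pass is restricted to subjects at or above the first cut-off,
  over grid candidates strictly above it; `second_stage = "full"` scans the
  whole cohort instead. Subsets below 20 subjects or 5 events report the
  second cut-off as unavailable rather than fitting on vapour.
- Candidates that leave one side empty of subjects or events, or where the
  partial-likelihood estimate runs away (monotone likelihood), are flagged
  unusable and kept in the table, never silently dropped.
- Group assignment uses half-open intervals with the boundary in the worse
  group: `hi = 0.45` is Medium, `hi = 0.65` is High.

Evaluation fits Cox models (Efron tie handling) with treatment contrasts
against the first exposure level, unadjusted or adjusted for age, sex,
education, BMI category, antihypertensive use, diabetes, number of
cardiovascular conditions, smoking and alcohol class. Subjects without an
event are right-censored at the end of their follow-up; the
cardio-respiratory endpoint treats deaths from other causes as censored at
the death time (cause-specific hazards — no subdistribution/Fine–Gray model
is attempted). The ROC AUC is computed for the *binary* died-by-end-of-
follow-up label of the chosen endpoint — not a time-dependent AUC — using
the continuous index by default, and equals the Mann–Whitney concordance
probability with tied pairs counting one half.

## The synthetic cohort generator

No individual-level data ship with the package, so `simulate_cohort()`
generates cohorts with the statistical structure the method consumes:

- **Blood pressure**: baseline (120 ± 15 mmHg between subjects) plus a slow
  sinusoidal oscillation (6 mmHg amplitude, 40 s period) plus stationary
  AR(1) noise (lag-1 correlation 0.5). The marginal noise SD is the
  irregularity knob: 1.5 mmHg at the median with a log-normal
  between-subject spread, which puts cohort sample entropy around
  0.65 ± 0.25 — the scale reported for community-dwelling older cohorts —
  and makes mean entropy strictly increasing in the noise knob. The
  noise-free limit is a smooth periodic series with entropy near zero.
- **SART**: per-trial omission probability 0.03 and commission probability
  0.45 at the median, each with logit-normal between-subject spread, GO
  reaction times normal (390 ± 80 ms, truncated at 150 ms). The per-cycle
  bad-performance probability then has a closed binomial form used as a test
  oracle; the implied cohort NBP distribution has median ≈ 3 with a long
  right tail.
- **Gait**: subject mean 136 ± 20 cm/s with 5 cm/s walk-to-walk noise.
- **Coupling**: a shared latent frailty factor correlates the three domains
  (default correlation 0.6), so the composite index is meaningful rather
  than the average of three independent noises.
- **Survival**: exponential proportional hazards, log-hazard linear in the
  *computed* index (slope 3 per index unit around a centre of 0.35) plus an
  age effect, baseline 0.008/year, administrative censoring at the 12-year
  horizon — roughly 10–14% cohort mortality. Optional planted step terms at
  chosen thresholds support cut-off-recovery experiments. Among deaths, the
  probability of a cardio-respiratory cause rises logistically with the
  index (so cardio-respiratory discrimination exceeds all-cause, as
  observed for this type of index); causes split 115:30 cardio:respiratory
  and 190:81 cancer:other.

The generator emulates the *statistical response surface* the pipeline
consumes — entropy responding to a noise-to-signal ratio, lapse rates
driving bad performances, proportional hazards in the index. It makes no
claim of physiological realism: there is no respiratory or baroreflex
structure in the BP model, no time-on-task fatigue in the SART model, no
informative censoring, and the components' joint distribution is a
single-factor Gaussian copula. Passing tests therefore demonstrate
correctness of the computational pipeline and recoverability of planted
effects under the stated models, not clinical validity on real cohorts.

## Verification strategy and problem sizes

- Entropy match fractions are compared *exactly* (identical doubles) against
  an independent brute-force double-loop enumeration on 200 random series of
  lengths 20–120, `m` in {1, 2}, `r` in 0.1–0.6.
- The AUC is compared exactly against an all-pairs concordance count with
  ties counted one half, on cohorts with deliberately tied scores.
- Cut-off recovery: 50 replicates of n = 2000 cohorts with a planted 3-fold
  hazard step at 0.45; the scan must land within one grid step in at least
  90% of replicates. Cox coverage: 50 replicates of a planted hazard ratio
  of 3 at n = 2000, with the 95% Wald interval required to cover the truth
  in at least 90%.
- End-to-end: one n = 2000 generated cohort must show a higher event rate in
  the Medium/High groups and an all-cause AUC above 0.5 at 99% confidence.

These sizes keep the whole suite around a minute on a single CPU while
leaving the Monte-Carlo margins wide relative to their binomial noise.

## Known limitations

- Reference ranges depend on the reference cohort's observed extremes, so
  indices computed against different cohorts are not directly comparable;
  persist ranges with `write_reference_json()` and reuse them for scoring.
- The published normalisation constants for the original cohort are not
  reproduced here; ranges must be fitted or supplied.
- The cut-off search inherits the instability of minimal-p selection in
  small strata; the scan tables and the size guards are the mitigation, not
  a cure.
- Competing risks are handled as cause-specific censoring only.
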