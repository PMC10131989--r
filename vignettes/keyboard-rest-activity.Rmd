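---
title: "Estimating rest-activity patterns from smartphone keyboard inactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rest-activity patterns from smartphone keyboard inactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kapsleep)
```

## The problem

Sleep timing and duration are usually tracked in the field with actigraphy or
morning sleep diaries. Both demand something of the participant; neither
scales to long observation windows over many people. Smartphone keyboards
offer a behavioral side channel: people type until shortly before they go to
bed and resume soon after they get up, so the *absence* of keystrokes at
night is a proxy for the rest period. `kapsleep` implements this proxy, the
matching diary-derived metrics, and the multilevel machinery needed to ask
how well — and for whom — the two modalities agree.

## The night axis

Every night-level time in the package is expressed in decimal hours since
12:00 noon of the night's *anchor date* (the evening the night begins): 7 PM
is 7.0, midnight 12.0, 3 PM the next day 27.0. This single monotone
coordinate removes all wrap-around arithmetic at midnight. Clock times
convert with a 15:00 boundary — times at or before 15:00 on a morning report
belong to the morning after the anchor, later times to the anchor evening —
because the nightly analysis window ends at 3 PM. Durations are always
computed on the absolute timeline, so a daylight-saving transition inside a
night yields elapsed hours, not wall-clock differences.

## Keyboard-derived estimates

For each participant-night, `extract_kap()` takes the events inside the
window from 7 PM to 3 PM the next day (night-axis `[7, 27]`, bounds
inclusive) and finds the longest gap between two consecutive keystrokes, the
*keystroke-absence period* (KAP). Its endpoints are the last-keystroke
(rest-onset) and first-keystroke (activity-onset) estimates; `kap_h` is the
gap length and `midpoint_kap` the midpoint, the keyboard analogue of
midsleep. Three choices deserve note:

* **Edge gaps are not candidates.** A KAP must be bracketed by keystrokes,
  because both endpoints are estimates of behavioral events. A night whose
  true rest extends past 3 PM is therefore mis-estimated; such nights
  surface as gross outliers and are left to the outlier rule.
* **Ties resolve to the earliest-starting gap**, which is deterministic and
  favors the nocturnal gap over a late-afternoon duplicate.
* **No minimum KAP duration is imposed.** The only screen is the pooled
  4-SD rule described below.

Nights with fewer than two in-window events are returned with
`valid = FALSE`, never as an error. `hours_with_activity()` counts the
distinct clock-hour bins of a calendar date containing at least one
keystroke; it is the day-level regularity covariate used in moderation
models. Counting calendar-hour bins makes the "between first and last
keystroke" qualification vacuous, so it is not separately enforced.

## Diary-derived estimates

`derive_diary_nights()` maps each morning report onto the night axis
(anchor = report date − 1) and derives: sleep onset = try-to-sleep +
latency; midsleep = (onset + offset) / 2; total sleep period = offset −
onset; total bed period = out-of-bed − bedtime. Midsleep is computed rather
than read, because the core consensus diary has no midsleep item. The
derivation is exact arithmetic: the test suite holds it to an independent
datetime-arithmetic oracle at 1e-9 hours. Ambiguous raw values (unparseable
clock strings, negative latencies) are coded missing on input with the row
retained; ordering violations after mapping (offset not after onset,
out-of-bed before bedtime) code only the affected derived fields missing.

**Outlier rule.** Before any modeling, each metric is screened with
`apply_outlier_rule()`: values more than 4 SD from that metric's pooled
mean (all participants and nights together) are coded missing. The rule is
applied per metric, pooled rather than per person, in a single pass without
re-iteration — the simplest reading of the rule; a per-person or iterated
variant would flag slightly different sets, and the choice is deliberately
conservative about discarding data.

## Agreement and equivalence

`pair_nights()` aligns the modalities into eight metric pairs (last
keystroke against bedtime, try-to-sleep and sleep onset; midpoint KAP
against midsleep; first keystroke against sleep offset and out-of-bed; KAP
against total sleep and total bed period), with `diff_h = keyboard − diary`
so negative values mean the keyboard estimate is earlier or shorter. A
night is a weekend night when its *morning* falls on Saturday or Sunday —
assignment by the sleep-offset day, since that is the day whose social
constraints (or their absence) shape the night.

`test_difference()` stacks the paired values in long format (two rows per
night) and fits `value ~ modality + (1 | participant)`. The modality
coefficient is the mean difference; the null test uses alpha = .01 (99% CI)
and equivalence uses the two one-sided tests criterion at the same alpha:
equivalence at Δ is declared when the 98% CI lies inside (−Δ, +Δ), with
Δ = 0.5 h and 1 h as the default bounds. Degrees of freedom are
Satterthwaite approximations throughout. Two caveats are intentional
properties of this design rather than oversights:

* There is no night-level random effect — only the participant intercept —
  so when the two modalities share night-to-night variation the model-based
  SE is *conservative* relative to a paired-difference analysis. The
  Monte-Carlo calibration (`tost_calibration()`) confirms the equivalence
  decision holds its size at the bound and its power at zero under this SE.
* `icc_unconditional()` reports the participant-level variance share from
  the intercept-only model; singular fits return ICC 0 with a flag.

`bland_altman_rm()` gives the repeated-measures agreement summary: bias
from the mixed model on the differences and limits of agreement
`bias ± 1.96·sqrt(var_between + var_within)` of the differences, so both
the person-level and night-level disagreement enter the limits.

## Association and moderation models

All association models grand-standardize outcome and predictor, so the
reported slope is a standardized β; REML estimation, Satterthwaite df and
99% CIs are used everywhere, with p between .01 and .05 read as a trend.
Because no single explained-variance definition is canonical for mixed
models, both the marginal (fixed-effects) and conditional (fixed + random)
ratios are reported.

Day-level predictors are cluster-mean centered with an empirical-Bayes
person mean: the fixed intercept plus the predicted random intercept from
the metric's own unconditional model. The person mean and the centered
deviation always reconstruct the observation exactly, and the person mean
enters every moderation model as a covariate, separating between-person
from within-person slopes. First-level moderation crosses the centered
keyboard metric with the (also cluster-mean-centered) hours-with-activity
count and with type of day. Random-slope models add a participant slope
for the centered score with unstructured intercept-slope covariance; the
likelihood-ratio test against the intercept-only model refits both by ML
and uses 2 df (slope variance + covariance). At the boundary (true slope
variance 0) this test is conservative, which the suite verifies by
simulation. Cross-level models add grand-mean-centered traits (chronotype
MSFsc, PSQI, trait self-control) as main effects and in interaction with
the centered keyboard score, after a pre-fit collinearity screen (pairwise
trait correlations and VIFs computed from the intended fixed-effects
design — before the fitter can silently drop rank-deficient columns).

## The synthetic cohort generator

Nothing in this package requires real data: `simulate_cohort()` generates
keystroke streams, diary reports and trait scores from a ground-truth
circadian model, and every downstream claim is tested against that truth
channel. The default configuration describes 157 participants over 7
nights starting Monday 2020-09-14, with:

* try-to-sleep ~ 00:30 population mean, person-level (chronotype) SD
  0.75 h against night-level SD 1.25 h — about a quarter of timing
  variance between persons; a 0.5 h weekend delay (deliberately modest, as
  under mild social restrictions); exponential pre-bed gap (mean 0.5 h),
  sleep latency (mean 16 min), rise lag (mean 0.5 h); sleep duration
  7.75 ± 0.8 h night-level with a 0.3 h habitual person offset.
* a homogeneous Poisson keystroke process during wake at 5 events/hour,
  with lognormal person- and day-level rate heterogeneity (SD 0.5 each):
  low-rate days have both fewer active hours and noisier keyboard
  estimates, which is the generative mechanism behind the
  hours-with-activity moderation.
* habitual perisleep behavior as a person trait: a mean-preserving
  lognormal multiplier on the pre-bed gap and rise lag and a Beta person
  propensity for in-bed use (typing until try-to-sleep, probability 0.7 on
  average). These put part of the keyboard-estimate variance between
  persons, as habitual phone use does.
* PSQI-driven nocturnal awakenings (0.2 per PSQI point per night), each
  emitting a 1-5 keystroke burst within 10 minutes with probability 0.15,
  at a uniform position in the sleep period. A burst splits the true rest
  gap, so the KAP algorithm returns the longer fragment — exactly the
  mechanism by which poor sleep quality should degrade the keyboard proxy.
  Raising the burst probability (e.g. to 1) makes within-person slopes
  attenuate visibly with PSQI, which the cross-level recovery test
  exploits; a mid-range awakening rate maximizes the PSQI *gradient*,
  since very high rates corrupt everyone's nights alike.
* diary reports = truth + Gaussian noise (SD 10 min) rounded to the diary's
  5-minute grid; PSQI ~ N(5.16, 2.27) rounded and clipped to 0-21, trait
  self-control ~ N(2.98, 0.56) clipped to 1-5; MSFsc derived from the
  person's own free-day midsleep plus report error.

A single master seed drives everything through deterministic
per-participant substreams, so identical configurations are byte-identical
and any subset of participants can be regenerated exactly.

**What the generator does and does not emulate.** It reproduces the
variance decomposition of timing metrics (ICCs ≈ 0.2-0.3), the lower — but
for the keyboard side higher-than-diary — duration ICCs, realistic means
(keyboard activity ≈ 14 h/day; KAP ≈ 8.6 h exceeding the reported sleep
period by ≈ 1 h), weekend delays in both modalities, and
stronger timing than duration associations. It does *not* emulate diurnal
typing profiles (the wake process is homogeneous), typing content or
inter-key dynamics, naps or split rest periods, app downtime, or DST
transitions; and the keyboard duration ICC stays below values reported for
real cohorts, because a homogeneous Poisson wake process cannot concentrate
more habit variance between persons without inflating night-level variance
alongside. Passing tests therefore demonstrate correctness of the
algorithms and calibration of the inference under this model, not
performance of keyboard monitoring on any real population.

## Numerical and design choices

* Degenerate nights in the generator (bedtime before the 7 PM window
  start, sleep under half an hour, out-of-bed past the 3 PM window end)
  are re-drawn with a bounded retry budget (100), then error.
* A participant who stays in bed past noon delays the start of the next
  day's wake segment, so no keystrokes are emitted while still in bed.
* Event timestamps live on a millisecond grid end to end; the ISO-8601
  writer rounds (rather than truncates) milliseconds so write/read round
  trips are exact multiset identities.
* `lmer` fits retry once with `bobyqa` and a raised evaluation budget
  before failing; singular fits are flagged, not hidden. If the stacked
  modality model degenerates entirely, `test_difference()` falls back to a
  paired t test with an explicit flag.
* Problem sizes in the validation suite were chosen to keep each check
  sharp but affordable: oracle equivalence on 1,000 random nights of 2 to
  2,000 events; exact diary arithmetic on 10,000 records; 20-replicate
  recovery runs at 150-200 participants × 7 nights for ICC, association,
  and slope-variation checks; 200 fast replicates for the size of the TOST
  and boundary-LRT decisions.

## Known limitations

The KAP algorithm assumes one consolidated nocturnal rest period for
daytime-active people; shift workers, nappers and phone-off intervals all
violate it, surfacing only through the outlier rule. The stacked
equivalence model's conservative SE is a feature for equivalence claims but
costs power for difference claims. And the cross-level moderation analysis
inherits the usual caveat that person-level moderators are observational:
the generator shows the burst mechanism is *sufficient* to produce
PSQI-dependent attenuation, not that it is the mechanism in real data.
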