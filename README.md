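# kapsleep

Rest-activity estimation from smartphone keyboard inactivity, with
sleep-diary comparison and multilevel agreement analysis.

## What this package is for

Smartphone keyboards generate a timestamped event per keystroke. Because
most people type until shortly before going to bed and resume soon after
getting up, the longest nightly *keystroke-absence period* (KAP) — the
longest gap in keyboard events between 7 PM and 3 PM the next day — is a
cheap, unobtrusive behavioral proxy for the rest period. `kapsleep` is for
researchers in digital phenotyping and sleep epidemiology who want to:

* extract KAP-based estimates from raw keystroke logs: last keystroke
  (rest onset), first keystroke (activity onset), KAP duration, and the
  KAP midpoint (midsleep proxy), plus a daily hours-with-activity
  regularity covariate;
* derive the corresponding self-reported metrics from morning sleep-diary
  records: bedtime, try-to-sleep, sleep onset (try-to-sleep + latency),
  midsleep, sleep offset, out-of-bed, total sleep period, total bed
  period;
* quantify agreement between the two modalities the way the multilevel
  literature does, accounting for nights nested in participants.

## The statistics at its core

For each of eight keyboard/diary metric pairs, with nights *t* nested in
participants *i*:

* **ICC** from the unconditional model
  *y*<sub>*it*</sub> = γ₀ + *u*<sub>*i*</sub> + ε<sub>*it*</sub>,
  ICC = σ²<sub>u</sub> / (σ²<sub>u</sub> + σ²<sub>ε</sub>).
* **Mean difference and equivalence**: modalities stacked long,
  *y* = γ₀ + γ₁·modality + *u*<sub>*i*</sub> + ε; γ₁ is the mean
  keyboard-minus-diary difference, tested at α = .01 (99% CI), with TOST
  equivalence declared at Δ ∈ {0.5 h, 1 h} when the 98% CI lies inside
  (−Δ, +Δ). Repeated-measures Bland-Altman limits use
  bias ± 1.96·√(σ²<sub>u,diff</sub> + σ²<sub>ε,diff</sub>).
* **Association**: standardized β from
  diary<sub>z</sub> = γ₀ + β·keyboard<sub>z</sub> + *u*<sub>*i*</sub> + ε,
  with Satterthwaite df and marginal/conditional R².
* **Moderation**: keyboard predictors are cluster-mean centered with
  empirical-Bayes person means from the unconditional model; day-level
  (hours with activity, weekday/weekend) and person-level (chronotype
  MSFsc, PSQI, trait self-control, grand-mean centered) moderators enter
  as interactions with the centered score; random-slope models quantify
  interindividual slope variation (LRT with 2 df).

A seeded synthetic cohort generator (`simulate_cohort()`) emulates a
student cohort — ~157 participants × 7 nights, realistic timing/duration
variance decomposition, weekend delays, PSQI-driven nocturnal keystroke
bursts, diary reporting noise — with a ground-truth channel, so the whole
pipeline is testable without any real data.

## Worked example

```r
library(kapsleep)

cfg <- kap_sim_config(n_participants = 40, n_nights = 7, seed = 2026)
cohort <- simulate_cohort(cfg)
#> <kap_cohort> 40 participants, 280 nights, 29214 keystroke events

ex <- extract_all_nights(cohort$events, cfg$start_date + 0:6, tz = cfg$timezone)
#> extract_all_nights: 280/280 nights valid (100.0%)
dn <- derive_diary_nights(cohort$diary)
paired <- pair_nights(apply_outlier_rule(ex$nights), apply_outlier_rule(dn),
                      ex$day_activity)

test_difference(paired[["kap.total_sleep_period"]])
#> mean diff +0.893 h, 99% CI [0.622, 1.164], p = 1.82e-16 (df 516.9)
#> 98% CI [0.648, 1.138]; equivalent at +/-0.5/1 h: FALSE/FALSE

fit_association(paired[["last_keystroke.bedtime"]])
#> Multilevel fit (280 obs, 40 participants; Satterthwaite df; alpha = 0.01)
#>         term  estimate     se    df         t        p  ci_lo ci_hi
#>  (Intercept) -3.93e-16 0.0584  38.9 -6.73e-15 1.00e+00 -0.158 0.158
#>         kb_z  7.32e-01 0.0391 274.0  1.87e+01 5.65e-51  0.631 0.833
#> R2 marginal 0.542, conditional 0.627

fit_random_slope(paired[["last_keystroke.bedtime"]])
#> slope SD 0.274; LRT 30.04 (df 2), p = 2.99e-07
```

Reading this: the keyboard-inferred rest period overestimates the
self-reported sleep period by ~0.9 h on average (not equivalent even at the
1 h bound in this small cohort), while the last keystroke tracks reported
bedtime with a standardized slope of 0.73 — and that slope varies across
participants with SD 0.27.

The full pipeline (simulate → extract → derive → agree → model → report,
with CSV/JSON artifacts and a digest manifest) runs via `run_pipeline()` or
the thin CLI at `inst/scripts/kapsleep.R`:

```sh
Rscript inst/scripts/kapsleep.R run --out-dir out --seed 1
```

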