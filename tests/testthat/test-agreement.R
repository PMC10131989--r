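make_paired_cohort <- function(seed = 13, n = 25, nights = 5, ...) {
  cfg <- kap_sim_config(n_participants = n, n_nights = nights, seed = seed, ...)
  cohort <- simulate_cohort(cfg)
  ex <- suppressMessages(extract_all_nights(
    cohort$events, cfg$start_date + seq_len(nights) - 1, tz = cfg$timezone))
  dn <- derive_diary_nights(cohort$diary)
  list(cohort = cohort, kb = ex$nights, dn = dn, da = ex$day_activity,
       paired = pair_nights(ex$nights, dn, ex$day_activity))
}

test_that("pairing joins on participant-night with the weekend convention", {
  pc <- make_paired_cohort()
  expect_named(pc$paired, kap_metric_pairs()$pair)
  p <- pc$paired[["last_keystroke.bedtime"]]
  expect_equal(nrow(p), 25 * 5)
  # Friday-evening anchor (Saturday morning) counts as weekend
  expect_equal(unique(as.character(
    p$type_of_day[format(p$anchor_date, "%u") == "5"])), "weekend")
  expect_equal(unique(as.character(
    p$type_of_day[format(p$anchor_date, "%u") == "2"])), "weekday")
  # diff sign convention: keyboard minus diary
  expect_equal(p$diff_h, p$keyboard - p$diary)
  # keyboard-valid + diary-missing -> diff missing, row retained
  dn2 <- pc$dn
  dn2$bedtime[1] <- NA
  p2 <- pair_nights(pc$kb, dn2, pc$da)[["last_keystroke.bedtime"]]
  key <- paste(p2$participant_id, p2$anchor_date)
  k1 <- paste(pc$dn$participant_id[1], pc$dn$anchor_date[1])
  expect_true(is.na(p2$diff_h[key == k1]))
  expect_false(is.na(p2$keyboard[key == k1]))
  # day-activity covariates line up with anchor and morning dates
  da_idx <- paste(pc$da$participant_id, pc$da$calendar_date)
  expect_equal(p$hours_prev_day,
               pc$da$hours_with_activity[match(paste(p$participant_id, p$anchor_date), da_idx)])
  expect_equal(p$hours_next_day,
               pc$da$hours_with_activity[match(paste(p$participant_id, p$anchor_date + 1), da_idx)])
})

test_that("unconditional ICC recovers generative variance shares", {
  set.seed(31)
  g <- rep(sprintf("S%03d", 1:200), each = 7)
  y <- rep(rnorm(200, 0, 1), each = 7) + rnorm(1400, 0, sqrt(3))
  res <- icc_unconditional(y, g)
  expect_equal(res$icc, 0.25, tolerance = 0.05 / 0.25)
  expect_equal(res$icc,
               res$var_between / (res$var_between + res$var_within))
  # pure noise -> icc ~ 0, flagged singular rather than erroring
  y0 <- rnorm(1400)
  res0 <- icc_unconditional(y0, g)
  expect_lt(res0$icc, 0.02)
  # one observation per participant is not separable
  expect_error(icc_unconditional(rnorm(50), sprintf("S%02d", 1:50)),
               "single observation")
})

test_that("modality test handles exact agreement and gross disagreement", {
  set.seed(7)
  base <- simulate_paired_diffs(60, 7, true_diff = 0, sd_between = 0.5,
                                sd_within = 1)
  same <- base
  same$keyboard <- same$diary
  same$diff_h <- 0
  res <- test_difference(same)
  expect_equal(res$mean_diff_h, 0, tolerance = 1e-10)
  expect_true(all(res$equivalent))

  far <- base
  far$keyboard <- far$diary + 2 + rnorm(nrow(far), 0, 0.01)
  far$diff_h <- far$keyboard - far$diary
  res2 <- test_difference(far)
  expect_lt(res2$nhst_p, 0.001)
  expect_false(any(res2$equivalent))
  # equivalence at the tighter bound implies it at the looser one
  expect_true(all(!res$equivalent[1] | res$equivalent[2]))
})

test_that("stacked modality model matches the balanced closed form", {
  set.seed(19)
  d <- simulate_paired_diffs(150, 7, true_diff = 0.2, sd_between = 0.5,
                             sd_within = 1)
  res <- test_difference(d)
  # balanced design: the modality coefficient is the mean difference
  expect_equal(res$mean_diff_h, mean(d$diff_h), tolerance = 1e-6)
  # closed-form SE from the known variance components
  se_cf <- sqrt(2 * 1^2 / nrow(d))
  expect_equal(res$se, se_cf, tolerance = 0.05)
  expect_equal(diff(res$ci98), 2 * qnorm(0.99) * se_cf, tolerance = 0.05)
})

test_that("swapping modalities negates the difference and mirrors the CIs", {
  set.seed(23)
  d <- simulate_paired_diffs(40, 5, true_diff = 0.3)
  swapped <- d
  swapped$keyboard <- d$diary
  swapped$diary <- d$keyboard
  swapped$diff_h <- -d$diff_h
  a <- test_difference(d)
  b <- test_difference(swapped)
  expect_equal(b$mean_diff_h, -a$mean_diff_h, tolerance = 1e-8)
  expect_equal(b$ci99, -rev(a$ci99), tolerance = 1e-8)
  expect_equal(b$nhst_p, a$nhst_p, tolerance = 1e-8)
})

test_that("repeated-measures Bland-Altman recovers known components", {
  # identical values: zero bias, degenerate limits
  d0 <- simulate_paired_diffs(20, 4)
  d0$keyboard <- d0$diary; d0$diff_h <- 0
  ba0 <- bland_altman_rm(d0)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa, c(0, 0))
  # constant additive offset
  dc <- d0
  dc$keyboard <- dc$diary + 0.7; dc$diff_h <- 0.7
  expect_equal(bland_altman_rm(dc)$bias, 0.7)
  # known difference components: between 0.5^2 * 2? no - diffs here have
  # var = 2 * sd_within^2 (between cancels in the shared-intercept model)
  set.seed(41)
  d <- simulate_paired_diffs(150, 7, true_diff = 0.3, sd_between = 0.5,
                             sd_within = 0.5)
  ba <- bland_altman_rm(d)
  sd_diff_cf <- sqrt(2) * 0.5
  expect_equal(ba$loa, 0.3 + c(-1.96, 1.96) * sd_diff_cf, tolerance = 0.05)
  cover <- mean(d$diff_h > ba$loa[1] & d$diff_h < ba$loa[2])
  expect_gt(cover, 0.92)
  expect_lt(cover, 0.98)
})

test_that("TOST calibration harness reports rates with guards", {
  expect_error(tost_calibration(1), "n_reps")
  set.seed(2)
  zero_bound <- tost_calibration(5, n_participants = 30, n_nights = 4,
                                 true_diff = 0, bound = 0)
  expect_equal(zero_bound$rate, 0)
  easy <- tost_calibration(10, n_participants = 60, n_nights = 5,
                           true_diff = 0, sd_within = 0.5, bound = 1)
  expect_equal(easy$rate, 1)
})
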