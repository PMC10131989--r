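test_that("extract_kap returns the defining example and its identities", {
  # keystrokes at 21:30, 22:00, then 07:30 and 08:00 next morning
  est <- extract_kap(c(9.5, 10, 19.5, 20))
  expect_true(est$valid)
  expect_equal(est$last_keystroke, 10)     # 22:00
  expect_equal(est$first_keystroke, 19.5)  # 07:30
  expect_equal(est$kap_h, 9.5)
  expect_equal(est$midpoint_kap, 14.75)    # 02:45
})

test_that("degenerate nights are invalid, never an error", {
  for (ev in list(numeric(0), 12, c(3, 5), c(12, NA))) {
    est <- extract_kap(ev)
    expect_false(est$valid)
    expect_true(is.na(est$kap_h))
    expect_true(is.na(est$midpoint_kap))
  }
  # events exactly at the window bounds are included
  est <- extract_kap(c(7, 27))
  expect_true(est$valid)
  expect_equal(est$kap_h, 20)
})

test_that("ties for the longest gap resolve to the earliest start", {
  est <- extract_kap(c(8, 12, 16, 20))
  expect_equal(est$last_keystroke, 8)
  expect_equal(est$first_keystroke, 12)
})

test_that("gap finder matches the quadratic oracle and its symmetries", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:60, 1)
    t <- runif(n, 7, 27)
    est <- extract_kap(t)
    bf <- bruteforce_max_gap(t)
    expect_equal(est$last_keystroke, bf$last)
    expect_equal(est$first_keystroke, bf$first)
    # permutation invariance
    est_perm <- extract_kap(sample(t))
    expect_identical(est_perm, est)
    # translation equivariance inside the window
    shift <- runif(1, -min(t) + 7.01, 27 - max(t) - 0.01)
    est_sh <- extract_kap(t + shift)
    expect_equal(est_sh$last_keystroke, est$last_keystroke + shift)
    expect_equal(est_sh$kap_h, est$kap_h)
    expect_equal(est_sh$midpoint_kap, est$midpoint_kap + shift)
    # conservation identities
    expect_equal(est$kap_h, est$first_keystroke - est$last_keystroke)
    expect_equal(est$midpoint_kap,
                 (est$first_keystroke + est$last_keystroke) / 2)
  }
})

test_that("hours_with_activity counts distinct hour bins", {
  base <- as.POSIXct("2020-09-14 00:00:00", tz = "UTC")
  ts <- base + c(9, 9.66, 13.99) * 3600 # 09:05-ish, 09:40-ish, 13:59-ish
  expect_equal(hours_with_activity(ts, as.Date("2020-09-14"), tz = "UTC"), 2L)
  expect_equal(hours_with_activity(ts, as.Date("2020-09-15"), tz = "UTC"), 0L)
  expect_equal(hours_with_activity(ts[0], as.Date("2020-09-14")), 0L)
  # brute-force distinct-bin count on a random stream
  set.seed(9)
  rnd <- base + runif(300, 0, 24) * 3600
  expect_equal(hours_with_activity(rnd, as.Date("2020-09-14"), tz = "UTC"),
               length(unique(floor(as.numeric(rnd - base, units = "hours")))))
})

test_that("extract_all_nights keeps invalid nights and matches the truth channel", {
  cfg <- kap_sim_config(n_participants = 2, n_nights = 3, seed = 8,
                        keystroke_rate_per_h = 600, sd_log_rate_person = 0,
                        sd_log_rate_day = 0, p_inbed_use = 0,
                        awakening_rate_per_psqi = 0, diary_noise_sd_min = 0)
  cohort <- simulate_cohort(cfg)
  anchors <- cfg$start_date + 0:2
  ex <- suppressMessages(extract_all_nights(cohort$events, anchors,
                                            tz = cfg$timezone))
  expect_equal(nrow(ex$nights), 6L)
  expect_true(all(ex$nights$valid))
  m <- merge(ex$nights, cohort$truth, by = c("participant_id", "anchor_date"))
  expect_true(all(abs(m$last_keystroke - m$true_bedtime) <= 0.01))

  # a participant silent for a full window yields valid = FALSE for it
  ev <- cohort$events
  drop <- ev$participant_id == "P001" &
    night_axis_hours(ev$timestamp, anchors[2], cfg$timezone) >= 7 &
    night_axis_hours(ev$timestamp, anchors[2], cfg$timezone) <= 27
  ex2 <- suppressMessages(extract_all_nights(ev[!drop, ], anchors,
                                             tz = cfg$timezone))
  row <- ex2$nights[ex2$nights$participant_id == "P001" &
                      ex2$nights$anchor_date == anchors[2], ]
  expect_false(row$valid)

  expect_warning(empty <- extract_all_nights(ev[0, ]), "empty event table")
  expect_equal(nrow(empty$nights), 0L)
})
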