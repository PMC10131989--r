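test_that("config validation names the offending field", {
  expect_s3_class(kap_sim_config(), "kap_sim_config")
  expect_error(kap_sim_config(n_nights = 0), "n_nights")
  expect_error(kap_sim_config(p_inbed_use = 1.2), "p_inbed_use")
  expect_error(kap_sim_config(sd_night_h = -1), "sd_night_h")
  expect_error(kap_sim_config(keystroke_rate_per_h = NA), "keystroke_rate_per_h")
})

test_that("config YAML round-trips and rejects unknown fields", {
  cfg <- tiny_config(weekend_delay_h = 0.75)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
  writeLines("keystroke_rate: 3", path)
  expect_error(read_sim_config(path), "unknown simulation config field")
})

test_that("same config and seed reproduce byte-identical cohorts", {
  a <- simulate_cohort(tiny_config())
  b <- simulate_cohort(tiny_config())
  expect_identical(a$events, b$events)
  expect_identical(a$diary, b$diary)
  expect_identical(a$traits, b$traits)
  expect_identical(a$truth, b$truth)
})

test_that("default cohort satisfies the ground-truth structure", {
  cohort <- simulate_cohort(kap_sim_config(seed = 5))
  tr <- cohort$truth
  expect_equal(nrow(tr), 157 * 7)
  expect_equal(anyDuplicated(tr[c("participant_id", "anchor_date")]), 0L)
  # ordering invariant for every night
  expect_true(all(tr$true_bedtime <= tr$true_try_sleep))
  expect_true(all(tr$true_try_sleep <= tr$true_sleep_onset))
  expect_true(all(tr$true_sleep_onset < tr$true_sleep_offset))
  expect_true(all(tr$true_sleep_offset <= tr$true_out_of_bed))
  # configured mean sleep duration is recovered in the diary reports
  dn <- derive_diary_nights(cohort$diary)
  expect_equal(mean(dn$total_sleep_period_h, na.rm = TRUE), 7.75,
               tolerance = 0.2 / 7.75)
  # weekend nights are later in truth, in both raw diary and (implicitly)
  # the keyboard stream derived from the same truth
  delay <- mean(tr$true_try_sleep[tr$weekend]) -
    mean(tr$true_try_sleep[!tr$weekend])
  expect_gt(delay, 0.2)
  # later simulated chronotypes report later diary timing
  pm <- tapply(dn$midsleep, dn$participant_id, mean, na.rm = TRUE)
  expect_gt(cor(cohort$traits$msfsc[match(names(pm), cohort$traits$participant_id)],
                pm), 0.3)
  # trait scores respect their scales
  expect_true(all(cohort$traits$psqi >= 0 & cohort$traits$psqi <= 21))
  expect_true(all(cohort$traits$tsc >= 1 & cohort$traits$tsc <= 5))
})

test_that("dense noiseless keystroke process converges to the truth channel", {
  cfg <- kap_sim_config(
    n_participants = 40, n_nights = 5, seed = 3,
    diary_noise_sd_min = 0, p_inbed_use = 0, awakening_rate_per_psqi = 0,
    keystroke_rate_per_h = 600, sd_log_rate_person = 0, sd_log_rate_day = 0
  )
  cohort <- simulate_cohort(cfg)
  ex <- suppressMessages(extract_all_nights(
    cohort$events, anchor_dates = cfg$start_date + seq_len(cfg$n_nights) - 1,
    tz = cfg$timezone))
  m <- merge(ex$nights, cohort$truth, by = c("participant_id", "anchor_date"))
  expect_true(all(m$valid))
  close_last <- abs(m$last_keystroke - m$true_bedtime) <= 0.01
  close_first <- abs(m$first_keystroke - m$true_out_of_bed) <= 0.01
  expect_gte(mean(close_last & close_first), 0.99)
})

test_that("simulate_night honors in-bed use and awakening mechanics", {
  cfg <- tiny_config()
  # in-bed use extends typing to the try-to-sleep time
  set.seed(1)
  night <- simulate_night(test_person(p_inbed = 1, rate = 60), cfg,
                          as.Date("2020-09-14"), weekend = FALSE)
  expect_gte(max(night$event_hours), night$truth$true_bedtime)
  # event times strictly increasing
  expect_true(all(diff(night$event_hours) > 0))
  # no awakenings -> silent sleep period
  set.seed(2)
  cfg0 <- tiny_config(awakening_rate_per_psqi = 0)
  n0 <- simulate_night(test_person(), cfg0, as.Date("2020-09-14"), FALSE)
  inside <- n0$event_hours > n0$truth$true_sleep_onset &
    n0$event_hours < n0$truth$true_sleep_offset
  expect_equal(sum(inside), 0L)
  # higher PSQI -> more awakening bursts in expectation
  set.seed(3)
  n_awk <- function(psqi) {
    mean(vapply(1:200, function(i) {
      simulate_night(test_person(psqi = psqi), cfg,
                     as.Date("2020-09-14"), FALSE)$truth$n_awakenings
    }, numeric(1)))
  }
  expect_gt(n_awk(13), n_awk(1))
})

test_that("configured variance decomposition propagates to downstream ICCs", {
  # between-person share 1 / (1 + 3) = 0.25 of the timing variance
  reps <- 20
  iccs <- numeric(reps)
  for (r in seq_len(reps)) {
    cfg <- kap_sim_config(n_participants = 60, n_nights = 7, seed = 100 + r,
                          sd_chronotype_h = 1, sd_night_h = sqrt(3),
                          diary_noise_sd_min = 5)
    cohort <- simulate_cohort(cfg)
    dn <- derive_diary_nights(cohort$diary)
    iccs[r] <- icc_unconditional(dn$try_to_sleep, dn$participant_id)$icc
  }
  expect_equal(mean(iccs), 0.25, tolerance = 0.05 / 0.25)
})
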