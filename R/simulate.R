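#' Simulate a synthetic keyboard + diary cohort with known ground truth
#'
#' Generates, from a per-person circadian sleep model, (i) a keystroke event
#' stream, (ii) morning sleep-diary records, (iii) person-level trait scores
#' and (iv) the ground-truth night table the first two are noisy views of.
#'
#' The generative model, per participant `i` and night `t`:
#' \describe{
#'   \item{timing}{try-to-sleep = population mean + chronotype offset
#'     `c_i ~ N(0, sd_chronotype_h)` + night noise `N(0, sd_night_h)` +
#'     `weekend_delay_h` on weekend nights. Bedtime precedes it by an
#'     exponential pre-bed gap; sleep onset follows it by an exponential
#'     latency; sleep offset = onset + duration
#'     `N(mean_sleep_h + d_i, sd_sleep_h)` with habitual offset
#'     `d_i ~ N(0, sd_sleep_person_h)`; out-of-bed = offset + exponential
#'     rise lag.}
#'   \item{keystrokes}{a homogeneous Poisson process during wake at a person-
#'     and night-specific rate (lognormal heterogeneity around
#'     `keystroke_rate_per_h`). Typing stops at bedtime, or continues in bed
#'     until try-to-sleep with probability `p_inbed_use`, and resumes at
#'     out-of-bed. Nocturnal awakenings (Poisson with mean
#'     `awakening_rate_per_psqi * PSQI`) each emit a 1-5 keystroke burst
#'     within 10 minutes with probability `p_keystroke_on_awakening`.}
#'   \item{diary}{ground truth plus independent Gaussian reporting noise
#'     (`diary_noise_sd_min`), rounded to the diary's 5-minute grid; latency
#'     is reported directly in minutes.}
#' }
#'
#' A single master seed drives everything; each participant gets a
#' deterministic substream, so regenerating any subset of participants
#' reproduces their data exactly.
#'
#' @param config a [kap_sim_config()].
#' @return a list of class `kap_cohort` with elements
#'   \describe{
#'     \item{events}{data.frame `participant_id`, `timestamp` (POSIXct,
#'       millisecond grid).}
#'     \item{diary}{raw diary records: `participant_id`, `report_date`,
#'       `bedtime`, `try_to_sleep` ("HH:MM"), `latency_min`, `sleep_offset`,
#'       `out_of_bed` ("HH:MM"), `woke_by_alarm`.}
#'     \item{traits}{`participant_id`, `msfsc` (clock hours), `psqi`, `tsc`,
#'       `social_jetlag_h`.}
#'     \item{truth}{per participant-night ground truth on the night axis:
#'       `true_bedtime`, `true_try_sleep`, `true_sleep_onset`,
#'       `true_sleep_offset`, `true_out_of_bed`, `n_awakenings`, `weekend`.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(kap_sim_config(n_participants = 3, n_nights = 2))
#' head(cohort$truth)
simulate_cohort <- function(config = kap_sim_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  part_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_participants)
  ids <- sprintf("P%03d", seq_len(cfg$n_participants))

  per_part <- lapply(seq_len(cfg$n_participants), function(i) {
    set.seed(part_seeds[i])
    simulate_participant(ids[i], cfg)
  })

  out <- list(
    events = do.call(rbind, lapply(per_part, `[[`, "events")),
    diary = do.call(rbind, lapply(per_part, `[[`, "diary")),
    traits = do.call(rbind, lapply(per_part, `[[`, "traits")),
    truth = do.call(rbind, lapply(per_part, `[[`, "truth")),
    config = cfg
  )
  rownames(out$events) <- rownames(out$diary) <- NULL
  rownames(out$traits) <- rownames(out$truth) <- NULL
  class(out) <- "kap_cohort"
  out
}

#' @export
print.kap_cohort <- function(x, ...) {
  cat(sprintf("<kap_cohort> %d participants, %d nights, %d keystroke events\n",
              nrow(x$traits), nrow(x$truth), nrow(x$events)))
  invisible(x)
}

# Person-level parameter draws, then all nights, then events on an absolute
# hour axis (hours since noon of the first anchor date).
#' @keywords internal
simulate_participant <- function(id, cfg) {
  # habitual perisleep behavior is a person trait: each participant gets a
  # mean-preserving lognormal multiplier on the pre-bed gap and rise lag and
  # a Beta-distributed in-bed-use propensity, so perisleep habits contribute
  # between-person variance to the keyboard-derived estimates
  habit <- function() exp(stats::rnorm(1, -0.5, 1)) # mean-preserving lognormal
  p_inbed_i <- if (cfg$p_inbed_use %in% c(0, 1)) cfg$p_inbed_use else {
    stats::rbeta(1, 4 * cfg$p_inbed_use, 4 * (1 - cfg$p_inbed_use))
  }
  person <- list(
    id = id,
    chronotype = stats::rnorm(1, 0, cfg$sd_chronotype_h),
    rate = cfg$keystroke_rate_per_h * exp(stats::rnorm(1, 0, cfg$sd_log_rate_person)),
    dur_shift = stats::rnorm(1, 0, cfg$sd_sleep_person_h),
    prebed_mean = cfg$mean_prebed_gap_h * habit(),
    rise_mean = cfg$mean_rise_lag_h * habit(),
    p_inbed = p_inbed_i,
    psqi = min(21L, max(0L, as.integer(round(stats::rnorm(1, cfg$psqi_mean, cfg$psqi_sd))))),
    tsc = min(5, max(1, stats::rnorm(1, cfg$tsc_mean, cfg$tsc_sd)))
  )
  # chronotype questionnaire: free-day midsleep, derived from the person's
  # own timing model plus a small report error
  free_midsleep <- cfg$mu_try_sleep + cfg$mean_latency_min / 60 +
    (cfg$mean_sleep_h + person$dur_shift) / 2 + cfg$weekend_delay_h +
    person$chronotype + stats::rnorm(1, 0, 0.25)
  traits <- data.frame(
    participant_id = id,
    msfsc = free_midsleep %% 24,
    psqi = person$psqi,
    tsc = person$tsc,
    social_jetlag_h = abs(cfg$weekend_delay_h + stats::rnorm(1, 0, 0.2)),
    stringsAsFactors = FALSE
  )

  nights <- vector("list", cfg$n_nights)
  wake_start <- 0
  for (n in seq_len(cfg$n_nights)) {
    anchor <- cfg$start_date + (n - 1)
    weekend <- format(anchor + 1, "%u") %in% c("6", "7")
    nights[[n]] <- simulate_night(person, cfg, anchor, weekend,
                                  final_night = n == cfg$n_nights,
                                  wake_start = wake_start)
    # a lie-in past noon delays the start of the next night's wake segment
    wake_start <- max(0, nights[[n]]$truth$true_out_of_bed - 24)
  }

  truth <- do.call(rbind, lapply(nights, `[[`, "truth"))
  diary <- do.call(rbind, lapply(nights, `[[`, "diary"))
  ev_abs <- unlist(lapply(seq_along(nights), function(n) {
    nights[[n]]$event_hours + 24 * (n - 1)
  }))
  ev_abs <- sort(ev_abs)
  noon1 <- anchor_noon(cfg$start_date, cfg$timezone)
  ts <- round(as.numeric(noon1) + ev_abs * 3600, 3) # millisecond grid
  ts <- unique(ts)
  events <- data.frame(
    participant_id = rep(id, length(ts)),
    timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = cfg$timezone),
    stringsAsFactors = FALSE
  )
  list(events = events, diary = diary, traits = traits, truth = truth)
}

#' Simulate a single participant-night
#'
#' Draws one night's ground truth, the corresponding diary report, and the
#' keystroke event times on the night's own axis (hours since noon of the
#' anchor date, spanning `[0, 24)`, or `[0, 27]` for the final night so the
#' last analysis window is fully covered). Wake-period events stop at bedtime
#' (or try-to-sleep under in-bed use) and resume at out-of-bed; the only
#' events inside the sleep period are awakening bursts. Degenerate timing
#' draws (bedtime before the 7 PM window start, sleep shorter than half an
#' hour, out-of-bed past the 3 PM window end) are re-drawn with a bounded
#' retry budget.
#'
#' Uses the current RNG state; callers seed per-participant substreams.
#'
#' @param person list of person-level parameters (`id`, `chronotype`, `rate`,
#'   `dur_shift`, `prebed_mean`, `rise_mean`, `p_inbed`, `psqi`).
#' @param cfg a validated [kap_sim_config()].
#' @param anchor_date anchor date of the night.
#' @param weekend logical, whether the night's morning is a Saturday/Sunday.
#' @param final_night logical, extend event generation to axis hour 27.
#' @param wake_start axis hour at which the day's wake period begins (carries
#'   a previous night's past-noon out-of-bed time forward; 0 otherwise).
#' @return list with `truth` (one-row data.frame), `diary` (one-row
#'   data.frame of raw clock-string reports) and `event_hours` (numeric,
#'   strictly increasing night-axis hours).
#' @export
simulate_night <- function(person, cfg, anchor_date, weekend,
                           final_night = FALSE, wake_start = 0) {
  rexp_mean <- function(m) if (m <= 0) 0 else stats::rexp(1, 1 / m)
  for (attempt in seq_len(100L)) {
    night_shift <- stats::rnorm(1, 0, cfg$sd_night_h)
    try_sleep <- (cfg$mu_try_sleep - 12) + person$chronotype + night_shift +
      if (weekend) cfg$weekend_delay_h else 0
    prebed <- rexp_mean(person$prebed_mean)
    bedtime <- try_sleep - prebed
    latency_h <- rexp_mean(cfg$mean_latency_min / 60)
    onset <- try_sleep + latency_h
    dur <- stats::rnorm(1, cfg$mean_sleep_h + person$dur_shift, cfg$sd_sleep_h)
    offset <- onset + dur
    rise <- rexp_mean(person$rise_mean)
    oob <- offset + rise
    if (bedtime > 7.05 && dur > 0.5 && oob < 26.95) break
    if (attempt == 100L) {
      stop("simulate_night: could not draw a plausible night after 100 attempts")
    }
  }

  # keystrokes: homogeneous Poisson on the wake segments of [0, 24) / [0, 27]
  rate <- person$rate * exp(stats::rnorm(1, 0, cfg$sd_log_rate_day))
  end_evening <- if (stats::runif(1) < person$p_inbed) try_sleep else bedtime
  day_end <- if (final_night) 27 else 24
  segments <- list(c(min(wake_start, end_evening), end_evening),
                   c(oob, max(oob, day_end)))
  ev <- unlist(lapply(segments, function(s) {
    len <- max(0, s[2] - s[1])
    k <- stats::rpois(1, rate * len)
    if (k == 0) numeric(0) else s[1] + sort(stats::runif(k)) * len
  }))

  n_awk <- stats::rpois(1, cfg$awakening_rate_per_psqi * person$psqi)
  if (n_awk > 0) {
    for (a in seq_len(n_awk)) {
      u <- stats::runif(1, onset, max(onset, offset - 1 / 6))
      if (stats::runif(1) < cfg$p_keystroke_on_awakening) {
        m <- sample.int(5L, 1L)
        burst <- u + sort(stats::runif(m, 0, 1 / 6))
        ev <- c(ev, pmin(burst, offset - 1e-6))
      }
    }
  }
  ev <- sort(unique(ev))

  truth <- data.frame(
    participant_id = person$id, anchor_date = as.Date(anchor_date),
    true_bedtime = bedtime, true_try_sleep = try_sleep,
    true_sleep_onset = onset, true_sleep_offset = offset,
    true_out_of_bed = oob, n_awakenings = n_awk, weekend = weekend,
    stringsAsFactors = FALSE
  )

  noise_h <- cfg$diary_noise_sd_min / 60
  grid5 <- function(x) round(x * 12) / 12 # 5-minute grid, in hours
  rep_bed <- grid5(bedtime + stats::rnorm(1, 0, noise_h))
  rep_try <- grid5(try_sleep + stats::rnorm(1, 0, noise_h))
  rep_off <- grid5(offset + stats::rnorm(1, 0, noise_h))
  rep_oob <- grid5(oob + stats::rnorm(1, 0, noise_h))
  rep_lat <- max(0, round((latency_h * 60 + stats::rnorm(1, 0, cfg$diary_noise_sd_min)) / 5) * 5)
  diary <- data.frame(
    participant_id = person$id,
    report_date = as.Date(anchor_date) + 1,
    bedtime = format_clock(clock_from_night_axis(rep_bed)),
    try_to_sleep = format_clock(clock_from_night_axis(rep_try)),
    latency_min = rep_lat,
    sleep_offset = format_clock(clock_from_night_axis(rep_off)),
    out_of_bed = format_clock(clock_from_night_axis(rep_oob)),
    woke_by_alarm = stats::runif(1) < if (weekend) 0.46 else 0.60,
    stringsAsFactors = FALSE
  )

  list(truth = truth, diary = diary, event_hours = ev)
}
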