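# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (diff/sort for gaps, night-axis arithmetic for
# diary derivation).

# Quadratic maximal-gap scan: for every event, find its successor by scanning
# all strictly later events; ties for the longest gap resolve to the earliest
# start.
bruteforce_max_gap <- function(t, window = c(7, 27)) {
  t <- t[!is.na(t) & t >= window[1] & t <= window[2]]
  if (length(t) < 2L) return(NULL)
  best <- NULL
  for (i in seq_along(t)) {
    later <- t[t > t[i]]
    if (!length(later)) next
    gap <- min(later) - t[i]
    if (is.null(best) || gap > best$gap ||
        (gap == best$gap && t[i] < best$last)) {
      best <- list(last = t[i], first = t[i] + gap, gap = gap)
    }
  }
  best
}

# Diary-derivation oracle in plain datetime arithmetic: clock strings are
# attached to the report morning (<= 15:00) or the previous evening, all
# quantities computed as POSIXct differences, then re-expressed as hours
# since noon of the anchor date.
diary_datetime_oracle <- function(rec) {
  rd <- as.Date(rec$report_date)
  anchor_noon <- as.POSIXct(paste(rd - 1, "12:00:00"), tz = "UTC")
  to_dt <- function(clock) {
    h <- kapsleep::parse_clock(clock)
    date <- ifelse(h <= 15, as.character(rd), as.character(rd - 1))
    as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + h * 3600
  }
  bed <- to_dt(rec$bedtime); try <- to_dt(rec$try_to_sleep)
  off <- to_dt(rec$sleep_offset); oob <- to_dt(rec$out_of_bed)
  onset <- try + as.numeric(rec$latency_min) * 60
  hrs <- function(dt) as.numeric(difftime(dt, anchor_noon, units = "hours"))
  list(
    bedtime = hrs(bed), try_to_sleep = hrs(try), sleep_onset = hrs(onset),
    midsleep = hrs(onset) + as.numeric(difftime(off, onset, units = "hours")) / 2,
    sleep_offset = hrs(off), out_of_bed = hrs(oob),
    tsp = as.numeric(difftime(off, onset, units = "hours")),
    tbp = as.numeric(difftime(oob, bed, units = "hours"))
  )
}

# Random well-ordered diary records on the minute grid.
random_diary_records <- function(n, seed) {
  set.seed(seed)
  grid_min <- function(x) round(x * 60) / 60
  bed <- grid_min(runif(n, 8, 14))
  try <- grid_min(bed + runif(n, 0, 1.5))
  lat <- round(runif(n, 0, 60))
  off <- grid_min(try + lat / 60 + runif(n, 3, 8))
  oob <- grid_min(off + runif(n, 0.1, 1.9))
  stopifnot(max(oob) < 27)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    report_date = as.Date("2021-03-02"),
    bedtime = kapsleep::format_clock(kapsleep::clock_from_night_axis(bed)),
    try_to_sleep = kapsleep::format_clock(kapsleep::clock_from_night_axis(try)),
    latency_min = lat,
    sleep_offset = kapsleep::format_clock(kapsleep::clock_from_night_axis(off)),
    out_of_bed = kapsleep::format_clock(kapsleep::clock_from_night_axis(oob)),
    stringsAsFactors = FALSE
  )
}

# Small, fast cohort configuration for structural tests.
tiny_config <- function(...) {
  kapsleep::kap_sim_config(n_participants = 6, n_nights = 3, seed = 11, ...)
}

# Minimal person-parameter list for direct simulate_night() calls.
test_person <- function(psqi = 5, p_inbed = 0, rate = 5) {
  list(id = "P001", chronotype = 0, rate = rate, dur_shift = 0,
       prebed_mean = 0.5, rise_mean = 0.5, p_inbed = p_inbed, psqi = psqi)
}
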