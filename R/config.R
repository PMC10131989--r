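#' Simulation configuration for the synthetic cohort generator
#'
#' Builds and validates the configuration driving [simulate_cohort()]. The
#' defaults describe a cohort of 157 students followed for 7 consecutive
#' nights, with timing, duration and trait distributions calibrated to a
#' typical student sample: mean try-to-sleep around 00:30, mean sleep period
#' 7.75 h, person-level timing SD 0.75 h against a night-level SD of 1.25 h
#' (so roughly a quarter of the timing variance sits between persons), a
#' weekday-to-weekend delay of half an hour, PSQI-dependent nocturnal
#' awakenings that can emit keystroke bursts, and 5-minute-grid diary
#' reporting noise.
#'
#' Clock-hour parameters use a continuous 24+ convention: `mu_try_sleep = 24.5`
#' means 00:30 after midnight.
#'
#' @param n_participants number of simulated participants.
#' @param n_nights nights per participant (>= 1).
#' @param start_date anchor date of the first night.
#' @param timezone Olson timezone for the generated timestamps.
#' @param mu_try_sleep population mean try-to-sleep time, clock hours (24+ for
#'   past midnight).
#' @param sd_chronotype_h SD of the person-level timing offset (hours).
#' @param sd_night_h SD of the night-level timing noise (hours).
#' @param weekend_delay_h later timing on weekend nights (hours; a night is a
#'   weekend night when its morning falls on Saturday or Sunday).
#' @param mean_latency_min mean sleep-onset latency (minutes, exponential).
#' @param mean_sleep_h population mean sleep duration (hours).
#' @param sd_sleep_h night-level SD of sleep duration (hours).
#' @param sd_sleep_person_h person-level SD of habitual sleep duration (hours).
#' @param mean_prebed_gap_h mean gap from bedtime to try-to-sleep (hours,
#'   exponential).
#' @param mean_rise_lag_h mean gap from sleep offset to out-of-bed (hours,
#'   exponential).
#' @param keystroke_rate_per_h population keystroke rate during wake
#'   (events/hour of the homogeneous Poisson process).
#' @param sd_log_rate_person lognormal SD of the person-level keystroke rate.
#' @param sd_log_rate_day lognormal SD of the day-level keystroke rate.
#' @param p_inbed_use probability, per night, that keystrokes continue past
#'   bedtime until the try-to-sleep time.
#' @param awakening_rate_per_psqi expected nocturnal awakenings per PSQI point.
#' @param p_keystroke_on_awakening probability an awakening emits a 1-5
#'   keystroke burst (within 10 minutes).
#' @param diary_noise_sd_min SD of the additive diary reporting noise
#'   (minutes); reports are then rounded to a 5-minute grid.
#' @param psqi_mean,psqi_sd population distribution of the PSQI global score
#'   (rounded, clipped to 0-21).
#' @param tsc_mean,tsc_sd population distribution of trait self-control
#'   (clipped to 1-5).
#' @param seed master RNG seed; per-participant substreams are derived from it
#'   deterministically.
#' @return an object of class `kap_sim_config` (a validated named list).
#' @seealso [simulate_cohort()], [read_sim_config()]
#' @export
kap_sim_config <- function(n_participants = 157,
                           n_nights = 7,
                           start_date = as.Date("2020-09-14"),
                           timezone = "Europe/Amsterdam",
                           mu_try_sleep = 24.5,
                           sd_chronotype_h = 0.75,
                           sd_night_h = 1.25,
                           weekend_delay_h = 0.5,
                           mean_latency_min = 16,
                           mean_sleep_h = 7.75,
                           sd_sleep_h = 0.8,
                           sd_sleep_person_h = 0.3,
                           mean_prebed_gap_h = 0.5,
                           mean_rise_lag_h = 0.5,
                           keystroke_rate_per_h = 5,
                           sd_log_rate_person = 0.5,
                           sd_log_rate_day = 0.5,
                           p_inbed_use = 0.7,
                           awakening_rate_per_psqi = 0.2,
                           p_keystroke_on_awakening = 0.15,
                           diary_noise_sd_min = 10,
                           psqi_mean = 5.16,
                           psqi_sd = 2.27,
                           tsc_mean = 2.98,
                           tsc_sd = 0.56,
                           seed = 1L) {
  cfg <- list(
    n_participants = n_participants, n_nights = n_nights,
    start_date = as.Date(start_date), timezone = timezone,
    mu_try_sleep = mu_try_sleep, sd_chronotype_h = sd_chronotype_h,
    sd_night_h = sd_night_h, weekend_delay_h = weekend_delay_h,
    mean_latency_min = mean_latency_min, mean_sleep_h = mean_sleep_h,
    sd_sleep_h = sd_sleep_h, sd_sleep_person_h = sd_sleep_person_h,
    mean_prebed_gap_h = mean_prebed_gap_h, mean_rise_lag_h = mean_rise_lag_h,
    keystroke_rate_per_h = keystroke_rate_per_h,
    sd_log_rate_person = sd_log_rate_person,
    sd_log_rate_day = sd_log_rate_day,
    p_inbed_use = p_inbed_use,
    awakening_rate_per_psqi = awakening_rate_per_psqi,
    p_keystroke_on_awakening = p_keystroke_on_awakening,
    diary_noise_sd_min = diary_noise_sd_min,
    psqi_mean = psqi_mean, psqi_sd = psqi_sd,
    tsc_mean = tsc_mean, tsc_sd = tsc_sd,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stop_field <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  }
  num1 <- function(field) {
    v <- cfg[[field]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || is.na(v)) {
      stop_field(field, "must be a single non-missing number")
    }
    v
  }
  counts <- c("n_participants", "n_nights")
  for (f in counts) {
    v <- num1(f)
    if (v < 1 || v != round(v)) stop_field(f, "must be a positive integer")
  }
  nonneg <- c("sd_chronotype_h", "sd_night_h", "mean_latency_min",
              "sd_sleep_h", "sd_sleep_person_h", "mean_prebed_gap_h",
              "mean_rise_lag_h", "keystroke_rate_per_h",
              "sd_log_rate_person", "sd_log_rate_day",
              "awakening_rate_per_psqi", "diary_noise_sd_min",
              "psqi_sd", "tsc_sd", "weekend_delay_h")
  for (f in nonneg) if (num1(f) < 0) stop_field(f, "must be >= 0")
  probs <- c("p_inbed_use", "p_keystroke_on_awakening")
  for (f in probs) {
    v <- num1(f)
    if (v < 0 || v > 1) stop_field(f, "must be a probability in [0, 1]")
  }
  for (f in c("mu_try_sleep", "mean_sleep_h", "psqi_mean", "tsc_mean")) num1(f)
  if (num1("mean_sleep_h") <= 0) stop_field("mean_sleep_h", "must be > 0")
  if (is.na(cfg$start_date)) stop_field("start_date", "must be a valid date")
  if (!is.character(cfg$timezone) || !(cfg$timezone %in% OlsonNames())) {
    stop_field("timezone", "must be a known Olson timezone name")
  }
  if (is.na(cfg$seed)) stop_field("seed", "must be an integer")
  structure(cfg, class = "kap_sim_config")
}

#' @export
print.kap_sim_config <- function(x, ...) {
  cat(sprintf("<kap_sim_config> %d participants x %d nights from %s (%s), seed %d\n",
              x$n_participants, x$n_nights, format(x$start_date), x$timezone,
              x$seed))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' The YAML schema has one key per [kap_sim_config()] field; missing keys fall
#' back to the documented defaults, unknown keys raise an error.
#'
#' @param path YAML file path.
#' @return `read_sim_config()` returns a validated `kap_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(kap_sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown simulation config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(kap_sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a `kap_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$start_date <- format(cfg$start_date)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
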