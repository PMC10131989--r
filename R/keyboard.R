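#' Longest keystroke-absence period (KAP) within a nightly window
#'
#' The keyboard-derived rest estimate: among the events falling inside the
#' nightly analysis window (7 PM on the anchor evening to 3 PM the next day,
#' night-axis hours 7 to 27, bounds inclusive), the longest gap between two
#' consecutive keystrokes. The keystroke starting the gap is the
#' last-keystroke estimate of rest onset, the keystroke ending it the
#' first-keystroke estimate of activity onset; `kap_h` is their difference
#' and `midpoint_kap` their mean. Gaps to the window edges are not
#' candidates: a KAP must be bracketed by keystrokes. Ties for the longest
#' gap resolve to the earliest-starting gap. With fewer than two events in
#' the window the night is returned with `valid = FALSE` and missing
#' estimates, never an error.
#'
#' @param event_hours numeric night-axis hours of one participant's events
#'   (any order; only events inside the window are used).
#' @param window numeric length-2, window start/end on the night axis.
#' @return one-row data.frame: `last_keystroke`, `first_keystroke`, `kap_h`,
#'   `midpoint_kap`, `n_events_in_window`, `valid`.
#' @export
#' @examples
#' # events at 21:30 and 22:00, then 07:30 and 08:00 the next morning
#' extract_kap(c(9.5, 10, 19.5, 20))
extract_kap <- function(event_hours, window = c(7, 27)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  t <- sort(event_hours[!is.na(event_hours) &
                          event_hours >= window[1] & event_hours <= window[2]])
  n <- length(t)
  if (n < 2L) {
    return(data.frame(last_keystroke = NA_real_, first_keystroke = NA_real_,
                      kap_h = NA_real_, midpoint_kap = NA_real_,
                      n_events_in_window = n, valid = FALSE))
  }
  gaps <- diff(t)
  i <- which.max(gaps) # which.max takes the first maximum: earliest start
  data.frame(
    last_keystroke = t[i], first_keystroke = t[i + 1L],
    kap_h = gaps[i], midpoint_kap = (t[i] + t[i + 1L]) / 2,
    n_events_in_window = n, valid = TRUE
  )
}

#' Hours of the day with keyboard activity
#'
#' Counts the distinct clock-hour bins (00-23) of a calendar date containing
#' at least one keystroke; the day-level regularity covariate.
#'
#' @param timestamps POSIXct events of one participant.
#' @param calendar_date the date to count.
#' @param tz timezone in which dates and hour bins are taken.
#' @return integer in 0..24.
#' @export
hours_with_activity <- function(timestamps, calendar_date, tz = "UTC") {
  if (length(timestamps) == 0L) return(0L)
  on_day <- as.Date(format(timestamps, "%Y-%m-%d", tz = tz)) == as.Date(calendar_date)
  if (!any(on_day)) return(0L)
  length(unique(format(timestamps[on_day], "%H", tz = tz)))
}

#' Extract keyboard night estimates and day-activity counts for a cohort
#'
#' Runs [extract_kap()] for every participant x anchor date and tabulates
#' [hours_with_activity()] for every participant x calendar date spanned by
#' the anchors. Nights with fewer than two in-window events are retained
#' with `valid = FALSE`; the overall validity rate is logged.
#'
#' @param events data.frame `participant_id`, `timestamp` (POSIXct).
#' @param anchor_dates vector of anchor dates (one per night). Defaults to
#'   every date from the first to the day before the last event date.
#' @param participants participant ids to extract; defaults to all present.
#' @param tz timezone used to anchor the nightly windows.
#' @param window night-axis window passed to [extract_kap()].
#' @return list with `nights` (one row per participant x anchor:
#'   KeyboardNightEstimate columns plus `participant_id`, `anchor_date`) and
#'   `day_activity` (`participant_id`, `calendar_date`,
#'   `hours_with_activity`).
#' @export
extract_all_nights <- function(events, anchor_dates = NULL,
                               participants = NULL, tz = "UTC",
                               window = c(7, 27)) {
  if (is.null(participants)) participants <- sort(unique(events$participant_id))
  if (nrow(events) == 0L || length(participants) == 0L) {
    warning("extract_all_nights: empty event table", call. = FALSE)
    return(list(
      nights = data.frame(participant_id = character(), anchor_date = as.Date(character()),
                          last_keystroke = numeric(), first_keystroke = numeric(),
                          kap_h = numeric(), midpoint_kap = numeric(),
                          n_events_in_window = integer(), valid = logical()),
      day_activity = data.frame(participant_id = character(),
                                calendar_date = as.Date(character()),
                                hours_with_activity = integer())
    ))
  }
  if (is.null(anchor_dates)) {
    dts <- as.Date(format(events$timestamp, "%Y-%m-%d", tz = tz))
    anchor_dates <- seq(min(dts), max(max(dts) - 1, min(dts)), by = "day")
  }
  anchor_dates <- as.Date(anchor_dates)
  cal_dates <- seq(min(anchor_dates), max(anchor_dates) + 1, by = "day")

  by_part <- split(events$timestamp, factor(events$participant_id, levels = participants))
  nights <- list(); activity <- list()
  for (pid in participants) {
    ts <- by_part[[pid]]
    abs_h <- if (length(ts)) {
      as.numeric(difftime(ts, anchor_noon(anchor_dates[1], tz), units = "hours"))
    } else numeric(0)
    for (k in seq_along(anchor_dates)) {
      offset_h <- 24 * as.numeric(anchor_dates[k] - anchor_dates[1])
      est <- extract_kap(abs_h - offset_h, window = window)
      nights[[length(nights) + 1L]] <- cbind(
        data.frame(participant_id = pid, anchor_date = anchor_dates[k],
                   stringsAsFactors = FALSE), est)
    }
    hrs <- vapply(cal_dates, function(d) hours_with_activity(ts, d, tz = tz),
                  integer(1))
    activity[[length(activity) + 1L]] <- data.frame(
      participant_id = pid, calendar_date = cal_dates,
      hours_with_activity = hrs, stringsAsFactors = FALSE)
  }
  nights <- do.call(rbind, nights)
  rownames(nights) <- NULL
  message(sprintf("extract_all_nights: %d/%d nights valid (%.1f%%)",
                  sum(nights$valid), nrow(nights),
                  100 * mean(nights$valid)))
  list(nights = nights, day_activity = do.call(rbind, activity))
}

#' Write keyboard night estimates as CSV
#'
#' Adds human-readable clock strings next to the night-axis hours.
#'
#' @param nights the `nights` table from [extract_all_nights()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_keyboard_nights <- function(nights, path) {
  d <- nights
  for (col in c("last_keystroke", "first_keystroke", "midpoint_kap")) {
    d[[paste0(col, "_clock")]] <- format_clock(clock_from_night_axis(d[[col]]))
  }
  d$anchor_date <- format(as.Date(d$anchor_date))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
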