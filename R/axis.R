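#' The night axis
#'
#' All night-level quantities in this package live on a common "night axis":
#' decimal hours since 12:00 noon of the night's *anchor date* (the evening
#' the night starts). On this axis 7 PM is 7.0, midnight is 12.0 and 3 PM of
#' the next day is 27.0, so every time within one night maps to a single
#' monotone coordinate and no arithmetic ever wraps around midnight.
#'
#' Clock times are mapped with the morning-report convention used for sleep
#' diaries: clock times at or before 15:00 belong to the morning after the
#' anchor date (axis = clock + 12), later clock times to the anchor evening
#' itself (axis = clock - 12). The analysis window for keyboard data ends at
#' 3 PM, so the boundary is 15:00.
#'
#' @name night-axis
#' @keywords internal
NULL

#' Convert clock hours to night-axis hours
#'
#' @param clock_h numeric clock time in decimal hours, in `[0, 24)`.
#' @return night-axis hours in `[3, 27)`; `NA` maps to `NA`.
#' @seealso [clock_from_night_axis()]
#' @export
#' @examples
#' night_axis_from_clock(23.5) # 11.5 (11:30 PM on the anchor evening)
#' night_axis_from_clock(1)    # 13   (01:00 the next morning)
night_axis_from_clock <- function(clock_h) {
  bad <- !is.na(clock_h) & (clock_h < 0 | clock_h >= 24)
  if (any(bad)) stop("clock hours must lie in [0, 24)")
  ifelse(clock_h <= 15, clock_h + 12, clock_h - 12)
}

#' Convert night-axis hours back to clock hours
#'
#' @param axis_h numeric night-axis hours.
#' @return clock hours in `[0, 24)`.
#' @export
clock_from_night_axis <- function(axis_h) {
  (axis_h + 12) %% 24
}

#' Parse "HH:MM" / "HH:MM:SS" clock strings to decimal hours
#'
#' Invalid or impossible values (hours > 23, minutes > 59, garbage) return
#' `NA` rather than raising, matching the diary policy of coding ambiguous
#' values as missing.
#'
#' @param x character vector of clock strings.
#' @return numeric decimal hours, `NA` where unparseable.
#' @export
parse_clock <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})(?::([0-9]{2}))?$", x))
  vapply(m, function(p) {
    if (length(p) == 0L) return(NA_real_)
    h <- as.numeric(p[2]); mi <- as.numeric(p[3])
    s <- if (p[4] == "") 0 else as.numeric(p[4])
    if (is.na(h) || h > 23 || mi > 59 || s > 59) return(NA_real_)
    h + mi / 60 + s / 3600
  }, numeric(1))
}

#' Format decimal clock hours as "HH:MM"
#'
#' @param clock_h numeric clock hours in `[0, 24)`.
#' @return character vector; `NA` stays `NA`.
#' @export
format_clock <- function(clock_h) {
  mins <- round(clock_h * 60) %% (24 * 60)
  out <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
  out[is.na(clock_h)] <- NA_character_
  out
}

#' Noon of an anchor date as an absolute instant
#'
#' @param anchor_date a `Date` (or string coercible to one).
#' @param tz Olson timezone name.
#' @return `POSIXct` at 12:00 local time on `anchor_date`.
#' @keywords internal
anchor_noon <- function(anchor_date, tz) {
  as.POSIXct(paste(as.Date(anchor_date), "12:00:00"), tz = tz)
}

#' Absolute timestamps to night-axis hours for a given anchor
#'
#' Durations are computed on the absolute timeline (`difftime`), so nights
#' containing a DST transition yield correct elapsed hours.
#'
#' @param timestamp `POSIXct` vector.
#' @param anchor_date the night's anchor date.
#' @param tz timezone used to place noon of the anchor date.
#' @return numeric night-axis hours.
#' @export
night_axis_hours <- function(timestamp, anchor_date, tz) {
  as.numeric(difftime(timestamp, anchor_noon(anchor_date, tz), units = "hours"))
}
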