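#' Read and write keystroke event tables
#'
#' Events are one row per keystroke: `participant_id`, `timestamp`.
#' Timestamps are written as ISO-8601 with an explicit UTC offset at
#' millisecond precision (`2020-09-14T21:03:11.042+0200`) and parsed back to
#' `POSIXct` on the same millisecond grid, so a write/read round trip is an
#' exact identity. On reading, events are sorted within participant and exact
#' duplicate records are dropped with a logged count.
#'
#' @param path file path (`.csv`, or `.jsonl` for JSON-lines).
#' @param default_tz timezone applied to timestamps that carry no UTC offset,
#'   and used as the display timezone of the result. When `NULL`, a timestamp
#'   without an offset is an error.
#' @param format `"csv"` or `"jsonl"`; the default infers from the file
#'   extension.
#' @return `read_events()`: data.frame `participant_id`, `timestamp`
#'   (POSIXct). `write_events()`: `path`, invisibly.
#' @export
read_events <- function(path, default_tz = "UTC", format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  if (format == "csv") {
    d <- utils::read.csv(path, colClasses = "character")
  } else {
    lines <- readLines(path)
    d <- do.call(rbind, lapply(lines, function(l) {
      as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
    }))
  }
  need <- c("participant_id", "timestamp")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("events table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ts <- parse_iso8601(d$timestamp, default_tz = default_tz)
  out <- data.frame(participant_id = d$participant_id, timestamp = ts,
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$timestamp), , drop = FALSE]
  dup <- duplicated(out)
  if (any(dup)) {
    message(sprintf("read_events: dropped %d exact duplicate record(s)", sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' @rdname read_events
#' @param events data.frame with `participant_id` and POSIXct `timestamp`.
#' @export
write_events <- function(events, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  stamp <- format_iso8601(events$timestamp)
  if (format == "csv") {
    utils::write.csv(
      data.frame(participant_id = events$participant_id, timestamp = stamp),
      path, row.names = FALSE, quote = FALSE
    )
  } else {
    writeLines(sprintf('{"participant_id":"%s","timestamp":"%s"}',
                       events$participant_id, stamp), path)
  }
  invisible(path)
}

# Millisecond component built by explicit rounding: %OS3 truncates, which
# would shift times stored a hair below the grid point by 1 ms.
#' @keywords internal
format_iso8601 <- function(ts) {
  tz <- attr(ts, "tzone")
  if (is.null(tz)) tz <- ""
  ms_total <- round(as.numeric(ts) * 1000)
  secs <- floor(ms_total / 1000)
  ms <- as.integer(ms_total - secs * 1000)
  base <- as.POSIXct(secs, origin = "1970-01-01", tz = tz)
  sprintf("%s.%03d%s", format(base, "%Y-%m-%dT%H:%M:%S"), ms,
          format(base, "%z"))
}

# Parse ISO-8601 timestamps; records with a [+-]HHMM / Z offset are absolute,
# the rest require default_tz. Unparseable entries raise, naming the line.
#' @keywords internal
parse_iso8601 <- function(x, default_tz = "UTC") {
  x <- trimws(x)
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x) # +02:00 -> +0200
  has_offset <- grepl("[+-][0-9]{4}$", x)
  out <- rep(as.POSIXct(NA), length(x))
  tz_out <- if (is.null(default_tz)) "UTC" else default_tz
  if (any(has_offset)) {
    p <- as.POSIXct(x[has_offset], format = "%Y-%m-%dT%H:%M:%OS%z", tz = tz_out)
    out[has_offset] <- p
  }
  if (any(!has_offset)) {
    if (is.null(default_tz)) {
      stop(sprintf("timestamp without UTC offset at line %d and no default timezone configured",
                   which(!has_offset)[1] + 1L), call. = FALSE)
    }
    p <- as.POSIXct(x[!has_offset], format = "%Y-%m-%dT%H:%M:%OS", tz = default_tz)
    out[!has_offset] <- p
  }
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop(sprintf("unparseable timestamp '%s' at line %d", x[which(bad)[1]],
                 which(bad)[1] + 1L), call. = FALSE)
  }
  # strptime leaves sub-ms float noise; snap back to the millisecond grid
  out <- as.POSIXct(round(as.numeric(out), 3), origin = "1970-01-01", tz = tz_out)
  out
}

#' Read and write morning sleep-diary tables
#'
#' The diary CSV has one row per participant-morning with columns
#' `participant_id`, `report_date` (ISO date of the morning report),
#' `bedtime`, `try_to_sleep`, `sleep_offset`, `out_of_bed` (24-hour "HH:MM"
#' strings), `latency_min` (minutes) and `woke_by_alarm` (logical). Ambiguous
#' or impossible values (unparseable clock strings, negative latencies) are
#' coded missing and the affected row is retained; structurally missing
#' required columns are an error.
#'
#' @param path CSV file path.
#' @return `read_diary()`: data.frame of diary records. `write_diary()`:
#'   `path`, invisibly.
#' @export
read_diary <- function(path) {
  if (!file.exists(path)) stop("diary file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("participant_id", "report_date", "bedtime", "try_to_sleep",
            "latency_min", "sleep_offset", "out_of_bed")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("diary table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  clean_clock <- function(x) {
    out <- x
    out[!is.na(x) & is.na(parse_clock(x))] <- NA_character_
    out[!nzchar(trimws(ifelse(is.na(out), "", out)))] <- NA_character_
    out
  }
  lat <- suppressWarnings(as.numeric(d$latency_min))
  lat[!is.na(lat) & lat < 0] <- NA_real_
  n_invalid <- sum(!is.na(d$latency_min) & nzchar(d$latency_min) & is.na(lat))
  out <- data.frame(
    participant_id = d$participant_id,
    report_date = as.Date(d$report_date),
    bedtime = clean_clock(d$bedtime),
    try_to_sleep = clean_clock(d$try_to_sleep),
    latency_min = lat,
    sleep_offset = clean_clock(d$sleep_offset),
    out_of_bed = clean_clock(d$out_of_bed),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$report_date))) {
    stop("diary table has missing/unparseable report_date", call. = FALSE)
  }
  out$woke_by_alarm <- if ("woke_by_alarm" %in% names(d)) {
    as.logical(d$woke_by_alarm)
  } else NA
  out
}

#' @rdname read_diary
#' @param diary data.frame of diary records as returned by [read_diary()] or
#'   [simulate_cohort()].
#' @export
write_diary <- function(diary, path) {
  d <- diary
  d$report_date <- format(as.Date(d$report_date))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write person-level trait tables
#'
#' Columns: `participant_id`, `msfsc` (corrected free-day midsleep, clock
#' hours), `psqi` (0-21), `tsc` (1-5) and optionally `social_jetlag_h`.
#' Out-of-range scores are coded missing with a message.
#'
#' @param path CSV file path.
#' @return `read_traits()`: data.frame of trait records. `write_traits()`:
#'   `path`, invisibly.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("traits file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "msfsc", "psqi", "tsc")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("traits table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_psqi <- !is.na(d$psqi) & (d$psqi < 0 | d$psqi > 21)
  bad_tsc <- !is.na(d$tsc) & (d$tsc < 1 | d$tsc > 5)
  if (any(bad_psqi) || any(bad_tsc)) {
    message(sprintf("read_traits: coded %d out-of-range score(s) as missing",
                    sum(bad_psqi) + sum(bad_tsc)))
    d$psqi[bad_psqi] <- NA
    d$tsc[bad_tsc] <- NA
  }
  d
}

#' @rdname read_traits
#' @param traits data.frame of trait records.
#' @export
write_traits <- function(traits, path) {
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
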