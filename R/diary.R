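#' Derive night-level sleep estimates from raw diary records
#'
#' Maps the morning report's clock strings onto the night axis (anchor date =
#' report date minus one day; clock times at or before 15:00 belong to the
#' report morning, later times to the anchor evening) and derives the eight
#' self-reported rest-activity metrics:
#' sleep onset = try-to-sleep + latency, midsleep = (onset + offset) / 2,
#' total sleep period = offset - onset, total bed period = out-of-bed -
#' bedtime. Missing inputs propagate to the derived values. Ordering
#' violations after mapping (sleep offset not after onset; out-of-bed before
#' bedtime) code the affected derived fields missing and are logged.
#'
#' @param diary data.frame of raw diary records (see [read_diary()]).
#' @return data.frame, one row per record: `participant_id`, `anchor_date`,
#'   `bedtime`, `try_to_sleep`, `sleep_onset`, `midsleep`, `sleep_offset`,
#'   `out_of_bed` (night-axis hours), `total_sleep_period_h`,
#'   `total_bed_period_h`, `woke_by_alarm`.
#' @export
#' @examples
#' rec <- data.frame(participant_id = "P001", report_date = as.Date("2020-09-15"),
#'                   bedtime = "23:00", try_to_sleep = "23:30", latency_min = 30,
#'                   sleep_offset = "07:30", out_of_bed = "08:00")
#' derive_diary_nights(rec) # onset 00:00, midsleep 03:45, TSP 7.5 h, TBP 9 h
derive_diary_nights <- function(diary) {
  ax <- function(col) night_axis_from_clock(parse_clock(diary[[col]]))
  bedtime <- ax("bedtime")
  try_to_sleep <- ax("try_to_sleep")
  sleep_offset <- ax("sleep_offset")
  out_of_bed <- ax("out_of_bed")
  latency_h <- as.numeric(diary$latency_min) / 60

  sleep_onset <- try_to_sleep + latency_h
  bad_sleep <- !is.na(sleep_onset) & !is.na(sleep_offset) & sleep_offset <= sleep_onset
  bad_bed <- !is.na(bedtime) & !is.na(out_of_bed) & out_of_bed < bedtime
  n_bad <- sum(bad_sleep) + sum(bad_bed)
  if (n_bad > 0) {
    message(sprintf(
      "derive_diary_nights: %d ordering violation(s); affected derived fields coded missing",
      n_bad))
  }

  midsleep <- (sleep_onset + sleep_offset) / 2
  tsp <- sleep_offset - sleep_onset
  tbp <- out_of_bed - bedtime
  midsleep[bad_sleep] <- NA_real_
  tsp[bad_sleep] <- NA_real_
  tbp[bad_bed] <- NA_real_

  data.frame(
    participant_id = diary$participant_id,
    anchor_date = as.Date(diary$report_date) - 1,
    bedtime = bedtime, try_to_sleep = try_to_sleep,
    sleep_onset = sleep_onset, midsleep = midsleep,
    sleep_offset = sleep_offset, out_of_bed = out_of_bed,
    total_sleep_period_h = tsp, total_bed_period_h = tbp,
    woke_by_alarm = if ("woke_by_alarm" %in% names(diary)) diary$woke_by_alarm else NA,
    stringsAsFactors = FALSE
  )
}

#' Flag gross outliers against the pooled mean
#'
#' Marks values whose absolute z score against the pooled (all participants,
#' all nights) mean and SD of the metric exceeds `k`; the flagged values are
#' coded missing before any modeling. The rule is applied per metric in a
#' single pass, without re-iteration after removal.
#'
#' @param values numeric series of one metric (may contain `NA`).
#' @param k SD multiplier; the default 4 flags values more than 4 SD from the
#'   mean.
#' @return logical vector, `TRUE` where the value is an outlier (`FALSE` for
#'   missing values).
#' @export
flag_outliers <- function(values, k = 4) {
  ok <- !is.na(values)
  if (!any(ok)) {
    warning("flag_outliers: all values missing; empty mask", call. = FALSE)
    return(rep(FALSE, length(values)))
  }
  if (sum(ok) < 3L) stop("flag_outliers: need at least 3 non-missing values")
  m <- mean(values[ok])
  s <- stats::sd(values[ok])
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  out <- abs(values - m) / s > k
  out[!ok] <- FALSE
  out
}

#' Apply the outlier rule to every metric column of a night table
#'
#' @param nights data.frame of night estimates.
#' @param cols metric columns to screen; defaults to every numeric estimate
#'   column present.
#' @param k SD multiplier passed to [flag_outliers()].
#' @return `nights` with flagged values set to `NA`; the per-column flag
#'   counts are attached as attribute `"n_outliers"`.
#' @export
apply_outlier_rule <- function(nights, cols = NULL, k = 4) {
  if (is.null(cols)) {
    candidates <- c("last_keystroke", "first_keystroke", "kap_h", "midpoint_kap",
                    "bedtime", "try_to_sleep", "sleep_onset", "midsleep",
                    "sleep_offset", "out_of_bed", "total_sleep_period_h",
                    "total_bed_period_h")
    cols <- intersect(candidates, names(nights))
  }
  counts <- integer(length(cols)); names(counts) <- cols
  for (col in cols) {
    bad <- flag_outliers(nights[[col]], k = k)
    counts[col] <- sum(bad)
    nights[[col]][bad] <- NA_real_
  }
  attr(nights, "n_outliers") <- counts
  nights
}

#' Write diary night estimates as CSV
#'
#' Mirrors the keyboard-night layout (night-axis hours plus clock strings)
#' so the two tables stack cleanly.
#'
#' @param nights output of [derive_diary_nights()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_diary_nights <- function(nights, path) {
  d <- nights
  for (col in c("bedtime", "try_to_sleep", "sleep_onset", "midsleep",
                "sleep_offset", "out_of_bed")) {
    d[[paste0(col, "_clock")]] <- format_clock(clock_from_night_axis(d[[col]]))
  }
  d$anchor_date <- format(as.Date(d$anchor_date))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
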