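#' The eight keyboard/diary metric pairs
#'
#' Each keyboard-derived proxy is compared with its self-reported
#' counterpart(s): the last keystroke with bedtime, try-to-sleep and sleep
#' onset; the midpoint of the keystroke-absence period with midsleep; the
#' first keystroke with sleep offset and out-of-bed; and the KAP duration
#' with the total sleep and total bed periods.
#'
#' @return data.frame with `pair`, `keyboard_col`, `diary_col`, `kind`
#'   (`"timing"` or `"duration"`).
#' @export
kap_metric_pairs <- function() {
  data.frame(
    pair = c("last_keystroke.bedtime", "last_keystroke.try_to_sleep",
             "last_keystroke.sleep_onset", "midpoint_kap.midsleep",
             "first_keystroke.sleep_offset", "first_keystroke.out_of_bed",
             "kap.total_sleep_period", "kap.total_bed_period"),
    keyboard_col = c("last_keystroke", "last_keystroke", "last_keystroke",
                     "midpoint_kap", "first_keystroke", "first_keystroke",
                     "kap_h", "kap_h"),
    diary_col = c("bedtime", "try_to_sleep", "sleep_onset", "midsleep",
                  "sleep_offset", "out_of_bed", "total_sleep_period_h",
                  "total_bed_period_h"),
    kind = c(rep("timing", 6), rep("duration", 2)),
    stringsAsFactors = FALSE
  )
}

#' Align keyboard and diary night estimates into paired-night tables
#'
#' Full outer join on participant x anchor date, one table per metric pair.
#' `diff_h = keyboard - diary`, so negative differences mean an earlier
#' timing or shorter duration for the keyboard-derived estimate. A night is
#' a weekend night when its morning (anchor date + 1) falls on Saturday or
#' Sunday. When a day-activity table is supplied, `hours_prev_day` is the
#' activity-hour count on the anchor date (the evening before the rest
#' period) and `hours_next_day` the count on the morning date.
#'
#' @param keyboard_nights `nights` table from [extract_all_nights()].
#' @param diary_nights output of [derive_diary_nights()].
#' @param day_activity optional `day_activity` table from
#'   [extract_all_nights()].
#' @param pairs which metric pairs to build; default all eight.
#' @return named list of paired-night data.frames (`participant_id`,
#'   `anchor_date`, `keyboard`, `diary`, `diff_h`, `type_of_day`,
#'   `hours_prev_day`, `hours_next_day`).
#' @export
pair_nights <- function(keyboard_nights, diary_nights, day_activity = NULL,
                        pairs = kap_metric_pairs()) {
  kb <- keyboard_nights
  dy <- diary_nights
  kb$anchor_date <- as.Date(kb$anchor_date)
  dy$anchor_date <- as.Date(dy$anchor_date)
  joined <- merge(kb, dy, by = c("participant_id", "anchor_date"),
                  all = TRUE, suffixes = c(".kb", ".dy"))
  if (nrow(joined) > 0 && !any(
    joined$participant_id %in% kb$participant_id &
      joined$participant_id %in% dy$participant_id)) {
    warning("pair_nights: no overlapping participant keys between modalities",
            call. = FALSE)
  }
  morning <- joined$anchor_date + 1
  joined$type_of_day <- factor(
    ifelse(format(morning, "%u") %in% c("6", "7"), "weekend", "weekday"),
    levels = c("weekday", "weekend"))
  if (!is.null(day_activity)) {
    da <- day_activity
    da$calendar_date <- as.Date(da$calendar_date)
    key <- function(p, d) paste(p, format(d))
    idx <- stats::setNames(da$hours_with_activity,
                           key(da$participant_id, da$calendar_date))
    joined$hours_prev_day <- unname(idx[key(joined$participant_id, joined$anchor_date)])
    joined$hours_next_day <- unname(idx[key(joined$participant_id, morning)])
  } else {
    joined$hours_prev_day <- NA_integer_
    joined$hours_next_day <- NA_integer_
  }

  out <- lapply(seq_len(nrow(pairs)), function(i) {
    kcol <- pairs$keyboard_col[i]
    dcol <- pairs$diary_col[i]
    if (kcol %in% names(joined)) k <- joined[[kcol]] else k <- joined[[paste0(kcol, ".kb")]]
    if (dcol %in% names(joined)) d <- joined[[dcol]] else d <- joined[[paste0(dcol, ".dy")]]
    data.frame(
      participant_id = joined$participant_id,
      anchor_date = joined$anchor_date,
      keyboard = k, diary = d, diff_h = k - d,
      type_of_day = joined$type_of_day,
      hours_prev_day = joined$hours_prev_day,
      hours_next_day = joined$hours_next_day,
      stringsAsFactors = FALSE
    )
  })
  stats::setNames(out, pairs$pair)
}

#' Intraclass correlation from an unconditional multilevel model
#'
#' Fits the intercept-only random-intercept model and reports the share of
#' variance at the participant level: `icc = var_between / (var_between +
#' var_within)`. A singular fit (zero between-participant variance) returns
#' `icc = 0` with `singular = TRUE` rather than an error.
#'
#' @param values numeric metric values (one per night).
#' @param participant_id grouping vector aligned with `values`.
#' @return list of class `kap_icc`: `icc`, `var_between`, `var_within`,
#'   `singular`, `n_obs`, `n_participants`.
#' @export
icc_unconditional <- function(values, participant_id) {
  ok <- !is.na(values) & !is.na(participant_id)
  d <- data.frame(y = values[ok], g = as.character(participant_id[ok]))
  tab <- table(d$g)
  if (length(tab) < 2L) stop("icc_unconditional: need >= 2 participants")
  if (max(tab) < 2L) {
    stop("icc_unconditional: every participant has a single observation; ",
         "between/within variance is not separable")
  }
  fit <- lmerTest::lmer(y ~ 1 + (1 | g), data = d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == "g"]
  vw <- vc$vcov[vc$grp == "Residual"]
  singular <- lme4::isSingular(fit)
  structure(list(
    icc = if (vb + vw > 0) vb / (vb + vw) else 0,
    var_between = vb, var_within = vw, singular = singular,
    n_obs = nrow(d), n_participants = length(tab), fit = fit
  ), class = "kap_icc")
}

#' @export
print.kap_icc <- function(x, ...) {
  cat(sprintf("ICC %.3f (between %.3f, within %.3f; %d participants, %d obs)%s\n",
              x$icc, x$var_between, x$var_within, x$n_participants, x$n_obs,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' Test modality differences: NHST and TOST equivalence
#'
#' Stacks the paired nights into long format (two rows per night: the diary
#' value and the keyboard value) and fits a multilevel model with modality
#' as a fixed factor and a participant random intercept. The modality
#' coefficient is the mean keyboard-minus-diary difference. The null
#' hypothesis of no difference is tested at alpha = .01 (99% CI); statistical
#' equivalence uses the two one-sided tests criterion at the same alpha:
#' equivalence at bound `delta` is declared when the 98% CI lies strictly
#' inside `(-delta, +delta)`. Degrees of freedom are Satterthwaite
#' approximations; if the mixed model cannot be fit (degenerate variance),
#' the function falls back to a paired t test and flags it.
#'
#' @param paired one paired-night table from [pair_nights()].
#' @param bounds equivalence bounds in hours (default 0.5 and 1).
#' @param alpha significance criterion (default .01).
#' @return list of class `kap_equivalence`: `mean_diff_h`, `se`, `df`,
#'   `nhst_t`, `nhst_p`, `ci99`, `ci98`, `tost_p` (named by bound),
#'   `equivalent` (named logical by bound), `n_obs`, `n_participants`,
#'   `fallback`.
#' @export
test_difference <- function(paired, bounds = c(0.5, 1), alpha = 0.01) {
  d <- paired[!is.na(paired$keyboard) & !is.na(paired$diary), , drop = FALSE]
  n_part <- length(unique(d$participant_id))
  if (n_part < 10L) {
    stop("test_difference: need >= 10 participants with both modalities")
  }
  long <- data.frame(
    value = c(d$diary, d$keyboard),
    modality = factor(rep(c("diary", "keyboard"), each = nrow(d)),
                      levels = c("diary", "keyboard")),
    participant_id = rep(d$participant_id, 2L)
  )
  fallback <- FALSE
  est <- se <- df <- tval <- p <- NA_real_
  fit <- tryCatch(
    lmerTest::lmer(value ~ modality + (1 | participant_id), data = long,
                   REML = TRUE),
    error = function(e) NULL)
  if (!is.null(fit)) {
    ct <- tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
    if (!is.null(ct) && "modalitykeyboard" %in% rownames(ct) &&
        is.finite(ct["modalitykeyboard", "Std. Error"]) &&
        ct["modalitykeyboard", "Std. Error"] > 0) {
      est <- ct["modalitykeyboard", "Estimate"]
      se <- ct["modalitykeyboard", "Std. Error"]
      df <- ct["modalitykeyboard", "df"]
      tval <- ct["modalitykeyboard", "t value"]
      p <- ct["modalitykeyboard", "Pr(>|t|)"]
    } else fit <- NULL
  }
  if (is.null(fit)) {
    warning("test_difference: degenerate mixed-model fit; falling back to a paired t test",
            call. = FALSE)
    fallback <- TRUE
    tt <- stats::t.test(d$diff_h)
    est <- unname(tt$estimate); se <- tt$stderr; df <- unname(tt$parameter)
    tval <- unname(tt$statistic); p <- tt$p.value
  }
  ci_at <- function(level) est + c(-1, 1) * stats::qt(1 - (1 - level) / 2, df) * se
  ci99 <- ci_at(1 - alpha)
  ci98 <- ci_at(1 - 2 * alpha)
  tost_p <- vapply(bounds, function(delta) {
    p_up <- stats::pt((est - delta) / se, df)        # H0: diff >= +delta
    p_lo <- stats::pt((est + delta) / se, df, lower.tail = FALSE)
    max(p_up, p_lo)
  }, numeric(1))
  equivalent <- ci98[1] > -bounds & ci98[2] < bounds
  names(tost_p) <- names(equivalent) <- paste0("delta_", bounds)
  structure(list(
    mean_diff_h = est, se = se, df = df, nhst_t = tval, nhst_p = p,
    ci99 = ci99, ci98 = ci98, tost_p = tost_p, equivalent = equivalent,
    bounds = bounds, alpha = alpha, n_obs = nrow(d),
    n_participants = n_part, fallback = fallback
  ), class = "kap_equivalence")
}

#' @export
print.kap_equivalence <- function(x, ...) {
  cat(sprintf("mean diff %+.3f h, 99%% CI [%.3f, %.3f], p = %.3g (df %.1f)\n",
              x$mean_diff_h, x$ci99[1], x$ci99[2], x$nhst_p, x$df))
  cat(sprintf("98%% CI [%.3f, %.3f]; equivalent at +/-%s h: %s\n",
              x$ci98[1], x$ci98[2],
              paste(x$bounds, collapse = "/"),
              paste(x$equivalent, collapse = "/")))
  invisible(x)
}

#' Repeated-measures Bland-Altman summary
#'
#' Agreement summary adjusted for repeated measures: the bias is the mean
#' difference from the unconditional multilevel model on the night-level
#' differences, and the limits of agreement are
#' `bias +/- 1.96 * sqrt(var_between + var_within)` of those differences, so
#' both the person-level and the night-level spread of the disagreement
#' enter the limits. The returned per-night table (mean of the two
#' modalities vs their difference) is the plotting surface.
#'
#' @param paired one paired-night table from [pair_nights()].
#' @return list of class `kap_bland_altman`: `bias`, `loa` (length 2),
#'   `var_between`, `var_within`, `per_night` data.frame, `n_obs`,
#'   `n_participants`.
#' @export
bland_altman_rm <- function(paired) {
  d <- paired[!is.na(paired$diff_h), , drop = FALSE]
  if (nrow(d) < 3L) stop("bland_altman_rm: need >= 3 paired nights")
  if (stats::sd(d$diff_h) < 1e-12) {
    bias <- mean(d$diff_h); vb <- 0; vw <- 0
  } else {
    fit <- lmerTest::lmer(diff_h ~ 1 + (1 | participant_id), data = d, REML = TRUE)
    bias <- unname(lme4::fixef(fit)[1])
    vc <- as.data.frame(lme4::VarCorr(fit))
    vb <- vc$vcov[vc$grp == "participant_id"]
    vw <- vc$vcov[vc$grp == "Residual"]
  }
  sd_tot <- sqrt(vb + vw)
  structure(list(
    bias = bias, loa = bias + c(-1.96, 1.96) * sd_tot,
    var_between = vb, var_within = vw,
    per_night = data.frame(
      participant_id = d$participant_id, anchor_date = d$anchor_date,
      mean_h = (d$keyboard + d$diary) / 2, diff_h = d$diff_h),
    n_obs = nrow(d), n_participants = length(unique(d$participant_id))
  ), class = "kap_bland_altman")
}

#' @export
print.kap_bland_altman <- function(x, ...) {
  cat(sprintf("bias %+.3f h, limits of agreement [%.3f, %.3f] (n = %d)\n",
              x$bias, x$loa[1], x$loa[2], x$n_obs))
  invisible(x)
}

#' Simulate paired modality measurements for calibration checks
#'
#' Validation harness: keyboard and diary values share a participant random
#' intercept (`sd_between`) and independent night-level noise (`sd_within`),
#' with a constant modality shift `true_diff` added to the keyboard side.
#'
#' @param n_participants,n_nights cohort size.
#' @param true_diff mean keyboard-minus-diary difference (hours).
#' @param sd_between SD of the shared participant intercept.
#' @param sd_within SD of each modality's night-level noise.
#' @param mu grand mean, default 0.
#' @return a paired-night data.frame usable by [test_difference()] and
#'   [bland_altman_rm()].
#' @export
simulate_paired_diffs <- function(n_participants, n_nights, true_diff = 0,
                                  sd_between = 0.5, sd_within = 1, mu = 0) {
  id <- rep(sprintf("S%03d", seq_len(n_participants)), each = n_nights)
  u <- rep(stats::rnorm(n_participants, 0, sd_between), each = n_nights)
  n <- n_participants * n_nights
  diary <- mu + u + stats::rnorm(n, 0, sd_within)
  keyboard <- mu + u + true_diff + stats::rnorm(n, 0, sd_within)
  data.frame(
    participant_id = id,
    anchor_date = rep(as.Date("2020-09-14") + seq_len(n_nights) - 1, n_participants),
    keyboard = keyboard, diary = diary, diff_h = keyboard - diary,
    type_of_day = factor("weekday", levels = c("weekday", "weekend")),
    hours_prev_day = NA_integer_, hours_next_day = NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Monte-Carlo calibration of the TOST equivalence decision
#'
#' Repeatedly simulates paired cohorts with a known true modality difference
#' and reports how often [test_difference()] declares equivalence at the
#' given bound. With the true difference placed exactly at the bound this
#' estimates the size of the equivalence test; with the true difference at
#' zero it estimates its power.
#'
#' @param n_reps number of Monte-Carlo replicates (>= 2).
#' @param n_participants,n_nights,true_diff,sd_between,sd_within passed to
#'   [simulate_paired_diffs()].
#' @param bound equivalence bound tested (hours).
#' @param alpha significance criterion passed to [test_difference()].
#' @return list: `rate` (declared-equivalence proportion), `mc_se`,
#'   `n_reps`.
#' @export
tost_calibration <- function(n_reps, n_participants = 150, n_nights = 7,
                             true_diff = 0.5, sd_between = 0.5,
                             sd_within = 1, bound = 0.5, alpha = 0.01) {
  if (n_reps < 2L) stop("tost_calibration: need n_reps >= 2")
  hits <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    d <- simulate_paired_diffs(n_participants, n_nights, true_diff,
                               sd_between, sd_within)
    res <- test_difference(d, bounds = bound, alpha = alpha)
    hits[r] <- unname(res$equivalent[1])
  }
  rate <- mean(hits)
  list(rate = rate, mc_se = sqrt(rate * (1 - rate) / n_reps), n_reps = n_reps)
}
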