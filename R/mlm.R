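#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x - mean(x, na.rm = TRUE))
  (x - mean(x, na.rm = TRUE)) / s
}

# Nakagawa-style explained-variance summary for a Gaussian mixed model:
# marginal = fixed effects only, conditional = fixed + random.
#' @keywords internal
r2_mixed <- function(fit) {
  var_f <- stats::var(as.numeric(stats::model.matrix(fit) %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_re <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  tot <- var_f + var_re + var_res
  list(marginal = var_f / tot, conditional = (var_f + var_re) / tot)
}

# Variance inflation factors from the correlation of the intended
# fixed-effects columns (intercept dropped): diag(solve(R)). Computed on the
# pre-fit design so rank-deficient terms are seen before the fitter drops
# them; a numerically singular correlation (e.g. duplicated predictors)
# yields Inf.
#' @keywords internal
vif_fixed <- function(X) {
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  if (ncol(X) < 2L) return(stats::setNames(rep(1, ncol(X)), colnames(X)))
  R <- stats::cor(X)
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(inv)) {
    return(stats::setNames(rep(Inf, ncol(X)), colnames(X)))
  }
  stats::setNames(diag(inv), colnames(X))
}

#' @keywords internal
coef_table <- function(fit, alpha = 0.01) {
  ct <- stats::coef(summary(fit))
  est <- ct[, "Estimate"]; se <- ct[, "Std. Error"]
  df <- ct[, "df"]; tv <- ct[, "t value"]; p <- ct[, "Pr(>|t|)"]
  q <- stats::qt(1 - alpha / 2, df)
  data.frame(term = rownames(ct), estimate = est, se = se, df = df, t = tv,
             p = p, ci_lo = est - q * se, ci_hi = est + q * se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @keywords internal
new_kap_mlm <- function(fit, data_n, extra = list(), alpha = 0.01) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  r2 <- r2_mixed(fit)
  out <- c(list(
    coefficients = coef_table(fit, alpha = alpha),
    var_components = vc,
    r2_marginal = r2$marginal, r2_conditional = r2$conditional,
    n_obs = data_n$n_obs, n_groups = data_n$n_groups,
    df_method = "satterthwaite", alpha = alpha,
    singular = lme4::isSingular(fit), fit = fit
  ), extra)
  class(out) <- "kap_mlm"
  out
}

#' @export
print.kap_mlm <- function(x, digits = 3, ...) {
  cat(sprintf("Multilevel fit (%d obs, %d participants; Satterthwaite df; alpha = %.2f)\n",
              x$n_obs, x$n_groups, x$alpha))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat(sprintf("R2 marginal %.3f, conditional %.3f%s\n", x$r2_marginal,
              x$r2_conditional, if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' @keywords internal
complete_pairs <- function(paired, extra_cols = character()) {
  keep <- !is.na(paired$keyboard) & !is.na(paired$diary)
  for (col in extra_cols) keep <- keep & !is.na(paired[[col]])
  paired[keep, , drop = FALSE]
}

#' Cross-modality association from a random-intercept model
#'
#' Regresses the grand-standardized self-reported estimate on the
#' grand-standardized keyboard-derived estimate with a participant random
#' intercept (REML; Satterthwaite degrees of freedom). The reported `beta`
#' is therefore a standardized slope; the 99% CI matches the alpha = .01
#' criterion. Marginal (fixed-effects) and conditional (fixed + random)
#' explained-variance ratios are reported.
#'
#' @param paired one paired-night table from [pair_nights()].
#' @param alpha significance criterion (default .01).
#' @return a `kap_mlm` with additional elements `beta` (the standardized
#'   slope row of the coefficient table) and `beta_std`.
#' @export
fit_association <- function(paired, alpha = 0.01) {
  d <- complete_pairs(paired)
  n_part <- length(unique(d$participant_id))
  if (n_part < 20L) stop("fit_association: need >= 20 participants")
  d$kb_z <- zscore(d$keyboard)
  d$dy_z <- zscore(d$diary)
  fit <- fit_lmer_safe(dy_z ~ kb_z + (1 | participant_id), d)
  out <- new_kap_mlm(fit, list(n_obs = nrow(d), n_groups = n_part),
                     alpha = alpha)
  b <- out$coefficients[out$coefficients$term == "kb_z", ]
  out$beta <- b
  out$beta_std <- b$estimate
  out
}

# lmer with a documented fallback: default optimizer first, then bobyqa with
# a raised evaluation budget; convergence failure after both is an error.
#' @keywords internal
fit_lmer_safe <- function(formula, data, REML = TRUE) {
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(formula, data = data, REML = REML)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    fit <- lmerTest::lmer(
      formula, data = data, REML = REML,
      control = lme4::lmerControl(optimizer = "bobyqa",
                                  optCtrl = list(maxfun = 1e5)))
  }
  fit
}

#' Cluster-mean center a day-level predictor
#'
#' Decomposes each observation into an empirical-Bayes person mean and a
#' within-person deviation. The person mean is the fixed intercept plus the
#' predicted random intercept from the metric's unconditional model, so it
#' is shrunken toward the grand mean for participants with few or noisy
#' nights; the centered score is the observation minus that person mean, and
#' the two always reconstruct the observation exactly. Participants absent
#' from the unconditional fit get the fixed intercept as person mean, with a
#' flag.
#'
#' @param values numeric day-level values.
#' @param participant_id grouping vector aligned with `values`.
#' @param unconditional optional `kap_icc` from [icc_unconditional()] for the
#'   same metric; computed internally when omitted.
#' @return data.frame `participant_id`, `value`, `person_mean`, `centered`,
#'   `shrunk_only` (flag for participants missing from the unconditional
#'   fit).
#' @export
center_predictor <- function(values, participant_id, unconditional = NULL) {
  if (is.null(unconditional)) {
    unconditional <- icc_unconditional(values, participant_id)
  }
  fit <- unconditional$fit
  mu <- unname(lme4::fixef(fit)[1])
  re <- lme4::ranef(fit)$g
  eb <- stats::setNames(mu + re[["(Intercept)"]], rownames(re))
  pid <- as.character(participant_id)
  pm <- unname(eb[pid])
  missing_grp <- is.na(pm)
  if (any(missing_grp)) pm[missing_grp] <- mu
  data.frame(
    participant_id = participant_id, value = values,
    person_mean = pm, centered = values - pm,
    shrunk_only = missing_grp, stringsAsFactors = FALSE
  )
}

#' @keywords internal
add_centered_keyboard <- function(d) {
  cp <- center_predictor(zscore(d$keyboard), d$participant_id)
  d$kb_cm <- cp$person_mean
  d$kb_cmc <- cp$centered
  d$dy_z <- zscore(d$diary)
  d
}

#' Day-level moderation of the cross-modality association
#'
#' Extends the association model with first-level (day-level) moderators:
#' the number of hours with keyboard activity (on the previous or next day)
#' and the type of day (weekday vs weekend). The keyboard metric enters as
#' its empirical-Bayes person mean plus the cluster-mean-centered daily
#' deviation; the hours moderator is cluster-mean-centered the same way; and
#' the interactions of the centered keyboard score with the centered hours
#' score and with type of day carry the moderation question.
#'
#' @param paired one paired-night table from [pair_nights()] built with a
#'   day-activity table.
#' @param hours_side `"prev"` or `"next"`: which day's activity-hours count
#'   moderates.
#' @param alpha significance criterion.
#' @return a `kap_mlm`; the interaction rows are
#'   `kb_cmc:hours_cmc` and `kb_cmc:type_of_dayweekend`.
#' @export
fit_first_level_moderation <- function(paired, hours_side = c("prev", "next"),
                                       alpha = 0.01) {
  hours_side <- match.arg(hours_side)
  hcol <- if (hours_side == "prev") "hours_prev_day" else "hours_next_day"
  d <- complete_pairs(paired, extra_cols = c(hcol, "type_of_day"))
  n_part <- length(unique(d$participant_id))
  if (n_part < 20L) stop("fit_first_level_moderation: need >= 20 participants")
  d <- add_centered_keyboard(d)
  hp <- center_predictor(zscore(as.numeric(d[[hcol]])), d$participant_id)
  d$hours_cm <- hp$person_mean
  d$hours_cmc <- hp$centered
  fit <- fit_lmer_safe(
    dy_z ~ kb_cmc + kb_cm + hours_cmc + hours_cm + type_of_day +
      kb_cmc:hours_cmc + kb_cmc:type_of_day + (1 | participant_id), d)
  new_kap_mlm(fit, list(n_obs = nrow(d), n_groups = n_part),
              extra = list(hours_side = hours_side), alpha = alpha)
}

#' Interindividual slope variation via a random-slope model
#'
#' Compares the random-intercept model (self-reported estimate on the
#' cluster-mean-centered keyboard estimate plus its person mean) against the
#' model adding a participant random slope for the centered score
#' (unstructured intercept-slope covariance). The slope SD is read from the
#' REML random-slope fit; the likelihood-ratio test (2 df: slope variance
#' plus intercept-slope covariance) compares ML refits of both models. A
#' boundary fit returns `slope_sd = 0` with the LRT still reported; the test
#' is conservative at the boundary.
#'
#' @param paired one paired-night table from [pair_nights()].
#' @param alpha significance criterion.
#' @return list of class `kap_random_slope`: `slope_sd`, `loglik`, `aic`,
#'   `lrt_stat`, `lrt_df`, `lrt_p`, `singular`, `n_obs`, `n_groups`, plus
#'   the two fits.
#' @export
fit_random_slope <- function(paired, alpha = 0.01) {
  d <- complete_pairs(paired)
  n_part <- length(unique(d$participant_id))
  if (n_part < 20L) stop("fit_random_slope: need >= 20 participants")
  d <- add_centered_keyboard(d)
  f0 <- dy_z ~ kb_cmc + kb_cm + (1 | participant_id)
  f1 <- dy_z ~ kb_cmc + kb_cm + (1 + kb_cmc | participant_id)
  m1 <- fit_lmer_safe(f1, d, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m1))
  slope_sd <- vc$sdcor[vc$grp == "participant_id" & vc$var1 == "kb_cmc" &
                         is.na(vc$var2)]
  m0_ml <- fit_lmer_safe(f0, d, REML = FALSE)
  m1_ml <- fit_lmer_safe(f1, d, REML = FALSE)
  lrt_stat <- max(0, 2 * (stats::logLik(m1_ml) - stats::logLik(m0_ml)))
  lrt_df <- 2L
  structure(list(
    slope_sd = slope_sd,
    loglik = as.numeric(stats::logLik(m1_ml)), aic = stats::AIC(m1_ml),
    lrt_stat = lrt_stat, lrt_df = lrt_df,
    lrt_p = stats::pchisq(lrt_stat, df = lrt_df, lower.tail = FALSE),
    singular = lme4::isSingular(m1),
    n_obs = nrow(d), n_groups = n_part,
    fit_slope = m1, fit_intercept = m0_ml
  ), class = "kap_random_slope")
}

#' @export
print.kap_random_slope <- function(x, ...) {
  cat(sprintf("slope SD %.3f; LRT %.2f (df %d), p = %.3g%s\n",
              x$slope_sd, x$lrt_stat, x$lrt_df, x$lrt_p,
              if (x$singular) " [boundary fit: conservative]" else ""))
  invisible(x)
}

#' Cross-level trait moderation of the cross-modality association
#'
#' Adds grand-mean-centered participant-level traits (chronotype MSFsc,
#' PSQI sleep quality, trait self-control) to the random-slope model, both
#' as main effects and in interaction with the cluster-mean-centered
#' keyboard estimate. Before fitting, pairwise trait correlations and the
#' variance inflation factors of the fixed-effects design are inspected;
#' VIFs above `vif_ceiling` raise a warning but the fit proceeds.
#'
#' @param paired one paired-night table from [pair_nights()].
#' @param traits trait table (`participant_id`, `msfsc`, `psqi`, `tsc`).
#' @param vif_ceiling VIF warning threshold.
#' @param alpha significance criterion.
#' @return a `kap_mlm` with additional elements `vif`, `trait_correlations`
#'   and `vif_flag`; the moderation rows are `kb_cmc:msfsc_c`,
#'   `kb_cmc:psqi_c`, `kb_cmc:tsc_c`.
#' @export
fit_cross_level <- function(paired, traits, vif_ceiling = 5, alpha = 0.01) {
  d <- complete_pairs(paired)
  d <- merge(d, traits[, c("participant_id", "msfsc", "psqi", "tsc")],
             by = "participant_id")
  d <- d[!is.na(d$msfsc) & !is.na(d$psqi) & !is.na(d$tsc), , drop = FALSE]
  n_part <- length(unique(d$participant_id))
  if (n_part < 20L) stop("fit_cross_level: need >= 20 participants with traits")
  d <- add_centered_keyboard(d)
  d$msfsc_c <- d$msfsc - mean(d$msfsc)
  d$psqi_c <- d$psqi - mean(d$psqi)
  d$tsc_c <- d$tsc - mean(d$tsc)
  trait_cor <- stats::cor(unique(d[, c("participant_id", "msfsc", "psqi", "tsc")])[, -1])
  fixed <- ~ kb_cmc + kb_cm + msfsc_c + psqi_c + tsc_c +
    kb_cmc:msfsc_c + kb_cmc:psqi_c + kb_cmc:tsc_c
  vifs <- vif_fixed(stats::model.matrix(fixed, d))
  vif_flag <- any(!is.finite(vifs)) || any(vifs > vif_ceiling)
  if (vif_flag) {
    warning(sprintf("fit_cross_level: VIF above %.1f for: %s",
                    vif_ceiling,
                    paste(names(vifs)[!is.finite(vifs) | vifs > vif_ceiling],
                          collapse = ", ")), call. = FALSE)
  }
  fit <- fit_lmer_safe(
    stats::update(fixed, dy_z ~ . + (1 + kb_cmc | participant_id)), d)
  new_kap_mlm(fit, list(n_obs = nrow(d), n_groups = n_part),
              extra = list(vif = vifs, trait_correlations = trait_cor,
                           vif_flag = vif_flag), alpha = alpha)
}

#' Simulate paired data with a known standardized slope
#'
#' Validation harness for the association and random-slope models: the
#' keyboard predictor has unit total variance split between a participant
#' intercept (`icc_x`) and night-level noise; the diary outcome follows the
#' within/between slope `beta` (common to both levels), an optional
#' participant-specific slope deviation on the within-person part
#' (`slope_sd`), a participant intercept and residual noise scaled so the
#' outcome's total variance is ~1, keeping `beta` a standardized slope.
#'
#' @param n_participants,n_nights cohort size.
#' @param beta true standardized slope.
#' @param icc_x between-participant share of the predictor variance.
#' @param slope_sd SD of participant slope deviations (standardized scale).
#' @param sd_intercept SD of the outcome's participant intercept.
#' @return a paired-night data.frame (`keyboard` = predictor, `diary` =
#'   outcome).
#' @export
simulate_paired_assoc <- function(n_participants, n_nights, beta = 0.75,
                                  icc_x = 0.3, slope_sd = 0,
                                  sd_intercept = NULL) {
  n <- n_participants * n_nights
  id <- rep(sprintf("S%03d", seq_len(n_participants)), each = n_nights)
  u <- rep(stats::rnorm(n_participants, 0, sqrt(icc_x)), each = n_nights)
  w <- stats::rnorm(n, 0, sqrt(1 - icc_x))
  x <- u + w
  s <- rep(stats::rnorm(n_participants, 0, slope_sd), each = n_nights)
  var_sig <- beta^2 + slope_sd^2 * (1 - icc_x)
  if (is.null(sd_intercept)) {
    sd_intercept <- sqrt(max(0.05, (1 - var_sig) / 2))
  }
  b0 <- rep(stats::rnorm(n_participants, 0, sd_intercept), each = n_nights)
  sd_res <- sqrt(max(0.05, 1 - var_sig - sd_intercept^2))
  y <- beta * x + s * w + b0 + stats::rnorm(n, 0, sd_res)
  data.frame(
    participant_id = id,
    anchor_date = rep(as.Date("2020-09-14") + seq_len(n_nights) - 1, n_participants),
    keyboard = x, diary = y, diff_h = x - y,
    type_of_day = factor("weekday", levels = c("weekday", "weekend")),
    hours_prev_day = NA_integer_, hours_next_day = NA_integer_,
    stringsAsFactors = FALSE
  )
}
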