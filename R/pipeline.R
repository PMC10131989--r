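#' Run the full keyboard/diary analysis pipeline
#'
#' Orchestrates the stages `simulate` (synthetic cohort to CSV), `extract`
#' (keyboard night estimates + day activity), `derive` (diary night
#' estimates), `agree` (paired nights, ICCs, NHST/TOST, Bland-Altman),
#' `model` (association, random-slope and cross-level models) and `report`
#' (run manifest with content digests). Stages read their inputs from
#' `out_dir`, so a subset can be re-run against existing artifacts; a
#' missing upstream artifact is a dependency error naming the stage. All
#' randomness flows from the seed in the simulation config, so re-running
#' with the same config reproduces byte-identical seeded outputs.
#'
#' @param config a [kap_sim_config()], a path to its YAML form, or `NULL`
#'   for the defaults.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of
#'   `c("simulate", "extract", "derive", "agree", "model", "report")`.
#' @param seed optional override of the config seed.
#' @return the run manifest (named list), invisibly. Written as
#'   `manifest.json` by the `report` stage.
#' @export
run_pipeline <- function(config = NULL, out_dir = ".",
                         stages = c("simulate", "extract", "derive",
                                    "agree", "model", "report"),
                         seed = NULL) {
  all_stages <- c("simulate", "extract", "derive", "agree", "model", "report")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (is.null(config)) {
    config <- kap_sim_config()
  } else if (is.character(config)) {
    config <- read_sim_config(config)
  } else {
    config <- validate_sim_config(config)
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config <- validate_sim_config(unclass(config))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f))) {
      stop(sprintf("stage '%s' requires missing artifact '%s' (run its upstream stage first)",
                   stage, f), call. = FALSE)
    }
    pth(f)
  }
  manifest <- list(
    package = "kapsleep",
    version = as.character(utils::packageVersion("kapsleep")),
    seed = config$seed,
    config = unclass(config),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  manifest$config$start_date <- format(config$start_date)
  record <- function(stage, outputs) {
    info <- lapply(outputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(pth(f))),
           rows = count_rows(pth(f)))
    })
    manifest$stages[[stage]] <<- info
  }
  anchors <- config$start_date + seq_len(config$n_nights) - 1

  if ("simulate" %in% stages) {
    message("stage simulate: generating cohort (seed ", config$seed, ")")
    cohort <- simulate_cohort(config)
    write_events(cohort$events, pth("events.csv"))
    write_diary(cohort$diary, pth("diary.csv"))
    write_traits(cohort$traits, pth("traits.csv"))
    truth <- cohort$truth
    truth$anchor_date <- format(truth$anchor_date)
    utils::write.csv(truth, pth("truth.csv"), row.names = FALSE, quote = FALSE)
    record("simulate", c("events.csv", "diary.csv", "traits.csv", "truth.csv"))
  }

  if ("extract" %in% stages) {
    message("stage extract: keyboard night estimates")
    events <- read_events(need("events.csv", "extract"),
                          default_tz = config$timezone)
    ex <- extract_all_nights(events, anchor_dates = anchors,
                             tz = config$timezone)
    write_keyboard_nights(ex$nights, pth("keyboard_nights.csv"))
    da <- ex$day_activity
    da$calendar_date <- format(da$calendar_date)
    utils::write.csv(da, pth("day_activity.csv"), row.names = FALSE, quote = FALSE)
    record("extract", c("keyboard_nights.csv", "day_activity.csv"))
  }

  if ("derive" %in% stages) {
    message("stage derive: diary night estimates")
    diary <- read_diary(need("diary.csv", "derive"))
    write_diary_nights(derive_diary_nights(diary), pth("diary_nights.csv"))
    record("derive", "diary_nights.csv")
  }

  if ("agree" %in% stages || "model" %in% stages) {
    kb <- utils::read.csv(need("keyboard_nights.csv", "agree/model"))
    dy <- utils::read.csv(need("diary_nights.csv", "agree/model"))
    da <- utils::read.csv(need("day_activity.csv", "agree/model"))
    kb <- apply_outlier_rule(kb)
    dy <- apply_outlier_rule(dy)
    paired <- pair_nights(kb, dy, da)
  }

  if ("agree" %in% stages) {
    message("stage agree: ICCs, differences, equivalence, Bland-Altman")
    pairs <- kap_metric_pairs()
    report <- lapply(pairs$pair, function(p) {
      pd <- paired[[p]]
      utils::write.csv(pd, pth(sprintf("paired_%s.csv", gsub("\\.", "_", p))),
                       row.names = FALSE, quote = FALSE, na = "")
      eq <- test_difference(pd)
      ba <- bland_altman_rm(pd)
      row <- pairs[pairs$pair == p, ]
      icc_kb <- icc_unconditional(kb[[row$keyboard_col]], kb$participant_id)
      icc_dy <- icc_unconditional(dy[[row$diary_col]], dy$participant_id)
      list(
        pair = p, kind = row$kind,
        mean_diff_h = eq$mean_diff_h, nhst_p = eq$nhst_p,
        ci99 = eq$ci99, ci98 = eq$ci98,
        equivalent_at_0p5 = unname(eq$equivalent[1]),
        equivalent_at_1p0 = unname(eq$equivalent[2]),
        n_obs = eq$n_obs, n_participants = eq$n_participants,
        bland_altman = list(bias = ba$bias, loa = ba$loa),
        icc_keyboard = icc_kb$icc, icc_diary = icc_dy$icc
      )
    })
    names(report) <- pairs$pair
    jsonlite::write_json(report, pth("agreement_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    record("agree", c("agreement_report.json",
                      sprintf("paired_%s.csv", gsub("\\.", "_", pairs$pair))))
  }

  if ("model" %in% stages) {
    message("stage model: association, random-slope and cross-level models")
    traits <- read_traits(need("traits.csv", "model"))
    pairs <- kap_metric_pairs()
    report <- lapply(pairs$pair, function(p) {
      pd <- paired[[p]]
      assoc <- fit_association(pd)
      rs <- fit_random_slope(pd)
      xl <- fit_cross_level(pd, traits)
      list(
        pair = p,
        association = list(
          beta = assoc$beta_std, ci99 = c(assoc$beta$ci_lo, assoc$beta$ci_hi),
          t = assoc$beta$t, df = assoc$beta$df, p = assoc$beta$p,
          r2_marginal = assoc$r2_marginal,
          r2_conditional = assoc$r2_conditional),
        random_slope = list(
          slope_sd = rs$slope_sd, lrt = rs$lrt_stat, lrt_df = rs$lrt_df,
          lrt_p = rs$lrt_p),
        cross_level = list(
          coefficients = xl$coefficients, vif = as.list(xl$vif))
      )
    })
    names(report) <- pairs$pair
    jsonlite::write_json(report, pth("model_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    record("model", "model_report.json")
  }

  if ("report" %in% stages) {
    message("stage report: writing manifest")
    existing <- intersect(
      c("events.csv", "diary.csv", "traits.csv", "truth.csv",
        "keyboard_nights.csv", "day_activity.csv", "diary_nights.csv",
        "agreement_report.json", "model_report.json"),
      list.files(out_dir))
    digests <- lapply(existing, function(f) {
      list(path = f, md5 = unname(tools::md5sum(pth(f))),
           rows = count_rows(pth(f)))
    })
    names(digests) <- existing
    manifest$outputs <- digests
    manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = 10, null = "null")
  }
  invisible(manifest)
}

#' @keywords internal
count_rows <- function(path) {
  if (grepl("\\.csv$", path)) max(0L, length(readLines(path)) - 1L) else NA_integer_
}
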