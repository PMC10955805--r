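# End-to-end orchestration: discover participants in a data directory,
# estimate sleep per participant, align streams, run the statistical
# layer, and write intermediate CSVs plus a machine-readable report.
# Deterministic: identical inputs and configuration give an identical
# report. Log lines go to stderr via message(); the report to file.

#' Run the full analysis pipeline
#'
#' Executes estimate -> align -> analyze over a data directory laid out
#' as [generate_cohort()] writes it: one `accel_<id>.csv` (and
#' optionally `events_<id>.csv`) per participant plus a `surveys.csv`.
#' Writes `sleep_estimates.csv`, `night_pairs.csv`, `psqi_windows.csv`,
#' `participant_means.csv`, `correlations.csv`, `mixed_model.json`,
#' `loocv.csv`, `report.json` and a configuration snapshot into
#' `out_dir`. Every number in the report is recomputable from those
#' CSVs alone.
#'
#' @param data_dir Input directory.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param config A [sleep_config()].
#' @return The report, invisibly: a list with participant counts,
#'   exclusion tallies, the correlation tables, the mixed-model table
#'   and the LOOCV mean absolute error.
#' @export
run_pipeline <- function(data_dir, out_dir = NULL, config = sleep_config()) {
  accel_files <- sort(list.files(data_dir, pattern = "^accel_.*\\.csv$",
                                 full.names = TRUE))
  if (length(accel_files) == 0) {
    stop("no participants found in ", data_dir, call. = FALSE)
  }
  ids <- sub("^accel_(.*)\\.csv$", "\\1", basename(accel_files))
  survey_path <- file.path(data_dir, "surveys.csv")
  if (!file.exists(survey_path)) {
    stop("no surveys.csv found in ", data_dir, call. = FALSE)
  }
  surveys <- read_surveys(survey_path)

  estimates <- list()
  for (k in seq_along(ids)) {
    accel <- read_accelerometer(accel_files[k], participant = ids[k])
    ev_path <- file.path(data_dir, paste0("events_", ids[k], ".csv"))
    events <- if (file.exists(ev_path)) {
      read_device_events(ev_path, participant = ids[k])
    } else NULL
    est <- withCallingHandlers(
      estimate_participant(accel, events, config),
      warning = function(w) {
        message("estimate: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    for (i in which(!est$included)) {
      message("excluded window: participant ", ids[k], ", window_start ",
              est$window_start[i], ": coverage ",
              signif(est$coverage[i], 3), " < threshold ",
              config$coverage_threshold)
    }
    estimates[[k]] <- est
  }
  estimates <- dplyr::bind_rows(estimates)

  tz <- config$tz_offset_minutes
  active_n <- daily_nights(surveys, "daily_duration", tz)
  quality_n <- daily_nights(surveys, "daily_quality", tz)
  passive_n <- passive_nights(estimates)
  pairs <- pair_nights(active_n, passive_n)

  # night-level table across all streams for participant means
  nights <- dplyr::full_join(
    dplyr::rename(active_n, active_hours = "score"),
    dplyr::rename(passive_n, passive_hours = "sleep_hours"),
    by = c("participant", "night"))
  nights <- dplyr::full_join(
    nights, dplyr::rename(quality_n, active_quality = "score"),
    by = c("participant", "night"))

  means_all <- participant_means(nights)
  means_paired <- participant_means(
    nights[, c("participant", "night", "active_hours", "passive_hours")],
    paired_only = TRUE)

  psqi_mean <- dplyr::summarise(
    dplyr::group_by(surveys[surveys$instrument == "psqi", ],
                    .data$participant),
    mean_psqi = mean(.data$score), .groups = "drop")
  means_all <- dplyr::left_join(means_all, psqi_mean, by = "participant")

  cor_cols <- intersect(c("mean_active_hours", "mean_passive_hours",
                          "mean_active_quality", "mean_psqi"),
                        names(means_all))
  cors <- correlation_matrix(means_all[, cor_cols])
  paired_cor <- if (nrow(means_paired) >= 3) {
    correlation_matrix(
      means_paired[, c("mean_active_hours", "mean_passive_hours")])
  } else NULL

  windows <- build_psqi_windows(surveys, estimates, tz)
  n_incomplete <- sum(!windows$complete)
  if (n_incomplete > 0) {
    message(n_incomplete,
            " PSQI window(s) excluded from modeling: absent predictors")
  }
  mixed <- tryCatch(fit_mixed_model(windows),
                    error = function(e) {
                      message("mixed model not fitted: ", conditionMessage(e))
                      NULL
                    })
  loocv <- tryCatch(loocv_linear_model(windows),
                    error = function(e) {
                      message("LOOCV not run: ", conditionMessage(e))
                      NULL
                    })

  valid_per_participant <- dplyr::summarise(
    dplyr::group_by(estimates, .data$participant),
    n_valid = sum(.data$included), .groups = "drop")

  report <- list(
    n_participants_in = length(ids),
    n_participants_with_valid_window =
      sum(valid_per_participant$n_valid >= 1),
    mean_valid_windows_per_participant =
      mean(valid_per_participant$n_valid),
    n_windows_total = nrow(estimates),
    n_windows_excluded_coverage = sum(!estimates$included),
    n_night_pairs = nrow(pairs),
    n_psqi_windows = nrow(windows),
    n_psqi_windows_incomplete = n_incomplete,
    correlation_mean_level = cors$table,
    correlation_paired = if (!is.null(paired_cor)) paired_cor$table else NULL,
    mixed_model = if (!is.null(mixed)) {
      list(table = mixed$table, ranef_var = mixed$ranef_var,
           resid_var = mixed$resid_var, n_obs = mixed$n_obs,
           n_groups = mixed$n_groups, singular = mixed$singular)
    } else NULL,
    loocv_mae = if (!is.null(loocv)) loocv$mae else NULL,
    loocv_n_predicted = if (!is.null(loocv)) loocv$n_predicted else NULL
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wcsv <- function(x, name) {
      readr::write_csv(x, file.path(out_dir, name), progress = FALSE)
    }
    wcsv(estimates, "sleep_estimates.csv")
    wcsv(pairs, "night_pairs.csv")
    wcsv(windows, "psqi_windows.csv")
    wcsv(means_all, "participant_means.csv")
    wcsv(cors$table, "correlations.csv")
    if (!is.null(mixed)) {
      jsonlite::write_json(report$mixed_model,
                           file.path(out_dir, "mixed_model.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
    if (!is.null(loocv)) wcsv(loocv$predictions, "loocv.csv")
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    snap <- unclass(config)
    jsonlite::write_json(snap, file.path(out_dir, "config_snapshot.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
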