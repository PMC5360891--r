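# Readers/writers for the CSV dialects and end-to-end pipeline orchestration.
#
# Session files carry ISO-8601 timestamps; internally all times are
# fractional days since each patient's first session (analyses are in days).

SESSION_ORIGIN <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

#' Write session streams to CSV
#'
#' One row per session: `patient_id`, ISO-8601 `timestamp`, the six symptom
#' answers, `reliever_increased`/`antibiotics`/`steroids`/`hcp_contact`
#' flags, `spo2`, `pulse_rate` (and `resp_rate` if present).
#'
#' @param sessions session data.frame (internal dialect, `t` in days).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path) {
  check_sessions_frame(sessions)
  out <- sessions
  out$timestamp <- format(SESSION_ORIGIN + out$t * 86400,
                          "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  cols <- c("patient_id", "timestamp", SYMPTOM_KEYS, "reliever_increased",
            "antibiotics", "steroids", "hcp_contact", "spo2", "pulse_rate")
  if ("resp_rate" %in% names(out)) cols <- c(cols, "resp_rate")
  utils::write.csv(out[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read session streams from CSV
#'
#' Validates the header and every row, parses ISO-8601 timestamps, sorts each
#' patient's sessions, converts timestamps to fractional days since that
#' patient's first session, and rejects duplicate (patient, timestamp) pairs
#' naming the offending line.
#'
#' @param path CSV path written by [write_sessions()] (or compatible).
#' @return Validated session data.frame with `t` in days.
#' @export
read_sessions <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "timestamp", SYMPTOM_KEYS, "reliever_increased",
              "antibiotics", "steroids", "hcp_contact", "spo2", "pulse_rate")
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0L)
    stopf("sessions CSV is missing column(s): %s",
          paste(absent, collapse = ", "))
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  bad <- which(is.na(ts))
  if (length(bad) > 0L)
    stopf("unparseable timestamp at data line(s) %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  dup <- which(duplicated(paste(raw$patient_id, raw$timestamp)))
  if (length(dup) > 0L)
    stopf("duplicate (patient, timestamp) at data line(s) %s",
          paste(utils::head(dup, 5L), collapse = ", "))
  raw$timestamp <- ts
  raw <- raw[order(raw$patient_id, raw$timestamp), , drop = FALSE]
  t_first <- stats::ave(as.numeric(raw$timestamp), raw$patient_id, FUN = min)
  raw$t <- (as.numeric(raw$timestamp) - t_first) / 86400
  raw$timestamp <- NULL
  for (fl in c("reliever_increased", "antibiotics", "steroids", "hcp_contact"))
    raw[[fl]] <- as.logical(raw[[fl]])
  rownames(raw) <- NULL
  check_sessions_frame(raw)
  raw
}

#' Write a PPG segment to CSV
#'
#' Header line `fs_hz,<rate>` followed by one sample per row.
#'
#' @param ppg a `ppg_segment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppg <- function(ppg, path) {
  stopifnot(inherits(ppg, "ppg_segment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("fs_hz,%.10g", ppg$fs_hz), con)
  writeLines(format(ppg$samples, digits = 10, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' Read a PPG segment from CSV
#'
#' @param path path written by [write_ppg()].
#' @return A `ppg_segment` (without ground-truth rates).
#' @export
read_ppg <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], ",")[[1]]
  if (length(hdr) != 2L || hdr[1] != "fs_hz")
    stopf("PPG CSV must start with a 'fs_hz,<rate>' header")
  fs <- as.numeric(hdr[2])
  samples <- as.numeric(lines[-1])
  structure(list(samples = samples, fs_hz = fs,
                 duration_s = length(samples) / fs,
                 hr_bpm = NA_real_, rr_brpm = NA_real_),
            class = "ppg_segment")
}

#' Pipeline configuration
#'
#' Bundles the tunable options of every stage with their defaults: 7-day
#' windows and guard bands, minimum 2 sessions per window, AR orders 4-12,
#' respiratory band 4-40 brpm, 10-fold cross-validation.
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort to
#'   generate (or `NULL` when `sessions` are supplied to [run_pipeline()]).
#' @param window_days,guard_days,min_sessions period-selection options.
#' @param rr_source `"ppg"` to estimate respiratory rate from per-session
#'   PPG segments, `"recorded"` to use the sessions' `resp_rate` column.
#' @param rr_orders,rr_band respiratory-rate estimator options.
#' @param ppg_fs_hz,ppg_noise_sd,ppg_am_depth,ppg_fm_depth synthetic PPG
#'   options (used when `rr_source = "ppg"` on a synthetic cohort).
#' @param cv_k,cv_reps cross-validation folds and repeats.
#' @param group_by_patient if `TRUE`, folds never split a patient across
#'   train and test.
#' @param seed root seed for every random stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            window_days = 7, guard_days = 7, min_sessions = 2,
                            rr_source = c("ppg", "recorded"),
                            rr_orders = 4:12, rr_band = c(4, 40),
                            ppg_fs_hz = 100, ppg_noise_sd = 0.02,
                            ppg_am_depth = 0.2, ppg_fm_depth = 0.05,
                            cv_k = 10, cv_reps = 100,
                            group_by_patient = FALSE, seed = 1L) {
  rr_source <- match.arg(rr_source)
  if (window_days <= 0 || window_days != round(window_days))
    stopf("window_days must be a positive integer")
  if (guard_days <= 0 || guard_days != round(guard_days))
    stopf("guard_days must be a positive integer")
  if (cv_k < 2) stopf("cv_k must be >= 2")
  if (cv_reps < 1) stopf("cv_reps must be >= 1")
  structure(list(cohort = cohort, window_days = window_days,
                 guard_days = guard_days, min_sessions = min_sessions,
                 rr_source = rr_source, rr_orders = rr_orders,
                 rr_band = rr_band, ppg_fs_hz = ppg_fs_hz,
                 ppg_noise_sd = ppg_noise_sd, ppg_am_depth = ppg_am_depth,
                 ppg_fm_depth = ppg_fm_depth, cv_k = cv_k,
                 cv_reps = cv_reps, group_by_patient = group_by_patient,
                 seed = as.integer(seed)), class = "pipeline_config")
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full identification-and-prediction pipeline
#'
#' Stages: (1) obtain sessions (generate a synthetic cohort, or use the
#' supplied streams); (2) run the finite-state machine per patient and
#' extract exacerbation events; (3) select stable and prodromal 7-day
#' periods; (4) attach vitals, estimating respiratory rate from PPG if
#' configured; (5) extract trend features; (6) cross-validate the logistic
#' classifier over all vital-sign subsets. Artifacts are optionally written
#' to `out_dir` with a manifest recording the configuration hash and seed.
#'
#' @param config a [pipeline_config()].
#' @param sessions optional session data.frame to analyse instead of a
#'   synthetic cohort.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return An object of class `copd_pipeline`: list with `sessions`,
#'   `timelines`, `events`, `periods`, `dataset`, `comparison`, `report`,
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), sessions = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  cohort <- NULL
  if (is.null(sessions)) {
    cohort <- stage("simulate", {
      cc <- config$cohort
      cc$seed <- child_seed(config$seed, "cohort")
      generate_cohort(cc)
    })
    sessions <- cohort$sessions
  }
  check_sessions_frame(sessions)

  per_patient <- split_patients(sessions)
  timelines <- stage("fsm", lapply(per_patient, run_fsm))
  events <- stage("fsm", do.call(rbind, lapply(timelines,
                                               extract_exacerbation_events)))
  rownames(events) <- NULL

  rr_est <- NULL
  if (config$rr_source == "ppg") {
    if (is.null(cohort))
      stopf("rr_source = 'ppg' requires a synthetic cohort (supply per-session PPG for recorded data)")
    rr_est <- stage("rr", cohort_rr_estimates(
      cohort, fs_hz = config$ppg_fs_hz, am_depth = config$ppg_am_depth,
      fm_depth = config$ppg_fm_depth, noise_sd = config$ppg_noise_sd,
      band_brpm = config$rr_band, orders = config$rr_orders))
  }

  periods <- stage("periods", {
    out <- list()
    for (pid in names(per_patient)) {
      tl <- timelines[[pid]]
      ss <- per_patient[[pid]]
      ev <- events[events$patient_id == pid, , drop = FALSE]
      if (config$rr_source == "ppg") ss$resp_rate <- NA_real_
      stab <- select_stable_periods(tl, ss, config$window_days,
                                    config$guard_days, config$min_sessions)
      pro <- select_prodromal_periods(tl, ev, ss, config$window_days,
                                      config$min_sessions)
      out <- c(out, lapply(c(stab, pro), attach_vitals,
                           rr_estimates = rr_est,
                           min_sessions = config$min_sessions))
    }
    Filter(Negate(is.null), out)
  })
  if (length(periods) == 0L) stopf("pipeline stage 'periods' failed: no usable periods")

  dataset <- stage("features", build_dataset(periods))
  comparison <- stage("classify", compare_feature_sets(
    dataset, k = config$cv_k, reps = config$cv_reps,
    seed = child_seed(config$seed, "cv"),
    group = if (config$group_by_patient) dataset$patient_id else NULL))

  report <- stage("report", pipeline_report(sessions, timelines, events,
                                            periods, dataset, comparison))
  result <- structure(list(sessions = sessions, timelines = timelines,
                           events = events, periods = periods,
                           dataset = dataset, comparison = comparison,
                           report = report, config = config,
                           cohort = cohort),
                      class = "copd_pipeline")
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

# Summary tables in the shape of a trial report: usage statistics, event
# length distribution, class-conditional vital means, AUC grid.
pipeline_report <- function(sessions, timelines, events, periods, dataset,
                            comparison) {
  per_patient <- split_patients(sessions)
  days <- vapply(per_patient, function(s) diff(range(s$t)) + 1, numeric(1))
  usage <- data.frame(
    n_patients = length(per_patient),
    total_days = sum(days),
    total_sessions = nrow(sessions),
    mean_sessions_per_week = 7 * nrow(sessions) / sum(days))
  closed <- events[!events$open, , drop = FALSE]
  event_lengths <- data.frame(
    total_events = nrow(events),
    length_1_7 = sum(closed$length_days <= 7),
    length_8_14 = sum(closed$length_days > 7 & closed$length_days <= 14),
    length_15_21 = sum(closed$length_days > 14 & closed$length_days <= 21),
    mean_length_days = if (nrow(closed)) mean(closed$length_days) else NA_real_,
    median_length_days = if (nrow(closed)) stats::median(closed$length_days) else NA_real_)
  pf <- periods_frame(periods)
  class_means <- do.call(rbind, lapply(c("stable", "prodromal"), function(lb) {
    d <- dataset[dataset$label == as.numeric(lb == "prodromal"), , drop = FALSE]
    data.frame(label = lb, n_periods = nrow(d),
               mean_sessions = mean(pf$n_sessions[pf$label == lb]),
               spo2 = mean(d$spo2_mean), pulse_rate = mean(d$pr_mean),
               resp_rate = mean(d$rr_mean))
  }))
  list(usage = usage, event_lengths = event_lengths,
       class_means = class_means, auc_table = comparison$table)
}

#' @export
print.copd_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf("COPD telemonitoring pipeline: %d patients, %d sessions over %.0f days\n",
              r$usage$n_patients, r$usage$total_sessions, r$usage$total_days))
  cat(sprintf("  %d exacerbation events (mean closed length %.1f days)\n",
              r$event_lengths$total_events, r$event_lengths$mean_length_days))
  cat(sprintf("  %d stable / %d prodromal periods\n",
              r$class_means$n_periods[1], r$class_means$n_periods[2]))
  cat("  cross-validated AUC by feature set:\n")
  print(r$auc_table[, c("features", "mean_auc")], row.names = FALSE)
  invisible(x)
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(result$config)
  write_sessions(result$sessions, file.path(out_dir, "sessions.csv"))
  tl <- do.call(rbind, lapply(result$timelines, function(x) {
    cbind(patient_id = x$patient_id,
          x$entries[, c("t", "state", "event_bit", "symptom_code")])
  }))
  utils::write.csv(tl, file.path(out_dir, "timeline.csv"), row.names = FALSE)
  utils::write.csv(result$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(periods_frame(result$periods),
                   file.path(out_dir, "periods.csv"), row.names = FALSE)
  utils::write.csv(result$dataset, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(result$comparison$table,
                   file.path(out_dir, "auc_table.csv"), row.names = FALSE)
  best <- result$comparison$summaries[["RR+PR+SpO2"]]
  if (!is.null(best)) {
    jsonlite::write_json(
      list(fpr_grid = best$fpr_grid, mean_tpr = best$mean_tpr,
           tpr_lo = best$tpr_lo, tpr_hi = best$tpr_hi, mean_auc = best$auc,
           auc_ci = best$auc_ci, auc_reps = best$auc_reps),
      file.path(out_dir, "roc_summary.json"), digits = NA)
  }
  jsonlite::write_json(
    list(config_hash = hash, seed = result$config$seed,
         report = result$report),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}
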