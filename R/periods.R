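# Extraction of labelled 7-day windows from a state timeline.
#
# "Stable" windows lie wholly inside a NORMAL stretch, separated by guard
# bands from any transitional/exacerbation state; "prodromal" windows are the
# 7 days immediately before an exacerbation event. Between sessions a patient
# inherits the state of the most recent session (a step function in time);
# before the first session the state is NORMAL.

state_at <- function(timeline, tau) {
  e <- timeline$entries
  idx <- findInterval(tau, e$t)
  ifelse(idx == 0L, "NORMAL", e$state[pmax(idx, 1L)])
}

new_period <- function(patient_id, label, start_t, window_days, sessions) {
  structure(list(patient_id = patient_id, label = label,
                 start_t = start_t, end_t = start_t + window_days,
                 sessions = sessions),
            class = "copd_period")
}

#' @export
print.copd_period <- function(x, ...) {
  cat(sprintf("%s period, patient '%s', days [%.2f, %.2f), %d sessions\n",
              x$label, x$patient_id, x$start_t, x$end_t, nrow(x$sessions)))
  invisible(x)
}

# Maximal NORMAL-state intervals [a, b) of a timeline, with flags saying
# whether each end abuts a transitional/exacerbation episode (guard needed)
# or the monitoring boundary (no guard needed).
normal_spans <- function(timeline, end_t = NULL) {
  e <- timeline$entries
  if (is.null(end_t)) end_t <- if (nrow(e) > 0L) max(e$t) else 0
  t <- c(0, e$t); s <- c("NORMAL", e$state)
  keep <- c(TRUE, s[-1] != s[-length(s)])
  t <- t[keep]; s <- s[keep]
  spans <- data.frame(start = numeric(0), end = numeric(0),
                      guard_left = logical(0), guard_right = logical(0))
  for (i in seq_along(s)) {
    if (s[i] != "NORMAL") next
    a <- t[i]
    b <- if (i < length(s)) t[i + 1L] else end_t
    if (b <= a) next
    spans <- rbind(spans, data.frame(
      start = a, end = b,
      guard_left = i > 1L,           # entered NORMAL from an episode
      guard_right = i < length(s)))  # left NORMAL into an episode
  }
  spans
}

#' Select stable 7-day periods from a state timeline
#'
#' Within each maximal NORMAL stretch, a guard band of `guard_days` is
#' trimmed after the return to NORMAL and before the next departure from it
#' (no guard is needed against the enrollment date or the end of monitoring).
#' The remaining span is tiled with consecutive non-overlapping windows of
#' `window_days` from the left; windows containing at least `min_sessions`
#' sessions are kept.
#'
#' @param timeline a `state_timeline` from [run_fsm()].
#' @param sessions the same patient's session data.frame.
#' @param window_days window length in days (default 7).
#' @param guard_days guard-band length in days (default 7).
#' @param min_sessions minimum sessions per window (default 2).
#' @param end_t end of monitoring in days; defaults to the last session time.
#' @return List of `copd_period` objects labelled `"stable"`.
#' @export
select_stable_periods <- function(timeline, sessions, window_days = 7,
                                  guard_days = 7, min_sessions = 2,
                                  end_t = NULL) {
  stopifnot(inherits(timeline, "state_timeline"))
  spans <- normal_spans(timeline, end_t)
  periods <- list()
  for (i in seq_len(nrow(spans))) {
    a <- spans$start[i] + if (spans$guard_left[i]) guard_days else 0
    b <- spans$end[i] - if (spans$guard_right[i]) guard_days else 0
    s <- a
    while (s + window_days <= b) {
      inside <- sessions$t >= s & sessions$t < s + window_days
      if (sum(inside) >= min_sessions) {
        memb <- sessions[inside, , drop = FALSE]
        stopifnot(all(state_at(timeline, memb$t) == "NORMAL"))
        periods[[length(periods) + 1L]] <-
          new_period(timeline$patient_id, "stable", s, window_days, memb)
      }
      s <- s + window_days
    }
  }
  periods
}

#' Select prodromal periods preceding exacerbation events
#'
#' For each exacerbation event a candidate window of `window_days` days
#' immediately before the event start is examined. It is retained only if the
#' patient was in the NORMAL or TRANSITIONAL state throughout the window
#' (which excludes events that follow a previous event within `window_days`)
#' and at least `min_sessions` diary sessions fall inside it.
#'
#' @param timeline a `state_timeline`.
#' @param events data.frame from [extract_exacerbation_events()].
#' @param sessions the patient's session data.frame.
#' @inheritParams select_stable_periods
#' @return List of `copd_period` objects labelled `"prodromal"`.
#' @export
select_prodromal_periods <- function(timeline, events, sessions,
                                     window_days = 7, min_sessions = 2) {
  stopifnot(inherits(timeline, "state_timeline"))
  periods <- list()
  for (i in seq_len(nrow(events))) {
    s0 <- events$start_t[i] - window_days
    inside <- sessions$t >= s0 & sessions$t < events$start_t[i]
    ok_states <- c("NORMAL", "TRANSITIONAL")
    # state throughout the window: at its left edge and at every session in it
    if (!state_at(timeline, s0) %in% ok_states) next
    if (!all(state_at(timeline, sessions$t[inside]) %in% ok_states)) next
    if (sum(inside) < min_sessions) next
    periods[[length(periods) + 1L]] <-
      new_period(timeline$patient_id, "prodromal", s0, window_days,
                 sessions[inside, , drop = FALSE])
  }
  periods
}

#' Attach aligned vital-sign triplets to a period
#'
#' Ensures every member session carries the three vitals (SpO2, pulse rate,
#' respiratory rate). Respiratory rate is taken from the session's
#' `resp_rate` column if present, otherwise looked up in `rr_estimates`
#' (matching on `patient_id` and `t`, using estimates of acceptable quality).
#' Sessions missing any vital are dropped; a period reduced below
#' `min_sessions` is dropped entirely (returns `NULL`).
#'
#' @param period a `copd_period`.
#' @param rr_estimates optional data.frame with `patient_id`, `t`, `rr_brpm`,
#'   `quality`.
#' @param min_sessions minimum retained sessions (default 2).
#' @return The period with complete `spo2`, `pulse_rate`, `resp_rate`
#'   columns, or `NULL` if too few complete sessions remain.
#' @export
attach_vitals <- function(period, rr_estimates = NULL, min_sessions = 2) {
  stopifnot(inherits(period, "copd_period"))
  s <- period$sessions
  if (is.null(s$resp_rate)) s$resp_rate <- NA_real_
  if (!is.null(rr_estimates) && nrow(rr_estimates) > 0L) {
    ok <- rr_estimates[rr_estimates$quality %in% c("ok", "low_confidence"), ,
                       drop = FALSE]
    key_s <- paste(s$patient_id, sprintf("%.6f", s$t))
    key_r <- paste(ok$patient_id, sprintf("%.6f", ok$t))
    hit <- match(key_s, key_r)
    fill <- is.na(s$resp_rate) & !is.na(hit)
    s$resp_rate[fill] <- ok$rr_brpm[hit[fill]]
  }
  complete <- !is.na(s$spo2) & !is.na(s$pulse_rate) & !is.na(s$resp_rate)
  s <- s[complete, , drop = FALSE]
  if (nrow(s) < min_sessions) {
    message(sprintf("dropping %s period for patient '%s' at day %.1f: only %d complete session(s)",
                    period$label, period$patient_id, period$start_t, nrow(s)))
    return(NULL)
  }
  period$sessions <- s
  period
}

#' Summarise a list of periods as a data.frame
#'
#' @param periods list of `copd_period` objects.
#' @return data.frame with one row per period.
#' @export
periods_frame <- function(periods) {
  if (length(periods) == 0L)
    return(data.frame(patient_id = character(0), label = character(0),
                      start_t = numeric(0), end_t = numeric(0),
                      n_sessions = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(periods, function(p) data.frame(
    patient_id = p$patient_id, label = p$label, start_t = p$start_t,
    end_t = p$end_t, n_sessions = nrow(p$sessions), stringsAsFactors = FALSE)))
}
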