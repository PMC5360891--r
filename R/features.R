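# Linear-trend features over 7-day periods.
#
# Each vital sign in a period is summarised by the gradient of a least-squares
# straight line (robust to irregular, sparse sampling) and the unweighted
# session mean. Times are normalised so the first session in the window is at
# time 0.

#' Fit a least-squares straight line to irregularly sampled values
#'
#' Times are shifted so the first observation is at 0; the gradient `m` and
#' intercept `c` minimise the sum of squared residuals
#' `sum_i (y_i - (m x_i + c))^2`.
#'
#' @param times observation times, days.
#' @param values vital-sign values.
#' @return List with `m` (units/day), `c` (units at window-local time 0),
#'   `mean` (arithmetic mean of `values`) and `n`.
#' @export
#' @examples
#' fit_trend(c(0, 1), c(10, 12))  # m = 2, c = 10
fit_trend <- function(times, values) {
  keep <- !is.na(times) & !is.na(values)
  times <- as.numeric(times[keep]); values <- as.numeric(values[keep])
  n <- length(times)
  if (n < 2L) stopf("trend fit needs at least 2 points, got %d", n)
  x <- times - times[1]
  if (all(x == x[1])) stopf("trend fit needs at least 2 distinct times")
  fit <- stats::lm.fit(cbind(intercept = 1, slope = x), values)
  list(m = unname(fit$coefficients["slope"]),
       c = unname(fit$coefficients["intercept"]),
       mean = mean(values), n = n)
}

FEATURE_COLS <- c("pr_mean", "pr_grad", "spo2_mean", "spo2_grad",
                  "rr_mean", "rr_grad")

#' Extract the 6-number feature vector from a period
#'
#' Per-vital mean and least-squares gradient over the window (pulse rate,
#' SpO2, respiratory rate), with the class label (stable = 0, prodromal = 1).
#' Sessions missing one vital are excluded for that vital only; a vital with
#' fewer than 2 usable values invalidates the period (returns `NULL`).
#'
#' @param period a `copd_period` with vitals attached ([attach_vitals()]).
#' @param extras if `TRUE`, also include per-vital standard deviation and
#'   intercept (off by default; they have not been found informative).
#' @return Named numeric vector of features plus `label`, or `NULL`.
#' @export
extract_features <- function(period, extras = FALSE) {
  stopifnot(inherits(period, "copd_period"))
  s <- period$sessions
  vitals <- c(pr = "pulse_rate", spo2 = "spo2", rr = "resp_rate")
  out <- c()
  for (v in names(vitals)) {
    y <- s[[vitals[[v]]]]
    ok <- !is.na(y)
    if (sum(ok) < 2L) {
      message(sprintf("dropping %s period for patient '%s' at day %.1f: <2 values for %s",
                      period$label, period$patient_id, period$start_t, v))
      return(NULL)
    }
    fit <- fit_trend(s$t[ok], y[ok])
    out[paste0(v, "_mean")] <- fit$mean
    out[paste0(v, "_grad")] <- fit$m
    if (extras) {
      out[paste0(v, "_sd")] <- stats::sd(y[ok])
      out[paste0(v, "_intercept")] <- fit$c
    }
  }
  out["label"] <- as.numeric(period$label == "prodromal")
  out
}

#' Build the feature matrix and labels from a list of periods
#'
#' Rows are ordered deterministically by (patient_id, start_t); duplicate
#' (patient, label, start) keys are rejected. A single-class dataset raises a
#' warning since cross-validation cannot be run on it.
#'
#' @param periods list of `copd_period` objects with vitals attached.
#' @param extras passed to [extract_features()].
#' @return data.frame with `patient_id`, `label`, `start_t` and the feature
#'   columns (`pr_mean`, `pr_grad`, `spo2_mean`, `spo2_grad`, `rr_mean`,
#'   `rr_grad`, plus extras if requested).
#' @export
build_dataset <- function(periods, extras = FALSE) {
  periods <- Filter(Negate(is.null), periods)
  if (length(periods) == 0L) stopf("no periods to build a dataset from")
  key <- vapply(periods, function(p)
    paste(p$patient_id, p$label, format(p$start_t, digits = 12)), character(1))
  if (anyDuplicated(key)) stopf("duplicate period keys: %s",
                                paste(unique(key[duplicated(key)]), collapse = "; "))
  ord <- order(vapply(periods, `[[`, character(1), "patient_id"),
               vapply(periods, `[[`, numeric(1), "start_t"))
  periods <- periods[ord]
  rows <- lapply(periods, extract_features, extras = extras)
  keep <- !vapply(rows, is.null, logical(1))
  periods <- periods[keep]; rows <- rows[keep]
  if (length(rows) == 0L) stopf("all periods were dropped during feature extraction")
  feat <- as.data.frame(do.call(rbind, rows))
  out <- data.frame(
    patient_id = vapply(periods, `[[`, character(1), "patient_id"),
    label = feat$label,
    start_t = vapply(periods, `[[`, numeric(1), "start_t"),
    feat[, setdiff(names(feat), "label"), drop = FALSE],
    stringsAsFactors = FALSE)
  counts <- table(factor(out$label, levels = c(0, 1)))
  if (any(counts == 0L))
    warning("dataset contains a single class; cross-validation will fail",
            call. = FALSE)
  attr(out, "class_counts") <- c(stable = unname(counts["0"]),
                                 prodromal = unname(counts["1"]))
  out
}
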