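# Respiratory rate from 30-second PPG segments.
#
# Pipeline: mean removal -> heart-rate-adaptive low-pass FIR (transition band
# 0.5 x HR to 1.2 x HR) -> decimation to ~4 Hz -> pointwise median of
# autoregressive power spectra over a range of model orders -> spectral peak
# within the respiratory band. Pulse rate can also be estimated from the
# band-passed waveform when the device value is absent.

as_ppg_segment <- function(ppg) {
  if (inherits(ppg, "ppg_segment")) return(ppg)
  stopf("expected a 'ppg_segment' object")
}

check_segment <- function(ppg) {
  if (ppg$fs_hz < 25) stopf("PPG sampling rate must be >= 25 Hz")
  if (ppg$duration_s < 20 || ppg$duration_s > 60)
    warning(sprintf("PPG segment is %.1f s; the estimator expects ~30 s",
                    ppg$duration_s), call. = FALSE)
  invisible(ppg)
}

#' Estimate pulse rate from a PPG segment
#'
#' Band-passes the waveform to the cardiac band (0.5-3 Hz), detects systolic
#' peaks, and returns 60 over the median inter-beat interval.
#'
#' @param ppg a `ppg_segment`.
#' @return List with `hr_bpm` and `quality` (`"ok"` or `"failed"`); fewer
#'   than 10 detected beats gives `quality = "failed"`.
#' @export
estimate_pulse_rate <- function(ppg) {
  ppg <- as_ppg_segment(ppg)
  check_segment(ppg)
  x <- ppg$samples - mean(ppg$samples)
  if (stats::sd(x) == 0) return(list(hr_bpm = NA_real_, quality = "failed"))
  bf <- signal::butter(3, c(0.5, 3) / (ppg$fs_hz / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, x))
  # local maxima above half the 90th amplitude percentile, >= 0.3 s apart
  thr <- 0.5 * stats::quantile(xf, 0.9)
  n <- length(xf)
  cand <- which(xf > thr &
                  xf >= c(-Inf, xf[-n]) & xf > c(xf[-1], -Inf))
  min_gap <- round(0.3 * ppg$fs_hz)
  peaks <- integer(0)
  for (i in cand) {
    if (length(peaks) == 0L || i - peaks[length(peaks)] >= min_gap) {
      peaks <- c(peaks, i)
    } else if (xf[i] > xf[peaks[length(peaks)]]) {
      peaks[length(peaks)] <- i
    }
  }
  if (length(peaks) < 10L) return(list(hr_bpm = NA_real_, quality = "failed"))
  ibi <- diff(peaks) / ppg$fs_hz
  list(hr_bpm = 60 / stats::median(ibi), quality = "ok")
}

# Kaiser-window linear-phase FIR low-pass meeting <=1 dB passband ripple and
# >=40 dB stopband attenuation over the requested transition band. Designs
# are cached: cohort runs reuse the same (heart rate, fs) pairs heavily.
.filter_cache <- new.env(parent = emptyenv())

design_lowpass <- function(f_pass, f_stop, fs_hz) {
  key <- sprintf("%.6g|%.6g|%.6g", f_pass, f_stop, fs_hz)
  if (!is.null(.filter_cache[[key]])) return(.filter_cache[[key]])
  dev <- c(10^(1 / 20) - 1, 10^(-40 / 20))  # passband ripple 1 dB, stop 40 dB
  ko <- signal::kaiserord(c(f_pass, f_stop), c(1, 0), dev, fs_hz)
  n <- ko$n + (ko$n %% 2L)                   # even order -> odd-length taps
  h <- signal::fir1(n, ko$Wc, type = "low",
                    window = signal::kaiser(n + 1, ko$beta))
  .filter_cache[[key]] <- h
  h
}

#' Heart-rate-adaptive low-pass filter for respiratory content
#'
#' Removes the mean and applies a linear-phase FIR low-pass whose transition
#' band runs from 0.5 x to 1.2 x the cardiac frequency, so the cardiac
#' component is attenuated while the respiratory (amplitude-modulation)
#' component at baseband is preserved. The filter is applied forward and the
#' constant group delay removed; edge samples without full filter support are
#' dropped.
#'
#' @param ppg a `ppg_segment` (or numeric vector with `fs_hz` supplied via a
#'   segment).
#' @param hr_bpm heart rate in beats/min, must lie in \[30, 200\].
#' @return List with `samples` (filtered, shortened), `fs_hz`.
#' @export
adaptive_lowpass <- function(ppg, hr_bpm) {
  ppg <- as_ppg_segment(ppg)
  if (is.na(hr_bpm) || hr_bpm < 30 || hr_bpm > 200)
    stopf("hr_bpm must lie in [30, 200]")
  f_h <- hr_bpm / 60
  h <- design_lowpass(0.5 * f_h, 1.2 * f_h, ppg$fs_hz)
  x <- ppg$samples - mean(ppg$samples)
  ntap <- length(h)
  if (length(x) < ntap)
    stopf("segment too short (%d samples) for the %d-tap filter",
          length(x), ntap)
  y <- as.numeric(stats::filter(x, h, method = "convolution", sides = 1))
  y <- y[ntap:length(y)]  # drop start-up transient; delay (ntap-1)/2 is constant
  list(samples = y, fs_hz = ppg$fs_hz)
}

#' Median of autoregressive power spectra over several model orders
#'
#' Fits a Burg autoregressive model at each requested order, evaluates each
#' model's power spectral density on a common frequency grid, and returns the
#' pointwise median across orders. The median makes the spectral estimate
#' robust to the occasional poorly-conditioned order.
#'
#' @param x numeric signal (mean is removed internally).
#' @param fs_hz sampling rate of `x`, Hz.
#' @param orders integer vector of AR orders (default 4:12).
#' @param f_max upper edge of the frequency grid, Hz (default 1).
#' @param df grid step, Hz (default 0.005).
#' @return List with `freq` (Hz) and `power` (median spectrum), or `NULL` if
#'   the signal is degenerate.
#' @export
ar_median_spectrum <- function(x, fs_hz, orders = 4:12, f_max = 1,
                               df = 0.005) {
  x <- as.numeric(x)
  if (length(x) < 4 * max(orders))
    stopf("signal length %d is below 4 x max AR order (%d)",
          length(x), max(orders))
  x <- x - mean(x)
  if (stats::sd(x) == 0) return(NULL)
  freq <- seq(0, f_max, by = df)
  z <- exp(-2i * pi * outer(freq / fs_hz, seq_len(max(orders))))
  specs <- vapply(orders, function(p) {
    fit <- stats::ar.burg(x, aic = FALSE, order.max = p, demean = FALSE)
    a <- fit$ar
    denom <- 1 - z[, seq_len(p), drop = FALSE] %*% a
    as.numeric(fit$var.pred / Mod(denom)^2)
  }, numeric(length(freq)))
  list(freq = freq, power = apply(specs, 1, stats::median))
}

#' Estimate respiratory rate from a PPG segment
#'
#' Runs the full pipeline: mean removal, heart-rate-adaptive low-pass
#' filtering ([adaptive_lowpass()]), FIR decimation to approximately 4 Hz,
#' and the median-of-AR-spectra estimate ([ar_median_spectrum()]); the
#' respiratory rate is 60 times the frequency of the spectral peak within
#' the respiratory band. If the peak rises less than 3 dB above the median
#' in-band power the estimate is flagged `low_confidence`.
#'
#' @param ppg a `ppg_segment`.
#' @param hr_bpm heart rate used to tune the filter; if `NULL`, estimated
#'   with [estimate_pulse_rate()].
#' @param band_brpm respiratory search band, breaths/min (default `c(4, 40)`).
#' @param orders AR model orders (default 4:12).
#' @return List with `rr_brpm`, `hr_bpm_used`, `quality`
#'   (`"ok"`, `"low_confidence"`, `"failed"`) and `spectrum`.
#' @export
estimate_respiratory_rate <- function(ppg, hr_bpm = NULL,
                                      band_brpm = c(4, 40), orders = 4:12) {
  ppg <- as_ppg_segment(ppg)
  check_segment(ppg)
  failed <- function() list(rr_brpm = NA_real_, hr_bpm_used = hr_bpm,
                            quality = "failed", spectrum = NULL)
  if (is.null(hr_bpm)) {
    pr <- estimate_pulse_rate(ppg)
    if (pr$quality == "failed") return(failed())
    hr_bpm <- pr$hr_bpm
  }
  lp <- adaptive_lowpass(ppg, hr_bpm)
  q <- max(1L, round(lp$fs_hz / 4))
  dec <- if (q > 1L) signal::decimate(lp$samples, q, ftype = "fir")
         else lp$samples
  fs_dec <- lp$fs_hz / q
  spec <- tryCatch(
    ar_median_spectrum(dec, fs_dec, orders = orders,
                       f_max = min(1, fs_dec / 2)),
    error = function(e) NULL)
  if (is.null(spec)) return(failed())
  band_hz <- band_brpm / 60
  in_band <- spec$freq >= band_hz[1] & spec$freq <= band_hz[2]
  if (!any(in_band)) return(failed())
  p_band <- spec$power[in_band]
  f_band <- spec$freq[in_band]
  peak <- which.max(p_band)
  quality <- if (10 * log10(p_band[peak] / stats::median(p_band)) < 3)
    "low_confidence" else "ok"
  list(rr_brpm = 60 * f_band[peak], hr_bpm_used = hr_bpm,
       quality = quality, spectrum = spec)
}

#' Estimate respiratory rate for every session in a cohort
#'
#' Synthesises (for synthetic cohorts) or loads each session's PPG segment
#' and runs [estimate_respiratory_rate()]. For a `copd_cohort`, a PPG segment
#' is generated per session from the session's latent pulse and respiratory
#' rates with a session-specific seed, so results are reproducible.
#'
#' @param cohort a `copd_cohort`.
#' @param fs_hz sampling rate for the synthesised segments.
#' @param am_depth,fm_depth,noise_sd modulation/noise of the synthesised PPG.
#' @param band_brpm,orders passed to [estimate_respiratory_rate()].
#' @return data.frame `patient_id`, `t`, `rr_brpm`, `hr_bpm_used`, `quality`.
#' @export
cohort_rr_estimates <- function(cohort, fs_hz = 100, am_depth = 0.2,
                                fm_depth = 0.05, noise_sd = 0.02,
                                band_brpm = c(4, 40), orders = 4:12) {
  stopifnot(inherits(cohort, "copd_cohort"))
  s <- cohort$sessions
  out <- data.frame(patient_id = s$patient_id, t = s$t,
                    rr_brpm = NA_real_, hr_bpm_used = NA_real_,
                    quality = "failed", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(s))) {
    cfg <- ppg_config(fs_hz = fs_hz, duration_s = 30,
                      hr_bpm = s$pulse_rate[i], rr_brpm = s$resp_rate[i],
                      am_depth = am_depth, fm_depth = fm_depth,
                      noise_sd = noise_sd,
                      seed = child_seed(cohort$config$seed, "ppg",
                                        s$patient_id[i], round(s$t[i] * 1e6)))
    est <- estimate_respiratory_rate(generate_ppg(cfg),
                                     hr_bpm = s$pulse_rate[i],
                                     band_brpm = band_brpm, orders = orders)
    out$rr_brpm[i] <- est$rr_brpm
    out$hr_bpm_used[i] <- est$hr_bpm_used
    out$quality[i] <- est$quality
  }
  out
}
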