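# Synthetic telemonitoring cohorts and modulated PPG waveforms with known
# ground truth. The generator emulates a year-long self-monitoring trial:
# ~5.3 sessions/week, exacerbation onsets as a Poisson process, log-normal
# episode lengths, diary answers constructed so the finite-state machine
# recovers the latent onsets, and class-conditional vitals that drift from
# stable towards prodromal means over the 7 days before each onset.

#' Configuration for a synthetic patient cohort
#'
#' Defaults reflect a year-long telemonitoring trial in moderate-to-severe
#' COPD: 5.3 sessions/week compliance, 3.6 exacerbations/patient/year,
#' episode lengths log-normal with mean 8.8 and median 4 days, stable
#' vital-sign means (SpO2 94%, pulse 80 bpm, respiratory rate 22 brpm)
#' against prodromal means (93, 83, 24). `prodromal_trend` is the per-day
#' drift of each vital over the 7 days before onset; its default,
#' `2 * (prodromal - stable) / 7`, starts the drift at the stable mean and
#' makes the 7-day window mean equal the prodromal mean.
#'
#' @param n_patients number of patients.
#' @param duration_days monitoring duration per patient, days.
#' @param sessions_per_week_mean mean diary sessions per week.
#' @param exacerbation_rate exacerbation onsets per patient per year.
#' @param exacerbation_length_mean mean episode length, days.
#' @param exacerbation_length_median median episode length, days (with the
#'   mean, fixes the log-normal shape).
#' @param stable_vitals_mean,prodromal_vitals_mean named numeric vectors
#'   `c(spo2=, pr=, rr=)` of class-conditional means.
#' @param vitals_sd named per-vital standard deviations.
#' @param prodromal_trend named per-vital drift, units/day, or `NULL` for the
#'   default above.
#' @param p_direct_medication probability that medication starts at the same
#'   session as the symptom worsening (direct NORMAL to EXACERBATION route);
#'   otherwise it starts one session later.
#' @param baseline_worse_prob per-session probability of a transient symptom
#'   worsening outside prodromal/episode phases.
#' @param prodromal_worse_prob per-session worsening probability during the 7
#'   days before an onset.
#' @param seed integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 20,
                          duration_days = 365,
                          sessions_per_week_mean = 5.3,
                          exacerbation_rate = 3.6,
                          exacerbation_length_mean = 8.8,
                          exacerbation_length_median = 4,
                          stable_vitals_mean = c(spo2 = 94, pr = 80, rr = 22),
                          prodromal_vitals_mean = c(spo2 = 93, pr = 83, rr = 24),
                          vitals_sd = c(spo2 = 2, pr = 8, rr = 3),
                          prodromal_trend = NULL,
                          p_direct_medication = 0.64,
                          baseline_worse_prob = 0.02,
                          prodromal_worse_prob = 0.35,
                          seed = 1L) {
  for (nm in c("spo2", "pr", "rr")) {
    if (is.na(stable_vitals_mean[nm]) || is.na(prodromal_vitals_mean[nm]) ||
        is.na(vitals_sd[nm]))
      stopf("vitals vectors must be named with spo2, pr, rr ('%s' missing)", nm)
  }
  if (n_patients < 1) stopf("n_patients must be positive")
  if (duration_days <= 0) stopf("duration_days must be strictly positive")
  if (sessions_per_week_mean <= 0 || sessions_per_week_mean > 7)
    stopf("sessions_per_week_mean must be in (0, 7]")
  if (exacerbation_rate < 0) stopf("exacerbation_rate must be non-negative")
  if (exacerbation_length_mean <= 0 || exacerbation_length_median <= 0)
    stopf("episode lengths must be strictly positive")
  if (exacerbation_length_median > exacerbation_length_mean)
    stopf("log-normal lengths require median <= mean")
  if (stable_vitals_mean["spo2"] <= 50 || stable_vitals_mean["spo2"] > 100 ||
      prodromal_vitals_mean["spo2"] <= 50 || prodromal_vitals_mean["spo2"] > 100)
    stopf("SpO2 means must lie in (50, 100]")
  if (prodromal_vitals_mean["spo2"] > stable_vitals_mean["spo2"])
    stopf("prodromal SpO2 mean must not exceed the stable mean")
  if (prodromal_vitals_mean["pr"] < stable_vitals_mean["pr"] ||
      prodromal_vitals_mean["rr"] < stable_vitals_mean["rr"])
    stopf("prodromal pulse/respiratory-rate means must be >= stable means")
  if (any(vitals_sd < 0)) stopf("vitals_sd must be non-negative")
  if (is.null(prodromal_trend))
    prodromal_trend <- 2 * (prodromal_vitals_mean - stable_vitals_mean) / 7
  structure(list(
    n_patients = as.integer(n_patients), duration_days = duration_days,
    sessions_per_week_mean = sessions_per_week_mean,
    exacerbation_rate = exacerbation_rate,
    exacerbation_length_mean = exacerbation_length_mean,
    exacerbation_length_median = exacerbation_length_median,
    stable_vitals_mean = stable_vitals_mean[c("spo2", "pr", "rr")],
    prodromal_vitals_mean = prodromal_vitals_mean[c("spo2", "pr", "rr")],
    vitals_sd = vitals_sd[c("spo2", "pr", "rr")],
    prodromal_trend = prodromal_trend[c("spo2", "pr", "rr")],
    p_direct_medication = p_direct_medication,
    baseline_worse_prob = baseline_worse_prob,
    prodromal_worse_prob = prodromal_worse_prob,
    seed = as.integer(seed)), class = "cohort_config")
}

empty_answers <- function(n) {
  out <- as.data.frame(matrix("no_change", n, length(SYMPTOM_KEYS)),
                       stringsAsFactors = FALSE)
  names(out) <- SYMPTOM_KEYS
  out
}

generate_patient <- function(config, pid, seed) {
  with_seed(seed, {
    dur <- config$duration_days
    lam <- config$exacerbation_rate / 365

    # latent onsets: Poisson process, thinned so episodes never overlap
    n_on <- stats::rpois(1, lam * dur)
    onsets <- sort(stats::runif(n_on, 0, dur))
    mu <- log(config$exacerbation_length_median)
    sg <- sqrt(2 * log(config$exacerbation_length_mean /
                         config$exacerbation_length_median))
    ep <- data.frame(onset = numeric(0), end = numeric(0),
                     entry_idx = integer(0), med_idx = integer(0),
                     exit_idx = integer(0))
    for (o in onsets) {
      if (nrow(ep) > 0L && o < ep$end[nrow(ep)] + 2) next
      len <- stats::rlnorm(1, mu, sg)
      ep <- rbind(ep, data.frame(onset = o, end = o + len,
                                 entry_idx = NA_integer_,
                                 med_idx = NA_integer_,
                                 exit_idx = NA_integer_))
    }

    # session times: daily Bernoulli compliance, daytime jitter (08:00-20:00)
    days <- which(stats::runif(dur) < config$sessions_per_week_mean / 7) - 1L
    t <- sort(days + stats::runif(length(days), 8 / 24, 20 / 24))
    n <- length(t)
    if (n == 0L)
      return(list(sessions = NULL,
                  episodes = data.frame(
                    patient_id = rep(pid, nrow(ep)), onset = ep$onset,
                    end = ep$end, entry_t = rep(NA_real_, nrow(ep)),
                    med_t = rep(NA_real_, nrow(ep)),
                    realized = rep(FALSE, nrow(ep)),
                    stringsAsFactors = FALSE)))

    # realized episode boundaries on the session grid
    prev_exit <- 0L
    for (k in seq_len(nrow(ep))) {
      cand <- which(t >= ep$onset[k])
      cand <- cand[cand > prev_exit]
      if (length(cand) == 0L) next
      entry <- cand[1]
      lag_ok <- entry + 1L <= n && t[entry + 1L] < ep$end[k]
      direct <- !lag_ok || stats::runif(1) < config$p_direct_medication
      med <- if (direct) entry else entry + 1L
      ex <- which(seq_len(n) > med & t >= ep$end[k])
      ep$entry_idx[k] <- entry
      ep$med_idx[k] <- med
      ep$exit_idx[k] <- if (length(ex) > 0L) ex[1] else NA_integer_
      prev_exit <- if (length(ex) > 0L) ex[1] else n
      if (is.na(ep$exit_idx[k])) break  # open episode ends the record
    }

    ans <- empty_answers(n)
    reliever <- rep(FALSE, n); abx <- rep(FALSE, n); ster <- rep(FALSE, n)

    role <- rep("stable", n)
    phase_ep <- rep(NA_integer_, n)   # episode index for vitals plateau
    phase_pro <- rep(NA_integer_, n)  # episode index for prodromal drift
    for (k in seq_len(nrow(ep))) {
      pro <- t >= ep$onset[k] - 7 & t < ep$onset[k]
      phase_pro[pro & is.na(phase_ep)] <- k
      inside <- t >= ep$onset[k] & t < ep$end[k]
      phase_ep[inside] <- k
    }

    for (k in seq_len(nrow(ep))) {
      if (is.na(ep$entry_idx[k])) next
      entry <- ep$entry_idx[k]; med <- ep$med_idx[k]; exi <- ep$exit_idx[k]
      last_in <- if (is.na(exi)) n else exi - 1L
      idx <- entry:last_in
      role[idx] <- "episode"
      ans$chest_tightness[idx] <- "worse"
      ans$breathlessness[idx] <- "worse"
      use_abx <- stats::runif(1) < 0.3
      if (use_abx) abx[med:last_in] <- TRUE else ster[med:last_in] <- TRUE
      reliever[idx] <- TRUE
      if (!is.na(exi)) {
        role[exi] <- "exit"
        ans$chest_tightness[exi] <- "improved"
        ans$breathlessness[exi] <- "improved"
      }
      pro_idx <- which(phase_pro == k & role == "stable")
      role[pro_idx] <- "prodromal"
    }

    # transient symptom worsenings outside episodes (normal variation)
    blip <- FALSE
    for (i in seq_len(n)) {
      if (!role[i] %in% c("stable", "prodromal")) { blip <- FALSE; next }
      p_enter <- if (role[i] == "prodromal") config$prodromal_worse_prob
                 else config$baseline_worse_prob
      if (!blip) {
        if (stats::runif(1) < p_enter) {
          blip <- TRUE
          ans$chest_tightness[i] <- "worse"
          ans$sputum_volume[i] <- "worse"
        }
      } else {
        if (stats::runif(1) < 0.5) {
          blip <- FALSE
          if (role[i] == "stable") {          # explicit improvement
            ans$chest_tightness[i] <- "improved"
            ans$sputum_volume[i] <- "improved"
          }                                    # prodromal: recovery via
        } else {                               # no_change vs previous worse
          ans$chest_tightness[i] <- "worse"
          ans$sputum_volume[i] <- "worse"
        }
      }
    }
    # occasional isolated reliever use outside episodes (never spans 48 h)
    iso <- role %in% c("stable", "prodromal") & stats::runif(n) < 0.03
    iso[which(iso)[c(FALSE, diff(which(iso)) == 1L)]] <- FALSE
    reliever[iso] <- TRUE

    # vitals around class-conditional means
    sm <- config$stable_vitals_mean; pm <- config$prodromal_vitals_mean
    sd <- config$vitals_sd; tr <- config$prodromal_trend
    mean_mat <- matrix(rep(sm, each = n), n, 3,
                       dimnames = list(NULL, c("spo2", "pr", "rr")))
    for (v in c("spo2", "pr", "rr")) {
      pro <- !is.na(phase_pro) & is.na(phase_ep)
      if (any(pro)) {
        tau <- t[pro] - ep$onset[phase_pro[pro]]     # in [-7, 0)
        mean_mat[pro, v] <- pm[v] + tr[v] * (tau + 3.5)
      }
      inside <- !is.na(phase_ep)
      mean_mat[inside, v] <- pm[v] + tr[v] * 3.5     # plateau at onset level
    }
    spo2 <- pmin(100, pmax(60, mean_mat[, "spo2"] + stats::rnorm(n, 0, sd["spo2"])))
    pr <- pmax(35, mean_mat[, "pr"] + stats::rnorm(n, 0, sd["pr"]))
    rr <- pmax(5, mean_mat[, "rr"] + stats::rnorm(n, 0, sd["rr"]))

    # shift so the first session defines t = 0
    t0 <- t[1]
    sessions <- data.frame(patient_id = pid, t = t - t0, ans,
                           reliever_increased = reliever, antibiotics = abx,
                           steroids = ster, hcp_contact = FALSE,
                           spo2 = round(spo2), pulse_rate = round(pr),
                           resp_rate = rr, phase = role,
                           stringsAsFactors = FALSE)
    episodes <- data.frame(
      patient_id = rep(pid, nrow(ep)),
      onset = ep$onset - t0, end = ep$end - t0,
      entry_t = ifelse(is.na(ep$entry_idx), NA_real_, t[ep$entry_idx] - t0),
      med_t = ifelse(is.na(ep$med_idx), NA_real_, t[ep$med_idx] - t0),
      realized = !is.na(ep$entry_idx), stringsAsFactors = FALSE)
    list(sessions = sessions, episodes = episodes)
  })
}

#' Generate a synthetic telemonitoring cohort
#'
#' Each patient alternates stable stretches and exacerbation episodes (onsets
#' a Poisson process, lengths log-normal). Diary answers and medication flags
#' are constructed so that running [run_fsm()] on the stream enters the
#' EXACERBATION state at (or one session after) each realized latent onset.
#' Vitals drift linearly from stable towards prodromal means over the 7 days
#' before each onset and are drawn around the stable means elsewhere.
#'
#' @param config a [cohort_config()].
#' @return An object of class `copd_cohort`: list with `sessions` (all
#'   patients, one row per session; `resp_rate` holds the latent
#'   ground-truth respiratory rate and `phase` the latent role of each
#'   session), `episodes` (latent onset/end times, realized entry times) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  pats <- lapply(seq_len(config$n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    generate_patient(config, pid, child_seed(config$seed, "patient", i))
  })
  sessions <- do.call(rbind, Filter(Negate(is.null),
                                    lapply(pats, `[[`, "sessions")))
  episodes <- do.call(rbind, lapply(pats, `[[`, "episodes"))
  rownames(sessions) <- NULL; rownames(episodes) <- NULL
  structure(list(sessions = sessions, episodes = episodes, config = config),
            class = "copd_cohort")
}

#' @export
print.copd_cohort <- function(x, ...) {
  cat(sprintf("Synthetic COPD cohort: %d patients, %d sessions, %d latent episodes (%d realized)\n",
              x$config$n_patients, nrow(x$sessions), nrow(x$episodes),
              sum(x$episodes$realized)))
  invisible(x)
}

#' Configuration for a synthetic PPG waveform
#'
#' @param fs_hz sampling rate, Hz.
#' @param duration_s segment length, seconds (default 30).
#' @param hr_bpm cardiac rate, beats/min.
#' @param rr_brpm respiratory rate, breaths/min.
#' @param am_depth fractional amplitude modulation by breathing, in \[0, 1).
#' @param fm_depth fractional modulation of the cardiac period (respiratory
#'   sinus arrhythmia), in \[0, 1).
#' @param noise_sd additive white-noise standard deviation.
#' @param seed integer seed or `NULL`.
#' @return A `ppg_config` list.
#' @export
ppg_config <- function(fs_hz = 100, duration_s = 30, hr_bpm = 75,
                       rr_brpm = 18, am_depth = 0.2, fm_depth = 0,
                       noise_sd = 0, seed = NULL) {
  if (!(rr_brpm > 0 && rr_brpm < hr_bpm))
    stopf("rr_brpm must satisfy 0 < rr_brpm < hr_bpm")
  if (fs_hz <= 2 * hr_bpm / 60)
    stopf("fs_hz must exceed twice the cardiac frequency")
  if (duration_s <= 2 * 60 / rr_brpm)
    stopf("duration_s must exceed two breath periods")
  if (am_depth < 0 || am_depth >= 1) stopf("am_depth must lie in [0, 1)")
  if (fm_depth < 0 || fm_depth >= 1) stopf("fm_depth must lie in [0, 1)")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  structure(list(fs_hz = fs_hz, duration_s = duration_s, hr_bpm = hr_bpm,
                 rr_brpm = rr_brpm, am_depth = am_depth, fm_depth = fm_depth,
                 noise_sd = noise_sd, seed = seed), class = "ppg_config")
}

#' Generate a respiration-modulated synthetic PPG segment
#'
#' A raised-cosine pulse train at the cardiac rate whose instantaneous
#' frequency is sinusoidally modulated at the respiratory frequency
#' (`fm_depth`) and whose amplitude is modulated by
#' `1 + am_depth * sin(2 pi f_r t)`, plus additive white noise. The pulse
#' shape is a smooth bump, not a physiological PPG template: only the
#' modulation structure matters for respiratory-rate estimation.
#'
#' @param config a [ppg_config()].
#' @return An object of class `ppg_segment`: list with `samples`, `fs_hz`,
#'   `duration_s`, and ground-truth `hr_bpm`, `rr_brpm`.
#' @export
generate_ppg <- function(config) {
  stopifnot(inherits(config, "ppg_config"))
  n <- round(config$fs_hz * config$duration_s)
  tt <- (seq_len(n) - 1) / config$fs_hz
  f_h <- config$hr_bpm / 60
  f_r <- config$rr_brpm / 60
  inst_f <- f_h * (1 + config$fm_depth * sin(2 * pi * f_r * tt))
  phase <- 2 * pi * cumsum(inst_f) / config$fs_hz
  pulse <- ((1 + cos(phase)) / 2)^2
  am <- 1 + config$am_depth * sin(2 * pi * f_r * tt)
  noise <- if (config$noise_sd > 0) {
    with_seed(config$seed, stats::rnorm(n, 0, config$noise_sd))
  } else rep(0, n)
  structure(list(samples = am * pulse + noise, fs_hz = config$fs_hz,
                 duration_s = config$duration_s, hr_bpm = config$hr_bpm,
                 rr_brpm = config$rr_brpm), class = "ppg_segment")
}

#' @export
print.ppg_segment <- function(x, ...) {
  cat(sprintf("PPG segment: %.1f s at %g Hz (%d samples), HR %g bpm, RR %g brpm\n",
              x$duration_s, x$fs_hz, length(x$samples), x$hr_bpm, x$rr_brpm))
  invisible(x)
}
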