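# Builders for small session streams used across tests.

SYMPTOMS <- c("chest_tightness", "breathlessness", "sputum_volume",
              "sputum_purulence", "cold_sore_throat", "run_down")

# n sessions at the given times, all answers "no_change", no medication.
base_sessions <- function(t, patient_id = "T1", spo2 = 94, pulse_rate = 80,
                          resp_rate = 22) {
  n <- length(t)
  out <- data.frame(patient_id = rep_len(patient_id, n), t = t,
                    stringsAsFactors = FALSE)
  for (k in SYMPTOMS) out[[k]] <- rep("no_change", n)
  out$reliever_increased <- rep_len(FALSE, n)
  out$antibiotics <- rep_len(FALSE, n)
  out$steroids <- rep_len(FALSE, n)
  out$hcp_contact <- rep_len(FALSE, n)
  out$spo2 <- rep_len(spo2, n)
  out$pulse_rate <- rep_len(pulse_rate, n)
  out$resp_rate <- rep_len(resp_rate, n)
  out
}

# Set symptom answers on row i: set_answers(s, 2, chest_tightness = "worse")
set_answers <- function(sessions, i, ...) {
  vals <- list(...)
  for (k in names(vals)) sessions[[k]][i] <- vals[[k]]
  sessions
}

# A state timeline built directly from (t, state) pairs, starting NORMAL.
toy_timeline <- function(t, state, patient_id = "T1") {
  prev <- c("NORMAL", state[-length(state)])
  structure(list(
    patient_id = patient_id,
    entries = data.frame(t = t, state = state, event_bit = 0L,
                         symptom_code = "00", prev_state = prev,
                         stringsAsFactors = FALSE),
    final_state = if (length(state)) state[length(state)] else "NORMAL"),
    class = "state_timeline")
}

# Session stream that drives the FSM through one exacerbation:
# worsening + steroids at t_onset, improvement at t_end.
episode_sessions <- function(t, t_onset, t_end, patient_id = "T1") {
  s <- base_sessions(t, patient_id)
  in_ep <- t >= t_onset & t < t_end
  entry <- which(in_ep)[1]
  s$chest_tightness[in_ep] <- "worse"
  s$breathlessness[in_ep] <- "worse"
  s$steroids[in_ep] <- TRUE
  exit <- which(t >= t_end)[1]
  if (!is.na(exit)) {
    s$chest_tightness[exit] <- "improved"
    s$breathlessness[exit] <- "improved"
  }
  s
}
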