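# Three-state finite-state machine over symptom-diary sessions.
#
# States: NORMAL, TRANSITIONAL, EXACERBATION. Each completed diary session is
# encoded as a 3-bit input: one medication-event bit and a 2-bit symptom code
# (00 no change, 10 worse, 11 improve; 01 is illegal).

#' Classify the symptom change reported in a diary session
#'
#' A session reports each of six symptoms (four "major": chest tightness,
#' breathlessness, sputum volume, sputum purulence; two "minor": cold/sore
#' throat, feeling run down) as improved, no change, or worse relative to the
#' patient's usual condition. A *significant worsening* is at least two
#' "worse" answers of which at least one is major. Improvement mirrors this:
#' at least two answers count as improving, at least one of them major, where
#' an answer counts toward improvement if it is "improved" now, or if it was
#' "worse" at the previous session and is "no_change" now.
#'
#' If both thresholds are met simultaneously, worsening takes precedence.
#'
#' @param current a single-session row (list or one-row data.frame) with the
#'   six symptom answers.
#' @param previous the previous session for the same patient, or `NULL` if
#'   `current` is the first session.
#' @return One of `"worse"`, `"improve"`, `"no_change"`.
#' @export
#' @examples
#' s <- as.list(setNames(rep("no_change", 6),
#'   c("chest_tightness", "breathlessness", "sputum_volume",
#'     "sputum_purulence", "cold_sore_throat", "run_down")))
#' s$breathlessness <- "worse"; s$cold_sore_throat <- "worse"
#' classify_symptom_change(s)
classify_symptom_change <- function(current, previous = NULL) {
  cur <- vapply(SYMPTOM_KEYS, function(k) {
    v <- current[[k]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stopf("missing answer for symptom '%s'", k)
    as.character(v)
  }, character(1))
  if (any(!cur %in% SYMPTOM_LEVELS))
    stopf("invalid symptom answer(s): %s",
          paste(cur[!cur %in% SYMPTOM_LEVELS], collapse = ", "))

  worse <- cur == "worse"
  improving <- cur == "improved"
  if (!is.null(previous)) {
    prev <- vapply(SYMPTOM_KEYS, function(k) as.character(previous[[k]]), character(1))
    improving <- improving | (prev == "worse" & cur == "no_change")
  }

  is_major <- SYMPTOM_KEYS %in% MAJOR_KEYS
  if (sum(worse) >= 2L && any(worse & is_major)) return("worse")
  if (sum(improving) >= 2L && any(improving & is_major)) return("improve")
  "no_change"
}

#' Detect a medication event at the last session of a history
#'
#' A medication event is either (a) *starting* oral steroids and/or
#' antibiotics — the flag is set at the current session after being absent at
#' the previous session, or after at least 7 flag-free days (a new course) —
#' or (b) increased reliever-inhaler use sustained for at least 48 hours: the
#' current session and a contiguous run of immediately preceding sessions all
#' have `reliever_increased` set, with inter-session gaps of at most 2 days,
#' and the run spans >= 2 days from first to current timestamp.
#'
#' @param history data.frame of sessions for one patient, ordered in time,
#'   ending at the session being evaluated.
#' @return `1L` if a medication event occurs at the final session, else `0L`.
#' @export
detect_medication_event <- function(history) {
  n <- nrow(history)
  if (n == 0L) return(0L)
  cur <- history[n, ]

  # (a) starting antibiotics/steroids: rising edge vs the previous session,
  # or resumption after >= 7 days since the flag was last seen.
  for (drug in c("antibiotics", "steroids")) {
    if (isTRUE(as.logical(cur[[drug]]))) {
      if (n == 1L) return(1L)
      prev_on <- as.logical(history[[drug]][seq_len(n - 1L)])
      if (!isTRUE(prev_on[n - 1L])) return(1L)
      last_on <- max(history$t[seq_len(n - 1L)][prev_on])
      if (cur$t - last_on >= 7) return(1L)
    }
  }

  # (b) sustained increased reliever use >= 48 h.
  if (isTRUE(as.logical(cur$reliever_increased))) {
    first_t <- cur$t
    i <- n - 1L
    t_next <- cur$t
    while (i >= 1L &&
           isTRUE(as.logical(history$reliever_increased[i])) &&
           (t_next - history$t[i]) <= 2) {
      first_t <- history$t[i]
      t_next <- history$t[i]
      i <- i - 1L
    }
    if (cur$t - first_t >= 2) return(1L)
  }
  0L
}

#' Encode a diary session as a 3-bit FSM input
#'
#' The event bit is 1 if a medication event is detected at this session or the
#' patient reported contact with a health-care professional (including
#' hospital admission); the 2-bit symptom code comes from
#' [classify_symptom_change()].
#'
#' @param session the current session row.
#' @param history sessions up to and including `session`, ordered in time.
#' @return List with `event_bit` (0/1) and `symptom_code` (`"00"`, `"10"`,
#'   `"11"`).
#' @export
encode_input <- function(session, history) {
  n <- nrow(history)
  previous <- if (n >= 2L) history[n - 1L, ] else NULL
  change <- classify_symptom_change(session, previous)
  code <- c(no_change = "00", worse = "10", improve = "11")[[change]]
  med <- detect_medication_event(history)
  hcp <- isTRUE(as.logical(session$hcp_contact))
  list(event_bit = as.integer(med == 1L || hcp), symptom_code = code)
}

#' Advance the patient state machine by one input
#'
#' Transition rules: a patient stays NORMAL regardless of medication unless
#' symptoms worsen; worsening moves the patient to TRANSITIONAL (no event) or
#' straight to EXACERBATION (with a medication event / HCP contact). From
#' TRANSITIONAL, improvement always returns to NORMAL; an event without
#' improvement escalates to EXACERBATION; otherwise the patient remains
#' TRANSITIONAL. From EXACERBATION the only exit is symptom improvement,
#' back to NORMAL.
#'
#' @param state one of `"NORMAL"`, `"TRANSITIONAL"`, `"EXACERBATION"`.
#' @param input list with `event_bit` in \{0, 1\} and `symptom_code` in
#'   \{"00", "10", "11"\}.
#' @return The next state.
#' @export
#' @examples
#' fsm_step("NORMAL", list(event_bit = 1L, symptom_code = "10"))
fsm_step <- function(state, input) {
  if (!state %in% FSM_STATES) stopf("unknown state '%s'", state)
  code <- as.character(input$symptom_code)
  ev <- as.integer(input$event_bit)
  if (!code %in% c("00", "10", "11"))
    stopf("illegal symptom code '%s' (01 is not a legal input)", code)
  if (!ev %in% c(0L, 1L)) stopf("event bit must be 0 or 1")

  switch(state,
    NORMAL = if (code == "10") {
      if (ev == 1L) "EXACERBATION" else "TRANSITIONAL"
    } else "NORMAL",
    TRANSITIONAL = if (code == "11") {
      "NORMAL"
    } else if (ev == 1L) {
      "EXACERBATION"
    } else "TRANSITIONAL",
    EXACERBATION = if (code == "11") "NORMAL" else "EXACERBATION"
  )
}

#' Run the finite-state machine over one patient's sessions
#'
#' The patient is assumed to start in the NORMAL state. Each session is
#' encoded with [encode_input()] and applied with [fsm_step()]; the state in
#' force after a session persists until the next session.
#'
#' @param sessions data.frame of diary sessions for a single patient, sorted
#'   strictly increasing in `t` (fractional days).
#' @return An object of class `state_timeline`: a list with `patient_id`,
#'   `entries` (data.frame `t`, `state`, `event_bit`, `symptom_code`,
#'   `prev_state`) and `final_state`.
#' @export
run_fsm <- function(sessions) {
  check_sessions_frame(sessions)
  check_sorted_single_patient(sessions)
  pid <- if (nrow(sessions) > 0L) sessions$patient_id[1] else NA_character_

  n <- nrow(sessions)
  state <- "NORMAL"
  st <- character(n); ev <- integer(n); code <- character(n); prev <- character(n)
  for (i in seq_len(n)) {
    input <- encode_input(sessions[i, ], sessions[seq_len(i), ])
    prev[i] <- state
    state <- fsm_step(state, input)
    st[i] <- state
    ev[i] <- input$event_bit
    code[i] <- input$symptom_code
  }
  structure(list(
    patient_id = pid,
    entries = data.frame(t = sessions$t, state = st, event_bit = ev,
                         symptom_code = code, prev_state = prev,
                         stringsAsFactors = FALSE),
    final_state = state
  ), class = "state_timeline")
}

#' @export
print.state_timeline <- function(x, ...) {
  n <- nrow(x$entries)
  cat(sprintf("State timeline for patient '%s': %d sessions, final state %s\n",
              x$patient_id, n, x$final_state))
  if (n > 0L) {
    occ <- table(factor(x$entries$state, levels = FSM_STATES))
    cat(sprintf("  session occupancy: NORMAL %d, TRANSITIONAL %d, EXACERBATION %d\n",
                occ[1], occ[2], occ[3]))
  }
  invisible(x)
}

#' Extract exacerbation events from a state timeline
#'
#' One event per maximal run of sessions in the EXACERBATION state. An event
#' starts at the session that enters the state and ends at the session that
#' exits back to NORMAL; if monitoring ends while still in EXACERBATION the
#' event is open-ended (`end_t = NA`) and its length is measured to the last
#' observed session. Lengths are the day span rounded up, with a minimum of
#' one day.
#'
#' @param timeline a `state_timeline`.
#' @return data.frame with `patient_id`, `start_t`, `end_t`, `length_days`,
#'   `open` (logical).
#' @export
extract_exacerbation_events <- function(timeline) {
  stopifnot(inherits(timeline, "state_timeline"))
  e <- timeline$entries
  out <- data.frame(patient_id = character(0), start_t = numeric(0),
                    end_t = numeric(0), length_days = numeric(0),
                    open = logical(0), stringsAsFactors = FALSE)
  if (nrow(e) == 0L) return(out)
  in_ex <- e$state == "EXACERBATION"
  entered <- in_ex & e$prev_state != "EXACERBATION"
  starts <- which(entered)
  for (s in starts) {
    after <- which(seq_len(nrow(e)) > s & e$state != "EXACERBATION")
    if (length(after) == 0L) {
      end_t <- NA_real_
      span <- e$t[nrow(e)] - e$t[s]
      open <- TRUE
    } else {
      end_t <- e$t[min(after)]
      span <- end_t - e$t[s]
      open <- FALSE
    }
    out <- rbind(out, data.frame(
      patient_id = timeline$patient_id, start_t = e$t[s], end_t = end_t,
      length_days = max(1, ceiling(span)), open = open,
      stringsAsFactors = FALSE))
  }
  out
}

#' Aggregate state-transition counts across patients
#'
#' Counts ordered state-to-state transitions (state changes only) and the
#' number of sessions completed in each state, across a list of timelines.
#' Also verifies per-patient bookkeeping: a patient who starts in NORMAL has
#' exactly one more exit from NORMAL than entries into it iff they finish in
#' a non-NORMAL state.
#'
#' @param timelines list of `state_timeline` objects, one per patient.
#' @return List with `transitions` (3x3 integer matrix, rows = from),
#'   `sessions_per_state` (named integer vector) and `n_final_non_normal`.
#' @export
transition_summary <- function(timelines) {
  trans <- matrix(0L, 3, 3, dimnames = list(FSM_STATES, FSM_STATES))
  occ <- setNames(integer(3), FSM_STATES)
  n_non_normal <- 0L
  for (tl in timelines) {
    stopifnot(inherits(tl, "state_timeline"))
    e <- tl$entries
    if (nrow(e) > 0L) {
      occ_t <- table(factor(e$state, levels = FSM_STATES))
      occ <- occ + as.integer(occ_t)
      ch <- e$prev_state != e$state
      for (i in which(ch))
        trans[e$prev_state[i], e$state[i]] <- trans[e$prev_state[i], e$state[i]] + 1L
    }
    fin_non_norm <- as.integer(tl$final_state != "NORMAL")
    n_non_normal <- n_non_normal + fin_non_norm
    exits <- sum(e$prev_state == "NORMAL" & e$state != "NORMAL")
    entries <- sum(e$prev_state != "NORMAL" & e$state == "NORMAL")
    if (exits - entries != fin_non_norm)
      stopf("bookkeeping violation for patient '%s'", tl$patient_id)
  }
  list(transitions = trans, sessions_per_state = occ,
       n_final_non_normal = n_non_normal)
}
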