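# Finite-state machine: symptom coding, medication events, transitions.

test_that("symptom worsening needs two answers including a major one", {
  s <- base_sessions(0)
  s <- set_answers(s, 1, breathlessness = "worse", cold_sore_throat = "worse")
  expect_equal(classify_symptom_change(s[1, ]), "worse")

  s <- base_sessions(0)
  s <- set_answers(s, 1, cold_sore_throat = "worse", run_down = "worse")
  expect_equal(classify_symptom_change(s[1, ]), "no_change")

  s <- base_sessions(0)
  s <- set_answers(s, 1, chest_tightness = "worse")
  expect_equal(classify_symptom_change(s[1, ]), "no_change")

  s <- base_sessions(0)
  for (k in SYMPTOMS) s[[k]][1] <- "improved"
  expect_equal(classify_symptom_change(s[1, ]), "improve")
})

test_that("improvement may be relative to the previous session's worsening", {
  s <- base_sessions(c(0, 1))
  s <- set_answers(s, 1, chest_tightness = "worse", breathlessness = "worse")
  # both previously-worse majors now back to no_change counts as improvement
  expect_equal(classify_symptom_change(s[2, ], s[1, ]), "improve")
  # only one answer improves relative to the previous session
  s2 <- set_answers(s, 2, chest_tightness = "worse")
  expect_equal(classify_symptom_change(s2[2, ], s2[1, ]), "no_change")
})

test_that("simultaneous worsening and improvement resolves to worse", {
  s <- base_sessions(0)
  s <- set_answers(s, 1, chest_tightness = "worse", breathlessness = "worse",
                   sputum_volume = "improved", sputum_purulence = "improved")
  expect_equal(classify_symptom_change(s[1, ]), "worse")
})

test_that("missing answers are a validation error", {
  s <- base_sessions(0)
  s$run_down[1] <- NA
  expect_error(classify_symptom_change(s[1, ]), "run_down")
})

test_that("starting steroids or antibiotics is a rising-edge medication event", {
  s <- base_sessions(c(0, 1, 2, 12))
  s$steroids <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(detect_medication_event(s[1:2, ]), 1L)   # start
  expect_equal(detect_medication_event(s[1:3, ]), 0L)   # continuation
  expect_equal(detect_medication_event(s[1:4, ]), 1L)   # new course after >= 7 d
  expect_equal(detect_medication_event(s[1, , drop = FALSE]), 0L)
})

test_that("increased reliever use must span at least 48 hours", {
  s <- base_sessions(c(0, 1, 2.1))
  s$reliever_increased <- c(FALSE, TRUE, FALSE)
  expect_equal(detect_medication_event(s[1:2, ]), 0L)   # isolated session

  s$reliever_increased <- TRUE
  expect_equal(detect_medication_event(s[1:2, ]), 0L)   # span 1 d
  expect_equal(detect_medication_event(s[1:3, ]), 1L)   # span 2.1 d

  # a gap of more than 2 days between sessions breaks the run
  g <- base_sessions(c(0, 3, 4, 5))
  g$reliever_increased <- TRUE
  expect_equal(detect_medication_event(g[1:2, ]), 0L)
  expect_equal(detect_medication_event(g[1:4, ]), 1L)   # 3 -> 5 spans 2 d
})

test_that("encode_input combines medication bit and symptom code", {
  s <- base_sessions(c(0, 1))
  s <- set_answers(s, 2, chest_tightness = "worse", sputum_volume = "worse")
  expect_equal(encode_input(s[2, ], s[1:2, ]),
               list(event_bit = 0L, symptom_code = "10"))

  s2 <- base_sessions(c(0, 1))
  s2 <- set_answers(s2, 2, chest_tightness = "improved",
                    breathlessness = "improved")
  s2$steroids[2] <- TRUE
  expect_equal(encode_input(s2[2, ], s2[1:2, ]),
               list(event_bit = 1L, symptom_code = "11"))

  s3 <- base_sessions(0)
  expect_equal(encode_input(s3[1, ], s3[1, , drop = FALSE]),
               list(event_bit = 0L, symptom_code = "00"))

  s4 <- base_sessions(0)
  s4$hcp_contact[1] <- TRUE
  expect_equal(encode_input(s4[1, ], s4[1, , drop = FALSE])$event_bit, 1L)
})

# Hand-transcribed truth table: state x (event bit, symptom code) -> state.
fsm_truth_table <- data.frame(
  state = rep(c("NORMAL", "TRANSITIONAL", "EXACERBATION"), each = 6),
  event = rep(c(0L, 1L), 9),
  code = rep(rep(c("00", "10", "11"), each = 2), 3),
  next_state = c(
    "NORMAL", "NORMAL", "TRANSITIONAL", "EXACERBATION", "NORMAL", "NORMAL",
    "TRANSITIONAL", "EXACERBATION", "TRANSITIONAL", "EXACERBATION",
    "NORMAL", "NORMAL",
    "EXACERBATION", "EXACERBATION", "EXACERBATION", "EXACERBATION",
    "NORMAL", "NORMAL"),
  stringsAsFactors = FALSE)

test_that("fsm_step matches the hand-coded truth table on all 18 pairs", {
  for (i in seq_len(nrow(fsm_truth_table))) {
    got <- fsm_step(fsm_truth_table$state[i],
                    list(event_bit = fsm_truth_table$event[i],
                         symptom_code = fsm_truth_table$code[i]))
    expect_equal(got, fsm_truth_table$next_state[i],
                 info = sprintf("(%s, (%d,%s))", fsm_truth_table$state[i],
                                fsm_truth_table$event[i],
                                fsm_truth_table$code[i]))
  }
})

test_that("no input leads from EXACERBATION to TRANSITIONAL", {
  for (ev in 0:1) for (code in c("00", "10", "11")) {
    expect_false(fsm_step("EXACERBATION",
                          list(event_bit = ev, symptom_code = code)) ==
                   "TRANSITIONAL")
  }
})

test_that("illegal inputs are rejected", {
  expect_error(fsm_step("NORMAL", list(event_bit = 0L, symptom_code = "01")),
               "illegal")
  expect_error(fsm_step("RECOVERING", list(event_bit = 0L, symptom_code = "00")),
               "unknown state")
})

test_that("run_fsm traces the expected state sequence", {
  # inputs (0,10), (1,00), (0,11) -> TRANSITIONAL, EXACERBATION, NORMAL
  s <- base_sessions(c(0, 1, 2))
  s <- set_answers(s, 1, chest_tightness = "worse", breathlessness = "worse")
  s <- set_answers(s, 2, chest_tightness = "worse")  # 1 worse, 1 credit: 00
  s$steroids[2:3] <- TRUE                            # start at session 2
  s <- set_answers(s, 3, chest_tightness = "improved",
                   breathlessness = "improved")
  tl <- run_fsm(s)
  expect_equal(tl$entries$symptom_code, c("10", "00", "11"))
  expect_equal(tl$entries$event_bit, c(0L, 1L, 0L))
  expect_equal(tl$entries$state, c("TRANSITIONAL", "EXACERBATION", "NORMAL"))
  expect_equal(tl$final_state, "NORMAL")
})

test_that("run_fsm handles the empty stream and rejects unsorted input", {
  tl <- run_fsm(base_sessions(numeric(0)))
  expect_equal(nrow(tl$entries), 0)
  expect_equal(tl$final_state, "NORMAL")
  expect_error(run_fsm(base_sessions(c(2, 1))), "increasing")
})

test_that("exacerbation events are maximal runs with ceiling day lengths", {
  s <- episode_sessions(t = c(0, 5, 10.2, 12, 14.5, 20),
                        t_onset = 10, t_end = 14)
  tl <- run_fsm(s)
  ev <- extract_exacerbation_events(tl)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_t, 10.2)
  expect_equal(ev$end_t, 14.5)
  expect_equal(ev$length_days, 5)  # ceil(4.3)
  expect_false(ev$open)

  # never entering the state gives no events
  expect_equal(nrow(extract_exacerbation_events(run_fsm(base_sessions(0:5)))), 0)

  # sub-day episode is floored at one day
  s1 <- episode_sessions(t = c(0, 1, 1.3, 2, 5), t_onset = 1, t_end = 1.9)
  ev1 <- extract_exacerbation_events(run_fsm(s1))
  expect_equal(ev1$length_days, 1)

  # monitoring ending in the state gives an open event
  s2 <- episode_sessions(t = c(0, 1, 2, 3), t_onset = 2, t_end = 99)
  ev2 <- extract_exacerbation_events(run_fsm(s2))
  expect_true(ev2$open)
  expect_true(is.na(ev2$end_t))
})

test_that("two separate exacerbation runs give two disjoint events", {
  s <- base_sessions(c(0, 1, 2, 10, 11, 12))
  for (i in c(2, 5)) {
    s <- set_answers(s, i, chest_tightness = "worse", breathlessness = "worse")
    s$steroids[i] <- TRUE
  }
  for (i in c(3, 6)) s <- set_answers(s, i, chest_tightness = "improved",
                                      breathlessness = "improved")
  ev <- extract_exacerbation_events(run_fsm(s))
  expect_equal(nrow(ev), 2)
  expect_true(ev$end_t[1] <= ev$start_t[2])
})

test_that("transition summary books exits and entries per patient", {
  # ends NORMAL: exits == entries
  s <- episode_sessions(t = 0:6, t_onset = 2, t_end = 4)
  tl <- run_fsm(s)
  ts1 <- transition_summary(list(tl))
  tr <- ts1$transitions
  expect_equal(sum(tr["NORMAL", c("TRANSITIONAL", "EXACERBATION")]),
               sum(tr[c("TRANSITIONAL", "EXACERBATION"), "NORMAL"]))
  expect_equal(ts1$n_final_non_normal, 0)

  # cohort of k patients ending non-NORMAL: difference equals k
  mk <- function(pid) {
    s <- episode_sessions(t = 0:4, t_onset = 2, t_end = 99, patient_id = pid)
    run_fsm(s)
  }
  tls <- lapply(c("A", "B", "C"), mk)
  ts2 <- transition_summary(tls)
  tr2 <- ts2$transitions
  diff_n <- sum(tr2["NORMAL", c("TRANSITIONAL", "EXACERBATION")]) -
    sum(tr2[c("TRANSITIONAL", "EXACERBATION"), "NORMAL"])
  expect_equal(diff_n, 3)
  expect_equal(ts2$n_final_non_normal, 3)

  # empty cohort
  ts0 <- transition_summary(list())
  expect_true(all(ts0$transitions == 0))
  expect_true(all(ts0$sessions_per_state == 0))
})

test_that("session-state occupancy partitions the sessions", {
  cohort <- generate_cohort(cohort_config(n_patients = 3, duration_days = 120,
                                          seed = 5))
  tls <- lapply(split(cohort$sessions, cohort$sessions$patient_id), run_fsm)
  ts <- transition_summary(tls)
  expect_equal(sum(ts$sessions_per_state), nrow(cohort$sessions))
})
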