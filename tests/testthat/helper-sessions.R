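# Build a session from per-question day vectors. Binary vectors hold "YES",
# "NO", "INVALID" or NA (absent); the weight vector holds kg values, NA
# (absent) or "INVALID". Questions left NULL are filled with benign answers
# (no symptoms, medication taken, stable 70 kg) so a test can exercise one
# rule without silent days tripping the non-response rule.
make_session <- function(days = 7, pid = "T01", start = "2017-09-04",
                         dyspnea = NULL, weight = NULL,
                         medication = NULL, fatigue = NULL) {
  if (is.null(dyspnea)) dyspnea <- rep("NO", days)
  if (is.null(fatigue)) fatigue <- rep("NO", days)
  if (is.null(medication)) medication <- rep("YES", days)
  if (is.null(weight)) weight <- rep(70, days)
  s <- new_session(patient_profile(pid, start, days))
  fill_binary <- function(s, q, vals) {
    stopifnot(length(vals) == days)
    for (d in seq_len(days)) {
      if (is.na(vals[d])) next
      s <- set_answer(s, d, q, parsed_answer(vals[d], raw_text = vals[d]))
    }
    s
  }
  s <- fill_binary(s, "DYSPNEA", dyspnea)
  s <- fill_binary(s, "MEDICATION", medication)
  s <- fill_binary(s, "FATIGUE", fatigue)
  stopifnot(length(weight) == days)
  for (d in seq_len(days)) {
    w <- weight[d]
    if (is.na(w)) next
    a <- if (identical(w, "INVALID")) parsed_answer("INVALID", raw_text = "?")
         else parsed_answer("NUMERIC", as.numeric(w), raw_text = as.character(w))
    s <- set_answer(s, d, "WEIGHT", a)
  }
  s
}

# Random session for property tests: each cell independently absent, invalid
# or a random value of the right shape.
random_session <- function(days, pid = "R01", p_absent = 0.25,
                           p_invalid = 0.1, p_yes = 0.4) {
  s <- new_session(patient_profile(pid, "2017-09-04", days))
  for (d in seq_len(days)) {
    for (q in c("DYSPNEA", "MEDICATION", "FATIGUE")) {
      u <- runif(1)
      if (u < p_absent) next
      a <- if (u < p_absent + p_invalid) parsed_answer("INVALID", raw_text = "??")
      else if (runif(1) < p_yes) parsed_answer("YES", raw_text = "yes")
      else parsed_answer("NO", raw_text = "no")
      s <- set_answer(s, d, q, a)
    }
    u <- runif(1)
    if (u >= p_absent) {
      a <- if (u < p_absent + p_invalid) parsed_answer("INVALID", raw_text = "??")
      else parsed_answer("NUMERIC", round(runif(1, 60, 90), 1))
      s <- set_answer(s, d, "WEIGHT", a)
    }
  }
  s
}

# Engine answer grids as plain vectors, for comparing against the oracles.
session_kind_vector <- function(s, q) {
  vapply(seq_len(s$profile$follow_up_days), function(d) {
    a <- hfsms:::session_answer(s, d, q)
    if (is.null(a)) NA_character_ else a$kind
  }, "")
}

session_weight_vector <- function(s) {
  vapply(seq_len(s$profile$follow_up_days), function(d) {
    a <- hfsms:::session_answer(s, d, "WEIGHT")
    if (!is.null(a) && a$kind == "NUMERIC") a$numeric_value else NA_real_
  }, 1)
}
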