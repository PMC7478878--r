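test_that("two consecutive affirmative dyspnea nights fire one alarm", {
  s <- make_session(7, dyspnea = c("YES", "YES", "NO", NA, NA, NA, NA))
  al <- evaluate_alarms(s)
  expect_equal(nrow(al), 1)
  expect_equal(al$rule, "DYSPNEA_STREAK")
  expect_equal(al$day_index, 2L)

  # alternating days never complete a streak
  alt <- make_session(7, dyspnea = c("YES", "NO", "YES", "NO", "YES", "NO", "YES"))
  expect_equal(nrow(evaluate_alarms(alt)), 0)

  # an uninterrupted week fires exactly once, on the day the streak completes
  wk <- make_session(7, dyspnea = rep("YES", 7))
  al <- evaluate_alarms(wk)
  expect_equal(al$rule, "DYSPNEA_STREAK")
  expect_equal(al$day_index, 2L)

  # a broken and resumed streak re-arms
  two <- make_session(7, dyspnea = c("YES", "YES", "NO", "YES", "YES", NA, NA))
  expect_equal(evaluate_alarms(two)$day_index, c(2L, 5L))
})

test_that("medication and fatigue streaks use their own predicates", {
  s <- make_session(7, medication = c("NO", "NO", rep("YES", 5)),
                    fatigue = c(NA, NA, "YES", "YES", NA, NA, NA))
  al <- evaluate_alarms(s)
  expect_setequal(al$rule, c("MEDICATION_STREAK", "FATIGUE_STREAK"))
  expect_equal(al$day_index[al$rule == "MEDICATION_STREAK"], 2L)
  expect_equal(al$day_index[al$rule == "FATIGUE_STREAK"], 4L)
  # affirmative medication answers are the healthy case
  ok <- make_session(7, medication = rep("YES", 7))
  expect_equal(nrow(evaluate_alarms(ok)), 0)
})

test_that("missing or invalid answers break symptom streaks", {
  gap <- make_session(7, dyspnea = c("YES", NA, "YES", NA, "YES", NA, "YES"))
  expect_equal(nrow(evaluate_alarms(gap)), 0)
  inv <- make_session(7, dyspnea = c("YES", "INVALID", "YES", "INVALID", "YES", NA, NA))
  expect_equal(nrow(evaluate_alarms(inv)), 0)
})

test_that("weight gain is judged against the window minimum", {
  up <- make_session(3, weight = c(70, 71, 72.5))
  al <- evaluate_alarms(up)
  expect_equal(al$rule, "WEIGHT_GAIN")
  expect_equal(al$day_index, 3L)

  # dip then surge: 71.5 - 69 = 2.5 >= 2 even though 71.5 - 70 < 2
  dip <- make_session(3, weight = c(70, 69, 71.5))
  expect_equal(evaluate_alarms(dip)$rule, "WEIGHT_GAIN")
  # under the endpoint-only flag the same trajectory stays silent
  expect_equal(nrow(evaluate_alarms(dip, alarm_config(weight_endpoint_only = TRUE))),
               0)

  # incomplete windows never fire
  holey <- make_session(5, weight = c(70, NA, 74, 75, NA))
  expect_equal(nrow(evaluate_alarms(holey)), 0)
  # an invalid weight invalidates its window
  inv <- make_session(3, weight = c(70, "INVALID", 74))
  expect_equal(nrow(evaluate_alarms(inv)), 0)
})

test_that("weight alarms debounce and re-arm like streaks", {
  # steady 1.5 kg/day climb: every window qualifies, only the first fires
  climb <- make_session(6, weight = 70 + 1.5 * (1:6))
  al <- evaluate_alarms(climb)
  expect_equal(al$rule, "WEIGHT_GAIN")
  expect_equal(al$day_index, 3L)

  # plateau breaks the condition, a second climb re-fires
  two <- make_session(9, weight = c(70, 71, 72.5, 72.5, 72.5, 72.5, 73, 74, 75))
  expect_equal(evaluate_alarms(two)$day_index, c(3L, 9L))
})

test_that("the optional loss rule stays off until configured", {
  drop <- make_session(3, weight = c(75, 74, 72))
  expect_equal(nrow(evaluate_alarms(drop)), 0)
  cfg <- alarm_config(weight_loss_kg = 2)
  al <- evaluate_alarms(drop, cfg)
  expect_equal(al$rule, "WEIGHT_LOSS")
  expect_equal(al$day_index, 3L)
})

test_that("non-response requires two fully silent consecutive days", {
  silent <- new_session(patient_profile("P01", "2017-09-04", 7))
  al <- evaluate_alarms(silent)
  expect_equal(al$rule, "NON_RESPONSE")
  expect_equal(al$day_index, 2L)  # once, despite seven silent days

  # a single answer of any kind (even invalid) makes a day responsive
  partial <- make_session(7, dyspnea = c(NA, "INVALID", NA, "NO", NA, "NO", NA),
                          weight = rep(NA, 7), medication = rep(NA, 7),
                          fatigue = rep(NA, 7))
  al <- evaluate_alarms(partial)
  expect_equal(nrow(al), 0)
})

test_that("adding answers never increases non-response alarms", {
  set.seed(11)
  for (rep in 1:25) {
    days <- sample(2:14, 1)
    s <- random_session(days, p_absent = 0.7)
    base <- sum(evaluate_alarms(s)$rule == "NON_RESPONSE")
    d <- sample(days, 1)
    q <- sample(c("DYSPNEA", "MEDICATION", "FATIGUE"), 1)
    if (is.null(hfsms:::session_answer(s, d, q))) {
      s2 <- set_answer(s, d, q, parsed_answer("NO"))
      expect_lte(sum(evaluate_alarms(s2)$rule == "NON_RESPONSE"), base)
    }
  }
})

test_that("streak engine agrees with brute-force run enumeration", {
  set.seed(101)
  cfgs <- list(alarm_config(), alarm_config(symptom_streak_days = 1),
               alarm_config(symptom_streak_days = 3, nonresponse_streak_days = 3))
  for (rep in 1:60) {
    days <- sample(1:14, 1)
    s <- random_session(days, p_absent = runif(1, 0.1, 0.6),
                        p_invalid = 0.15, p_yes = runif(1, 0.2, 0.8))
    cfg <- cfgs[[sample(length(cfgs), 1)]]
    al <- evaluate_alarms(s, cfg)
    for (spec in list(c("DYSPNEA", "YES", "DYSPNEA_STREAK"),
                      c("MEDICATION", "NO", "MEDICATION_STREAK"),
                      c("FATIGUE", "YES", "FATIGUE_STREAK"))) {
      kinds <- session_kind_vector(s, spec[1])
      want <- oracle_streak_days(!is.na(kinds) & kinds == spec[2],
                                 cfg$symptom_streak_days)
      expect_equal(sort(al$day_index[al$rule == spec[3]]), want,
                   info = paste(spec[3], "days", days))
    }
    silent <- vapply(seq_len(days),
                     function(d) hfsms:::day_response_count(s, d) == 0L, TRUE)
    want <- oracle_streak_days(silent, cfg$nonresponse_streak_days)
    expect_equal(sort(al$day_index[al$rule == "NON_RESPONSE"]), want)

    weights <- session_weight_vector(s)
    want <- oracle_weight_days(weights, cfg$weight_window_days, cfg$weight_gain_kg)
    expect_equal(sort(al$day_index[al$rule == "WEIGHT_GAIN"]), want)
  }
})

test_that("threshold limits behave as expected", {
  s <- make_session(7, dyspnea = c("NO", "YES", "NO", "YES", "YES", "NO", "YES"))
  # threshold 1: every YES day following a non-YES day fires
  al <- evaluate_alarms(s, alarm_config(symptom_streak_days = 1))
  expect_equal(al$day_index[al$rule == "DYSPNEA_STREAK"], c(2L, 4L, 7L))
  # threshold longer than the window: nothing can fire
  al <- evaluate_alarms(s, alarm_config(symptom_streak_days = 8))
  expect_equal(nrow(al[al$rule == "DYSPNEA_STREAK", ]), 0)
})

test_that("evaluation is deterministic and refuses malformed sessions", {
  s <- random_session(10)
  expect_identical(evaluate_alarms(s), evaluate_alarms(s))
  broken <- s
  broken$records <- broken$records[-3]
  expect_error(evaluate_alarms(broken), "invalid session")
})

test_that("every alarm notifies both the patient and the manager", {
  quiet <- new_session(patient_profile("P01", "2017-09-04", 3))
  expect_equal(dispatch_alarms(evaluate_alarms(quiet))$rule, "NON_RESPONSE")
  s <- make_session(7, dyspnea = c("YES", "YES", rep("NO", 5)))
  notes <- dispatch_alarms(evaluate_alarms(s))
  expect_equal(nrow(notes), 1)
  expect_equal(notes$recipients, "PATIENT,MANAGER")
  empty <- dispatch_alarms(evaluate_alarms(make_session(3, dyspnea = rep("NO", 3),
                                                       weight = rep(70, 3),
                                                       medication = rep("YES", 3),
                                                       fatigue = rep("NO", 3))))
  expect_equal(nrow(empty), 0)
})
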