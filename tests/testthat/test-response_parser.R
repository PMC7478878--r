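test_that("binary parsing is case-insensitive, trimmed and accent-folded", {
  expect_equal(parse_binary("YES")$kind, "YES")
  expect_equal(parse_binary("  nÃo ")$kind, "NO")
  expect_equal(parse_binary("Sim")$kind, "YES")
  expect_equal(parse_binary("- no.")$kind, "NO")
  expect_equal(parse_binary("maybe")$kind, "INVALID")
  expect_equal(parse_binary("")$kind, "INVALID")
  # raw text survives verbatim for audit
  expect_equal(parse_binary("  nÃo ")$raw_text, "  nÃo ")
})

test_that("every configured affirmative and negative token parses as such", {
  for (tok in hfsms:::default_yes_tokens()) {
    expect_equal(parse_binary(tok)$kind, "YES", label = tok)
    expect_equal(parse_binary(toupper(tok))$kind, "YES", label = toupper(tok))
  }
  for (tok in hfsms:::default_no_tokens()) {
    expect_equal(parse_binary(tok)$kind, "NO", label = tok)
  }
  # custom token sets replace the defaults
  expect_equal(parse_binary("ja", yes_tokens = "ja")$kind, "YES")
  expect_equal(parse_binary("yes", yes_tokens = "ja")$kind, "INVALID")
})

test_that("weight parsing accepts both decimal separators and a kg suffix", {
  expect_equal(parse_weight("72.5")$numeric_value, 72.5)
  expect_equal(parse_weight("72,5 kg")$numeric_value, 72.5)
  expect_equal(parse_weight(" 80 Kg ")$numeric_value, 80)
  expect_equal(parse_weight("68")$kind, "NUMERIC")
  expect_equal(parse_weight("heavy")$kind, "INVALID")
  expect_equal(parse_weight("70 or 71")$kind, "INVALID")
  expect_equal(parse_weight("0")$kind, "INVALID")
  expect_equal(parse_weight("512")$kind, "INVALID")
  expect_equal(parse_weight("-5")$numeric_value, 5)  # leading dash is SMS noise
})

test_that("replies attach to the oldest open question of matching shape", {
  s <- new_session(patient_profile("P01", "2017-09-04", 7))
  day3 <- as.Date("2017-09-04") + 2

  s <- attach_reply(s, day3, "NO")
  a <- hfsms:::session_answer(s, 3, "DYSPNEA")  # morning slot first
  expect_equal(a$kind, "NO")

  s <- attach_reply(s, day3, "72.5")
  expect_equal(hfsms:::session_answer(s, 3, "WEIGHT")$numeric_value, 72.5)

  # next binary reply falls through to the evening slot
  s <- attach_reply(s, day3, "yes")
  expect_equal(hfsms:::session_answer(s, 3, "MEDICATION")$kind, "YES")

  # numeric reply with weight already answered is discarded
  expect_warning(s2 <- attach_reply(s, day3, "74,0"), "already answered")
  expect_equal(hfsms:::session_answer(s2, 3, "WEIGHT")$numeric_value, 72.5)

  # out-of-window reply leaves the session unchanged
  before <- attach_reply(s, as.Date("2017-08-01"), "yes")
  expect_identical(before$records, s$records)
})

test_that("an explicit question id targets directly and parses by answer kind", {
  s <- new_session(patient_profile("P01", "2017-09-04", 7))
  day1 <- as.Date("2017-09-04")
  s <- attach_reply(s, day1, "yes", question_id = "FATIGUE")
  expect_equal(hfsms:::session_answer(s, 1, "FATIGUE")$kind, "YES")
  expect_null(hfsms:::session_answer(s, 1, "DYSPNEA"))
  s <- attach_reply(s, day1, "80,5", question_id = "WEIGHT")
  expect_equal(hfsms:::session_answer(s, 1, "WEIGHT")$numeric_value, 80.5)
  expect_error(attach_reply(s, day1, "yes", question_id = "PULSE"),
               "unknown question id")
})

test_that("unrecognized replies still count as a response", {
  s <- new_session(patient_profile("P01", "2017-09-04", 7))
  s <- attach_reply(s, as.Date("2017-09-04"), "what?")
  expect_equal(hfsms:::session_answer(s, 1, "DYSPNEA")$kind, "INVALID")
  expect_equal(hfsms:::day_response_count(s, 1), 1)
})

test_that("attachment never creates a second answer for the same cell", {
  set.seed(7)
  for (rep in 1:10) {
    s <- new_session(patient_profile("P01", "2017-09-04", 5))
    texts <- sample(c("yes", "no", "71", "72,5", "??"), 12, replace = TRUE)
    dates <- as.Date("2017-09-04") + sample(0:4, 12, replace = TRUE)
    for (i in seq_along(texts)) {
      suppressWarnings(
        s <- attach_reply(s, dates[i], texts[i], time = sprintf("10:%02d", i))
      )
    }
    expect_length(validate_session(s), 0)
    for (r in s$records) expect_false(anyDuplicated(names(r$answers)) > 0)
  }
})

test_that("replaying an identical inbound log is idempotent", {
  sessions <- list(new_session(patient_profile("P01", "2017-09-04", 7)))
  log <- data.frame(
    patient_id = "P01",
    date = as.character(as.Date("2017-09-04") + c(0, 0, 1)),
    time = c("08:00", "08:05", "08:00"),
    raw_text = c("no", "70.5", "yes"),
    question_id = NA_character_,
    stringsAsFactors = FALSE
  )
  once <- attach_log(sessions, log)
  twice <- attach_log(once, log)
  expect_identical(twice[[1]]$records, once[[1]]$records)
  expect_equal(hfsms:::session_answer(once[[1]], 1, "DYSPNEA")$kind, "NO")
  expect_equal(hfsms:::session_answer(once[[1]], 2, "DYSPNEA")$kind, "YES")

  expect_error(attach_log(once, transform(log, patient_id = "P99")),
               "unknown patient")
})

test_that("inbound logs round-trip through CSV and JSON lines", {
  log <- data.frame(
    patient_id = c("P01", "P02"),
    date = c("2017-09-04", "2017-09-05"),
    time = c("08:00", "20:00"),
    raw_text = c("no", "72,5 kg"),
    question_id = c(NA, "WEIGHT"),
    stringsAsFactors = FALSE
  )
  csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(log, csv, row.names = FALSE, na = "")
  got <- read_inbound_log(csv)
  expect_equal(got$raw_text, log$raw_text)
  expect_equal(got$patient_id, log$patient_id)

  jsonl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(log)), function(i) {
    row <- as.list(log[i, ])
    if (is.na(row$question_id)) row$question_id <- NULL
    as.character(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null"))
  }, ""), jsonl)
  got2 <- read_inbound_log(jsonl)
  expect_equal(got2$raw_text, log$raw_text)
  expect_equal(got2$question_id, log$question_id)
})
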