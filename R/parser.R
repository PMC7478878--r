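#' Token sets for binary replies
#'
#' Matching is case-insensitive after whitespace trimming and removal of a
#' leading dash or trailing punctuation; accents are folded so that
#' "não" and "nao" both read as negative. Defaults cover English and
#' Portuguese, the languages of the deployed protocol.
#'
#' @name binary_tokens
NULL

default_yes_tokens <- function() c("yes", "y", "sim", "s", "1")
default_no_tokens <- function() c("no", "n", "nao", "0")

normalize_token <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("^[-*•]+\\s*", "", x)
  x <- gsub("[[:space:]]*[.!]+$", "", x)
  # fold accented vowels and c-cedilla so Portuguese spellings match
  x <- chartr("áàâãéêíóôõúüç",
              "aaaaeeiooouuc", x)
  trimws(x)
}

#' Parse a binary (yes/no) reply
#'
#' @param raw_text Inbound SMS text.
#' @param yes_tokens,no_tokens Affirmative and negative token sets; matching
#'   is case-insensitive, whitespace-trimmed and accent-folded. Anything
#'   outside both sets parses as \code{INVALID} (a value, not an error).
#' @return A \code{\link{parsed_answer}} of kind \code{YES}, \code{NO} or
#'   \code{INVALID}.
#' @export
#' @examples
#' parse_binary("YES")$kind
#' parse_binary("  nÃo ")$kind
#' parse_binary("maybe")$kind
parse_binary <- function(raw_text,
                         yes_tokens = default_yes_tokens(),
                         no_tokens = default_no_tokens()) {
  tok <- normalize_token(raw_text)
  if (tok %in% normalize_token(yes_tokens)) {
    parsed_answer("YES", raw_text = raw_text)
  } else if (tok %in% normalize_token(no_tokens)) {
    parsed_answer("NO", raw_text = raw_text)
  } else {
    parsed_answer("INVALID", raw_text = raw_text)
  }
}

#' Parse a weight reply
#'
#' Extracts a single decimal number from the text; both dot and comma decimal
#' separators are accepted, and an optional trailing "kg"/"kgs"/"quilos"
#' token is ignored. Values must lie strictly between 0 and 500 kg; anything
#' else (no number, two numbers, out of range) parses as \code{INVALID}.
#'
#' @param raw_text Inbound SMS text.
#' @return A \code{\link{parsed_answer}} of kind \code{NUMERIC} or
#'   \code{INVALID}.
#' @export
#' @examples
#' parse_weight("72.5")$numeric_value
#' parse_weight("72,5 kg")$numeric_value
#' parse_weight("heavy")$kind
parse_weight <- function(raw_text) {
  txt <- normalize_token(raw_text)
  txt <- sub("\\s*(kg|kgs|kilo|kilos|quilo|quilos)\\s*$", "", txt)
  m <- gregexpr("[0-9]+([.,][0-9]+)?", txt)[[1]]
  hits <- if (m[1] == -1L) character() else regmatches(txt, list(m))[[1]]
  rest <- gsub("[0-9]+([.,][0-9]+)?", "", txt)
  if (length(hits) != 1L || grepl("[[:alnum:]]", rest)) {
    return(parsed_answer("INVALID", raw_text = raw_text))
  }
  value <- suppressWarnings(as.numeric(sub(",", ".", hits, fixed = TRUE)))
  if (is.na(value) || value <= 0 || value >= 500) {
    return(parsed_answer("INVALID", raw_text = raw_text))
  }
  parsed_answer("NUMERIC", numeric_value = value, raw_text = raw_text)
}

#' Attach one inbound reply to a session
#'
#' SMS replies carry no reference to the question asked, so attachment is by
#' arrival order within the calendar day of receipt (local midnight
#' boundary): a numeric-looking reply goes to the day's weight question, a
#' binary reply to the oldest unanswered binary question in slot order
#' (morning before evening), and an unrecognized reply to the oldest
#' unanswered question of any kind, recorded as \code{INVALID}. When
#' \code{question_id} is supplied (the extended log format) the reply is
#' targeted directly and parsed according to that question's answer kind.
#'
#' A reply that finds no open question that day, falls outside the window, or
#' duplicates an already-consumed reply (same patient, date, time and text)
#' is discarded and the session returned unchanged; conflicting duplicates
#' are discarded first-wins with a warning.
#'
#' @param session An \code{hf_session}.
#' @param received_at Date (or date-coercible) of receipt.
#' @param raw_text Verbatim reply text.
#' @param time Optional time-of-day string, used only for duplicate detection
#'   and log ordering.
#' @param question_id Optional explicit target question id.
#' @return The (possibly unchanged) session.
#' @export
attach_reply <- function(session, received_at, raw_text, time = "",
                         question_id = NA_character_) {
  stopifnot(inherits(session, "hf_session"))
  day <- date_to_day(session$profile, received_at)
  key <- paste(session$profile$patient_id, as.character(received_at),
               time, raw_text, question_id, sep = "\r")
  if (key %in% session$inbound_seen) return(session)  # identical duplicate
  session$inbound_seen <- c(session$inbound_seen, key)
  if (is.na(day)) return(session)  # outside the window

  catalog <- session$catalog
  open <- function(q) is.null(session_answer(session, day, q))

  if (!is.na(question_id) && nzchar(question_id)) {
    if (!question_id %in% catalog$id) {
      stop("unknown question id in inbound log: ", question_id)
    }
    kind <- catalog$answer_kind[catalog$id == question_id]
    ans <- if (kind == "NUMERIC_KG") parse_weight(raw_text) else parse_binary(raw_text)
    if (!open(question_id)) {
      warning(sprintf("patient %s day %d: duplicate reply for %s discarded (first wins)",
                      session$profile$patient_id, day, question_id))
      return(session)
    }
    return(set_answer(session, day, question_id, ans))
  }

  slot_ids <- catalog_slot_order(catalog)
  as_weight <- parse_weight(raw_text)
  if (as_weight$kind == "NUMERIC") {
    wq <- catalog$id[catalog$answer_kind == "NUMERIC_KG"]
    if (open(wq)) return(set_answer(session, day, wq, as_weight))
    warning(sprintf("patient %s day %d: numeric reply discarded, weight already answered",
                    session$profile$patient_id, day))
    return(session)
  }
  as_binary <- parse_binary(raw_text)
  candidates <- if (as_binary$kind %in% c("YES", "NO")) {
    slot_ids[slot_ids %in% catalog$id[catalog$answer_kind == "BINARY"]]
  } else {
    slot_ids  # INVALID still marks a response; oldest open question of any kind
  }
  for (q in candidates) {
    if (open(q)) {
      ans <- if (catalog$answer_kind[catalog$id == q] == "NUMERIC_KG" &&
                 as_binary$kind == "INVALID") {
        parsed_answer("INVALID", raw_text = raw_text)
      } else {
        as_binary
      }
      return(set_answer(session, day, q, ans))
    }
  }
  warning(sprintf("patient %s day %d: reply '%s' discarded, no open question accepts it",
                  session$profile$patient_id, day, raw_text))
  session
}

#' Read an inbound SMS log
#'
#' Accepts CSV with columns \code{patient_id, date, time, raw_text} and an
#' optional \code{question_id} column, or the same records as JSON lines
#' (one object per line). Raw text is preserved verbatim.
#'
#' @param path Log file; format picked by extension (\code{.csv} vs
#'   \code{.jsonl}/\code{.json}) or forced with \code{format}.
#' @param format \code{"csv"}, \code{"jsonl"} or \code{"auto"}.
#' @return A data.frame with columns \code{patient_id, date, time, raw_text,
#'   question_id}, ordered as received.
#' @export
read_inbound_log <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    log <- utils::read.csv(path, colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
    log <- do.call(rbind, lapply(rows, function(r) {
      data.frame(patient_id = as.character(r$patient_id),
                 date = as.character(r$date),
                 time = if (is.null(r$time)) "" else as.character(r$time),
                 raw_text = as.character(r$raw_text),
                 question_id = if (is.null(r$question_id)) NA_character_ else as.character(r$question_id),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(log)) {
      log <- data.frame(patient_id = character(), date = character(),
                        time = character(), raw_text = character(),
                        question_id = character(), stringsAsFactors = FALSE)
    }
  }
  need <- c("patient_id", "date", "raw_text")
  if (!all(need %in% names(log))) {
    stop("inbound log must provide columns ", paste(need, collapse = ", "))
  }
  if (is.null(log$time)) log$time <- rep("", nrow(log))
  if (is.null(log$question_id)) log$question_id <- rep(NA_character_, nrow(log))
  log[, c("patient_id", "date", "time", "raw_text", "question_id")]
}

#' Replay an inbound log onto a cohort of sessions
#'
#' Rows are applied in file order within each calendar day, so the
#' arrival-order attachment contract of \code{\link{attach_reply}} holds.
#' Replaying the same log twice leaves the sessions unchanged.
#'
#' @param sessions Named or unnamed list of \code{hf_session}s.
#' @param log Data.frame as returned by \code{\link{read_inbound_log}}.
#' @param strict Error on a patient id absent from the cohort (default);
#'   otherwise such rows are skipped with a warning.
#' @return The list of sessions, updated.
#' @export
attach_log <- function(sessions, log, strict = TRUE) {
  ids <- vapply(sessions, function(s) s$profile$patient_id, "")
  names(sessions) <- ids
  for (i in seq_len(nrow(log))) {
    pid <- log$patient_id[i]
    if (!pid %in% ids) {
      if (strict) stop("inbound log row ", i, ": unknown patient ", pid)
      warning("skipping reply for unknown patient ", pid)
      next
    }
    sessions[[pid]] <- attach_reply(
      sessions[[pid]],
      received_at = as.Date(log$date[i]),
      raw_text = log$raw_text[i],
      time = log$time[i],
      question_id = log$question_id[i]
    )
  }
  sessions
}

#' Serialize sessions to the inbound-log CSV format
#'
#' Writes one row per recorded answer in the extended five-column format
#' (\code{patient_id, date, time, raw_text, question_id}); replaying the file
#' onto empty sessions with \code{\link{attach_log}} reconstructs the same
#' answer grid (round-trip).
#'
#' @param sessions List of \code{hf_session}s.
#' @param path Output CSV path, or \code{NULL} to return the data.frame only.
#' @param schedule_cfg Schedule configuration supplying the morning/evening
#'   clock times stamped on the rows.
#' @return The log data.frame, invisibly when written to a file.
#' @export
write_inbound_log <- function(sessions, path = NULL,
                              schedule_cfg = schedule_config()) {
  rows <- list()
  for (s in sessions) {
    slot_ids <- catalog_slot_order(s$catalog)
    for (r in s$records) {
      for (q in slot_ids[slot_ids %in% names(r$answers)]) {
        a <- r$answers[[q]]
        slot <- s$catalog$slot[s$catalog$id == q]
        base <- if (slot == "MORNING") schedule_cfg$morning_time else schedule_cfg$evening_time
        # stagger within the slot so times stay unique per question
        offset <- match(q, slot_ids) - 1L
        time <- sprintf("%s:%02d", base, offset)
        raw <- if (nzchar(a$raw_text)) a$raw_text else switch(
          a$kind,
          YES = "yes", NO = "no",
          NUMERIC = formatC(a$numeric_value, format = "fg"),
          INVALID = "?"
        )
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = s$profile$patient_id,
          date = as.character(day_date(s$profile, r$day_index)),
          time = time, raw_text = raw, question_id = q,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  log <- if (length(rows)) do.call(rbind, rows) else data.frame(
    patient_id = character(), date = character(), time = character(),
    raw_text = character(), question_id = character(), stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.csv(log, path, row.names = FALSE)
    return(invisible(log))
  }
  log
}
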