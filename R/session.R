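#' Patient enrollment record
#'
#' @param patient_id Opaque unique identifier.
#' @param follow_up_start First follow-up date (coerced with
#'   \code{\link{as.Date}}); messaging starts within the first week after
#'   hospital discharge.
#' @param follow_up_days Length of the monitoring window in days (>= 1).
#' @param metadata Free-form named list of inert descriptors (age, sex,
#'   ejection fraction, ...); never consulted by the engine.
#' @return An object of class \code{hf_profile}.
#' @export
patient_profile <- function(patient_id, follow_up_start,
                            follow_up_days = 7L, metadata = list()) {
  patient_id <- as.character(patient_id)
  follow_up_start <- as.Date(follow_up_start)
  follow_up_days <- as.integer(follow_up_days)
  if (!nzchar(patient_id)) stop("patient_id must be non-empty")
  if (is.na(follow_up_start)) stop("follow_up_start must be a valid date")
  if (is.na(follow_up_days) || follow_up_days < 1L) {
    stop("follow_up_days must be >= 1")
  }
  structure(
    list(patient_id = patient_id, follow_up_start = follow_up_start,
         follow_up_days = follow_up_days, metadata = metadata),
    class = "hf_profile"
  )
}

#' Parsed inbound answer
#'
#' A value, not an error: unrecognized text becomes \code{kind = "INVALID"}.
#' Invalid answers count as "responded" for the non-response alarm rule but
#' never satisfy a symptom predicate and break weight windows.
#'
#' @param kind One of \code{"YES"}, \code{"NO"}, \code{"NUMERIC"},
#'   \code{"INVALID"}.
#' @param numeric_value Weight in kg; present iff \code{kind == "NUMERIC"},
#'   and then must lie strictly between 0 and 500.
#' @param raw_text Verbatim inbound text, preserved for audit.
#' @return An object of class \code{hf_answer}.
#' @export
parsed_answer <- function(kind, numeric_value = NA_real_, raw_text = "") {
  kind <- match.arg(kind, c("YES", "NO", "NUMERIC", "INVALID"))
  numeric_value <- as.numeric(numeric_value)
  if (kind == "NUMERIC") {
    if (is.na(numeric_value) || numeric_value <= 0 || numeric_value >= 500) {
      stop("NUMERIC answers require a weight strictly between 0 and 500 kg")
    }
  } else if (!is.na(numeric_value)) {
    stop("numeric_value is only allowed when kind is NUMERIC")
  }
  structure(list(kind = kind, numeric_value = numeric_value,
                 raw_text = as.character(raw_text)),
            class = "hf_answer")
}

#' Create an empty monitoring session
#'
#' A session is one patient's follow-up window: the profile, one daily record
#' per day (holding at most one parsed answer per question), and the alarms
#' raised so far. Records are created empty; answers arrive through
#' \code{\link{set_answer}} or \code{\link{attach_reply}}.
#'
#' @param profile A \code{\link{patient_profile}}.
#' @param catalog Question catalog the session is monitored against.
#' @return An object of class \code{hf_session}.
#' @export
new_session <- function(profile, catalog = default_question_catalog()) {
  stopifnot(inherits(profile, "hf_profile"))
  bad <- validate_catalog(catalog)
  if (length(bad)) stop("invalid catalog: ", paste(bad, collapse = "; "))
  records <- lapply(seq_len(profile$follow_up_days), function(d) {
    list(day_index = d, answers = list(), missing_reason = character())
  })
  structure(
    list(profile = profile, catalog = catalog, records = records,
         alarms = NULL, inbound_seen = character()),
    class = "hf_session"
  )
}

#' Set one answer in a session's day grid
#'
#' @param session An \code{hf_session}.
#' @param day_index 1-based day within the window.
#' @param question_id Question id from the session's catalog.
#' @param answer An \code{\link{parsed_answer}}, or \code{NULL} to clear.
#' @param overwrite Replace an existing answer? Default \code{FALSE} (the
#'   engine is first-wins).
#' @return The modified session.
#' @export
set_answer <- function(session, day_index, question_id, answer,
                       overwrite = FALSE) {
  stopifnot(inherits(session, "hf_session"))
  day_index <- as.integer(day_index)
  if (is.na(day_index) || day_index < 1L ||
      day_index > session$profile$follow_up_days) {
    stop("day_index outside the follow-up window")
  }
  if (!question_id %in% session$catalog$id) {
    stop("unknown question id: ", question_id)
  }
  if (!is.null(answer)) stopifnot(inherits(answer, "hf_answer"))
  have <- session$records[[day_index]]$answers[[question_id]]
  if (!is.null(have) && !is.null(answer) && !overwrite) {
    stop("day ", day_index, " already holds an answer for ", question_id)
  }
  session$records[[day_index]]$answers[[question_id]] <- answer
  session
}

# Fetch the answer for (day, question), or NULL when absent.
session_answer <- function(session, day_index, question_id) {
  session$records[[day_index]]$answers[[question_id]]
}

# Number of answers recorded on a day (any kind, including INVALID).
day_response_count <- function(session, day_index) {
  length(session$records[[day_index]]$answers)
}

#' Check the structural invariants of a session
#'
#' Violations are returned as descriptions naming the field and day, never
#' raised, so a caller can report all of them at once.
#'
#' @param session An \code{hf_session}.
#' @return Character vector of violations; empty when the session is
#'   well-formed.
#' @export
validate_session <- function(session) {
  v <- character()
  if (!inherits(session, "hf_session")) return("not an hf_session object")
  n <- session$profile$follow_up_days
  if (length(session$records) != n) {
    v <- c(v, sprintf("session holds %d daily records for a %d-day window",
                      length(session$records), n))
  }
  days <- vapply(session$records, function(r) as.integer(r$day_index), 1L)
  dup <- unique(days[duplicated(days)])
  for (d in dup) v <- c(v, sprintf("duplicate day_index %d", d))
  if (!length(dup) && length(days) == n && !identical(days, seq_len(n))) {
    v <- c(v, "daily records are not the gap-free sequence 1..follow_up_days")
  }
  out <- days[days < 1L | days > n]
  for (d in out) v <- c(v, sprintf("day_index %d outside the window", d))
  for (r in session$records) {
    ids <- names(r$answers)
    unknown <- setdiff(ids, session$catalog$id)
    for (q in unknown) {
      v <- c(v, sprintf("day %d: answer for unknown question %s", r$day_index, q))
    }
    for (q in intersect(ids, session$catalog$id)) {
      a <- r$answers[[q]]
      if (!inherits(a, "hf_answer")) {
        v <- c(v, sprintf("day %d: %s answer is not an hf_answer", r$day_index, q))
        next
      }
      kind_exp <- session$catalog$answer_kind[session$catalog$id == q]
      if (kind_exp == "NUMERIC_KG" && a$kind %in% c("YES", "NO")) {
        v <- c(v, sprintf("day %d: binary answer recorded for numeric question %s",
                          r$day_index, q))
      }
      if (kind_exp == "BINARY" && a$kind == "NUMERIC") {
        v <- c(v, sprintf("day %d: numeric answer recorded for binary question %s",
                          r$day_index, q))
      }
      if (a$kind == "NUMERIC" &&
          (is.na(a$numeric_value) || a$numeric_value <= 0 || a$numeric_value >= 500)) {
        v <- c(v, sprintf("day %d: %s weight outside (0, 500) kg", r$day_index, q))
      }
    }
  }
  v
}

#' @export
print.hf_session <- function(x, ...) {
  n_ans <- sum(vapply(x$records, function(r) length(r$answers), 1L))
  cat(sprintf("<hf_session> patient %s: %d-day window from %s, %d answers recorded\n",
              x$profile$patient_id, x$profile$follow_up_days,
              format(x$profile$follow_up_start), n_ans))
  invisible(x)
}

#' @export
print.hf_profile <- function(x, ...) {
  cat(sprintf("<hf_profile> %s: %d days from %s\n", x$patient_id,
              x$follow_up_days, format(x$follow_up_start)))
  invisible(x)
}

# Calendar date of a session day.
day_date <- function(profile, day_index) {
  profile$follow_up_start + (as.integer(day_index) - 1L)
}

# Day index of a calendar date, or NA when outside the window.
date_to_day <- function(profile, date) {
  d <- as.integer(as.Date(date) - profile$follow_up_start) + 1L
  if (is.na(d) || d < 1L || d > profile$follow_up_days) NA_integer_ else d
}
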