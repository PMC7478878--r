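#' Build the outbound message plan for one patient window
#'
#' Every follow-up day carries the four feedback questions (two per slot, in
#' catalog slot order), and educational messages go out on days
#' \code{educational_first_day}, then every \code{educational_period_days},
#' cycling through the educational catalog in fixed order. The plan is a pure
#' function of its inputs.
#'
#' @param profile A \code{\link{patient_profile}}.
#' @param catalog Question catalog (must validate).
#' @param edu Educational message catalog.
#' @param cfg A \code{\link{schedule_config}}.
#' @return A data.frame with columns \code{patient_id, day_index, slot, kind,
#'   payload, status}, sorted by day then slot (morning, evening,
#'   educational); all rows start with \code{status = "PLANNED"}.
#' @export
#' @examples
#' p <- patient_profile("P01", "2017-09-04", 7)
#' sched <- build_schedule(p)
#' table(sched$kind)
build_schedule <- function(profile,
                           catalog = default_question_catalog(),
                           edu = default_educational_catalog(),
                           cfg = schedule_config()) {
  stopifnot(inherits(profile, "hf_profile"))
  bad <- validate_catalog(catalog)
  if (length(bad)) stop("invalid question catalog: ", paste(bad, collapse = "; "))
  bad <- validate_educational_catalog(edu)
  if (length(bad)) stop("invalid educational catalog: ", paste(bad, collapse = "; "))

  n <- profile$follow_up_days
  slot_ids <- catalog_slot_order(catalog)
  feedback <- data.frame(
    patient_id = profile$patient_id,
    day_index = rep(seq_len(n), each = length(slot_ids)),
    slot = rep(catalog$slot[match(slot_ids, catalog$id)], times = n),
    kind = "FEEDBACK",
    payload = rep(slot_ids, times = n),
    stringsAsFactors = FALSE
  )
  edu_days <- if (cfg$educational_first_day > n) integer() else {
    seq(from = cfg$educational_first_day, to = n,
        by = cfg$educational_period_days)
  }
  educational <- if (length(edu_days)) {
    data.frame(
      patient_id = profile$patient_id,
      day_index = as.integer(edu_days),
      slot = "EDUCATIONAL",
      kind = "EDUCATIONAL",
      payload = edu$id[((seq_along(edu_days) - 1L) %% nrow(edu)) + 1L],
      stringsAsFactors = FALSE
    )
  } else {
    feedback[0, 1:5]
  }
  plan <- rbind(feedback, educational)
  slot_rank <- match(plan$slot, c("MORNING", "EVENING", "EDUCATIONAL"))
  plan <- plan[order(plan$day_index, slot_rank), ]
  plan$status <- ifelse(plan$kind == "EDUCATIONAL", "SENT", "PLANNED")
  rownames(plan) <- NULL
  plan
}

#' Total feedback messages scheduled for a cohort
#'
#' Four feedback questions per patient-day, summed over each patient's
#' window.
#'
#' @param profiles List of \code{\link{patient_profile}}s.
#' @param catalog Question catalog (defines the per-day message count).
#' @return Non-negative integer count.
#' @export
cohort_feedback_count <- function(profiles, catalog = default_question_catalog()) {
  if (!length(profiles)) return(0L)
  per_day <- nrow(catalog)
  sum(vapply(profiles, function(p) per_day * p$follow_up_days, 1L))
}

#' Mark schedule rows answered or unanswered from a session
#'
#' A feedback message counts as \code{ANSWERED} when the session's daily
#' record holds any parsed answer for that question — including an
#' \code{INVALID} one: the patient responded, and validity matters only to
#' the alarm rules. Educational rows stay \code{SENT}.
#'
#' @param schedule Plan from \code{\link{build_schedule}}.
#' @param session The same patient's \code{hf_session}.
#' @return The schedule with updated \code{status}.
#' @export
apply_responses <- function(schedule, session) {
  stopifnot(inherits(session, "hf_session"))
  if (!all(schedule$patient_id == session$profile$patient_id)) {
    stop("schedule and session refer to different patients")
  }
  fb <- which(schedule$kind == "FEEDBACK")
  answered <- vapply(fb, function(i) {
    d <- schedule$day_index[i]
    d >= 1L && d <= session$profile$follow_up_days &&
      !is.null(session_answer(session, d, schedule$payload[i]))
  }, TRUE)
  schedule$status[fb] <- ifelse(answered, "ANSWERED", "UNANSWERED")
  schedule
}

#' Write an outbound plan as CSV
#'
#' Fixed column order: \code{patient_id, day_index, slot, kind, payload,
#' status}.
#'
#' @param schedule Plan data.frame (one or several patients' rows bound
#'   together).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  cols <- c("patient_id", "day_index", "slot", "kind", "payload", "status")
  utils::write.csv(schedule[, cols], path, row.names = FALSE)
  invisible(path)
}
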