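#' Feedback question catalog
#'
#' The monitoring protocol asks four patient-reported questions per day, two
#' in the morning and two in the evening. Three are binary (yes/no) symptom or
#' adherence probes; one asks for the morning body weight in kilograms, the
#' key congestion marker in heart failure.
#'
#' A catalog is a data.frame with columns \code{id}, \code{text},
#' \code{answer_kind} (\code{"BINARY"} or \code{"NUMERIC_KG"}) and \code{slot}
#' (\code{"MORNING"} or \code{"EVENING"}). The weight question is the only
#' numeric one, each id appears once, and each slot holds exactly two
#' questions; \code{\link{validate_catalog}} enforces this.
#'
#' @param meals If \code{TRUE}, the evening medication-adherence question is
#'   replaced by a meals question ("Have you eaten all your meals today?"),
#'   an alternative wording used during protocol development. The default
#'   catalog uses the medication question, which is the one the alarm rules
#'   are defined on.
#' @return A question catalog data.frame with 4 rows.
#' @seealso [default_educational_catalog()], [validate_catalog()]
#' @export
#' @examples
#' default_question_catalog()
default_question_catalog <- function(meals = FALSE) {
  stopifnot(is.logical(meals), length(meals) == 1L)
  adherence <- if (meals) {
    list(id = "MEALS", text = "Have you eaten all your meals today?")
  } else {
    list(id = "MEDICATION", text = "Have you taken all your medications today?")
  }
  cat <- data.frame(
    id = c("DYSPNEA", "WEIGHT", adherence$id, "FATIGUE"),
    text = c(
      "During last night, did you wake up with shortness of breath once?",
      "What's your weight today?",
      adherence$text,
      "Have you felt more tired today than you did yesterday?"
    ),
    answer_kind = c("BINARY", "NUMERIC_KG", "BINARY", "BINARY"),
    slot = c("MORNING", "MORNING", "EVENING", "EVENING"),
    stringsAsFactors = FALSE
  )
  class(cat) <- c("hf_question_catalog", "data.frame")
  cat
}

#' Educational message catalog
#'
#' Unidirectional self-care reinforcements. They require no answer, are never
#' matched to a reply, and are cycled in fixed order by the scheduler (one
#' message every \code{educational_period_days}).
#'
#' @return A data.frame with columns \code{id} and \code{text}.
#' @export
default_educational_catalog <- function() {
  cat <- data.frame(
    id = c("SALT", "FLUID", "WEIGH"),
    text = c(
      "Avoid processed meats because they all contain a lot of salt.",
      "Shortness of breath is one of the symptoms caused by the accumulation of fluid in the body.",
      paste(
        "It is important for patients with heart failure to weigh themselves",
        "regularly at the same time each day and record their weight."
      )
    ),
    stringsAsFactors = FALSE
  )
  class(cat) <- c("hf_edu_catalog", "data.frame")
  cat
}

#' Validate a question catalog
#'
#' @param catalog A question catalog data.frame.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_catalog <- function(catalog) {
  v <- character()
  need <- c("id", "text", "answer_kind", "slot")
  if (!is.data.frame(catalog) || !all(need %in% names(catalog))) {
    return(sprintf("catalog must be a data.frame with columns %s",
                   paste(need, collapse = ", ")))
  }
  if (anyDuplicated(catalog$id)) {
    v <- c(v, sprintf("duplicate question id: %s",
                      paste(unique(catalog$id[duplicated(catalog$id)]), collapse = ", ")))
  }
  bad_kind <- setdiff(unique(catalog$answer_kind), c("BINARY", "NUMERIC_KG"))
  if (length(bad_kind)) {
    v <- c(v, sprintf("unknown answer_kind: %s", paste(bad_kind, collapse = ", ")))
  }
  bad_slot <- setdiff(unique(catalog$slot), c("MORNING", "EVENING"))
  if (length(bad_slot)) {
    v <- c(v, sprintf("unknown slot: %s", paste(bad_slot, collapse = ", ")))
  }
  numeric_ids <- catalog$id[catalog$answer_kind == "NUMERIC_KG"]
  if (!identical(numeric_ids, "WEIGHT")) {
    v <- c(v, "WEIGHT must be the only NUMERIC_KG question")
  }
  for (s in c("MORNING", "EVENING")) {
    n <- sum(catalog$slot == s)
    if (n != 2L) v <- c(v, sprintf("slot %s holds %d questions, expected 2", s, n))
  }
  if (any(!nzchar(catalog$text))) v <- c(v, "question text must be non-empty")
  v
}

#' Validate an educational catalog
#'
#' @param edu An educational catalog data.frame.
#' @return Character vector of violations; empty when valid.
#' @export
validate_educational_catalog <- function(edu) {
  v <- character()
  if (!is.data.frame(edu) || !all(c("id", "text") %in% names(edu))) {
    return("educational catalog must be a data.frame with columns id, text")
  }
  if (nrow(edu) < 1L) v <- c(v, "educational catalog is empty")
  if (anyDuplicated(edu$id)) v <- c(v, "duplicate educational message id")
  if (any(!nzchar(edu$text))) v <- c(v, "educational text must be non-empty")
  v
}

# Question ids of a catalog in delivery order: morning slot first, then
# evening, preserving within-slot catalog order. This is the tie-break order
# used when matching free replies to open questions.
catalog_slot_order <- function(catalog) {
  catalog$id[order(match(catalog$slot, c("MORNING", "EVENING")))]
}
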