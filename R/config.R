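#' Message schedule configuration
#'
#' Clock times are used for ordering serialized logs only; the engine itself
#' is day-granular (a "day" is one local calendar date of the follow-up
#' window, day 1 = first follow-up day).
#'
#' @param morning_time,evening_time Times of day ("HH:MM") at which the two
#'   morning and two evening feedback questions go out.
#' @param educational_period_days Send one educational message every this many
#'   days.
#' @param educational_first_day Day index of the first educational message.
#' @param follow_up_days_default Window length used when an enrollment record
#'   does not state one; the protocol monitors the first week after hospital
#'   discharge.
#' @return An object of class \code{hf_schedule_config}.
#' @export
schedule_config <- function(morning_time = "08:00",
                            evening_time = "20:00",
                            educational_period_days = 2L,
                            educational_first_day = 2L,
                            follow_up_days_default = 7L) {
  cfg <- list(
    morning_time = as.character(morning_time),
    evening_time = as.character(evening_time),
    educational_period_days = as.integer(educational_period_days),
    educational_first_day = as.integer(educational_first_day),
    follow_up_days_default = as.integer(follow_up_days_default)
  )
  if (cfg$morning_time >= cfg$evening_time) {
    stop("morning_time must be earlier than evening_time")
  }
  counts <- unlist(cfg[c("educational_period_days", "educational_first_day",
                         "follow_up_days_default")])
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("all day counts must be positive integers")
  }
  structure(cfg, class = "hf_schedule_config")
}

#' Alarm rule thresholds
#'
#' Thresholds for the five automatic checks run over each patient's day grid.
#' The defaults encode the clinical flowchart: two consecutive days for the
#' non-response and symptom/medication streak rules, and a 2.0 kg weight gain
#' within three consecutive fully-observed days for the congestion check.
#'
#' @param symptom_streak_days Consecutive days of an affirmative dyspnea or
#'   fatigue answer (or negative medication answer) that fire a streak alarm.
#' @param nonresponse_streak_days Consecutive days with zero answers across
#'   all four questions that fire the non-response alarm.
#' @param weight_gain_kg Gain (kg) within the weight window that fires the
#'   weight alarm.
#' @param weight_window_days Length of the sliding weight window (>= 2 days);
#'   every day in a window must carry a valid numeric weight.
#' @param weight_loss_kg Optional symmetric loss threshold (kg); \code{NULL}
#'   (the default) disables the loss rule.
#' @param weight_endpoint_only If \code{TRUE}, the weight rule compares last
#'   vs first day of the window; the default compares last vs the window
#'   minimum, which also catches a dip-then-surge trajectory.
#' @return An object of class \code{hf_alarm_config}.
#' @export
alarm_config <- function(symptom_streak_days = 2L,
                         nonresponse_streak_days = 2L,
                         weight_gain_kg = 2.0,
                         weight_window_days = 3L,
                         weight_loss_kg = NULL,
                         weight_endpoint_only = FALSE) {
  cfg <- list(
    symptom_streak_days = as.integer(symptom_streak_days),
    nonresponse_streak_days = as.integer(nonresponse_streak_days),
    weight_gain_kg = as.numeric(weight_gain_kg),
    weight_window_days = as.integer(weight_window_days),
    weight_loss_kg = if (!is.null(weight_loss_kg)) as.numeric(weight_loss_kg),
    weight_endpoint_only = isTRUE(weight_endpoint_only)
  )
  if (cfg$symptom_streak_days < 1L || cfg$nonresponse_streak_days < 1L) {
    stop("streak lengths must be >= 1 day")
  }
  if (cfg$weight_window_days < 2L) stop("weight_window_days must be >= 2")
  if (!is.finite(cfg$weight_gain_kg) || cfg$weight_gain_kg <= 0) {
    stop("weight_gain_kg must be a positive number")
  }
  if (!is.null(cfg$weight_loss_kg) &&
      (!is.finite(cfg$weight_loss_kg) || cfg$weight_loss_kg <= 0)) {
    stop("weight_loss_kg must be NULL or a positive number")
  }
  structure(cfg, class = "hf_alarm_config")
}

#' Read and write the engine configuration file
#'
#' The whole configuration (question catalog, educational catalog, schedule,
#' alarm thresholds) round-trips through one YAML document with top-level
#' keys \code{questions}, \code{educational}, \code{schedule}, \code{alarms}.
#'
#' @param path File path of the YAML configuration.
#' @param questions,educational,schedule,alarms Components to serialize;
#'   defaults are the protocol defaults.
#' @return \code{read_config} returns a list with validated components
#'   \code{questions}, \code{educational}, \code{schedule}, \code{alarms};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
write_config <- function(path,
                         questions = default_question_catalog(),
                         educational = default_educational_catalog(),
                         schedule = schedule_config(),
                         alarms = alarm_config()) {
  doc <- list(
    questions = lapply(seq_len(nrow(questions)), function(i) as.list(questions[i, ])),
    educational = lapply(seq_len(nrow(educational)), function(i) as.list(educational[i, ])),
    schedule = unclass(schedule),
    alarms = Filter(Negate(is.null), unclass(alarms))
  )
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  for (key in c("questions", "educational", "schedule", "alarms")) {
    if (is.null(doc[[key]])) stop("configuration is missing the '", key, "' section")
  }
  questions <- do.call(rbind, lapply(doc$questions, function(q) {
    as.data.frame(q[c("id", "text", "answer_kind", "slot")], stringsAsFactors = FALSE)
  }))
  class(questions) <- c("hf_question_catalog", "data.frame")
  bad <- validate_catalog(questions)
  if (length(bad)) stop("invalid question catalog: ", paste(bad, collapse = "; "))
  educational <- do.call(rbind, lapply(doc$educational, function(m) {
    as.data.frame(m[c("id", "text")], stringsAsFactors = FALSE)
  }))
  class(educational) <- c("hf_edu_catalog", "data.frame")
  bad <- validate_educational_catalog(educational)
  if (length(bad)) stop("invalid educational catalog: ", paste(bad, collapse = "; "))
  schedule <- do.call(schedule_config, doc$schedule)
  alarms <- do.call(alarm_config, doc$alarms)
  list(questions = questions, educational = educational,
       schedule = schedule, alarms = alarms)
}
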