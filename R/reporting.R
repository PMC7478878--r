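#' Aggregate a cohort into summary counts
#'
#' Computes the counts a monitoring report prints: feedback messages sent,
#' answered and unanswered (globally and per question), unanswered messages
#' by tagged reason, and alarms by rule. Conservation holds by construction:
#' answered + unanswered = sent, globally and per question, and the per-rule
#' alarm counts sum to the total.
#'
#' @param sessions List of \code{hf_session}s.
#' @param schedules Optional list of schedules aligned with \code{sessions}
#'   (same patient order); built from the profiles when \code{NULL}.
#' @param alarms Optional precomputed cohort alarms data.frame; computed
#'   with \code{\link{evaluate_cohort_alarms}} when \code{NULL}.
#' @param alarm_cfg Alarm thresholds used when \code{alarms} is \code{NULL}.
#' @param schedule_cfg Schedule configuration used when \code{schedules} is
#'   \code{NULL}.
#' @return An object of class \code{hf_summary}: a list with elements
#'   \code{n_patients}, \code{feedback_sent}, \code{feedback_answered},
#'   \code{feedback_unanswered}, \code{unanswered_by_reason},
#'   \code{alarms_by_rule}, \code{per_question}.
#' @export
summarize_cohort <- function(sessions, schedules = NULL, alarms = NULL,
                             alarm_cfg = alarm_config(),
                             schedule_cfg = schedule_config()) {
  if (is.null(schedules)) {
    schedules <- lapply(sessions, function(s) {
      build_schedule(s$profile, s$catalog, cfg = schedule_cfg)
    })
  }
  if (length(schedules) != length(sessions)) {
    stop("schedules and sessions must be aligned one to one")
  }
  for (i in seq_along(sessions)) {
    sp <- unique(schedules[[i]]$patient_id)
    if (!identical(sp, sessions[[i]]$profile$patient_id)) {
      stop("schedule ", i, " refers to patient ", paste(sp, collapse = "/"),
           ", session to ", sessions[[i]]$profile$patient_id)
    }
  }
  if (is.null(alarms)) {
    alarms <- if (length(sessions)) evaluate_cohort_alarms(sessions, alarm_cfg)
              else data.frame(rule = character())
  }

  marked <- mapply(apply_responses, schedules, sessions, SIMPLIFY = FALSE)
  parts <- lapply(marked, function(m) m[m$kind == "FEEDBACK", ])
  fb <- if (length(parts)) do.call(rbind, parts) else NULL
  qids <- if (length(sessions)) sessions[[1]]$catalog$id else character()
  per_question <- lapply(stats::setNames(qids, qids), function(q) {
    rows <- fb[fb$payload == q, ]
    list(answered = sum(rows$status == "ANSWERED"), sent = nrow(rows))
  })
  reasons <- as.character(unlist(lapply(sessions, function(s) {
    unlist(lapply(s$records, function(r) unname(r$missing_reason)))
  })))
  rules <- c("NON_RESPONSE", "DYSPNEA_STREAK", "WEIGHT_GAIN",
             "MEDICATION_STREAK", "FATIGUE_STREAK")
  alarms_by_rule <- lapply(stats::setNames(rules, rules),
                           function(r) sum(alarms$rule == r))
  extra <- setdiff(unique(alarms$rule), rules)
  for (r in extra) alarms_by_rule[[r]] <- sum(alarms$rule == r)

  structure(list(
    n_patients = length(sessions),
    feedback_sent = if (is.null(fb)) 0L else nrow(fb),
    feedback_answered = if (is.null(fb)) 0L else sum(fb$status == "ANSWERED"),
    feedback_unanswered = if (is.null(fb)) 0L else sum(fb$status == "UNANSWERED"),
    unanswered_by_reason = as.list(table(reasons)),
    alarms_by_rule = alarms_by_rule,
    per_question = per_question
  ), class = "hf_summary")
}

#' @export
print.hf_summary <- function(x, ...) {
  cat(sprintf("<hf_summary> %d patients: %d feedback messages sent, %d answered, %d unanswered\n",
              x$n_patients, x$feedback_sent, x$feedback_answered,
              x$feedback_unanswered))
  for (q in names(x$per_question)) {
    cat(sprintf("  %-11s %d/%d answered\n", q,
                x$per_question[[q]]$answered, x$per_question[[q]]$sent))
  }
  tot <- sum(unlist(x$alarms_by_rule))
  cat(sprintf("  alarms: %d (%s)\n", tot,
              paste(sprintf("%s=%d", names(x$alarms_by_rule),
                            unlist(x$alarms_by_rule)), collapse = ", ")))
  invisible(x)
}

#' Write a summary as JSON
#'
#' Fixed key names as in \code{\link{summarize_cohort}}; counts are written
#' as bare numbers.
#'
#' @param summary An \code{hf_summary}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read and write patient enrollment CSVs
#'
#' Columns \code{patient_id, follow_up_start, follow_up_days}; extra columns
#' are kept as inert metadata.
#'
#' @param path CSV file.
#' @return \code{read_profiles} returns a list of
#'   \code{\link{patient_profile}}s.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "follow_up_start", "follow_up_days")
  if (!all(need %in% names(df))) {
    stop("profile CSV must have columns ", paste(need, collapse = ", "))
  }
  meta_cols <- setdiff(names(df), need)
  lapply(seq_len(nrow(df)), function(i) {
    patient_profile(df$patient_id[i], df$follow_up_start[i],
                    df$follow_up_days[i],
                    metadata = as.list(df[i, meta_cols, drop = FALSE]))
  })
}

#' @rdname read_profiles
#' @param profiles List of \code{hf_profile}s.
#' @export
write_profiles <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(patient_id = p$patient_id,
               follow_up_start = as.character(p$follow_up_start),
               follow_up_days = p$follow_up_days,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run the full monitoring pipeline and write its artifacts
#'
#' Executes schedule, replay, alarm evaluation, dispatch and summary in one
#' call, then writes four artifacts into \code{out_dir}: \code{sessions.csv}
#' (the answer grid in inbound-log format), \code{alarms.csv},
#' \code{notifications.jsonl} and \code{summary.json}.
#'
#' Exactly one input mode must be chosen: \code{sim} (generate a synthetic
#' cohort), \code{fixture = TRUE} (replay the shipped prototype cohort), or
#' \code{profiles} plus an optional \code{inbound} log (replay recorded
#' traffic; with no log every message is unanswered).
#'
#' @param out_dir Output directory, created if needed.
#' @param sim An \code{\link{sim_config}}, or \code{NULL}.
#' @param fixture Replay the canonical prototype cohort?
#' @param profiles Path to an enrollment CSV, or a list of profiles.
#' @param inbound Path to an inbound log (CSV or JSON lines), or \code{NULL}.
#' @param config Path to a YAML engine configuration, or \code{NULL} for the
#'   defaults.
#' @return The \code{hf_summary}, invisibly.
#' @export
run_pipeline <- function(out_dir, sim = NULL, fixture = FALSE,
                         profiles = NULL, inbound = NULL, config = NULL) {
  modes <- c(!is.null(sim), isTRUE(fixture), !is.null(profiles))
  if (sum(modes) != 1L) {
    stop("choose exactly one input mode: sim, fixture, or profiles")
  }
  cfgs <- if (!is.null(config)) read_config(config) else list(
    questions = default_question_catalog(),
    educational = default_educational_catalog(),
    schedule = schedule_config(),
    alarms = alarm_config()
  )
  sessions <- if (!is.null(sim)) {
    generate_cohort(sim, catalog = cfgs$questions)
  } else if (isTRUE(fixture)) {
    prototype_cohort()
  } else {
    profs <- if (is.character(profiles)) read_profiles(profiles) else profiles
    ss <- lapply(profs, new_session, catalog = cfgs$questions)
    if (!is.null(inbound)) ss <- attach_log(ss, read_inbound_log(inbound))
    ss
  }

  schedules <- lapply(sessions, function(s) {
    build_schedule(s$profile, cfgs$questions, cfgs$educational, cfgs$schedule)
  })
  alarms <- if (length(sessions)) evaluate_cohort_alarms(sessions, cfgs$alarms)
            else data.frame(patient_id = character(), rule = character(),
                            day_index = integer(), detail = character())
  notifications <- dispatch_alarms(alarms)
  summary <- summarize_cohort(sessions, schedules, alarms)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_inbound_log(sessions, file.path(out_dir, "sessions.csv"),
                    schedule_cfg = cfgs$schedule)
  write_alarms_csv(alarms, file.path(out_dir, "alarms.csv"))
  write_notifications_jsonl(notifications, file.path(out_dir, "notifications.jsonl"))
  write_summary_json(summary, file.path(out_dir, "summary.json"))
  invisible(summary)
}
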