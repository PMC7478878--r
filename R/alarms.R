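#' Evaluate the automatic alarm rules over a session
#'
#' Scans the day grid in order and applies the five checks of the clinical
#' flowchart:
#' \describe{
#'   \item{NON_RESPONSE}{zero answers across all four questions on
#'     \code{nonresponse_streak_days} consecutive days. A partial responder
#'     (any answer, even invalid) is not a non-responder.}
#'   \item{DYSPNEA_STREAK}{affirmative nocturnal-dyspnea answer on
#'     \code{symptom_streak_days} consecutive days.}
#'   \item{WEIGHT_GAIN}{over a window of \code{weight_window_days}
#'     consecutive days all carrying valid numeric weights, last weight minus
#'     the window minimum (or minus the first weight when
#'     \code{weight_endpoint_only}) is at least \code{weight_gain_kg}.}
#'   \item{MEDICATION_STREAK}{negative medication-adherence answer on
#'     \code{symptom_streak_days} consecutive days.}
#'   \item{FATIGUE_STREAK}{affirmative worsening-fatigue answer on
#'     \code{symptom_streak_days} consecutive days.}
#' }
#' Each rule is debounced: it fires once when the condition is first
#' completed and re-arms only after a day that breaks it, so an uninterrupted
#' 7-day symptom run raises one alarm, not six. Missing or \code{INVALID}
#' answers break symptom and medication streaks and invalidate weight
#' windows; streaks never extend before day 1 (no pre-enrollment history).
#' An optional symmetric weight-loss rule (\code{WEIGHT_LOSS}) runs only when
#' \code{weight_loss_kg} is set.
#'
#' @param session An \code{hf_session} that passes
#'   \code{\link{validate_session}}.
#' @param cfg An \code{\link{alarm_config}}.
#' @return A data.frame of alarms with columns \code{patient_id, rule,
#'   day_index, detail}; \code{day_index} is the day the condition was
#'   completed. Zero rows when nothing fires. Pure function of its inputs.
#' @export
#' @examples
#' s <- new_session(patient_profile("P01", "2017-09-04", 7))
#' for (d in 1:2) s <- set_answer(s, d, "DYSPNEA", parsed_answer("YES"))
#' evaluate_alarms(s)
evaluate_alarms <- function(session, cfg = alarm_config()) {
  stopifnot(inherits(session, "hf_session"), inherits(cfg, "hf_alarm_config"))
  bad <- validate_session(session)
  if (length(bad)) stop("invalid session: ", paste(bad, collapse = "; "))

  n <- session$profile$follow_up_days
  pid <- session$profile$patient_id
  out <- list()
  add <- function(rule, day, detail) {
    out[[length(out) + 1L]] <<- data.frame(
      patient_id = pid, rule = rule, day_index = as.integer(day),
      detail = detail, stringsAsFactors = FALSE)
  }

  answer_kind <- function(q) {
    vapply(seq_len(n), function(d) {
      a <- session_answer(session, d, q)
      if (is.null(a)) NA_character_ else a$kind
    }, "")
  }

  streak_scan <- function(qualifies, threshold, rule, detail_fmt) {
    run <- 0L
    fired <- FALSE
    for (d in seq_len(n)) {
      if (isTRUE(qualifies[d])) {
        run <- run + 1L
        if (!fired && run >= threshold) {
          add(rule, d, sprintf(detail_fmt, threshold, d - threshold + 1L, d))
          fired <- TRUE
        }
      } else {
        run <- 0L
        fired <- FALSE
      }
    }
  }

  # symptom / medication streaks (only over questions present in the catalog)
  binary_rules <- list(
    list(q = "DYSPNEA", value = "YES", rule = "DYSPNEA_STREAK",
         fmt = "woke with shortness of breath on %d consecutive nights (days %d-%d)"),
    list(q = "MEDICATION", value = "NO", rule = "MEDICATION_STREAK",
         fmt = "missed medications on %d consecutive days (days %d-%d)"),
    list(q = "FATIGUE", value = "YES", rule = "FATIGUE_STREAK",
         fmt = "felt more fatigued on %d consecutive days (days %d-%d)")
  )
  for (br in binary_rules) {
    if (!br$q %in% session$catalog$id) next
    kinds <- answer_kind(br$q)
    streak_scan(!is.na(kinds) & kinds == br$value,
                cfg$symptom_streak_days, br$rule, br$fmt)
  }

  # non-response: a day with zero answers of any kind
  silent <- vapply(seq_len(n), function(d) day_response_count(session, d) == 0L, TRUE)
  streak_scan(silent, cfg$nonresponse_streak_days, "NON_RESPONSE",
              "no response to any question on %d consecutive days (days %d-%d)")

  # weight window rules, with re-arm debounce on the window condition
  wq <- session$catalog$id[session$catalog$answer_kind == "NUMERIC_KG"]
  if (length(wq) == 1L) {
    weights <- vapply(seq_len(n), function(d) {
      a <- session_answer(session, d, wq)
      if (!is.null(a) && a$kind == "NUMERIC") a$numeric_value else NA_real_
    }, 1)
    w <- cfg$weight_window_days
    weight_scan <- function(delta_fun, threshold, rule, fmt) {
      armed <- TRUE
      for (d in seq_len(n)) {
        if (d < w) next
        win <- weights[(d - w + 1L):d]
        qualifies <- !anyNA(win) && delta_fun(win) >= threshold
        if (qualifies) {
          if (armed) {
            add(rule, d, sprintf(fmt, delta_fun(win), w, d - w + 1L, d))
            armed <- FALSE
          }
        } else {
          armed <- TRUE
        }
      }
    }
    gain <- if (cfg$weight_endpoint_only) {
      function(win) win[length(win)] - win[1]
    } else {
      function(win) win[length(win)] - min(win)
    }
    weight_scan(gain, cfg$weight_gain_kg, "WEIGHT_GAIN",
                "gained %.1f kg within %d consecutive days (days %d-%d)")
    if (!is.null(cfg$weight_loss_kg)) {
      loss <- if (cfg$weight_endpoint_only) {
        function(win) win[1] - win[length(win)]
      } else {
        function(win) max(win) - win[length(win)]
      }
      weight_scan(loss, cfg$weight_loss_kg, "WEIGHT_LOSS",
                  "lost %.1f kg within %d consecutive days (days %d-%d)")
    }
  }

  alarms <- if (length(out)) do.call(rbind, out) else data.frame(
    patient_id = character(), rule = character(),
    day_index = integer(), detail = character(), stringsAsFactors = FALSE)
  alarms[order(alarms$day_index), , drop = FALSE]
}

#' Evaluate alarms for a whole cohort
#'
#' @param sessions List of \code{hf_session}s.
#' @param cfg An \code{\link{alarm_config}}.
#' @return One alarms data.frame, rows of all patients bound together.
#' @export
evaluate_cohort_alarms <- function(sessions, cfg = alarm_config()) {
  res <- lapply(sessions, evaluate_alarms, cfg = cfg)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Turn alarms into notifications
#'
#' Every alarm notifies both the patient and the manager in charge of the
#' monitoring system at the hospital; order is preserved.
#'
#' @param alarms Alarms data.frame from \code{\link{evaluate_alarms}}.
#' @return A data.frame with the alarm columns plus \code{recipients}
#'   (always \code{"PATIENT,MANAGER"}), one row per alarm.
#' @export
dispatch_alarms <- function(alarms) {
  out <- alarms
  out$recipients <- rep("PATIENT,MANAGER", nrow(alarms))
  out
}

#' Write alarms and notifications to disk
#'
#' Alarms go to CSV (columns \code{patient_id, rule, day_index, detail});
#' notifications to JSON lines, one object per notification with the
#' recipients as an array.
#'
#' @param alarms Alarms data.frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_alarms_csv <- function(alarms, path) {
  utils::write.csv(alarms[, c("patient_id", "rule", "day_index", "detail")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_alarms_csv
#' @param notifications Notifications data.frame from
#'   \code{\link{dispatch_alarms}}.
#' @export
write_notifications_jsonl <- function(notifications, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(notifications))) {
    obj <- list(
      patient_id = notifications$patient_id[i],
      rule = notifications$rule[i],
      day_index = notifications$day_index[i],
      detail = notifications$detail[i],
      recipients = strsplit(notifications$recipients[i], ",", fixed = TRUE)[[1]]
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}
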