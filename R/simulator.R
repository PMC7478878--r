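#' Simulation configuration
#'
#' Defaults emulate the prototype study conditions: a cohort of ten patients
#' monitored for the first week after discharge (September 2017), high
#' adherence (about 94% of feedback questions answered), occasional nights
#' with dyspnea and days with worsening fatigue, full medication adherence,
#' and stable body weight.
#'
#' @param n_patients Cohort size.
#' @param follow_up_days Window length applied to every simulated patient.
#' @param response_prob Probability that a given question is answered on a
#'   given day; a single value or a vector named by question id.
#' @param p_dyspnea,p_fatigue Daily probability of an affirmative symptom
#'   answer, given a response.
#' @param p_med_miss Daily probability of a negative medication answer,
#'   given a response.
#' @param weight_baseline_kg,weight_drift_kg,weight_noise_sd_kg Weight model:
#'   weight on day d is baseline + drift * d + Gaussian noise, rounded to
#'   0.1 kg.
#' @param outage_start,outage_days Optional contiguous outage window (e.g. a
#'   power cut): on days \code{outage_start .. outage_start+outage_days-1}
#'   no question is answered. \code{NULL} disables it.
#' @param start_date Follow-up start date shared by the cohort.
#' @param seed Optional RNG seed; the same seed and configuration reproduce
#'   the cohort bit for bit.
#' @return An object of class \code{hf_sim_config}.
#' @export
sim_config <- function(n_patients = 10L,
                       follow_up_days = 7L,
                       response_prob = 0.94,
                       p_dyspnea = 0.10,
                       p_fatigue = 0.15,
                       p_med_miss = 0,
                       weight_baseline_kg = 70,
                       weight_drift_kg = 0,
                       weight_noise_sd_kg = 0.3,
                       outage_start = NULL,
                       outage_days = NULL,
                       start_date = "2017-09-04",
                       seed = NULL) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    follow_up_days = as.integer(follow_up_days),
    response_prob = response_prob,
    p_dyspnea = as.numeric(p_dyspnea),
    p_fatigue = as.numeric(p_fatigue),
    p_med_miss = as.numeric(p_med_miss),
    weight_baseline_kg = as.numeric(weight_baseline_kg),
    weight_drift_kg = as.numeric(weight_drift_kg),
    weight_noise_sd_kg = as.numeric(weight_noise_sd_kg),
    outage_start = if (!is.null(outage_start)) as.integer(outage_start),
    outage_days = if (!is.null(outage_days)) as.integer(outage_days),
    start_date = as.Date(start_date),
    seed = if (!is.null(seed)) as.integer(seed)
  )
  probs <- c(unlist(cfg$response_prob), cfg$p_dyspnea, cfg$p_fatigue, cfg$p_med_miss)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (cfg$n_patients < 0L) stop("n_patients must be >= 0")
  if (cfg$follow_up_days < 1L) stop("follow_up_days must be >= 1")
  if (cfg$weight_noise_sd_kg < 0) stop("weight_noise_sd_kg must be >= 0")
  structure(cfg, class = "hf_sim_config")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cohort of monitoring sessions
#'
#' Each answer is present independently with the per-question response
#' probability; present binary answers are drawn from the symptom and
#' medication-miss probabilities, and weights follow the linear-drift model
#' rounded to 0.1 kg. An optional outage window silences every question on a
#' contiguous run of days, emulating the message loss a power cut causes.
#'
#' @param cfg An \code{\link{sim_config}}.
#' @param catalog Question catalog the sessions are built against.
#' @return List of \code{n_patients} \code{hf_session}s, each passing
#'   \code{\link{validate_session}}.
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 2, seed = 1))
#' validate_session(cohort[[1]])
generate_cohort <- function(cfg = sim_config(),
                            catalog = default_question_catalog()) {
  stopifnot(inherits(cfg, "hf_sim_config"))
  qids <- catalog$id
  rp <- cfg$response_prob
  if (is.null(names(rp))) {
    rp <- stats::setNames(rep_len(as.numeric(rp), length(qids)), qids)
  } else {
    missing_q <- setdiff(qids, names(rp))
    if (length(missing_q)) {
      stop("response_prob lacks entries for: ", paste(missing_q, collapse = ", "))
    }
    rp <- rp[qids]
  }
  outage <- if (!is.null(cfg$outage_start) && !is.null(cfg$outage_days)) {
    seq(cfg$outage_start, length.out = cfg$outage_days)
  } else {
    integer()
  }

  with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_patients), function(i) {
      profile <- patient_profile(sprintf("SIM%03d", i), cfg$start_date,
                                 cfg$follow_up_days)
      s <- new_session(profile, catalog)
      for (d in seq_len(cfg$follow_up_days)) {
        if (d %in% outage) {
          s$records[[d]]$missing_reason[qids] <- "POWER_OUTAGE"
          next
        }
        for (q in qids) {
          if (stats::runif(1) > rp[[q]]) next
          kind <- catalog$answer_kind[catalog$id == q]
          ans <- if (kind == "NUMERIC_KG") {
            w <- cfg$weight_baseline_kg + cfg$weight_drift_kg * d +
              stats::rnorm(1, sd = cfg$weight_noise_sd_kg)
            w <- max(round(w, 1), 0.1)
            parsed_answer("NUMERIC", numeric_value = w,
                          raw_text = formatC(w, format = "f", digits = 1))
          } else {
            p_yes <- switch(q,
                            DYSPNEA = cfg$p_dyspnea,
                            FATIGUE = cfg$p_fatigue,
                            MEDICATION = 1 - cfg$p_med_miss,
                            MEALS = 1 - cfg$p_med_miss,
                            0)
            kindchr <- if (stats::runif(1) < p_yes) "YES" else "NO"
            parsed_answer(kindchr, raw_text = tolower(kindchr))
          }
          s <- set_answer(s, d, q, ans)
        }
      }
      s
    })
  })
}
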