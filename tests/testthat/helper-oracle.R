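# Independent brute-force oracles for the alarm rules. These deliberately
# avoid the engine's scan loop: streaks come from rle() run enumeration,
# weight alarms from a closed-form condition on the set of qualifying days.

# One alarm per maximal TRUE run of length >= threshold, fired on the day the
# run first reaches the threshold.
oracle_streak_days <- function(qualifies, threshold) {
  qualifies[is.na(qualifies)] <- FALSE
  r <- rle(qualifies)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= threshold
  as.integer(starts[keep] + threshold - 1L)
}

# Weight rule with re-arm debounce: day d (>= window) qualifies when the
# window ending at d is fully observed and delta >= threshold; an alarm fires
# on every qualifying day not preceded by a qualifying day.
oracle_weight_days <- function(weights, window, threshold,
                               endpoint_only = FALSE) {
  n <- length(weights)
  if (n < window) return(integer())
  qual <- vapply(seq_len(n), function(d) {
    if (d < window) return(FALSE)
    win <- weights[(d - window + 1L):d]
    if (anyNA(win)) return(FALSE)
    delta <- if (endpoint_only) win[window] - win[1] else win[window] - min(win)
    delta >= threshold
  }, TRUE)
  which(qual & !c(FALSE, qual[-n]))
}
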