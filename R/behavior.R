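#' Classify Go/NoGo trials and attribute responses
#'
#' Assigns each button press to the most recent stimulus whose response
#' window contains it, keeps at most one (the first) response per trial, and
#' scores every trial as Hit, Miss, FalseAlarm, or CorrectRejection.
#'
#' By default the upper edge of the response window is capped at the next
#' stimulus onset so attribution windows can never overlap. With
#' `cap_at_next_onset = FALSE` a window longer than the shortest
#' onset-to-onset interval is a configuration error.
#'
#' @param events an [event_stream()].
#' @param response_window `(min_ms, max_ms)` post-stimulus interval in which
#'   a press counts as a response to that stimulus.
#' @param cap_at_next_onset logical; cap each trial's window at the next
#'   stimulus onset (default TRUE).
#' @return data.frame of class `trial_table` with columns `trial`, `onset_s`,
#'   `type`, `outcome`, `rt_ms` (NA unless Hit or FalseAlarm). The number of
#'   unattributed presses is stored in attribute `n_unattributed`.
#' @export
classify_trials <- function(events, response_window = c(100, 1000),
                            cap_at_next_onset = TRUE) {
  stopifnot(inherits(events, "event_stream"),
            length(response_window) == 2L,
            response_window[1] >= 0,
            response_window[1] < response_window[2])
  stim <- events$stimuli
  n <- nrow(stim)
  onset <- stim$onset_s
  next_onset <- c(onset[-1], Inf)
  lo <- onset + response_window[1] / 1000
  hi <- onset + response_window[2] / 1000
  if (cap_at_next_onset) {
    hi <- pmin(hi, next_onset)
  } else if (n > 1 &&
             response_window[2] / 1000 > min(diff(onset))) {
    stop("response window exceeds the minimum onset-to-onset interval; ",
         "windows would overlap (set cap_at_next_onset = TRUE)")
  }
  rt_ms <- rep(NA_real_, n)
  responded <- rep(FALSE, n)
  unattributed <- 0L
  for (tr in sort(events$responses$time_s)) {
    # most recent stimulus whose window contains the press
    k <- which(lo <= tr & tr < hi)
    if (length(k) == 0L) {
      unattributed <- unattributed + 1L
      next
    }
    k <- max(k)
    if (responded[k]) next  # keep first press only
    responded[k] <- TRUE
    rt_ms[k] <- (tr - onset[k]) * 1000
  }
  outcome <- ifelse(stim$type == "Go",
                    ifelse(responded, "Hit", "Miss"),
                    ifelse(responded, "FalseAlarm", "CorrectRejection"))
  out <- data.frame(trial = seq_len(n), onset_s = onset, type = stim$type,
                    outcome = outcome, rt_ms = rt_ms)
  class(out) <- c("trial_table", "data.frame")
  attr(out, "n_unattributed") <- unattributed
  out
}

#' Signal-detection sensitivity (d-prime)
#'
#' Computes d' = z(hit rate) - z(false-alarm rate), where z is the standard
#' normal quantile. The log-linear extreme-rate correction (add 0.5 to each
#' numerator count and 1 to each denominator) is applied by default so that
#' perfect blocks (hit rate 1 or false-alarm rate 0) stay finite.
#'
#' @param n_hit,n_miss number of Go trials with / without a press.
#' @param n_fa,n_cr number of NoGo trials with / without a press.
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return d' (dimensionless scalar).
#' @export
#' @examples
#' dprime(72, 8, 2, 18)                      # typical block
#' dprime(90, 10, 10, 90, correction = "none")  # H=.9, FA=.1 -> 2.5631
dprime <- function(n_hit, n_miss, n_fa, n_cr,
                   correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  stopifnot(n_hit >= 0, n_miss >= 0, n_fa >= 0, n_cr >= 0)
  n_go <- n_hit + n_miss
  n_nogo <- n_fa + n_cr
  if (n_go == 0 || n_nogo == 0) {
    stop("dprime: need at least one Go and one NoGo trial")
  }
  if (correction == "loglinear") {
    h <- (n_hit + 0.5) / (n_go + 1)
    f <- (n_fa + 0.5) / (n_nogo + 1)
  } else {
    h <- n_hit / n_go
    f <- n_fa / n_nogo
  }
  stats::qnorm(h) - stats::qnorm(f)
}

#' Mean reaction time over Hits
#'
#' Reaction time is defined over successful Go trials (Hits) only; false-alarm
#' presses are excluded.
#'
#' @param trials a `trial_table` from [classify_trials()].
#' @return mean RT in ms, or `NA` (with a warning) if the block has no Hits.
#' @export
mean_rt <- function(trials) {
  stopifnot(inherits(trials, "trial_table"))
  rts <- trials$rt_ms[trials$outcome == "Hit"]
  if (length(rts) == 0L) {
    warning("mean_rt: no Hits in block; returning NA")
    return(NA_real_)
  }
  mean(rts)
}

#' Summarize one block of Go/NoGo behavior
#'
#' @param trials a `trial_table`.
#' @param correction passed to [dprime()].
#' @return one-row data.frame with outcome counts, `d_prime`, and
#'   `mean_rt_ms`.
#' @export
summarize_behavior <- function(trials, correction = "loglinear") {
  stopifnot(inherits(trials, "trial_table"))
  n_hit <- sum(trials$outcome == "Hit")
  n_miss <- sum(trials$outcome == "Miss")
  n_fa <- sum(trials$outcome == "FalseAlarm")
  n_cr <- sum(trials$outcome == "CorrectRejection")
  data.frame(
    n_hit = n_hit, n_miss = n_miss, n_fa = n_fa, n_cr = n_cr,
    d_prime = dprime(n_hit, n_miss, n_fa, n_cr, correction = correction),
    mean_rt_ms = if (n_hit > 0) mean(trials$rt_ms[trials$outcome == "Hit"])
                 else NA_real_
  )
}
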