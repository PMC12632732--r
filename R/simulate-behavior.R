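#' Configuration for the Go/NoGo behavior simulator
#'
#' Emulates one block of the visual Go/NoGo task: a stream of Go ('X') and
#' NoGo ('O') stimuli, each shown for `stimulus_duration` ms and followed by a
#' uniformly drawn inter-stimulus interval, with button presses generated per
#' trial from hit / false-alarm probabilities and a lognormal reaction-time
#' distribution.
#'
#' @param n_trials trials per block (task default 180).
#' @param p_nogo probability of a NoGo stimulus (default 0.20).
#' @param stimulus_duration stimulus presentation time, ms.
#' @param isi_range inter-stimulus interval range `(min, max)`, ms.
#' @param hit_rate probability of a press on a Go trial.
#' @param false_alarm_rate probability of a press on a NoGo trial.
#' @param rt_median median reaction time, ms.
#' @param rt_lognormal_sigma sigma of the lognormal RT distribution.
#' @param nogo_placement `"exact"` places `round(p_nogo * n_trials)` NoGo
#'   stimuli at random positions (default, deterministic counts);
#'   `"bernoulli"` draws each trial type independently.
#' @param seed integer seed.
#' @return object of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(n_trials = 180L,
                                p_nogo = 0.20,
                                stimulus_duration = 400,
                                isi_range = c(200, 400),
                                hit_rate = 0.95,
                                false_alarm_rate = 0.15,
                                rt_median = 350,
                                rt_lognormal_sigma = 0.2,
                                nogo_placement = c("exact", "bernoulli"),
                                seed = 1L) {
  nogo_placement <- match.arg(nogo_placement)
  stopifnot(
    n_trials > 0, p_nogo >= 0, p_nogo <= 1,
    stimulus_duration > 0,
    length(isi_range) == 2L, isi_range[1] <= isi_range[2], isi_range[1] >= 0,
    hit_rate >= 0, hit_rate <= 1,
    false_alarm_rate >= 0, false_alarm_rate <= 1,
    rt_median > 0, rt_lognormal_sigma >= 0
  )
  structure(
    list(n_trials = as.integer(n_trials), p_nogo = p_nogo,
         stimulus_duration = stimulus_duration, isi_range = isi_range,
         hit_rate = hit_rate, false_alarm_rate = false_alarm_rate,
         rt_median = rt_median, rt_lognormal_sigma = rt_lognormal_sigma,
         nogo_placement = nogo_placement, seed = as.integer(seed)),
    class = "behavior_sim_config"
  )
}

#' Simulate one Go/NoGo block
#'
#' @param config a [behavior_sim_config()].
#' @return an `event_stream`: list with `stimuli` (data.frame `onset_s`,
#'   `type`) and `responses` (data.frame `time_s`), plus a `ground_truth`
#'   attribute holding the intended outcome of every trial.
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "behavior_sim_config"))
  set.seed(config$seed)
  n <- config$n_trials
  isi <- stats::runif(n, config$isi_range[1], config$isi_range[2])
  soa_s <- (config$stimulus_duration + isi) / 1000
  onset <- cumsum(c(0, soa_s[-n]))
  type <- rep("Go", n)
  if (config$nogo_placement == "exact") {
    n_nogo <- round(config$p_nogo * n)
    type[sample.int(n, n_nogo)] <- "NoGo"
  } else {
    type[stats::runif(n) < config$p_nogo] <- "NoGo"
  }
  press_p <- ifelse(type == "Go", config$hit_rate, config$false_alarm_rate)
  pressed <- stats::runif(n) < press_p
  mu <- log(config$rt_median)
  rt_ms <- exp(stats::rnorm(n, mu, config$rt_lognormal_sigma))
  resp_time <- onset + rt_ms / 1000
  truth <- data.frame(
    trial = seq_len(n), type = type, pressed = pressed,
    rt_ms = ifelse(pressed, rt_ms, NA_real_),
    outcome = ifelse(type == "Go",
                     ifelse(pressed, "Hit", "Miss"),
                     ifelse(pressed, "FalseAlarm", "CorrectRejection"))
  )
  ev <- event_stream(
    stimuli = data.frame(onset_s = onset, type = type),
    responses = data.frame(time_s = sort(resp_time[pressed]))
  )
  attr(ev, "ground_truth") <- truth
  ev
}

#' Event stream container
#'
#' Timestamped stimulus and response events for one task block.
#'
#' @param stimuli data.frame with `onset_s` (strictly increasing) and `type`
#'   (`"Go"` or `"NoGo"`).
#' @param responses data.frame with `time_s` (non-negative button-press
#'   times).
#' @return object of class `event_stream`.
#' @export
event_stream <- function(stimuli, responses) {
  stopifnot(all(c("onset_s", "type") %in% names(stimuli)),
            "time_s" %in% names(responses))
  if (nrow(stimuli) > 1 && any(diff(stimuli$onset_s) <= 0)) {
    stop("event_stream: stimulus onsets must be strictly increasing")
  }
  if (any(responses$time_s < 0)) {
    stop("event_stream: response times must be non-negative")
  }
  if (!all(stimuli$type %in% c("Go", "NoGo"))) {
    stop("event_stream: stimulus type must be 'Go' or 'NoGo'")
  }
  structure(list(stimuli = as.data.frame(stimuli),
                 responses = as.data.frame(responses)),
            class = "event_stream")
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> %d stimuli (%d NoGo), %d responses\n",
              nrow(x$stimuli), sum(x$stimuli$type == "NoGo"),
              nrow(x$responses)))
  invisible(x)
}
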