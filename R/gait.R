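#' Detect heel strikes from a heel-marker trajectory
#'
#' A heel strike is the sample at which the heel marker is most anterior on
#' the anterior-posterior (AP) axis, i.e. a local maximum of the AP
#' coordinate. Candidate maxima are found with [pracma::findpeaks()] and then
#' filtered by a minimum peak separation of `0.5 * expected_stride_time` and
#' a minimum topographic prominence of `0.25 *` the median AP peak-to-trough
#' excursion. Both thresholds are exposed for tuning.
#'
#' @param traj a [marker_trajectory()].
#' @param expected_stride_time expected stride duration, seconds.
#' @param min_separation_frac minimum peak separation as a fraction of
#'   `expected_stride_time` (default 0.5).
#' @param min_prominence_frac minimum prominence as a fraction of the median
#'   peak-to-trough excursion (default 0.25).
#' @return integer vector of strictly increasing 1-based sample indices.
#' @export
detect_heel_strikes <- function(traj, expected_stride_time,
                                min_separation_frac = 0.5,
                                min_prominence_frac = 0.25) {
  stopifnot(inherits(traj, "marker_trajectory"), expected_stride_time > 0)
  ap <- traj$y_mm
  fs <- attr(traj, "sample_rate")
  pk <- pracma::findpeaks(ap)
  if (is.null(pk) || nrow(pk) < 2L) {
    stop("detect_heel_strikes: fewer than 2 AP peaks found (insufficient data)")
  }
  cand <- sort(pk[, 2])
  # separation first, so the excursion estimate sees stride-scale peaks
  # rather than noise bumps
  min_sep <- min_separation_frac * expected_stride_time * fs
  cand <- sort(.enforce_separation(cand, ap[cand], min_sep))
  if (length(cand) < 2L) {
    stop("detect_heel_strikes: fewer than 2 heel strikes detected")
  }
  # median peak-to-trough excursion over the candidate strides
  trough <- vapply(seq_len(length(cand) - 1L), function(k) {
    min(ap[cand[k]:cand[k + 1L]])
  }, numeric(1))
  excursion <- stats::median(ap[cand[-length(cand)]] - trough)
  prom <- .peak_prominence(ap, cand)
  strikes <- as.integer(cand[prom >= min_prominence_frac * excursion])
  if (length(strikes) < 2L) {
    stop("detect_heel_strikes: fewer than 2 heel strikes detected")
  }
  strikes
}

# topographic prominence: height above the higher of the two key saddles
.peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    left_bound <- 1L
    higher <- which(peaks < p & x[peaks] > x[p])
    if (length(higher) > 0) left_bound <- max(peaks[higher])
    right_bound <- length(x)
    higher <- which(peaks > p & x[peaks] > x[p])
    if (length(higher) > 0) right_bound <- min(peaks[higher])
    left_min <- if (p > left_bound) min(x[left_bound:p]) else x[p]
    right_min <- if (right_bound > p) min(x[p:right_bound]) else x[p]
    x[p] - max(left_min, right_min)
  }, numeric(1))
}

# greedy highest-first selection under a minimum index separation
.enforce_separation <- function(idx, height, min_sep) {
  ord <- order(height, decreasing = TRUE)
  kept <- integer(0)
  for (i in idx[ord]) {
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  kept
}

#' Detect heel lifts between consecutive heel strikes
#'
#' The heel lift is the most posterior point of the heel marker within a
#' stride: for each consecutive pair of same-foot strikes, the index of the
#' minimum AP value strictly between them. Plateau ties break to the earliest
#' sample.
#'
#' @param traj a [marker_trajectory()].
#' @param strikes strictly increasing heel-strike sample indices (>= 2).
#' @return integer vector of `length(strikes) - 1` lift indices, interleaving
#'   the strikes.
#' @export
detect_heel_lifts <- function(traj, strikes) {
  stopifnot(inherits(traj, "marker_trajectory"), length(strikes) >= 2L,
            all(diff(strikes) > 0))
  ap <- traj$y_mm
  vapply(seq_len(length(strikes) - 1L), function(k) {
    lo <- strikes[k] + 1L
    hi <- strikes[k + 1L] - 1L
    if (lo > hi) stop("detect_heel_lifts: adjacent strikes with no interior")
    seg <- ap[lo:hi]
    as.integer(lo + which.min(seg) - 1L)  # which.min takes the earliest tie
  }, integer(1))
}

#' Stride times from heel-strike indices
#'
#' @param strikes strictly increasing strike sample indices (>= 2).
#' @param sample_rate Hz.
#' @return numeric vector of stride times in ms.
#' @export
compute_stride_times <- function(strikes, sample_rate) {
  stopifnot(length(strikes) >= 2L, all(diff(strikes) > 0), sample_rate > 0)
  diff(strikes) / sample_rate * 1000
}

#' Stride lengths from heel-lift and heel-strike positions
#'
#' Stride length is the AP distance from a heel lift to the next heel strike.
#' Non-positive lengths indicate a data-quality problem; they are retained
#' but flagged with a warning and recorded in the `flagged` attribute.
#'
#' @param traj a [marker_trajectory()].
#' @param lifts heel-lift sample indices.
#' @param strikes heel-strike sample indices; each lift must be followed by a
#'   strike.
#' @return numeric vector of stride lengths in mm (attribute `flagged` marks
#'   non-positive values).
#' @export
compute_stride_lengths <- function(traj, lifts, strikes) {
  stopifnot(inherits(traj, "marker_trajectory"))
  ap <- traj$y_mm
  lens <- vapply(lifts, function(l) {
    nxt <- strikes[strikes > l]
    if (length(nxt) == 0L) {
      stop("compute_stride_lengths: lift at sample ", l,
           " has no following strike")
    }
    ap[min(nxt)] - ap[l]
  }, numeric(1))
  bad <- lens <= 0
  if (any(bad)) {
    warning(sum(bad), " stride length(s) <= 0 mm retained and flagged")
  }
  attr(lens, "flagged") <- which(bad)
  lens
}

#' Step widths at right heel strikes
#'
#' Lateral (ML) distance between the two heel markers at the time of each
#' right heel strike. Strike indices outside the left trajectory are skipped
#' with a warning.
#'
#' @param left,right time-aligned [marker_trajectory()] objects at the same
#'   sample rate.
#' @param right_strikes right-foot heel-strike sample indices.
#' @return numeric vector of step widths in mm.
#' @export
compute_step_widths <- function(left, right, right_strikes) {
  stopifnot(inherits(left, "marker_trajectory"),
            inherits(right, "marker_trajectory"))
  if (!isTRUE(all.equal(attr(left, "sample_rate"),
                        attr(right, "sample_rate")))) {
    stop("compute_step_widths: trajectories have different sample rates")
  }
  ok <- right_strikes >= 1L & right_strikes <= nrow(left) &
    right_strikes <= nrow(right)
  if (any(!ok)) {
    warning(sum(!ok), " strike index(es) outside trajectory range skipped")
  }
  idx <- right_strikes[ok]
  abs(left$x_mm[idx] - right$x_mm[idx])
}

#' Block-level gait summary: means and CV%
#'
#' @param stride_times_ms,stride_lengths_mm,step_widths_mm non-empty numeric
#'   vectors for one block.
#' @param min_strides warn if fewer strides than this contribute (partial
#'   blocks are still summarized).
#' @return one-row data.frame of class `gait_metrics` with mean and CV%
#'   (sample SD / mean x 100) of each measure.
#' @export
summarize_gait <- function(stride_times_ms, stride_lengths_mm,
                           step_widths_mm, min_strides = 10L) {
  lists <- list(stride_time = stride_times_ms,
                stride_length = stride_lengths_mm,
                step_width = step_widths_mm)
  for (nm in names(lists)) {
    if (length(lists[[nm]]) == 0L) stop("summarize_gait: empty ", nm, " list")
  }
  n_str <- length(stride_times_ms)
  if (n_str < min_strides) {
    warning("summarize_gait: only ", n_str, " strides in block (< ",
            min_strides, ")")
  }
  out <- data.frame(n_strides = n_str)
  for (nm in names(lists)) {
    x <- lists[[nm]]
    m <- mean(x)
    if (m <= 0) stop("summarize_gait: non-positive mean for ", nm,
                     "; CV undefined")
    out[[paste0("mean_", nm)]] <- m
    out[[paste0("cv_", nm)]] <- cv_percent(x)
  }
  class(out) <- c("gait_metrics", "data.frame")
  out
}

#' Full gait analysis of one simulated or recorded block
#'
#' Convenience wrapper: detects strikes and lifts on both feet, computes
#' stride times and lengths from the right foot, step widths at right heel
#' strikes, and summarizes the block.
#'
#' @param left,right heel [marker_trajectory()] objects.
#' @param expected_stride_time seconds; passed to [detect_heel_strikes()].
#' @return list with `events` (per-foot strike/lift indices), `strides`
#'   (per-stride values), and `metrics` (a `gait_metrics` row).
#' @export
analyze_gait <- function(left, right, expected_stride_time = 1.3) {
  r_strikes <- detect_heel_strikes(right, expected_stride_time)
  r_lifts <- detect_heel_lifts(right, r_strikes)
  l_strikes <- detect_heel_strikes(left, expected_stride_time)
  l_lifts <- detect_heel_lifts(left, l_strikes)
  fs <- attr(right, "sample_rate")
  st <- compute_stride_times(r_strikes, fs)
  sl <- compute_stride_lengths(right, r_lifts, r_strikes)
  sw <- compute_step_widths(left, right, r_strikes)
  list(
    events = list(right = list(strikes = r_strikes, lifts = r_lifts),
                  left = list(strikes = l_strikes, lifts = l_lifts)),
    strides = list(stride_times_ms = st, stride_lengths_mm = sl,
                   step_widths_mm = sw),
    metrics = summarize_gait(st, sl, sw)
  )
}
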