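#' Configuration for the treadmill gait simulator
#'
#' Ground-truth parameters for a block of treadmill walking recorded by two
#' heel markers. Means and coefficients of variation (CV%) are the quantities
#' the gait module later estimates, so the simulator retains every per-stride
#' draw as ground truth.
#'
#' @param mean_stride_time mean stride duration, seconds.
#' @param mean_stride_length mean anterior-posterior heel excursion, mm.
#' @param mean_step_width mean lateral distance between heels, mm.
#' @param cv_stride_time,cv_stride_length,cv_step_width coefficients of
#'   variation of the per-stride draws, percent.
#' @param duty_factor fraction of the stride spent in stance (0-1).
#' @param n_strides number of strides to generate (>= 2).
#' @param sample_rate marker sampling rate, Hz.
#' @param seed integer seed; the simulation is deterministic given the config.
#' @return object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(mean_stride_time = 1.3,
                            mean_stride_length = 1237,
                            mean_step_width = 196,
                            cv_stride_time = 3,
                            cv_stride_length = 3,
                            cv_step_width = 9,
                            duty_factor = 0.62,
                            n_strides = 100,
                            sample_rate = 100,
                            seed = 1L) {
  stopifnot(
    mean_stride_time > 0, mean_stride_length > 0, mean_step_width > 0,
    cv_stride_time >= 0, cv_stride_length >= 0, cv_step_width >= 0,
    duty_factor > 0, duty_factor < 1,
    n_strides >= 2, sample_rate > 0
  )
  structure(
    list(
      mean_stride_time = mean_stride_time,
      mean_stride_length = mean_stride_length,
      mean_step_width = mean_step_width,
      cv_stride_time = cv_stride_time,
      cv_stride_length = cv_stride_length,
      cv_step_width = cv_step_width,
      duty_factor = duty_factor,
      n_strides = as.integer(n_strides),
      sample_rate = sample_rate,
      seed = as.integer(seed)
    ),
    class = "gait_sim_config"
  )
}

# positive normal draws; resample non-positive values with bounded retries
.rpos <- function(n, mean, cv, max_retry = 100L) {
  sd <- cv / 100 * mean
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_retry)) {
    bad <- x <= 0
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("could not draw positive gait parameters; CV too large?")
}

#' Simulate heel-marker trajectories for one walking block
#'
#' Generates left and right heel trajectories at `sample_rate` Hz. Within each
#' stride the anterior-posterior (AP) coordinate starts at its most anterior
#' point (+L/2, heel strike), descends piecewise-linearly during stance to the
#' most posterior point (-L/2, heel lift), and returns along a half-cosine
#' during swing to the next strike, so each stride has a unique maximum and
#' minimum by construction. The mediolateral (ML) coordinate is constant
#' within a step at +-W/2 per foot. Feet are phase-shifted by half a stride.
#'
#' @param config a [gait_sim_config()].
#' @return list with elements `left` and `right`, each a `marker_trajectory`
#'   (see [marker_trajectory()]) whose `ground_truth` attribute records the
#'   drawn stride times/lengths/widths and the true strike/lift sample
#'   indices.
#' @export
simulate_gait <- function(config) {
  stopifnot(inherits(config, "gait_sim_config"))
  set.seed(config$seed)
  feet <- list()
  half <- config$mean_stride_time / 2
  for (side in c("right", "left")) {
    offset <- if (side == "right") 0 else half
    feet[[side]] <- .simulate_foot(config, side, offset)
  }
  n <- min(nrow(feet$right$traj), nrow(feet$left$traj))
  for (side in c("right", "left")) {
    feet[[side]]$traj <- feet[[side]]$traj[seq_len(n), , drop = FALSE]
  }
  out <- list(
    left = marker_trajectory(feet$left$traj, sample_rate = config$sample_rate,
                             marker_id = "heel_left", side = "left"),
    right = marker_trajectory(feet$right$traj,
                              sample_rate = config$sample_rate,
                              marker_id = "heel_right", side = "right")
  )
  attr(out$left, "ground_truth") <- feet$left$truth
  attr(out$right, "ground_truth") <- feet$right$truth
  out
}

.simulate_foot <- function(config, side, time_offset) {
  ns <- config$n_strides
  fs <- config$sample_rate
  T_i <- .rpos(ns, config$mean_stride_time, config$cv_stride_time)
  L_i <- .rpos(ns + 1L, config$mean_stride_length, config$cv_stride_length)
  W_i <- .rpos(ns + 1L, config$mean_step_width, config$cv_step_width)
  strike_t <- time_offset + cumsum(c(0, T_i))   # ns + 1 strikes
  total <- strike_t[length(strike_t)]
  t <- seq(0, total, by = 1 / fs)
  ap <- rep(NA_real_, length(t))
  ml <- rep(NA_real_, length(t))
  z <- rep(0, length(t))
  ml_sign <- if (side == "right") 1 else -1
  # before the first strike: hold at the first anterior position
  pre <- t < strike_t[1]
  ap[pre] <- L_i[1] / 2
  ml[pre] <- ml_sign * W_i[1] / 2
  lift_t <- numeric(ns)
  for (k in seq_len(ns)) {
    t0 <- strike_t[k]
    t1 <- strike_t[k + 1]
    stance_end <- t0 + config$duty_factor * T_i[k]
    lift_t[k] <- stance_end
    idx <- which(t >= t0 & t < t1)
    tk <- t[idx]
    stance <- tk < stance_end
    apk <- numeric(length(tk))
    apk[stance] <- L_i[k] / 2 - (tk[stance] - t0) /
      (stance_end - t0) * L_i[k]
    s <- (tk[!stance] - stance_end) / (t1 - stance_end)
    apk[!stance] <- -L_i[k] / 2 +
      (L_i[k] / 2 + L_i[k + 1] / 2) * (1 - cos(pi * s)) / 2
    ap[idx] <- apk
    ml[idx] <- ml_sign * W_i[k] / 2
    z[idx][!stance] <- 30 * sin(pi * s)  # small vertical arc during swing
  }
  tail <- t >= strike_t[ns + 1]
  ap[tail] <- L_i[ns + 1] / 2
  ml[tail] <- ml_sign * W_i[ns + 1] / 2
  traj <- data.frame(time_s = t, x_mm = ml, y_mm = ap, z_mm = z)
  truth <- list(
    stride_times_s = T_i,
    stride_lengths_mm = L_i,
    half_widths_mm = W_i / 2,
    strike_samples = round(strike_t * fs) + 1L,  # 1-based sample indices
    lift_samples = round(lift_t * fs) + 1L,
    strike_times_s = strike_t,
    lift_times_s = lift_t
  )
  list(traj = traj, truth = truth)
}

#' Heel-marker trajectory container
#'
#' @param data data.frame with columns `time_s`, `x_mm` (mediolateral),
#'   `y_mm` (anterior-posterior, anterior positive), `z_mm` (vertical).
#' @param sample_rate sampling rate in Hz; samples must be uniform.
#' @param marker_id marker identifier string.
#' @param side `"left"` or `"right"`.
#' @return data.frame of class `marker_trajectory` with metadata attributes.
#' @export
marker_trajectory <- function(data, sample_rate, marker_id = "heel",
                              side = c("left", "right")) {
  side <- match.arg(side)
  stopifnot(all(c("time_s", "x_mm", "y_mm", "z_mm") %in% names(data)))
  if (nrow(data) >= 3) {
    dt <- diff(data$time_s)
    if (max(abs(dt - 1 / sample_rate)) > 1e-6 / sample_rate + 1e-9) {
      stop("marker_trajectory: samples are not uniform at sample_rate")
    }
  }
  structure(as.data.frame(data), class = c("marker_trajectory", "data.frame"),
            sample_rate = sample_rate, marker_id = marker_id, side = side)
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf("<marker_trajectory> %s (%s), %d samples @ %g Hz\n",
              attr(x, "marker_id"), attr(x, "side"), nrow(x),
              attr(x, "sample_rate")))
  invisible(x)
}
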