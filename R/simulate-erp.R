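#' ERP component template for the epoch simulator
#'
#' A component is a Gaussian time course (peak latency, temporal width)
#' multiplied by a spatial weight map that decays with great-circle distance
#' from a center electrode. Polarity conventions are enforced: N2 must be
#' negative, P2 and P3 positive.
#'
#' @param name `"P2"`, `"N2"`, or `"P3"`.
#' @param peak_latency peak time, ms post-stimulus.
#' @param peak_amplitude signed peak value at the center electrode, uV.
#' @param temporal_width Gaussian SD of the time course, ms.
#' @param spatial_center electrode label at which the component peaks.
#' @param spatial_spread angular SD of the scalp weight map, radians.
#' @return object of class `erp_component`.
#' @export
erp_component <- function(name = c("P2", "N2", "P3"), peak_latency,
                          peak_amplitude, temporal_width = 40,
                          spatial_center = NULL, spatial_spread = 0.8) {
  name <- match.arg(name)
  if (name == "N2" && peak_amplitude >= 0) {
    stop("erp_component: N2 amplitude must be negative")
  }
  if (name != "N2" && peak_amplitude <= 0) {
    stop("erp_component: ", name, " amplitude must be positive")
  }
  spatial_center <- spatial_center %||%
    switch(name, P2 = "FCz", N2 = "FCz", P3 = "CPz")
  electrode_positions(spatial_center)  # errors on unknown labels
  structure(list(name = name, peak_latency = peak_latency,
                 peak_amplitude = peak_amplitude,
                 temporal_width = temporal_width,
                 spatial_center = spatial_center,
                 spatial_spread = spatial_spread),
            class = "erp_component")
}

#' Configuration for the ERP epoch simulator
#'
#' @param channels electrode labels (subset of [electrode_positions()]);
#'   default is the full 64-channel 10-10 montage.
#' @param sample_rate Hz.
#' @param epoch_window epoch window in ms, default `c(-100, 800)`.
#' @param components list of [erp_component()] templates.
#' @param latency_jitter_sd trial-to-trial latency jitter SD, ms.
#' @param noise_sd marginal SD of the additive noise, uV.
#' @param noise_ar1 lag-1 autocorrelation of the noise (0 <= r < 1);
#'   spatially independent across channels.
#' @param n_trials_per_cell trials generated per call.
#' @param seed integer seed.
#' @return object of class `erp_sim_config`.
#' @export
erp_sim_config <- function(channels = electrode_positions()$label,
                           sample_rate = 512,
                           epoch_window = c(-100, 800),
                           components = list(),
                           latency_jitter_sd = 0,
                           noise_sd = 0,
                           noise_ar1 = 0,
                           n_trials_per_cell = 30L,
                           seed = 1L) {
  stopifnot(noise_ar1 >= 0, noise_ar1 < 1, noise_sd >= 0,
            latency_jitter_sd >= 0, n_trials_per_cell >= 1,
            sample_rate > 0, epoch_window[1] < epoch_window[2])
  electrode_positions(channels)  # validate labels
  for (cmp in components) stopifnot(inherits(cmp, "erp_component"))
  structure(list(channels = channels, sample_rate = sample_rate,
                 epoch_window = epoch_window, components = components,
                 latency_jitter_sd = latency_jitter_sd, noise_sd = noise_sd,
                 noise_ar1 = noise_ar1,
                 n_trials_per_cell = as.integer(n_trials_per_cell),
                 seed = as.integer(seed)),
            class = "erp_sim_config")
}

#' Simulate one cell of epoched EEG
#'
#' Each trial is the sum over components of a scaled Gaussian time course
#' (centered at the jittered peak latency) times a spatial weight map
#' `exp(-0.5 (angle / spread)^2)` from the component's center electrode,
#' plus lag-1 autoregressive Gaussian noise that is independent across
#' channels. Deterministic given the config and `seed`.
#'
#' @param config an [erp_sim_config()].
#' @param condition,response_type,group,participant labels attached to every
#'   trial.
#' @param amp_scale named numeric: per-component amplitude multipliers for
#'   this cell (unnamed scalar scales all components).
#' @param n_trials number of trials (default from config).
#' @param seed seed for this cell (default `config$seed`).
#' @return an `epoch_set` (see [epoch_eeg()]).
#' @export
simulate_erp_epochs <- function(config, condition = "S-NF-T",
                                response_type = "Hit", group = "TD",
                                participant = "P01", amp_scale = 1,
                                n_trials = NULL, seed = NULL) {
  stopifnot(inherits(config, "erp_sim_config"))
  set.seed(seed %||% config$seed)
  n_trials <- n_trials %||% config$n_trials_per_cell
  fs <- config$sample_rate
  lo <- ceiling(config$epoch_window[1] / 1000 * fs)
  hi <- floor(config$epoch_window[2] / 1000 * fs)
  times <- (lo:hi) / fs
  nc <- length(config$channels)
  nt <- length(times)
  pos <- electrode_positions(config$channels)
  dat <- array(0, dim = c(nc, nt, n_trials),
               dimnames = list(config$channels, NULL, NULL))
  for (cmp in config$components) {
    sc <- if (!is.null(names(amp_scale))) {
      if (cmp$name %in% names(amp_scale)) amp_scale[[cmp$name]] else 1
    } else {
      amp_scale[[1]]
    }
    ang <- electrode_angles(as.matrix(pos[, c("x", "y", "z")]),
                            electrode_positions(cmp$spatial_center)[,
                              c("x", "y", "z"), drop = FALSE])[, 1]
    w <- exp(-0.5 * (ang / cmp$spatial_spread)^2)
    jit <- stats::rnorm(n_trials, 0, config$latency_jitter_sd)
    for (tr in seq_len(n_trials)) {
      lat_s <- (cmp$peak_latency + jit[tr]) / 1000
      tc <- exp(-0.5 * ((times - lat_s) / (cmp$temporal_width / 1000))^2)
      dat[, , tr] <- dat[, , tr] +
        (cmp$peak_amplitude * sc) * tcrossprod(w, tc)
    }
  }
  if (config$noise_sd > 0) {
    a <- config$noise_ar1
    innov_sd <- config$noise_sd * sqrt(1 - a^2)
    noise <- array(stats::rnorm(nc * nt * n_trials, 0, config$noise_sd),
                   dim = c(nc, nt, n_trials))
    if (a > 0) {
      for (j in 2:nt) {
        noise[, j, ] <- a * noise[, j - 1L, ] +
          (innov_sd / config$noise_sd) * noise[, j, ]
      }
    }
    dat <- dat + noise
  }
  labels <- data.frame(condition = rep(condition, n_trials),
                       response_type = rep(response_type, n_trials),
                       group = rep(group, n_trials),
                       participant = rep(participant, n_trials))
  structure(list(data = dat, times = times, sample_rate = fs,
                 channels = config$channels, labels = labels),
            class = "epoch_set", n_dropped = 0L)
}

#' Combine epoch sets
#'
#' Concatenates trials of epoch sets sharing channels and time axes.
#'
#' @param ... `epoch_set` objects (or a single list of them).
#' @return combined `epoch_set`.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "epoch_set")) {
    sets <- sets[[1]]
  }
  stopifnot(length(sets) >= 1L)
  ref <- sets[[1]]
  for (s in sets) {
    stopifnot(inherits(s, "epoch_set"),
              identical(s$channels, ref$channels),
              length(s$times) == length(ref$times))
  }
  dat <- array(unlist(lapply(sets, function(s) s$data)),
               dim = c(dim(ref$data)[1], dim(ref$data)[2],
                       sum(vapply(sets, function(s) dim(s$data)[3],
                                  integer(1)))),
               dimnames = list(ref$channels, NULL, NULL))
  labels <- do.call(rbind, lapply(sets, function(s) s$labels))
  rownames(labels) <- NULL
  structure(list(data = dat, times = ref$times,
                 sample_rate = ref$sample_rate, channels = ref$channels,
                 labels = labels),
            class = "epoch_set", n_dropped = 0L)
}
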