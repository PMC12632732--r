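#' Continuous multichannel EEG container
#'
#' @param data channels x samples numeric matrix, microvolts.
#' @param sample_rate Hz.
#' @param channels character vector of unique electrode labels, one per row.
#' @param events optional data.frame of stimulus events (`onset_s` plus any
#'   label columns such as `type`, `condition`).
#' @return object of class `eeg_continuous`.
#' @export
eeg_continuous <- function(data, sample_rate, channels, events = NULL) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(channels), sample_rate > 0)
  if (anyDuplicated(channels)) stop("eeg_continuous: duplicate channel labels")
  dimnames(data) <- list(as.character(channels), NULL)
  structure(list(data = data, sample_rate = sample_rate,
                 channels = as.character(channels), events = events),
            class = "eeg_continuous")
}

#' @export
print.eeg_continuous <- function(x, ...) {
  cat(sprintf("<eeg_continuous> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sample_rate))
  invisible(x)
}

#' Zero-phase FIR band-pass filter
#'
#' Applies a Hamming-windowed linear-phase band-pass kernel forward and
#' backward ([signal::filtfilt()]) for zero net phase shift. The default
#' kernel length targets a transition bandwidth of `transition` Hz at the low
#' edge (approximately `3.3 / transition * sample_rate` taps); it is capped
#' so the signal is at least three times the filter order, with a warning
#' when the cap widens the transition band.
#'
#' @param eeg an [eeg_continuous()].
#' @param low,high band edges in Hz.
#' @param transition target transition bandwidth in Hz (sets the default
#'   order).
#' @param order optional even filter order overriding the default.
#' @return filtered `eeg_continuous`.
#' @export
bandpass_filter <- function(eeg, low = 0.25, high = 40, transition = 0.25,
                            order = NULL) {
  stopifnot(inherits(eeg, "eeg_continuous"), low > 0, high > low)
  fs <- eeg$sample_rate
  if (fs <= 2 * high) stop("bandpass_filter: sample rate must exceed 2*high")
  n <- ncol(eeg$data)
  if (is.null(order)) {
    order <- ceiling(3.3 / transition * fs / 2) * 2
    cap <- floor((n - 1) / 3 / 2) * 2
    if (cap < order) {
      warning("bandpass_filter: filter order capped at ", cap,
              " by signal length; transition band widened")
      order <- cap
    }
  }
  if (order < 2 || n <= 3 * order) {
    stop("bandpass_filter: signal too short for the filter padding ",
         "requirements")
  }
  b <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass",
                    window = signal::hamming(order + 1))
  out <- t(apply(eeg$data, 1, function(ch) signal::filtfilt(b, ch)))
  eeg$data <- out
  eeg
}

#' Re-reference to the channel average
#'
#' Subtracts the per-sample mean across channels from every channel, so the
#' channel sum is zero at each sample. Idempotent.
#'
#' @param eeg an [eeg_continuous()].
#' @return re-referenced `eeg_continuous`.
#' @export
average_reference <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_continuous"), nrow(eeg$data) >= 2)
  eeg$data <- sweep(eeg$data, 2, colMeans(eeg$data))
  eeg
}

# interpolation kernel g(cos angle): truncated Legendre series,
# Perrin-style spherical spline with stiffness m
.spline_g <- function(cosang, m = 4, n_terms = 20) {
  g <- array(0, dim = dim(as.matrix(cosang)))
  x <- as.matrix(cosang)
  p_prev <- matrix(1, nrow(x), ncol(x))   # P_0
  p_cur <- x                              # P_1
  for (n in seq_len(n_terms)) {
    g <- g + (2 * n + 1) / (n * (n + 1))^m * p_cur
    p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  g / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels with a spherical-spline reconstruction
#' (stiffness m = 4, truncated Legendre expansion, ridge regularization) from
#' the remaining good channels, using the idealized spherical layout of
#' [electrode_positions()].
#'
#' @param eeg an [eeg_continuous()] whose labels resolve in the layout.
#' @param bad character vector of channel labels to rebuild.
#' @param stiffness spline stiffness exponent m.
#' @param n_terms Legendre series truncation.
#' @param lambda ridge regularization added to the spline system.
#' @return `eeg_continuous` with the bad channels replaced.
#' @export
interpolate_bad_channels <- function(eeg, bad, stiffness = 4, n_terms = 20,
                                     lambda = 1e-5) {
  stopifnot(inherits(eeg, "eeg_continuous"))
  if (length(bad) == 0L) return(eeg)
  miss <- setdiff(bad, eeg$channels)
  if (length(miss) > 0) stop("unknown bad channel(s): ",
                             paste(miss, collapse = ", "))
  good <- setdiff(eeg$channels, bad)
  if (length(good) < 4L) {
    stop("interpolate_bad_channels: need at least 4 good channels")
  }
  pos <- electrode_positions(eeg$channels)
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  rownames(xyz) <- pos$label
  gi <- xyz[good, , drop = FALSE]
  bi <- xyz[bad, , drop = FALSE]
  G <- .spline_g(gi %*% t(gi), m = stiffness, n_terms = n_terms)
  Gb <- .spline_g(bi %*% t(gi), m = stiffness, n_terms = n_terms)
  ng <- length(good)
  A <- rbind(cbind(G + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  v <- eeg$data[match(good, eeg$channels), , drop = FALSE]
  sol <- solve(A, rbind(v, 0))
  cc <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1L, ]
  recon <- Gb %*% cc + matrix(c0, nrow(bi), length(c0), byrow = TRUE)
  eeg$data[match(bad, eeg$channels), ] <- recon
  eeg
}

#' Flag suspect channels (robust power outliers and flatlines)
#'
#' Candidate bad channels are those whose log total power has a robust
#' z-score (median/MAD) above `z_thresh`, or that are flat. The returned
#' labels are candidates to confirm and pass to
#' [interpolate_bad_channels()]; nothing is interpolated automatically.
#'
#' @param eeg an [eeg_continuous()].
#' @param z_thresh robust-z threshold on log channel power.
#' @return character vector of flagged channel labels (possibly empty).
#' @export
flag_bad_channels <- function(eeg, z_thresh = 5) {
  stopifnot(inherits(eeg, "eeg_continuous"))
  pw <- rowMeans(eeg$data^2)
  flat <- pw < .Machine$double.eps
  lp <- log(pmax(pw, .Machine$double.xmin))
  med <- stats::median(lp)
  madv <- stats::mad(lp)
  z <- if (madv > 0) abs(lp - med) / madv else rep(0, length(lp))
  eeg$channels[flat | z > z_thresh]
}

#' Epoch continuous EEG around stimulus onsets
#'
#' Cuts per-trial windows time-locked to stimulus onset and subtracts the
#' per-channel mean of the baseline interval. Window bounds are rounded
#' inward to whole samples (ceiling of the lower bound, floor of the upper),
#' so -100..800 ms at 512 Hz yields samples -51..409, i.e. 461 samples.
#' Events too close to the recording edge are dropped and counted.
#'
#' @param eeg an [eeg_continuous()].
#' @param events data.frame with `onset_s` plus optional label columns
#'   (`condition`, `response_type`, `group`, `participant`); defaults to
#'   `eeg$events`.
#' @param window epoch window in ms, default `c(-100, 800)`.
#' @param baseline baseline interval in ms, default `c(-100, 0)`; `NULL`
#'   disables baseline correction.
#' @return an `epoch_set`: list with `data` (channels x time x trials),
#'   `times` (s, relative to onset), `sample_rate`, `channels`, and `labels`
#'   (one row per kept trial, sorted by condition then response type).
#'   Attribute `n_dropped` counts edge-dropped events.
#' @export
epoch_eeg <- function(eeg, events = NULL, window = c(-100, 800),
                      baseline = c(-100, 0)) {
  stopifnot(inherits(eeg, "eeg_continuous"))
  if (is.null(events)) events <- eeg$events
  if (is.null(events) || nrow(events) == 0L) stop("epoch_eeg: no events")
  fs <- eeg$sample_rate
  lo <- ceiling(window[1] / 1000 * fs)
  hi <- floor(window[2] / 1000 * fs)
  times <- (lo:hi) / fs
  n_samp <- ncol(eeg$data)
  onset_samp <- round(events$onset_s * fs) + 1L
  keep <- onset_samp + lo >= 1L & onset_samp + hi <= n_samp
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("epoch_eeg: dropped ", n_dropped, " event(s) at recording edge")
  }
  if (!any(keep)) stop("epoch_eeg: no events fully inside the recording")
  events <- events[keep, , drop = FALSE]
  onset_samp <- onset_samp[keep]
  sort_cols <- intersect(c("condition", "response_type"), names(events))
  if (length(sort_cols) > 0) {
    ord <- do.call(order, events[sort_cols])
    events <- events[ord, , drop = FALSE]
    onset_samp <- onset_samp[ord]
  }
  nt <- nrow(events)
  dat <- array(NA_real_, dim = c(nrow(eeg$data), length(times), nt),
               dimnames = list(eeg$channels, NULL, NULL))
  if (!is.null(baseline)) {
    bsel <- times >= baseline[1] / 1000 & times <= baseline[2] / 1000
    if (!any(bsel)) stop("epoch_eeg: baseline interval contains no samples")
  }
  for (i in seq_len(nt)) {
    seg <- eeg$data[, (onset_samp[i] + lo):(onset_samp[i] + hi),
                    drop = FALSE]
    if (!is.null(baseline)) {
      seg <- seg - rowMeans(seg[, bsel, drop = FALSE])
    }
    dat[, , i] <- seg
  }
  labels <- events[, setdiff(names(events), "onset_s"), drop = FALSE]
  rownames(labels) <- NULL
  structure(list(data = dat, times = times, sample_rate = fs,
                 channels = eeg$channels, labels = labels),
            class = "epoch_set", n_dropped = n_dropped)
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d channels x %d samples x %d trials @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sample_rate))
  invisible(x)
}

# select trials of an epoch_set by label values (NULL = keep all)
.select_trials <- function(epochs, condition = NULL, response_type = NULL,
                           group = NULL, participant = NULL) {
  keep <- rep(TRUE, dim(epochs$data)[3])
  for (col in c("condition", "response_type", "group", "participant")) {
    val <- get(col)
    if (!is.null(val)) {
      if (!col %in% names(epochs$labels)) {
        stop("epoch labels have no column '", col, "'")
      }
      keep <- keep & epochs$labels[[col]] %in% val
    }
  }
  keep
}

#' Per-participant average waveforms
#'
#' Averages trials within each participant for the selected cell. This is the
#' unit on which grand averages and pointwise t-tests operate.
#'
#' @param epochs an `epoch_set` whose labels include `participant`.
#' @inheritParams grand_average
#' @return array participants x channels x time (participant dimnames set).
#' @export
participant_averages <- function(epochs, condition = NULL,
                                 response_type = NULL, group = NULL) {
  stopifnot(inherits(epochs, "epoch_set"),
            "participant" %in% names(epochs$labels))
  keep <- .select_trials(epochs, condition, response_type, group)
  if (!any(keep)) stop("participant_averages: empty cell")
  ids <- unique(epochs$labels$participant[keep])
  out <- array(NA_real_,
               dim = c(length(ids), dim(epochs$data)[1], dim(epochs$data)[2]),
               dimnames = list(ids, epochs$channels, NULL))
  for (i in seq_along(ids)) {
    sel <- keep & epochs$labels$participant == ids[i]
    out[i, , ] <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  }
  out
}

#' Grand-average ERP
#'
#' Participant-level averages are formed first, then averaged across
#' participants with equal weight regardless of trial counts.
#'
#' @param epochs an `epoch_set`.
#' @param condition,response_type,group optional label filters.
#' @return an `erp_average`: list with `data` (channels x time), `times`,
#'   `sample_rate`, `channels`, `n` (participants), `labels`.
#' @export
grand_average <- function(epochs, condition = NULL, response_type = NULL,
                          group = NULL) {
  if ("participant" %in% names(epochs$labels)) {
    pa <- participant_averages(epochs, condition, response_type, group)
    dat <- apply(pa, c(2, 3), mean)
    n <- dim(pa)[1]
  } else {
    keep <- .select_trials(epochs, condition, response_type, group)
    if (!any(keep)) stop("grand_average: empty cell")
    dat <- apply(epochs$data[, , keep, drop = FALSE], c(1, 2), mean)
    n <- sum(keep)
  }
  erp_average(dat, epochs$times, epochs$sample_rate, epochs$channels, n,
              labels = list(condition = condition,
                            response_type = response_type, group = group))
}

#' Averaged-ERP container
#'
#' @param data channels x time matrix, microvolts.
#' @param times time axis in seconds relative to stimulus onset.
#' @param sample_rate Hz.
#' @param channels electrode labels.
#' @param n number of participants (or trials) contributing.
#' @param labels metadata list.
#' @return object of class `erp_average`.
#' @export
erp_average <- function(data, times, sample_rate, channels, n = NA_integer_,
                        labels = list()) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(channels), ncol(data) == length(times),
            all(is.finite(data)))
  structure(list(data = data, times = times, sample_rate = sample_rate,
                 channels = as.character(channels), n = n, labels = labels),
            class = "erp_average")
}

#' Difference wave (Correct Rejections minus Hits)
#'
#' @param cr_avg,hit_avg `erp_average` objects with identical channels and
#'   time axes.
#' @return `erp_average` of the elementwise difference `cr_avg - hit_avg`.
#' @export
difference_wave <- function(cr_avg, hit_avg) {
  stopifnot(inherits(cr_avg, "erp_average"), inherits(hit_avg, "erp_average"))
  if (!identical(cr_avg$channels, hit_avg$channels) ||
      length(cr_avg$times) != length(hit_avg$times) ||
      max(abs(cr_avg$times - hit_avg$times)) > 1e-9) {
    stop("difference_wave: channel/time axes do not match")
  }
  erp_average(cr_avg$data - hit_avg$data, cr_avg$times, cr_avg$sample_rate,
              cr_avg$channels, n = min(cr_avg$n, hit_avg$n),
              labels = utils::modifyList(cr_avg$labels,
                                         list(response_type = "CR-Hit")))
}

#' ERP component definition
#'
#' Default electrode, latency window, and polarity for the P2, N2, and P3
#' components of the Go/NoGo task: P2 at FCz 200-280 ms (positive), N2 at FCz
#' 280-380 ms (negative), P3 at CPz 350-500 ms (positive). Topographic
#' half-widths are +-25 ms for P2/N2 and +-50 ms for the prolonged P3.
#' Group-adjusted latency windows can be supplied via `window`.
#'
#' @param name `"P2"`, `"N2"`, or `"P3"`.
#' @param electrode override the default electrode.
#' @param window override the default latency window, ms.
#' @param topo_halfwidth override the topographic half-width, ms.
#' @return object of class `component_spec`.
#' @export
#' @examples
#' component_spec("P3")
#' component_spec("P3", window = c(363, 463))  # group-adjusted window
component_spec <- function(name = c("P2", "N2", "P3"), electrode = NULL,
                           window = NULL, topo_halfwidth = NULL) {
  name <- match.arg(name)
  defaults <- list(
    P2 = list(electrode = "FCz", window = c(200, 280), polarity = 1,
              topo_halfwidth = 25),
    N2 = list(electrode = "FCz", window = c(280, 380), polarity = -1,
              topo_halfwidth = 25),
    P3 = list(electrode = "CPz", window = c(350, 500), polarity = 1,
              topo_halfwidth = 50)
  )[[name]]
  spec <- list(
    name = name,
    electrode = electrode %||% defaults$electrode,
    window = window %||% defaults$window,
    polarity = defaults$polarity,
    topo_halfwidth = topo_halfwidth %||% defaults$topo_halfwidth
  )
  stopifnot(length(spec$window) == 2L, spec$window[1] < spec$window[2])
  structure(spec, class = "component_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Peak amplitude and latency of an ERP component
#'
#' Finds the signed extremum (maximum for positive components, minimum for
#' negative) of the specified electrode's waveform within the component
#' window. Ties break to the earliest sample. A peak landing on the window
#' edge is flagged as a boundary peak.
#'
#' @param avg an `erp_average`.
#' @param spec a [component_spec()].
#' @return data.frame with `component`, `electrode`, `amplitude` (uV),
#'   `latency_ms`, and `boundary` (logical).
#' @export
extract_peak <- function(avg, spec) {
  stopifnot(inherits(avg, "erp_average"), inherits(spec, "component_spec"))
  ch <- match(spec$electrode, avg$channels)
  if (is.na(ch)) stop("extract_peak: electrode ", spec$electrode,
                      " not present")
  sel <- which(avg$times * 1000 >= spec$window[1] &
               avg$times * 1000 <= spec$window[2])
  if (length(sel) == 0L) stop("extract_peak: window outside epoch")
  w <- avg$data[ch, sel] * spec$polarity
  k <- which.max(w)   # earliest tie
  data.frame(
    component = spec$name, electrode = spec$electrode,
    amplitude = avg$data[ch, sel[k]],
    latency_ms = avg$times[sel[k]] * 1000,
    boundary = k == 1L || k == length(sel)
  )
}

#' Per-channel mean over a topographic time window
#'
#' @param avg an `erp_average`.
#' @param center window center, ms.
#' @param halfwidth half-width, ms; `0` returns the nearest-sample value.
#' @return named numeric vector, one mean per channel.
#' @export
topographic_window_mean <- function(avg, center, halfwidth) {
  stopifnot(inherits(avg, "erp_average"), halfwidth >= 0)
  t_ms <- avg$times * 1000
  if (center - halfwidth < min(t_ms) - 1e-9 ||
      center + halfwidth > max(t_ms) + 1e-9) {
    stop("topographic_window_mean: window outside epoch")
  }
  if (halfwidth == 0) {
    sel <- which.min(abs(t_ms - center))
  } else {
    sel <- which(t_ms >= center - halfwidth & t_ms <= center + halfwidth)
  }
  out <- rowMeans(avg$data[, sel, drop = FALSE])
  names(out) <- avg$channels
  out
}
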