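#' Write marker trajectories to a long-format motion TSV
#'
#' Columns: `time_s`, `marker_id`, `x_mm`, `y_mm`, `z_mm`.
#'
#' @param trajectories list of [marker_trajectory()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motion <- function(trajectories, path) {
  rows <- lapply(trajectories, function(tr) {
    stopifnot(inherits(tr, "marker_trajectory"))
    data.frame(time_s = tr$time_s, marker_id = attr(tr, "marker_id"),
               x_mm = tr$x_mm, y_mm = tr$y_mm, z_mm = tr$z_mm)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format motion TSV
#'
#' Expects header `time_s, marker_id, x_mm, y_mm, z_mm`. Per marker the time
#' stamps must be strictly increasing on a uniform grid; gaps of at most
#' `max_gap` missing samples are filled by linear interpolation (and
#' flagged), longer gaps keep the longest contiguous segment with a warning.
#'
#' @param path motion TSV file.
#' @param max_gap longest gap (in samples) to interpolate.
#' @return named list of [marker_trajectory()] objects; each carries a
#'   `n_filled` attribute counting interpolated samples.
#' @export
read_motion <- function(path, max_gap = 5L) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_s", "marker_id", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(raw))) {
    stop("read_motion: expected columns ", paste(need, collapse = ", "))
  }
  out <- list()
  for (id in unique(raw$marker_id)) {
    d <- raw[raw$marker_id == id, , drop = FALSE]
    if (anyDuplicated(d$time_s)) {
      stop("read_motion: duplicated timestamp for marker ", id)
    }
    if (any(diff(d$time_s) <= 0)) {
      stop("read_motion: non-monotone time for marker ", id)
    }
    dt <- stats::median(diff(d$time_s))
    fs <- 1 / dt
    grid_idx <- round((d$time_s - d$time_s[1]) / dt)
    n_grid <- grid_idx[length(grid_idx)] + 1L
    gaps <- diff(grid_idx) - 1L
    if (any(gaps > max_gap)) {
      # keep the longest contiguous run of short-gapped samples
      brk <- which(gaps > max_gap)
      bounds <- c(0L, brk, length(grid_idx))
      lens <- diff(bounds)
      seg <- which.max(lens)
      keep <- (bounds[seg] + 1L):bounds[seg + 1L]
      warning("read_motion: marker ", id, " has a gap > ", max_gap,
              " samples; keeping the longest contiguous segment (",
              length(keep), " rows)")
      d <- d[keep, , drop = FALSE]
      grid_idx <- round((d$time_s - d$time_s[1]) / dt)
      n_grid <- grid_idx[length(grid_idx)] + 1L
    }
    full_t <- d$time_s[1] + (seq_len(n_grid) - 1L) * dt
    n_filled <- n_grid - nrow(d)
    interp <- function(col) {
      stats::approx(d$time_s, d[[col]], xout = full_t, rule = 2)$y
    }
    filled <- data.frame(time_s = full_t, x_mm = interp("x_mm"),
                         y_mm = interp("y_mm"), z_mm = interp("z_mm"))
    side <- if (grepl("left", id, ignore.case = TRUE)) "left" else "right"
    tr <- marker_trajectory(filled, sample_rate = fs, marker_id = id,
                            side = side)
    attr(tr, "n_filled") <- n_filled
    out[[id]] <- tr
  }
  out
}

#' Write an event stream to TSV
#'
#' Columns: `onset_s`, `event_type` (`stimulus` / `response`), `code`
#' (`Go` / `NoGo` / `press`).
#'
#' @param events an [event_stream()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_stream"))
  tab <- rbind(
    data.frame(onset_s = events$stimuli$onset_s, event_type = "stimulus",
               code = events$stimuli$type),
    data.frame(onset_s = events$responses$time_s, event_type = "response",
               code = "press")
  )
  tab <- tab[order(tab$onset_s), ]
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event stream from TSV
#'
#' @param path events TSV with columns `onset_s`, `event_type`, `code`.
#' @return an [event_stream()].
#' @export
read_events <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "event_type", "code")
  if (!all(need %in% names(raw))) {
    stop("read_events: expected columns ", paste(need, collapse = ", "))
  }
  stim <- raw[raw$event_type == "stimulus", , drop = FALSE]
  resp <- raw[raw$event_type == "response", , drop = FALSE]
  event_stream(
    stimuli = data.frame(onset_s = stim$onset_s, type = stim$code),
    responses = data.frame(time_s = resp$onset_s)
  )
}

#' Write electrode locations to TSV
#'
#' @param positions data.frame as returned by [electrode_positions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_electrode_locations <- function(positions, path) {
  utils::write.table(positions[, c("label", "theta_deg", "azimuth_deg")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read electrode locations from TSV
#'
#' @param path TSV with columns `label`, `theta_deg`, `azimuth_deg`.
#' @return data.frame with `label`, unit-vector `x`, `y`, `z`, and the
#'   spherical angles.
#' @export
read_electrode_locations <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "theta_deg", "azimuth_deg")
  if (!all(need %in% names(raw))) {
    stop("read_electrode_locations: expected columns ",
         paste(need, collapse = ", "))
  }
  xyz <- .sph_to_xyz(raw$theta_deg, raw$azimuth_deg)
  data.frame(label = raw$label, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             theta_deg = raw$theta_deg, azimuth_deg = raw$azimuth_deg)
}

#' Write continuous EEG as a delimited channel matrix
#'
#' Samples are rows, channels are columns (header = labels). A YAML sidecar
#' `<path>.yaml` records the sample rate.
#'
#' @param eeg an [eeg_continuous()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_eeg_matrix <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_continuous"))
  m <- t(eeg$data)
  colnames(m) <- eeg$channels
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(sample_rate = eeg$sample_rate),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read continuous EEG from a delimited matrix plus locations file
#'
#' @param path TSV with one column per channel (header = labels), one row
#'   per sample.
#' @param locations_path electrode-locations TSV
#'   (see [read_electrode_locations()]); every data label must resolve, and
#'   channels are reordered to the locations file.
#' @param sample_rate optional Hz; defaults to the `<path>.yaml` sidecar.
#' @return an [eeg_continuous()].
#' @export
read_eeg <- function(path, locations_path, sample_rate = NULL) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  loc <- read_electrode_locations(locations_path)
  miss <- setdiff(colnames(m), loc$label)
  if (length(miss) > 0) {
    stop("read_eeg: no location for channel(s): ",
         paste(miss, collapse = ", "))
  }
  if (is.null(sample_rate)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar)) {
      stop("read_eeg: sample_rate not given and sidecar ", sidecar,
           " not found")
    }
    sample_rate <- yaml::read_yaml(sidecar)$sample_rate
  }
  order_labels <- loc$label[loc$label %in% colnames(m)]
  eeg_continuous(t(m[, order_labels, drop = FALSE]), sample_rate,
                 order_labels)
}
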