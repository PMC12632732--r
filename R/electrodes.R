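#' Idealized spherical 10-10 electrode layout
#'
#' Returns scalp positions for the 64-channel extended 10-20 ("10-10") montage
#' on an idealized unit sphere. Anchor electrodes (midline and the 10%
#' circumference ring) are placed at 18-degree steps; interior rows are filled
#' by spherical linear interpolation between the midline and outer-ring anchor
#' of the same row. Coordinates use x = right, y = anterior, z = vertex.
#'
#' The geometry is deliberately idealized: it is used for simulating spatial
#' component topographies, for spherical-spline interpolation, and for
#' plotting -- none of which require subject-specific head shapes.
#'
#' @param labels optional character vector; restrict and order the table to
#'   these labels (error if any is unknown).
#' @return data.frame with columns `label`, `x`, `y`, `z` (unit vectors),
#'   `theta_deg` (polar angle from the vertex) and `azimuth_deg`
#'   (0 = anterior midline, positive toward the right ear, +-180 = inion).
#' @export
#' @examples
#' head(electrode_positions())
#' electrode_positions(c("FCz", "CPz"))
electrode_positions <- function(labels = NULL) {
  tab <- .electrode_table()
  if (!is.null(labels)) {
    miss <- setdiff(labels, tab$label)
    if (length(miss) > 0L) {
      stop("unknown electrode label(s): ", paste(miss, collapse = ", "))
    }
    tab <- tab[match(labels, tab$label), , drop = FALSE]
    rownames(tab) <- NULL
  }
  tab
}

# polar/azimuth (degrees) -> unit vector
.sph_to_xyz <- function(theta_deg, az_deg) {
  th <- theta_deg * pi / 180
  az <- az_deg * pi / 180
  cbind(x = sin(th) * sin(az), y = sin(th) * cos(az), z = cos(th))
}

# spherical linear interpolation between unit vectors u and v at fraction f
.slerp <- function(u, v, f) {
  om <- acos(pmin(1, pmax(-1, sum(u * v))))
  if (om < 1e-12) return(u)
  (sin((1 - f) * om) * u + sin(f * om) * v) / sin(om)
}

.electrode_table <- function() {
  anchors <- list()
  add <- function(lst, label, theta, az) {
    lst[[label]] <- .sph_to_xyz(theta, az)[1, ]
    lst
  }
  # midline, nasion-inion arc in 10% (18 degree) steps
  mid <- c(Fpz = 0, AFz = 1, Fz = 2, FCz = 3, Cz = 4, CPz = 5, Pz = 6,
           POz = 7, Oz = 8)
  for (lab in names(mid)) {
    step <- mid[[lab]]
    theta <- abs(72 - 18 * step)
    az <- if (step <= 4) 0 else 180
    anchors <- add(anchors, lab, theta, az)
  }
  # outer ring at polar 72, 18-degree azimuth steps (right positive)
  ring <- c(Fp = 1, AF = 2, F = 3, FT = 4, T = 5, TP = 6, P = 7, PO = 8,
            O = 9)
  ring_lab <- c(Fp = "Fp", AF = "AF", F = "F", FT = "FT", T = "T", TP = "TP",
                P = "P", PO = "PO", O = "O")
  ring_num <- list(Fp = c(1, 2), AF = c(7, 8), F = c(7, 8), FT = c(7, 8),
                   T = c(7, 8), TP = c(7, 8), P = c(7, 8), PO = c(7, 8),
                   O = c(1, 2))
  for (row in names(ring)) {
    az <- 18 * ring[[row]]
    nums <- ring_num[[row]]
    anchors <- add(anchors, paste0(ring_lab[[row]], nums[1]), 72, -az) # left
    anchors <- add(anchors, paste0(ring_lab[[row]], nums[2]), 72, az)  # right
  }
  # interior rows: slerp midline anchor -> outer anchor of the same row
  interior <- list(
    F  = list(mid = "Fz",  outer = c("F7", "F8"),   nums = c(1, 3, 5), den = 4),
    FC = list(mid = "FCz", outer = c("FT7", "FT8"), nums = c(1, 3, 5), den = 4),
    C  = list(mid = "Cz",  outer = c("T7", "T8"),   nums = c(1, 3, 5), den = 4),
    CP = list(mid = "CPz", outer = c("TP7", "TP8"), nums = c(1, 3, 5), den = 4),
    P  = list(mid = "Pz",  outer = c("P7", "P8"),   nums = c(1, 3, 5), den = 4),
    AF = list(mid = "AFz", outer = c("AF7", "AF8"), nums = 3, den = 2),
    PO = list(mid = "POz", outer = c("PO7", "PO8"), nums = 3, den = 2)
  )
  for (row in names(interior)) {
    info <- interior[[row]]
    u <- anchors[[info$mid]]
    for (side in 1:2) {
      v <- anchors[[info$outer[side]]]
      for (k in seq_along(info$nums)) {
        f <- k / info$den
        num <- info$nums[k] + (side == 2) # odd left, even right
        anchors[[paste0(row, num)]] <- .slerp(u, v, f)
      }
    }
  }
  # below-ring positions
  anchors <- add(anchors, "P9", 90, -126)
  anchors <- add(anchors, "P10", 90, 126)
  anchors <- add(anchors, "Iz", 90, 180)

  order64 <- c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5",
               "FC3", "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3",
               "CP1", "P1", "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz",
               "Oz", "POz", "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz",
               "Fz", "F2", "F4", "F6", "F8", "FT8", "FC6", "FC4", "FC2",
               "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6", "CP4",
               "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
  xyz <- t(vapply(order64, function(l) anchors[[l]], numeric(3)))
  xyz <- xyz / sqrt(rowSums(xyz^2))
  data.frame(
    label = order64,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    theta_deg = acos(pmin(1, pmax(-1, xyz[, 3]))) * 180 / pi,
    azimuth_deg = atan2(xyz[, 1], xyz[, 2]) * 180 / pi,
    row.names = NULL
  )
}

#' Great-circle angular distances between electrodes
#'
#' @param from,to electrode labels or n x 3 matrices of unit vectors.
#' @return matrix of central angles in radians, `length(from)` x `length(to)`.
#' @export
electrode_angles <- function(from, to = from) {
  as_xyz <- function(v) {
    if (is.character(v)) {
      p <- electrode_positions(v)
      as.matrix(p[, c("x", "y", "z")])
    } else {
      m <- as.matrix(v)
      m / sqrt(rowSums(m^2))
    }
  }
  a <- as_xyz(from)
  b <- as_xyz(to)
  cosang <- a %*% t(b)
  cosang[] <- pmin(1, pmax(-1, cosang))
  acos(cosang)
}
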