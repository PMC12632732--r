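#' Pointwise paired t-map across channels and time
#'
#' Two-tailed paired t-test at every channel x sample on per-participant
#' average waveforms (e.g. Hits vs Correct Rejections). Samples with zero
#' difference variance get t = 0 and are flagged never-significant.
#'
#' @param a,b participants x channels x time arrays (as returned by
#'   [participant_averages()]) with the same participants in the same order.
#' @param times time axis in seconds (length = 3rd dimension).
#' @param sample_rate Hz.
#' @return a `t_map`: list with `t`, `p` (channels x time), `df`,
#'   `contrast = "paired"`, `zero_variance` mask, `times`, `sample_rate`,
#'   `channels`.
#' @export
pointwise_paired_t <- function(a, b, times, sample_rate) {
  stopifnot(length(dim(a)) == 3L, identical(dim(a), dim(b)))
  if (!is.null(dimnames(a)[[1]]) && !is.null(dimnames(b)[[1]]) &&
      !identical(dimnames(a)[[1]], dimnames(b)[[1]])) {
    stop("pointwise_paired_t: participant sets differ")
  }
  n <- dim(a)[1]
  if (n < 3L) stop("pointwise_paired_t: need at least 3 participants")
  d <- a - b
  m <- colMeans(d)                       # channels x time
  v <- (colMeans(d^2) - m^2) * n / (n - 1)
  v[v < 0] <- 0
  zero <- v <= .Machine$double.eps * pmax(m^2, 1)
  tval <- matrix(0, nrow(m), ncol(m))
  tval[!zero] <- m[!zero] / sqrt(v[!zero] / n)
  .t_map(tval, df = n - 1L, contrast = "paired", zero = zero,
         times = times, sample_rate = sample_rate,
         channels = dimnames(a)[[2]])
}

#' Pointwise independent-groups t-map
#'
#' Two-sample pooled-variance t at every channel x sample, typically applied
#' to per-participant difference waves (CR minus Hit) from two groups.
#'
#' @param group_a,group_b participants x channels x time arrays.
#' @inheritParams pointwise_paired_t
#' @return a `t_map` with `contrast = "independent"` and
#'   `df = nA + nB - 2`.
#' @export
pointwise_independent_t <- function(group_a, group_b, times, sample_rate) {
  stopifnot(length(dim(group_a)) == 3L, length(dim(group_b)) == 3L,
            identical(dim(group_a)[2:3], dim(group_b)[2:3]))
  na <- dim(group_a)[1]
  nb <- dim(group_b)[1]
  if (na < 2L || nb < 2L) {
    stop("pointwise_independent_t: need at least 2 participants per group")
  }
  ma <- colMeans(group_a)
  mb <- colMeans(group_b)
  va <- (colMeans(group_a^2) - ma^2) * na / (na - 1)
  vb <- (colMeans(group_b^2) - mb^2) * nb / (nb - 1)
  va[va < 0] <- 0
  vb[vb < 0] <- 0
  pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  zero <- pooled <= .Machine$double.eps * pmax((ma - mb)^2, 1)
  se <- sqrt(pooled * (1 / na + 1 / nb))
  tval <- matrix(0, nrow(ma), ncol(ma))
  tval[!zero] <- (ma - mb)[!zero] / se[!zero]
  .t_map(tval, df = na + nb - 2L, contrast = "independent", zero = zero,
         times = times, sample_rate = sample_rate,
         channels = dimnames(group_a)[[2]])
}

.t_map <- function(tval, df, contrast, zero, times, sample_rate, channels) {
  p <- 2 * stats::pt(-abs(tval), df)
  p[zero] <- 1
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(tval)))
  dimnames(tval) <- dimnames(p) <- list(channels, NULL)
  structure(list(t = tval, p = p, df = df, contrast = contrast,
                 zero_variance = zero, times = times,
                 sample_rate = sample_rate, channels = channels),
            class = "t_map")
}

#' @export
print.t_map <- function(x, ...) {
  cat(sprintf("<t_map> %s, df = %d, %d channels x %d samples\n",
              x$contrast, x$df, nrow(x$t), ncol(x$t)))
  invisible(x)
}

#' Consecutivity-based significant clusters
#'
#' Scans each channel for maximal runs of consecutive samples with
#' `p < alpha` and constant t sign, and reports runs of at least `min_run`
#' samples. A sign flip splits a run even when p stays below alpha, since it
#' marks a reversal of the effect direction. At 512 Hz the default
#' `min_run = 10` corresponds to about 19.5 ms.
#'
#' @param tmap a `t_map`.
#' @param alpha pointwise two-tailed significance threshold.
#' @param min_run minimum run length in samples.
#' @return data.frame with one row per cluster: `channel`, `start_ms`,
#'   `end_ms`, `length`, `mean_t`, `peak_t`, `sign`.
#' @export
find_clusters <- function(tmap, alpha = 0.05, min_run = 10L) {
  stopifnot(inherits(tmap, "t_map"), alpha > 0, alpha < 1, min_run >= 1)
  t_ms <- tmap$times * 1000
  res <- list()
  for (ch in seq_len(nrow(tmap$t))) {
    sig <- tmap$p[ch, ] < alpha & !tmap$zero_variance[ch, ]
    state <- ifelse(sig, sign(tmap$t[ch, ]), 0)
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      if (r$values[k] != 0 && r$lengths[k] >= min_run) {
        i0 <- starts[k]
        i1 <- ends[k]
        tv <- tmap$t[ch, i0:i1]
        res[[length(res) + 1L]] <- data.frame(
          channel = tmap$channels[ch],
          start_ms = t_ms[i0], end_ms = t_ms[i1],
          length = i1 - i0 + 1L,
          mean_t = mean(tv), peak_t = tv[which.max(abs(tv))],
          sign = ifelse(r$values[k] > 0, "+", "-")
        )
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(channel = character(), start_ms = numeric(),
                      end_ms = numeric(), length = integer(),
                      mean_t = numeric(), peak_t = numeric(),
                      sign = character()))
  }
  do.call(rbind, res)
}

#' Channels x time significance mask
#'
#' @param tmap a `t_map`.
#' @param clusters output of [find_clusters()]; only samples inside reported
#'   clusters are marked.
#' @return integer matrix (channels x time) with values -1, 0, +1.
#' @export
cluster_mask <- function(tmap, clusters) {
  mask <- matrix(0L, nrow(tmap$t), ncol(tmap$t),
                 dimnames = dimnames(tmap$t))
  t_ms <- tmap$times * 1000
  for (i in seq_len(nrow(clusters))) {
    ch <- match(clusters$channel[i], tmap$channels)
    sel <- t_ms >= clusters$start_ms[i] & t_ms <= clusters$end_ms[i]
    mask[ch, sel] <- if (clusters$sign[i] == "+") 1L else -1L
  }
  mask
}
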