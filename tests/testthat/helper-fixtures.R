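# shared builders for small in-code fixtures

# noiseless gait config whose stance end lands exactly on the sample grid
noiseless_gait_config <- function(n_strides = 20, seed = 1L) {
  gait_sim_config(
    mean_stride_time = 1.2, mean_stride_length = 600, mean_step_width = 200,
    cv_stride_time = 0, cv_stride_length = 0, cv_step_width = 0,
    duty_factor = 0.625, n_strides = n_strides, seed = seed
  )
}

# minimal t_map for synthetic cluster grids
make_tmap <- function(tmat, df, sample_rate = 512) {
  tmat <- as.matrix(tmat)
  p <- 2 * pt(-abs(tmat), df)
  zero <- matrix(FALSE, nrow(tmat), ncol(tmat))
  channels <- paste0("ch", seq_len(nrow(tmat)))
  dimnames(tmat) <- dimnames(p) <- list(channels, NULL)
  structure(list(t = tmat, p = p, df = df, contrast = "paired",
                 zero_variance = zero,
                 times = (seq_len(ncol(tmat)) - 1) / sample_rate,
                 sample_rate = sample_rate, channels = channels),
            class = "t_map")
}

# brute-force cluster oracle: enumerate maximal same-sign significant runs
brute_force_clusters <- function(tmap, alpha = 0.05, min_run = 10L) {
  out <- list()
  for (ch in seq_len(nrow(tmap$t))) {
    sig <- tmap$p[ch, ] < alpha & !tmap$zero_variance[ch, ]
    sgn <- sign(tmap$t[ch, ])
    n <- length(sig)
    i <- 1L
    while (i <= n) {
      if (sig[i]) {
        j <- i
        while (j < n && sig[j + 1L] && sgn[j + 1L] == sgn[i]) j <- j + 1L
        if (j - i + 1L >= min_run) {
          out[[length(out) + 1L]] <- data.frame(
            channel = tmap$channels[ch], start = i, end = j,
            sign = ifelse(sgn[i] > 0, "+", "-"))
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(channel = character(), start = integer(),
                      end = integer(), sign = character()))
  }
  do.call(rbind, out)
}

# long-format split-plot dataset with known factor structure
make_splitplot_data <- function(n_per_group = 6, k_within = 3, seed = 1L,
                                effect = 0) {
  set.seed(seed)
  n <- 2 * n_per_group
  d <- expand.grid(participant = sprintf("s%02d", seq_len(n)),
                   condition = paste0("c", seq_len(k_within)))
  d$group <- rep(rep(c("TD", "ASD"), each = n_per_group), k_within)
  d$value <- rnorm(nrow(d)) +
    effect * as.numeric(factor(d$condition)) * (d$group == "TD")
  d
}
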