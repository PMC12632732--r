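#' Split-plot repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate mixed ("split-plot") ANOVA for designs with one or more
#' crossed within-subject factors and an optional between-subjects grouping
#' factor with possibly unequal group sizes. Each within-involving effect is
#' tested by projecting the subject x cell matrix onto orthonormal contrasts
#' for that effect and fitting the between design (effect-coded, so the
#' between factor is tested with Type III sums of squares). The
#' Greenhouse-Geisser epsilon is estimated from the contrast-projected
#' residual covariance M as `(tr M)^2 / (c * tr M^2)` with `c` the number of
#' contrasts, clamped to `[1/c, 1]`, and is exactly 1 whenever `c = 1`
#' (e.g. a two-level factor). Mauchly's sphericity test is reported per
#' within stratum; both uncorrected and GG-corrected p-values are returned
#' so that the correction can be applied "where appropriate".
#'
#' @param data long-format data.frame: one row per subject x within-cell.
#' @param dv name of the numeric response column.
#' @param within character vector of within-subject factor column names.
#' @param between optional name of the between-subjects factor column.
#' @param subject name of the subject identifier column.
#' @return data.frame of class `rm_anova` with one row per effect: `effect`,
#'   `df1`, `df2` (uncorrected), `F`, `p` (uncorrected), `gg_epsilon`,
#'   `p_gg`, `pes` (partial eta squared), `mauchly_p`.
#' @export
#' @examples
#' d <- expand.grid(participant = factor(1:8), condition = factor(1:3))
#' d$value <- rnorm(nrow(d)) + as.numeric(d$condition)
#' rm_anova(d, "value", within = "condition")
rm_anova <- function(data, dv = "value", within, between = NULL,
                     subject = "participant") {
  stopifnot(is.data.frame(data), dv %in% names(data),
            all(within %in% names(data)), subject %in% names(data))
  if (!is.null(between)) stopifnot(between %in% names(data))
  data <- as.data.frame(data)
  for (col in c(within, between, subject)) data[[col]] <- factor(data[[col]])
  w_levels <- lapply(data[within], levels)
  k_f <- vapply(w_levels, length, integer(1))
  cells <- do.call(expand.grid,
                   c(w_levels, list(KEEP.OUT.ATTRS = FALSE,
                                    stringsAsFactors = TRUE)))
  names(cells) <- within
  cell_id <- interaction(cells[within], drop = FALSE, lex.order = FALSE)
  obs_id <- interaction(data[within], drop = FALSE, lex.order = FALSE)
  subj <- levels(data[[subject]])
  n <- length(subj)
  # subject x cell response matrix; error on missing or duplicated cells
  Y <- matrix(NA_real_, n, nrow(cells),
              dimnames = list(subj, as.character(cell_id)))
  idx <- cbind(match(data[[subject]], subj),
               match(as.character(obs_id), as.character(cell_id)))
  if (anyDuplicated(idx)) {
    stop("rm_anova: more than one observation per subject x cell")
  }
  Y[idx] <- data[[dv]]
  if (anyNA(Y)) stop("rm_anova: incomplete within-subject design")

  # between design, effect-coded (Type III for the between factor)
  if (!is.null(between)) {
    gmap <- tapply(as.character(data[[between]]),
                   data[[subject]], function(x) {
                     u <- unique(x)
                     if (length(u) != 1L) {
                       stop("rm_anova: subject in more than one group")
                     }
                     u
                   })
    grp <- factor(gmap[subj])
    if (any(table(grp) < 2L)) {
      stop("rm_anova: need at least 2 subjects per group")
    }
    X <- stats::model.matrix(~grp,
                             contrasts.arg = list(grp = stats::contr.sum))
  } else {
    X <- matrix(1, n, 1)
  }
  p_x <- ncol(X)
  XtXi <- solve(crossprod(X))

  # orthonormal contrast columns per factor (and unit vector when averaged)
  contr <- lapply(k_f, function(k) stats::contr.poly(k))
  ones <- lapply(k_f, function(k) matrix(1 / sqrt(k), k, 1))

  # cell ordering follows expand.grid (first factor fastest): the projection
  # over cells is kron(last factor, ..., first factor)
  proj_for <- function(in_term) {
    M <- matrix(1, 1, 1)
    for (i in rev(seq_along(within))) {
      M <- M %x% (if (in_term[i]) contr[[i]] else ones[[i]])
    }
    M
  }

  ss_h <- function(B, U, L) {
    LB <- L %*% B
    H <- t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
    sum(diag(H))
  }

  test_stratum <- function(C_mat, label_within, has_between_rows) {
    U <- Y %*% C_mat
    cdim <- ncol(C_mat)
    B <- XtXi %*% crossprod(X, U)
    E <- crossprod(U - X %*% B)
    df_e <- (n - p_x) * cdim
    ss_e <- sum(diag(E))
    # GG epsilon and Mauchly from the stratum residual covariance
    if (cdim == 1L) {
      eps <- 1
      mauchly <- NA_real_
    } else {
      eps <- sum(diag(E))^2 / (cdim * sum(E * E))
      eps <- min(1, max(1 / cdim, eps))
      S <- E / (n - p_x)
      detS <- det(S)
      if (detS <= 0) {
        mauchly <- 0
      } else {
        W <- detS / (sum(diag(S)) / cdim)^cdim
        f <- (2 * cdim^2 + cdim + 2) / (6 * cdim)
        chi2 <- -(n - p_x - f) * log(W)
        mauchly <- stats::pchisq(chi2, cdim * (cdim + 1) / 2 - 1,
                                 lower.tail = FALSE)
      }
    }
    rows <- list()
    emit <- function(name, L) {
      ssh <- ss_h(B, U, L)
      df1 <- nrow(L) * cdim
      Fv <- (ssh / df1) / (ss_e / df_e)
      rows[[length(rows) + 1L]] <<- data.frame(
        effect = name, df1 = df1, df2 = df_e, F = Fv,
        p = stats::pf(Fv, df1, df_e, lower.tail = FALSE),
        gg_epsilon = eps,
        p_gg = stats::pf(Fv, eps * df1, eps * df_e, lower.tail = FALSE),
        pes = ssh / (ssh + ss_e),
        mauchly_p = mauchly
      )
    }
    emit(label_within, matrix(c(1, rep(0, p_x - 1)), 1, p_x))
    if (has_between_rows) {
      L <- cbind(matrix(0, p_x - 1, 1), diag(p_x - 1))
      emit(paste0(between, ":", label_within), L)
    }
    do.call(rbind, rows)
  }

  out <- list()
  # between-subjects stratum on the cell-averaged responses
  if (!is.null(between)) {
    U0 <- Y %*% proj_for(rep(FALSE, length(within)))
    B0 <- XtXi %*% crossprod(X, U0)
    E0 <- crossprod(U0 - X %*% B0)
    L <- cbind(matrix(0, p_x - 1, 1), diag(p_x - 1))
    ssh <- ss_h(B0, U0, L)
    df1 <- p_x - 1
    df2 <- n - p_x
    Fv <- (ssh / df1) / (sum(diag(E0)) / df2)
    out[[length(out) + 1L]] <- data.frame(
      effect = between, df1 = df1, df2 = df2, F = Fv,
      p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
      gg_epsilon = 1,
      p_gg = stats::pf(Fv, df1, df2, lower.tail = FALSE),
      pes = ssh / (ssh + sum(diag(E0))),
      mauchly_p = NA_real_
    )
  }
  # all within-involving effects
  n_w <- length(within)
  for (subset_code in seq_len(2^n_w - 1L)) {
    in_term <- as.logical(bitwAnd(subset_code, 2^(seq_len(n_w) - 1L)))
    label <- paste(within[in_term], collapse = ":")
    out[[length(out) + 1L]] <-
      test_stratum(proj_for(in_term), label, !is.null(between))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("rm_anova", "data.frame")
  res
}

#' Bonferroni-corrected pairwise comparisons
#'
#' Paired t-tests for a within-subject factor (on subject means averaged
#' over any other within factors) or independent t-tests for the
#' between-subjects factor (on subject means). Raw p-values are multiplied
#' by the number of pairs and capped at 1; effect sizes are pooled-SD
#' Cohen's d.
#'
#' @inheritParams rm_anova
#' @param factor name of the factor whose levels are compared.
#' @param paired force paired / independent comparisons; default guesses
#'   from whether subjects appear at several levels of `factor`.
#' @return data.frame with one row per pair: `level_1`, `level_2`,
#'   `mean_1`, `mean_2`, `mean_diff`, `t`, `df`, `p_raw`, `p_bonferroni`,
#'   `cohens_d`.
#' @export
pairwise_bonferroni <- function(data, dv = "value", factor,
                                subject = "participant", paired = NULL) {
  stopifnot(factor %in% names(data), dv %in% names(data),
            subject %in% names(data))
  data <- as.data.frame(data)
  data[[factor]] <- base::factor(data[[factor]])
  lev <- levels(data[[factor]])
  if (length(lev) < 2L) stop("pairwise_bonferroni: factor has one level")
  # subject means per level
  agg <- stats::aggregate(data[[dv]],
                          by = list(subject = data[[subject]],
                                    level = data[[factor]]),
                          FUN = mean)
  if (is.null(paired)) {
    per_subj <- table(unique(agg[c("subject", "level")])$subject)
    paired <- any(per_subj > 1L)
  }
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  n_pairs <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x1 <- agg$x[agg$level == pr[1]]
    x2 <- agg$x[agg$level == pr[2]]
    if (paired) {
      s1 <- agg$subject[agg$level == pr[1]]
      s2 <- agg$subject[agg$level == pr[2]]
      common <- intersect(s1, s2)
      x1 <- x1[match(common, s1)]
      x2 <- x2[match(common, s2)]
      tt <- stats::t.test(x1, x2, paired = TRUE)
    } else {
      tt <- stats::t.test(x1, x2, var.equal = TRUE)
    }
    d <- cohens_d_pooled(mean(x1), stats::sd(x1), length(x1),
                         mean(x2), stats::sd(x2), length(x2))
    data.frame(level_1 = pr[1], level_2 = pr[2],
               mean_1 = mean(x1), mean_2 = mean(x2),
               mean_diff = mean(x1) - mean(x2),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, tt$p.value * n_pairs),
               cohens_d = d)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_comparisons") <- n_pairs
  attr(out, "paired") <- paired
  out
}

#' Pooled-SD Cohen's d from summary statistics
#'
#' `d = (m1 - m2) / s_pooled` with
#' `s_pooled = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param m1,s1,n1 mean, SD, and size of the first sample.
#' @param m2,s2,n2 mean, SD, and size of the second sample.
#' @return Cohen's d.
#' @export
#' @examples
#' cohens_d_pooled(2.599, 1.41, 18, 3.830, 1.41, 17)  # -0.873
cohens_d_pooled <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("cohens_d_pooled: zero pooled SD")
  (m1 - m2) / sp
}

#' Two-sample Student t-test from summary statistics
#'
#' Pooled-variance t with `df = n1 + n2 - 2` and a two-tailed p-value, for
#' re-deriving printed test statistics from reported group means and SDs.
#'
#' @inheritParams cohens_d_pooled
#' @return list with `t`, `df`, `p`.
#' @export
#' @examples
#' ttest_from_summary(1.47, 0.531, 11, 1.89, 0.329, 12)  # t ~ -2.30, df 21
ttest_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("ttest_from_summary: zero pooled variance")
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Coefficient of variation in percent
#'
#' `CV% = sample SD / mean * 100` (n - 1 denominator).
#'
#' @param values numeric vector with positive mean and length >= 2.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  if (m <= 0) stop("cv_percent: mean must be positive")
  stats::sd(values) / m * 100
}

#' Convert miles per hour to meters per second
#'
#' @param mph speed in miles per hour.
#' @return speed in m/s (1 mph = 0.44704 m/s).
#' @export
mph_to_mps <- function(mph) mph * 0.44704
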