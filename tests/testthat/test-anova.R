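test_that("split-plot F statistics equal the aov Error-strata oracle", {
  for (seed in 1:4) {
    d <- make_splitplot_data(n_per_group = 6, k_within = 3, seed = seed,
                             effect = 0.5)
    r <- rm_anova(d, "value", within = "condition", between = "group")
    a <- summary(aov(value ~ group * condition +
                       Error(participant / condition), data = d))
    f_between <- a[["Error: participant"]][[1]]["group", "F value"]
    f_within <- a[["Error: participant:condition"]][[1]][
      c("condition", "group:condition"), "F value"]
    expect_lt(abs(r$F[r$effect == "group"] - f_between), 1e-8)
    expect_lt(abs(r$F[r$effect == "condition"] - f_within[1]), 1e-8)
    expect_lt(abs(r$F[r$effect == "group:condition"] - f_within[2]), 1e-8)
  }
})

test_that("two-within-factor designs match aov, including the interaction stratum", {
  set.seed(11)
  d <- expand.grid(participant = sprintf("s%02d", 1:10),
                   flow = c("F", "NF"), task = c("T", "NT"))
  d$value <- rnorm(nrow(d)) + (d$flow == "F") * 0.4 +
    (d$flow == "F") * (d$task == "T") * 0.6
  r <- rm_anova(d, "value", within = c("flow", "task"))
  a <- summary(aov(value ~ flow * task +
                     Error(participant / (flow * task)), data = d))
  expect_lt(abs(r$F[r$effect == "flow"] -
                  a[["Error: participant:flow"]][[1]]["flow", "F value"]),
            1e-8)
  expect_lt(abs(r$F[r$effect == "task"] -
                  a[["Error: participant:task"]][[1]]["task", "F value"]),
            1e-8)
  expect_lt(abs(r$F[r$effect == "flow:task"] -
                  a[["Error: participant:flow:task"]][[1]]["flow:task",
                                                           "F value"]),
            1e-8)
  # every two-level within effect has epsilon exactly 1
  expect_true(all(r$gg_epsilon == 1))
})

test_that("GG epsilon and corrected p match the car multivariate oracle", {
  set.seed(7)
  n <- 16
  grp <- factor(rep(c("TD", "ASD"), each = 8))
  mix <- matrix(c(1, .8, .3, 0, 0, 1, .5, .2, 0, 0, 1, .4, 0, 0, 0, 1), 4, 4)
  Y <- matrix(rnorm(n * 4), n, 4) %*% mix
  d <- data.frame(participant = rep(sprintf("s%02d", 1:n), 4),
                  group = rep(grp, 4),
                  cond = factor(rep(1:4, each = n)), value = c(Y))
  r <- rm_anova(d, "value", within = "cond", between = "group")
  mlm <- lm(Y ~ grp, contrasts = list(grp = contr.sum))
  ca <- suppressWarnings(summary(
    car::Anova(mlm, idata = data.frame(cond = factor(1:4)),
               idesign = ~cond, type = 3),
    multivariate = FALSE))
  adj <- ca$pval.adjustments
  expect_equal(r$gg_epsilon[r$effect == "cond"],
               unname(adj["cond", "GG eps"]), tolerance = 1e-8)
  expect_equal(r$p_gg[r$effect == "cond"],
               unname(adj["cond", "Pr(>F[GG])"]), tolerance = 1e-8)
  expect_equal(r$p_gg[r$effect == "group:cond"],
               unname(adj["grp:cond", "Pr(>F[GG])"]), tolerance = 1e-8)
})

test_that("epsilon is exactly 1 for spherical (compound-symmetric) residuals", {
  # construct residuals whose contrast-projected covariance is a multiple of I
  set.seed(5)
  n <- 12
  k <- 4
  C <- contr.poly(k)
  U <- matrix(rnorm(n * (k - 1)), n, k - 1)
  U <- scale(U, center = TRUE, scale = FALSE)
  U <- U %*% solve(chol(crossprod(U) / (n - 1)))   # whiten: cov exactly I
  Y <- 5 + U %*% t(C)                              # spherical within-part
  d <- data.frame(participant = rep(sprintf("s%02d", 1:n), k),
                  cond = factor(rep(1:k, each = n)), value = c(Y))
  r <- rm_anova(d, "value", within = "cond")
  expect_equal(r$gg_epsilon[r$effect == "cond"], 1, tolerance = 1e-10)
})

test_that("partial eta squared satisfies the F identity for every effect", {
  d <- make_splitplot_data(n_per_group = 5, seed = 3, effect = 0.8)
  r <- rm_anova(d, "value", within = "condition", between = "group")
  expect_equal(r$pes, r$F * r$df1 / (r$F * r$df1 + r$df2), tolerance = 1e-12)
  # the identity also recovers printed effect sizes from F and dfs
  expect_lt(abs(8.157 * 2 / (8.157 * 2 + 72) - 0.185), 5e-4)
})

test_that("type-I error of the within test is calibrated at alpha = 0.05", {
  n_sims <- 2000
  rejections <- 0L
  d0 <- expand.grid(participant = sprintf("s%02d", 1:12),
                    cond = c("a", "b", "c"))
  d0$group <- rep(rep(c("TD", "ASD"), each = 6), 3)
  set.seed(1234)
  for (i in seq_len(n_sims)) {
    d0$value <- rnorm(36)
    r <- rm_anova(d0, "value", within = "cond", between = "group")
    if (r$p[r$effect == "cond"] < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_sims
  ci_half <- 3 * sqrt(0.05 * 0.95 / n_sims)
  expect_lt(abs(rate - 0.05), ci_half)
})

test_that("rm_anova rejects malformed designs", {
  d <- make_splitplot_data(n_per_group = 4)
  expect_error(rm_anova(d[-1, ], "value", within = "condition",
                        between = "group"), "incomplete")
  d2 <- rbind(d, d[1, ])
  expect_error(rm_anova(d2, "value", within = "condition",
                        between = "group"), "more than one observation")
  d3 <- d
  d3$group[d3$participant == "s01"] <-
    ifelse(d3$condition[d3$participant == "s01"] == "c1", "TD", "ASD")
  expect_error(rm_anova(d3, "value", within = "condition",
                        between = "group"), "more than one group")
})

test_that("Bonferroni pairwise comparisons count, cap, and standardize", {
  d <- make_splitplot_data(n_per_group = 6, k_within = 3, seed = 9,
                           effect = 0.3)
  pw <- pairwise_bonferroni(d, "value", factor = "condition")
  expect_equal(nrow(pw), 3L)
  expect_equal(attr(pw, "n_comparisons"), 3L)
  expect_true(attr(pw, "paired"))
  expect_true(all(pw$p_bonferroni <= 1))
  expect_equal(pw$p_bonferroni, pmin(1, pw$p_raw * 3))
  # symmetric differences give t = 0 and corrected p = 1
  ds <- data.frame(participant = rep(c("s1", "s2"), 2),
                   lev = rep(c("a", "b"), each = 2),
                   value = c(0, 1, 1, 0))
  pw0 <- pairwise_bonferroni(ds, "value", factor = "lev")
  expect_equal(pw0$t, 0)
  expect_equal(pw0$p_bonferroni, 1)
  # between-group comparison falls back to independent tests
  pg <- pairwise_bonferroni(d, "value", factor = "group")
  expect_false(attr(pg, "paired"))
  expect_equal(pg$df, 10)
})

test_that("Cohen's d and the summary t-test reproduce closed forms", {
  expect_equal(cohens_d_pooled(2.599, 1.41, 18, 3.830, 1.41, 17),
               (2.599 - 3.830) / 1.41, tolerance = 1e-12)
  expect_equal(cohens_d_pooled(5, 2, 30, 5, 2, 30), 0)
  # unit standardization: one pooled SD of separation gives d = 1
  expect_equal(cohens_d_pooled(11, 2, 50, 9, 2, 50), 1)
  expect_error(cohens_d_pooled(1, 0, 10, 1, 0, 10), "zero pooled")
  tt <- ttest_from_summary(5, 2, 12, 5, 2, 12)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  expect_equal(qt(0.975, 21), 2.0796, tolerance = 1e-4)
})

test_that("cv_percent computes sample-SD CV and is scale invariant", {
  expect_equal(cv_percent(c(1, 2, 3)), 50)
  expect_equal(cv_percent(rep(4, 10)), 0)
  x <- rlnorm(20)
  expect_equal(cv_percent(7 * x), cv_percent(x), tolerance = 1e-12)
  expect_error(cv_percent(c(-2, 1)), "positive")
})
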