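test_that("shapiro-wilk gate: bounds, affine invariance, reference value", {
  expect_error(shapiro_wilk(c(1, 2)), "\\[3, 5000\\]")
  x <- c(2.1, 2.5, 2.3, 3.0, 2.8, 3.2, 2.9, 2.4, 2.7, 3.1)
  r1 <- shapiro_wilk(x)
  r2 <- shapiro_wilk(3.7 * x + 11)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  # frozen reference from an independent implementation (scipy.stats.shapiro)
  expect_equal(r1$statistic, 0.9648074985, tolerance = 1e-6)
  expect_equal(r1$p, 0.8389775640, tolerance = 1e-4)
})

test_that("t test variants: identity, welch-satterthwaite df, student value", {
  x <- c(1.2, 3.4, 2.2, 4.8)
  r <- t_test(x, x, "student")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # closed-form Welch df: samples engineered to have exact variances 1 and 4
  x1 <- (c(-2, -1, 0, 1, 2) / sqrt(2.5)) + 10
  y0 <- 1:10
  y1 <- (y0 - mean(y0)) * sqrt(4 / var(y0)) + 12
  expect_equal(var(x1), 1, tolerance = 1e-12)
  expect_equal(var(y1), 4, tolerance = 1e-12)
  rw <- t_test(x1, y1, "welch")
  df_oracle <- (1 / 5 + 4 / 10)^2 / ((1 / 5)^2 / 4 + (4 / 10)^2 / 9)
  expect_equal(df_oracle, 12.96, tolerance = 1e-10)
  expect_equal(rw$df, df_oracle, tolerance = 1e-10)

  # pooled-variance hand example
  rs <- t_test(c(1, 2, 3), c(2, 3, 4), "student")
  expect_equal(rs$statistic, -sqrt(1.5), tolerance = 1e-10)
  expect_equal(rs$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(rs$df, 4)

  expect_error(t_test(c(1, 1, 1), c(1, 1, 1)), "undefined|constant")
  expect_error(t_test(1, c(1, 2)), "n >= 2")
})

test_that("one-way anova: t^2 identity, zero F, brute-force SS oracle", {
  set.seed(1)
  a <- rnorm(8); b <- rnorm(9, 0.5)
  f2 <- one_way_anova(list(a, b))
  t2 <- t_test(a, b, "student")
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p, t2$p, tolerance = 1e-10)

  expect_equal(one_way_anova(list(c(1, 3), c(0, 4)))$statistic, 0,
               tolerance = 1e-12)

  groups <- list(c(3.1, 2.8, 3.6), c(4.0, 4.4, 3.9, 4.1), c(2.0, 2.5))
  mine <- one_way_anova(groups)
  oracle <- oracle_anova(groups)
  expect_equal(mine$statistic, oracle$F, tolerance = 1e-10)
  expect_equal(mine$df, oracle$df)
  expect_equal(mine$p, oracle$p, tolerance = 1e-10)

  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
})

test_that("kruskal-wallis: hand rank example, ties, degenerate case", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4)))
  expect_equal(r$statistic, 2.4, tolerance = 1e-10)
  expect_equal(r$df, 1)

  same <- kruskal_wallis(list(c(5, 5), c(5, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # tie correction can only increase H: compare tied fixture against the
  # uncorrected statistic computed by hand from mid-ranks
  g <- list(c(1, 2, 2), c(2, 3, 4))
  tied <- kruskal_wallis(g)
  ranks <- rank(unlist(g))
  n <- length(ranks)
  groups_r <- split(ranks, rep(1:2, each = 3))
  h_uncorrected <- 12 / (n * (n + 1)) *
    sum(vapply(groups_r, function(rr) length(rr) * (mean(rr) - (n + 1) / 2)^2, 0))
  expect_gte(tied$statistic, h_uncorrected - 1e-12)
})

test_that("dunnett reduces to the unadjusted t comparison at two groups", {
  set.seed(4)
  g0 <- rnorm(10); g1 <- rnorm(10, 1)
  d <- dunnett(list(g0, g1))
  tt <- t_test(g0, g1, "student")
  expect_equal(d$t[1], -tt$statistic, tolerance = 1e-10)
  expect_equal(d$p_adjusted[1], tt$p, tolerance = 1e-3)
  expect_equal(d$p_unadjusted[1], tt$p, tolerance = 1e-10)
})

test_that("dunnett critical value matches a monte-carlo multivariate-t oracle", {
  # balanced k = 3, n = 10 per group, alpha = 0.05, two-sided
  set.seed(8)
  groups <- lapply(1:3, function(i) rnorm(10))
  d <- dunnett(groups, control_index = 1)
  crit <- attr(d, "critical")

  # oracle: max |T| over the two comparisons, T built from first principles
  nsim <- 2e5
  df <- 27
  rho <- 0.5  # balanced many-to-one correlation: lambda_i lambda_j = 0.5
  z1 <- rnorm(nsim); z2 <- rnorm(nsim); shared <- rnorm(nsim)
  Z1 <- sqrt(rho) * shared + sqrt(1 - rho) * z1
  Z2 <- sqrt(rho) * shared + sqrt(1 - rho) * z2
  S <- sqrt(rchisq(nsim, df) / df)
  maxT <- pmax(abs(Z1 / S), abs(Z2 / S))
  crit_mc <- unname(quantile(maxT, 0.95))
  expect_equal(crit, crit_mc, tolerance = 0.01)
})

test_that("dunnett agrees with multcomp and is null on identical groups", {
  skip_if_not_installed("multcomp")
  set.seed(10)
  dat <- data.frame(y = c(rnorm(8), rnorm(8, 1.2), rnorm(8, 0.3)),
                    g = factor(rep(c("ctrl", "a", "b"), each = 8),
                               levels = c("ctrl", "a", "b")))
  groups <- split(dat$y, dat$g)[c("ctrl", "a", "b")]
  mine <- dunnett(groups, control_index = 1)
  fit <- multcomp::glht(stats::aov(y ~ g, dat),
                        linfct = multcomp::mcp(g = "Dunnett"))
  ref <- summary(fit)$test
  expect_equal(unname(mine$t), unname(ref$tstat), tolerance = 1e-8)
  expect_equal(unname(mine$p_adjusted), unname(as.numeric(ref$pvalues)),
               tolerance = 5e-3)

  same <- dunnett(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_false(any(same$significant))
  expect_error(dunnett(list(rnorm(5), rnorm(5)), control_index = 3),
               "out of range")
})

test_that("rm-anova matches the aov error-strata oracle on a balanced fixture", {
  set.seed(6)
  tab <- toy_table(n_per_group = 5, days = c(2, 4, 7), seed = 6,
                   splx_shift = 1)
  mine <- rm_anova(tab, "mass")

  dat <- data.frame(y = tab$mass, s = factor(tab$animal_id),
                    w = factor(tab$day), g = factor(tab$group))
  fit <- summary(stats::aov(y ~ g * w + Error(s/w), data = dat))
  between <- fit[["Error: s"]][[1]]
  within <- fit[["Error: s:w"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  expect_equal(mine$between$statistic, between["g", "F value"],
               tolerance = 1e-10)
  expect_equal(mine$between$p, between["g", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(mine$within$statistic, within["w", "F value"],
               tolerance = 1e-10)
  expect_equal(mine$interaction$statistic, within["g:w", "F value"],
               tolerance = 1e-10)
  expect_equal(unname(mine$within$df), c(2, 16))

  # epsilon bounds and the corrected df scaling
  eps <- mine$epsilon[["greenhouse_geisser"]]
  expect_gte(eps, 1 / 2)
  expect_lte(eps, 1)
  expect_equal(unname(mine$within_corrected$df), eps * c(2, 16),
               tolerance = 1e-12)
})

test_that("rm-anova: epsilon is exactly 1 at two within levels; errors on gaps", {
  tab <- toy_table(n_per_group = 4, days = c(2, 4), seed = 7)
  fit <- rm_anova(tab, "ns")
  expect_equal(fit$epsilon[["greenhouse_geisser"]], 1)
  expect_equal(unname(fit$within_corrected$df), unname(fit$within$df))

  gap <- tab[-1, ]
  expect_error(rm_anova(gap, "ns"), "listwise|complete")
})

test_that("grid significance summary counts match a hand-checkable fixture", {
  mk_res <- function(id, splx, sham) {
    structure(list(
      splx = structure(list(condition_id = id, class = "SPLX",
                            accuracies = splx, mean_acc = mean(splx),
                            sd_acc = sd(splx)), class = "accuracy_result"),
      sham = structure(list(condition_id = id, class = "SPL-sham",
                            accuracies = sham, mean_acc = mean(sham),
                            sd_acc = sd(sham)), class = "accuracy_result")),
      class = "condition_result")
  }
  mk_cond <- function(excluded) {
    structure(list(day_filter = "all-days", excluded = excluded,
                   variables = c("day", "mass", "mr_il"),
                   id = mcaonet:::condition_id("all-days", excluded)),
              class = "ablation_condition")
  }
  conds <- list(mk_cond(character(0)), mk_cond("mass"), mk_cond("mr_il"))
  base_acc <- c(0.80, 0.81, 0.79, 0.80, 0.82)
  far_acc <- base_acc - 0.30      # clearly below baseline
  near_acc <- base_acc - 0.001    # indistinguishable from baseline
  results <- list(mk_res(conds[[1]]$id, base_acc, base_acc + 0.001),
                  mk_res(conds[[2]]$id, far_acc, base_acc),
                  mk_res(conds[[3]]$id, near_acc, far_acc))
  names(results) <- vapply(conds, function(cn) cn$id, "")
  grid <- structure(list(conditions = conds, results = results,
                         replicates = 5, master_seed = 1),
                    class = "grid_result")
  rep <- summarize_grid_significance(grid, alpha = 0.05)
  el <- rep[["all-days"]]
  # SPLX: only the far-shifted condition differs from baseline
  expect_equal(unname(el$counts$splx_vs_baseline[c("count", "denominator")]),
               c(1, 2))
  # SPL-sham: only condition 3 (far_acc) differs from its baseline
  expect_equal(unname(el$counts$sham_vs_baseline[c("count", "denominator")]),
               c(1, 2))
  # class-vs-class: conditions 2 and 3 have a 0.3 separation, baseline none
  expect_equal(unname(el$counts$class_vs_class[c("count", "denominator")]),
               c(2, 3))
  expect_equal(el$largest_splx_minus_sham$condition, conds[[3]]$id)
  expect_equal(el$largest_splx_minus_sham$value, mean(near_acc) - mean(far_acc),
               tolerance = 1e-12)

  # identical replicate vectors everywhere: all counts zero
  same <- lapply(conds, function(cn) mk_res(cn$id, base_acc, base_acc))
  names(same) <- names(results)
  grid0 <- structure(list(conditions = conds, results = same,
                          replicates = 5, master_seed = 1),
                     class = "grid_result")
  rep0 <- summarize_grid_significance(grid0, alpha = 0.05)
  expect_equal(unname(rep0[["all-days"]]$counts$splx_vs_baseline[["count"]]), 0)
  expect_equal(unname(rep0[["all-days"]]$counts$class_vs_class[["count"]]), 0)

  # incomplete grid is refused with the missing condition named
  grid_bad <- grid
  grid_bad$results <- grid$results[1:2]
  expect_error(summarize_grid_significance(grid_bad), "missing")
})
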