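test_result <- function(statistic_name, statistic, df, p, alpha = 0.05,
                        adjusted_p = NA_real_, method = statistic_name) {
  structure(list(statistic_name = statistic_name, statistic = statistic,
                 df = df, p = p, alpha = alpha, adjusted_p = adjusted_p,
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 6), collapse = ", ")
  cat(sprintf("%s: %s(%s) = %.4f, p = %.4g (alpha = %g)\n",
              x$method, x$statistic_name, dfs, x$statistic, x$p, x$alpha))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Normality gate used before choosing between parametric and rank-based
#' comparisons.
#'
#' @param sample numeric vector, `3 <= n <= 5000`.
#' @param alpha significance level recorded in the result.
#' @return A `test_result` with statistic `W`.
#' @export
shapiro_wilk <- function(sample, alpha = 0.05) {
  n <- length(sample)
  if (n < 3 || n > 5000)
    stop("shapiro_wilk error: sample size must be in [3, 5000]", call. = FALSE)
  st <- shapiro.test(sample)
  test_result("W", unname(st$statistic), df = n, p = st$p.value,
              alpha = alpha, method = "Shapiro-Wilk normality test")
}

#' Two-sample / paired t test
#'
#' `welch` (default) uses the Welch-Satterthwaite fractional degrees of
#' freedom, `student` the pooled-variance test, `paired` the paired test on
#' equal-length samples.  Two-sided throughout.
#'
#' @param x,y numeric samples (`n >= 2` each; equal lengths when paired).
#' @param variant `"welch"`, `"student"` or `"paired"`.
#' @param alpha significance level recorded in the result.
#' @return A `test_result` with statistic `t` (df fractional for Welch).
#' @export
t_test <- function(x, y, variant = c("welch", "student", "paired"),
                   alpha = 0.05) {
  variant <- match.arg(variant)
  if (length(x) < 2 || length(y) < 2)
    stop("t_test error: each sample needs n >= 2", call. = FALSE)
  if (variant == "paired" && length(x) != length(y))
    stop("t_test error: paired samples must have equal length", call. = FALSE)
  st <- tryCatch(
    switch(variant,
           welch = t.test(x, y),
           student = t.test(x, y, var.equal = TRUE),
           paired = t.test(x, y, paired = TRUE)),
    error = function(e)
      stop("t_test error: undefined statistic (", conditionMessage(e), ")",
           call. = FALSE))
  test_result("t", unname(st$statistic), df = unname(st$parameter),
              p = st$p.value, alpha = alpha,
              method = sprintf("%s t test (two-sided)", variant))
}

#' One-way between-groups ANOVA
#'
#' @param groups list of numeric samples (>= 2 groups, each `n >= 2`).
#' @param alpha significance level recorded in the result.
#' @return A `test_result` with statistic `F` and df `(k - 1, N - k)`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (length(groups) < 2 || any(vapply(groups, length, 0L) < 2))
    stop("one_way_anova error: need >= 2 groups of n >= 2", call. = FALSE)
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  st <- oneway.test(values ~ g, var.equal = TRUE)
  if (!is.finite(st$statistic))
    stop("one_way_anova error: degenerate data (zero within-group variance with equal means)",
         call. = FALSE)
  test_result("F", unname(st$statistic),
              df = unname(c(st$parameter[1], st$parameter[2])),
              p = st$p.value, alpha = alpha, method = "one-way ANOVA")
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with a chi-square reference on `k - 1` df.  All values
#' identical is returned as `H = 0`, `p = 1` rather than an error.
#'
#' @param groups list of numeric samples (>= 2 groups, total `N >= 3`).
#' @param alpha significance level recorded in the result.
#' @return A `test_result` with statistic `H`.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (length(groups) < 2 || length(unlist(groups)) < 3)
    stop("kruskal_wallis error: need >= 2 groups, total N >= 3", call. = FALSE)
  values <- unlist(groups)
  k <- length(groups)
  if (length(unique(values)) == 1L)
    return(test_result("H", 0, df = k - 1, p = 1, alpha = alpha,
                       method = "Kruskal-Wallis H test"))
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  st <- kruskal.test(values, g)
  test_result("H", unname(st$statistic), df = unname(st$parameter),
              p = st$p.value, alpha = alpha, method = "Kruskal-Wallis H test")
}

# Dunnett correlation structure and statistics for many-to-one comparisons
.dunnett_stats <- function(groups, control_index) {
  k <- length(groups)
  ns <- vapply(groups, length, 0L)
  means <- vapply(groups, mean, 0)
  N <- sum(ns)
  df <- N - k
  sp2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0)) / df
  others <- setdiff(seq_len(k), control_index)
  n0 <- ns[control_index]
  diffs <- means[others] - means[control_index]
  se <- sqrt(sp2 * (1 / ns[others] + 1 / n0))
  tstat <- ifelse(se > 0, diffs / se, ifelse(diffs == 0, 0, Inf * sign(diffs)))
  lam <- sqrt(ns[others] / (ns[others] + n0))
  R <- outer(lam, lam)
  diag(R) <- 1
  list(others = others, diffs = diffs, t = tstat, df = df, corr = R,
       zero_variance = sp2 == 0)
}

#' Dunnett many-to-one comparisons against a control
#'
#' Compares every group against the designated control with familywise error
#' controlled through the equicoordinate quantile of the multivariate t
#' distribution of the comparison statistics (numerical integration via the
#' mvtnorm algorithms; the integration seed is fixed so results are
#' reproducible).  Two-sided.
#'
#' @param groups list of numeric samples.
#' @param control_index index of the control group in `groups`.
#' @param alpha familywise significance level.
#' @return A data frame of class `dunnett_result`: one row per non-control
#'   group with the mean difference, t statistic, df, unadjusted and
#'   Dunnett-adjusted p, and the significance flag; the critical value is
#'   attached as attribute `critical`.
#' @export
dunnett <- function(groups, control_index = 1L, alpha = 0.05) {
  if (length(groups) < 2)
    stop("dunnett error: need >= 2 groups", call. = FALSE)
  if (control_index < 1 || control_index > length(groups))
    stop("dunnett error: control index out of range", call. = FALSE)
  st <- .dunnett_stats(groups, control_index)
  m <- length(st$others)
  crit <- with_seed(20240405, mvtnorm::qmvt(
    1 - alpha, tail = "both.tails", df = st$df, corr = st$corr)$quantile)
  adj_p <- vapply(seq_len(m), function(i) {
    ti <- abs(st$t[i])
    if (!is.finite(ti)) return(0)
    with_seed(20240405 + i,
              1 - mvtnorm::pmvt(lower = rep(-ti, m), upper = rep(ti, m),
                                df = st$df, corr = st$corr)[1])
  }, 0)
  adj_p <- pmin(pmax(adj_p, 0), 1)
  unadj_p <- ifelse(is.finite(st$t), 2 * pt(-abs(st$t), st$df),
                    ifelse(st$t == 0, 1, 0))
  out <- data.frame(group = st$others,
                    diff = st$diffs,
                    t = st$t,
                    df = st$df,
                    p_unadjusted = unadj_p,
                    p_adjusted = adj_p,
                    alpha = alpha,
                    significant = adj_p < alpha)
  attr(out, "critical") <- crit
  class(out) <- c("dunnett_result", "data.frame")
  out
}

# orthonormal contrast matrix with k-1 rows (for epsilon estimation)
.orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  C <- t(C)
  C / sqrt(rowSums(C^2))
}

#' Repeated-measures (split-plot) ANOVA with sphericity correction
#'
#' Mixed between x within ANOVA on complete balanced data: every subject
#' observed at every within level.  The between factor is tested against the
#' subject-within-group mean square; the within factor and the interaction
#' against the residual within-subject mean square.  Sphericity is handled
#' by Greenhouse-Geisser epsilon scaling of both numerator and denominator
#' df (Huynh-Feldt available via `correction = "huynh-feldt"`); uncorrected
#' and corrected results are both reported.
#'
#' @param table long-format data frame.
#' @param response name of the response column.
#' @param subject,within,between column names for subject id, within-subject
#'   factor and between-subjects factor.
#' @param alpha significance level recorded in the results.
#' @param correction `"greenhouse-geisser"` (default) or `"huynh-feldt"`.
#' @return List of class `rm_anova_result`: `test_result`s `between`,
#'   `within`, `interaction` (uncorrected) and `within_corrected`,
#'   `interaction_corrected`, plus `epsilon` and the SS table.
#' @export
rm_anova <- function(table, response, subject = "animal_id", within = "day",
                     between = "group", alpha = 0.05,
                     correction = c("greenhouse-geisser", "huynh-feldt")) {
  correction <- match.arg(correction)
  y <- table[[response]]
  s <- factor(table[[subject]])
  w <- factor(table[[within]])
  b <- factor(table[[between]])
  k <- nlevels(w)
  tab <- table(s, w)
  if (any(tab != 1L))
    stop("rm_anova error: design not complete/balanced (each subject must be observed exactly once at every within level); apply listwise deletion or imputation upstream",
         call. = FALSE)
  subj_group <- tapply(as.character(b), s, function(v) v[1])
  g <- length(unique(subj_group))
  N <- nlevels(s)
  if (k < 2) stop("rm_anova error: need >= 2 within levels", call. = FALSE)

  GM <- mean(y)
  ss_total <- sum((y - GM)^2)
  subj_means <- tapply(y, s, mean)
  ss_between_subj <- k * sum((subj_means - GM)^2)
  grp_of_subj <- factor(subj_group)
  grp_means <- tapply(subj_means, grp_of_subj, mean)
  n_per_grp <- table(grp_of_subj)
  ss_group <- k * sum(n_per_grp * (grp_means - GM)^2)
  ss_subj_within <- ss_between_subj - ss_group
  day_means <- tapply(y, w, mean)
  ss_within_factor <- N * sum((day_means - GM)^2)
  cell_means <- tapply(y, list(b, w), mean)
  ss_cells <- sum(as.numeric(n_per_grp[rownames(cell_means)]) *
                  (cell_means - GM)^2)
  ss_interaction <- ss_cells - ss_group - ss_within_factor
  ss_error <- ss_total - ss_between_subj - ss_within_factor - ss_interaction

  df_group <- g - 1
  df_subj <- N - g
  df_within <- k - 1
  df_inter <- (g - 1) * (k - 1)
  df_error <- (N - g) * (k - 1)

  ms <- function(ss, df) ss / df
  f_group <- ms(ss_group, df_group) / ms(ss_subj_within, df_subj)
  f_within <- ms(ss_within_factor, df_within) / ms(ss_error, df_error)
  f_inter <- ms(ss_interaction, df_inter) / ms(ss_error, df_error)

  # pooled within-group covariance of the subject x within-level matrix
  wide <- matrix(NA_real_, N, k,
                 dimnames = list(levels(s), levels(w)))
  wide[cbind(as.character(s), as.character(w))] <- y
  Spool <- matrix(0, k, k)
  wt <- 0
  for (gl in levels(grp_of_subj)) {
    rows <- wide[names(subj_group)[subj_group == gl], , drop = FALSE]
    if (nrow(rows) >= 2) {
      Spool <- Spool + (nrow(rows) - 1) * stats::cov(rows)
      wt <- wt + nrow(rows) - 1
    }
  }
  Spool <- Spool / max(wt, 1)
  C <- .orthonormal_contrasts(k)
  M <- C %*% Spool %*% t(C)
  gg <- (sum(diag(M)))^2 / ((k - 1) * sum(M^2))
  gg <- min(max(gg, 1 / (k - 1)), 1)
  hf <- ((N + 1) * (k - 1) * gg - 2) / ((k - 1) * (N - g - (k - 1) * gg))
  hf <- min(max(hf, gg), 1)
  eps <- if (correction == "greenhouse-geisser") gg else hf

  res <- list(
    between = test_result("F", f_group, c(df_group, df_subj),
                          pf(f_group, df_group, df_subj, lower.tail = FALSE),
                          alpha, method = sprintf("RM-ANOVA between (%s)", between)),
    within = test_result("F", f_within, c(df_within, df_error),
                         pf(f_within, df_within, df_error, lower.tail = FALSE),
                         alpha, method = sprintf("RM-ANOVA within (%s), uncorrected", within)),
    interaction = test_result("F", f_inter, c(df_inter, df_error),
                              pf(f_inter, df_inter, df_error, lower.tail = FALSE),
                              alpha, method = "RM-ANOVA interaction, uncorrected"),
    within_corrected = test_result(
      "F", f_within, eps * c(df_within, df_error),
      pf(f_within, eps * df_within, eps * df_error, lower.tail = FALSE),
      alpha, method = sprintf("RM-ANOVA within (%s), %s-corrected", within, correction)),
    interaction_corrected = test_result(
      "F", f_inter, eps * c(df_inter, df_error),
      pf(f_inter, eps * df_inter, eps * df_error, lower.tail = FALSE),
      alpha, method = sprintf("RM-ANOVA interaction, %s-corrected", correction)),
    epsilon = c(greenhouse_geisser = gg, huynh_feldt = hf),
    ss = c(group = ss_group, subj_within_group = ss_subj_within,
           within = ss_within_factor, interaction = ss_interaction,
           error = ss_error, total = ss_total))
  class(res) <- "rm_anova_result"
  res
}

# limit-case two-sample comparison used by the grid summary: identical
# replicate vectors are never significant, zero-variance separation always is
.safe_welch_p <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    return(list(t = if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y)),
                df = length(x) + length(y) - 2,
                p = if (mean(x) == mean(y)) 1 else 0))
  }
  st <- t.test(x, y)
  list(t = unname(st$statistic), df = unname(st$parameter), p = st$p.value)
}

#' Significance summary of an ablation grid
#'
#' Reproduces the reporting structure of the ablation experiment: per day
#' filter, (a) Dunnett-adjusted comparisons of every exclusion condition's
#' per-replicate accuracies against the baseline (complete-variable)
#' condition, separately per class, with counts over `#conditions - 1`;
#' (b) per-condition SPLX versus SPL-sham t tests with counts over
#' `#conditions`; and (c) the largest signed differences between the two
#' class accuracies and the conditions achieving them.
#'
#' @param grid a `grid_result` (complete for each day filter it contains).
#' @param alpha significance level.
#' @return A list of class `comparison_report`, one entry per day filter,
#'   each with data frames `baseline_comparisons` and `class_comparisons`
#'   plus a `counts` list.
#' @export
summarize_grid_significance <- function(grid, alpha = 0.05) {
  all_ids <- vapply(grid$conditions, function(cn) cn$id, "")
  absent <- setdiff(all_ids, names(grid$results))
  if (length(absent))
    stop(sprintf("incomplete grid: missing condition result(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  filters <- unique(vapply(grid$conditions, function(cn) cn$day_filter, ""))
  report <- list()
  for (df_name in filters) {
    conds <- Filter(function(cn) cn$day_filter == df_name, grid$conditions)
    ids <- vapply(conds, function(cn) cn$id, "")
    baseline_id <- condition_id(df_name, character(0))
    if (!baseline_id %in% ids)
      stop(sprintf("incomplete grid: missing baseline condition '%s'",
                   baseline_id), call. = FALSE)
    missing_res <- setdiff(ids, names(grid$results))
    if (length(missing_res))
      stop(sprintf("incomplete grid: missing condition result(s): %s",
                   paste(missing_res, collapse = ", ")), call. = FALSE)
    excl_ids <- setdiff(ids, baseline_id)

    base_res <- grid$results[[baseline_id]]
    baseline_rows <- list()
    for (cls in c("splx", "sham")) {
      cls_label <- if (cls == "splx") "SPLX" else "SPL-sham"
      groups <- c(list(base_res[[cls]]$accuracies),
                  lapply(excl_ids, function(id)
                    grid$results[[id]][[cls]]$accuracies))
      if (length(excl_ids)) {
        dn <- dunnett(groups, control_index = 1L, alpha = alpha)
        baseline_rows[[cls]] <- data.frame(
          class = cls_label, condition = excl_ids,
          diff_vs_baseline = dn$diff, t = dn$t,
          p_adjusted = dn$p_adjusted, significant = dn$significant,
          stringsAsFactors = FALSE)
      }
    }
    baseline_comparisons <- do.call(rbind, baseline_rows)

    class_rows <- lapply(ids, function(id) {
      res <- grid$results[[id]]
      w <- .safe_welch_p(res$splx$accuracies, res$sham$accuracies)
      data.frame(condition = id,
                 splx_minus_sham = res$splx$mean_acc - res$sham$mean_acc,
                 t = w$t, df = w$df, p = w$p, significant = w$p < alpha,
                 stringsAsFactors = FALSE)
    })
    class_comparisons <- do.call(rbind, class_rows)

    n_excl <- length(excl_ids)
    cnt <- function(v) sum(v, na.rm = TRUE)
    splx_sig <- cnt(baseline_comparisons$significant[
      baseline_comparisons$class == "SPLX"])
    sham_sig <- cnt(baseline_comparisons$significant[
      baseline_comparisons$class == "SPL-sham"])
    cls_sig <- cnt(class_comparisons$significant)
    best_pos <- class_comparisons[which.max(class_comparisons$splx_minus_sham), ]
    best_neg <- class_comparisons[which.min(class_comparisons$splx_minus_sham), ]
    report[[df_name]] <- list(
      baseline_comparisons = baseline_comparisons,
      class_comparisons = class_comparisons,
      counts = list(
        splx_vs_baseline = c(count = splx_sig, denominator = n_excl,
                             percent = if (n_excl) 100 * splx_sig / n_excl else NA),
        sham_vs_baseline = c(count = sham_sig, denominator = n_excl,
                             percent = if (n_excl) 100 * sham_sig / n_excl else NA),
        class_vs_class = c(count = cls_sig, denominator = length(ids),
                           percent = 100 * cls_sig / length(ids))),
      largest_splx_minus_sham = list(condition = best_pos$condition,
                                     value = best_pos$splx_minus_sham),
      largest_sham_minus_splx = list(condition = best_neg$condition,
                                     value = -best_neg$splx_minus_sham),
      alpha = alpha)
  }
  class(report) <- "comparison_report"
  report
}
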