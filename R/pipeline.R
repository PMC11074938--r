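#' Scale profiles for pipeline runs
#'
#' `full` uses the headline settings (15 members, 20 replicates, up to 200
#' epochs, all three day filters, all 127 variable conditions).
#' `scaled-down` is the desk-scale profile used throughout the package's own
#' calibration experiments: 5 members, 5 replicates, 50 epochs, full
#' variable set, one day filter.  `smoke` is a minutes-scale end-to-end
#' check: 3 members, 3 replicates, 20 epochs, a 2-variable universe and 100
#' animals per simulated group.
#'
#' @param name one of `"full"`, `"scaled-down"`, `"smoke"`.
#' @return Named list of caps applied by [run_config()].
#' @export
scale_profile <- function(name = c("scaled-down", "smoke", "full")) {
  name <- match.arg(name)
  switch(name,
    "full" = list(population_size = 500L, n_members = 15L, replicates = 20L,
                  epochs = 200L, patience = 20L,
                  variables = .CANONICAL_FEATURES, day_filters = .DAY_FILTERS),
    "scaled-down" = list(population_size = 500L, n_members = 5L,
                         replicates = 5L, epochs = 50L, patience = 5L,
                         variables = .CANONICAL_FEATURES,
                         day_filters = "all-days"),
    "smoke" = list(population_size = 100L, n_members = 3L, replicates = 3L,
                   epochs = 20L, patience = 5L,
                   variables = c("day", "mr_il"), day_filters = "all-days"))
}

#' Assemble a full pipeline run configuration
#'
#' Bundles the nested stage configurations, applies the scale profile's
#' caps, and rewires every stage seed off the single master seed (via
#' [derive_seed()]) so a run is a pure function of (config, master seed).
#'
#' @param cohort a [cohort_config()].
#' @param simulation a [simulation_config()].
#' @param network a [network_spec()].
#' @param ensemble an [ensemble_config()].
#' @param alpha significance level for all grid statistics.
#' @param seed master seed.
#' @param profile scale profile name (see [scale_profile()]).
#' @param output_dir run directory (created by [run_pipeline()]).
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       simulation = simulation_config(),
                       network = network_spec(),
                       ensemble = ensemble_config(),
                       alpha = 0.05,
                       seed = 1L,
                       profile = "scaled-down",
                       output_dir = tempfile("mcaonet_run_")) {
  prof <- scale_profile(profile)
  simulation$population_size <- prof$population_size
  ensemble$n_members <- prof$n_members
  ensemble$replicates <- prof$replicates
  network$epochs <- prof$epochs
  network$patience <- prof$patience
  cohort$seed <- derive_seed(seed, "cohort")
  simulation$seed <- derive_seed(seed, "simulate")
  ensemble$seed <- derive_seed(seed, "grid")
  structure(list(cohort = cohort, simulation = simulation, network = network,
                 ensemble = ensemble, variables = prof$variables,
                 day_filters = prof$day_filters, alpha = alpha,
                 seed = as.integer(seed), profile = profile,
                 output_dir = output_dir),
            class = "run_config")
}

.log_line <- function(logfile, fmt, ...) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
              sprintf(fmt, ...)),
      file = logfile, append = TRUE)
}

#' Run the full pipeline: generate, fit, simulate, ablate, summarise
#'
#' Executes the end-to-end in-silico experiment and persists every input,
#' intermediate and result as delimited text in the run directory:
#' `cohort.csv`, `estimators.csv`, `population.csv`, per-day-filter grid
#' results and significance tables, the frequentist baseline report, the
#' resolved configuration (`resolved_config.yaml`) and a human-readable
#' `report.md`.  Re-running with the same configuration and master seed
#' reproduces every result file byte-identically (wall-clock timestamps go
#' only to `run.log`).
#'
#' @param config a [run_config()].
#' @param cohort_table optional pre-existing observation table; when given,
#'   the generation stage is skipped and this table is used instead.
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config, cohort_table = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  logfile <- out("run.log")
  stage <- function(name, expr) {
    t0 <- Sys.time()
    .log_line(logfile, "stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      .log_line(logfile, "stage %s: FAILED (%s)", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    .log_line(logfile, "stage %s: done in %.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  yaml::write_yaml(.serializable_config(config), out("resolved_config.yaml"))

  cohort <- stage("generate", {
    tab <- if (is.null(cohort_table)) generate_cohort(config$cohort)
           else validate_observation_table(cohort_table)
    write_observation_table(tab, out("cohort.csv"))
    tab
  })

  est <- stage("fit-estimators", {
    e <- fit_estimators(cohort,
                        covariance = config$simulation$correlation == "mv-normal")
    write_estimator_set(e, out("estimators.csv"))
    e
  })

  pop <- stage("simulate", {
    p <- simulate_population(est, config$simulation)
    write_observation_table(p$table, out("population.csv"))
    p
  })

  grids <- list()
  for (df_name in config$day_filters) {
    grids[[df_name]] <- stage(paste0("ablate-", df_name), {
      conds <- enumerate_conditions(config$variables, df_name)
      g <- run_grid(pop$table, conds, config$network, config$ensemble,
                    checkpoint_dir = out("checkpoints", df_name))
      write_grid_result(g, out(sprintf("grid_%s.csv", df_name)))
      g
    })
    stage(paste0("stats-", df_name), {
      rep <- summarize_grid_significance(grids[[df_name]], config$alpha)
      el <- rep[[df_name]]
      if (!is.null(el$baseline_comparisons))
        write.csv(el$baseline_comparisons,
                  out(sprintf("significance_baseline_%s.csv", df_name)),
                  row.names = FALSE)
      write.csv(el$class_comparisons,
                out(sprintf("significance_class_%s.csv", df_name)),
                row.names = FALSE)
      counts <- do.call(rbind, lapply(names(el$counts), function(nm)
        data.frame(comparison = nm, count = el$counts[[nm]][["count"]],
                   denominator = el$counts[[nm]][["denominator"]],
                   percent = el$counts[[nm]][["percent"]])))
      write.csv(counts, out(sprintf("significance_counts_%s.csv", df_name)),
                row.names = FALSE)
    })
  }

  stage("baseline", {
    rep <- baseline_report(cohort, alpha = config$alpha)
    write.csv(rep$rm_anova, out("baseline_rm_anova.csv"), row.names = FALSE)
    write.csv(rep$per_day, out("baseline_per_day.csv"), row.names = FALSE)
    write.csv(rep$ci, out("baseline_ci.csv"), row.names = FALSE)
  })

  stage("report", make_report(config$output_dir))
  invisible(config$output_dir)
}

.serializable_config <- function(config) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (is.list(v) && is.null(names(v))) v
           else if (is.list(v)) strip(v) else v)
  }
  out <- strip(config)
  out$output_dir <- NULL  # machine-local; keeps run artifacts portable
  out
}

#' Frequentist baseline report for an observation table
#'
#' Runs, per measured variable, the conventional analyses the classifier
#' pipeline is contrasted with: a repeated-measures group x day ANOVA with
#' Greenhouse-Geisser correction, per-day two-group Welch t tests and
#' Kruskal-Wallis tests with a per-group Shapiro-Wilk normality gate
#' (the gate is reported, both tests are stored), and per-(group x day)
#' t-based 95% confidence intervals with an overlap flag.  Animals with
#' incomplete day coverage are listwise-deleted for the RM-ANOVA and the
#' deletion is recorded.
#'
#' @param table observation table with >= 2 animals per group per day.
#' @param alpha significance level.
#' @return List of class `baseline_report` with data frames `rm_anova`,
#'   `per_day`, `ci` and the character vector `dropped_animals`.
#' @export
baseline_report <- function(table, alpha = 0.05) {
  validate_observation_table(table)
  days <- sort(unique(table$day))
  complete_ids <- names(which(tapply(table$day, table$animal_id,
                                     function(d) length(unique(d))) == length(days)))
  dropped <- setdiff(unique(table$animal_id), complete_ids)
  complete <- table[table$animal_id %in% complete_ids, , drop = FALSE]

  rm_rows <- list()
  for (v in .MEASURED_VARS) {
    if (length(days) < 2) {
      rm_rows[[v]] <- data.frame(variable = v, effect = "skipped",
                                 statistic = NA, df1 = NA, df2 = NA, p = NA,
                                 epsilon = NA,
                                 note = "single day: RM-ANOVA not applicable")
      next
    }
    fit <- tryCatch(rm_anova(complete, v, alpha = alpha),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rm_rows[[v]] <- data.frame(variable = v, effect = "skipped",
                                 statistic = NA, df1 = NA, df2 = NA, p = NA,
                                 epsilon = NA, note = conditionMessage(fit))
      next
    }
    eff <- function(nm, tr, eps = NA) data.frame(
      variable = v, effect = nm, statistic = tr$statistic,
      df1 = tr$df[1], df2 = tr$df[2], p = tr$p, epsilon = eps, note = "")
    rm_rows[[v]] <- rbind(
      eff("group", fit$between),
      eff("day (GG-corrected)", fit$within_corrected,
          fit$epsilon[["greenhouse_geisser"]]),
      eff("group:day (GG-corrected)", fit$interaction_corrected,
          fit$epsilon[["greenhouse_geisser"]]))
  }

  day_rows <- list()
  ci_rows <- list()
  for (v in .MEASURED_VARS) {
    for (d in days) {
      xs <- lapply(.GROUPS, function(g)
        table[[v]][table$group == g & table$day == d])
      names(xs) <- .GROUPS
      if (any(vapply(xs, length, 0L) < 2))
        stop(sprintf("baseline_report error: fewer than 2 animals in a (group, day=%s) cell", d),
             call. = FALSE)
      sw_p <- vapply(xs, function(x) {
        if (length(x) < 3 || length(unique(x)) == 1L) return(NA_real_)
        shapiro_wilk(x, alpha)$p
      }, 0)
      normal_ok <- all(is.na(sw_p) | sw_p >= alpha)
      tt <- tryCatch(t_test(xs[[1]], xs[[2]], "welch", alpha),
                     error = function(e) NULL)
      kw <- kruskal_wallis(xs, alpha)
      day_rows[[paste(v, d)]] <- data.frame(
        variable = v, day = d,
        shapiro_p_splx = sw_p[["SPLX"]], shapiro_p_sham = sw_p[["SPL-sham"]],
        gate = if (normal_ok) "parametric" else "rank-based",
        t = if (is.null(tt)) NA else tt$statistic,
        t_df = if (is.null(tt)) NA else tt$df,
        t_p = if (is.null(tt)) NA else tt$p,
        kw_h = kw$statistic, kw_p = kw$p)
      for (g in .GROUPS) {
        x <- xs[[g]]
        m <- mean(x); sem <- sd(x) / sqrt(length(x))
        tq <- qt(1 - alpha / 2, length(x) - 1)
        ci_rows[[paste(v, d, g)]] <- data.frame(
          variable = v, day = d, group = g, n = length(x), mean = m,
          ci_low = m - tq * sem, ci_high = m + tq * sem)
      }
    }
  }
  ci <- do.call(rbind, ci_rows)
  rownames(ci) <- NULL
  # CI overlap flag per (variable, day)
  ci$overlap <- NA
  for (v in .MEASURED_VARS) for (d in days) {
    sel <- ci$variable == v & ci$day == d
    lo <- ci$ci_low[sel]; hi <- ci$ci_high[sel]
    ci$overlap[sel] <- max(lo) <= min(hi)
  }
  out <- list(rm_anova = do.call(rbind, rm_rows),
              per_day = do.call(rbind, day_rows),
              ci = ci, dropped_animals = dropped, alpha = alpha)
  rownames(out$rm_anova) <- rownames(out$per_day) <- NULL
  class(out) <- "baseline_report"
  out
}

#' Consolidate a completed run directory into a human-readable report
#'
#' Regenerating the report from the same run directory is byte-identical;
#' every number in it comes from the persisted CSV intermediates.  An
#' incomplete run produces a report flagged as partial.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return Path of the written `report.md`, invisibly.
#' @export
make_report <- function(run_dir) {
  p <- function(...) file.path(run_dir, ...)
  lines <- c("# In-silico group-separation experiment", "")
  partial <- FALSE
  grids <- list.files(run_dir, pattern = "^grid_.*\\.csv$")
  if (!length(grids)) partial <- TRUE
  for (gf in sort(grids)) {
    df_name <- sub("^grid_(.*)\\.csv$", "\\1", gf)
    g <- read.csv(p(gf), stringsAsFactors = FALSE)
    lines <- c(lines, sprintf("## Day filter: %s", df_name), "",
               sprintf("Conditions evaluated: %d", length(unique(g$condition))),
               "")
    for (cls in unique(g$class)) {
      sub_g <- g[g$class == cls, ]
      best <- sub_g[which.max(sub_g$mean_acc), ]
      worst <- sub_g[which.min(sub_g$mean_acc), ]
      lines <- c(lines,
        sprintf("- %s: best %.4f +/- %.4f (%s); worst %.4f +/- %.4f (%s)",
                cls, best$mean_acc, best$sd_acc, best$condition,
                worst$mean_acc, worst$sd_acc, worst$condition))
    }
    cf <- p(sprintf("significance_counts_%s.csv", df_name))
    if (file.exists(cf)) {
      cc <- read.csv(cf, stringsAsFactors = FALSE)
      lines <- c(lines, "", "Significance counts:")
      lines <- c(lines, sprintf("- %s: %d/%d (%.1f%%)", cc$comparison,
                                cc$count, cc$denominator, cc$percent))
    } else partial <- TRUE
    lines <- c(lines, "")
  }
  if (file.exists(p("baseline_rm_anova.csv"))) {
    rm <- read.csv(p("baseline_rm_anova.csv"), stringsAsFactors = FALSE)
    grp <- rm[rm$effect == "group", ]
    lines <- c(lines, "## Frequentist baseline (cohort scale)", "",
               sprintf("- %s: group effect F(%s, %s) = %s, p = %s",
                       grp$variable, format(grp$df1), format(grp$df2),
                       format(round(grp$statistic, 3)),
                       format(round(grp$p, 4))),
               "")
  } else partial <- TRUE
  if (partial) lines <- c("# PARTIAL REPORT (incomplete run)", "", lines)
  writeLines(lines, p("report.md"))
  invisible(p("report.md"))
}
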