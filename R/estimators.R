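#' Fit per-cell parameter estimators
#'
#' Computes, for every (group x day x variable) cell of an observation table,
#' the sample size, sample mean, sample SD (n - 1 denominator), standard
#' error, and the central-t two-sided 95% confidence interval
#' `mean +/- t(0.975, n-1) * sem`.  These estimators are the bridge between
#' the small observed cohort and the large simulated populations the
#' classifier is trained on.
#'
#' @param table a validated observation table.
#' @param covariance if `TRUE`, also stores the per-(group x day) sample
#'   covariance matrix across the six measured variables, shrunk towards its
#'   diagonal (starting weight 0.1, raised until positive definite) — 13-odd
#'   animals cannot support a raw 6x6 covariance reliably.
#' @return A data frame of class `estimator_set` with columns
#'   `group, day, variable, n, mean, sd, sem, ci95_low, ci95_high`, carrying
#'   the covariance list and a content fingerprint as attributes.
#' @export
fit_estimators <- function(table, covariance = FALSE) {
  validate_observation_table(table)
  days <- sort(unique(table$day))
  rows <- list()
  covs <- list()
  for (g in .GROUPS) {
    for (d in days) {
      cell <- table[table$group == g & table$day == d, , drop = FALSE]
      n <- nrow(cell)
      if (n < 2L)
        stop(sprintf("estimation error: cell (group=%s, day=%s) has n=%d < 2",
                     g, d, n), call. = FALSE)
      for (v in .MEASURED_VARS) {
        x <- cell[[v]]
        m <- mean(x)
        s <- sd(x)
        sem <- s / sqrt(n)
        tq <- qt(0.975, n - 1)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, day = d, variable = v, n = n, mean = m, sd = s,
          sem = sem, ci95_low = m - tq * sem, ci95_high = m + tq * sem,
          stringsAsFactors = FALSE)
      }
      if (covariance) {
        S <- stats::cov(as.matrix(cell[.MEASURED_VARS]))
        covs[[paste(g, d, sep = "|")]] <- shrink_covariance(S)
      }
    }
  }
  est <- do.call(rbind, rows)
  attr(est, "days") <- days
  attr(est, "covariance") <- if (covariance) covs else NULL
  attr(est, "fingerprint") <- fingerprint(est)
  class(est) <- c("estimator_set", "data.frame")
  est
}

# convex shrinkage towards the diagonal until positive definite
shrink_covariance <- function(S, start = 0.1) {
  D <- diag(diag(S), nrow = nrow(S))
  if (any(diag(S) <= 0)) diag(D)[diag(D) <= 0] <- 1e-12
  w <- start
  repeat {
    Sh <- (1 - w) * S + w * D
    ok <- tryCatch({ chol(Sh); TRUE }, error = function(e) FALSE)
    if (ok) return(Sh)
    if (w >= 1) return(D + diag(1e-12, nrow(S)))
    w <- min(1, w + 0.1)
  }
}

#' Simulation configuration for artificial populations
#'
#' @param population_size animals per group in the simulated population
#'   (default 500).
#' @param mode `"ci-perturbed"` (default) draws each cell's population mean
#'   uniformly from that cell's 95% confidence interval before sampling
#'   values around it — propagating the small-sample uncertainty of the
#'   estimators; `"plugin"` uses the estimated means directly.
#' @param correlation `"independent"` (default) draws variables
#'   independently within a cell; `"mv-normal"` draws the six measured
#'   variables jointly from the stored cell covariance (requires
#'   `fit_estimators(..., covariance = TRUE)`).
#' @param seed integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(population_size = 500L,
                              mode = c("ci-perturbed", "plugin"),
                              correlation = c("independent", "mv-normal"),
                              seed = 1L) {
  mode <- match.arg(mode)
  correlation <- match.arg(correlation)
  if (population_size < 2L)
    stop_config("population_size", "must be >= 2")
  structure(list(population_size = as.integer(population_size), mode = mode,
                 correlation = correlation, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate an artificial population from fitted estimators
#'
#' Draws `population_size` animals per group, each observed on every day of
#' the estimator set.  Cell values are Gaussian for mass, neurological score
#' and hemisphere volumes, and moment-matched log-normal for the
#' bioluminescence variables (matching the estimated raw-scale mean and SD).
#' In `ci-perturbed` mode each cell's population mean is first drawn
#' uniformly from its 95% CI (once per call); `plugin` mode uses the
#' estimated means as-is.  Neurological scores are rounded and clamped to the
#' Garcia range, other positive variables are floored at 1% of the (absolute)
#' cell mean.  Deterministic under a fixed seed.
#'
#' @param est an `estimator_set` from [fit_estimators()].
#' @param config a [simulation_config()].
#' @return A list of class `simulated_population` with elements `table` (an
#'   observation table) and `provenance` (estimator fingerprint, config).
#' @export
simulate_population <- function(est, config) {
  stopifnot(inherits(est, "estimator_set"), inherits(config, "simulation_config"))
  covs <- attr(est, "covariance")
  if (config$correlation == "mv-normal" && is.null(covs))
    stop_config("correlation",
                "is 'mv-normal' but the estimator set has no covariance; refit with covariance = TRUE")
  table <- with_seed(config$seed, .simulate_impl(est, config, covs))
  structure(list(table = table,
                 provenance = list(estimator_fingerprint = attr(est, "fingerprint"),
                                   config = config, seed = config$seed)),
            class = "simulated_population")
}

.simulate_impl <- function(est, config, covs) {
  days <- attr(est, "days") %||% sort(unique(est$day))
  N <- config$population_size
  out <- list()
  for (g in .GROUPS) {
    ids <- sprintf("SIM_%s_%05d", sub("-", "", g), seq_len(N))
    for (d in days) {
      cell_df <- est[est$group == g & est$day == d, , drop = FALSE]
      cell <- setNames(split(cell_df, seq_len(nrow(cell_df))), cell_df$variable)
      # population means for this cell, per mode
      mu <- vapply(.MEASURED_VARS, function(v) {
        r <- cell[[v]]
        if (config$mode == "ci-perturbed") runif(1, r$ci95_low, r$ci95_high)
        else r$mean
      }, 0)
      sds <- vapply(.MEASURED_VARS, function(v) cell[[v]]$sd, 0)
      if (config$correlation == "mv-normal") {
        S <- covs[[paste(g, d, sep = "|")]]
        vals <- rmvn(N, mu, S)
      } else {
        vals <- matrix(0, N, length(.MEASURED_VARS),
                       dimnames = list(NULL, .MEASURED_VARS))
        for (v in .MEASURED_VARS) {
          m <- mu[[v]]; s <- sds[[v]]
          if (v %in% c("bli_flux", "bli_radiance") && m > 0 && s > 0) {
            sig2 <- log(1 + (s / m)^2)
            vals[, v] <- exp(rnorm(N, log(m) - sig2 / 2, sqrt(sig2)))
          } else {
            vals[, v] <- rnorm(N, m, s)
          }
        }
      }
      df <- data.frame(animal_id = ids, group = g, day = d,
                       stringsAsFactors = FALSE)
      for (v in .MEASURED_VARS) {
        x <- vals[, v]
        if (v == "ns") x <- pmin(pmax(round_half_away(x), 3), 18)
        else x <- pmax(x, 0.01 * max(abs(mu[[v]]), .Machine$double.eps))
        df[[v]] <- x
      }
      out[[length(out) + 1L]] <- df
    }
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(match(tab$group, .GROUPS), tab$animal_id, tab$day), ]
  rownames(tab) <- NULL
  validate_observation_table(tab)
  tab
}

# multivariate normal draw via Cholesky (deterministic given R's RNG state)
rmvn <- function(n, mu, S) {
  p <- length(mu)
  R <- tryCatch(chol(S), error = function(e) chol(S + diag(1e-8, p)))
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z %*% R
  X <- sweep(X, 2, mu, "+")
  colnames(X) <- names(mu)
  X
}

#' Write / read an estimator set
#'
#' One CSV record per (group x day x variable) cell.  If the set carries
#' covariance matrices they are written alongside in long format to
#' `<path>.cov.csv` and restored on read.
#'
#' @param est an `estimator_set`.
#' @param path file path.
#' @return `read_estimator_set()` returns the restored `estimator_set`.
#' @export
write_estimator_set <- function(est, path) {
  write.csv(as.data.frame(est), path, row.names = FALSE, quote = FALSE)
  covs <- attr(est, "covariance")
  if (!is.null(covs)) {
    rows <- do.call(rbind, lapply(names(covs), function(key) {
      S <- covs[[key]]
      gd <- strsplit(key, "|", fixed = TRUE)[[1]]
      expand <- expand.grid(var1 = .MEASURED_VARS, var2 = .MEASURED_VARS,
                            stringsAsFactors = FALSE)
      data.frame(group = gd[1], day = gd[2], expand,
                 value = S[cbind(expand$var1, expand$var2)])
    }))
    write.csv(rows, paste0(path, ".cov.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_estimator_set
#' @export
read_estimator_set <- function(path) {
  est <- read.csv(path, stringsAsFactors = FALSE)
  attr(est, "days") <- sort(unique(est$day))
  covpath <- paste0(path, ".cov.csv")
  if (file.exists(covpath)) {
    rows <- read.csv(covpath, stringsAsFactors = FALSE)
    covs <- list()
    for (key in unique(paste(rows$group, rows$day, sep = "|"))) {
      gd <- strsplit(key, "|", fixed = TRUE)[[1]]
      sub <- rows[rows$group == gd[1] & rows$day == as.numeric(gd[2]), ]
      S <- matrix(0, length(.MEASURED_VARS), length(.MEASURED_VARS),
                  dimnames = list(.MEASURED_VARS, .MEASURED_VARS))
      S[cbind(sub$var1, sub$var2)] <- sub$value
      covs[[key]] <- S
    }
    attr(est, "covariance") <- covs
  }
  attr(est, "fingerprint") <- fingerprint(as.data.frame(est)[
    c("group", "day", "variable", "n", "mean", "sd", "sem",
      "ci95_low", "ci95_high")])
  class(est) <- c("estimator_set", "data.frame")
  est
}

#' All-zero group effect (null configuration helper)
#'
#' @return Named list mapping every measured variable to 0, suitable for
#'   `cohort_config(group_effect = zero_group_effect())`.
#' @export
zero_group_effect <- function() {
  setNames(as.list(rep(0, length(.MEASURED_VARS))), .MEASURED_VARS)
}
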