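.DAY_FILTERS <- c("all-days", "no-day2", "no-day2-day4")

condition_id <- function(day_filter, excluded) {
  paste0(day_filter, "|",
         if (length(excluded) == 0L) "baseline"
         else paste0("excl:", paste(sort(excluded), collapse = "+")))
}

#' Enumerate the exhaustive variable-exclusion conditions
#'
#' Returns the baseline (nothing excluded) plus one condition for every
#' non-empty proper subset of `variables` taken as the exclusion set:
#' `2^k - 1` conditions for `k` variables, so 127 for the canonical seven.
#' Order is canonical — by exclusion-set size, then lexicographic — and the
#' baseline comes first.
#'
#' @param variables variable universe (subset of [canonical_features()]).
#' @param day_filter one of `"all-days"`, `"no-day2"`, `"no-day2-day4"`.
#' @return List of `ablation_condition` objects, each with fields
#'   `day_filter`, `excluded`, `variables` and `id`.
#' @export
enumerate_conditions <- function(variables = canonical_features(),
                                 day_filter = "all-days") {
  day_filter <- match.arg(day_filter, .DAY_FILTERS)
  if (length(variables) == 0L)
    stop("enumeration error: empty variable set", call. = FALSE)
  bad <- setdiff(variables, .CANONICAL_FEATURES)
  if (length(bad))
    stop(sprintf("enumeration error: unknown variable(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  variables <- sort(unique(variables))
  k <- length(variables)
  excl_sets <- list(character(0))
  if (k > 1L) {
    for (size in seq_len(k - 1L)) {
      cols <- utils::combn(variables, size)
      excl_sets <- c(excl_sets,
                     lapply(seq_len(ncol(cols)), function(j) cols[, j]))
    }
  }
  lapply(excl_sets, function(ex)
    structure(list(day_filter = day_filter, excluded = ex,
                   variables = variables,
                   id = condition_id(day_filter, ex)),
              class = "ablation_condition"))
}

#' Apply an ablation condition to an observation table
#'
#' Removes the filtered-out days' rows and restricts the feature set to the
#' non-excluded variables (the class label and animal id always remain; when
#' `day` is excluded as a feature its column stays in the table but is no
#' longer fed to the network).
#'
#' @param table observation table.
#' @param condition an `ablation_condition`.
#' @return The filtered table with attributes `features` (remaining inputs)
#'   and `condition_id`.
#' @export
apply_condition <- function(table, condition) {
  stopifnot(inherits(condition, "ablation_condition"))
  features <- setdiff(condition$variables, condition$excluded)
  if (length(features) == 0L)
    stop("ablation error: exclusion equals the full variable set", call. = FALSE)
  keep <- switch(condition$day_filter,
                 "all-days" = rep(TRUE, nrow(table)),
                 "no-day2" = table$day != 2,
                 "no-day2-day4" = !table$day %in% c(2, 4))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "features") <- features
  attr(out, "condition_id") <- condition$id
  out
}

.checkpoint_path <- function(dir, id) {
  file.path(dir, paste0(gsub("[^A-Za-z0-9]+", "_", id), ".csv"))
}

#' Run the ablation grid
#'
#' Evaluates every condition with [evaluate_condition()], deriving each
#' condition's seed from the master seed and the condition id so results do
#' not depend on execution order.  With a checkpoint directory, completed
#' conditions are written as small CSVs and reloaded verbatim on resume.
#'
#' @param table observation table (typically a simulated population).
#' @param conditions list from [enumerate_conditions()] (may mix day
#'   filters).
#' @param spec a [network_spec()].
#' @param config an [ensemble_config()]; `config$seed` is the grid's master
#'   seed.
#' @param checkpoint_dir optional directory for checkpoint/resume.
#' @return An object of class `grid_result`: per-condition
#'   `condition_result`s plus the run metadata.
#' @export
run_grid <- function(table, conditions, spec, config, checkpoint_dir = NULL) {
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  results <- list()
  for (cond in conditions) {
    ds <- apply_condition(table, cond)
    cond_config <- config
    cond_config$seed <- derive_seed(config$seed, "condition", cond$id)
    res <- NULL
    if (!is.null(checkpoint_dir)) {
      cp <- .checkpoint_path(checkpoint_dir, cond$id)
      if (file.exists(cp)) {
        chk <- tryCatch(read.csv(cp, stringsAsFactors = FALSE),
                        error = function(e) NULL)
        ok <- !is.null(chk) &&
          all(c("replicate", "splx", "sham") %in% names(chk)) &&
          nrow(chk) == config$replicates &&
          all(is.finite(c(chk$splx, chk$sham)))
        if (!ok)
          stop(sprintf("resume error: corrupt checkpoint for condition '%s' at %s",
                       cond$id, cp), call. = FALSE)
        res <- structure(list(
          splx = accuracy_result(cond$id, "SPLX", chk$splx),
          sham = accuracy_result(cond$id, "SPL-sham", chk$sham)),
          class = "condition_result")
      }
    }
    if (is.null(res)) {
      res <- evaluate_condition(ds, spec, cond_config)
      if (!is.null(checkpoint_dir)) {
        chk <- data.frame(replicate = seq_along(res$splx$accuracies),
                          splx = res$splx$accuracies,
                          sham = res$sham$accuracies)
        write.csv(chk, .checkpoint_path(checkpoint_dir, cond$id),
                  row.names = FALSE, quote = FALSE)
      }
    }
    results[[cond$id]] <- res
  }
  structure(list(conditions = conditions, results = results,
                 replicates = config$replicates,
                 master_seed = config$seed),
            class = "grid_result")
}

#' Tabular summary of a grid result
#'
#' @param grid a `grid_result`.
#' @return Data frame with one row per condition and class: day filter,
#'   excluded variables, mean and SD accuracy, replicate count and the
#'   serialized per-replicate accuracies (so every statistic downstream is
#'   recomputable from this table alone).
#' @export
grid_summary <- function(grid) {
  rows <- lapply(grid$conditions, function(cond) {
    res <- grid$results[[cond$id]]
    do.call(rbind, lapply(list(res$splx, res$sham), function(a)
      data.frame(condition = cond$id,
                 day_filter = cond$day_filter,
                 excluded = paste(cond$excluded, collapse = "+"),
                 class = a$class,
                 mean_acc = a$mean_acc,
                 sd_acc = a$sd_acc,
                 n_replicates = length(a$accuracies),
                 accuracies = paste(format(a$accuracies, digits = 17,
                                           scientific = FALSE, trim = TRUE),
                                    collapse = ";"),
                 stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a grid summary as delimited text
#' @param grid a `grid_result`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_grid_result <- function(grid, path) {
  write.csv(grid_summary(grid), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
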