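#' Ensemble training configuration
#'
#' @param n_members networks per consensus ensemble (default 15).
#' @param train_fraction fraction of animals per class assigned to training
#'   (default 0.70, with the remaining 30% held out for validation).
#' @param bootstrap resample training animals with replacement per member
#'   (default `TRUE`).
#' @param tie_break class returned on an exact vote tie (default
#'   `"SPL-sham"`).
#' @param replicates independent split-train-evaluate repetitions used by
#'   [evaluate_condition()] (default 20; at least 2 so an SD exists).
#' @param seed master seed; all per-replicate, per-split and per-member seeds
#'   are derived from it with [derive_seed()].
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 15L,
                            train_fraction = 0.7,
                            bootstrap = TRUE,
                            tie_break = "SPL-sham",
                            replicates = 20L,
                            seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop_config("train_fraction", "must lie in (0, 1)")
  if (n_members < 1L) stop_config("n_members", "must be >= 1")
  if (replicates < 2L) stop_config("replicates", "must be >= 2")
  if (!tie_break %in% .GROUPS)
    stop_config("tie_break", "must be 'SPLX' or 'SPL-sham'")
  structure(list(n_members = as.integer(n_members),
                 train_fraction = train_fraction,
                 bootstrap = isTRUE(bootstrap),
                 tie_break = tie_break,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

.carry_features <- function(subset_table, source_table) {
  attr(subset_table, "features") <- attr(source_table, "features")
  attr(subset_table, "condition_id") <- attr(source_table, "condition_id")
  subset_table
}

#' Split a table into training and validation partitions by animal
#'
#' The split is stratified by class and performed at the animal level: per
#' class, `floor(train_fraction * n_class)` animals (at least 1, at most
#' `n_class - 1`) go to training and all their rows travel with them, so no
#' animal's repeated measures straddle the partitions.
#'
#' @param table observation table.
#' @param train_fraction training fraction in (0, 1).
#' @param seed integer seed; identical table and seed give identical splits.
#' @return List with elements `train` and `validation`.
#' @export
split_data <- function(table, train_fraction, seed) {
  per_class <- lapply(.GROUPS, function(g)
    sort(unique(table$animal_id[table$group == g])))
  names(per_class) <- .GROUPS
  small <- vapply(per_class, length, 0L) < 2L
  if (any(small))
    stop(sprintf("split error: class(es) with fewer than 2 animals: %s",
                 paste(.GROUPS[small], collapse = ", ")), call. = FALSE)
  train_ids <- with_seed(seed, unlist(lapply(.GROUPS, function(g) {
    ids <- per_class[[g]]
    k <- min(max(1L, floor(train_fraction * length(ids))), length(ids) - 1L)
    sample(ids, k)
  })))
  is_train <- table$animal_id %in% train_ids
  list(train = .carry_features(table[is_train, , drop = FALSE], table),
       validation = .carry_features(table[!is_train, , drop = FALSE], table))
}

#' Train a consensus ensemble of MLPs
#'
#' Performs one stratified animal-level 70/30 split, then trains
#' `config$n_members` members.  With `bootstrap = TRUE` each member sees an
#' animal-level resample (with replacement) of the training partition;
#' members always early-stop against the shared held-out validation
#' partition.
#'
#' @param table model-ready observation table (its `features` attribute
#'   selects the inputs).
#' @param spec a [network_spec()].
#' @param config an [ensemble_config()].
#' @return An object of class `mlp_ensemble` carrying the members and the
#'   held-out validation partition.
#' @export
train_ensemble <- function(table, spec, config) {
  parts <- split_data(table, config$train_fraction,
                      derive_seed(config$seed, "split"))
  members <- vector("list", config$n_members)
  for (i in seq_len(config$n_members)) {
    train_i <- parts$train
    if (config$bootstrap) {
      ids <- sort(unique(parts$train$animal_id))
      picked <- with_seed(derive_seed(config$seed, "bootstrap", i),
                          sample(ids, length(ids), replace = TRUE))
      rows <- unlist(lapply(picked, function(id)
        which(parts$train$animal_id == id)))
      train_i <- .carry_features(parts$train[rows, , drop = FALSE], table)
    }
    if (length(unique(train_i$group)) < 2L) {
      # a pathological resample can drop a class; redraw deterministically
      train_i <- parts$train
    }
    members[[i]] <- train_member(train_i, spec,
                                 derive_seed(config$seed, "member", i),
                                 monitor_table = parts$validation)
  }
  structure(list(members = members, validation = parts$validation,
                 train = parts$train, spec = spec, config = config,
                 features = .dataset_features(table)),
            class = "mlp_ensemble")
}

#' Consensus (majority-vote) class prediction
#'
#' Each member votes `SPLX` when its P(SPLX) is at least 0.5; the ensemble
#' label is the majority vote, with exact ties resolved to the configured
#' tie-break class.
#'
#' @param ensemble an `mlp_ensemble`.
#' @param records rows to classify (must carry the ensemble's features).
#' @return Character vector of class labels.
#' @export
consensus_predict <- function(ensemble, records) {
  votes <- vapply(ensemble$members,
                  function(m) predict(m, records) >= 0.5,
                  logical(nrow(records)))
  votes <- matrix(votes, nrow = nrow(records))
  n_splx <- rowSums(votes)
  n_memb <- length(ensemble$members)
  out <- ifelse(n_splx * 2 > n_memb, "SPLX",
                ifelse(n_splx * 2 < n_memb, "SPL-sham",
                       ensemble$config$tie_break))
  out
}

#' Class-conditional prediction accuracy (recall of one class)
#'
#' @param true_labels,predicted_labels character vectors of equal length.
#' @param target_class the class whose records are scored.
#' @return Fraction of `target_class` records predicted as `target_class`.
#' @export
class_accuracy <- function(true_labels, predicted_labels, target_class) {
  sel <- true_labels == target_class
  if (!any(sel))
    stop(sprintf("undefined accuracy: no records of class '%s'", target_class),
         call. = FALSE)
  mean(predicted_labels[sel] == target_class)
}

accuracy_result <- function(condition_id, class, accs) {
  stopifnot(all(accs >= 0 & accs <= 1))
  structure(list(condition_id = condition_id, class = class,
                 accuracies = accs, mean_acc = mean(accs),
                 sd_acc = sd(accs)),
            class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("%s | %s: %.4f +/- %.4f (%d replicates)\n",
              x$condition_id, x$class, x$mean_acc, x$sd_acc,
              length(x$accuracies)))
  invisible(x)
}

#' Evaluate one ablation condition: replicated ensemble accuracy
#'
#' Repeats split -> bootstrap-train -> consensus-predict -> per-class
#' accuracy `config$replicates` times with independently derived seeds, and
#' summarises each class's validation recall as mean over SD across
#' replicates — the quantity the downstream grid statistics compare.
#'
#' @param dataset model-ready observation table (see [apply_condition()]).
#' @param spec a [network_spec()]; its `input_dim` is adapted to the
#'   dataset's feature count.
#' @param config an [ensemble_config()].
#' @return List of class `condition_result` with `accuracy_result`s `splx`
#'   and `sham`.
#' @export
evaluate_condition <- function(dataset, spec, config) {
  features <- .dataset_features(dataset)
  if (spec$input_dim != length(features)) {
    spec$input_dim <- length(features)
  }
  cond_id <- attr(dataset, "condition_id") %||% "adhoc"
  acc <- matrix(NA_real_, config$replicates, 2,
                dimnames = list(NULL, .GROUPS))
  for (r in seq_len(config$replicates)) {
    rep_config <- config
    rep_config$seed <- derive_seed(config$seed, cond_id, "replicate", r)
    ens <- train_ensemble(dataset, spec, rep_config)
    pred <- consensus_predict(ens, ens$validation)
    for (g in .GROUPS)
      acc[r, g] <- class_accuracy(ens$validation$group, pred, g)
  }
  structure(list(splx = accuracy_result(cond_id, "SPLX", acc[, "SPLX"]),
                 sham = accuracy_result(cond_id, "SPL-sham", acc[, "SPL-sham"])),
            class = "condition_result")
}
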