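#' Network architecture and training specification
#'
#' Defines the multilayer perceptron used throughout the pipeline: exactly
#' seven hidden layers, rectified-linear activations on hidden layers 1-6 and
#' a logistic sigmoid on hidden layer 7, dropout after every hidden layer, a
#' single sigmoid output unit giving P(SPLX), Adam optimisation of the binary
#' cross-entropy, and early stopping on monitoring loss.  The default widths
#' 72-96-72-48-32-16-8 with a 7-feature input give 20 313 trainable
#' parameters.
#'
#' @param input_dim number of input features (default 7, the canonical set).
#' @param hidden_widths widths of the seven hidden layers.
#' @param dropout_rate dropout probability per hidden layer, in `[0, 1)`.
#' @param learning_rate initial Adam learning rate.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without monitoring-loss
#'   improvement); `0` disables early stopping.
#' @param batch_size minibatch size.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(input_dim = 7L,
                         hidden_widths = c(72L, 96L, 72L, 48L, 32L, 16L, 8L),
                         dropout_rate = 0.2,
                         learning_rate = 1e-3,
                         epochs = 200L,
                         patience = 20L,
                         batch_size = 32L) {
  if (length(hidden_widths) != 7L)
    stop_config("hidden_widths", "must name exactly 7 hidden layers")
  if (any(hidden_widths < 1L)) stop_config("hidden_widths", "must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_config("dropout_rate", "must lie in [0, 1)")
  if (input_dim < 1L) stop_config("input_dim", "must be >= 1")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_widths = as.integer(hidden_widths),
                 dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size)),
            class = "network_spec")
}

#' Trainable parameter count of a network specification
#' @param spec a [network_spec()].
#' @return Integer number of weights plus biases.
#' @export
n_parameters <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden_widths, 1L)
  sum(dims[-length(dims)] * dims[-1]) + sum(dims[-1])
}

.dataset_features <- function(table) {
  attr(table, "features") %||% .CANONICAL_FEATURES
}

.feature_matrix <- function(table, features) {
  missing_f <- setdiff(features, names(table))
  if (length(missing_f))
    stop(sprintf("prediction error: feature mismatch, missing: %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  as.matrix(as.data.frame(lapply(table[features], as.numeric)))
}

#' Train a single MLP member
#'
#' Features are z-scored with training-set statistics that are frozen into
#' the member; constant features get unit scale.  When a monitoring table is
#' supplied and the spec's patience is positive, training early-stops on its
#' binary cross-entropy and the best weights are restored.
#'
#' @param train_table observation-table rows to train on (both classes must
#'   be present); its `features` attribute, if any, selects the input
#'   variables.
#' @param spec a [network_spec()] whose `input_dim` matches the feature set.
#' @param seed integer seed controlling init, shuffling and dropout.
#' @param monitor_table optional held-out rows monitored for early stopping.
#' @return An object of class `mlp_member`; `predict()` on it returns
#'   P(SPLX) per row.  Identical inputs and seed give identical members.
#' @export
train_member <- function(train_table, spec, seed, monitor_table = NULL) {
  features <- .dataset_features(train_table)
  if (length(features) != spec$input_dim)
    stop(sprintf("training error: spec input_dim %d does not match %d features",
                 spec$input_dim, length(features)), call. = FALSE)
  if (nrow(train_table) == 0L)
    stop("training error: empty training set", call. = FALSE)
  if (length(unique(train_table$group)) < 2L)
    stop("training error: training set contains a single class", call. = FALSE)
  X <- .feature_matrix(train_table, features)
  y <- as.numeric(train_table$group == "SPLX")
  centers <- colMeans(X)
  scales <- apply(X, 2, sd)
  scales[!is.finite(scales) | scales == 0] <- 1
  Xs <- scale(X, center = centers, scale = scales)
  if (!is.null(monitor_table) && nrow(monitor_table) > 0L && spec$patience > 0L) {
    Xm <- scale(.feature_matrix(monitor_table, features),
                center = centers, scale = scales)
    ym <- as.numeric(monitor_table$group == "SPLX")
  } else {
    Xm <- matrix(0, 0, length(features))
    ym <- numeric(0)
  }
  fit <- cpp_mlp_train(Xs, y, Xm, ym, spec$hidden_widths,
                       spec$dropout_rate, spec$learning_rate,
                       spec$epochs, spec$batch_size, spec$patience,
                       as.numeric(seed))
  structure(list(W = fit$W, b = fit$b, features = features,
                 centers = centers, scales = scales,
                 n_hidden = length(spec$hidden_widths),
                 initial_loss = fit$initial_loss,
                 final_loss = fit$final_loss,
                 epochs_run = fit$epochs_run,
                 seed = as.integer(seed)),
            class = "mlp_member")
}

#' @export
predict.mlp_member <- function(object, newdata, ...) {
  X <- .feature_matrix(newdata, object$features)
  Xs <- scale(X, center = object$centers, scale = object$scales)
  as.numeric(cpp_mlp_predict(object$W, object$b, Xs, object$n_hidden))
}
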