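#' @useDynLib mcaonet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate kruskal.test oneway.test pf predict pt qt
#'   quantile rbinom rnorm runif sd setNames shapiro.test t.test var
#' @importFrom utils capture.output combn read.csv write.csv
NULL

# The seven canonical input variables of the classifier: observation day plus
# the six measured outcomes (mass in g, Garcia neurological score, MRI
# ipsi-/contralateral hemisphere volumes in mm^3, BLI peak flux in photons/s,
# BLI peak radiance in photons/s/cm^2/sr).
.MEASURED_VARS <- c("mass", "ns", "mr_il", "mr_cl", "bli_flux", "bli_radiance")
.CANONICAL_FEATURES <- c("day", .MEASURED_VARS)
.GROUPS <- c("SPLX", "SPL-sham")
.TABLE_COLUMNS <- c("animal_id", "group", "day", .MEASURED_VARS)

#' Canonical classifier features
#'
#' The seven variables the classifier can see: the post-stroke day and the six
#' measured outcomes.
#' @return Character vector of length 7.
#' @export
canonical_features <- function() .CANONICAL_FEATURES

#' Derive a child seed from a master seed and a path of labels
#'
#' Counter-based seed derivation: the master seed and an arbitrary path of
#' labels (stage name, condition id, replicate index, ...) are hashed to a
#' positive integer below 2^31 - 1.  The derivation depends only on the path,
#' never on execution order, so parallel or resumed runs reproduce the same
#' per-task seeds.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return A single integer seed in \[1, 2147483646\].
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "/")
  bytes <- utf8ToInt(key)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h) + 1L
}

# Evaluate expr under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# round half away from zero, platform-stable (unlike round()'s banker's rule)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# short content fingerprint of a data frame (provenance stamping)
fingerprint <- function(df) {
  s <- paste(capture.output(write.csv(df, row.names = FALSE)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("fp%010d", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}
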