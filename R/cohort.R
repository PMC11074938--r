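#' Configuration for a synthetic splenectomy-MCAO cohort
#'
#' Describes the study design emulated by [generate_cohort()]: two groups of
#' mice (splenectomized, `SPLX`, and sham-operated, `SPL-sham`) followed after
#' middle cerebral artery occlusion, with six outcome variables recorded on a
#' fixed set of post-stroke days.  The real study this design mirrors enrolled
#' 13 SPLX and 14 sham survivors observed on days 2, 4, 7 and 28; those are
#' the defaults.
#'
#' All distributional settings are stand-ins chosen to look like a plausible
#' mouse MCAO cohort — the motivating study deposited no raw data, so none of
#' these numbers are estimates of real parameters.
#'
#' @param n_splx,n_sham animals per group (defaults 13 and 14).
#' @param days strictly increasing positive post-stroke observation days.
#' @param baseline_mean,baseline_sd named per-variable location and scale.
#'   For `mass`, `ns`, `mr_il`, `mr_cl` these are on the raw scale (g, Garcia
#'   score units, mm^3).  For the bioluminescence variables (`bli_flux`,
#'   `bli_radiance`), which span orders of magnitude and are generated
#'   log-normally, `baseline_mean` is the baseline median on the raw scale and
#'   `baseline_sd` is the standard deviation of the natural log.
#' @param time_profile named list, one numeric vector per variable with one
#'   entry per day: additive shift for the Gaussian variables, multiplicative
#'   fold change for the log-normal ones.  Encodes the stroke effect.
#' @param group_effect named list: standardized group difference
#'   (SPLX minus sham) per variable, in units of `baseline_sd`; a scalar or a
#'   per-day vector.  Zero everywhere is the null configuration.
#' @param within_animal_rho correlation, in `[0, 1)`, of one animal's
#'   deviations across days (exchangeable animal-level random intercept).
#' @param positive_floor strictly positive Gaussian variables are clamped at
#'   `positive_floor * baseline_mean` (log-normal variables are positive by
#'   construction).
#' @param seed integer RNG seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_splx = 13L,
                          n_sham = 14L,
                          days = c(2L, 4L, 7L, 28L),
                          baseline_mean = NULL,
                          baseline_sd = NULL,
                          time_profile = NULL,
                          group_effect = NULL,
                          within_animal_rho = 0.5,
                          positive_floor = 0.01,
                          seed = 1L) {
  def_mean <- c(mass = 26, ns = 18, mr_il = 228, mr_cl = 225,
                bli_flux = 1e6, bli_radiance = 5e4)
  def_sd <- c(mass = 1.8, ns = 1.2, mr_il = 10, mr_cl = 9,
              bli_flux = 0.5, bli_radiance = 0.5)
  nd <- length(days)
  def_profile <- list(
    mass = c(-3.0, -3.5, -2.5, -0.8),
    ns = c(-7.0, -6.0, -4.5, -2.0),
    mr_il = c(25, 18, 10, -4),
    mr_cl = c(0, 0, 1, 2),
    bli_flux = c(5, 3.5, 2, 1),
    bli_radiance = c(4, 3, 1.8, 1))
  # modest protective SPLX signal by default, below frequentist detectability
  def_effect <- list(mass = 0.2, ns = 0.3, mr_il = -0.3, mr_cl = 0,
                     bli_flux = -0.3, bli_radiance = -0.3)
  if (nd != 4L && is.null(time_profile)) {
    # default trajectories are defined for the canonical 4 days; otherwise flat
    def_profile <- lapply(names(def_profile), function(v)
      rep(if (v %in% c("bli_flux", "bli_radiance")) 1 else 0, nd))
    names(def_profile) <- .MEASURED_VARS
  }
  cfg <- list(
    n_splx = as.integer(n_splx), n_sham = as.integer(n_sham),
    days = as.numeric(days),
    baseline_mean = .merge_named(def_mean, baseline_mean, "baseline_mean"),
    baseline_sd = .merge_named(def_sd, baseline_sd, "baseline_sd"),
    time_profile = .merge_named(def_profile, time_profile, "time_profile"),
    group_effect = .merge_named(def_effect, group_effect, "group_effect"),
    within_animal_rho = within_animal_rho,
    positive_floor = positive_floor,
    seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

.merge_named <- function(defaults, user, field) {
  if (is.null(user)) return(defaults)
  bad <- setdiff(names(user), .MEASURED_VARS)
  if (length(bad) || is.null(names(user)))
    stop_config(field, sprintf("has unknown variable(s): %s",
                               paste(bad, collapse = ", ")))
  defaults[names(user)] <- user
  defaults
}

#' Validate a cohort configuration
#'
#' @param cfg a `cohort_config`.
#' @return `cfg`, invisibly, or an error naming the offending field.
#' @export
validate_cohort_config <- function(cfg) {
  if (cfg$n_splx < 2L) stop_config("n_splx", "must be >= 2")
  if (cfg$n_sham < 2L) stop_config("n_sham", "must be >= 2")
  if (length(cfg$days) < 1L || any(cfg$days <= 0) ||
      any(diff(cfg$days) <= 0))
    stop_config("days", "must be strictly increasing and positive")
  if (any(cfg$baseline_sd < 0)) stop_config("baseline_sd", "must be >= 0")
  if (any(cfg$baseline_mean[c("mass", "mr_il", "mr_cl",
                              "bli_flux", "bli_radiance")] <= 0))
    stop_config("baseline_mean", "must be > 0 for positive-valued variables")
  if (cfg$within_animal_rho < 0 || cfg$within_animal_rho >= 1)
    stop_config("within_animal_rho", "must lie in [0, 1)")
  if (cfg$positive_floor <= 0 || cfg$positive_floor >= 1)
    stop_config("positive_floor", "must lie in (0, 1)")
  nd <- length(cfg$days)
  for (v in .MEASURED_VARS) {
    if (length(cfg$time_profile[[v]]) != nd)
      stop_config("time_profile", sprintf("for '%s' needs %d entries", v, nd))
    ge <- cfg$group_effect[[v]]
    if (!length(ge) %in% c(1L, nd))
      stop_config("group_effect",
                  sprintf("for '%s' must be scalar or length %d", v, nd))
  }
  invisible(cfg)
}

#' Generate a synthetic cohort table
#'
#' Draws one row per animal and day.  Each variable is generated as
#' baseline + time profile + group effect + correlated animal-level deviation
#' + independent noise.  The animal-level intercept carries a fraction
#' `within_animal_rho` of the total deviation variance (`baseline_sd^2`), the
#' day-level noise the rest, so deviations of one animal across days have
#' exchangeable correlation `within_animal_rho` and total SD `baseline_sd`.
#' Bioluminescence variables are generated on the log scale (log-normal on the
#' raw scale); the neurological score is rounded half-away-from-zero to an
#' integer and clamped to the Garcia range 3-18.
#'
#' @param config a [cohort_config()].
#' @return An observation table (data frame) with columns
#'   `animal_id, group, day, mass, ns, mr_il, mr_cl, bli_flux, bli_radiance`,
#'   passing [validate_observation_table()].  Identical config and seed yield
#'   an identical table.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(cfg) {
  ids <- c(sprintf("SPLX_%02d", seq_len(cfg$n_splx)),
           sprintf("SHAM_%02d", seq_len(cfg$n_sham)))
  groups <- rep(.GROUPS, c(cfg$n_splx, cfg$n_sham))
  n_animal <- length(ids)
  nd <- length(cfg$days)
  out <- data.frame(
    animal_id = rep(ids, each = nd),
    group = rep(groups, each = nd),
    day = rep(cfg$days, times = n_animal),
    stringsAsFactors = FALSE)
  rho <- cfg$within_animal_rho
  for (v in .MEASURED_VARS) {
    sdv <- cfg$baseline_sd[[v]]
    ge <- cfg$group_effect[[v]]
    if (length(ge) == 1L) ge <- rep(ge, nd)
    intercept <- rnorm(n_animal, 0, sqrt(rho) * sdv)
    noise <- rnorm(n_animal * nd, 0, sqrt(1 - rho) * sdv)
    eff <- ifelse(rep(groups, each = nd) == "SPLX", rep(ge, n_animal), 0) * sdv
    dev <- rep(intercept, each = nd) + noise + eff
    if (v %in% c("bli_flux", "bli_radiance")) {
      mu <- log(cfg$baseline_mean[[v]]) + log(rep(cfg$time_profile[[v]], n_animal))
      out[[v]] <- exp(mu + dev)
    } else {
      y <- cfg$baseline_mean[[v]] + rep(cfg$time_profile[[v]], n_animal) + dev
      if (v == "ns") {
        out[[v]] <- pmin(pmax(round_half_away(y), 3), 18)
      } else {
        out[[v]] <- pmax(y, cfg$positive_floor * cfg$baseline_mean[[v]])
      }
    }
  }
  validate_observation_table(out)
  out
}

#' Validate an observation table
#'
#' Checks the structural invariants of the long-format animal-day table:
#' required columns, unique `(animal_id, day)` pairs, the two canonical group
#' labels with one label per animal, Garcia bounds 3-18 on `ns`, and strict
#' positivity of mass, volumes and bioluminescence.
#'
#' @param table data frame to check.
#' @return `table`, invisibly; errors cite the offending rows.
#' @export
validate_observation_table <- function(table) {
  missing_cols <- setdiff(.TABLE_COLUMNS, names(table))
  if (length(missing_cols))
    stop(sprintf("observation table parse error: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  dup <- duplicated(table[c("animal_id", "day")])
  if (any(dup))
    stop(sprintf("observation table parse error: duplicate (animal_id, day) at row(s) %s",
                 paste(which(dup), collapse = ", ")), call. = FALSE)
  bad_grp <- !table$group %in% .GROUPS
  if (any(bad_grp))
    stop(sprintf("observation table parse error: unknown group label at row(s) %s (must be 'SPLX' or 'SPL-sham')",
                 paste(which(bad_grp), collapse = ", ")), call. = FALSE)
  multi <- tapply(table$group, table$animal_id,
                  function(g) length(unique(g)) > 1L)
  if (any(multi))
    stop(sprintf("observation table validation error: animal(s) with multiple group labels: %s",
                 paste(names(multi)[multi], collapse = ", ")), call. = FALSE)
  bad_ns <- table$ns < 3 | table$ns > 18
  if (any(bad_ns))
    stop(sprintf("observation table validation error: ns outside Garcia scale bounds [3, 18] at row(s) %s",
                 paste(which(bad_ns), collapse = ", ")), call. = FALSE)
  for (v in c("mass", "mr_il", "mr_cl", "bli_flux", "bli_radiance")) {
    bad <- !is.finite(table[[v]]) | table[[v]] <= 0
    if (any(bad))
      stop(sprintf("observation table validation error: non-positive %s at row(s) %s",
                   v, paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(table)
}

#' Write / read an observation table
#'
#' Comma-separated, UTF-8, dot decimal separator, canonical header
#' `animal_id,group,day,mass,ns,mr_il,mr_cl,bli_flux,bli_radiance`.
#' `read_observation_table()` validates on read.
#'
#' @param table an observation table.
#' @param path file path.
#' @return `read_observation_table()` returns the validated data frame;
#'   `write_observation_table()` returns `path` invisibly.
#' @export
write_observation_table <- function(table, path) {
  validate_observation_table(table)
  write.csv(table[.TABLE_COLUMNS], path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_observation_table
#' @export
read_observation_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_observation_table(tab)
  tab[.TABLE_COLUMNS]
}
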