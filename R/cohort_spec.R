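#' Scenario specification for the synthetic athlete cohort
#'
#' Bundles every parameter the generator needs: group sizes, per-group
#' baseline and 12-month endpoint calibration for the named features, the
#' psychology-to-immunity lag, the serial mediation chain coefficients, the
#' resilience-tertile response dynamics, and the degradation (missingness /
#' outlier) settings.
#'
#' Time is indexed in bi-weekly steps `0 .. n_timepoints - 1`; the last
#' index is the 12-month endpoint, so month `m` corresponds to index
#' `m * (n_timepoints - 1) / 12`.
#'
#' @param n_per_group Integer vector of dietary-group sizes, named
#'   `high_carb`, `high_protein`, `balanced`. Default `c(68, 65, 67)`.
#' @param n_timepoints Number of bi-weekly time points `T` (default 24).
#' @param baseline_profiles Per-group mean/SD list for calibrated features;
#'   see [default_baseline_profiles()].
#' @param trajectory_targets Per-group 12-month endpoint mean/SD list; see
#'   [default_trajectory_targets()]. Features absent here stay flat.
#' @param lag_steps Number of bi-weekly steps by which psychological change
#'   precedes immune change (default 3, about 1.5 months).
#' @param mediation_coeffs Named numeric vector `a1, a2, b1, b2, cprime`
#'   for the diet -> psychology -> cortisol -> immunity chain.
#' @param subgroup_dynamics Per-tertile response dynamics: a list with
#'   entries `low`, `moderate`, `high`, each `(onset_months, onset_sd,
#'   rate_per_month, plateau_months, plateau_sd, amplitude)`.
#' @param missing_rate Fraction of cells masked per athlete, in `[0, 0.2)`.
#' @param outlier_rate Fraction of cells displaced by >= 4 population SDs.
#' @param noise_scale Within-athlete iid noise SD, in units of each
#'   feature's baseline SD (default 0.25).
#' @param ar_phi,ar_sd AR(1) parameters of the shared within-athlete
#'   psychological shock that propagates into immune markers after
#'   `lag_steps` (defaults 0.6 and 0.45 SD units).
#' @param lag_gain Gain with which the lagged psychological shock enters
#'   immune markers (default 0.9).
#' @param seed Integer seed for the generator.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_per_group = c(high_carb = 68, high_protein = 65,
                                        balanced = 67),
                        n_timepoints = 24,
                        baseline_profiles = default_baseline_profiles(),
                        trajectory_targets = default_trajectory_targets(),
                        lag_steps = 3,
                        mediation_coeffs = c(a1 = 0.5, a2 = 0.6, b1 = 0.4,
                                             b2 = 0.4, cprime = 0.2),
                        subgroup_dynamics = default_subgroup_dynamics(),
                        missing_rate = 0,
                        outlier_rate = 0,
                        noise_scale = 0.25,
                        ar_phi = 0.6,
                        ar_sd = 0.45,
                        lag_gain = 0.9,
                        seed = 1L) {
  spec <- list(
    n_per_group = n_per_group, n_timepoints = as.integer(n_timepoints),
    baseline_profiles = baseline_profiles,
    trajectory_targets = trajectory_targets,
    lag_steps = as.integer(lag_steps),
    mediation_coeffs = mediation_coeffs,
    subgroup_dynamics = subgroup_dynamics,
    missing_rate = missing_rate, outlier_rate = outlier_rate,
    noise_scale = noise_scale, ar_phi = ar_phi, ar_sd = ar_sd,
    lag_gain = lag_gain, seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Default resilience-tertile response dynamics
#'
#' Onset and plateau times (months, with between-athlete SDs) per baseline
#' resilience tertile, plus the per-month improvement rate the subgroups
#' exhibit and a relative improvement-amplitude multiplier (normalised to
#' mean 1 within each dietary group at generation time).
#'
#' @return Named list with entries `high`, `moderate`, `low`.
#' @export
default_subgroup_dynamics <- function() {
  list(
    high     = list(onset_months = 1.2, onset_sd = 0.3, rate_per_month = 0.43,
                    plateau_months = 6.8, plateau_sd = 1.2, amplitude = 1.25),
    moderate = list(onset_months = 2.1, onset_sd = 0.5, rate_per_month = 0.18,
                    plateau_months = 9.5, plateau_sd = 1.8, amplitude = 1.00),
    low      = list(onset_months = 3.8, onset_sd = 0.9, rate_per_month = 0.10,
                    plateau_months = 11.2, plateau_sd = 2.1, amplitude = 0.75)
  )
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$n_per_group <= 0)) {
    stop("cohort_spec: all group sizes must be positive", call. = FALSE)
  }
  if (!all(DIET_GROUPS %in% names(spec$n_per_group))) {
    stop("cohort_spec: n_per_group must be named high_carb/high_protein/balanced",
         call. = FALSE)
  }
  if (spec$n_timepoints < 2) {
    stop("cohort_spec: need at least 2 time points", call. = FALSE)
  }
  if (spec$lag_steps < 0) stop("cohort_spec: lag_steps must be >= 0", call. = FALSE)
  if (spec$missing_rate < 0 || spec$missing_rate >= 0.2) {
    stop("cohort_spec: missing_rate must lie in [0, 0.2) (inclusion rule: ",
         "athletes must have < 20% missing values)", call. = FALSE)
  }
  if (spec$outlier_rate < 0 || spec$outlier_rate > 0.2) {
    stop("cohort_spec: outlier_rate must lie in [0, 0.2]", call. = FALSE)
  }
  for (feat in names(spec$baseline_profiles)) {
    prof <- spec$baseline_profiles[[feat]]
    if (any(prof$sd <= 0)) {
      stop("cohort_spec: baseline SD for '", feat, "' must be > 0", call. = FALSE)
    }
    if (feat %in% PSYCH_FEATURES &&
        (any(prof$mean < 0) || any(prof$mean > 10))) {
      stop("cohort_spec: psychological scale mean for '", feat,
           "' must lie in [0, 10]", call. = FALSE)
    }
  }
  needed <- c("a1", "a2", "b1", "b2", "cprime")
  if (!all(needed %in% names(spec$mediation_coeffs))) {
    stop("cohort_spec: mediation_coeffs must contain ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  athletes:", sum(x$n_per_group), sprintf("(%s)",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
            collapse = ", ")), "\n")
  cat("  time points:", x$n_timepoints, "bi-weekly steps\n")
  cat("  psych->immune lag:", x$lag_steps, "steps (",
      round(steps_to_months(x$lag_steps, x$n_timepoints), 2), "months )\n")
  cat("  mediation chain:", paste(sprintf("%s=%.2f",
      names(x$mediation_coeffs), x$mediation_coeffs), collapse = ", "), "\n")
  cat("  missing_rate:", x$missing_rate, " outlier_rate:", x$outlier_rate, "\n")
  invisible(x)
}

#' Convert bi-weekly time indices to months (and back)
#'
#' The panel spans 12 months over `n_timepoints` bi-weekly indices, with the
#' last index at exactly 12 months.
#'
#' @param steps,months Numeric vectors.
#' @param n_timepoints Number of time points in the panel.
#' @return Numeric vector.
#' @export
steps_to_months <- function(steps, n_timepoints = 24) {
  steps * 12 / (n_timepoints - 1)
}

#' @rdname steps_to_months
#' @export
months_to_steps <- function(months, n_timepoints = 24) {
  months * (n_timepoints - 1) / 12
}
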