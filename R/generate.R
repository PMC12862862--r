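#' Classify dietary pattern from macronutrient intake
#'
#' Labelling rules: high-carbohydrate = more than 60% of energy from
#' carbohydrate with protein below 1.2 g/kg/day; high-protein = protein at
#' or above 1.6 g/kg/day with 45-55% carbohydrate; balanced = 50-60%
#' carbohydrate with 1.2-1.6 g/kg/day protein.
#'
#' @param carb_pct_energy Percent of total energy from carbohydrate.
#' @param protein_g_kg Protein intake in g per kg body weight per day.
#' @return Character vector in `{high_carb, high_protein, balanced, other}`.
#' @export
classify_dietary_pattern <- function(carb_pct_energy, protein_g_kg) {
  dplyr::case_when(
    carb_pct_energy > 60 & protein_g_kg < 1.2 ~ "high_carb",
    protein_g_kg >= 1.6 & carb_pct_energy >= 45 & carb_pct_energy <= 55 ~
      "high_protein",
    carb_pct_energy >= 50 & carb_pct_energy <= 60 &
      protein_g_kg >= 1.2 & protein_g_kg <= 1.6 ~ "balanced",
    TRUE ~ "other"
  )
}

# Intake truncation windows that keep sampled macronutrient values inside
# each group's labelling rule.
intake_limits <- function(group, feature) {
  lims <- list(
    high_carb    = list(carb_pct_energy = c(60.2, 72), protein_g_kg = c(0.6, 1.18)),
    high_protein = list(carb_pct_energy = c(45.2, 54.8), protein_g_kg = c(1.6, 2.6)),
    balanced     = list(carb_pct_energy = c(50.2, 59.8), protein_g_kg = c(1.2, 1.6))
  )
  lims[[group]][[feature]]
}

#' Generate the baseline (time 0) panel
#'
#' Draws one row per athlete at `time_index` 0. Calibrated features use the
#' per-group means/SDs in `spec$baseline_profiles`; the remaining features
#' use the shared filler profiles. A single latent per-athlete "strain"
#' factor induces the planted cross-sectional correlation between the
#' psychological and immune blocks; macronutrient intake is truncated to
#' each group's labelling window so the dietary classification rules
#' reproduce the group labels. Resilience tertiles are assigned from the
#' generated baseline resilience score.
#'
#' @param spec A [cohort_spec()].
#' @return Long-format athlete panel restricted to `time_index == 0`.
#' @export
generate_baseline <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- sum(spec$n_per_group)
  groups <- rep(DIET_GROUPS, times = spec$n_per_group[DIET_GROUPS])
  ids <- sprintf("A%04d", seq_len(n))
  strain <- stats::rnorm(n)
  loadings <- strain_loadings()
  fillers <- default_filler_profiles()

  wide <- tibble::tibble(athlete_id = ids, group = groups, time_index = 0L)
  for (feat in ALL_FEATURES) {
    lam <- if (feat %in% names(loadings)) loadings[[feat]] else 0
    noise <- lam * strain + sqrt(1 - lam^2) * stats::rnorm(n)
    if (feat %in% names(spec$baseline_profiles)) {
      prof <- spec$baseline_profiles[[feat]]
      x <- prof$mean[groups] + prof$sd[groups] * noise
      if (feat %in% c("carb_pct_energy", "protein_g_kg")) {
        for (g in DIET_GROUPS) {
          lim <- intake_limits(g, feat)
          sel <- groups == g
          x[sel] <- pmin(pmax(x[sel], lim[1]), lim[2])
        }
      }
    } else {
      prof <- fillers[[feat]]
      x <- prof$mean + prof$sd * noise
    }
    x <- clip_to_scale(x, feat, spec)
    wide[[feat]] <- unname(x)
  }
  wide$tertile <- unname(stratify_tertiles(
    tibble::tibble(athlete_id = ids, value = wide$resilience)))
  panel <- panel_long(wide[, c("athlete_id", "group", "tertile", "time_index",
                               ALL_FEATURES)])
  check_panel(panel)
  panel
}

# Clip values to the feature's natural scale: psychological scores to
# [0, 10], concentrations/volumes to strictly positive.
clip_to_scale <- function(x, feat, spec) {
  if (feat %in% PSYCH_FEATURES) return(pmin(pmax(x, 0), 10))
  mu <- if (feat %in% names(spec$baseline_profiles)) {
    mean(spec$baseline_profiles[[feat]]$mean)
  } else {
    default_filler_profiles()[[feat]]$mean
  }
  pmax(x, 0.02 * abs(mu))
}

# Saturating-exponential response fraction at month m for an athlete with
# the given onset and plateau (months): 0 before onset, ~95% of the way by
# the plateau, normalised so the 12-month endpoint fraction is exactly 1.
saturating_fraction <- function(m, onset, plateau) {
  k <- 3 / pmax(plateau - onset, 0.5)
  num <- ifelse(m <= onset, 0, 1 - exp(-k * (m - onset)))
  den <- 1 - exp(-k * pmax(12 - onset, 0.1))
  pmin(num / den, 1.25)
}

#' Extend a baseline panel to full 12-month trajectories
#'
#' Plants the longitudinal structure the downstream analyses estimate:
#'
#' * each calibrated feature follows a saturating-exponential path from its
#'   baseline toward a per-athlete 12-month endpoint whose group mean is the
#'   `trajectory_targets` calibration;
#' * onset and plateau times (and an improvement-amplitude multiplier,
#'   normalised to mean 1 within each dietary group) come from the athlete's
#'   resilience tertile;
#' * immune markers follow the psychological response curve delayed by
#'   `lag_steps` bi-weekly steps, and a shared within-athlete AR(1)
#'   psychological shock re-enters the immune markers after the same lag,
#'   so a lag-correlation scan peaks at the planted lag;
#' * per-athlete endpoint deviations follow the serial chain
#'   diet -> psychological improvement -> cortisol reduction -> immune
#'   improvement with coefficients `spec$mediation_coeffs` (group-centred,
#'   so the group calibration is unaffected).
#'
#' @param baseline Panel from [generate_baseline()] (time 0 only).
#' @param spec The same [cohort_spec()].
#' @return Long-format panel covering all `n_timepoints` indices, with the
#'   per-athlete chain scores attached as attribute `chain_scores`.
#' @export
generate_trajectories <- function(baseline, spec) {
  validate_cohort_spec(spec)
  check_panel(baseline)
  if (any(baseline$time_index != 0)) {
    stop("generate_trajectories: baseline panel must only contain time 0",
         call. = FALSE)
  }
  wide0 <- panel_wide(baseline)
  if (!all(ALL_FEATURES %in% names(wide0))) {
    stop("generate_trajectories: baseline is missing feature columns",
         call. = FALSE)
  }
  set.seed(spec$seed + 1000L)
  n <- nrow(wide0)
  tt <- spec$n_timepoints
  months <- steps_to_months(0:(tt - 1), tt)
  groups <- wide0$group
  tertiles <- wide0$tertile
  lag <- spec$lag_steps
  lag_c <- floor(lag / 2)

  # per-athlete response dynamics from the resilience tertile
  dyn <- spec$subgroup_dynamics
  onset <- plateau <- amp <- numeric(n)
  for (tr in names(dyn)) {
    sel <- tertiles == tr
    d <- dyn[[tr]]
    onset[sel] <- pmax(stats::rnorm(sum(sel), d$onset_months, d$onset_sd), 0.2)
    plateau[sel] <- stats::rnorm(sum(sel), d$plateau_months, d$plateau_sd)
    amp[sel] <- d$amplitude * (d$rate_per_month > 0)
  }
  plateau <- pmax(plateau, onset + 1)
  # graded dependence of the response amplitude on baseline psychological
  # state (strongest for resilience, then fatigue, stress, sleep quality),
  # on top of the tertile amplitude; within-group z-scores keep the group
  # calibration unbiased after renormalisation
  zb <- function(feat) {
    v <- wide0[[feat]]
    stats::ave(v, groups, FUN = function(z) (z - mean(z)) / max(sd(z), 1e-9))
  }
  amp <- amp * pmax(1 + 0.30 * zb("resilience") + 0.22 * zb("fatigue") +
                      0.16 * zb("stress") + 0.03 * zb("sleep_quality"), 0.2)
  for (g in DIET_GROUPS) {       # keep group endpoint calibration unbiased
    sel <- groups == g
    m <- mean(amp[sel])
    if (m > 0) amp[sel] <- amp[sel] / m
  }

  # serial mediation chain on athlete-level improvement deviations
  mc <- spec$mediation_coeffs
  x_diet <- c(high_carb = 0, high_protein = 0.5, balanced = 1)[groups] +
    stats::rnorm(n, 0, 0.15)
  p_dev <- mc[["a1"]] * x_diet + stats::rnorm(n, 0, 0.4)
  c_dev <- mc[["a2"]] * p_dev + stats::rnorm(n, 0, 0.4)
  i_dev <- mc[["b1"]] * p_dev + mc[["b2"]] * c_dev + mc[["cprime"]] * x_diet +
    stats::rnorm(n, 0, 0.4)
  center <- function(v) stats::ave(v, groups, FUN = function(z) z - mean(z))
  p_c <- center(p_dev); c_c <- center(c_dev); i_c <- center(i_dev)

  # shared AR(1) psychological shock, simulated from t = -lag so immune
  # markers have a lagged copy from the first index onwards
  phi <- spec$ar_phi
  innov_sd <- spec$ar_sd * sqrt(1 - phi^2)
  n_u <- tt + lag
  u <- matrix(0, n, n_u)
  u[, 1] <- stats::rnorm(n, 0, spec$ar_sd)
  for (t in 2:n_u) u[, t] <- phi * u[, t - 1] + stats::rnorm(n, 0, innov_sd)
  u_now <- u[, (lag + 1):n_u, drop = FALSE]          # u_t for t = 0..T-1
  u_lag <- u[, (lag + 1 - lag):(n_u - lag), drop = FALSE]     # u_{t-lag}
  u_lag_c <- u[, (lag + 1 - lag_c):(n_u - lag_c), drop = FALSE]

  # response-fraction curves (N x T): psychological at t, immune delayed
  s_psych <- outer(seq_len(n), seq_len(tt), function(i, t)
    saturating_fraction(months[t], onset[i], plateau[i]))
  shift_months <- steps_to_months(pmax(0:(tt - 1) - lag, 0), tt) *
    ((0:(tt - 1)) >= lag)
  s_imm <- outer(seq_len(n), seq_len(tt), function(i, t)
    saturating_fraction(shift_months[t], onset[i], plateau[i]))
  shift_months_c <- steps_to_months(pmax(0:(tt - 1) - lag_c, 0), tt) *
    ((0:(tt - 1)) >= lag_c)
  s_cort <- outer(seq_len(n), seq_len(tt), function(i, t)
    saturating_fraction(shift_months_c[t], onset[i], plateau[i]))

  fillers <- default_filler_profiles()
  dir_all <- feature_direction(ALL_FEATURES)
  names(dir_all) <- ALL_FEATURES
  value_mats <- vector("list", length(ALL_FEATURES))
  names(value_mats) <- ALL_FEATURES

  for (feat in ALL_FEATURES) {
    x0 <- wide0[[feat]]
    if (feat %in% names(spec$baseline_profiles)) {
      base_mean <- spec$baseline_profiles[[feat]]$mean[groups]
      base_sd <- spec$baseline_profiles[[feat]]$sd[groups]
    } else {
      base_mean <- rep(fillers[[feat]]$mean, n)
      base_sd <- rep(fillers[[feat]]$sd, n)
    }
    dirk <- dir_all[[feat]]
    # endpoint and total change
    if (feat %in% names(spec$trajectory_targets)) {
      tg <- spec$trajectory_targets[[feat]]
      endpoint <- tg$mean[groups] + (tg$sd[groups] / base_sd) * (x0 - base_mean)
      delta <- (endpoint - x0) * amp
      dev <- if (feat %in% PSYCH_FEATURES) {
        -dirk * base_sd * 0.3 * p_c
      } else if (feat == "cortisol") {
        -base_sd * 0.3 * c_c
      } else if (feat %in% IMMUNE_FEATURES) {
        -dirk * base_sd * 0.3 * i_c
      } else {
        0
      }
      delta <- delta + dev
      s_mat <- if (feat %in% PSYCH_FEATURES) s_psych
               else if (feat == "cortisol") s_cort
               else s_imm
      trend <- delta * s_mat
    } else {
      trend <- matrix(0, n, tt)
    }
    noise <- matrix(stats::rnorm(n * tt, 0, base_sd * spec$noise_scale), n, tt)
    shock <- matrix(0, n, tt)
    if (feat %in% PSYCH_FEATURES && dirk != 0) {
      shock <- dirk * base_sd * u_now
    } else if (feat %in% c("il6", "tnf_alpha", "crp", "iga")) {
      shock <- dirk * base_sd * spec$lag_gain * u_lag
    } else if (feat == "cortisol") {
      shock <- base_sd * 0.6 * u_lag_c
    }
    v <- x0 + trend + noise + shock
    v[, 1] <- x0                      # time 0 stays exactly the baseline draw
    v <- clip_to_scale(v, feat, spec)
    value_mats[[feat]] <- matrix(v, n, tt)
  }

  wide <- tidyr::expand_grid(
    athlete_id = wide0$athlete_id, time_index = 0:(tt - 1)) |>
    dplyr::arrange(.data$athlete_id, .data$time_index)
  ord <- match(wide$athlete_id, wide0$athlete_id)
  wide$group <- groups[ord]
  wide$tertile <- tertiles[ord]
  for (feat in ALL_FEATURES) {
    wide[[feat]] <- value_mats[[feat]][cbind(ord, wide$time_index + 1L)]
  }
  panel <- panel_long(wide[, c("athlete_id", "group", "tertile", "time_index",
                               ALL_FEATURES)])
  attr(panel, "chain_scores") <- tibble::tibble(
    athlete_id = wide0$athlete_id, group = groups, x = unname(x_diet),
    p = unname(p_dev), c = unname(c_dev), i = unname(i_dev),
    onset = onset, plateau = plateau, amplitude = amp)
  check_panel(panel)
  panel
}

#' Inject missingness and outliers into a panel
#'
#' Masks a fixed fraction of each athlete's cells (MCAR) and displaces a
#' fraction of the remaining cells by more than 4 population SDs away from
#' the feature mean, recording the ground truth in the `ground_truth`
#' attribute so preprocessing can be validated against it.
#'
#' @param panel Full panel from [generate_trajectories()].
#' @param spec The [cohort_spec()] holding `missing_rate` and
#'   `outlier_rate`.
#' @return The degraded panel with attribute `ground_truth`: a tibble of
#'   `(athlete_id, time_index, feature, kind, true_value)`.
#' @export
degrade_panel <- function(panel, spec) {
  validate_cohort_spec(spec)
  check_panel(panel)
  if (spec$missing_rate == 0 && spec$outlier_rate == 0) {
    attr(panel, "ground_truth") <- tibble::tibble(
      athlete_id = character(), time_index = integer(),
      feature = character(), kind = character(), true_value = numeric())
    return(panel)
  }
  set.seed(spec$seed + 2000L)
  panel <- dplyr::arrange(panel, .data$athlete_id, .data$feature,
                          .data$time_index)
  pop_stats <- panel |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mu = mean(.data$value), sigma = stats::sd(.data$value),
                     .groups = "drop")
  ids <- unique(panel$athlete_id)
  gt <- vector("list", length(ids))
  value <- panel$value
  for (j in seq_along(ids)) {
    rows <- which(panel$athlete_id == ids[j])
    ncell <- length(rows)
    n_miss <- round(spec$missing_rate * ncell)
    n_out <- round(spec$outlier_rate * ncell)
    pick <- sample(rows, n_miss + n_out)
    miss_rows <- pick[seq_len(n_miss)]
    out_rows <- pick[seq_len(n_out) + n_miss]
    recs <- list()
    if (n_miss > 0) {
      recs$missing <- tibble::tibble(
        athlete_id = ids[j], time_index = panel$time_index[miss_rows],
        feature = panel$feature[miss_rows], kind = "missing",
        true_value = value[miss_rows])
      value[miss_rows] <- NA_real_
    }
    if (n_out > 0) {
      st <- pop_stats[match(panel$feature[out_rows], pop_stats$feature), ]
      sgn <- sign(value[out_rows] - st$mu)
      sgn[sgn == 0] <- sample(c(-1, 1), sum(sgn == 0), replace = TRUE)
      displaced <- st$mu + sgn * (4.5 + stats::rexp(n_out, 2)) * st$sigma
      recs$outlier <- tibble::tibble(
        athlete_id = ids[j], time_index = panel$time_index[out_rows],
        feature = panel$feature[out_rows], kind = "outlier",
        true_value = value[out_rows])
      value[out_rows] <- displaced
    }
    gt[[j]] <- dplyr::bind_rows(recs)
  }
  panel$value <- value
  attr(panel, "ground_truth") <- dplyr::bind_rows(gt)
  check_panel(panel)
  panel
}

#' Generate a complete cohort in one call
#'
#' Runs [generate_baseline()], [generate_trajectories()] and (when the spec
#' requests missingness or outliers) [degrade_panel()].
#'
#' @param spec A [cohort_spec()].
#' @return Long-format panel; attributes `chain_scores` and `ground_truth`
#'   carry the planted per-athlete chain and the degradation mask.
#' @export
generate_cohort <- function(spec) {
  baseline <- generate_baseline(spec)
  panel <- generate_trajectories(baseline, spec)
  chain <- attr(panel, "chain_scores")
  panel <- degrade_panel(panel, spec)
  attr(panel, "chain_scores") <- chain
  panel
}

#' Simulate data from the serial mediation chain
#'
#' Draws `x -> m1 -> m2 -> y` from the linear-Gaussian chain
#' `m1 = a1 x + e`, `m2 = a2 m1 + e`, `y = cprime x + b1 m1 + b2 m2 + e`
#' with iid noise of SD `noise_sd`. In the noiseless limit the
#' regression-based serial indirect effect equals `a1 * a2 * b2` exactly.
#'
#' @param n Sample size.
#' @param a1,a2,b1,b2,cprime Path coefficients.
#' @param noise_sd Noise SD on each structural equation.
#' @param x Optional exposure vector (default standard normal).
#' @param seed Integer seed.
#' @return Tibble with columns `x`, `m1`, `m2`, `y`.
#' @export
simulate_mediation_data <- function(n, a1 = 0.5, a2 = 0.6, b1 = 0.4,
                                    b2 = 0.4, cprime = 0.2, noise_sd = 0.5,
                                    x = NULL, seed = 1L) {
  set.seed(seed)
  if (is.null(x)) x <- stats::rnorm(n)
  m1 <- a1 * x + stats::rnorm(n, 0, noise_sd)
  m2 <- a2 * m1 + stats::rnorm(n, 0, noise_sd)
  y <- cprime * x + b1 * m1 + b2 * m2 + stats::rnorm(n, 0, noise_sd)
  tibble::tibble(x = x, m1 = m1, m2 = m2, y = y)
}

#' Athlete-level change scores for mediation analysis
#'
#' Collapses a panel to one row per athlete with the exposure (diet quality
#' score 0 / 0.5 / 1 for high-carb / high-protein / balanced), the
#' psychological improvement composite `m1`, the cortisol reduction `m2`,
#' and the immune improvement composite `y`, each as baseline-to-endpoint
#' change in direction-of-benefit SD units (averaging the first and last
#' two time points to damp measurement noise).
#'
#' @param panel Long-format panel covering baseline and endpoint.
#' @param psych_vars,immune_vars Feature sets for the two composites.
#' @return Tibble `(athlete_id, group, x, m1, m2, y)`.
#' @export
athlete_change_scores <- function(panel,
                                  psych_vars = c("fatigue", "stress",
                                                 "sleep_quality", "resilience"),
                                  immune_vars = c("il6", "tnf_alpha", "crp",
                                                  "iga")) {
  check_panel(panel)
  tmax <- max(panel$time_index)
  edge <- panel |>
    dplyr::filter(.data$feature %in% c(psych_vars, immune_vars, "cortisol"),
                  .data$time_index %in% c(0, 1, tmax - 1, tmax)) |>
    dplyr::mutate(end = .data$time_index >= tmax - 1) |>
    dplyr::group_by(.data$athlete_id, .data$group, .data$feature, .data$end) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "end", values_from = "value",
                       names_prefix = "t_")
  sds <- edge |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(sigma = stats::sd(.data$t_FALSE, na.rm = TRUE),
                     .groups = "drop")
  edge <- edge |>
    dplyr::left_join(sds, by = "feature") |>
    dplyr::mutate(
      direction = ifelse(feature_direction(.data$feature) == 0, 1,
                         feature_direction(.data$feature)),
      improvement = .data$direction * (.data$t_FALSE - .data$t_TRUE) /
        .data$sigma)
  per_set <- function(vars) {
    edge |>
      dplyr::filter(.data$feature %in% vars) |>
      dplyr::group_by(.data$athlete_id, .data$group) |>
      dplyr::summarise(score = mean(.data$improvement, na.rm = TRUE),
                       .groups = "drop")
  }
  m1 <- per_set(psych_vars)
  m2 <- per_set("cortisol")
  y <- per_set(immune_vars)
  out <- m1 |>
    dplyr::rename(m1 = "score") |>
    dplyr::left_join(dplyr::rename(m2, m2 = "score"),
                     by = c("athlete_id", "group")) |>
    dplyr::left_join(dplyr::rename(y, y = "score"),
                     by = c("athlete_id", "group")) |>
    dplyr::mutate(x = c(high_carb = 0, high_protein = 0.5,
                        balanced = 1)[.data$group]) |>
    dplyr::select("athlete_id", "group", "x", "m1", "m2", "y")
  out
}
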