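#' Split athletes into resilience tertiles
#'
#' Ranks athletes by a baseline variable (ascending) and assigns tertile
#' labels `low` / `moderate` / `high` with sizes differing by at most one.
#' When `n` is not divisible by 3 the extra athletes go to the outer
#' tertiles (one remainder: moderate; two: low and high), so `n = 200`
#' yields 67/66/67. Ties are broken deterministically by `athlete_id`.
#'
#' @param baseline Either a long-format panel (the `variable` feature at
#'   time 0 is used) or a tibble with columns `athlete_id` and `value`.
#' @param variable Feature to stratify on (default `"resilience"`).
#' @return Named character vector of tertile labels, names = athlete ids.
#' @export
stratify_tertiles <- function(baseline, variable = "resilience") {
  if ("feature" %in% names(baseline)) {
    t0 <- min(baseline$time_index)
    baseline <- baseline |>
      dplyr::filter(.data$feature == variable, .data$time_index == t0) |>
      dplyr::select("athlete_id", "value")
  }
  if (anyNA(baseline$value)) {
    stop("stratify_tertiles: '", variable,
         "' must be observed for all athletes", call. = FALSE)
  }
  n <- nrow(baseline)
  if (n < 3) stop("stratify_tertiles: need at least 3 athletes", call. = FALSE)
  if (length(unique(baseline$value)) == 1) {
    warning("stratify_tertiles: all values tied; splitting by athlete_id order")
  }
  base <- n %/% 3
  r <- n %% 3
  sizes <- c(low = base + (r == 2), moderate = base + (r == 1),
             high = base + (r == 2))
  ord <- order(baseline$value, baseline$athlete_id)
  labels <- rep(RESILIENCE_TERTILES, times = sizes)
  stats::setNames(labels[order(ord)], baseline$athlete_id)
}

#' Random-intercept mixed model for longitudinal outcomes
#'
#' Fits `outcome ~ fixed effects (+ interactions) + (1 | athlete_id)` by
#' REML via `lmerTest`, accounting for within-athlete clustering. Fixed
#' effects may be feature names or panel metadata columns (`group`,
#' `tertile`, `time_index`, `month`).
#'
#' @param panel Long-format panel.
#' @param outcome Outcome feature name.
#' @param fixed_effects Character vector of fixed-effect terms.
#' @param interactions Optional character vector of interaction terms
#'   (e.g. `"group:month"`); each gets a Wald test.
#' @return List with the fitted model, a tidy fixed-effects table
#'   (estimate, SE, df, t, p), the random-intercept and residual variances,
#'   and interaction test rows.
#' @export
fit_random_intercept <- function(panel, outcome, fixed_effects,
                                 interactions = character()) {
  wide <- panel_wide(panel)
  wide$month <- steps_to_months(wide$time_index,
                                max(wide$time_index) + 1)
  obs_per <- table(wide$athlete_id[!is.na(wide[[outcome]])])
  if (any(obs_per < 2)) {
    stop("fit_random_intercept: every athlete needs >= 2 observations",
         call. = FALSE)
  }
  rhs <- paste(c(fixed_effects, interactions, "(1 | athlete_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- tryCatch(
    lmerTest::lmer(form, data = wide, REML = TRUE),
    error = function(e) stop("fit_random_intercept: model did not converge: ",
                             conditionMessage(e), call. = FALSE))
  smry <- summary(fit)
  coefs <- as.data.frame(smry$coefficients)
  names(coefs) <- c("estimate", "se", "df", "t_value", "p_value")
  coefs <- tibble::as_tibble(coefs, rownames = "term")
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri_var <- vc$vcov[vc$grp == "athlete_id"][1]
  res_var <- vc$vcov[vc$grp == "Residual"][1]
  inter_rows <- coefs[grepl(":", coefs$term), ]
  list(model = fit, fixed = coefs, random_intercept_var = ri_var,
       residual_var = res_var, interaction_tests = inter_rows)
}

#' Baseline-to-endpoint change summary per dietary group
#'
#' For each group: baseline and endpoint mean +/- SD, delta (endpoint minus
#' baseline), percent change (relative to the baseline mean), Cohen's d
#' (|delta| over the pooled baseline/endpoint SD), the share of athletes
#' reaching the minimal clinically important difference, and a within-group
#' paired test (t-test, or Wilcoxon signed-rank when the change-score
#' normality gate fails).
#'
#' The MCID is an improvement of at least `max(1.0, 0.5 * baseline SD)`
#' points in the beneficial direction; reaching the boundary exactly counts
#' as improved.
#'
#' @param panel Long-format panel with baseline and endpoint time points.
#' @param outcome Feature to summarise.
#' @param groups Optional subset of groups (default: all present).
#' @param direction `"decrease"` or `"increase"`: the beneficial direction.
#'   Defaults to the feature's registered direction of benefit.
#' @param mcid_points Absolute MCID floor in points (default 1.0).
#' @param baseline_index,endpoint_index Time indices (defaults: min / max).
#' @return Tibble, one row per group.
#' @export
summarize_change <- function(panel, outcome, groups = NULL,
                             direction = NULL, mcid_points = 1,
                             baseline_index = NULL, endpoint_index = NULL) {
  check_panel(panel)
  dat <- dplyr::filter(panel, .data$feature == outcome)
  if (!nrow(dat)) stop("summarize_change: unknown outcome ", outcome,
                       call. = FALSE)
  if (is.null(baseline_index)) baseline_index <- min(dat$time_index)
  if (is.null(endpoint_index)) endpoint_index <- max(dat$time_index)
  if (is.null(direction)) {
    d <- feature_direction(outcome)
    direction <- if (d >= 0) "decrease" else "increase"
  }
  sgn <- if (direction == "decrease") 1 else -1
  wide <- dat |>
    dplyr::filter(.data$time_index %in% c(baseline_index, endpoint_index)) |>
    dplyr::mutate(when = ifelse(.data$time_index == baseline_index,
                                "baseline", "endpoint")) |>
    dplyr::select("athlete_id", "group", "when", "value") |>
    tidyr::pivot_wider(names_from = "when", values_from = "value")
  dropped <- sum(is.na(wide$endpoint) | is.na(wide$baseline))
  if (dropped > 0) {
    message("summarize_change: excluding ", dropped,
            " athlete(s) without both baseline and endpoint values")
    wide <- wide[!is.na(wide$endpoint) & !is.na(wide$baseline), ]
  }
  if (!is.null(groups)) wide <- dplyr::filter(wide, .data$group %in% groups)
  wide |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      b_mean <- mean(d$baseline); b_sd <- stats::sd(d$baseline)
      e_mean <- mean(d$endpoint); e_sd <- stats::sd(d$endpoint)
      delta <- e_mean - b_mean
      pooled <- sqrt((b_sd^2 + e_sd^2) / 2)
      improvement <- sgn * (d$baseline - d$endpoint)
      mcid <- max(mcid_points, 0.5 * b_sd)
      diffs <- d$endpoint - d$baseline
      p <- if (length(diffs) >= 3 && stats::sd(diffs) > 0) {
        if (normality_gate_fails(diffs)) {
          stats::wilcox.test(d$endpoint, d$baseline, paired = TRUE,
                            exact = FALSE)$p.value
        } else {
          stats::t.test(d$endpoint, d$baseline, paired = TRUE)$p.value
        }
      } else NA_real_
      tibble::tibble(
        outcome = outcome,
        baseline_mean = b_mean, baseline_sd = b_sd,
        endpoint_mean = e_mean, endpoint_sd = e_sd,
        delta = delta,
        percent_change = 100 * abs(delta) / b_mean,
        cohen_d = if (pooled > 0) abs(delta) / pooled else NA_real_,
        mcid = mcid,
        clinical_improvement_pct = 100 * mean(improvement >= mcid),
        n = nrow(d), p_value = p)
    }) |>
    dplyr::ungroup()
}

#' Characterise a response trajectory (onset, rate, plateau)
#'
#' Operational definitions, applied to a (group-mean or per-athlete)
#' trajectory on a monthly grid after linear interpolation to 0.1-month
#' resolution:
#'
#' * onset: earliest month at which cumulative improvement reaches `mcid`
#'   and is sustained for two consecutive observed points;
#' * plateau: earliest post-onset month at which the rolling
#'   `rate_window`-point improvement slope falls below `plateau_slope`
#'   points/month;
#' * improvement rate: least-squares slope of cumulative improvement
#'   between onset and plateau, in points/month.
#'
#' @param months Numeric vector of observation months (increasing).
#' @param values Trajectory values at those months.
#' @param mcid Improvement threshold defining onset (e.g. half the baseline
#'   SD).
#' @param direction `"decrease"` (improvement = drop in value) or
#'   `"increase"`.
#' @param rate_window Number of consecutive points in the rolling slope
#'   (default 3).
#' @param plateau_slope Slope threshold in points/month (default 0.05).
#' @return One-row tibble: `baseline_score`, `final_score`,
#'   `improvement_rate`, `onset_months`, `plateau_months`.
#' @export
characterize_response <- function(months, values, mcid,
                                  direction = "decrease", rate_window = 3,
                                  plateau_slope = 0.05) {
  stopifnot(length(months) == length(values), !is.unsorted(months))
  if (length(months) < rate_window + 1) {
    stop("characterize_response: trajectory too short", call. = FALSE)
  }
  sgn <- if (direction == "decrease") 1 else -1
  ci <- sgn * (values[1] - values)     # cumulative improvement, points
  no_onset <- tibble::tibble(
    baseline_score = values[1], final_score = values[length(values)],
    improvement_rate = 0, onset_months = NA_real_, plateau_months = NA_real_)

  sustained <- which(ci >= mcid & dplyr::lead(ci, default = Inf) >= mcid)
  sustained <- sustained[sustained < length(ci)]
  if (!length(sustained)) return(no_onset)
  j <- sustained[1]
  onset <- if (j == 1 || ci[j - 1] >= mcid) {
    months[j]
  } else {                     # linear interpolation of the mcid crossing
    months[j - 1] + (mcid - ci[j - 1]) / (ci[j] - ci[j - 1]) *
      (months[j] - months[j - 1])
  }
  onset <- round(onset, 1)

  # rolling improvement slope, evaluated on a 0.1-month interpolated grid
  # with a window spanning rate_window observed points
  fine <- seq(months[1], months[length(months)], by = 0.1)
  ci_f <- stats::approx(months, ci, fine)$y
  w <- (rate_window - 1) * stats::median(diff(months))
  slope_at <- function(m) {
    lo <- max(m - w / 2, fine[1]); hi <- min(m + w / 2, fine[length(fine)])
    (stats::approx(fine, ci_f, hi)$y - stats::approx(fine, ci_f, lo)$y) /
      (hi - lo)
  }
  # plateau requires the slope to stay below threshold for the following
  # month, so a single noisy dip in a group-mean trajectory does not
  # trigger it
  plateau <- NA_real_
  for (m in fine[fine > onset]) {
    checks <- pmin(m + c(0, 0.5), fine[length(fine)])
    if (all(vapply(checks, slope_at, numeric(1)) < plateau_slope)) {
      plateau <- round(m, 1); break
    }
  }
  hi_rate <- if (is.na(plateau)) fine[length(fine)] else plateau
  in_rate <- fine >= onset & fine <= hi_rate
  rate <- if (sum(in_rate) >= 2) {
    unname(stats::coef(stats::lm.fit(cbind(1, fine[in_rate]),
                                     ci_f[in_rate]))[2])
  } else 0
  tibble::tibble(
    baseline_score = values[1], final_score = values[length(values)],
    improvement_rate = max(rate, 0), onset_months = onset,
    plateau_months = plateau)
}

#' Resilience-subgroup response profiles from a panel
#'
#' Builds the composite psychological health score (mean of fatigue and
#' stress, both 0-10 with lower = better), averages it per tertile and time
#' point, and characterises each tertile's group-mean trajectory.
#'
#' @param panel Long-format panel with a `tertile` column.
#' @param score_features Features averaged into the composite.
#' @param smooth Apply a 3-point moving average to each tertile's
#'   group-mean trajectory before characterisation (default TRUE; damps
#'   sampling noise in the rolling-slope plateau detector).
#' @return Tibble with one row per tertile (ordered high/moderate/low).
#' @export
subgroup_profiles <- function(panel,
                              score_features = c("fatigue", "stress"),
                              smooth = TRUE) {
  check_panel(panel)
  if (!"tertile" %in% names(panel)) {
    stop("subgroup_profiles: panel has no tertile column", call. = FALSE)
  }
  tt <- max(panel$time_index) + 1
  comp <- panel |>
    dplyr::filter(.data$feature %in% score_features) |>
    dplyr::group_by(.data$athlete_id, .data$tertile, .data$time_index) |>
    dplyr::summarise(score = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  base_sd <- comp |>
    dplyr::filter(.data$time_index == 0) |>
    dplyr::pull(.data$score) |>
    stats::sd(na.rm = TRUE)
  traj <- comp |>
    dplyr::group_by(.data$tertile, .data$time_index) |>
    dplyr::summarise(score = mean(.data$score, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(month = steps_to_months(.data$time_index, tt))
  out <- traj |>
    dplyr::group_by(.data$tertile) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$month)
      v <- d$score
      if (smooth && length(v) >= 3) {
        sm <- as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
        sm[1] <- v[1]; sm[length(sm)] <- v[length(v)]
        v <- sm
      }
      # bi-weekly spacing: a 5-point window spans ~2 months, matching the
      # "3 monthly points" rolling-slope convention
      characterize_response(d$month, v, mcid = 0.5 * base_sd,
                            direction = "decrease", rate_window = 5)
    }) |>
    dplyr::ungroup()
  out[order(match(out$tertile, c("high", "moderate", "low"))), ]
}

#' Bonferroni adjustment within variable families
#'
#' Multiplies each p-value by its family's size, capped at 1.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @param family Vector identifying the family of each p-value (a single
#'   value applies one family to all).
#' @return Adjusted p-values in the original order.
#' @export
adjust_pvalues <- function(pvals, family = 1) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  family <- rep_len(family, length(pvals))
  out <- pvals
  for (f in unique(family)) {
    sel <- family == f
    out[sel] <- stats::p.adjust(pvals[sel], method = "bonferroni")
  }
  out
}
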