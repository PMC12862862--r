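#' Preprocessing configuration
#'
#' @param outlier_k SD multiplier for the outlier screen (default 3).
#' @param shapiro_alpha Significance level of the Shapiro-Wilk normality
#'   gate (default 0.05).
#' @param skew_gate Additional |skewness| requirement before a feature is
#'   log-transformed; guards against the Shapiro-Wilk test's
#'   oversensitivity at large n (default 1).
#' @param mice_iterations Chained-equation sweeps (default 10).
#' @param mice_seed Seed for the imputation.
#' @param pmm_k Number of predictive-mean-matching donors (default 5).
#' @param scale_modes Named character vector overriding the per-feature
#'   scaling mode: `zscore`, `rescale_0_10`, `log_then_zscore`, or `auto`
#'   (z-score, with a Shapiro-gated log transform for strictly positive
#'   non-normal features). Defaults: psychological scales `rescale_0_10`,
#'   everything else `auto`.
#' @param psych_range Declared instrument range used by `rescale_0_10`
#'   (default `c(0, 10)`, i.e. the identity for 0-10 scales).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(outlier_k = 3, shapiro_alpha = 0.05,
                              skew_gate = 1, mice_iterations = 10,
                              mice_seed = 1L, pmm_k = 5,
                              scale_modes = character(),
                              psych_range = c(0, 10)) {
  stopifnot(outlier_k > 0, shapiro_alpha > 0, shapiro_alpha < 1)
  structure(list(outlier_k = outlier_k, shapiro_alpha = shapiro_alpha,
                 skew_gate = skew_gate,
                 mice_iterations = as.integer(mice_iterations),
                 mice_seed = as.integer(mice_seed), pmm_k = as.integer(pmm_k),
                 scale_modes = scale_modes, psych_range = psych_range),
            class = "preprocess_config")
}

scale_mode_for <- function(feature, config) {
  if (feature %in% names(config$scale_modes)) {
    return(config$scale_modes[[feature]])
  }
  if (feature %in% PSYCH_FEATURES) "rescale_0_10" else "auto"
}

#' Flag and blank cells beyond k population SDs
#'
#' Computes each feature's mean and SD over all observed cells; cells with
#' `|value - mean| > k * SD` (strict inequality, so a value at exactly k SD
#' is retained) are set to missing and flagged. Constant features (SD 0)
#' yield no flags.
#'
#' @param panel Long-format panel.
#' @param config A [preprocess_config()].
#' @return List: `panel` (flagged cells blanked) and `flags` (tibble of
#'   flagged cells with their original values).
#' @export
screen_outliers <- function(panel, config = preprocess_config()) {
  check_panel(panel)
  st <- panel |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(n_obs = sum(!is.na(.data$value)),
                     mu = mean(.data$value, na.rm = TRUE),
                     sigma = stats::sd(.data$value, na.rm = TRUE),
                     .groups = "drop")
  if (any(st$n_obs == 0)) {
    stop("screen_outliers: feature(s) with no observed values: ",
         paste(st$feature[st$n_obs == 0], collapse = ", "), call. = FALSE)
  }
  if (any(st$n_obs < 2)) {
    stop("screen_outliers: feature(s) need >= 2 observed values: ",
         paste(st$feature[st$n_obs < 2], collapse = ", "), call. = FALSE)
  }
  idx <- match(panel$feature, st$feature)
  sigma <- st$sigma[idx]
  flag <- !is.na(panel$value) & sigma > 0 &
    abs(panel$value - st$mu[idx]) > config$outlier_k * sigma
  flags <- panel[flag, c("athlete_id", "time_index", "feature", "value")]
  panel$value[flag] <- NA_real_
  list(panel = panel, flags = tibble::as_tibble(flags))
}

#' Chained-equation imputation with predictive mean matching
#'
#' Fills missing cells by iterated chained regressions: each incomplete
#' feature is regressed on all other features (current completions), and
#' each missing cell receives the observed value of one of `pmm_k` donors
#' whose fitted values are closest to the cell's prediction. Missing cells
#' are mean-initialised; `mice_iterations` full sweeps are run. Observed
#' cells are never changed and seeded runs are reproducible. Features with
#' more than 50% missing overall fall back to mean imputation with a
#' warning.
#'
#' @param panel Long-format panel (per-athlete missing fraction must be
#'   below 0.2).
#' @param config A [preprocess_config()].
#' @return Completed panel with no missing cells.
#' @export
impute_chained <- function(panel, config = preprocess_config()) {
  check_panel(panel)
  miss_by_athlete <- panel |>
    dplyr::group_by(.data$athlete_id) |>
    dplyr::summarise(frac = mean(is.na(.data$value)), .groups = "drop")
  if (any(miss_by_athlete$frac >= 0.2)) {
    stop("impute_chained: athlete(s) with >= 20% missing violate the ",
         "inclusion rule: ",
         paste(miss_by_athlete$athlete_id[miss_by_athlete$frac >= 0.2],
               collapse = ", "), call. = FALSE)
  }
  if (!anyNA(panel$value)) return(panel)
  set.seed(config$mice_seed)
  wide <- panel_wide(panel)
  feats <- intersect(panel_features(panel), names(wide))
  m <- as.matrix(wide[, feats])
  na_mask <- is.na(m)
  col_missing <- colSums(na_mask)
  fallback <- col_missing > 0.5 * nrow(m)
  if (any(fallback)) {
    warning("impute_chained: feature(s) with > 50% missing mean-imputed: ",
            paste(feats[fallback], collapse = ", "))
  }
  col_means <- colMeans(m, na.rm = TRUE)
  for (j in seq_along(feats)) m[na_mask[, j], j] <- col_means[j]

  active <- which(col_missing > 0 & !fallback)
  predictors <- which(apply(m, 2, stats::sd) > 0)
  for (iter in seq_len(config$mice_iterations)) {
    for (j in active) {
      obs <- !na_mask[, j]
      preds <- setdiff(predictors, j)
      X <- cbind(1, m[, preds, drop = FALSE])
      fit <- stats::lm.fit(X[obs, , drop = FALSE], m[obs, j])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      yhat <- drop(X %*% beta)
      m[!obs, j] <- pmm_draw(yhat[obs], m[obs, j], yhat[!obs], config$pmm_k)
    }
  }
  for (j in seq_along(feats)) wide[[feats[j]]] <- m[, j]
  long <- panel_long(wide)
  # restore the caller's row order
  key <- function(p) paste(p$athlete_id, p$time_index, p$feature)
  panel$value <- long$value[match(key(panel), key(long))]
  panel
}

# Predictive mean matching: for each target prediction, sample one of the
# k observed values whose fitted values are closest (window search on the
# sorted fitted values keeps this O(n log n)).
pmm_draw <- function(yhat_obs, y_obs, yhat_mis, k) {
  ord <- order(yhat_obs)
  sorted_hat <- yhat_obs[ord]
  sorted_y <- y_obs[ord]
  n <- length(sorted_hat)
  k <- min(k, n)
  vapply(yhat_mis, function(p) {
    pos <- findInterval(p, sorted_hat)
    lo <- max(1, pos - k); hi <- min(n, pos + k)
    window <- lo:hi
    near <- window[order(abs(sorted_hat[window] - p))[seq_len(k)]]
    sorted_y[sample(near, 1)]
  }, numeric(1))
}

#' Normalise features (Shapiro-gated log, z-score, 0-10 rescale)
#'
#' Applies each feature's scaling mode: `auto`/`log_then_zscore` features
#' that are strictly positive and fail the normality gate (Shapiro-Wilk
#' p < `shapiro_alpha` and |skewness| > `skew_gate`) are log-transformed,
#' then z-scored; `zscore` features are z-scored directly; `rescale_0_10`
#' features are affinely mapped from the declared instrument range to
#' [0, 10]. Scaling parameters (means, SDs, log decisions) are estimated on
#' training athletes only and applied unchanged to everyone else. Constant
#' features z-score to all zeros with a warning.
#'
#' @param panel Complete (no missing cells) long-format panel.
#' @param config A [preprocess_config()].
#' @param train_athletes Athlete ids used to fit the scaling (default: all).
#' @param scaling Optional scaling table from a previous call, to apply
#'   frozen parameters to new data.
#' @return Normalised panel with the fitted parameters in attribute
#'   `scaling`.
#' @export
normalize_features <- function(panel, config = preprocess_config(),
                               train_athletes = NULL, scaling = NULL) {
  check_panel(panel)
  if (anyNA(panel$value)) {
    stop("normalize_features: panel still has missing cells; impute first",
         call. = FALSE)
  }
  feats <- panel_features(panel)
  if (is.null(scaling)) {
    fit_rows <- if (is.null(train_athletes)) rep(TRUE, nrow(panel))
                else panel$athlete_id %in% train_athletes
    scaling <- lapply(feats, function(f) {
      v <- panel$value[fit_rows & panel$feature == f]
      mode <- scale_mode_for(f, config)
      if (mode == "rescale_0_10") {
        return(list(feature = f, mode = mode, center = config$psych_range[1],
                    scale = diff(config$psych_range), logged = FALSE))
      }
      logged <- if (mode == "log_then_zscore") {
        if (any(v <= 0)) stop("normalize_features: log requested for '", f,
                              "' but values are not strictly positive",
                              call. = FALSE)
        TRUE
      } else {
        all(v > 0) && normality_gate_fails(v, config$shapiro_alpha,
                                           config$skew_gate)
      }
      if (logged) v <- log(v)
      s <- stats::sd(v)
      if (s == 0) {
        warning("normalize_features: constant feature '", f,
                "' z-scored to zeros")
        s <- 1
      }
      list(feature = f, mode = "zscore", center = mean(v), scale = s,
           logged = logged)
    })
    names(scaling) <- feats
  }
  value <- panel$value
  for (f in feats) {
    sc <- scaling[[f]]
    if (is.null(sc)) stop("normalize_features: no scaling for feature ", f,
                          call. = FALSE)
    rows <- panel$feature == f
    v <- value[rows]
    if (sc$mode == "rescale_0_10") {
      value[rows] <- (v - sc$center) / sc$scale * 10
    } else {
      if (sc$logged) v <- log(v)
      value[rows] <- (v - sc$center) / sc$scale
    }
  }
  panel$value <- value
  attr(panel, "scaling") <- scaling
  panel
}

#' Engineer interaction, seasonal and composite features
#'
#' Adds, without altering existing columns:
#' * product interaction features for each configured (nutrition,
#'   training-phase) column pair, named `a_x_b`;
#' * annual seasonal terms `season_sin` / `season_cos` of the bi-weekly
#'   time index (week = 2 * time_index over a 52.18-week year), so time 0
#'   maps to (0, 1);
#' * composite indices: the mean of the z-scored member features.
#'
#' @param panel Long-format panel (normally after [normalize_features()]).
#' @param interactions List of 2-element character vectors.
#' @param composites Named list of member-feature vectors.
#' @return Panel with the engineered rows appended.
#' @export
engineer_features <- function(panel,
                              interactions = list(
                                c("carb_pct_energy", "training_load"),
                                c("protein_g_kg", "training_load")),
                              composites = list(
                                inflammation_index = c("il6", "tnf_alpha",
                                                       "crp"),
                                psych_strain_index = c("fatigue", "stress"))) {
  check_panel(panel)
  feats <- panel_features(panel)
  wanted <- unique(c(unlist(interactions), unlist(composites)))
  unknown <- setdiff(wanted, feats)
  if (length(unknown)) {
    stop("engineer_features: unknown column(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  wide <- panel_wide(panel)
  new_cols <- character()
  for (pair in interactions) {
    nm <- paste0(pair[1], "_x_", pair[2])
    wide[[nm]] <- wide[[pair[1]]] * wide[[pair[2]]]
    new_cols <- c(new_cols, nm)
  }
  week <- 2 * wide$time_index
  wide$season_sin <- sin(2 * pi * week / 52.18)
  wide$season_cos <- cos(2 * pi * week / 52.18)
  new_cols <- c(new_cols, "season_sin", "season_cos")
  for (nm in names(composites)) {
    members <- composites[[nm]]
    zs <- vapply(members, function(f) {
      v <- wide[[f]]
      s <- stats::sd(v, na.rm = TRUE)
      if (is.na(s) || s == 0) s <- 1
      (v - mean(v, na.rm = TRUE)) / s
    }, numeric(nrow(wide)))
    wide[[nm]] <- rowMeans(zs)
    new_cols <- c(new_cols, nm)
  }
  id_cols <- intersect(c("athlete_id", "group", "tertile", "time_index"),
                       names(wide))
  panel_long(wide[, c(id_cols, feats, new_cols)])
}

#' Weekly averaging of finer-grained observations
#'
#' Collapses rows to one per (grouping, week), averaging numeric columns;
#' week `w` covers time values `[w * period, (w + 1) * period)`.
#'
#' @param data Data frame with a numeric time column.
#' @param time_col Name of the time column (e.g. day).
#' @param period Time units per week (default 7 for daily data).
#' @param id_cols Grouping columns kept alongside the week.
#' @return Tibble with a `week` column and averaged values.
#' @export
aggregate_weekly <- function(data, time_col = "day", period = 7,
                             id_cols = intersect("athlete_id", names(data))) {
  data$week <- data[[time_col]] %/% period
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      c(time_col, "week"))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(id_cols, "week")))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num_cols),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
}

#' Athlete holdout plus forward-chaining temporal folds
#'
#' Splits athletes 80/20 (stratified by dietary group, largest-remainder
#' rounding) and lays out `n_folds` forward-chained validation windows of
#' `window` bi-weekly steps over the time axis. Fold `k` validates on
#' indices `start_k .. start_k + window - 1` with
#' `start_k = (T - 1) - window * (n_folds + 1 - k)`, trains on
#' `0 .. start_k - gap_steps - 1`, and leaves `gap_steps` indices (two
#' months by default) between them, so chronological order is never
#' violated.
#'
#' @param panel Long-format panel.
#' @param train_frac Fraction of athletes in the training split.
#' @param n_folds Number of forward-chained folds (default 5).
#' @param gap_steps Minimum gap between training and validation windows in
#'   bi-weekly steps (default 4 = two months).
#' @param window Validation window length in steps (default 3).
#' @param min_train Minimum training window length required of the first
#'   fold (default 4).
#' @param seed Seed for the athlete split.
#' @return A `split_plan`: `train_athletes`, `test_athletes`, `folds`
#'   tibble, and the geometry parameters.
#' @export
make_temporal_split <- function(panel, train_frac = 0.8, n_folds = 5,
                                gap_steps = 4, window = 3, min_train = 4,
                                seed = 1L) {
  check_panel(panel)
  tt <- max(panel$time_index) + 1
  starts <- (tt - 1) - window * (n_folds + 1 - seq_len(n_folds))
  if (starts[1] - gap_steps < min_train) {
    stop("make_temporal_split: T = ", tt, " is too small: first fold would ",
         "train on ", starts[1] - gap_steps, " step(s) (< ", min_train,
         ") with ", n_folds, " folds of window ", window, " and gap ",
         gap_steps, call. = FALSE)
  }
  ath <- panel_athletes(panel)
  set.seed(seed)
  total_train <- round(train_frac * nrow(ath))
  by_group <- split(ath$athlete_id, ath$group)
  exact <- vapply(by_group, length, integer(1)) * train_frac
  base <- floor(exact)
  extra <- total_train - sum(base)
  if (extra > 0) {
    give <- order(exact - base, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  train_ids <- unlist(lapply(seq_along(by_group), function(i) {
    sample(by_group[[i]], base[i])
  }), use.names = FALSE)
  test_ids <- setdiff(ath$athlete_id, train_ids)
  folds <- tibble::tibble(
    fold = seq_len(n_folds),
    train_start = 0L, train_end = as.integer(starts - gap_steps - 1),
    gap_start = as.integer(starts - gap_steps),
    gap_end = as.integer(starts - 1),
    valid_start = as.integer(starts),
    valid_end = as.integer(starts + window - 1))
  plan <- structure(list(train_athletes = sort(train_ids),
                         test_athletes = sort(test_ids), folds = folds,
                         gap_steps = gap_steps, window = window,
                         n_timepoints = tt, train_frac = train_frac),
                    class = "split_plan")
  validate_split_plan(plan)
  plan
}

#' Assert the leakage-guard invariants of a split plan
#'
#' Errors unless the train/test athlete sets are disjoint and every fold's
#' training window precedes its validation window by at least the gap.
#'
#' @param plan A `split_plan`.
#' @export
validate_split_plan <- function(plan) {
  stopifnot(inherits(plan, "split_plan"))
  if (length(intersect(plan$train_athletes, plan$test_athletes))) {
    stop("split_plan: train and test athletes overlap", call. = FALSE)
  }
  f <- plan$folds
  if (any(f$train_end + plan$gap_steps >= f$valid_start)) {
    stop("split_plan: temporal leakage: a fold's training window ends ",
         "within the gap of its validation window", call. = FALSE)
  }
  if (any(f$valid_end >= plan$n_timepoints)) {
    stop("split_plan: validation window beyond the panel", call. = FALSE)
  }
  invisible(plan)
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test athletes; %d folds (gap %d, window %d)\n",
              length(x$train_athletes), length(x$test_athletes),
              nrow(x$folds), x$gap_steps, x$window))
  print(x$folds)
  invisible(x)
}
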