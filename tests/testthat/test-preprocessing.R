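make_two_feature_panel <- function(values_a, values_b = NULL) {
  n <- length(values_a)
  rows <- tibble::tibble(
    athlete_id = rep(sprintf("P%03d", seq_len(n)), if (is.null(values_b)) 1 else 2),
    group = "balanced",
    time_index = 0L,
    feature = rep(c("fa", "fb")[seq_len(1 + !is.null(values_b))], each = n),
    value = c(values_a, values_b))
  rows
}

test_that("outlier screen flags beyond k SD strictly and spares constants", {
  const <- make_two_feature_panel(rep(5, 20))
  out <- screen_outliers(const)
  expect_equal(nrow(out$flags), 0)

  set.seed(1)
  vals <- c(rnorm(1000), 10)
  panel <- make_two_feature_panel(vals)
  res <- screen_outliers(panel)
  mu <- mean(vals); sdv <- sd(vals)        # oracle includes the outlier
  expect_true(abs(10 - mu) > 3 * sdv)
  expect_true("P1001" %in% res$flags$athlete_id)
  expect_true(is.na(res$panel$value[res$panel$athlete_id == "P1001"]))
  # every flagged cell satisfies the oracle threshold
  expect_true(all(abs(res$flags$value - mu) > 3 * sdv))

  # a value at exactly k SDs is retained (strict inequality)
  v2 <- vals[1:50]
  k_exact <- abs(v2[7] - mean(v2)) / sd(v2)
  res2 <- screen_outliers(make_two_feature_panel(v2),
                          preprocess_config(outlier_k = k_exact))
  expect_false("P007" %in% res2$flags$athlete_id)

  all_na <- make_two_feature_panel(rep(NA_real_, 5))
  expect_error(screen_outliers(all_na), "fa")
})

make_longitudinal_pair_panel <- function(n_athletes, tt, rho = 0.8,
                                         seed = 7) {
  set.seed(seed)
  n <- n_athletes * tt
  a <- rnorm(n)
  b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  tibble::tibble(
    athlete_id = rep(rep(sprintf("P%03d", seq_len(n_athletes)), each = tt), 2),
    group = "balanced",
    time_index = rep(rep(0:(tt - 1), n_athletes), 2),
    feature = rep(c("fa", "fb"), each = n),
    value = c(a, b))
}

test_that("chained imputation completes panels, beats mean imputation, and is seeded", {
  panel <- make_longitudinal_pair_panel(30, 10)
  clean <- impute_chained(panel)
  expect_identical(clean$value, panel$value)   # identity with no missing

  set.seed(8)
  miss_idx <- sample(which(panel$feature == "fb"), 30)
  truth <- panel$value[miss_idx]
  holed <- panel; holed$value[miss_idx] <- NA
  done <- impute_chained(holed, preprocess_config(mice_seed = 3))
  expect_false(anyNA(done$value))
  # observed cells untouched
  expect_identical(done$value[-miss_idx], panel$value[-miss_idx])
  imp_rmse <- sqrt(mean((done$value[miss_idx] - truth)^2))
  mean_rmse <- sqrt(mean((mean(holed$value[holed$feature == "fb"],
                               na.rm = TRUE) - truth)^2))
  expect_lt(imp_rmse, mean_rmse)

  done2 <- impute_chained(holed, preprocess_config(mice_seed = 3))
  expect_identical(done$value, done2$value)
  done3 <- impute_chained(holed, preprocess_config(mice_seed = 4))
  expect_false(identical(done$value, done3$value))
})

test_that("athletes above the 20% missing inclusion rule are rejected", {
  panel <- make_longitudinal_pair_panel(5, 10)
  panel$value[panel$athlete_id == "P001" & panel$feature == "fb"] <- NA
  expect_error(impute_chained(panel), "20%")
})

test_that("normality gate drives the log transform correctly", {
  set.seed(2)
  normal_vals <- rnorm(200, 10, 1)
  lognormal_vals <- exp(rnorm(200, 0.5, 0.8))
  panel <- make_two_feature_panel(normal_vals, lognormal_vals)
  norm <- normalize_features(panel)
  scaling <- attr(norm, "scaling")
  expect_false(scaling$fa$logged)
  expect_true(scaling$fb$logged)
  post_skew <- sample_skewness(norm$value[norm$feature == "fb"])
  expect_lt(abs(post_skew), abs(sample_skewness(lognormal_vals)))
  # z-scored outputs
  expect_equal(mean(norm$value[norm$feature == "fa"]), 0, tolerance = 1e-9)
  expect_equal(sd(norm$value[norm$feature == "fa"]), 1, tolerance = 1e-9)
})

test_that("constant features z-score to zeros with a warning", {
  panel <- make_two_feature_panel(rep(4, 30))
  expect_warning(norm <- normalize_features(panel), "constant")
  expect_true(all(norm$value == 0))
})

test_that("explicit log request on non-positive values errors", {
  panel <- make_two_feature_panel(c(rnorm(20), -1))
  cfg <- preprocess_config(scale_modes = c(fa = "log_then_zscore"))
  expect_error(normalize_features(panel, cfg), "strictly positive")
})

test_that("scaling is fitted on training athletes only and applied frozen", {
  set.seed(3)
  panel <- make_two_feature_panel(c(rnorm(50), rnorm(10, 5)))
  train <- sprintf("P%03d", 1:50)
  norm <- normalize_features(panel, train_athletes = train)
  v_train <- norm$value[norm$athlete_id %in% train]
  v_test <- norm$value[!norm$athlete_id %in% train]
  expect_equal(mean(v_train), 0, tolerance = 1e-9)
  expect_gt(mean(v_test), 2)    # shifted test athletes stay shifted
  # applying the frozen scaling to new data reuses the same parameters
  norm2 <- normalize_features(panel, scaling = attr(norm, "scaling"))
  expect_equal(norm2$value, norm$value)
})

test_that("the cleaning pipeline is idempotent on clean normalized panels", {
  panel <- small_panel()
  norm1 <- normalize_features(panel)
  norm2 <- normalize_features(norm1)
  expect_equal(norm2$value, norm1$value, tolerance = 1e-10)
})

test_that("feature engineering adds interactions, seasonal and composite terms", {
  panel <- small_panel()
  eng <- engineer_features(panel)
  w <- panel_wide(eng)
  expect_equal(w$carb_pct_energy_x_training_load,
               w$carb_pct_energy * w$training_load)
  expect_equal(w$season_sin[w$time_index == 0][1], 0)
  expect_equal(w$season_cos[w$time_index == 0][1], 1)
  # composite of two identical columns equals the z-scored column
  eng2 <- engineer_features(panel, interactions = list(),
                            composites = list(cc = c("fatigue", "fatigue")))
  w2 <- panel_wide(eng2)
  z <- (w2$fatigue - mean(w2$fatigue)) / sd(w2$fatigue)
  expect_equal(w2$cc, z, tolerance = 1e-12)
  expect_error(engineer_features(panel,
                                 interactions = list(c("nope", "fatigue"))),
               "nope")
})

test_that("weekly aggregation collapses daily rows to weekly means", {
  daily <- tibble::tibble(athlete_id = "A", day = 0:13, x = 1:14)
  wk <- aggregate_weekly(daily, "day")
  expect_equal(nrow(wk), 2)
  expect_equal(wk$x, c(mean(1:7), mean(8:14)))
})

test_that("temporal split yields the 160/40 athlete holdout and documented folds", {
  panel <- full_panel()
  plan <- make_temporal_split(panel)
  expect_length(plan$train_athletes, 160)
  expect_length(plan$test_athletes, 40)
  expect_length(intersect(plan$train_athletes, plan$test_athletes), 0)
  # enumerated fold formula: T = 24, 5 folds, window 3, gap 4
  expect_equal(plan$folds$valid_start, c(8L, 11L, 14L, 17L, 20L))
  expect_equal(plan$folds$train_end, plan$folds$valid_start - 4L - 1L)
  expect_true(all(plan$folds$train_end + plan$gap_steps <
                    plan$folds$valid_start))
  # stratification: per-group train counts differ from 0.8*n by < 1
  tr_groups <- table(panel_athletes(panel)$group[
    panel_athletes(panel)$athlete_id %in% plan$train_athletes])
  expect_true(all(abs(tr_groups - 0.8 * c(balanced = 67, high_carb = 68,
                                          high_protein = 65)) <= 1))
})

test_that("a too-short panel produces an arithmetic error message", {
  panel <- small_panel() |> dplyr::filter(time_index < 10)
  expect_error(make_temporal_split(panel, n_folds = 5),
               "too small")
})
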