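tiny_temporal_cfg <- function(epochs = 10)
  temporal_branch_config(embed_dim = 8, lstm_units = 8, bilstm_units = 8,
                         final_units = 4, max_epochs = epochs,
                         early_stop_patience = epochs, dropout = 0.1,
                         learning_rate = 0.01, seed = 2)

test_that("attention fusion follows the softmax contract", {
  h1 <- matrix(c(1, 2)); h2 <- matrix(c(3, 0))
  # zero projection: equal logits, midpoint fusion
  fz <- fuse_attention(h1, h2, matrix(0, 2, 2))
  expect_equal(fz$alpha, matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(as.numeric(fz$z), c(2, 1))
  expect_equal(rowSums(fz$alpha), c(1, 1))
  # logits (ln 3, 0) -> alpha (0.75, 0.25)
  w <- rbind(c(log(3), 0), c(0, 0))
  fz2 <- fuse_attention(matrix(1), matrix(1), w)
  expect_equal(as.numeric(fz2$alpha), c(0.75, 0.25))
  expect_error(fuse_attention(matrix(1:2, 1), matrix(1), diag(2)),
               "dimension")
  expect_error(fuse_attention(matrix(1), matrix(1), matrix(0, 2, 5)), "W")
})

test_that("attention weights always form a 2-point distribution", {
  set.seed(1)
  for (i in 1:20) {
    h1 <- matrix(rnorm(6), 3); h2 <- matrix(rnorm(6), 3)
    w <- matrix(rnorm(2 * 5), 2)
    a <- fuse_attention(h1, h2, w)$alpha
    expect_true(all(a >= 0))
    expect_equal(rowSums(a), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("boost branch respects its contracts", {
  panel <- small_panel()
  plan <- make_temporal_split(panel)
  norm <- normalize_features(panel, train_athletes = plan$train_athletes)
  cfg <- boost_branch_config(n_estimators = 40, subsample = 1, seed = 3)

  bb1 <- train_boost_branch(norm, plan, cfg, "fatigue")
  bb2 <- train_boost_branch(norm, plan, cfg, "fatigue")
  ids <- plan$train_athletes[1:10]
  expect_equal(bb1$predict(ids), bb2$predict(ids))   # subsample=1 determinism

  # pure-noise labels: no skill on held-out athletes
  noise_panel <- norm
  set.seed(4)
  noise_rows <- noise_panel$feature == "fatigue"
  noise_panel$value[noise_rows] <- rnorm(sum(noise_rows))
  bbn <- train_boost_branch(noise_panel, plan, cfg, "fatigue")
  w <- panel_wide(noise_panel)
  f <- bbn$fold
  y_val <- pniflow:::window_outcome(w, bbn$val_athletes,
                                    f$valid_start:f$valid_end, "fatigue")
  r2 <- 1 - sum((bbn$predict(bbn$val_athletes) - y_val)^2) /
    sum((y_val - mean(y_val))^2)
  expect_lt(r2, 0.1)
})

test_that("a single-feature step function is recovered on training data", {
  set.seed(5)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("u", "v")))
  y <- as.numeric(x[, 1] > 0)
  booster <- xgboost::xgboost(x = x, y = y, objective = "reg:squarederror",
                              nrounds = 60, max_depth = 2,
                              learning_rate = 0.3, subsample = 1,
                              nthreads = 1, seed = 1, verbosity = 0)
  expect_lt(max(abs(predict(booster, x) - y)), 0.05)
})

test_that("temporal branch learns a memorisable panel and reports history", {
  panel <- small_panel()
  plan <- make_temporal_split(panel)
  norm <- normalize_features(panel, train_athletes = plan$train_athletes)
  tb <- train_temporal_branch(norm, plan, tiny_temporal_cfg(12), "fatigue")
  expect_equal(ncol(tb$represent(plan$train_athletes[1:3])), 4)
  expect_lte(tb$history$epochs_run,
             tb$history$best_epoch + 12)
  expect_true(all(is.finite(tb$history$val_loss)))
})

test_that("evaluation metrics match hand arithmetic and degenerate cases", {
  # confusion counts TP=41 FN=4 TN=38 FP=7
  cr <- confusion_rates(tp = 41, fn = 4, tn = 38, fp = 7)
  expect_equal(round(cr$sensitivity, 3), 0.911)
  expect_equal(round(cr$specificity, 3), 0.844)

  ev <- evaluate_predictions(c(1, 2, 3), c(1, 2, 3),
                             scores = c(0.9, 0.8, 0.1),
                             labels = c(TRUE, TRUE, FALSE), threshold = 0.5)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$r_squared, 1)
  expect_equal(ev$auc, 1)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  set.seed(6)
  n <- 1e4
  ev2 <- evaluate_predictions(scores = runif(n),
                              labels = rep(c(TRUE, FALSE), n / 2))
  expect_lt(abs(ev2$auc - 0.5), 0.02)

  expect_warning(ev3 <- evaluate_predictions(scores = runif(5),
                                             labels = rep(TRUE, 5)),
                 "single-class")
  expect_true(is.na(ev3$auc))

  ev4 <- evaluate_predictions(rep(2, 5), rep(2, 5))
  expect_equal(ev4$rmse, 0)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- rnorm(200)
  labels <- runif(200) < plogis(scores)
  ours <- pniflow:::auc_rank(scores, labels)
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("chronology violations in a split plan are rejected", {
  panel <- small_panel()
  plan <- make_temporal_split(panel)
  broken <- plan
  broken$folds$train_end[2] <- broken$folds$valid_start[2]  # shuffled order
  expect_error(validate_split_plan(broken), "leakage")
  overlap <- plan
  overlap$test_athletes[1] <- overlap$train_athletes[1]
  expect_error(validate_split_plan(overlap), "overlap")
})

test_that("training never reads test-athlete outcomes or features", {
  panel <- small_panel()
  plan <- make_temporal_split(panel)
  norm <- normalize_features(panel, train_athletes = plan$train_athletes)
  cfg_t <- tiny_temporal_cfg(6)
  cfg_b <- boost_branch_config(n_estimators = 20, seed = 3)
  h_clean <- train_hybrid(norm, plan, "fatigue", cfg_t, cfg_b,
                          raw_panel = panel, folds = c(4, 5))
  # poison every test-athlete cell; training must be bit-identical
  poisoned <- norm
  poisoned$value[poisoned$athlete_id %in% plan$test_athletes] <- 1e9
  praw <- panel
  praw$value[praw$athlete_id %in% plan$test_athletes] <- 1e9
  h_poison <- train_hybrid(poisoned, plan, "fatigue", cfg_t, cfg_b,
                           raw_panel = praw, folds = c(4, 5))
  expect_identical(h_clean$fusion_w, h_poison$fusion_w)
  expect_identical(coef(h_clean$classifier), coef(h_poison$classifier))
  ids <- plan$train_athletes[1:8]
  expect_identical(predict(h_clean, ids), predict(h_poison, ids))
})
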