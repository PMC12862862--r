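#' Configuration of the temporal (recurrent) branch
#'
#' Architecture shape: embedding, LSTM, bidirectional LSTM, final LSTM,
#' dense head. `profile = "paper"` uses the full-size layout (embedding
#' 52->128, LSTM 128, bidirectional 128 per direction, final 64, learning
#' rate 0.001, batch 32, up to 100 epochs, patience 10); the default
#' `"desk"` profile preserves the shape at desk scale (32 / 32 / 16,
#' embedding 32) with a faster learning rate so it converges in few epochs.
#'
#' @param profile `"desk"` or `"paper"`, or override fields directly.
#' @param embed_dim,lstm_units,bilstm_units,final_units Layer widths
#'   (`bilstm_units` is per direction).
#' @param dropout,learning_rate,batch_size,max_epochs Training
#'   hyperparameters.
#' @param adam_betas,early_stop_patience,seed Optimiser betas, patience,
#'   and initialisation seed.
#' @return A `temporal_branch_config` list.
#' @export
temporal_branch_config <- function(profile = "desk", embed_dim = NULL,
                                   lstm_units = NULL, bilstm_units = NULL,
                                   final_units = NULL, dropout = 0.3,
                                   learning_rate = NULL, batch_size = 32,
                                   max_epochs = NULL, adam_betas = c(0.9, 0.999),
                                   early_stop_patience = 10, seed = 1L) {
  defaults <- switch(profile,
    desk = list(embed_dim = 32, lstm_units = 32, bilstm_units = 32,
                final_units = 16, learning_rate = 0.005, max_epochs = 40),
    paper = list(embed_dim = 128, lstm_units = 128, bilstm_units = 128,
                 final_units = 64, learning_rate = 0.001, max_epochs = 100),
    stop("temporal_branch_config: unknown profile ", profile, call. = FALSE))
  cfg <- list(
    embed_dim = embed_dim %||% defaults$embed_dim,
    lstm_units = lstm_units %||% defaults$lstm_units,
    bilstm_units = bilstm_units %||% defaults$bilstm_units,
    final_units = final_units %||% defaults$final_units,
    dropout = dropout,
    learning_rate = learning_rate %||% defaults$learning_rate,
    batch_size = batch_size,
    max_epochs = max_epochs %||% defaults$max_epochs,
    adam_betas = adam_betas, early_stop_patience = early_stop_patience,
    seed = as.integer(seed), profile = profile)
  stopifnot(cfg$dropout >= 0, cfg$dropout < 1,
            cfg$early_stop_patience <= cfg$max_epochs)
  structure(cfg, class = "temporal_branch_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration of the gradient-boosting branch
#'
#' Full-size (`"paper"`) profile: 500 estimators, depth 6, learning rate
#' 0.1, subsample 0.8. The `"desk"` default shrinks to 100 estimators.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param n_estimators,max_depth,learning_rate,subsample,seed Usual
#'   boosting hyperparameters.
#' @return A `boost_branch_config` list.
#' @export
boost_branch_config <- function(profile = "desk", n_estimators = NULL,
                                max_depth = 6, learning_rate = 0.1,
                                subsample = 0.8, seed = 1L) {
  n_default <- switch(profile, desk = 100, paper = 500,
                      stop("boost_branch_config: unknown profile ", profile,
                           call. = FALSE))
  cfg <- list(n_estimators = n_estimators %||% n_default,
              max_depth = max_depth, learning_rate = learning_rate,
              subsample = subsample, seed = as.integer(seed),
              profile = profile)
  stopifnot(cfg$n_estimators >= 1, cfg$subsample > 0, cfg$subsample <= 1)
  structure(cfg, class = "boost_branch_config")
}

# (B, T, D) sequence array for the given athletes over a time range,
# athletes ordered by id.
build_sequences <- function(wide, athletes, time_range, features) {
  d <- wide[wide$athlete_id %in% athletes &
              wide$time_index %in% time_range, ]
  d <- d[order(d$athlete_id, d$time_index), ]
  n <- length(unique(d$athlete_id))
  tt <- length(time_range)
  x <- array(NA_real_, c(n, tt, length(features)),
             dimnames = list(sort(unique(d$athlete_id)), NULL, features))
  for (j in seq_along(features)) {
    x[, , j] <- matrix(d[[features[j]]], n, tt, byrow = TRUE)
  }
  x
}

# Per-athlete static feature table over a time window: window mean, linear
# slope, and last value of every feature.
build_static_features <- function(wide, athletes, time_range, features) {
  d <- wide[wide$athlete_id %in% athletes &
              wide$time_index %in% time_range, ]
  d <- d[order(d$athlete_id, d$time_index), ]
  ids <- sort(unique(d$athlete_id))
  tt <- length(time_range)
  tvec <- seq_len(tt) - mean(seq_len(tt))
  denom <- sum(tvec^2)
  out <- matrix(NA_real_, length(ids), 3 * length(features))
  cn <- character(3 * length(features))
  for (j in seq_along(features)) {
    m <- matrix(d[[features[j]]], length(ids), tt, byrow = TRUE)
    out[, 3 * j - 2] <- rowMeans(m)
    out[, 3 * j - 1] <- as.numeric(m %*% tvec) / denom
    out[, 3 * j] <- m[, tt]
    cn[(3 * j - 2):(3 * j)] <- paste0(features[j], c("_mean", "_slope",
                                                     "_last"))
  }
  colnames(out) <- cn
  rownames(out) <- ids
  out
}

# Mean outcome over a time window, per athlete (ordered by id).
window_outcome <- function(wide, athletes, time_range, outcome) {
  d <- wide[wide$athlete_id %in% athletes &
              wide$time_index %in% time_range, c("athlete_id", outcome)]
  v <- tapply(d[[outcome]], d$athlete_id, mean)
  stats::setNames(as.numeric(v), names(v))[sort(names(v))]
}

#' Train the recurrent (temporal) branch for one fold
#'
#' Fits the LSTM on the fold's training window, predicting the mean outcome
#' over the fold's validation window, with early stopping on a held-out
#' subset of the training athletes.
#'
#' @param panel Normalised, complete long-format panel.
#' @param plan A `split_plan`; only `plan$train_athletes` are ever read.
#' @param config A [temporal_branch_config()].
#' @param outcome Outcome feature name.
#' @param fold Fold number (default: the last fold, longest history).
#' @param features Input features (default: all features in the panel).
#' @param val_frac Fraction of training athletes held out for early
#'   stopping (default 0.15).
#' @return List: trained `net`, prediction/representation closures, the
#'   fold geometry, fit/validation athlete ids, and validation RMSE.
#' @export
train_temporal_branch <- function(panel, plan, config = temporal_branch_config(),
                                  outcome = "fatigue", fold = NULL,
                                  features = NULL, val_frac = 0.15,
                                  athletes = NULL) {
  validate_split_plan(plan)
  wide <- panel_wide(panel)
  features <- features %||% panel_features(panel)
  f <- plan$folds[fold %||% nrow(plan$folds), ]
  train_range <- f$train_start:f$train_end
  valid_range <- f$valid_start:f$valid_end
  set.seed(config$seed)
  tr_ids <- sort(athletes %||% plan$train_athletes)
  stopifnot(all(tr_ids %in% plan$train_athletes))
  n_val <- max(2, round(val_frac * length(tr_ids)))
  val_ids <- sort(sample(tr_ids, n_val))
  fit_ids <- setdiff(tr_ids, val_ids)
  x_fit <- build_sequences(wide, fit_ids, train_range, features)
  x_val <- build_sequences(wide, val_ids, train_range, features)
  y_fit <- window_outcome(wide, fit_ids, valid_range, outcome)
  y_val <- window_outcome(wide, val_ids, valid_range, outcome)
  if (anyNA(x_fit) || anyNA(y_fit)) {
    stop("train_temporal_branch: panel has missing values; impute first",
         call. = FALSE)
  }
  net <- lstm_net(
    input_dim = length(features), embed_dim = config$embed_dim,
    layers = list(list(units = config$lstm_units, bidirectional = FALSE),
                  list(units = config$bilstm_units, bidirectional = TRUE),
                  list(units = config$final_units, bidirectional = FALSE)),
    output_dim = 1, dropout = config$dropout, seed = config$seed)
  net <- fit_lstm(net, x_fit, matrix(y_fit), x_val, matrix(y_val),
                  learning_rate = config$learning_rate,
                  batch_size = config$batch_size,
                  max_epochs = config$max_epochs,
                  adam_betas = config$adam_betas,
                  patience = config$early_stop_patience, seed = config$seed)
  predict_for <- function(ids) {
    x <- build_sequences(wide, sort(ids), train_range, features)
    stats::setNames(as.numeric(predict_lstm(net, x)), sort(ids))
  }
  represent_for <- function(ids) {
    x <- build_sequences(wide, sort(ids), train_range, features)
    h <- predict_lstm(net, x, representation = TRUE)
    rownames(h) <- sort(ids)
    h
  }
  val_rmse <- rmse(predict_for(val_ids), y_val)
  list(net = net, predict = predict_for, represent = represent_for,
       features = features, outcome = outcome, fold = f,
       fit_athletes = fit_ids, val_athletes = val_ids,
       history = net$history, val_rmse = val_rmse)
}

#' Train the gradient-boosting branch for one fold
#'
#' Fits an xgboost regressor on per-athlete static features (window mean,
#' slope, last value of every feature over the fold's training window),
#' predicting the mean outcome over the fold's validation window.
#'
#' @inheritParams train_temporal_branch
#' @param config A [boost_branch_config()].
#' @return List: fitted `booster`, prediction closure, static feature
#'   matrix builder, fold geometry, and validation RMSE.
#' @export
train_boost_branch <- function(panel, plan, config = boost_branch_config(),
                               outcome = "fatigue", fold = NULL,
                               features = NULL, val_frac = 0.15,
                               athletes = NULL) {
  validate_split_plan(plan)
  wide <- panel_wide(panel)
  features <- features %||% panel_features(panel)
  f <- plan$folds[fold %||% nrow(plan$folds), ]
  train_range <- f$train_start:f$train_end
  valid_range <- f$valid_start:f$valid_end
  set.seed(config$seed)
  tr_ids <- sort(athletes %||% plan$train_athletes)
  stopifnot(all(tr_ids %in% plan$train_athletes))
  n_val <- max(2, round(val_frac * length(tr_ids)))
  val_ids <- sort(sample(tr_ids, n_val))
  fit_ids <- setdiff(tr_ids, val_ids)
  x_fit <- build_static_features(wide, fit_ids, train_range, features)
  y_fit <- window_outcome(wide, fit_ids, valid_range, outcome)
  if (nrow(x_fit) != length(y_fit)) {
    stop("train_boost_branch: feature/label length mismatch", call. = FALSE)
  }
  booster <- xgboost::xgboost(
    x = x_fit, y = y_fit, objective = "reg:squarederror",
    nrounds = config$n_estimators, max_depth = config$max_depth,
    learning_rate = config$learning_rate, subsample = config$subsample,
    nthreads = 1, seed = config$seed, verbosity = 0)
  predict_for <- function(ids) {
    x <- build_static_features(wide, sort(ids), train_range, features)
    stats::setNames(predict(booster, x), sort(ids))
  }
  y_val <- window_outcome(wide, val_ids, valid_range, outcome)
  list(booster = booster, predict = predict_for, features = features,
       outcome = outcome, fold = f, fit_athletes = fit_ids,
       val_athletes = val_ids, static_builder = function(ids)
         build_static_features(wide, sort(ids), train_range, features),
       val_rmse = rmse(predict_for(val_ids), y_val))
}

#' Attention-weighted fusion of the two branch outputs
#'
#' Computes `alpha = softmax(W [h1; h2])` per input row and the fused
#' representation `z = alpha_1 h1 + alpha_2 h2`. Both branch outputs must
#' already live in a common dimension.
#'
#' @param h_lstm,h_boost Numeric matrices `B x K` (or vectors, treated as
#'   `B x 1`).
#' @param w Projection matrix `2 x 2K` producing the two attention logits
#'   (or `2 x (2K + 1)` with a leading intercept column).
#' @return List: `z` (`B x K`), `alpha` (`B x 2`, rows sum to one).
#' @export
fuse_attention <- function(h_lstm, h_boost, w) {
  h1 <- as.matrix(h_lstm); h2 <- as.matrix(h_boost)
  if (!all(dim(h1) == dim(h2))) {
    stop("fuse_attention: branch outputs differ in dimension (",
         paste(dim(h1), collapse = "x"), " vs ",
         paste(dim(h2), collapse = "x"), "); project to a common size first",
         call. = FALSE)
  }
  concat <- cbind(h1, h2)
  if (ncol(w) == ncol(concat) + 1) concat <- cbind(1, concat)
  if (ncol(w) != ncol(concat) || nrow(w) != 2) {
    stop("fuse_attention: W must be 2 x ", ncol(cbind(h1, h2)), " (or 2 x ",
         ncol(cbind(h1, h2)) + 1, " with intercept)", call. = FALSE)
  }
  logits <- concat %*% t(w)
  alpha <- softmax(logits)
  z <- alpha[, 1] * h1 + alpha[, 2] * h2
  list(z = z, alpha = alpha)
}

# Learn the fusion projection W (with intercept column) on (frozen) branch
# outputs. Two candidate families: (a) a fully learned input-dependent
# attention (ridge-penalised, multi-start BFGS), and (b) constant
# attention (intercept-only W over a grid of alphas, which includes
# near-pure single-branch fallbacks). The family is chosen by k-fold
# cross-validation within the fusion data, then refitted on all of it, so
# the fused model never loses to the better single branch merely because
# the attention parameters overfitted a small validation set.
fit_fusion_weights <- function(h1, h2, y, ridge = 0.05, cv_folds = 5) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  k <- ncol(h1)
  p <- 2 * (2 * k + 1)
  alphas <- c(0.001, seq(0.05, 0.95, by = 0.05), 0.999)
  const_w <- function(a) {
    wa <- matrix(0, 2, 2 * k + 1)
    wa[1, 1] <- log(a / (1 - a))
    wa
  }
  fit_learned <- function(idx) {
    obj <- function(wv) {
      w <- matrix(wv, 2)
      fz <- fuse_attention(h1[idx, , drop = FALSE], h2[idx, , drop = FALSE],
                           w)
      mean((fz$z - y[idx])^2) + ridge * sum(w[, -1]^2)
    }
    starts <- list(rep(0, p), `[<-`(rep(0, p), 1, 4), `[<-`(rep(0, p), 2, 4))
    fits <- lapply(starts, function(s)
      stats::optim(s, obj, method = "BFGS", control = list(maxit = 300)))
    matrix(fits[[which.min(vapply(fits, `[[`, numeric(1),
                                  "value"))]]$par, 2)
  }
  fit_const <- function(idx) {
    mse <- vapply(alphas, function(a)
      mean((fuse_attention(h1[idx, , drop = FALSE], h2[idx, , drop = FALSE],
                           const_w(a))$z - y[idx])^2), numeric(1))
    const_w(alphas[which.min(mse)])
  }
  n <- nrow(h1)
  cv_folds <- min(cv_folds, n)
  fold_of <- rep_len(seq_len(cv_folds), n)
  cv_mse <- function(fitter) {
    err <- 0
    for (f in seq_len(cv_folds)) {
      w <- fitter(which(fold_of != f))
      hold <- which(fold_of == f)
      err <- err + sum((fuse_attention(h1[hold, , drop = FALSE],
                                       h2[hold, , drop = FALSE], w)$z -
                          y[hold])^2)
    }
    err / n
  }
  if (cv_mse(fit_learned) <= cv_mse(fit_const)) {
    fit_learned(seq_len(n))
  } else {
    fit_const(seq_len(n))
  }
}

#' Train the full hybrid recurrent + boosting predictor
#'
#' Staged protocol: for each forward-chained fold, both branches are fitted
#' on the fold's training window (early stopping and fusion fitting use a
#' held-out subset of training athletes); the attention projection `W` is
#' then learned on the pooled held-out branch predictions, and a
#' non-responder classifier (logistic regression on the fused prediction
#' and the baseline outcome value) is fitted with its decision threshold
#' chosen by Youden's J on the held-out athletes. Test athletes are never
#' read during training.
#'
#' @param panel Normalised, complete panel.
#' @param plan A `split_plan`.
#' @param outcome Primary outcome feature (default `"fatigue"`).
#' @param temporal_config,boost_config Branch configurations.
#' @param raw_panel Optional raw-scale panel used for the responder label
#'   (improvement of at least `mcid` points at the final time point);
#'   defaults to `panel`.
#' @param mcid Minimal clinically important difference in raw points
#'   (default 1.0). Non-responders fail to improve by `mcid`.
#' @param folds Which folds to fit (default: all).
#' @return A `trained_hybrid` object.
#' @export
train_hybrid <- function(panel, plan, outcome = "fatigue",
                         temporal_config = temporal_branch_config(),
                         boost_config = boost_branch_config(),
                         raw_panel = NULL, mcid = 1.0, folds = NULL) {
  validate_split_plan(plan)
  folds <- folds %||% seq_len(nrow(plan$folds))
  branches <- lapply(folds, function(k) {
    tb <- train_temporal_branch(panel, plan, temporal_config, outcome,
                                fold = k)
    bb <- train_boost_branch(panel, plan, boost_config, outcome, fold = k)
    list(temporal = tb, boost = bb, fold = k)
  })
  # held-out per-fold predictions (diagnostics / fold breakdown)
  pool <- lapply(branches, function(br) {
    ids <- br$temporal$val_athletes
    y <- window_outcome(panel_wide(panel), ids,
                        br$temporal$fold$valid_start:br$temporal$fold$valid_end,
                        outcome)
    tibble::tibble(athlete_id = ids, h1 = unname(br$temporal$predict(ids)),
                   h2 = unname(br$boost$predict(ids)), y = unname(y),
                   fold = br$fold)
  })
  pool <- dplyr::bind_rows(pool)

  # Cross-fitted fusion data on the final fold geometry: each half of the
  # training athletes is predicted by branches trained on the other half,
  # giving out-of-sample branch outputs for every training athlete.
  final_k <- folds[length(folds)]
  tr_ids <- sort(plan$train_athletes)
  set.seed(temporal_config$seed + 7L)
  half_a <- sort(sample(tr_ids, floor(length(tr_ids) / 2)))
  half_b <- setdiff(tr_ids, half_a)
  wide_all <- panel_wide(panel)
  fgeom <- plan$folds[final_k, ]
  fuse_rows <- lapply(list(c(1, 2), c(2, 1)), function(ix) {
    halves <- list(half_a, half_b)
    fit_on <- halves[[ix[1]]]; pred_on <- halves[[ix[2]]]
    tb <- train_temporal_branch(panel, plan, temporal_config, outcome,
                                fold = final_k, athletes = fit_on)
    bb <- train_boost_branch(panel, plan, boost_config, outcome,
                             fold = final_k, athletes = fit_on)
    y <- window_outcome(wide_all, pred_on,
                        fgeom$valid_start:fgeom$valid_end, outcome)
    tibble::tibble(athlete_id = sort(pred_on),
                   h1 = unname(tb$predict(pred_on)),
                   h2 = unname(bb$predict(pred_on)), y = unname(y))
  })
  fuse_df <- dplyr::bind_rows(fuse_rows)
  w <- fit_fusion_weights(matrix(fuse_df$h1), matrix(fuse_df$h2), fuse_df$y)

  final <- branches[[length(branches)]]
  label_panel <- raw_panel %||% panel
  resp <- responder_labels(label_panel, outcome, mcid)
  wide <- panel_wide(panel)
  base_tr <- window_outcome(wide, tr_ids, 0, outcome)
  # classifier and decision threshold are both fitted on the cross-fitted
  # branch outputs: out-of-sample fused scores for every training athlete,
  # matching the score distribution seen on new athletes (in-sample scores
  # are over-sharp and mis-place the threshold)
  fz_cf <- fuse_attention(matrix(fuse_df$h1), matrix(fuse_df$h2), w)
  clf_df <- data.frame(
    nonresponder = as.integer(!resp[fuse_df$athlete_id]),
    z = as.numeric(fz_cf$z),
    baseline = unname(base_tr[match(fuse_df$athlete_id, tr_ids)]))
  classifier <- stats::glm(nonresponder ~ z + baseline, data = clf_df,
                           family = stats::binomial())
  cf_scores <- stats::predict(classifier, clf_df, type = "response")
  threshold <- youden_threshold(cf_scores, clf_df$nonresponder == 1)

  structure(list(
    branches = branches, fusion_w = w, pool = pool, outcome = outcome,
    plan = plan, classifier = classifier, threshold = threshold,
    mcid = mcid, responder = resp,
    temporal_config = temporal_config, boost_config = boost_config,
    final_fold = final$fold, panel_wide = wide),
    class = "trained_hybrid")
}

# TRUE = responder: improvement of >= mcid raw points (beneficial
# direction) between baseline and endpoint; both are measured as the mean
# of two adjacent time points to damp single-visit measurement noise.
responder_labels <- function(panel, outcome, mcid = 1.0) {
  d <- feature_direction(outcome)
  sgn <- if (d == 0 || d > 0) 1 else -1
  wide <- panel_wide(dplyr::filter(panel, .data$feature == outcome))
  tmax <- max(wide$time_index)
  ids <- unique(wide$athlete_id)
  first <- window_outcome(wide, ids, 0:min(1, tmax), outcome)
  last <- window_outcome(wide, ids, max(0, tmax - 1):tmax, outcome)
  improvement <- sgn * (first - last)
  stats::setNames(improvement >= mcid, names(first))
}

youden_threshold <- function(scores, positives) {
  if (length(unique(positives)) < 2) return(0.5)
  cand <- sort(unique(scores))
  j <- vapply(cand, function(th) {
    pred <- scores >= th
    sens <- mean(pred[positives]); spec <- mean(!pred[!positives])
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Predict with a trained hybrid model
#'
#' @param object A `trained_hybrid`.
#' @param athletes Athlete ids (default: the plan's test athletes).
#' @param ... Unused.
#' @return Tibble with per-athlete branch predictions, attention weights,
#'   fused prediction, and non-responder probability.
#' @export
predict.trained_hybrid <- function(object, athletes = NULL, ...) {
  ids <- sort(athletes %||% object$plan$test_athletes)
  final <- object$branches[[length(object$branches)]]
  h1 <- final$temporal$predict(ids)
  h2 <- final$boost$predict(ids)
  fz <- fuse_attention(matrix(h1), matrix(h2), object$fusion_w)
  base <- window_outcome(object$panel_wide, ids, 0, object$outcome)
  prob <- stats::predict(object$classifier,
                         data.frame(z = as.numeric(fz$z),
                                    baseline = unname(base)),
                         type = "response")
  tibble::tibble(athlete_id = ids, h_lstm = unname(h1), h_boost = unname(h2),
                 alpha_lstm = fz$alpha[, 1], alpha_boost = fz$alpha[, 2],
                 fused = as.numeric(fz$z),
                 nonresponder_prob = as.numeric(prob),
                 nonresponder_pred = as.numeric(prob) >= object$threshold)
}

#' Evaluation metrics for predictions
#'
#' RMSE, R-squared and MAPE for continuous predictions; rank-statistic
#' (Mann-Whitney) AUC, and sensitivity / specificity at the supplied
#' threshold for the classifier scores. Single-class truth yields `NA` AUC
#' with a warning; MAPE excludes truths with `|y| < 0.1`.
#'
#' @param predictions,truth Aligned numeric vectors.
#' @param scores Classifier scores (optional).
#' @param labels Logical/0-1 truth for the classifier (positive = event).
#' @param threshold Decision threshold for sensitivity/specificity.
#' @return An `eval_report` list.
#' @export
evaluate_predictions <- function(predictions = NULL, truth = NULL,
                                 scores = NULL, labels = NULL,
                                 threshold = 0.5) {
  out <- list()
  if (!is.null(predictions)) {
    stopifnot(length(predictions) == length(truth))
    out$rmse <- rmse(predictions, truth)
    out$r_squared <- r_squared(predictions, truth)
    out$mape <- mape(predictions, truth)
  }
  if (!is.null(scores)) {
    labels <- as.logical(labels)
    stopifnot(length(scores) == length(labels))
    if (length(unique(labels)) < 2) {
      warning("evaluate_predictions: single-class truth; AUC undefined")
      out$auc <- NA_real_
      out$sensitivity <- NA_real_
      out$specificity <- NA_real_
    } else {
      out$auc <- auc_rank(scores, labels)
      pred <- scores >= threshold
      out$sensitivity <- sum(pred & labels) / sum(labels)
      out$specificity <- sum(!pred & !labels) / sum(!labels)
      out$threshold <- threshold
      out$confusion <- c(tp = sum(pred & labels), fn = sum(!pred & labels),
                         tn = sum(!pred & !labels), fp = sum(pred & !labels))
    }
  }
  structure(out, class = "eval_report")
}

# Mann-Whitney AUC via average ranks (tie-aware).
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels); n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity / specificity from confusion counts
#'
#' @param tp,fn,tn,fp Confusion-matrix counts.
#' @return List with `sensitivity` = TP/(TP+FN) and `specificity` =
#'   TN/(TN+FP).
#' @export
confusion_rates <- function(tp, fn, tn, fp) {
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Evaluate a trained hybrid on its held-out test athletes
#'
#' @param model A `trained_hybrid`.
#' @param athletes Athlete ids (default: test athletes).
#' @return An `eval_report` with regression and classification metrics.
#' @export
evaluate_hybrid <- function(model, athletes = NULL) {
  ids <- sort(athletes %||% model$plan$test_athletes)
  preds <- predict(model, ids)
  final <- model$branches[[length(model$branches)]]
  truth <- window_outcome(model$panel_wide, ids,
                          final$temporal$fold$valid_start:
                            final$temporal$fold$valid_end, model$outcome)
  nonresp <- !model$responder[ids]
  evaluate_predictions(preds$fused, unname(truth),
                       scores = preds$nonresponder_prob, labels = nonresp,
                       threshold = model$threshold)
}

#' Compare the hybrid against its single branches on test athletes
#'
#' Trains nothing new: reads the final-fold branch predictions and the
#' fused prediction for the test athletes and reports the three RMSEs.
#'
#' @param model A `trained_hybrid`.
#' @return Tibble with columns `model` and `rmse`.
#' @export
compare_branches <- function(model) {
  ids <- sort(model$plan$test_athletes)
  preds <- predict(model, ids)
  final <- model$branches[[length(model$branches)]]
  truth <- unname(window_outcome(model$panel_wide, ids,
                                 final$temporal$fold$valid_start:
                                   final$temporal$fold$valid_end,
                                 model$outcome))
  tibble::tibble(
    model = c("temporal_only", "boost_only", "hybrid"),
    rmse = c(rmse(preds$h_lstm, truth), rmse(preds$h_boost, truth),
             rmse(preds$fused, truth)))
}

#' @export
print.trained_hybrid <- function(x, ...) {
  cat("<trained_hybrid> outcome:", x$outcome, "\n")
  final <- x$branches[[length(x$branches)]]
  cat("  folds fitted:", length(x$branches), " final fold window: [",
      final$temporal$fold$valid_start, ",",
      final$temporal$fold$valid_end, "]\n")
  cat("  fusion W:\n"); print(round(x$fusion_w, 4))
  invisible(x)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (nm in setdiff(names(x), "confusion")) {
    cat(sprintf("  %-12s %s\n", nm, paste(round(unlist(x[[nm]]), 4),
                                          collapse = " ")))
  }
  invisible(x)
}
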