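#' Sampling-based Shapley attribution
#'
#' Permutation-sampling estimator of Shapley values: for every instance,
#' `n_samples` random feature permutations are drawn, each paired with a
#' background row; features are switched from the background value to the
#' instance value along the permutation, and each feature's marginal
#' prediction change is its contribution. Contributions telescope, so each
#' instance's attributions sum exactly to `f(x)` minus the mean prediction
#' over that instance's sampled background rows (local accuracy); the
#' Monte-Carlo error of individual attributions shrinks as
#' `1 / sqrt(n_samples)`.
#'
#' @param pred_fun Function mapping a numeric matrix (rows = instances) to
#'   a numeric prediction vector.
#' @param x Instance matrix `n x d`.
#' @param background Background matrix `m x d` (the reference
#'   distribution).
#' @param n_samples Permutations per instance (must be at least `d + 2`).
#' @param seed Seed.
#' @return List: `phi` (`n x d` attribution matrix), `baseline` (per
#'   instance: mean prediction over its sampled background rows), `pred`
#'   (`f(x)`).
#' @export
shap_sampling <- function(pred_fun, x, background, n_samples = 100,
                          seed = 1L) {
  x <- as.matrix(x); background <- as.matrix(background)
  d <- ncol(x)
  if (n_samples < d + 2) {
    stop("shap_sampling: n_samples must be at least n_features + 2 (= ",
         d + 2, ")", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(x)
  phi <- matrix(0, n, d, dimnames = list(rownames(x), colnames(x)))
  baseline <- numeric(n)
  pred <- as.numeric(pred_fun(x))
  for (i in seq_len(n)) {
    zi <- background[sample.int(nrow(background), n_samples, replace = TRUE),
                     , drop = FALSE]
    perms <- replicate(n_samples, sample.int(d), simplify = FALSE)
    # rows: for each permutation, the d + 1 step-wise hybrids
    big <- matrix(0, n_samples * (d + 1), d)
    for (s in seq_len(n_samples)) {
      row0 <- zi[s, ]
      block <- matrix(row0, d + 1, d, byrow = TRUE)
      pi_s <- perms[[s]]
      for (k in seq_len(d)) {
        block[(k + 1):(d + 1), pi_s[k]] <- x[i, pi_s[k]]
      }
      big[((s - 1) * (d + 1) + 1):(s * (d + 1)), ] <- block
    }
    colnames(big) <- colnames(x)
    f_all <- matrix(as.numeric(pred_fun(big)), d + 1, n_samples)
    contrib <- f_all[-1, , drop = FALSE] - f_all[-(d + 1), , drop = FALSE]
    acc <- numeric(d)
    for (s in seq_len(n_samples)) acc[perms[[s]]] <- acc[perms[[s]]] +
        contrib[, s]
    phi[i, ] <- acc / n_samples
    baseline[i] <- mean(f_all[1, ])
  }
  list(phi = phi, baseline = baseline, pred = pred)
}

resolve_pred_fun <- function(model) {
  if (is.function(model)) return(model)
  if (inherits(model, "xgb.Booster")) {
    return(function(m) stats::predict(model, as.matrix(m)))
  }
  if (inherits(model, c("lm", "glm"))) {
    return(function(m) stats::predict(model, as.data.frame(m)))
  }
  stop("shap: cannot derive a prediction function from class ",
       paste(class(model), collapse = "/"), call. = FALSE)
}

#' Global Shapley feature importance
#'
#' Mean absolute Shapley value per feature across instances, with ranks.
#' Optional `feature_groups` (a named mapping column -> group) sums
#' attributions within each group before ranking, which lets engineered
#' per-feature statistics be reported under their parent feature.
#'
#' @param model Prediction function, fitted xgboost booster, or lm/glm.
#' @param data Instance matrix.
#' @param background Background matrix (default: up to 50 rows sampled from
#'   `data`).
#' @param n_samples Permutations per instance.
#' @param seed Seed.
#' @param feature_groups Optional named character vector mapping columns of
#'   `data` to group labels.
#' @return An `importance_table`: tibble (feature, importance, rank) with
#'   the per-instance signed attributions in attribute `phi`, plus
#'   `baseline` and `pred`.
#' @export
shap_importance <- function(model, data, background = NULL, n_samples = 100,
                            seed = 1L, feature_groups = NULL) {
  pred_fun <- resolve_pred_fun(model)
  data <- as.matrix(data)
  if (is.null(background)) {
    set.seed(seed)
    background <- data[sample.int(nrow(data), min(50, nrow(data))), ,
                       drop = FALSE]
  }
  sh <- shap_sampling(pred_fun, data, background, n_samples, seed)
  phi <- sh$phi
  if (!is.null(feature_groups)) {
    groups <- feature_groups[colnames(phi)]
    agg <- sapply(unique(groups), function(g)
      rowSums(phi[, groups == g, drop = FALSE]))
    phi <- matrix(agg, nrow = nrow(phi),
                  dimnames = list(rownames(sh$phi), unique(groups)))
  }
  imp <- colMeans(abs(phi))
  tab <- tibble::tibble(feature = names(imp), importance = unname(imp))
  tab <- tab[order(-tab$importance), ]
  tab$rank <- seq_len(nrow(tab))
  structure(tab, phi = phi, baseline = sh$baseline, pred = sh$pred,
            class = c("importance_table", class(tab)))
}

#' Shapley dependency records for one feature
#'
#' Per-instance (feature value, Shapley value, colour-feature value)
#' triples with a Spearman monotone-trend statistic.
#'
#' @param model,data,background,n_samples,seed As in [shap_importance()].
#' @param feature Feature to analyse.
#' @param colour_feature Feature whose value is attached for moderation
#'   analysis (default: none).
#' @return Tibble `(value, shap, colour)` with attributes
#'   `trend_spearman` and `trend_p`.
#' @export
shap_dependency <- function(model, data, feature, colour_feature = NULL,
                            background = NULL, n_samples = 100, seed = 1L) {
  data <- as.matrix(data)
  if (!feature %in% colnames(data)) {
    stop("shap_dependency: feature '", feature, "' not in data",
         call. = FALSE)
  }
  imp <- shap_importance(model, data, background, n_samples, seed)
  phi <- attr(imp, "phi")
  v <- data[, feature]
  out <- tibble::tibble(
    value = v, shap = phi[, feature],
    colour = if (!is.null(colour_feature)) data[, colour_feature]
             else NA_real_)
  if (stats::sd(v) == 0) {
    warning("shap_dependency: constant feature; trend undefined")
    attr(out, "trend_spearman") <- NA_real_
    attr(out, "trend_p") <- NA_real_
  } else if (stats::sd(out$shap) == 0) {
    attr(out, "trend_spearman") <- NA_real_
    attr(out, "trend_p") <- NA_real_
  } else {
    ct <- stats::cor.test(v, out$shap, method = "spearman", exact = FALSE)
    attr(out, "trend_spearman") <- unname(ct$estimate)
    attr(out, "trend_p") <- ct$p.value
  }
  out
}

#' Shapley importance for a trained hybrid model
#'
#' Attributes the fused regression head over the per-athlete static feature
#' view (window mean, slope and last value of each feature feeding the
#' boosting branch; the temporal branch's contribution enters through the
#' attention fusion at its background-mean value, so it lands in the
#' baseline term). Attributions of the three statistics of a feature are
#' summed and reported under the parent feature.
#'
#' @param model A `trained_hybrid`.
#' @param athletes Athletes to attribute (default: training athletes).
#' @param background_n Background sample size (default 50).
#' @param n_samples Permutations per instance.
#' @param seed Seed.
#' @return An `importance_table` over parent features.
#' @export
shap_importance_hybrid <- function(model, athletes = NULL, background_n = 50,
                                   n_samples = NULL, seed = 1L) {
  final <- model$branches[[length(model$branches)]]
  ids <- sort(athletes %||% model$plan$train_athletes)
  x <- final$boost$static_builder(ids)
  set.seed(seed)
  bg_ids <- sort(sample(model$plan$train_athletes,
                        min(background_n, length(model$plan$train_athletes))))
  bg <- final$boost$static_builder(bg_ids)
  h1_const <- mean(final$temporal$predict(bg_ids))
  w <- model$fusion_w
  pred_fun <- function(m) {
    h2 <- stats::predict(final$boost$booster, as.matrix(m))
    fz <- fuse_attention(matrix(rep(h1_const, length(h2))), matrix(h2), w)
    as.numeric(fz$z)
  }
  groups <- sub("_(mean|slope|last)$", "", colnames(x))
  names(groups) <- colnames(x)
  n_samples <- n_samples %||% (ncol(x) + 2)
  shap_importance(pred_fun, x, background = bg, n_samples = n_samples,
                  seed = seed, feature_groups = groups)
}

#' Shapley attribution of predicted dietary-pattern response to baseline
#' characteristics
#'
#' Trains a gradient-boosting response model on raw baseline (time 0)
#' features predicting each athlete's 12-month improvement in the primary
#' outcome (in the beneficial direction), then attributes its predictions
#' with sampling-based Shapley values over the raw baseline feature space.
#' This is the per-athlete response-attribution view: which baseline
#' psychological and physiological characteristics drive a favourable
#' predicted response.
#'
#' @param panel Raw-scale long-format panel covering baseline and
#'   endpoint.
#' @param athletes Athletes used to train the response model (e.g. the
#'   training split; default all).
#' @param outcome Primary outcome feature (default `"fatigue"`).
#' @param features Baseline features attributed (default: all 52).
#' @param config A [boost_branch_config()] for the response model.
#' @param n_samples,seed Passed to [shap_importance()].
#' @return An `importance_table` over baseline features, with the fitted
#'   response model in attribute `model`.
#' @export
shap_response_importance <- function(panel, athletes = NULL,
                                     outcome = "fatigue", features = NULL,
                                     config = boost_branch_config(max_depth = 3),
                                     n_samples = NULL, seed = 1L) {
  check_panel(panel)
  features <- features %||% intersect(ALL_FEATURES, panel_features(panel))
  ids <- sort(athletes %||% unique(panel$athlete_id))
  wide <- panel_wide(panel)
  x0 <- as.matrix(wide[wide$time_index == 0 & wide$athlete_id %in% ids,
                       features])
  rownames(x0) <- sort(ids)
  tmax <- max(wide$time_index)
  d <- feature_direction(outcome)
  sgn <- if (d == 0 || d > 0) 1 else -1
  first <- window_outcome(wide, ids, 0:1, outcome)     # 2-point averages
  last <- window_outcome(wide, ids, (tmax - 1):tmax, outcome)
  improvement <- sgn * (first - last)
  booster <- xgboost::xgboost(
    x = x0, y = unname(improvement), objective = "reg:squarederror",
    nrounds = config$n_estimators, max_depth = config$max_depth,
    learning_rate = config$learning_rate, subsample = config$subsample,
    nthreads = 1, seed = config$seed, verbosity = 0)
  n_samples <- n_samples %||% (ncol(x0) + 2)
  imp <- shap_importance(booster, x0, n_samples = n_samples, seed = seed)
  attr(imp, "model") <- booster
  imp
}
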