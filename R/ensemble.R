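# Stacking ensemble: three boosting-family base learners produce
# out-of-fold (OOF) positive-class scores which become meta-features for a
# logistic-regression meta-classifier; base learners are refit on the full
# table for inference.

#' Stacking configuration
#'
#' Defaults follow the screening pipeline's published operating point: an
#' XGBoost-style booster (learning rate 0.1, max depth 6, 100 rounds), an
#' AdaBoost over trees capped at 31 leaves with 0.8 per-tree feature
#' subsampling (100 estimators), a LightGBM-style leaf-wise booster (50
#' rounds, 31 leaves), and a logistic meta-classifier with inverse
#' regularization C = 1 (ridge, `lambda = 1/(n C)`).
#'
#' @param n_folds Number of stratified folds for OOF meta-features
#'   (default 5).
#' @param xgb_params List: `eta`, `max_depth`, `nrounds`.
#' @param ada_params List: `n_estimators`, `max_leaves`, `colsample`.
#' @param lgb_params List: `nrounds`, `max_leaves`, `eta`.
#' @param meta_C Inverse regularization strength of the meta logistic
#'   regression.
#' @param seed Integer seed governing folding, subsampling and booster
#'   seeds.
#' @return An object of class `stacking_config`.
#' @export
stacking_config <- function(n_folds = 5,
                            xgb_params = list(eta = 0.1, max_depth = 6, nrounds = 100),
                            ada_params = list(n_estimators = 100, max_leaves = 31,
                                              colsample = 0.8),
                            lgb_params = list(nrounds = 50, max_leaves = 31,
                                              eta = 0.1),
                            meta_C = 1.0, seed = 1L) {
  stopifnot(n_folds >= 2, meta_C > 0)
  structure(list(n_folds = as.integer(n_folds), xgb_params = xgb_params,
                 ada_params = ada_params, lgb_params = lgb_params,
                 meta_C = meta_C, seed = as.integer(seed)),
            class = "stacking_config")
}

# ---- base learners ---------------------------------------------------------

fit_xgb_learner <- function(X, y, eta, max_depth, nrounds, max_leaves = 0,
                            grow_policy = "depthwise") {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  params <- list(objective = "binary:logistic", eta = eta,
                 max_depth = max_depth, nthread = 1, tree_method = "hist",
                 grow_policy = grow_policy,
                 seed = sample.int(2147483646L, 1))
  if (max_leaves > 0) params$max_leaves <- max_leaves
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  structure(list(booster = booster), class = "xgb_learner")
}

predict_learner <- function(model, X) UseMethod("predict_learner")

#' @export
predict_learner.xgb_learner <- function(model, X) {
  as.numeric(stats::predict(model$booster, xgboost::xgb.DMatrix(X)))
}

# prune an rpart tree to at most `max_leaves` terminal nodes using its
# cost-complexity sequence (nested subtrees; leaves = nsplit + 1)
prune_to_leaves <- function(fit, max_leaves) {
  cp <- fit$cptable
  ok <- which(cp[, "nsplit"] + 1 <= max_leaves)
  if (!length(ok)) return(fit)
  row <- ok[which.max(cp[ok, "nsplit"])]
  if (cp[row, "nsplit"] == max(cp[, "nsplit"])) return(fit)
  rpart::prune(fit, cp = cp[row, "CP"])
}

# discrete AdaBoost (SAMME, two classes) over rpart trees capped at
# `max_leaves` leaves, with per-estimator feature subsampling
fit_ada_learner <- function(X, y, n_estimators, max_leaves, colsample) {
  n <- nrow(X); p <- ncol(X)
  w <- rep(1 / n, n)
  yfac <- factor(y, levels = c(0, 1))
  models <- vector("list", n_estimators)
  feat_sets <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  used <- 0L
  for (m in seq_len(n_estimators)) {
    fs <- sort(sample.int(p, max(1L, round(colsample * p))))
    df <- as.data.frame(X[, fs, drop = FALSE])
    df$.y <- yfac
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "class",
                        control = rpart::rpart.control(cp = 1e-4, xval = 0,
                                                       maxdepth = 10,
                                                       minbucket = 5))
    fit <- prune_to_leaves(fit, max_leaves)
    pred <- stats::predict(fit, df, type = "class")
    miss <- as.numeric(pred != yfac)
    err <- sum(w * miss)
    if (err <= 1e-12) {
      used <- used + 1L
      models[[used]] <- fit; feat_sets[[used]] <- fs; alphas[used] <- 10
      break
    }
    if (err >= 0.5) {
      if (used == 0L) {
        used <- 1L
        models[[1]] <- fit; feat_sets[[1]] <- fs; alphas[1] <- 1e-3
      }
      break
    }
    alpha <- log((1 - err) / err)
    used <- used + 1L
    models[[used]] <- fit; feat_sets[[used]] <- fs; alphas[used] <- alpha
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  structure(list(models = models[seq_len(used)],
                 feat_sets = feat_sets[seq_len(used)],
                 alphas = alphas[seq_len(used)]),
            class = "ada_learner")
}

#' @export
predict_learner.ada_learner <- function(model, X) {
  votes <- numeric(nrow(X))
  total <- sum(model$alphas)
  for (m in seq_along(model$models)) {
    df <- as.data.frame(X[, model$feat_sets[[m]], drop = FALSE])
    pred <- stats::predict(model$models[[m]], df, type = "class")
    votes <- votes + model$alphas[m] * (pred == "1")
  }
  votes / max(total, .Machine$double.eps)
}

base_learner_fits <- function(config) {
  list(
    xgb = function(X, y) fit_xgb_learner(X, y,
      eta = config$xgb_params$eta, max_depth = config$xgb_params$max_depth,
      nrounds = config$xgb_params$nrounds),
    ada = function(X, y) fit_ada_learner(X, y,
      n_estimators = config$ada_params$n_estimators,
      max_leaves = config$ada_params$max_leaves,
      colsample = config$ada_params$colsample),
    lgb = function(X, y) fit_xgb_learner(X, y,
      eta = config$lgb_params$eta, max_depth = 0,
      nrounds = config$lgb_params$nrounds,
      max_leaves = config$lgb_params$max_leaves, grow_policy = "lossguide")
  )
}

stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    rows <- which(labels == cls)
    fold[rows] <- sample(rep(seq_len(n_folds), length.out = length(rows)))
  }
  fold
}

# ---- stacking --------------------------------------------------------------

#' Out-of-fold meta-features
#'
#' Stratified `n_folds`-fold scheme: entry `(i, b)` is base learner `b`'s
#' positive-class score for row `i`, produced by a model trained on every
#' fold except row `i`'s — no row's meta-feature derives from a model that
#' saw it. Deterministic given the config seed.
#'
#' @param table A `cohort_table` with both classes present.
#' @param config A `stacking_config`.
#' @return A list with `meta` (an `n x B` matrix of scores in `[0, 1]`)
#'   and `fold_assignment`.
#' @export
build_meta_features <- function(table, config = stacking_config()) {
  stopifnot(inherits(table, "cohort_table"), inherits(config, "stacking_config"))
  X <- table$values; y <- table$labels
  fits <- base_learner_fits(config)
  with_seed(config$seed, {
    fold <- stratified_folds(y, config$n_folds)
    for (k in seq_len(config$n_folds)) {
      if (length(unique(y[fold == k])) < 2) {
        stop("fold ", k, " does not contain both classes", call. = FALSE)
      }
    }
    meta <- matrix(NA_real_, nrow(X), length(fits),
                   dimnames = list(NULL, names(fits)))
    for (k in seq_len(config$n_folds)) {
      tr <- fold != k
      for (b in seq_along(fits)) {
        model <- fits[[b]](X[tr, , drop = FALSE], y[tr])
        meta[!tr, b] <- predict_learner(model, X[!tr, , drop = FALSE])
      }
    }
    list(meta = meta, fold_assignment = fold)
  })
}

#' Train the stacking ensemble
#'
#' Builds OOF meta-features, fits the logistic meta-classifier on them
#' against the true labels, then refits each base learner on the full table
#' for inference.
#'
#' @param table A `cohort_table` with both classes present.
#' @param config A `stacking_config`.
#' @return An object of class `stacking_model`.
#' @export
train_stacking <- function(table, config = stacking_config()) {
  oof <- build_meta_features(table, config)
  y <- table$labels
  lambda <- 1 / (length(y) * config$meta_C)
  # glmnet wants a decreasing path; end it at the target ridge penalty
  path <- exp(seq(log(max(1, lambda * 1e4)), log(lambda), length.out = 30))
  meta_fit <- glmnet::glmnet(oof$meta, y, family = "binomial", alpha = 0,
                             lambda = path, standardize = FALSE)
  fits <- base_learner_fits(config)
  base_models <- with_seed(derive_seed(config$seed, "refit"), {
    lapply(fits, function(f) f(table$values, y))
  })
  structure(list(base_models = base_models, meta_fit = meta_fit,
                 lambda = lambda, fold_assignment = oof$fold_assignment,
                 oof_meta = oof$meta, config = config,
                 feature_names = table$schema$features$name),
            class = "stacking_model")
}

#' Predict positive-class scores
#'
#' @param model A fitted model (`stacking_model` or `single_booster`).
#' @param table A `cohort_table` whose schema matches the training schema.
#' @return Numeric vector of scores in `[0, 1]`, one per row.
#' @export
predict_scores <- function(model, table) UseMethod("predict_scores")

#' @export
predict_scores.stacking_model <- function(model, table) {
  stopifnot(inherits(table, "cohort_table"))
  if (!identical(table$schema$features$name, model$feature_names)) {
    stop("table schema does not match the training schema", call. = FALSE)
  }
  meta <- vapply(model$base_models,
                 function(m) predict_learner(m, table$values),
                 numeric(n_rows(table)))
  if (n_rows(table) == 1) meta <- matrix(meta, nrow = 1)
  colnames(meta) <- names(model$base_models)
  as.numeric(stats::predict(model$meta_fit, meta, s = model$lambda,
                            type = "response"))
}

#' Train the single-booster baseline
#'
#' The unaugmented comparator: one XGBoost-style learner (learning rate
#' 0.1, depth 6, 100 rounds) trained directly on the table.
#'
#' @param table A `cohort_table`.
#' @param seed Integer seed.
#' @param nrounds,eta,max_depth Booster hyperparameters.
#' @return An object of class `single_booster` usable with
#'   [predict_scores()].
#' @export
train_baseline_booster <- function(table, seed = 1L, nrounds = 100, eta = 0.1,
                                   max_depth = 6) {
  stopifnot(inherits(table, "cohort_table"))
  model <- with_seed(seed, {
    fit_xgb_learner(table$values, table$labels, eta = eta,
                    max_depth = max_depth, nrounds = nrounds)
  })
  structure(list(model = model, feature_names = table$schema$features$name),
            class = "single_booster")
}

#' @export
predict_scores.single_booster <- function(model, table) {
  stopifnot(inherits(table, "cohort_table"))
  if (!identical(table$schema$features$name, model$feature_names)) {
    stop("table schema does not match the training schema", call. = FALSE)
  }
  predict_learner(model$model, table$values)
}
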