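#' Hyperparameter grid for the gradient-boosted MoS regressor
#'
#' The default grid is the full Cartesian product of
#' `n_estimators {100, 200, 300}`, `max_depth {3, 5, 7}`,
#' `learning_rate {0.01, 0.1, 0.2}`, `subsample {0.8, 1.0}` and
#' `colsample_bytree {0.8, 1.0}` — 108 combinations — evaluated by
#' 5-fold cross-validated mean absolute error.
#'
#' @param n_estimators,max_depth,learning_rate,subsample,colsample_bytree
#'   Candidate values (non-empty vectors).
#' @param folds Cross-validation folds (>= 2, default 5).
#' @return A list of class `model_grid`.
#' @export
model_grid <- function(n_estimators = c(100, 200, 300),
                       max_depth = c(3, 5, 7),
                       learning_rate = c(0.01, 0.1, 0.2),
                       subsample = c(0.8, 1.0),
                       colsample_bytree = c(0.8, 1.0),
                       folds = 5) {
  stopifnot(length(n_estimators) > 0, length(max_depth) > 0,
            length(learning_rate) > 0, length(subsample) > 0,
            length(colsample_bytree) > 0, folds >= 2)
  structure(list(n_estimators = n_estimators, max_depth = max_depth,
                 learning_rate = learning_rate, subsample = subsample,
                 colsample_bytree = colsample_bytree, folds = folds),
            class = "model_grid")
}

#' Model feature set for MoS prediction
#'
#' @return Character vector of the predictor columns (CoM coordinates,
#'   CoM velocity, step width, and the Age/BMI/Fall-history categories).
#' @export
mos_features <- function() {
  c("X_Coordinate_CoM", "Y_Coordinate_CoM", "CoM_Velocity", "Step_Width",
    "Age", "BMI", "Fall_History")
}

#' Random row-level train/test split
#'
#' @param table Gait table with at least 10 rows.
#' @param ratio Training fraction in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return A list with `train` and `test` data.frames (disjoint,
#'   exhaustive).
#' @export
split_real <- function(table, ratio = 0.7, seed = 1) {
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)",
                                      call. = FALSE)
  if (nrow(table) < 10) stop("need at least 10 rows to split", call. = FALSE)
  set.seed(seed)
  n_train <- round(nrow(table) * ratio)
  idx <- sample(nrow(table), n_train)
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}

xgb_params <- function(combo, seed) {
  list(max_depth = combo$max_depth, eta = combo$learning_rate,
       subsample = combo$subsample, colsample_bytree = combo$colsample_bytree,
       objective = "reg:squarederror", tree_method = "hist",
       nthread = 1, seed = seed)
}

#' Grid-search a gradient-boosted regressor by cross-validated MAE
#'
#' Evaluates the full Cartesian product of the grid values with k-fold
#' cross-validation (folds shuffled by the run seed), selects the
#' combination minimizing the mean validation MAE (ties go to the first
#' combination in grid order), and refits it on all training rows.
#'
#' @param train Training table containing the features and target.
#' @param grid A [model_grid()].
#' @param seed Integer seed (fold shuffling and booster seed).
#' @param features Predictor columns (default [mos_features()]).
#' @param target Target column (default `"MoS"`).
#' @return A list of class `mos_model` with the fitted booster, the
#'   chosen hyperparameters, the CV table, and fold assignments.
#' @export
train_model <- function(train, grid = model_grid(), seed = 1,
                        features = mos_features(), target = "MoS") {
  miss <- setdiff(c(features, target), names(train))
  if (length(miss)) stop("training table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(train) < grid$folds) stop("fewer training rows than folds",
                                     call. = FALSE)
  X <- as.matrix(train[, features, drop = FALSE])
  y <- train[[target]]
  set.seed(seed)
  fold_id <- sample(rep(seq_len(grid$folds), length.out = nrow(train)))
  combos <- expand.grid(n_estimators = grid$n_estimators,
                        max_depth = grid$max_depth,
                        learning_rate = grid$learning_rate,
                        subsample = grid$subsample,
                        colsample_bytree = grid$colsample_bytree,
                        KEEP.OUT.ATTRS = FALSE)
  cv_mae <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    combo <- combos[i, ]
    fold_mae <- numeric(grid$folds)
    for (k in seq_len(grid$folds)) {
      tr <- fold_id != k
      dtrain <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
      booster <- xgboost::xgb.train(params = xgb_params(combo, seed),
                                    data = dtrain,
                                    nrounds = combo$n_estimators,
                                    verbose = 0)
      pred <- predict(booster, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
      fold_mae[k] <- mean(abs(y[!tr] - pred))
    }
    cv_mae[i] <- mean(fold_mae)
  }
  best <- which.min(cv_mae)
  best_combo <- combos[best, ]
  dall <- xgboost::xgb.DMatrix(X, label = y)
  booster <- xgboost::xgb.train(params = xgb_params(best_combo, seed),
                                data = dall,
                                nrounds = best_combo$n_estimators,
                                verbose = 0)
  structure(
    list(booster = booster,
         best_params = as.list(best_combo),
         cv = cbind(combos, cv_mae = cv_mae),
         features = features, target = target,
         fold_id = fold_id, seed = seed),
    class = "mos_model"
  )
}

#' Regression accuracy metrics
#'
#' MAE, MSE, RMSE (= sqrt(MSE)) and the coefficient of determination
#' `R^2 = 1 - SSE/SST`. R^2 is undefined for a zero-variance target; it
#' is returned as `NA` with `r2_defined = FALSE`.
#'
#' @param y Actual values.
#' @param yhat Predicted values (same length, >= 2).
#' @return A list of class `eval_metrics`: `mae`, `mse`, `rmse`, `r2`,
#'   `r2_defined`, `n`.
#' @export
compute_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2) stop("need at least two observations", call. = FALSE)
  err <- y - yhat
  mse <- mean(err^2)
  sst <- sum((y - mean(y))^2)
  r2_defined <- sst > 0
  structure(
    list(mae = mean(abs(err)), mse = mse, rmse = sqrt(mse),
         r2 = if (r2_defined) 1 - sum(err^2) / sst else NA_real_,
         r2_defined = r2_defined, n = length(y)),
    class = "eval_metrics"
  )
}

#' Per-row SHAP values of a fitted gradient-boosted model
#'
#' Tree-SHAP feature contributions: one column per feature plus the base
#' value column (`BIAS` / `(Intercept)` depending on the xgboost
#' version). Contributions satisfy local accuracy — base plus the
#' per-feature values sum to the prediction on every row.
#'
#' @param model A [train_model()] result.
#' @param X Feature table (or matrix) with the model's feature columns.
#' @return Numeric matrix (n x features + BIAS).
#' @export
shap_values <- function(model, X) {
  stopifnot(inherits(model, "mos_model"))
  if (is.data.frame(X)) {
    miss <- setdiff(model$features, names(X))
    if (length(miss)) stop("feature mismatch: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    X <- as.matrix(X[, model$features, drop = FALSE])
  }
  predict(model$booster, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
}

#' SHAP attribution summary
#'
#' Mean absolute SHAP value per feature plus the model base value.
#'
#' @inheritParams shap_values
#' @return A list of class `attribution_report` with `mean_abs_shap`
#'   (named vector) and `base_value`.
#' @export
shap_summary <- function(model, X) {
  contrib <- shap_values(model, X)
  bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  bias <- contrib[, bias_col]
  contrib <- contrib[, setdiff(colnames(contrib), bias_col), drop = FALSE]
  structure(
    list(mean_abs_shap = colMeans(abs(contrib)),
         base_value = mean(bias)),
    class = "attribution_report"
  )
}

evaluation_report <- function(mode, metrics, model, shap, n_train, n_test,
                              seed) {
  structure(
    list(mode = mode, metrics = metrics,
         best_params = model$best_params, shap = shap,
         n_train = n_train, n_test = n_test, seed = seed),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<evaluation_report> %s (train %d / test %d)\n",
              x$mode, x$n_train, x$n_test))
  cat(sprintf("  MAE %.4f | MSE %.4f | RMSE %.4f | R2 %.4f\n",
              m$mae, m$mse, m$rmse, m$r2))
  invisible(x)
}

#' Train on real, test on real (TRTR)
#'
#' Splits the real table 70:30 at row level, fits the min-max scaler on
#' the training split only, grid-searches the regressor and evaluates on
#' the held-out rows, with SHAP attribution on the test features.
#'
#' @param real Preprocessed real gait table.
#' @param grid A [model_grid()].
#' @param seed Integer seed (split, folds, booster).
#' @param ratio Training fraction (default 0.7).
#' @return An `evaluation_report`.
#' @export
run_trtr <- function(real, grid = model_grid(), seed = 1, ratio = 0.7) {
  check_gait_table(real)
  parts <- split_real(real, ratio = ratio, seed = seed)
  scaler <- fit_minmax(parts$train)
  train <- apply_minmax(parts$train, scaler)
  test <- apply_minmax(parts$test, scaler)
  model <- train_model(train, grid, seed = seed)
  pred <- predict(model$booster,
                  xgboost::xgb.DMatrix(as.matrix(test[, model$features])))
  evaluation_report("TRTR", compute_metrics(test$MoS, pred), model,
                    shap_summary(model, test[, model$features]),
                    nrow(train), nrow(test), seed)
}

#' Train on synthetic, test on real (TSTR)
#'
#' Trains on all synthetic rows (the scaler is fitted on the synthetic
#' training data) and evaluates on the complete real table, with SHAP
#' attribution on the real features.
#'
#' @param synthetic Synthetic gait table (same schema as `real`).
#' @param real Complete real gait table.
#' @inheritParams run_trtr
#' @return An `evaluation_report`.
#' @export
run_tstr <- function(synthetic, real, grid = model_grid(), seed = 1) {
  check_gait_table(synthetic)
  check_gait_table(real)
  scaler <- fit_minmax(synthetic)
  train <- apply_minmax(synthetic, scaler)
  test <- apply_minmax(real, scaler)
  model <- train_model(train, grid, seed = seed)
  pred <- predict(model$booster,
                  xgboost::xgb.DMatrix(as.matrix(test[, model$features])))
  evaluation_report("TSTR", compute_metrics(test$MoS, pred), model,
                    shap_summary(model, test[, model$features]),
                    nrow(train), nrow(test), seed)
}

#' Compare TRTR and TSTR evaluation reports
#'
#' Per metric: `delta = TSTR - TRTR` and
#' `percent = |delta| / TRTR * 100` (direction kept separately; the
#' percent is flagged undefined when the TRTR reference is zero). SHAP
#' attribution changes are reported the same way per feature.
#'
#' @param trtr,tstr `evaluation_report`s from [run_trtr()] /
#'   [run_tstr()].
#' @return A list of class `comparison_report` with `metrics` and `shap`
#'   data.frames.
#' @export
compare_reports <- function(trtr, tstr) {
  metric_names <- c("mae", "mse", "rmse", "r2")
  rows <- lapply(metric_names, function(m) {
    ref <- trtr$metrics[[m]]
    val <- tstr$metrics[[m]]
    delta <- val - ref
    data.frame(metric = m, trtr = ref, tstr = val, delta = delta,
               percent = if (is.na(ref) || ref == 0) NA_real_ else
                 abs(delta) / abs(ref) * 100,
               direction = if (is.na(delta) || delta == 0) "=" else
                 if (delta > 0) "up" else "down")
  })
  shap_rows <- NULL
  if (!is.null(trtr$shap) && !is.null(tstr$shap)) {
    feats <- names(trtr$shap$mean_abs_shap)
    shap_rows <- do.call(rbind, lapply(feats, function(f) {
      ref <- trtr$shap$mean_abs_shap[[f]]
      val <- tstr$shap$mean_abs_shap[[f]]
      delta <- val - ref
      data.frame(feature = f, trtr = ref, tstr = val, delta = delta,
                 percent = if (ref == 0) NA_real_ else
                   abs(delta) / ref * 100,
                 direction = if (delta == 0) "=" else
                   if (delta > 0) "up" else "down")
    }))
  }
  structure(list(metrics = do.call(rbind, rows), shap = shap_rows),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> TSTR vs TRTR\n")
  print(x$metrics, row.names = FALSE)
  if (!is.null(x$shap)) {
    cat("SHAP mean |value| changes:\n")
    print(x$shap, row.names = FALSE)
  }
  invisible(x)
}
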