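tiny_grid <- function() {
  model_grid(n_estimators = 60, max_depth = 3, learning_rate = 0.1,
             subsample = 1.0, colsample_bytree = 1.0)
}

test_that("the train/test split is exact, disjoint and seed-stable", {
  tab <- small_gait_table(seed = 60)[1:100, ]
  parts <- split_real(tab, ratio = 0.7, seed = 1)
  expect_equal(nrow(parts$train), 70)
  expect_equal(nrow(parts$test), 30)
  expect_identical(split_real(tab, ratio = 0.7, seed = 1)$train,
                   parts$train)
  # union of parts equals the original as multisets
  recombined <- rbind(parts$train, parts$test)
  expect_equal(sort(recombined$MoS), sort(tab$MoS))
  expect_error(split_real(tab, ratio = 1.2), "\\(0, 1\\)")
})

test_that("regression metrics satisfy their identities", {
  m <- compute_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$mse, 2 / 3)
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$rmse, 0.8165, tolerance = 1e-4)
  expect_equal(m$r2, 0)

  perfect <- compute_metrics(c(1, 5, 9), c(1, 5, 9))
  expect_equal(unlist(perfect[c("mae", "mse", "rmse")]),
               c(mae = 0, mse = 0, rmse = 0))
  expect_equal(perfect$r2, 1)

  set.seed(61)
  for (i in 1:10) {
    y <- rnorm(50); yhat <- y + rnorm(50, 0, 0.3)
    mm <- compute_metrics(y, yhat)
    expect_equal(mm$rmse^2, mm$mse, tolerance = 1e-12)
    expect_lte(mm$mae, mm$rmse + 1e-12)  # power-mean inequality
    expect_lte(mm$r2, 1)
  }

  flat <- compute_metrics(rep(2, 5), rnorm(5))
  expect_false(flat$r2_defined)
  expect_true(is.na(flat$r2))
})

test_that("a singleton grid equals direct training and grids select by CV MAE", {
  tab <- small_gait_table(seed = 62)
  fit <- train_model(tab, tiny_grid(), seed = 2)
  expect_equal(nrow(fit$cv), 1)
  expect_equal(fit$best_params$n_estimators, 60)

  grid2 <- model_grid(n_estimators = c(5, 120), max_depth = c(1, 4),
                      learning_rate = 0.3, subsample = 1.0,
                      colsample_bytree = 1.0)
  fit2 <- train_model(tab, grid2, seed = 3)
  expect_equal(nrow(fit2$cv), 4)  # full Cartesian product
  best_row <- which.min(fit2$cv$cv_mae)
  expect_equal(fit2$best_params$max_depth, fit2$cv$max_depth[best_row])
  # chosen model beats the worst grid point on CV MAE
  expect_lt(min(fit2$cv$cv_mae), max(fit2$cv$cv_mae))

  expect_error(train_model(tab[1:3, ], tiny_grid()), "folds")
})

test_that("the printed hyperparameter lists expand to 108 combinations", {
  grid <- model_grid()
  n_combos <- length(grid$n_estimators) * length(grid$max_depth) *
    length(grid$learning_rate) * length(grid$subsample) *
    length(grid$colsample_bytree)
  expect_equal(n_combos, 108)
  expect_equal(grid$folds, 5)
})

test_that("SHAP values satisfy local accuracy and isolate unused features", {
  tab <- small_gait_table(seed = 63)
  fit <- train_model(tab, tiny_grid(), seed = 4)
  X <- tab[1:50, fit$features]
  contrib <- shap_values(fit, X)
  pred <- predict(fit$booster, xgboost::xgb.DMatrix(as.matrix(X)))
  expect_equal(unname(rowSums(contrib)), unname(pred), tolerance = 1e-4)

  # a depth-1 forest fed a single informative feature attributes only it
  n <- 400
  toy <- data.frame(A = rep(c(0, 1), n / 2), B = rnorm(n))
  toy$y <- 3 * toy$A
  stump <- train_model(toy,
                       model_grid(n_estimators = 30, max_depth = 1,
                                  learning_rate = 0.5, subsample = 1,
                                  colsample_bytree = 1),
                       seed = 5, features = c("A", "B"), target = "y")
  s <- shap_summary(stump, toy[, c("A", "B")])
  expect_lt(s$mean_abs_shap[["B"]], 1e-8)
  expect_gt(s$mean_abs_shap[["A"]], 1)
  sv <- shap_values(stump, toy[, c("A", "B")])
  pred_toy <- predict(stump$booster,
                      xgboost::xgb.DMatrix(as.matrix(toy[, c("A", "B")])))
  expect_equal(unname(sv[, "A"]), unname(pred_toy - s$base_value),
               tolerance = 1e-5)

  expect_error(shap_values(fit, tab[, 1:3]), "feature mismatch")
})

test_that("TRTR and TSTR find the learnable fixture signal deterministically", {
  tab <- simulate_gait_table(fixture_spec(n_participants = 8,
                                          total_rows = 800), seed = 64)
  trtr <- run_trtr(tab, tiny_grid(), seed = 6)
  expect_gt(trtr$metrics$r2, 0)
  expect_equal(trtr$n_test, nrow(tab) - round(0.7 * nrow(tab)))
  expect_named(trtr$best_params,
               c("n_estimators", "max_depth", "learning_rate",
                 "subsample", "colsample_bytree"))
  trtr2 <- run_trtr(tab, tiny_grid(), seed = 6)
  expect_equal(trtr2$metrics$mae, trtr$metrics$mae)

  m <- fit_synthesizer(tab, derive_metadata(tab), seed = 7)
  syn <- generate_validated(m, gait_constraints(), seed = 8)
  tstr <- run_tstr(syn, tab, tiny_grid(), seed = 6)
  expect_gt(tstr$metrics$r2, 0)
  expect_equal(tstr$n_test, nrow(tab))  # full real table
  expect_equal(tstr$n_train, nrow(syn))

  bad <- syn[, -which(names(syn) == "MoS")]
  expect_error(run_tstr(bad, tab, tiny_grid()), "gait-table column")
})

test_that("report comparison computes deltas, percents and directions", {
  mk <- function(mae, mse, rmse, r2, shap) {
    structure(list(mode = "x",
                   metrics = list(mae = mae, mse = mse, rmse = rmse, r2 = r2),
                   shap = list(mean_abs_shap = shap, base_value = 0)),
              class = "evaluation_report")
  }
  trtr <- mk(3.4672, 18.7308, 4.3279, 0.7321,
             c(Step_Width = 0.719645, Fall_History = 0.026910))
  tstr <- mk(1.4479, 3.5790, 1.8918, 0.9603,
             c(Step_Width = 1.642897, Fall_History = 0.508422))
  cmp <- compare_reports(trtr, tstr)
  mae_row <- cmp$metrics[cmp$metrics$metric == "mae", ]
  expect_equal(mae_row$delta, -2.0193)
  expect_equal(mae_row$percent, 58.2, tolerance = 0.05 / 58.2)
  expect_equal(mae_row$direction, "down")
  r2_row <- cmp$metrics[cmp$metrics$metric == "r2", ]
  expect_equal(r2_row$delta, 0.2282)
  expect_equal(r2_row$percent, 31.2, tolerance = 0.05 / 31.2)
  expect_equal(r2_row$direction, "up")
  sw <- cmp$shap[cmp$shap$feature == "Step_Width", ]
  expect_equal(sw$percent, 128.3, tolerance = 0.05 / 128.3)
  expect_equal(sw$direction, "up")

  same <- compare_reports(trtr, trtr)
  expect_true(all(same$metrics$delta == 0))
  expect_true(all(same$metrics$percent == 0))

  zero <- mk(0, 0, 0, 0.5, c(Step_Width = 0, Fall_History = 1))
  cmp0 <- compare_reports(zero, tstr)
  expect_true(is.na(cmp0$metrics$percent[cmp0$metrics$metric == "mae"]))
})
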