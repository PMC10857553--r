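test_that("scaler standardizes input columns only and round-trips", {
  tr <- learnable_trace(400)
  ds <- build_dataset(tr, window_spec(4, 2, 3))
  sc <- fit_scaler(ds)
  expect_length(sc$mean, ncol(ds$X))
  expect_true(all(sc$std > 0))
  Z <- scale_inputs(sc, ds$X)
  expect_equal(unname(colMeans(Z)), rep(0, ncol(Z)), tolerance = 1e-10)
  expect_equal(unscale_inputs(sc, Z), ds$X, tolerance = 1e-10)

  # degenerate variance is replaced by 1, with a warning
  const <- build_dataset(vital_trace(0:59, rep(95, 60)), window_spec(4, 2, 3))
  expect_warning(sc2 <- fit_scaler(const), "zero-variance")
  expect_true(all(sc2$std == 1))
  expect_equal(unname(sc2$mean), rep(95, 4))
  expect_error(fit_scaler(matrix(1, 1, 3)), "2 rows")
})

test_that("splits have the right sizes and are seed-reproducible", {
  ds <- build_dataset(learnable_trace(200), window_spec(4, 2, 3))
  p100 <- split_dataset(new_ds <- local({
    k <- 100
    structure(list(X = ds$X[1:k, ], y = ds$y[1:k], spec = ds$spec, n_rows = k),
              class = "supervised_dataset")
  }), seed = 4)
  expect_equal(p100$train$n_rows, 70)
  expect_equal(p100$val$n_rows, 15)
  expect_equal(p100$test$n_rows, 15)
  expect_setequal(c(p100$idx$train, p100$idx$val, p100$idx$test), 1:100)

  again <- split_dataset(new_ds, seed = 4)
  expect_identical(p100$idx, again$idx)
  other <- split_dataset(new_ds, seed = 5)
  expect_false(identical(p100$idx$train, other$idx$train))

  tiny <- structure(list(X = ds$X[1:5, ], y = ds$y[1:5], spec = ds$spec,
                         n_rows = 5L), class = "supervised_dataset")
  expect_error(split_dataset(tiny), "too few")
})

test_that("training drives a constant signal to near-zero error", {
  const <- build_dataset(vital_trace(0:199, rep(95, 200)), window_spec(4, 2, 3))
  m <- train_forecaster(tiny_fcnn(), const, fast_protocol())
  expect_lt(m$metrics$mae, 0.01)
  g <- train_forecaster(tiny_gru(), const, fast_protocol())
  expect_lt(g$metrics$mae, 0.01)
})

test_that("a trained network beats the persistence baseline on smooth structure", {
  ds <- build_dataset(learnable_trace(1500), window_spec(5, 2, 5))
  base <- persistence_baseline(ds)
  m <- train_forecaster(tiny_fcnn(), ds, fast_protocol(max_epochs = 60))
  expect_lt(m$metrics$mae, base$mae)
})

test_that("training is deterministic under a pinned seed", {
  ds <- build_dataset(learnable_trace(600), window_spec(4, 2, 3))
  a <- train_forecaster(tiny_fcnn(), ds, fast_protocol(max_epochs = 15))
  b <- train_forecaster(tiny_fcnn(), ds, fast_protocol(max_epochs = 15))
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$net$params, b$net$params)
})

test_that("predictions come back in saturation units regardless of scaling", {
  ds <- build_dataset(learnable_trace(800), window_spec(4, 2, 3))
  m <- train_forecaster(tiny_fcnn(), ds, fast_protocol(max_epochs = 40))
  preds <- predict(m, ds)
  expect_true(all(preds > 70 & preds < 110))
  expect_equal(length(preds), ds$n_rows)
  expect_length(residuals(m), m$metrics$n)
  expect_type(coef(m), "list")
})

test_that("repeat evaluation reports mean and spread, keeping the best weights", {
  ds <- build_dataset(learnable_trace(700), window_spec(4, 2, 3))
  proto <- fast_protocol(repeats = 3, max_epochs = 15)
  m <- evaluate_repeats(tiny_fcnn(), ds, proto)
  expect_equal(nrow(m$per_repeat), 3)
  expect_equal(m$metrics$mae, mean(m$per_repeat$mae))
  expect_true(is.finite(m$metrics_std$mae))
  expect_gte(m$metrics$mae, min(m$per_repeat$mae))
  expect_lte(m$metrics$mae, max(m$per_repeat$mae))
  expect_equal(m$best_repeat, which.min(m$per_repeat$fitness))

  single <- evaluate_repeats(tiny_fcnn(), ds, fast_protocol(repeats = 1, max_epochs = 10))
  expect_equal(unlist(single$metrics_std), c(mae = 0, mse = 0, mape = 0, max_ae = 0))
})

test_that("fcnn and gru consume the same rows; the reshape loses nothing", {
  tr <- learnable_trace(500)
  ds <- build_dataset(tr, window_spec(4, 2, 3, "spo2_hr"))
  expect_equal(ncol(ds$X), 8)
  m <- train_forecaster(tiny_gru(), ds, fast_protocol(max_epochs = 10))
  # reshape round trip: timestep t of channel k is column (k-1)*w + t
  net <- m$net
  steps <- oxipredict:::gru_steps(net, ds$X[1:3, , drop = FALSE])
  expect_length(steps, 4)
  rebuilt <- do.call(cbind, c(lapply(steps, function(s) s[, 1]),
                              lapply(steps, function(s) s[, 2])))
  expect_equal(unname(rebuilt), unname(ds$X[1:3, ]))
  expect_length(predict(m, ds$X[1:5, , drop = FALSE]), 5)
})
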