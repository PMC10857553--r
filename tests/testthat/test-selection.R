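make_grid_fixture <- function() {
  # a noiseless short-horizon task and a noisy long-horizon one: the first
  # should dominate the second on every error metric
  noisy <- simulate_trace(sim_config(duration = 900, noise_sd = 1.5,
                                     episode_rate = 20, dropout_prob = 0,
                                     seed = 8))
  list(easy = build_dataset(learnable_trace(900), window_spec(4, 2, 3)),
       hard = build_dataset(noisy, window_spec(3, 1, 40)))
}

test_that("the grid evaluates |A|*|D| cells and tracks the per-algorithm argmin", {
  fix <- make_grid_fixture()
  datasets <- list(fix$easy, fix$hard)
  archs <- list(fcnn = list(tiny_fcnn()), gru = list(tiny_gru()))
  proto <- fast_protocol(repeats = 1, max_epochs = 12)
  sel <- select_forecaster(datasets, archs, protocol = proto)
  expect_equal(sel$n_cells, 4)
  expect_equal(nrow(sel$cells), 4)
  # argmin per algorithm against a brute-force re-scan of recorded fitness
  for (alg in c("fcnn", "gru")) {
    rows <- sel$cells[sel$cells$algorithm == alg, ]
    expect_equal(sel$per_algorithm[[alg]]$fitness, min(rows$fit))
    win <- rows[which.min(rows$fit), ]
    expect_equal(sel$per_algorithm[[alg]]$spec$w, win$w)
    expect_equal(sel$per_algorithm[[alg]]$spec$f, win$f)
  }
  # deterministic under the pinned protocol seed
  sel2 <- select_forecaster(datasets, archs, protocol = proto)
  expect_equal(sel$cells, sel2$cells)

  expect_error(select_forecaster(list(), archs), "non-empty")
  expect_error(select_forecaster(datasets, list(fcnn = list())), "at least one")
})

test_that("a dominating dataset wins; exact ties go to the earlier cell", {
  fix <- make_grid_fixture()
  proto <- fast_protocol(repeats = 1, max_epochs = 12)
  sel <- select_forecaster(list(fix$easy, fix$hard),
                           list(fcnn = list(tiny_fcnn())), protocol = proto)
  rows <- sel$cells
  # the short-horizon dataset should dominate the 40 s horizon on every metric
  expect_true(all(rows[1, c("mae", "mse", "mape", "max")] <
                    rows[2, c("mae", "mse", "mape", "max")]))
  expect_equal(sel$per_algorithm$fcnn$dataset_index, 1L)

  # identical datasets produce an exact tie: first cell is retained
  tie <- select_forecaster(list(fix$easy, fix$easy),
                           list(fcnn = list(tiny_fcnn())), protocol = proto)
  expect_equal(tie$cells$fit[1], tie$cells$fit[2])
  expect_equal(tie$per_algorithm$fcnn$dataset_index, 1L)
})

test_that("finalize re-scores winners on full datasets and picks the minimum", {
  fix <- make_grid_fixture()
  datasets <- list(fix$easy, fix$hard)
  archs <- list(fcnn = list(tiny_fcnn()), gru = list(tiny_gru()))
  sel <- select_forecaster(datasets, archs,
                           protocol = fast_protocol(repeats = 1, max_epochs = 12))
  fin <- finalize_selection(sel, datasets)
  expect_equal(nrow(fin$full_table), 2)
  expect_equal(fin$overall_best$fitness, min(fin$full_table$fit))
  # definitional cross-check: full-dataset fitness = fitness of metrics on all rows
  for (alg in c("fcnn", "gru")) {
    win <- fin$per_algorithm[[alg]]
    ds <- datasets[[win$dataset_index]]
    rep <- compute_metrics(ds$y, predict(win$model, ds))
    expect_equal(fin$full_table$fit[fin$full_table$algorithm == alg],
                 fitness(rep, fin$params))
  }
  # single algorithm: its winner is the overall best
  solo <- finalize_selection(
    select_forecaster(datasets, list(fcnn = list(tiny_fcnn())),
                      protocol = fast_protocol(repeats = 1, max_epochs = 12)),
    datasets)
  expect_equal(solo$overall_best$algorithm, "fcnn")

  rep_df <- grid_report(sel)
  expect_named(rep_df, c("algorithm", "architecture", "w", "s", "f", "Data",
                         "MAE", "MSE", "MAPE", "Max", "Fit"))
})

test_that("deployment bundles round-trip predictions and validate their schema", {
  ds <- build_dataset(learnable_trace(900), window_spec(4, 2, 3))
  m <- train_forecaster(tiny_fcnn(), ds, fast_protocol(max_epochs = 25))
  dir <- withr::local_tempdir()
  bundle <- export_bundle(m, dir)
  expect_true(file.exists(file.path(dir, "config.json")))

  held <- ds$X[1:100, , drop = FALSE]
  expect_lt(max(abs(predict(bundle, held) - predict(m, held))), 1e-6)

  # reload from disk alone reproduces full-dataset fitness (end-to-end replay)
  fresh <- load_bundle(dir)
  f1 <- fitness(compute_metrics(ds$y, predict(fresh, ds)))
  f2 <- fitness(compute_metrics(ds$y, predict(m, ds)))
  expect_equal(f1, f2, tolerance = 1e-10)

  # schema violations name the missing field
  cfg <- jsonlite::fromJSON(file.path(dir, "config.json"))
  cfg$scaler$std <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  expect_error(load_bundle(dir), "'std'")
  cfg$scaler <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  expect_error(load_bundle(dir), "'scaler'")
})
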