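test_that("row_count matches the enumeration arithmetic", {
  expect_equal(row_count(130, window_spec(20, 5, 20)), 10)
  expect_equal(row_count(120, window_spec(20, 5, 20)), 0)
  # both specs share s*w + f = 120, hence identical counts
  expect_equal(row_count(200, window_spec(20, 5, 20)), 80)
  expect_equal(row_count(200, window_spec(10, 10, 20)), 80)
  expect_equal(row_count(0, window_spec(2, 1, 1)), 0)
})

test_that("row counts depend on the spec only through s*w + f", {
  a <- window_spec(20, 5, 20)
  b <- window_spec(10, 10, 20)
  for (n in c(0, 50, 119, 120, 121, 500, 12345)) {
    expect_identical(row_count(n, a), row_count(n, b))
  }
})

test_that("build_rows reproduces the strided index arithmetic on a ramp", {
  ramp <- vital_trace(0:129, seq_len(130) / 2)  # spo2 must be <= 100
  spec <- window_spec(2, 3, 4)
  ds <- build_rows(ramp, spec)
  expect_equal(ds$n_rows, 120)
  # first row: inputs at indices 1 and 4, target at 1 + 6 + 4 = 11
  expect_equal(unname(ds$X[1, ]), c(1, 4) / 2)
  expect_equal(ds$y[1], 11 / 2)
  # last row's target lands on the final element
  expect_equal(ds$y[120], 130 / 2)
})

test_that("constant segments give all-constant rows; short segments give none", {
  const <- vital_trace(0:59, rep(95, 60))
  ds <- build_rows(const, window_spec(5, 2, 3))
  expect_gt(ds$n_rows, 0)
  expect_true(all(ds$X == 95) && all(ds$y == 95))

  short <- vital_trace(0:4, rep(95, 5))
  expect_equal(build_rows(short, window_spec(20, 1, 1))$n_rows, 0)
})

test_that("build_rows equals the brute-force oracle on random segments", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(5:500, 1)
    spo2 <- sample(seq(80, 100, by = 0.5), n, replace = TRUE)
    hr <- sample(60:120, n, replace = TRUE)
    w <- sample(1:20, 1); s <- sample(1:10, 1); f <- sample(1:25, 1)
    ch <- sample(c("spo2", "spo2_hr"), 1)
    seg <- vital_trace(seq_len(n) - 1, spo2, hr = hr)
    ds <- build_rows(seg, window_spec(w, s, f, ch))
    oracle <- brute_force_rows(spo2, hr, w, s, f, ch)
    expect_equal(ds$n_rows, nrow(oracle))
    expect_equal(row_count(n, window_spec(w, s, f, ch)), nrow(oracle))
    if (nrow(oracle) > 0) {
      expect_equal(unname(cbind(ds$X, ds$y)), unname(oracle))
    }
  }
})

test_that("heart-rate channel appends hr columns with future spo2 as target", {
  seg <- vital_trace(0:29, 90 + (0:29) %% 5, hr = 70 + (0:29))
  ds <- build_rows(seg, window_spec(3, 2, 2, "spo2_hr"))
  expect_equal(ncol(ds$X), 6)
  # row 1: spo2 at indices 1,3,5 then hr at the same indices
  expect_equal(unname(ds$X[1, ]), c(seg$spo2[c(1, 3, 5)], seg$hr[c(1, 3, 5)]))
  expect_equal(ds$y[1], seg$spo2[1 + 6 + 2])
})

test_that("datasets concatenate per-segment rows and never straddle gaps", {
  # two runs of lengths 130 and 5; only the first yields rows
  ts <- c(0:129, 200:204)
  tr <- vital_trace(ts, rep(c(95, 94), length.out = length(ts)))
  spec <- window_spec(2, 3, 4)
  ds <- build_dataset(tr, spec)
  expect_equal(ds$n_rows, 120)

  # splitting an otherwise-valid span strictly reduces the row count
  unsplit <- vital_trace(0:99, rep(95, 100))
  split_ts <- c(0:49, 54:103)
  split_tr <- vital_trace(split_ts, rep(95, 100))
  expect_lt(build_dataset(split_tr, spec)$n_rows,
            build_dataset(unsplit, spec)$n_rows)
  # per-segment sum equals the dataset size
  segs <- segment_continuous(split_tr)
  expect_equal(build_dataset(split_tr, spec)$n_rows,
               sum(vapply(segs, function(sg) row_count(nrow(sg), spec), integer(1))))

  expect_equal(build_dataset(vital_trace(numeric(0), numeric(0)), spec)$n_rows, 0)
})

test_that("dataset_grid yields one tagged dataset per spec, deterministically", {
  tr <- simulate_trace(sim_config(duration = 900, seed = 5))
  specs <- default_grid()
  grid <- dataset_grid(tr, specs)
  expect_length(grid, 5)
  for (k in seq_along(grid)) {
    expect_identical(grid[[k]]$spec, specs[[k]])
    segs <- segment_continuous(tr)
    expect_equal(grid[[k]]$n_rows,
                 sum(vapply(segs, function(sg) row_count(nrow(sg), specs[[k]]),
                            integer(1))))
  }
  # duplicate spec in the list duplicates the dataset; identical inputs are
  # byte-identical
  dup <- dataset_grid(tr, list(specs[[1]], specs[[1]]))
  expect_identical(dup[[1]], dup[[2]])
  expect_identical(grid[[1]], dataset_grid(tr, specs[1])[[1]])
  expect_error(dataset_grid(tr, list()), "non-empty")
})

test_that("dataset CSV + sidecar round trip preserves rows and spec", {
  tr <- simulate_trace(sim_config(duration = 400, seed = 9))
  ds <- build_dataset(tr, window_spec(4, 2, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$X, ds$X)
  expect_equal(back$y, ds$y)
  expect_identical(back$spec, ds$spec)
})
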