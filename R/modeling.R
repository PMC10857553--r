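#' Forecaster architectures
#'
#' `fcnn_architecture()` describes a fully connected feed-forward regressor;
#' the reference configuration has hidden layers of 128, 64 and 32 ReLU
#' units, an input layer sized by the window (`w` columns per channel) and
#' a single linear output — the predicted saturation at the horizon.
#' `gru_architecture()` describes a single gated-recurrent-unit layer (the
#' window is consumed as `w` timesteps of one or two channels) followed by
#' a linear read-out; its default width is comparable to the fcnn's first
#' layer.
#'
#' @param hidden integer vector of hidden-layer widths.
#' @param activation hidden activation; only `"relu"` is implemented.
#' @param units recurrent state size.
#' @param id display identifier; a default is derived from the shape.
#' @return an object of class `model_architecture` with fields `family`
#'   (`"fcnn"` or `"gru"`), `hidden_spec`, `activation`, `id`.
#' @export
fcnn_architecture <- function(hidden = c(128, 64, 32), activation = "relu",
                              id = NULL) {
  if (length(hidden) < 1 || any(hidden < 1)) {
    stop("'hidden' must be a non-empty vector of positive widths", call. = FALSE)
  }
  if (!identical(activation, "relu")) {
    stop("only the 'relu' activation is implemented", call. = FALSE)
  }
  structure(list(family = "fcnn", hidden_spec = as.integer(hidden),
                 activation = activation,
                 id = id %||% paste0("fcnn-", paste(hidden, collapse = "-"))),
            class = "model_architecture")
}

#' @rdname fcnn_architecture
#' @export
gru_architecture <- function(units = 128, id = NULL) {
  if (length(units) != 1 || units < 1) {
    stop("'units' must be a single positive width", call. = FALSE)
  }
  structure(list(family = "gru", hidden_spec = as.integer(units),
                 activation = "tanh/sigmoid",
                 id = id %||% paste0("gru-", units)),
            class = "model_architecture")
}

#' @export
print.model_architecture <- function(x, ...) {
  cat(sprintf("<model_architecture> %s (%s, hidden %s)\n",
              x$id, x$family, paste(x$hidden_spec, collapse = "-")))
  invisible(x)
}

#' Training protocol
#'
#' The repeated-training protocol: each repeat re-randomizes the
#' train/validation/test partition (70/15/15 by default), trains until
#' validation MSE stops improving for `patience` epochs (best weights
#' restored) and evaluates on the held-out test split; metrics are averaged
#' over `repeats` runs.
#'
#' @param fractions train/validation/test fractions, positive, summing to 1.
#' @param repeats number of training repetitions (default 10).
#' @param patience early-stopping patience in epochs.
#' @param max_epochs hard epoch cap.
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param seed base seed; repeat `r` derives its own partition seed from it.
#' @return an object of class `training_protocol`.
#' @export
training_protocol <- function(fractions = c(0.70, 0.15, 0.15), repeats = 10L,
                              patience = 10L, max_epochs = 200L,
                              batch_size = 32L, learning_rate = 1e-3,
                              seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("'fractions' must be three positive numbers summing to 1", call. = FALSE)
  }
  if (repeats < 1) stop("'repeats' must be >= 1", call. = FALSE)
  structure(list(fractions = fractions, repeats = as.integer(repeats),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "training_protocol")
}

#' Fit an input scaler
#'
#' Column means and standard deviations of the input columns only (the
#' target stays in saturation units; predictions therefore come out in
#' percent without inverse-transforming). Zero-variance columns get their
#' standard deviation replaced by 1, with a warning, so constant inputs map
#' to zero rather than NaN.
#'
#' @param dataset a `supervised_dataset` with at least 2 rows, or a numeric
#'   input matrix.
#' @return an object of class `spo2_scaler` with fields `mean` and `std`.
#' @export
fit_scaler <- function(dataset) {
  X <- if (inherits(dataset, "supervised_dataset")) dataset$X else as.matrix(dataset)
  if (nrow(X) < 2) stop("need at least 2 rows to fit a scaler", call. = FALSE)
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  if (any(sdev == 0)) {
    warning("zero-variance input column(s); standard deviation replaced by 1")
    sdev[sdev == 0] <- 1
  }
  structure(list(mean = mu, std = sdev), class = "spo2_scaler")
}

#' Apply / invert an input scaler
#'
#' @param scaler a [fit_scaler()] result.
#' @param X input matrix in original units (or scaled units for the inverse).
#' @return the (un)standardized matrix.
#' @export
scale_inputs <- function(scaler, X) {
  stopifnot(inherits(scaler, "spo2_scaler"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$std, "/")
}

#' @rdname scale_inputs
#' @export
unscale_inputs <- function(scaler, X) {
  stopifnot(inherits(scaler, "spo2_scaler"))
  sweep(sweep(X, 2, scaler$std, "*"), 2, scaler$mean, "+")
}

#' Random train/validation/test partition
#'
#' Disjoint row partition with sizes within one row of the exact fractions,
#' reproducible under a fixed seed.
#'
#' @param dataset a `supervised_dataset` with at least 10 rows.
#' @param fractions three positive fractions summing to 1.
#' @param seed RNG seed.
#' @return a list with `supervised_dataset` elements `train`, `val`, `test`
#'   and the integer index vectors used (`idx`).
#' @export
split_dataset <- function(dataset, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(inherits(dataset, "supervised_dataset"))
  n <- dataset$n_rows
  if (n < 10) stop("too few rows to partition (need >= 10)", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  n_tr <- round(n * fractions[1])
  n_val <- round(n * fractions[2])
  idx <- list(train = perm[seq_len(n_tr)],
              val = perm[n_tr + seq_len(n_val)],
              test = perm[(n_tr + n_val + 1L):n])
  subset_ds <- function(rows) {
    new_supervised_dataset(dataset$X[rows, , drop = FALSE],
                           dataset$y[rows], dataset$spec)
  }
  list(train = subset_ds(idx$train), val = subset_ds(idx$val),
       test = subset_ds(idx$test), idx = idx)
}

init_network <- function(architecture, dataset, y_mean) {
  spec <- dataset$spec
  input_dim <- ncol(dataset$X)
  if (input_dim != spec$w * n_channels(spec)) {
    stop("dataset input width is inconsistent with its window spec", call. = FALSE)
  }
  if (architecture$family == "fcnn") {
    mlp_init(input_dim, architecture$hidden_spec, y_mean)
  } else {
    gru_init(n_channels(spec), architecture$hidden_spec[1], spec$w, y_mean)
  }
}

#' Train a single SpO2 forecaster
#'
#' One pass of the protocol: partition the dataset, standardize inputs with
#' statistics of the training split, train the network with early stopping
#' on validation MSE, and evaluate on the held-out test split.
#'
#' @param architecture a [fcnn_architecture()] or [gru_architecture()].
#' @param dataset a `supervised_dataset` from [build_dataset()].
#' @param protocol a [training_protocol()].
#' @param seed seed for this run (default `protocol$seed`); governs the
#'   partition, weight initialization and batch shuffling, so identical
#'   calls give identical metrics.
#' @return an object of class `spo2_forecaster`; see
#'   [predict.spo2_forecaster()] and friends.
#' @export
train_forecaster <- function(architecture, dataset,
                             protocol = training_protocol(),
                             seed = protocol$seed) {
  stopifnot(inherits(architecture, "model_architecture"),
            inherits(dataset, "supervised_dataset"),
            inherits(protocol, "training_protocol"))
  if (dataset$n_rows == 0) stop("dataset is empty", call. = FALSE)
  parts <- split_dataset(dataset, protocol$fractions, seed)
  scaler <- withCallingHandlers(
    fit_scaler(parts$train),
    warning = function(w) invokeRestart("muffleWarning"))
  Xtr <- scale_inputs(scaler, parts$train$X)
  Xval <- scale_inputs(scaler, parts$val$X)
  Xte <- scale_inputs(scaler, parts$test$X)

  set.seed(seed + 1L)
  net <- init_network(architecture, dataset, mean(parts$train$y))
  net <- train_network(net, Xtr, parts$train$y, Xval, parts$val$y,
                       learning_rate = protocol$learning_rate,
                       batch_size = protocol$batch_size,
                       max_epochs = protocol$max_epochs,
                       patience = protocol$patience)
  pred_test <- net_predict(net, Xte)
  metrics <- compute_metrics(parts$test$y, pred_test)
  structure(list(architecture = architecture, spec = dataset$spec,
                 scaler = scaler, net = net, protocol = protocol,
                 metrics = metrics, metrics_std = NULL,
                 repeats = 1L, seed = seed,
                 y_test = parts$test$y, pred_test = pred_test,
                 history = net$history),
            class = "spo2_forecaster")
}

#' Repeated training with averaged metrics
#'
#' Trains `protocol$repeats` times, re-randomizing the partition each
#' repeat, and reports the per-metric mean and standard deviation over
#' repeats. The returned forecaster carries the weights of the repeat with
#' the lowest composite fitness (ties: earliest repeat).
#'
#' @inheritParams train_forecaster
#' @param params [fitness_params()] used to pick the best repeat.
#' @return a `spo2_forecaster` whose `metrics` are means over repeats, with
#'   `metrics_std` (per-metric sd) and a `per_repeat` data frame attached.
#' @export
evaluate_repeats <- function(architecture, dataset,
                             protocol = training_protocol(),
                             params = fitness_params()) {
  runs <- vector("list", protocol$repeats)
  for (r in seq_len(protocol$repeats)) {
    runs[[r]] <- train_forecaster(architecture, dataset, protocol,
                                  seed = protocol$seed + (r - 1L))
  }
  tab <- do.call(rbind, lapply(seq_along(runs), function(r) {
    m <- runs[[r]]$metrics
    data.frame(repeat_ = r, mae = m$mae, mse = m$mse, mape = m$mape,
               max_ae = m$max_ae, n = m$n,
               fitness = fitness(m, params))
  }))
  best_r <- which.min(tab$fitness)  # which.min returns the first minimum
  out <- runs[[best_r]]
  out$metrics <- structure(list(mae = mean(tab$mae), mse = mean(tab$mse),
                                mape = mean(tab$mape),
                                max_ae = mean(tab$max_ae),
                                n = as.integer(round(mean(tab$n)))),
                           class = "metrics_report")
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  out$metrics_std <- list(mae = sd0(tab$mae), mse = sd0(tab$mse),
                          mape = sd0(tab$mape), max_ae = sd0(tab$max_ae))
  out$repeats <- protocol$repeats
  out$per_repeat <- tab
  out$best_repeat <- best_r
  out
}

#' Persistence baseline
#'
#' The naive forecaster that predicts the last observed saturation in the
#' window; any trained model worth deploying must beat it.
#'
#' @param dataset a `supervised_dataset`.
#' @return a `metrics_report` of the baseline on the full dataset.
#' @export
persistence_baseline <- function(dataset) {
  stopifnot(inherits(dataset, "supervised_dataset"))
  compute_metrics(dataset$y, dataset$X[, dataset$spec$w])
}

#' Predict from a trained forecaster
#'
#' @param object a `spo2_forecaster`.
#' @param newdata a numeric input matrix in original units (one row per
#'   window, `w * channels` columns) or a `supervised_dataset`.
#' @param ... unused.
#' @return predicted saturations, percent.
#' @export
predict.spo2_forecaster <- function(object, newdata, ...) {
  if (inherits(newdata, "supervised_dataset")) newdata <- newdata$X
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  net_predict(object$net, scale_inputs(object$scaler, newdata))
}

#' @export
print.spo2_forecaster <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<spo2_forecaster> %s on (w=%d, s=%d, f=%d, %s)\n",
              x$architecture$id, x$spec$w, x$spec$s, x$spec$f, x$spec$channels))
  cat(sprintf("  test metrics%s: MAE %.3f, MSE %.3f, MAPE %.3f, MaxAE %.3f (n=%d)\n",
              if (x$repeats > 1) sprintf(" (mean of %d repeats)", x$repeats) else "",
              m$mae, m$mse, m$mape, m$max_ae, m$n))
  cat(sprintf("  fitness (default weights): %.3f\n", fitness(m)))
  invisible(x)
}

#' @export
summary.spo2_forecaster <- function(object, ...) {
  print(object)
  cat(sprintf("  protocol: %d/%d/%d%% split, repeats=%d, patience=%d, lr=%g, batch=%d\n",
              round(100 * object$protocol$fractions[1]),
              round(100 * object$protocol$fractions[2]),
              round(100 * object$protocol$fractions[3]),
              object$protocol$repeats, object$protocol$patience,
              object$protocol$learning_rate, object$protocol$batch_size))
  if (!is.null(object$metrics_std)) {
    s <- object$metrics_std
    cat(sprintf("  sd over repeats: MAE %.3f, MSE %.3f, MAPE %.3f, MaxAE %.3f\n",
                s$mae, s$mse, s$mape, s$max_ae))
  }
  cat(sprintf("  trained epochs (best repeat): %d\n", length(object$history)))
  invisible(object)
}

#' @export
residuals.spo2_forecaster <- function(object, ...) {
  object$y_test - object$pred_test
}

#' @export
coef.spo2_forecaster <- function(object, ...) {
  object$net$params
}

#' @export
plot.spo2_forecaster <- function(x, ...) {
  graphics::plot(x$y_test, x$pred_test,
                 xlab = "observed SpO2 (%)", ylab = "predicted SpO2 (%)",
                 main = sprintf("%s, held-out test split", x$architecture$id), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
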