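#' Exhaustive grid selection of the best forecaster
#'
#' Trains every architecture of every learning algorithm on every candidate
#' dataset (|A| x |D| cells), ranks cells by composite [fitness()] of the
#' mean test metrics over repeats, and keeps, for each algorithm, the cell
#' with the strictly lowest fitness (ties resolved by iteration order:
#' algorithms as listed, then architectures, then datasets). Follow with
#' [finalize_selection()] to pick the overall winner.
#'
#' @param datasets non-empty list of `supervised_dataset` objects (each
#'   carries its window spec), e.g. from [dataset_grid()].
#' @param architectures named list mapping algorithm id to a list of
#'   [fcnn_architecture()] / [gru_architecture()] objects.
#' @param params a [fitness_params()].
#' @param protocol a [training_protocol()]; its seed makes the whole grid
#'   deterministic.
#' @return an object of class `forecaster_selection` with fields
#'   `per_algorithm` (winner per algorithm), `cells` (metrics of every
#'   evaluated cell) and the inputs used.
#' @export
select_forecaster <- function(datasets,
                              architectures = list(
                                fcnn = list(fcnn_architecture()),
                                gru = list(gru_architecture())),
                              params = fitness_params(),
                              protocol = training_protocol()) {
  if (length(datasets) == 0) stop("'datasets' must be non-empty", call. = FALSE)
  if (length(architectures) == 0 || is.null(names(architectures)) ||
      any(!nzchar(names(architectures)))) {
    stop("'architectures' must be a non-empty named list (algorithm -> architectures)",
         call. = FALSE)
  }
  if (any(vapply(architectures, length, integer(1)) == 0)) {
    stop("every algorithm needs at least one architecture", call. = FALSE)
  }
  cells <- list()
  per_algorithm <- list()
  for (alg in names(architectures)) {
    best <- NULL
    for (arch in architectures[[alg]]) {
      for (d in seq_along(datasets)) {
        ds <- datasets[[d]]
        model <- evaluate_repeats(arch, ds, protocol, params)
        fit <- fitness(model$metrics, params)
        cells[[length(cells) + 1L]] <- data.frame(
          algorithm = alg, architecture = arch$id,
          w = ds$spec$w, s = ds$spec$s, f = ds$spec$f,
          data = ds$n_rows,
          mae = model$metrics$mae, mse = model$metrics$mse,
          mape = model$metrics$mape, max = model$metrics$max_ae,
          fit = fit)
        if (is.null(best) || fit < best$fitness) {
          best <- list(fitness = fit, model = model, spec = ds$spec,
                       dataset_index = d, architecture = arch$id)
        }
      }
    }
    per_algorithm[[alg]] <- best
  }
  structure(list(per_algorithm = per_algorithm,
                 cells = do.call(rbind, cells),
                 params = params, protocol = protocol,
                 n_cells = length(cells)),
            class = "forecaster_selection")
}

#' Pick the overall best model on full datasets
#'
#' Re-scores each per-algorithm winner on its \emph{entire} dataset (all
#' rows, not just the test split) and selects the model with the lowest
#' full-dataset fitness as the one to deploy.
#'
#' @param sel a [select_forecaster()] result.
#' @param datasets the same dataset list passed to [select_forecaster()].
#' @return `sel` with fields `full_table` (per-algorithm full-dataset
#'   metrics) and `overall_best` (`algorithm`, `fitness`, `model`, `spec`)
#'   added.
#' @export
finalize_selection <- function(sel, datasets) {
  stopifnot(inherits(sel, "forecaster_selection"))
  rows <- list()
  best <- NULL
  for (alg in names(sel$per_algorithm)) {
    win <- sel$per_algorithm[[alg]]
    ds <- datasets[[win$dataset_index]]
    rep <- compute_metrics(ds$y, predict(win$model, ds))
    fit <- fitness(rep, sel$params)
    rows[[length(rows) + 1L]] <- data.frame(
      algorithm = alg, architecture = win$architecture,
      w = win$spec$w, s = win$spec$s, f = win$spec$f, data = ds$n_rows,
      mae = rep$mae, mse = rep$mse, mape = rep$mape, max = rep$max_ae,
      fit = fit)
    if (is.null(best) || fit < best$fitness) {
      best <- list(algorithm = alg, fitness = fit, model = win$model,
                   spec = win$spec, dataset_index = win$dataset_index)
    }
  }
  sel$full_table <- do.call(rbind, rows)
  sel$overall_best <- best
  sel
}

#' @export
print.forecaster_selection <- function(x, ...) {
  cat(sprintf("<forecaster_selection> %d grid cells evaluated\n", x$n_cells))
  print(grid_report(x), row.names = FALSE, digits = 4)
  for (alg in names(x$per_algorithm)) {
    w <- x$per_algorithm[[alg]]
    cat(sprintf("  best %s: %s on (w=%d,s=%d,f=%d), fitness %.3f\n",
                alg, w$architecture, w$spec$w, w$spec$s, w$spec$f, w$fitness))
  }
  if (!is.null(x$overall_best)) {
    b <- x$overall_best
    cat(sprintf("  overall best (full-dataset fitness %.3f): %s / (w=%d,s=%d,f=%d)\n",
                b$fitness, b$algorithm, b$spec$w, b$spec$s, b$spec$f))
  }
  invisible(x)
}

#' Grid report shaped like the published per-patient tables
#'
#' One row per evaluated grid cell with columns `w`, `s`, `f`, `Data`,
#' `MAE`, `MSE`, `MAPE`, `Max`, `Fit` (plus the algorithm/architecture in
#' front), sorted by MAE within algorithm.
#'
#' @param sel a [select_forecaster()] result.
#' @param file optional CSV path to write the report to.
#' @return the report data frame, invisibly when `file` is given.
#' @export
grid_report <- function(sel, file = NULL) {
  stopifnot(inherits(sel, "forecaster_selection"))
  df <- sel$cells
  df <- df[order(df$algorithm, df$mae), ]
  out <- data.frame(algorithm = df$algorithm, architecture = df$architecture,
                    w = df$w, s = df$s, f = df$f, Data = df$data,
                    MAE = df$mae, MSE = df$mse, MAPE = df$mape,
                    Max = df$max, Fit = df$fit)
  if (!is.null(file)) {
    write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

bundle_config_fields <- c("model_id", "algorithm", "w", "s", "f", "channels",
                          "input_length", "scaler")

#' Export a deployment bundle
#'
#' Writes a self-contained directory: `weights.rds` (the trained network)
#' plus `config.json` describing everything an edge runtime needs to use it
#' — model id, algorithm family, window spec, input length, and the scaling
#' mean/std vectors applied to inputs before inference.
#'
#' @param model a trained `spo2_forecaster`.
#' @param out_dir directory to create/populate.
#' @return an object of class `deployment_bundle` (also the value of
#'   [load_bundle()] on `out_dir`).
#' @export
export_bundle <- function(model, out_dir) {
  stopifnot(inherits(model, "spo2_forecaster"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- model$spec
  config <- list(model_id = model$architecture$id,
                 algorithm = model$architecture$family,
                 w = spec$w, s = spec$s, f = spec$f,
                 channels = spec$channels,
                 input_length = spec$w * n_channels(spec),
                 scaler = list(mean = unname(model$scaler$mean),
                               std = unname(model$scaler$std)))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(model$net, file.path(out_dir, "weights.rds"))
  load_bundle(out_dir)
}

#' Load a deployment bundle
#'
#' Validates the JSON config schema (every missing required field is named
#' in the error) and returns a streaming-ready predictor usable with
#' [predict.deployment_bundle()], [stream_push()] and [replay()].
#'
#' @param dir bundle directory written by [export_bundle()].
#' @return an object of class `deployment_bundle`.
#' @export
load_bundle <- function(dir) {
  cfg_path <- file.path(dir, "config.json")
  if (!file.exists(cfg_path)) stop(sprintf("no config.json in '%s'", dir), call. = FALSE)
  config <- jsonlite::fromJSON(cfg_path)
  for (field in bundle_config_fields) {
    if (is.null(config[[field]])) {
      stop(sprintf("deployment config is missing required field '%s'", field),
           call. = FALSE)
    }
  }
  for (field in c("mean", "std")) {
    if (is.null(config$scaler[[field]])) {
      stop(sprintf("deployment config is missing required field '%s'", field),
           call. = FALSE)
    }
  }
  spec <- window_spec(config$w, config$s, config$f, config$channels)
  if (config$input_length != spec$w * n_channels(spec)) {
    stop("deployment config 'input_length' is inconsistent with the window spec",
         call. = FALSE)
  }
  net <- readRDS(file.path(dir, "weights.rds"))
  scaler <- structure(list(mean = config$scaler$mean, std = config$scaler$std),
                      class = "spo2_scaler")
  structure(list(config = config, spec = spec, scaler = scaler, net = net,
                 dir = dir),
            class = "deployment_bundle")
}

#' @export
print.deployment_bundle <- function(x, ...) {
  cat(sprintf("<deployment_bundle> %s (%s), w=%d s=%d f=%d, %s, %d inputs\n",
              x$config$model_id, x$config$algorithm, x$spec$w, x$spec$s,
              x$spec$f, x$spec$channels, x$config$input_length))
  invisible(x)
}

#' @param object a `deployment_bundle`.
#' @param newdata raw input matrix, `input_length` columns.
#' @param ... unused.
#' @rdname load_bundle
#' @export
predict.deployment_bundle <- function(object, newdata, ...) {
  if (inherits(newdata, "supervised_dataset")) newdata <- newdata$X
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  net_predict(object$net, scale_inputs(object$scaler, newdata))
}
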