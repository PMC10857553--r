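#' Prediction-error metrics
#'
#' Computes the four error summaries used to rank forecasters: mean absolute
#' error (MAE, saturation points), mean squared error (MSE), mean absolute
#' percentage error (MAPE, in percent) and the largest absolute error over
#' the evaluation set (MaxAE, the tables' "Max").
#'
#' @param y_true observed saturations; strictly positive (MAPE divides by
#'   them).
#' @param y_pred predicted saturations, same length.
#' @return an object of class `metrics_report` with fields `mae`, `mse`,
#'   `mape`, `max_ae` and `n`. Values are kept at full precision; round
#'   only for display.
#' @examples
#' compute_metrics(c(90, 90), c(89, 92))
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("'y_true' and 'y_pred' must have equal length", call. = FALSE)
  }
  if (length(y_true) < 1) stop("need at least one evaluated pair", call. = FALSE)
  if (any(y_true <= 0)) {
    stop("MAPE is undefined: 'y_true' contains non-positive values", call. = FALSE)
  }
  e <- y_pred - y_true
  structure(list(mae = mean(abs(e)),
                 mse = mean(e^2),
                 mape = 100 * mean(abs(e) / y_true),
                 max_ae = max(abs(e)),
                 n = length(e)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  cat(sprintf("<metrics_report> n=%d  MAE=%.*f  MSE=%.*f  MAPE=%.*f  MaxAE=%.*f\n",
              x$n, digits, x$mae, digits, x$mse, digits, x$mape, digits, x$max_ae))
  invisible(x)
}

#' Weights of the composite fitness score
#'
#' Defaults are the study weights: alpha = 5, beta = 2.5, gamma = 1.67,
#' delta = 1.25. Alpha divides the maximum error, damping the influence of
#' a single outlier prediction; the remaining weights multiply MSE, MAPE
#' and MAE.
#'
#' @param alpha,beta,gamma,delta positive weights.
#' @return an object of class `fitness_params`.
#' @export
fitness_params <- function(alpha = 5, beta = 2.5, gamma = 1.67, delta = 1.25) {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("fitness weights must be positive and finite", call. = FALSE)
  }
  structure(as.list(vals), class = "fitness_params")
}

#' Composite fitness of a forecaster (lower is better)
#'
#' \deqn{fitness = MaxAE/\alpha + \beta \cdot MSE + \gamma \cdot MAPE + \delta \cdot MAE}
#'
#' A single scalar balancing worst-case error (damped by `alpha`) against
#' the three mean error measures; model/dataset combinations are ranked by
#' it and the minimum wins.
#'
#' @param report a `metrics_report` from [compute_metrics()], or any list
#'   with fields `mae`, `mse`, `mape`, `max_ae`.
#' @param params a [fitness_params()].
#' @return a single numeric score.
#' @examples
#' r <- compute_metrics(c(90, 90), c(89, 92))
#' fitness(r)
#' @export
fitness <- function(report, params = fitness_params()) {
  stopifnot(inherits(params, "fitness_params"))
  need <- c("mae", "mse", "mape", "max_ae")
  if (!all(need %in% names(report))) {
    stop("'report' must carry mae, mse, mape and max_ae", call. = FALSE)
  }
  report$max_ae / params$alpha + params$beta * report$mse +
    params$gamma * report$mape + params$delta * report$mae
}

#' Serialize a metrics report (plus its fitness) as JSON
#'
#' @inheritParams fitness
#' @return a JSON string `{mae, mse, mape, max_ae, n, fitness}`.
#' @export
metrics_json <- function(report, params = fitness_params()) {
  jsonlite::toJSON(list(mae = report$mae, mse = report$mse, mape = report$mape,
                        max_ae = report$max_ae, n = report$n,
                        fitness = fitness(report, params)),
                   auto_unbox = TRUE, digits = NA)
}

#' Reference pilot-study results
#'
#' Error metrics reported for five patients (A–E), each evaluated over five
#' sliding-window configurations, in the pilot evaluation this package's
#' selection methodology follows. Columns: `patient`, `w`, `s`, `f`, `data`
#' (number of input patterns), `mae`, `mse`, `mape`, `max` and the
#' published composite fitness `fit`. Useful for validating the fitness
#' arithmetic and the report layout against published numbers.
#'
#' @return a data frame of 25 rows (5 patients x 5 configurations).
#' @export
pilot_results <- function() {
  path <- system.file("extdata", "pilot_study_results.csv",
                      package = "oxipredict", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Relative difference between two pattern counts
#'
#' Percent increase of count `a` over reference count `b`,
#' `100 * (a - b) / b`; used in dataset-size comparisons across patients.
#'
#' @param a,b positive pattern counts.
#' @return percent difference (numeric).
#' @export
pattern_count_increase <- function(a, b) {
  stopifnot(b > 0)
  100 * (a - b) / b
}
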