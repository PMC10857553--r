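#' Define a sliding-window dataset shape
#'
#' A supervised dataset is characterized by the window size `w` (number of
#' past data points per input channel), the stride `s` (spacing, in data
#' points, between consecutive window elements) and the prediction horizon
#' `f` (forward offset of the target). For a continuous run `x`, row `i`
#' takes inputs \eqn{x_{i + s(j-1)}} for \eqn{j = 1..w} and the target
#' \eqn{x_{i + s w + f}}: the target sits one stride plus `f` points beyond
#' the last window element. At 1 Hz sampling, points are seconds.
#'
#' @param w window size in data points (>= 1).
#' @param s stride in elements (>= 1).
#' @param f prediction horizon in data points (>= 1).
#' @param channels `"spo2"` for saturation-only inputs, `"spo2_hr"` to
#'   append the heart-rate values at the same window indices.
#' @return an object of class `window_spec`.
#' @seealso [build_dataset()], [row_count()], [default_grid()]
#' @export
window_spec <- function(w, s = 1, f = 1, channels = c("spo2", "spo2_hr")) {
  channels <- match.arg(channels)
  if (!is.numeric(w) || length(w) != 1 || w < 1 || w != floor(w)) {
    stop("'w' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(s) || length(s) != 1 || s < 1 || s != floor(s)) {
    stop("'s' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(f) || length(f) != 1 || f < 1 || f != floor(f)) {
    stop("'f' must be a positive integer", call. = FALSE)
  }
  structure(list(w = as.integer(w), s = as.integer(s), f = as.integer(f),
                 channels = channels),
            class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> w=%d, s=%d, f=%d, channels=%s\n",
              x$w, x$s, x$f, x$channels))
  invisible(x)
}

n_channels <- function(spec) if (spec$channels == "spo2_hr") 2L else 1L

#' The default candidate grid of window shapes
#'
#' The five configurations retained after preliminary screening across
#' patients: `<w20,s10,f20>`, `<w20,s10,f30>`, `<w20,s10,f40>`,
#' `<w20,s5,f20>` and `<w10,s10,f20>`.
#'
#' @param channels channel selection passed to [window_spec()].
#' @return a list of five `window_spec` objects.
#' @export
default_grid <- function(channels = "spo2") {
  list(window_spec(20, 10, 20, channels),
       window_spec(20, 10, 30, channels),
       window_spec(20, 10, 40, channels),
       window_spec(20, 5, 20, channels),
       window_spec(10, 10, 20, channels))
}

#' Number of supervised rows a segment yields
#'
#' A segment of `n` points yields `max(0, n - s*w - f)` rows: the start
#' index ranges over `1 .. n - s*w - f` so that the last row's target lands
#' exactly on the segment's final point. The count depends on the spec only
#' through `s*w + f`, which is why, e.g., `(w=20,s=5,f=20)` and
#' `(w=10,s=10,f=20)` always produce identical dataset sizes.
#'
#' @param n segment length in data points.
#' @param spec a [window_spec()].
#' @return an integer row count.
#' @export
row_count <- function(n, spec) {
  stopifnot(inherits(spec, "window_spec"), is.numeric(n), n >= 0)
  max(0L, as.integer(n) - spec$s * spec$w - spec$f)
}

new_supervised_dataset <- function(X, y, spec) {
  cn <- paste0("x", seq_len(ncol(X)))
  dimnames(X) <- list(NULL, cn)
  structure(list(X = X, y = as.numeric(y), spec = spec, n_rows = nrow(X)),
            class = "supervised_dataset")
}

empty_dataset <- function(spec) {
  new_supervised_dataset(matrix(numeric(0), nrow = 0,
                                ncol = spec$w * n_channels(spec)),
                         numeric(0), spec)
}

#' @export
print.supervised_dataset <- function(x, ...) {
  cat(sprintf("<supervised_dataset> %d rows, %d input columns (w=%d, s=%d, f=%d, %s)\n",
              x$n_rows, ncol(x$X), x$spec$w, x$spec$s, x$spec$f, x$spec$channels))
  invisible(x)
}

#' Build supervised rows from one continuous segment
#'
#' Slides the strided window over a single time-continuous segment. Row `i`
#' (1-based) collects the SpO2 values at segment indices
#' `i + s*(0:(w-1))` as inputs and the SpO2 at `i + s*w + f` as target; with
#' `channels = "spo2_hr"` the heart-rate values at the same input indices
#' are appended as `w` further columns (the target is always future SpO2).
#' A segment shorter than one full window-plus-horizon span contributes no
#' rows.
#'
#' @param segment a `vital_trace` segment from [segment_continuous()].
#' @param spec a [window_spec()].
#' @return a `supervised_dataset` with fields `X` (inputs), `y` (targets),
#'   `spec` and `n_rows`.
#' @export
build_rows <- function(segment, spec) {
  stopifnot(inherits(segment, "vital_trace"), inherits(spec, "window_spec"))
  n <- nrow(segment)
  m <- row_count(n, spec)
  if (m == 0L) return(empty_dataset(spec))
  w <- spec$w; s <- spec$s; f <- spec$f
  i <- seq_len(m)
  # index matrix: m rows, w columns; entry [i, j] = i + s*(j-1)
  idx <- outer(i, s * (seq_len(w) - 1L), `+`)
  X <- matrix(segment$spo2[idx], nrow = m, ncol = w)
  if (spec$channels == "spo2_hr") {
    hr <- segment$hr
    if (anyNA(hr[seq_len(max(idx))])) {
      stop("heart-rate channel requested but hr is missing within the segment",
           call. = FALSE)
    }
    X <- cbind(X, matrix(hr[idx], nrow = m, ncol = w))
  }
  y <- segment$spo2[i + s * w + f]
  new_supervised_dataset(X, y, spec)
}

#' Build a supervised dataset from a whole trace
#'
#' Segments the trace at dropout gaps (see [segment_continuous()]) and
#' concatenates the rows each segment yields under [build_rows()]; no row
#' ever mixes samples from both sides of a gap.
#'
#' @param trace a [vital_trace()].
#' @param spec a [window_spec()].
#' @param max_gap continuity threshold in seconds (default 3).
#' @return a `supervised_dataset`; possibly empty.
#' @export
build_dataset <- function(trace, spec, max_gap = 3) {
  segs <- segment_continuous(trace, max_gap)
  parts <- lapply(segs, build_rows, spec = spec)
  parts <- parts[vapply(parts, function(p) p$n_rows > 0L, logical(1))]
  if (length(parts) == 0) return(empty_dataset(spec))
  new_supervised_dataset(do.call(rbind, lapply(parts, `[[`, "X")),
                         unlist(lapply(parts, `[[`, "y")), spec)
}

#' Build one dataset per window spec
#'
#' @param trace a [vital_trace()].
#' @param specs non-empty list of [window_spec()] objects.
#' @param max_gap continuity threshold in seconds.
#' @return a list of `supervised_dataset`, one per spec, in order.
#' @export
dataset_grid <- function(trace, specs = default_grid(), max_gap = 3) {
  if (length(specs) == 0) stop("'specs' must be non-empty", call. = FALSE)
  lapply(specs, function(sp) build_dataset(trace, sp, max_gap))
}

#' Persist a supervised dataset as CSV plus a JSON sidecar
#'
#' The CSV holds columns `x1..x{w*channels},y`; the sidecar `<path>.json`
#' records `{w, s, f, channels, n_rows}` so the shape survives round trips.
#'
#' @param dataset a `supervised_dataset`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "supervised_dataset"))
  df <- as.data.frame(dataset$X)
  df$y <- dataset$y
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(w = dataset$spec$w, s = dataset$spec$s, f = dataset$spec$f,
               channels = dataset$spec$channels, n_rows = dataset$n_rows)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  df <- read.csv(path)
  spec <- window_spec(meta$w, meta$s, meta$f, meta$channels)
  X <- as.matrix(df[, setdiff(names(df), "y"), drop = FALSE])
  new_supervised_dataset(X, df$y, spec)
}
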