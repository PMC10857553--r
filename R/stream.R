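#' Streaming inference state
#'
#' Holds the rolling buffer the edge loop needs: the last
#' `s*(w-1)+1` samples of the current time-continuous run. A dropout gap
#' (consecutive timestamps more than `max_gap` s apart) empties the buffer,
#' so no prediction ever mixes samples from both sides of a gap.
#'
#' @param bundle a [load_bundle()] / [export_bundle()] result.
#' @param max_gap continuity threshold in seconds (default 3, matching
#'   [segment_continuous()]).
#' @return an object of class `stream_state`.
#' @seealso [stream_push()], [replay()]
#' @export
stream_state <- function(bundle, max_gap = 3) {
  stopifnot(inherits(bundle, "deployment_bundle"))
  spec <- bundle$spec
  structure(list(bundle = bundle, spec = spec, max_gap = max_gap,
                 span = spec$s * (spec$w - 1L) + 1L,
                 buf_ts = numeric(0), buf_spo2 = numeric(0),
                 buf_hr = numeric(0),
                 last_timestamp = -Inf),
            class = "stream_state")
}

#' Push one sample through the streaming predictor
#'
#' Appends the sample to the rolling buffer (resetting it first if the gap
#' since the previous sample exceeds `max_gap`). Once the buffer spans
#' `s*(w-1)+1` samples, the strided window ending at the newest sample is
#' fed to the model and a forecast is emitted for time
#' `timestamp + s + f` seconds — the same target offset the training rows
#' use.
#'
#' @param state a [stream_state()].
#' @param timestamp sample time, seconds; must exceed the previous push's.
#' @param spo2 measured saturation, percent.
#' @param hr heart rate, bpm; required by `spo2_hr` bundles (a sample
#'   without it is rejected with a warning, no imputation).
#' @return a list with the updated `state` and `prediction` — either `NULL`
#'   or `list(value, for_timestamp)`.
#' @export
stream_push <- function(state, timestamp, spo2, hr = NA_real_) {
  stopifnot(inherits(state, "stream_state"))
  if (timestamp <= state$last_timestamp) {
    stop("timestamps must be strictly increasing in a stream", call. = FALSE)
  }
  state$last_timestamp <- timestamp
  needs_hr <- state$spec$channels == "spo2_hr"
  if (needs_hr && is.na(hr)) {
    warning("sample rejected: bundle requires heart rate and none was given")
    return(list(state = state, prediction = NULL))
  }
  nb <- length(state$buf_ts)
  if (nb > 0 && timestamp - state$buf_ts[nb] > state$max_gap) {
    state$buf_ts <- numeric(0)
    state$buf_spo2 <- numeric(0)
    state$buf_hr <- numeric(0)
  }
  state$buf_ts <- c(state$buf_ts, timestamp)
  state$buf_spo2 <- c(state$buf_spo2, spo2)
  state$buf_hr <- c(state$buf_hr, hr)
  if (length(state$buf_ts) > state$span) {
    keep <- (length(state$buf_ts) - state$span + 1L):length(state$buf_ts)
    state$buf_ts <- state$buf_ts[keep]
    state$buf_spo2 <- state$buf_spo2[keep]
    state$buf_hr <- state$buf_hr[keep]
  }
  prediction <- NULL
  if (length(state$buf_ts) == state$span) {
    pos <- seq(1L, state$span, by = state$spec$s)
    x <- state$buf_spo2[pos]
    if (needs_hr) x <- c(x, state$buf_hr[pos])
    value <- as.numeric(predict(state$bundle, matrix(x, nrow = 1L)))
    prediction <- list(value = value,
                       for_timestamp = timestamp + state$spec$s + state$spec$f)
  }
  list(state = state, prediction = prediction)
}

#' Replay a recorded trace through a deployment bundle
#'
#' Batch-mode equivalent of feeding the trace sample-by-sample through
#' [stream_push()]: for every sample with a full strided window of history
#' inside its continuous segment, the model's forecast is stored in the
#' trace's `prediction` column at the emitting sample's row. The forecast
#' at row `k` refers to time `timestamp[k] + s + f`.
#'
#' @param trace a [vital_trace()].
#' @param bundle a `deployment_bundle`.
#' @param max_gap continuity threshold in seconds.
#' @return `trace` with the `prediction` column populated where a forecast
#'   was emitted.
#' @export
replay <- function(trace, bundle, max_gap = 3) {
  stopifnot(inherits(trace, "vital_trace"), inherits(bundle, "deployment_bundle"))
  spec <- bundle$spec
  w <- spec$w; s <- spec$s
  span <- s * (w - 1L) + 1L
  preds <- rep(NA_real_, nrow(trace))
  breaks <- which(diff(trace$timestamp) > max_gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, nrow(trace))
  if (nrow(trace) == 0) starts <- integer(0)
  for (g in seq_along(starts)) {
    lo <- starts[g]; hi <- ends[g]
    n <- hi - lo + 1L
    if (n < span) next
    k <- span:n  # segment-local emitting indices
    idx <- outer(k - s * (w - 1L), s * (seq_len(w) - 1L), `+`)
    seg_spo2 <- trace$spo2[lo:hi]
    X <- matrix(seg_spo2[idx], nrow = length(k), ncol = w)
    if (spec$channels == "spo2_hr") {
      seg_hr <- trace$hr[lo:hi]
      if (anyNA(seg_hr)) {
        stop("bundle requires heart rate but the trace has missing hr values",
             call. = FALSE)
      }
      X <- cbind(X, matrix(seg_hr[idx], nrow = length(k), ncol = w))
    }
    preds[lo + k - 1L] <- predict(bundle, X)
  }
  trace$prediction <- preds
  trace
}
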