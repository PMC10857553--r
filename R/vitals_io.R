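#' Construct a vital-sign trace
#'
#' A `vital_trace` is an ordered sequence of timestamped pulse-oximeter
#' readings: SpO2 in percent, optionally heart rate in bpm and a model
#' prediction in percent. It is stored as a data frame with columns
#' `timestamp`, `spo2`, `hr`, `prediction` (the last two may be `NA`).
#'
#' Readings the oximeter discarded for poor signal quality simply never
#' appear, so consecutive timestamps may differ by more than the sampling
#' interval; [segment_continuous()] recovers the time-continuous runs.
#'
#' @param timestamp numeric vector, seconds since epoch; finite,
#'   non-negative, strictly increasing.
#' @param spo2 numeric vector, percent saturation in \[0, 100\].
#' @param hr optional numeric vector, beats per minute in (0, 300); `NA`
#'   where unavailable.
#' @param prediction optional numeric vector of forecast saturations
#'   (present in uploaded edge bundles).
#' @param patient_id opaque string identifier.
#' @return an object of class `vital_trace` (a data frame).
#' @seealso [read_trace()], [segment_continuous()], [simulate_trace()]
#' @export
vital_trace <- function(timestamp, spo2, hr = NULL, prediction = NULL,
                        patient_id = NA_character_) {
  n <- length(timestamp)
  if (length(spo2) != n) {
    stop("'timestamp' and 'spo2' must have equal length", call. = FALSE)
  }
  if (is.null(hr)) hr <- rep(NA_real_, n)
  if (is.null(prediction)) prediction <- rep(NA_real_, n)
  if (length(hr) != n || length(prediction) != n) {
    stop("'hr' and 'prediction' must match the number of samples", call. = FALSE)
  }
  timestamp <- as.numeric(timestamp)
  spo2 <- as.numeric(spo2)
  hr <- as.numeric(hr)
  prediction <- as.numeric(prediction)

  if (n > 0) {
    if (anyNA(timestamp) || any(!is.finite(timestamp))) {
      stop("timestamps must be finite", call. = FALSE)
    }
    if (any(timestamp < 0)) {
      stop("timestamps must be non-negative", call. = FALSE)
    }
    d <- diff(timestamp)
    if (any(d == 0)) {
      stop("duplicate timestamps are not allowed", call. = FALSE)
    }
    if (any(d < 0)) {
      stop("timestamps must be strictly increasing", call. = FALSE)
    }
    if (anyNA(spo2) || any(spo2 < 0 | spo2 > 100)) {
      stop("spo2 values must lie within [0, 100]", call. = FALSE)
    }
    hr_ok <- is.na(hr) | (hr > 0 & hr < 300)
    if (!all(hr_ok)) {
      stop("hr values must lie within (0, 300) when present", call. = FALSE)
    }
  }
  out <- data.frame(timestamp = timestamp, spo2 = spo2, hr = hr,
                    prediction = prediction)
  attr(out, "patient_id") <- patient_id
  class(out) <- c("vital_trace", "data.frame")
  out
}

#' @export
print.vital_trace <- function(x, ...) {
  pid <- attr(x, "patient_id")
  cat(sprintf("<vital_trace> %d samples%s\n", nrow(x),
              if (!is.na(pid)) paste0(", patient ", pid) else ""))
  if (nrow(x) > 0) {
    cat(sprintf("  time span: %.0f s (%.0f .. %.0f)\n",
                x$timestamp[nrow(x)] - x$timestamp[1],
                x$timestamp[1], x$timestamp[nrow(x)]))
    cat(sprintf("  spo2: median %.0f%%, range [%.0f, %.0f]\n",
                stats::median(x$spo2), min(x$spo2), max(x$spo2)))
    if (any(!is.na(x$hr))) {
      cat(sprintf("  hr: median %.0f bpm\n", stats::median(x$hr, na.rm = TRUE)))
    }
  }
  invisible(x)
}

trace_from_frame <- function(df, patient_id = NA_character_, where = "input") {
  need <- c("timestamp", "spo2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  ord <- order(df$timestamp)
  df <- df[ord, , drop = FALSE]
  vital_trace(df$timestamp, df$spo2,
              hr = if ("hr" %in% names(df)) df$hr else NULL,
              prediction = if ("prediction" %in% names(df)) df$prediction else NULL,
              patient_id = patient_id)
}

num_or_stop <- function(x, col, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & nzchar(trimws(x)))
  if (length(bad) > 0) {
    # +1 for the header line
    stop(sprintf("parse error in '%s' line %d: column '%s' value '%s' is not numeric",
                 path, bad[1] + 1L, col, x[bad[1]]), call. = FALSE)
  }
  v
}

#' Read a vital-sign trace from disk
#'
#' Reads either the CSV dialect (header `timestamp,spo2,hr`) or a JSONL
#' bundle (one `{"timestamp": ..., "spo2": ..., ...}` object per line, the
#' format edge devices upload). Rows are sorted by timestamp; duplicate
#' timestamps and out-of-range values are rejected.
#'
#' @param path file to read.
#' @param format `"csv"` or `"jsonl"`; by default guessed from the file
#'   extension (`.jsonl`/`.json` select JSONL, anything else CSV).
#' @param patient_id identifier to attach to the trace.
#' @return a [vital_trace()]. An empty file body yields an empty trace.
#' @export
read_trace <- function(path, format = c("auto", "csv", "jsonl"),
                       patient_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0) return(vital_trace(numeric(0), numeric(0), patient_id = patient_id))
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (nrow(df) == 0) return(vital_trace(numeric(0), numeric(0), patient_id = patient_id))
    for (col in intersect(c("timestamp", "spo2", "hr", "prediction"), names(df))) {
      df[[col]] <- num_or_stop(df[[col]], col, path)
    }
    trace_from_frame(df, patient_id, where = path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(vital_trace(numeric(0), numeric(0), patient_id = patient_id))
    recs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        stop(sprintf("parse error in '%s' line %d: %s",
                                     path, i, conditionMessage(e)), call. = FALSE)
                      })
      recs[[i]] <- data.frame(
        timestamp = as.numeric(rec$timestamp %||% NA_real_),
        spo2 = as.numeric(rec$spo2 %||% NA_real_),
        hr = as.numeric(rec$hr %||% NA_real_),
        prediction = as.numeric(rec$prediction %||% NA_real_))
    }
    df <- do.call(rbind, recs)
    if (anyNA(df$timestamp) || anyNA(df$spo2)) {
      bad <- which(is.na(df$timestamp) | is.na(df$spo2))[1]
      stop(sprintf("parse error in '%s' line %d: record lacks timestamp or spo2",
                   path, bad), call. = FALSE)
    }
    trace_from_frame(df, patient_id, where = path)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trace as CSV
#'
#' Writes columns `timestamp,spo2,hr` (plus `prediction` when any sample
#' carries one), the dialect [read_trace()] reads back.
#'
#' @param trace a [vital_trace()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "vital_trace"))
  df <- as.data.frame(trace)
  if (all(is.na(df$prediction))) df$prediction <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a trace as a JSONL data bundle
#'
#' One JSON object per line with keys `timestamp`, `spo2` and, where
#' present, `hr` and `prediction` — the record shape an edge device uploads
#' (reading, heart rate and the computed saturation forecast). Keys whose
#' value is missing are omitted from the record.
#'
#' @inheritParams write_trace
#' @return `path`, invisibly. `read_trace(path, "jsonl")` reproduces the trace.
#' @export
write_bundle <- function(trace, path) {
  stopifnot(inherits(trace, "vital_trace"))
  con <- tryCatch(file(path, open = "w"),
                  error = function(e) stop(sprintf("cannot write '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  for (i in seq_len(nrow(trace))) {
    rec <- list(timestamp = trace$timestamp[i], spo2 = trace$spo2[i])
    if (!is.na(trace$hr[i])) rec$hr <- trace$hr[i]
    if (!is.na(trace$prediction[i])) rec$prediction <- trace$prediction[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Split a trace into time-continuous segments
#'
#' Consecutive samples whose timestamps differ by at most `max_gap` seconds
#' belong to the same continuous run; a larger difference (a dropout gap)
#' starts a new run. A difference of exactly `max_gap` is still continuous.
#' Supervised windows are only ever built inside one segment, so no input
#' pattern straddles a gap.
#'
#' @param trace a [vital_trace()].
#' @param max_gap largest timestamp difference, in seconds, still considered
#'   continuous (default 3).
#' @return a list of `vital_trace` segments whose concatenation is `trace`;
#'   an empty trace gives an empty list.
#' @export
segment_continuous <- function(trace, max_gap = 3) {
  stopifnot(inherits(trace, "vital_trace"), max_gap > 0)
  n <- nrow(trace)
  if (n == 0) return(list())
  breaks <- which(diff(trace$timestamp) > max_gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  lapply(seq_along(starts), function(k) {
    seg <- trace[starts[k]:ends[k], , drop = FALSE]
    attr(seg, "patient_id") <- attr(trace, "patient_id")
    class(seg) <- class(trace)
    seg
  })
}
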