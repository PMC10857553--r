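# Independent brute-force oracle for strided-window enumeration: slides the
# 1-based start index i and gathers input/target indices literally, one row
# at a time, without any closed-form count.
brute_force_rows <- function(spo2, hr, w, s, f, channels = "spo2") {
  n <- length(spo2)
  rows <- list()
  i <- 1L
  repeat {
    in_idx <- i + s * (seq_len(w) - 1L)
    tgt_idx <- i + s * w + f
    if (tgt_idx > n) break
    row <- spo2[in_idx]
    if (channels == "spo2_hr") row <- c(row, hr[in_idx])
    rows[[length(rows) + 1L]] <- c(row, spo2[tgt_idx])
    i <- i + 1L
  }
  if (length(rows) == 0) {
    return(matrix(numeric(0), nrow = 0,
                  ncol = w * (if (channels == "spo2_hr") 2L else 1L) + 1L))
  }
  do.call(rbind, rows)
}

# brute-force gap scan: number of runs = 1 + gaps exceeding the threshold
brute_force_n_segments <- function(timestamps, max_gap = 3) {
  if (length(timestamps) == 0) return(0L)
  n_seg <- 1L
  for (k in seq_len(length(timestamps) - 1L)) {
    if (timestamps[k + 1L] - timestamps[k] > max_gap) n_seg <- n_seg + 1L
  }
  n_seg
}

# small fast configurations shared by the modeling/selection tests
tiny_fcnn <- function() fcnn_architecture(c(16, 8), id = "fcnn-tiny")
tiny_gru <- function() gru_architecture(8, id = "gru-tiny")
fast_protocol <- function(repeats = 1L, seed = 42L, max_epochs = 40L) {
  training_protocol(repeats = repeats, max_epochs = max_epochs,
                    patience = 5L, seed = seed)
}

# a noiseless, gap-free learnable trace: slow sinusoid around baseline
learnable_trace <- function(n = 1500, period = 300) {
  t <- 0:(n - 1)
  spo2 <- 92 + 4 * sin(2 * pi * t / period)
  vital_trace(t, spo2, hr = rep(70, n))
}
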