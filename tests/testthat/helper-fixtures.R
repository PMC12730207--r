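# Shared fixtures, built in code. Heavyweight objects are memoised per
# session so several test files can reuse them.

local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(local_cache[[key]])) local_cache[[key]] <- force(expr)
  local_cache[[key]]
}

# A tone clip at the pipeline rate.
tone_clip <- function(freq, dur = 1, fs = 11025, amp = 1) {
  audio_clip(amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs), fs)
}

# Small synthetic dataset shared by the protocol-level tests. 13 default
# profiles, reduced clip count; preprocessing applied once.
protocol_dataset <- function() {
  cached("protocol_dataset", {
    ds <- generate_dataset(default_profiles(), n_per_species = 16, master_seed = 2024)
    ds$clip <- lapply(ds$clip, preprocess_clip)
    ds
  })
}

# Well-separated Gaussian classification task. `seed` fixes the class
# centers, `data_seed` the unit-variance draws around them, so train and
# test sets can share centers but not samples.
gaussian_task <- function(k, n_per_class, dim = 8, sep = 6, seed = 1,
                          data_seed = seed + 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim), k, dim)
  centers <- sep * centers / sqrt(rowSums(centers ^ 2))
  set.seed(data_seed)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per_class * dim), n_per_class, dim), 2, centers[i, ], "+")
  }))
  list(x = x, y = rep(sprintf("sp%02d", seq_len(k)), each = n_per_class))
}

# Two well-separated Gaussian classes in 2-D: centers +3 and -3 on each
# coordinate, unit variance (Bayes error far below 1e-3).
two_class_task <- function(n_per_class = 100, seed = 1) {
  set.seed(seed)
  list(x = rbind(matrix(rnorm(n_per_class * 2), ncol = 2) + 3,
                 matrix(rnorm(n_per_class * 2), ncol = 2) - 3),
       y = rep(c("pos", "neg"), each = n_per_class))
}

# Independent modal-label oracle (count, then first appearance among ties).
oracle_mode <- function(labels) {
  best <- NULL
  best_n <- -1L
  for (lab in unique(labels)) {
    n <- sum(labels == lab)
    if (n > best_n) {
      best <- lab
      best_n <- n
    }
  }
  best
}

# FFT peak frequency of a signal (Hz).
fft_peak_hz <- function(x, fs) {
  mag <- Mod(stats::fft(x))[seq_len(length(x) %/% 2)]
  (which.max(mag[-1])) * fs / length(x)
}
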