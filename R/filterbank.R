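# Auditory filterbanks: the ERB-spaced gammatone bank modeling cochlear
# frequency selectivity, and the mel-spaced triangular bank used as the
# conventional baseline.

#' ERB and mel frequency-scale helpers
#'
#' Glasberg–Moore equivalent rectangular bandwidth (ERB) of the auditory
#' filter at frequency `f`: `ERB(f) = 24.7 (4.37 f / 1000 + 1)` Hz. The
#' ERB-rate scale `21.4 log10(1 + 0.00437 f)` maps frequency so equal steps
#' span equal numbers of auditory filters; `erb_rate_to_hz()` inverts it.
#' The mel scale is `2595 log10(1 + f / 700)`.
#'
#' @param f frequency in Hz.
#' @param r ERB-rate value.
#' @param m mel value.
#' @return numeric vector of the same length as the input.
#' @name frequency-scales
NULL

#' @rdname frequency-scales
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' @rdname frequency-scales
#' @export
hz_to_erb_rate <- function(f) 21.4 * log10(1 + 0.00437 * f)

#' @rdname frequency-scales
#' @export
erb_rate_to_hz <- function(r) (10 ^ (r / 21.4) - 1) / 0.00437

#' @rdname frequency-scales
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname frequency-scales
#' @export
mel_to_hz <- function(m) 700 * (10 ^ (m / 2595) - 1)

#' Design an ERB-spaced gammatone filterbank
#'
#' `N` 4th-order gammatone filters whose center frequencies are the `N`
#' points equally spaced on the ERB-rate scale between `fmin` and `fmax`
#' inclusive — i.e. distributed in proportion to their bandwidth, as in the
#' cochlea. Each filter is realized as a cascade of four second-order
#' sections (the standard all-pole digital gammatone approximation) with
#' bandwidth `1.019 * ERB(fc)`.
#'
#' @param N number of filters (2–128).
#' @param fs sampling frequency in Hz.
#' @param fmin,fmax frequency interval covered by the bank; `fmax` defaults
#'   to the Nyquist frequency.
#' @return a `gammatone_fb`: list with `N`, `fs`, `center_freqs`,
#'   `bandwidths` (ERB at each center, Hz), `order` (4), and the per-filter
#'   second-order-section coefficients.
#' @examples
#' fb <- gammatone_bank(16, fs = 11025)
#' fb$center_freqs
#' @export
gammatone_bank <- function(N, fs, fmin = 50, fmax = fs / 2) {
  if (!is_count(N) || N < 2 || N > 128) stopf("`N` must be an integer in [2, 128]")
  if (fmin <= 0 || fmin >= fmax) stopf("Need 0 < fmin < fmax")
  if (fmax > fs / 2) stopf("`fmax` (%g Hz) exceeds the Nyquist frequency %g Hz", fmax, fs / 2)
  cf <- erb_rate_to_hz(seq(hz_to_erb_rate(fmin), hz_to_erb_rate(fmax), length.out = N))
  cf[1] <- fmin
  cf[N] <- fmax
  sos <- gammatone_sos(cf, fs)
  structure(
    list(N = as.integer(N), fs = fs, center_freqs = cf,
         bandwidths = erb_bandwidth(cf), order = 4L,
         sos_b = sos$b, sos_a = sos$a),
    class = c("gammatone_fb", "filterbank")
  )
}

# All-pole digital gammatone: four second-order sections per filter sharing
# the pole pair of a damped resonator at fc with decay 2*pi*1.019*ERB(fc),
# with zeros chosen so the cascade matches the 4th-order gammatone envelope.
gammatone_sos <- function(cf, fs, bw_factor = 1.019) {
  T <- 1 / fs
  B <- 2 * pi * bw_factor * erb_bandwidth(cf)
  theta <- 2 * cf * pi * T
  ct <- cos(theta); st <- sin(theta)
  eB <- exp(B * T)
  a1 <- -2 * ct / eB
  a2 <- exp(-2 * B * T)
  sq_p <- sqrt(3 + 2 ^ 1.5)
  sq_m <- sqrt(3 - 2 ^ 1.5)
  z1 <- -(2 * T * ct / eB + 2 * sq_p * T * st / eB) / 2
  z2 <- -(2 * T * ct / eB - 2 * sq_p * T * st / eB) / 2
  z3 <- -(2 * T * ct / eB + 2 * sq_m * T * st / eB) / 2
  z4 <- -(2 * T * ct / eB - 2 * sq_m * T * st / eB) / 2
  e2 <- exp(4i * cf * pi * T)
  eb2 <- exp(-(B * T) + 2i * cf * pi * T)
  gain <- abs(
    (-2 * e2 * T + 2 * eb2 * T * (ct - sq_m * st)) *
    (-2 * e2 * T + 2 * eb2 * T * (ct + sq_m * st)) *
    (-2 * e2 * T + 2 * eb2 * T * (ct - sq_p * st)) *
    (-2 * e2 * T + 2 * eb2 * T * (ct + sq_p * st)) /
    (-2 / exp(2 * B * T) - 2 * e2 + 2 * (1 + e2) / eB) ^ 4
  )
  n <- length(cf)
  # rows: 4 consecutive sections per filter
  b <- matrix(0, nrow = 4 * n, ncol = 3)
  a <- matrix(0, nrow = 4 * n, ncol = 3)
  zs <- rbind(z1, z2, z3, z4)
  for (g in seq_len(n)) {
    for (s in 1:4) {
      r <- (g - 1) * 4 + s
      scale <- if (s == 1) gain[g] else 1
      b[r, ] <- c(T, zs[s, g], 0) / scale
      a[r, ] <- c(1, a1[g], a2[g])
    }
  }
  list(b = b, a = a)
}

#' @export
print.gammatone_fb <- function(x, ...) {
  cat(sprintf("<gammatone_fb> %d filters @ %g Hz, centers %.1f-%.1f Hz (ERB-spaced)\n",
              x$N, x$fs, min(x$center_freqs), max(x$center_freqs)))
  invisible(x)
}

#' Magnitude response of a filterbank
#'
#' Evaluates every filter's magnitude response on a frequency grid; used for
#' inspection, peak-localization checks and [autoplot.gammatone_fb()].
#'
#' @param bank a `gammatone_fb` or `triangular_fb`.
#' @param freqs frequencies (Hz) at which to evaluate; defaults to a dense
#'   grid up to Nyquist.
#' @return a tibble with columns `filter`, `center_freq`, `freq`, `magnitude`.
#' @export
bank_response <- function(bank, freqs = NULL) {
  if (is.null(freqs)) freqs <- seq(1, bank$fs / 2, length.out = 512)
  if (inherits(bank, "gammatone_fb")) {
    resp <- purrr::map_dfr(seq_len(bank$N), function(g) {
      rows <- (g - 1) * 4 + 1:4
      h <- rep(1, length(freqs))
      for (r in rows) {
        h <- h * iir_response(bank$sos_b[r, ], bank$sos_a[r, ], freqs, bank$fs)
      }
      tibble(filter = g, center_freq = bank$center_freqs[g], freq = freqs, magnitude = h)
    })
  } else {
    grid_f <- (seq_len(nrow(bank$weights)) - 1) * bank$fs / bank$nfft
    resp <- purrr::map_dfr(seq_len(bank$N), function(g) {
      tibble(filter = g, center_freq = bank$center_freqs[g],
             freq = grid_f, magnitude = bank$weights[, g])
    })
  }
  resp
}

#' Gammatone filter output energies per frame
#'
#' Filters every frame independently (zero initial state) with each of the
#' bank's `N` gammatone filters and returns the output energies
#' `S[g] = sum of squared output samples`, the first stage of the cochlear
#' feature computation.
#'
#' @param bank a `gammatone_fb` from [gammatone_bank()].
#' @param frames a `frame_seq` from [frame_signal()], or a single numeric
#'   frame, or an `NS x n` matrix of frame columns.
#' @return an `N x n_frames` matrix of non-negative energies.
#' @export
filter_energies <- function(bank, frames) {
  stopifnot(inherits(bank, "gammatone_fb"))
  mat <- frames_as_matrix(frames)
  if (ncol(mat) == 0) return(matrix(numeric(0), nrow = bank$N, ncol = 0))
  if (nrow(mat) < 2) stopf("Frames must contain at least 2 samples")
  cpp_frame_bank_energies(mat, bank$sos_b, bank$sos_a, bank$N)
}

frames_as_matrix <- function(frames) {
  if (inherits(frames, "frame_seq")) frames$frames
  else if (is.matrix(frames)) frames
  else matrix(as.numeric(frames), ncol = 1)
}

#' Design a mel-spaced triangular filterbank
#'
#' The conventional baseline: `N` triangular weighting functions over the
#' one-sided FFT magnitude spectrum, with centers equally spaced on the mel
#' scale between `fmin` and `fmax` and each triangle spanning its two
#' neighboring centers.
#'
#' @inheritParams gammatone_bank
#' @param nfft FFT length used when weighting frames; defaults at energy
#'   computation time to the frame length.
#' @return a `triangular_fb`: list with `N`, `fs`, `center_freqs`, `nfft`
#'   and the `weights` matrix (`nfft/2 + 1` rows, one column per filter).
#' @export
triangular_bank <- function(N, fs, fmin = 50, fmax = fs / 2, nfft = 512) {
  if (!is_count(N) || N < 2 || N > 128) stopf("`N` must be an integer in [2, 128]")
  if (fmin < 0 || fmin >= fmax) stopf("Need 0 <= fmin < fmax")
  if (fmax > fs / 2) stopf("`fmax` (%g Hz) exceeds the Nyquist frequency %g Hz", fmax, fs / 2)
  centers <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = N))
  centers[1] <- fmin
  centers[N] <- fmax
  # Edge triangles extend symmetrically beyond the end centers
  lower <- c(centers[1] - (centers[2] - centers[1]), centers[-N])
  upper <- c(centers[-1], centers[N] + (centers[N] - centers[N - 1]))
  grid_f <- (0:(nfft %/% 2)) * fs / nfft
  w <- vapply(seq_len(N), function(g) {
    up <- (grid_f - lower[g]) / (centers[g] - lower[g])
    down <- (upper[g] - grid_f) / (upper[g] - centers[g])
    pmax(0, pmin(up, down))
  }, numeric(length(grid_f)))
  structure(
    list(N = as.integer(N), fs = fs, center_freqs = centers, nfft = as.integer(nfft),
         weights = matrix(w, ncol = N)),
    class = c("triangular_fb", "filterbank")
  )
}

#' @export
print.triangular_fb <- function(x, ...) {
  cat(sprintf("<triangular_fb> %d filters @ %g Hz, centers %.1f-%.1f Hz (mel-spaced)\n",
              x$N, x$fs, min(x$center_freqs), max(x$center_freqs)))
  invisible(x)
}

#' Triangular filterbank energies per frame
#'
#' `S[g]` = sum over FFT bins of the triangle-weighted squared one-sided
#' magnitude spectrum of the (unwindowed) frame.
#'
#' @param bank a `triangular_fb`.
#' @param frames a `frame_seq`, numeric frame, or matrix of frame columns.
#' @return an `N x n_frames` matrix of non-negative energies.
#' @export
triangular_energies <- function(bank, frames) {
  stopifnot(inherits(bank, "triangular_fb"))
  mat <- frames_as_matrix(frames)
  if (ncol(mat) == 0) return(matrix(numeric(0), nrow = bank$N, ncol = 0))
  ns <- nrow(mat)
  if (ns != bank$nfft) {
    bank <- triangular_bank(bank$N, bank$fs, min(bank$center_freqs),
                            max(bank$center_freqs), nfft = ns)
  }
  spec <- stats::mvfft(mat)
  half <- Mod(spec[1:(ns %/% 2 + 1), , drop = FALSE]) ^ 2
  t(bank$weights[seq_len(nrow(half)), , drop = FALSE]) %*% half
}
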