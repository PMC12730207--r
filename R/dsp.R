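# Shared signal-processing primitives: band-limited resampling, Butterworth
# high-pass design, zero-phase filtering. These are implemented here because
# no DSP package is available in the target toolchain; each is pinned by
# analytic oracle tests (FFT-peak preservation, designed magnitude response).

# Band-limited (FFT-domain) resampling to exactly n_out samples.
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(length.out = n_out)
  nyq_in <- n %/% 2
  nyq_out <- n_out %/% 2
  k <- min(nyq_in, nyq_out)      # positive frequencies copied (excl. DC)
  Y[1] <- X[1]
  if (k >= 1) {
    Y[2:(k + 1)] <- X[2:(k + 1)]
    Y[n_out - (1:k) + 1] <- X[n - (1:k) + 1]
  }
  # Split a shared Nyquist bin to keep the result real and energy-consistent
  if (n %% 2 == 0 && n_out > n && nyq_in >= 1) {
    Y[nyq_in + 1] <- X[nyq_in + 1] / 2
    Y[n_out - nyq_in + 1] <- Conj(X[nyq_in + 1]) / 2
  }
  if (n_out < n && n_out %% 2 == 0) {
    # Fold energy straddling the new Nyquist into a real bin
    Y[nyq_out + 1] <- Re(Y[nyq_out + 1])
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Butterworth high-pass design via analog prototype + bilinear transform.
# Returns list(b, a) with a[1] == 1.
butter_highpass <- function(order, fc, fs) {
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  # Analog lowpass prototype poles (unit cutoff, left half-plane)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 2 * fs * tan(pi * fc / fs)
  # LP -> HP: s -> warped / s
  p_hp <- warped / p_lp
  z_hp <- rep(0 + 0i, order)
  # Bilinear transform
  fs2 <- 2 * fs
  p_z <- (fs2 + p_hp) / (fs2 - p_hp)
  z_z <- (fs2 + z_hp) / (fs2 - z_hp)
  gain <- Re(prod(fs2 - z_hp) / prod(fs2 - p_hp))
  b <- Re(poly_from_roots(z_z)) * gain
  a <- Re(poly_from_roots(p_z))
  # Normalize so |H| = 1 exactly at Nyquist (z = -1)
  zf <- (-1) ^ (0:order)
  b <- b * abs(sum(a * zf) / sum(b * zf))
  list(b = b, a = a / a[1])
}

# Monic polynomial coefficients from roots (descending powers).
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs) * ri
  coefs
}

# Steady-state initial filter state (direct form II transposed) for a unit
# step input; scaled by the first sample in filtfilt.
filter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (n == 1) return(numeric(0))
  A <- rbind(-a[2:n], cbind(diag(1, n - 2, n - 2), rep(0, n - 2)))
  B <- b[2:n] - a[2:n] * b[1]
  as.numeric(solve(diag(n - 1) - t(A), B))
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# steady-state edge initialization. `padlen` must cover the filter's
# transient (for a low cutoff, a few times fs / cutoff samples).
filtfilt <- function(b, a, x, padlen = 3 * (max(length(b), length(a)) - 1) * 10) {
  n <- length(x)
  padlen <- min(n - 1, padlen)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
    post <- 2 * x[n] - x[seq(n - 1, n - padlen)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  zi <- filter_zi(b, a)
  y <- cpp_iir_filter(ext, b, a, zi * ext[1])
  y <- rev(y)
  y <- cpp_iir_filter(y, b, a, zi * y[1])
  y <- rev(y)
  if (padlen > 0) y <- y[(padlen + 1):(padlen + n)]
  y
}

# Magnitude response of an IIR filter at frequencies f (Hz).
iir_response <- function(b, a, f, fs) {
  w <- exp(-1i * 2 * pi * f / fs)
  hb <- vapply(w, function(z) sum(b * z ^ (seq_along(b) - 1)), complex(1))
  ha <- vapply(w, function(z) sum(a * z ^ (seq_along(a) - 1)), complex(1))
  abs(hb / ha)
}
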