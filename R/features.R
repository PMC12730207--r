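# Cochlear feature computation: log-energy DCT coefficients, delta vectors,
# and per-vocalization aggregates over frames.

# Orthonormal type-II DCT matrix (cached per size).
dct_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      k <- 0:(n - 1)
      m <- sqrt(2 / n) * cos(pi * outer(k, k + 0.5) / n)
      m[1, ] <- sqrt(1 / n)
      cache[[key]] <- m
    }
    cache[[key]]
  }
})

#' Cochlear coefficients from filter output energies
#'
#' The cepstral-style stage: `GC = DCT(log10(S))` with an orthonormal
#' type-II DCT, energies floored at `floor_eps` so silent frames stay
#' finite. With `use_log_dct = FALSE` the energies pass through unchanged —
#' the "raw energy" feature modes.
#'
#' @param S non-negative energy vector (length `N`) or `N x n_frames` matrix.
#' @param use_log_dct apply the log10 + DCT stage (default `TRUE`).
#' @param floor_eps positive floor applied before the logarithm.
#' @return object of the same shape as `S`.
#' @export
gc_coefficients <- function(S, use_log_dct = TRUE, floor_eps = 1e-12) {
  if (any(S < 0)) stopf("Energies must be non-negative")
  if (!use_log_dct) return(S)
  if (is.matrix(S)) {
    dct_matrix(nrow(S)) %*% log10(pmax(S, floor_eps))
  } else {
    as.numeric(dct_matrix(length(S)) %*% log10(pmax(S, floor_eps)))
  }
}

#' Frame-to-frame delta vectors
#'
#' `delta(n) = GC(n) - GC(n-1)` for `n >= 2`; the first frame's delta is the
#' zero vector, keeping the frame count constant.
#'
#' @param GC an `N x n_frames` matrix of per-frame coefficient columns.
#' @return a matrix of the same shape.
#' @export
delta_sequence <- function(GC) {
  GC <- as.matrix(GC)
  if (ncol(GC) < 1) stopf("Need at least one frame")
  cbind(0 * GC[, 1], GC[, -1, drop = FALSE] - GC[, -ncol(GC), drop = FALSE],
        deparse.level = 0)
}

#' Aggregate per-frame features over a vocalization
#'
#' Elementwise mean (`AVGC`) and population standard deviation (`STDGC`) over
#' frames of the concatenated `[GC, delta]` vectors (each of length `2N`).
#' A single frame yields a zero `STDGC` with a warning.
#'
#' @param GC `N x n_frames` coefficient matrix.
#' @param delta optional matching delta matrix; computed with
#'   [delta_sequence()] when omitted.
#' @param include_delta concatenate deltas before aggregating (default
#'   `TRUE`); with `FALSE` the aggregates cover `GC` alone (length `N`).
#' @return list with `AVGC` and `STDGC`, numeric vectors of length `2N`
#'   (or `N`).
#' @export
aggregate_vocalization <- function(GC, delta = NULL, include_delta = TRUE) {
  GC <- as.matrix(GC)
  if (ncol(GC) < 1) stopf("Need at least one frame")
  if (ncol(GC) < 2) rlang::warn("Single frame: standard deviation is zero by convention")
  if (is.null(delta)) delta <- delta_sequence(GC)
  v <- if (include_delta) rbind(GC, as.matrix(delta)) else GC
  avg <- rowMeans(v)
  stddev <- sqrt(rowMeans((v - avg) ^ 2))  # population SD over frames
  list(AVGC = avg, STDGC = stddev)
}

#' Per-frame cochlear features of a frame sequence
#'
#' Runs the full cochlear stage on a frame sequence: filterbank energies
#' `S`, coefficients `GC` (log-DCT or raw), and delta vectors.
#'
#' @param fseq a `frame_seq` from [frame_signal()].
#' @param bank a `gammatone_fb` (or `triangular_fb` for the baseline).
#' @param use_log_dct apply the log10 + DCT stage.
#' @param floor_eps floor before the logarithm.
#' @return list with matrices `S`, `GC`, `delta` (`N x Ns_i` each) and the
#'   flag `mode_log_dct`.
#' @export
cochlear_features <- function(fseq, bank, use_log_dct = TRUE, floor_eps = 1e-12) {
  S <- if (inherits(bank, "triangular_fb")) {
    triangular_energies(bank, fseq)
  } else {
    filter_energies(bank, fseq)
  }
  GC <- gc_coefficients(S, use_log_dct = use_log_dct, floor_eps = floor_eps)
  list(S = S, GC = GC, delta = delta_sequence(GC), mode_log_dct = use_log_dct)
}
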