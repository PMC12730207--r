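# Scalar per-vocalization features: duration d, active-frame rate R, and the
# active-frequency interval [Lf, Hf]. Both thresholded features interpolate
# between the recording's own minimum and maximum (min-max thresholds) with
# strict inequalities.

#' Spectral frame energies
#'
#' Energy of each frame computed in the Fourier domain:
#' `E(n) = sum_{j=1..NS/2} |FT_n(j)|^2` over the one-sided spectrum of the
#' unwindowed frame, excluding the DC bin (the 20 Hz high-pass has removed
#' DC already).
#'
#' @param fseq a `frame_seq` from [frame_signal()].
#' @return numeric vector of length `Ns_i`.
#' @export
frame_stft_energies <- function(fseq) {
  stopifnot(inherits(fseq, "frame_seq"))
  if (fseq$Ns_i == 0) return(numeric(0))
  mag2 <- Mod(frame_spectra(fseq)) ^ 2
  colSums(mag2)
}

# One-sided spectra, bins j = 1 .. NS %/% 2 (DC excluded), one column per frame.
frame_spectra <- function(fseq) {
  spec <- stats::mvfft(fseq$frames)
  nf <- fseq$NS %/% 2L
  spec[1L + seq_len(nf), , drop = FALSE]
}

#' Rate of active frames
#'
#' Fraction of frames whose spectral energy strictly exceeds
#' `TE = mE + ET * (ME - mE)`. With all-equal energies the rate is 0 for
#' every `ET` (strict inequality).
#'
#' @param E per-frame energies, e.g. from [frame_stft_energies()].
#' @param ET threshold fraction in \[0, 1\].
#' @return list with `R` (rate in \[0, 1\]), `HE` (active-frame count) and
#'   `thresholds` (named vector `mE`, `ME`, `TE`).
#' @export
active_frame_rate <- function(E, ET = 0.005) {
  if (length(E) == 0) stopf("Active-frame rate is undefined for an empty frame sequence")
  thr <- activity_threshold(E, ET)
  he <- sum(E > thr[["TE"]])
  list(R = he / length(E), HE = he, thresholds = thr)
}

#' Active-frequency interval
#'
#' Lowest and highest frequencies whose one-sided spectral magnitude strictly
#' exceeds `Tft = mft + ftT * (Mft - mft)` in at least one frame, where
#' `mft`/`Mft` are the global minimum/maximum magnitudes over all frames and
#' bins of the vocalization. Frequencies lie on the bin grid `j * fs / NS`,
#' `j = 1 .. NS/2`. An empty active set (e.g. `ftT = 1`) degenerates to
#' `Lf = Hf =` the frequency of the global-maximum bin, flagged via the
#' `degenerate` field.
#'
#' @param fseq a `frame_seq` from [frame_signal()].
#' @param ftT threshold fraction in \[0, 1\].
#' @return list with `Lf`, `Hf` (Hz), `thresholds` (`mft`, `Mft`, `Tft`) and
#'   `degenerate` flag.
#' @export
active_frequency_interval <- function(fseq, ftT = 0.1) {
  stopifnot(inherits(fseq, "frame_seq"))
  if (fseq$Ns_i == 0) stopf("Active-frequency interval is undefined for an empty frame sequence")
  mag <- Mod(frame_spectra(fseq))
  thr <- activity_threshold(mag, ftT)
  names(thr) <- c("mft", "Mft", "Tft")
  active <- which(apply(mag > thr[["Tft"]], 1, any))
  bin_hz <- fseq$fs / fseq$NS
  if (length(active) == 0) {
    peak <- which(mag == thr[["Mft"]], arr.ind = TRUE)[1, "row"]
    f <- as.numeric(peak) * bin_hz
    return(list(Lf = f, Hf = f, thresholds = thr, degenerate = TRUE))
  }
  list(Lf = min(active) * bin_hz, Hf = max(active) * bin_hz,
       thresholds = thr, degenerate = FALSE)
}

#' Retained share of the analyzable frequency band
#'
#' `(Hf - Lf) / (fs/2 - fs/NS)`: the active interval's width as a fraction
#' of the widest interval the bin grid can express, used for threshold
#' sensitivity sweeps. A degenerate interval returns 0.
#'
#' @inheritParams active_frequency_interval
#' @return a fraction in \[0, 1\].
#' @export
interval_reduction <- function(fseq, ftT = 0.1) {
  iv <- active_frequency_interval(fseq, ftT)
  if (iv$degenerate) return(0)
  (iv$Hf - iv$Lf) / (fseq$fs / 2 - fseq$fs / fseq$NS)
}

#' Scalar features of one vocalization
#'
#' Duration `d` (seconds), active-frame rate `R`, and active-frequency
#' interval `[Lf, Hf]` for a preprocessed clip, as one tibble row.
#'
#' @param clip an [audio_clip()] at the pipeline rate.
#' @param frame_duration_ms framing used for the spectral features.
#' @param ET energy-threshold fraction for `R`.
#' @param ftT spectral-threshold fraction for `Lf`/`Hf`.
#' @return a one-row tibble: `source_id`, `species`, `d`, `R`, `Lf`, `Hf`.
#' @export
scalar_features <- function(clip, frame_duration_ms = 40, ET = 0.005, ftT = 0.1) {
  stopifnot(inherits(clip, "audio_clip"))
  fseq <- frame_signal(clip, frame_duration_ms)
  if (fseq$Ns_i == 0) stopf("Clip %s is shorter than one frame", clip$source_id)
  rate <- active_frame_rate(frame_stft_energies(fseq), ET)
  iv <- active_frequency_interval(fseq, ftT)
  tibble(source_id = clip$source_id, species = clip$label,
         d = length(clip$samples) / clip$fs, R = rate$R, Lf = iv$Lf, Hf = iv$Hf)
}
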