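#' Construct an audio clip
#'
#' The unit every preprocessing step transforms: a mono sampled signal with
#' its sampling frequency, plus an optional species label and a recording
#' identifier used to track provenance through feature tables.
#'
#' @param samples numeric vector of amplitudes, nominally in \[-1, 1\].
#' @param fs sampling frequency in Hz (> 0).
#' @param label optional species label.
#' @param source_id recording identifier.
#' @return an object of class `audio_clip`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * seq(0, 1, by = 1 / 11025)), 11025)
#' clip
#' @export
audio_clip <- function(samples, fs, label = NA_character_, source_id = "clip") {
  if (!is.numeric(samples) || length(samples) == 0) {
    stopf("`samples` must be a non-empty numeric vector")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stopf("`fs` must be a positive scalar")
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         label = as.character(label), source_id = as.character(source_id)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %d samples @ %g Hz (%.3f s)%s\n",
              x$source_id, length(x$samples), x$fs, length(x$samples) / x$fs,
              if (is.na(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

#' Load a WAV recording as a mono audio clip
#'
#' Reads PCM (8/16/24/32-bit) and IEEE-float WAV files. Multi-channel
#' recordings are averaged to mono; samples are scaled to \[-1, 1\].
#'
#' @param path path to a WAV file.
#' @param label optional species label attached to the clip.
#' @return an [audio_clip()].
#' @export
load_audio <- function(path, label = NA_character_) {
  w <- read_wav(path)
  audio_clip(w$samples, w$fs, label = label,
             source_id = tools::file_path_sans_ext(basename(path)))
}

#' Resample a clip to a target sampling frequency
#'
#' Band-limited (anti-aliased) resampling in the frequency domain. The
#' pipeline default brings every recording to 11,025 Hz so filterbank design
#' and frame geometry are identical across inputs. A clip already at the
#' target rate is returned unchanged.
#'
#' @param clip an [audio_clip()].
#' @param target_fs target sampling frequency in Hz.
#' @return an [audio_clip()] at `target_fs` whose length is
#'   `round(length * target_fs / fs)` within one sample.
#' @export
resample_clip <- function(clip, target_fs = 11025) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(target_fs) || length(target_fs) != 1 || target_fs <= 0) {
    stopf("`target_fs` must be a positive scalar frequency")
  }
  if (clip$fs == target_fs) return(clip)
  n_out <- max(1L, as.integer(round(length(clip$samples) * target_fs / clip$fs)))
  clip$samples <- fft_resample(clip$samples, n_out)
  clip$fs <- target_fs
  clip
}

#' High-pass filter a clip at 20 Hz
#'
#' Removes DC, microphone rumble and handling noise below 20 Hz with a
#' 4th-order Butterworth high-pass applied forward and backward (zero phase).
#' Output length equals input length.
#'
#' @param clip an [audio_clip()] (any rate; designed for the 11,025 Hz
#'   pipeline rate).
#' @param cutoff_hz high-pass cutoff, default 20 Hz.
#' @param order Butterworth order for each pass, default 4.
#' @return the filtered [audio_clip()].
#' @export
highpass_clip <- function(clip, cutoff_hz = 20, order = 4) {
  stopifnot(inherits(clip, "audio_clip"))
  ba <- butter_highpass(order, cutoff_hz, clip$fs)
  clip$samples <- filtfilt(ba$b, ba$a, clip$samples,
                           padlen = ceiling(3 * clip$fs / cutoff_hz))
  clip
}

#' Preprocess a clip to the pipeline's uniform representation
#'
#' Convenience wrapper: resample to `target_fs` then high-pass at 20 Hz.
#'
#' @inheritParams resample_clip
#' @param cutoff_hz high-pass cutoff in Hz.
#' @return an [audio_clip()] at `target_fs`, high-passed.
#' @export
preprocess_clip <- function(clip, target_fs = 11025, cutoff_hz = 20) {
  highpass_clip(resample_clip(clip, target_fs), cutoff_hz)
}

#' Cut a clip into fixed-length frames with 50% overlap
#'
#' Frames of `frame_duration_ms` milliseconds are taken every `floor(NS/2)`
#' samples (50% overlap); a trailing partial frame is discarded. A clip
#' shorter than one frame yields an empty frame sequence (`Ns_i = 0`) rather
#' than an error.
#'
#' @param clip an [audio_clip()].
#' @param frame_duration_ms frame duration in milliseconds (10–200).
#' @return a `frame_seq`: list with `frames` (an `NS x Ns_i` matrix, one
#'   column per frame), `NS`, `hop`, `Ns_i`, `frame_duration_ms`, `fs`,
#'   `source_id`.
#' @export
frame_signal <- function(clip, frame_duration_ms = 40) {
  stopifnot(inherits(clip, "audio_clip"))
  if (frame_duration_ms < 10 || frame_duration_ms > 200) {
    stopf("`frame_duration_ms` must lie in [10, 200], got %g", frame_duration_ms)
  }
  ns <- as.integer(round(clip$fs * frame_duration_ms / 1000))
  hop <- ns %/% 2L
  n <- length(clip$samples)
  n_frames <- if (n >= ns) (n - ns) %/% hop + 1L else 0L
  frames <- if (n_frames > 0) {
    starts <- (seq_len(n_frames) - 1L) * hop
    vapply(starts, function(s) clip$samples[(s + 1L):(s + ns)], numeric(ns))
  } else {
    matrix(numeric(0), nrow = ns, ncol = 0)
  }
  structure(
    list(frames = matrix(frames, nrow = ns), NS = ns, hop = hop,
         Ns_i = n_frames, frame_duration_ms = frame_duration_ms,
         fs = clip$fs, source_id = clip$source_id),
    class = "frame_seq"
  )
}

#' @export
print.frame_seq <- function(x, ...) {
  cat(sprintf("<frame_seq> %s: %d frames of %d samples (%g ms, hop %d) @ %g Hz\n",
              x$source_id, x$Ns_i, x$NS, x$frame_duration_ms, x$hop, x$fs))
  invisible(x)
}

# Time-domain frame energies (sum of squared samples per frame).
frame_time_energies <- function(fseq) {
  if (fseq$Ns_i == 0) return(numeric(0))
  colSums(fseq$frames ^ 2)
}

#' Remove silent frames by energy threshold
#'
#' Keeps exactly the frames whose energy strictly exceeds
#' `TE = mE + ET * (ME - mE)`, where `mE`/`ME` are the minimum and maximum
#' frame energies of this recording. With all-equal energies no frame
#' strictly exceeds the threshold and everything is removed (flagged with a
#' warning, not an error).
#'
#' @param fseq a `frame_seq` from [frame_signal()].
#' @param ET energy-threshold fraction in \[0, 1\] interpolating between the
#'   recording's min and max frame energy (default 0.005).
#' @return the filtered `frame_seq`, with attributes `kept_fraction` (kept /
#'   original frames) and `thresholds` (named vector `mE`, `ME`, `TE`).
#' @export
remove_silent_frames <- function(fseq, ET = 0.005) {
  stopifnot(inherits(fseq, "frame_seq"))
  if (fseq$Ns_i < 1) stopf("Cannot remove silence from an empty frame sequence")
  e <- frame_time_energies(fseq)
  thr <- activity_threshold(e, ET)
  keep <- e > thr[["TE"]]
  if (!any(keep)) {
    rlang::warn(sprintf("All %d frames fall at or below the energy threshold; none kept (%s)",
                        fseq$Ns_i, fseq$source_id))
  }
  out <- fseq
  out$frames <- fseq$frames[, keep, drop = FALSE]
  out$Ns_i <- sum(keep)
  attr(out, "kept_fraction") <- mean(keep)
  attr(out, "thresholds") <- thr
  out
}

# TE = mE + ET * (ME - mE); shared by silence removal and the active-frame
# rate feature.
activity_threshold <- function(values, fraction) {
  m <- min(values)
  M <- max(values)
  c(mE = m, ME = M, TE = m + fraction * (M - m))
}
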