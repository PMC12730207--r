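# Feature-vector formation: the four modes combining granularity
# (vocalization vs frame) with the cochlear coefficient stage (raw filter
# energies vs log-DCT coefficients).
#
#   P1: one vector per vocalization, raw energies     [d, R, Lf, Hf, AVGC, STDGC]
#   P2: one vector per retained frame, raw energies   [S, delta]
#   P3: one vector per vocalization, log-DCT          [d, R, Lf, Hf, AVGC, STDGC]
#   P4: one vector per retained frame, log-DCT        [GC, delta]

#' Feature extraction parameters
#'
#' Bundle of the tunable parameters shared across the pipeline, with the
#' reference defaults: `N = 30` filters, `ET = 0.005`, `ftT = 0.1`,
#' 40 ms frames.
#'
#' @param N number of filters.
#' @param ET energy-threshold fraction (silence removal / active-frame rate).
#' @param ftT spectral-threshold fraction (active-frequency interval).
#' @param frame_duration_ms frame duration in milliseconds.
#' @param fmin,fmax filterbank frequency interval (Hz); `fmax = NULL` means
#'   Nyquist.
#' @param include_delta concatenate delta vectors into frame vectors and
#'   aggregates.
#' @param filterbank `"gammatone"` (cochlear model) or `"triangular"`
#'   (mel-spaced baseline).
#' @return a named list of class `feature_params`.
#' @export
feature_params <- function(N = 30, ET = 0.005, ftT = 0.1, frame_duration_ms = 40,
                           fmin = 50, fmax = NULL, include_delta = TRUE,
                           filterbank = c("gammatone", "triangular")) {
  structure(
    list(N = N, ET = ET, ftT = ftT, frame_duration_ms = frame_duration_ms,
         fmin = fmin, fmax = fmax, include_delta = include_delta,
         filterbank = match.arg(filterbank)),
    class = "feature_params"
  )
}

make_bank <- function(params, fs) {
  fmax <- if (is.null(params$fmax)) fs / 2 else params$fmax
  if (params$filterbank == "triangular") {
    triangular_bank(params$N, fs, params$fmin, fmax)
  } else {
    gammatone_bank(params$N, fs, params$fmin, fmax)
  }
}

#' Build feature vectors for one recording
#'
#' Assembles one of the four feature formations for a preprocessed clip.
#' Vocalization modes (P1/P3) aggregate over all frames and prepend the
#' scalar features, yielding one vector of length `4 + 4N`. Frame modes
#' (P2/P4) apply energy-based silence removal first and yield one vector of
#' length `2N` per retained frame. P1/P2 use raw filter output energies;
#' P3/P4 apply the log10 + DCT stage.
#'
#' @param clip an [audio_clip()] at the pipeline rate (see
#'   [preprocess_clip()]).
#' @param mode `"P1"`, `"P2"`, `"P3"` or `"P4"`.
#' @param params a [feature_params()].
#' @param bank optional pre-built filterbank (rebuilt from `params`
#'   otherwise; pass one when extracting many recordings).
#' @return a tibble with columns `source_id`, `species`, `mode`,
#'   `frame_index` (`NA` for vocalization modes) and feature columns
#'   `v001`, `v002`, ... A clip shorter than one frame yields zero rows.
#' @export
build_vectors <- function(clip, mode = c("P4", "P1", "P2", "P3"),
                          params = feature_params(), bank = NULL) {
  stopifnot(inherits(clip, "audio_clip"))
  mode <- match.arg(mode)
  if (is.null(bank)) bank <- make_bank(params, clip$fs)
  fseq <- frame_signal(clip, params$frame_duration_ms)
  if (fseq$Ns_i == 0) {
    rlang::warn(sprintf("Clip %s shorter than one %g ms frame; no features",
                        clip$source_id, params$frame_duration_ms))
    return(feature_tibble(matrix(numeric(0), nrow = 0, ncol = 0), clip, mode, integer(0)))
  }
  use_log_dct <- mode %in% c("P3", "P4")

  if (mode %in% c("P2", "P4")) {
    kept <- remove_silent_frames(fseq, params$ET)
    if (kept$Ns_i == 0) {
      return(feature_tibble(matrix(numeric(0), nrow = 0, ncol = 2 * params$N),
                            clip, mode, integer(0)))
    }
    feats <- cochlear_features(kept, bank, use_log_dct = use_log_dct)
    v <- if (params$include_delta) rbind(feats$GC, feats$delta) else feats$GC
    feature_tibble(t(v), clip, mode, seq_len(kept$Ns_i))
  } else {
    feats <- cochlear_features(fseq, bank, use_log_dct = use_log_dct)
    agg <- aggregate_vocalization(feats$GC, feats$delta,
                                  include_delta = params$include_delta)
    rate <- active_frame_rate(frame_stft_energies(fseq), params$ET)
    iv <- active_frequency_interval(fseq, params$ftT)
    v <- c(length(clip$samples) / clip$fs, rate$R, iv$Lf, iv$Hf, agg$AVGC, agg$STDGC)
    feature_tibble(matrix(v, nrow = 1), clip, mode, NA_integer_)
  }
}

feature_tibble <- function(mat, clip, mode, frame_index) {
  p <- ncol(mat)
  colnames(mat) <- if (p > 0) sprintf("v%03d", seq_len(p)) else character(0)
  out <- as_tibble(mat)
  tibble(source_id = clip$source_id, species = clip$label, mode = mode,
         frame_index = frame_index)[seq_len(nrow(mat)), ] |>
    dplyr::bind_cols(out)
}

#' Build a feature table for a whole dataset
#'
#' Maps [build_vectors()] over the clips of a dataset tibble (one list-column
#' `clip` of [audio_clip()]s, as produced by [generate_dataset()] or
#' [load_audio_dir()]), reusing one filterbank.
#'
#' @param dataset tibble with a `clip` list-column.
#' @param mode feature formation mode, see [build_vectors()].
#' @param params a [feature_params()].
#' @return a tibble of feature vectors (see [build_vectors()]).
#' @export
build_feature_table <- function(dataset, mode = "P4", params = feature_params()) {
  stopifnot(is.data.frame(dataset), "clip" %in% names(dataset))
  fs <- dataset$clip[[1]]$fs
  bank <- make_bank(params, fs)
  purrr::map_dfr(dataset$clip, build_vectors, mode = mode, params = params, bank = bank)
}

# Numeric feature matrix + labels from a feature tibble.
feature_matrix <- function(features) {
  vcols <- grep("^v[0-9]+$", names(features), value = TRUE)
  x <- as.matrix(features[, vcols, drop = FALSE])
  if (any(!is.finite(x))) stopf("Feature table contains non-finite values")
  list(x = x, y = features$species, source_id = features$source_id)
}

#' Load a directory of labeled WAV recordings
#'
#' The real-data path: reads `dir/<species>/<recording>.wav` (or a flat
#' directory with labels taken from file-name prefixes before the first
#' underscore) and preprocesses every clip to the pipeline rate.
#'
#' @param dir directory containing WAV files.
#' @param target_fs pipeline sampling rate.
#' @return a tibble with columns `species`, `source_id` and list-column
#'   `clip`.
#' @export
load_audio_dir <- function(dir, target_fs = 11025) {
  if (!dir.exists(dir)) stopf("Directory does not exist: %s", dir)
  subdirs <- list.dirs(dir, recursive = FALSE)
  files <- if (length(subdirs) > 0) {
    purrr::map_dfr(subdirs, function(d) {
      tibble(species = basename(d),
             path = list.files(d, pattern = "\\.wav$", ignore.case = TRUE, full.names = TRUE))
    })
  } else {
    paths <- list.files(dir, pattern = "\\.wav$", ignore.case = TRUE, full.names = TRUE)
    tibble(species = sub("_.*$", "", tools::file_path_sans_ext(basename(paths))),
           path = paths)
  }
  if (nrow(files) == 0) stopf("No WAV files found under %s", dir)
  files |>
    dplyr::mutate(
      clip = purrr::map2(.data$path, .data$species,
                         ~ preprocess_clip(load_audio(.x, label = .y), target_fs)),
      source_id = purrr::map_chr(.data$clip, "source_id")
    ) |>
    dplyr::select("species", "source_id", "clip")
}
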