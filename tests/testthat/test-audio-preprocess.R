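# Audio loading, resampling, high-pass filtering, framing, silence removal.

test_that("WAV round trip preserves mono audio and scaling", {
  clip <- tone_clip(440, dur = 0.2)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, path)
  loaded <- load_audio(path)
  expect_equal(loaded$fs, 11025)
  expect_equal(length(loaded$samples), length(clip$samples))
  expect_lt(max(abs(loaded$samples - clip$samples)), 1e-3) # 16-bit quantization
  expect_true(all(abs(loaded$samples) <= 1))
})

test_that("stereo WAV input is averaged to mono with length preserved", {
  # hand-written stereo file: left = tone, right = -tone
  fs <- 8000
  n <- 800
  left <- as.integer(round(sin(2 * pi * 100 * (0:(n - 1)) / fs) * 16000))
  right <- -left
  inter <- as.integer(rbind(left, right))
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n * 4), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little"); writeBin(2L, con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * 4), con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little"); writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n * 4L, con, 4, endian = "little")
  writeBin(inter, con, 2, endian = "little")
  close(con)
  clip <- load_audio(path)
  expect_equal(length(clip$samples), n)
  expect_equal(clip$fs, fs)
  expect_lt(max(abs(clip$samples)), 1e-4) # channels cancel
})

test_that("empty or missing files raise input errors naming the path", {
  expect_error(load_audio("/nonexistent/file.wav"), "file.wav")
  path <- withr::local_tempfile(fileext = ".wav")
  writeLines("", path)
  expect_error(load_audio(path), "wav", ignore.case = TRUE)
})

test_that("2:1 resampling halves the length and identity is bit-exact", {
  clip <- audio_clip(rnorm(22050), 22050)
  out <- resample_clip(clip, 11025)
  expect_equal(out$fs, 11025)
  expect_lte(abs(length(out$samples) - 11025), 1)
  same <- audio_clip(rnorm(500), 11025)
  expect_identical(resample_clip(same, 11025), same)
  expect_error(resample_clip(same, -1), "positive")
})

test_that("resampling preserves pure tone frequencies below 0.45 * target_fs", {
  # FFT-peak oracle on the resampled signal
  for (f in c(250, 1000, 3100, 4900)) {
    clip <- audio_clip(sin(2 * pi * f * (0:44099) / 44100), 44100)
    out <- resample_clip(clip, 11025)
    bin_hz <- out$fs / length(out$samples)
    expect_lt(abs(fft_peak_hz(out$samples, out$fs) - f), bin_hz + 1e-9,
              label = sprintf("tone %g Hz", f))
  }
})

test_that("resampling arbitrary ratios gives round(n * ratio) samples", {
  clip <- audio_clip(rnorm(48000), 48000)
  out <- resample_clip(clip, 11025)
  expect_lte(abs(length(out$samples) - round(48000 * 11025 / 48000)), 1)
})

test_that("20 Hz high-pass rejects DC and low tones, passes the audio band", {
  dc <- highpass_clip(audio_clip(rep(1, 11025), 11025))
  expect_lt(sqrt(mean(dc$samples ^ 2)), 1e-3)

  s5 <- tone_clip(5, dur = 2)
  out5 <- highpass_clip(s5)
  expect_lte(sqrt(mean(out5$samples ^ 2)), 0.1 * sqrt(mean(s5$samples ^ 2)))
  # designed magnitude response agrees with the measured RMS ratio
  ba <- cochleaR:::butter_highpass(4, 20, 11025)
  h5 <- cochleaR:::iir_response(ba$b, ba$a, 5, 11025) ^ 2 # two passes
  measured <- sqrt(mean(out5$samples ^ 2)) / sqrt(mean(s5$samples ^ 2))
  expect_lt(abs(measured - h5), 0.01)

  s1k <- tone_clip(1000, dur = 1)
  out1k <- highpass_clip(s1k)
  expect_lt(abs(sqrt(mean(out1k$samples ^ 2)) / sqrt(mean(s1k$samples ^ 2)) - 1), 0.1)
  expect_equal(length(out1k$samples), length(s1k$samples))
  # gain at 100 Hz within +-1 dB of unity (two passes)
  h100_db <- 20 * log10(cochleaR:::iir_response(ba$b, ba$a, 100, 11025) ^ 2)
  expect_lt(abs(h100_db), 1)
})

test_that("framing follows NS = round(fs * ms / 1000), hop = floor(NS/2)", {
  clip <- audio_clip(rnorm(11025), 11025)
  fseq <- frame_signal(clip, 40)
  expect_equal(fseq$NS, 441L)
  expect_equal(fseq$hop, 220L)
  expect_equal(fseq$Ns_i, 49L)
  expect_equal(dim(fseq$frames), c(441L, 49L))
  # boundary: exactly one frame
  one <- frame_signal(audio_clip(rnorm(441), 11025), 40)
  expect_equal(one$Ns_i, 1L)
  # shorter than one frame: empty, not an error
  short <- frame_signal(audio_clip(rnorm(100), 11025), 40)
  expect_equal(short$Ns_i, 0L)
  # shorter frames give more frames
  expect_gt(frame_signal(clip, 20)$Ns_i, fseq$Ns_i)
  expect_error(frame_signal(clip, 5), "frame_duration_ms")
})

test_that("frame counts match a brute-force sliding-window oracle", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(200:30000, 1)
    ms <- sample(10:200, 1)
    clip <- audio_clip(rnorm(n), 11025)
    fseq <- frame_signal(clip, ms)
    ns <- round(11025 * ms / 1000)
    hop <- ns %/% 2
    count <- 0L
    start <- 1L
    while (start + ns - 1L <= n) {
      count <- count + 1L
      start <- start + hop
    }
    expect_equal(fseq$Ns_i, count, label = sprintf("n=%d ms=%d", n, ms))
    if (count > 0) {
      expect_equal(fseq$frames[, count], clip$samples[(count - 1) * hop + 1:ns])
    }
  }
})

test_that("silence removal keeps frames strictly above the min-max threshold", {
  # energies [1,2,3,4] at ET = 0.5 -> TE = 2.5, keep frames 3 and 4
  fs <- 100
  frames <- sapply(sqrt(1:4), function(a) rep(a / sqrt(10), 10)) # energies 1,2,3,4
  fseq <- structure(list(frames = frames, NS = 10L, hop = 5L, Ns_i = 4L,
                         frame_duration_ms = 100, fs = fs, source_id = "x"),
                    class = "frame_seq")
  kept <- remove_silent_frames(fseq, 0.5)
  expect_equal(kept$Ns_i, 2L)
  expect_equal(attr(kept, "kept_fraction"), 0.5)
  expect_equal(kept$frames, frames[, 3:4])

  # ET = 1: nothing strictly exceeds the max
  none <- suppressWarnings(remove_silent_frames(fseq, 1))
  expect_equal(none$Ns_i, 0L)
  expect_warning(remove_silent_frames(fseq, 1), "none kept")
  # ET = 0: everything above the minimum survives
  all_above <- remove_silent_frames(fseq, 0)
  expect_equal(all_above$Ns_i, 3L)
  # all-equal energies: all frames removed under strict inequality
  flat <- fseq
  flat$frames <- matrix(0.3, 10, 4)
  expect_warning(out <- remove_silent_frames(flat, 0.5), "none kept")
  expect_equal(out$Ns_i, 0L)
})

test_that("silence removal is idempotent and kept fraction non-increasing in ET", {
  set.seed(7)
  clip <- generate_vocalization(default_profiles()[[5]], seed = 31)
  fseq <- frame_signal(clip, 40)
  kept1 <- remove_silent_frames(fseq, 0.005)
  # idempotence at the original thresholds: all survivors exceed original TE
  thr <- attr(kept1, "thresholds")
  expect_true(all(colSums(kept1$frames ^ 2) > thr[["TE"]]))
  fractions <- sapply(c(0, 0.001, 0.01, 0.1, 0.5, 0.9),
                      function(et) attr(remove_silent_frames(fseq, et), "kept_fraction"))
  expect_true(all(diff(fractions) <= 1e-12))
})
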