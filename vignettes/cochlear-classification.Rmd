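---
title: "Cochlear-inspired features for vocalization classification: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cochlear-inspired features for vocalization classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cochleaR)
```

## The problem and the approach

Animal vocalizations carry species identity in their spectral content, their
temporal activity pattern, and their duration. `cochleaR` classifies
recordings by combining a biomimetic spectral front end — a gammatone
filterbank whose filters are spaced like the auditory filters of the human
cochlea — with a handful of interpretable scalar features and a small
feed-forward network. This vignette documents the model, its tunable
parameters, the numerical conventions, and the design decisions taken where
the problem statement was genuinely open.

## Preprocessing

Every clip is brought to a uniform representation before feature
extraction:

1. **Resampling to 11,025 Hz.** All filterbank geometry and frame sizes
   assume this rate; it keeps the full band of most terrestrial
   vocalizations while bounding compute. Resampling is band-limited
   (anti-aliased) and performed in the frequency domain: the spectrum is
   truncated or zero-padded to the target length. A classical polyphase FIR
   resampler would satisfy the same contract; the FFT method was chosen
   because it is compact, exactly length-controlled
   (`n_out = round(n · target/fs)`), and this package has no DSP dependency
   to lean on. Tone frequencies below 0.45 × target rate are preserved to
   within one FFT bin (tested).
2. **20 Hz high-pass.** A 4th-order Butterworth high-pass applied forward
   and backward (zero phase) removes DC, rumble and handling noise.
   Forward–backward filtering squares the magnitude response, so the
   effective attenuation at 5 Hz is far beyond the 20 dB contract while the
   gain at 100 Hz stays within 1 dB of unity. The reflection padding used at
   the clip edges is sized as `3 · fs / cutoff` samples — the filter's
   transient at a 20 Hz cutoff lasts hundreds of samples, and shorter
   padding leaves a low-frequency edge artifact that visibly contaminates
   the active-frequency interval of the final frames (this was observed and
   is pinned by a test).
3. **Framing.** Frames of `frame_duration_ms` (default 40 ms) with 50%
   overlap: `NS = round(fs · ms / 1000)`, `hop = floor(NS/2)`; a trailing
   partial frame is discarded, and a clip shorter than one frame yields an
   empty frame sequence rather than an error. No window taper is applied
   anywhere — the features are defined on plain (rectangular) frames, which
   keeps the Parseval relation between time- and frequency-domain energies
   exact and is pinned by the oracle tests.

## Scalar features

For a vocalization with frames `n = 1 … Ns`, spectral energies
`E(n) = Σ_{j=1}^{NS/2} |FT_n(j)|²` are computed over the one-sided DFT
excluding the DC bin (the high-pass has already removed DC; the bin index
range starts at 1). Thresholds interpolate between the recording's own
extremes:

* `TE = mE + ET·(ME − mE)` — frames with `E > TE` (strict) are *active*;
  the rate `R = HE/Ns` is a feature, and the same rule (computed on
  time-domain energies, which Parseval makes proportional) drives silence
  removal before frame-based training.
* `Tft = mft + ftT·(Mft − mft)` over all frames' magnitude spectra — a bin
  is active if it strictly exceeds `Tft` in *any* frame; `Lf`/`Hf` are the
  lowest/highest active-bin frequencies `j·fs/NS`.

Conventions worth noting: all comparisons are strict (so all-equal energies
mean *no* active frame at any threshold — the rate is 0, and silence removal
removes everything, flagged with a warning); thresholds are per-recording,
not global, matching the per-recording indexing of the min/max quantities;
an empty active-bin set (e.g. `ftT = 1`) degenerates to `Lf = Hf =` the
global-maximum bin and is flagged. Whether the thresholding spectra reuse
the 50%-overlap framing is ambiguous in the original description (it says so
itself); this package reuses the one framing pipeline everywhere, so every
spectral quantity comes from the same frames.

## Cochlear features

The gammatone bank has `N` filters (default 30) whose center frequencies
are the `N` points equally spaced on the ERB-rate scale
`21.4·log10(1 + 0.00437 f)` between `fmin` (default 50 Hz) and `fmax`
(default Nyquist), endpoints inclusive. Bandwidths follow Glasberg–Moore,
`ERB(f) = 24.7·(4.37 f/1000 + 1)`, scaled by the conventional 1.019 factor;
each filter is the standard all-pole digital gammatone: four second-order
sections sharing a damped-resonator pole pair, implemented in C++ and
applied to each frame independently from zero state. Filter output energies
`S[g]` (sums of squared output samples) feed the cepstral stage
`GC = DCT(log10(max(S, ε)))` with an orthonormal type-II DCT and
`ε = 1e-12`, so silent frames produce finite features. Delta vectors are
first differences with a zero vector for the first frame (keeping the frame
count constant), and per-vocalization aggregates are the elementwise mean
and *population* standard deviation (divide by the frame count — determinate
for small counts) of the concatenated `[GC, Δ]` vectors, giving `AVGC` and
`STDGC` of length `2N`.

The four feature formations combine two axes: granularity (one vector per
vocalization with the scalar block prepended, `4 + 4N` long, vs one `2N`
vector per frame) and coefficient stage (raw energies vs log-DCT). The raw
modes are literally the log-DCT modes with the cepstral stage replaced by
the identity, and the implementation shares that code path — the equality is
bit-for-bit, and tested as such. Per-frame vectors include the delta block
(the delta is attached to every vector before any aggregation is even
mentioned, so frame modes carry it too); a flag disables this for
experiments. Silence removal applies only to frame-granularity modes;
vocalization aggregates use all frames.

The mel-spaced triangular bank (same `N`, same frequency interval, centers
equispaced on `2595·log10(1 + f/700)`, each triangle spanning its two
neighbors over the one-sided FFT magnitudes) provides the conventional
baseline for head-to-head comparisons.

## The classifier

A feed-forward network with hidden layers of 50 and 25 ReLU cells and a
softmax output minimizes cross-entropy — the standard companion of a softmax
layer. The solver is a quasi-Newton method: `optim`'s limited-memory BFGS
(`L-BFGS-B`), run in chunks with the stopping rules checked between chunks:
training stops at 1000 iterations, or as soon as the loss *or* the
infinity-norm of its gradient falls below 1e-6. Weight initialization is
He-style from a seeded generator; with a fixed seed, retraining reproduces
identical weights (tested bit-exact).

Features are z-scored with statistics fitted on the training set only.
Whether the original system standardized its inputs is unknown; here the
scalar features live on scales of hertz and seconds next to cepstral
coefficients of order one, and quasi-Newton training is scale-sensitive, so
standardization is the default with a switch (`standardize = FALSE`) for
fidelity experiments. Before frame-based training, classes are balanced by
subsampling every class to the smallest per-class frame count (seeded,
deterministic). Prediction ties at the softmax argmax break toward the
lowest class index for determinism.

## Decisions and evaluation

Frame decisions are fused three ways: majority voting over consecutive,
non-overlapping groups of `m` frames within a recording (the last partial
group votes as-is), the per-recording mode of all frame decisions, and the
dual-network rule — two networks trained on different frame durations
(defaults 20 ms and 80 ms, the two strongest single durations) each produce
a per-recording decision, the test is accepted only if they agree, and
recognition rates are computed over accepted tests. Voting ties break to
the earliest-appearing tied label, a deterministic, order-respecting rule.

The evaluation protocol is five repeated stratified 90/10 splits (per class:
shuffle, first 45 recordings train, next 5 test, by default), not disjoint
folds — repeated random splits keep the training set large on small
corpora. Metrics are the confusion matrix, accuracy, and macro-averaged
(equal class weight) precision, recall and `F1 = 2PR/(P+R)`, with empty
prediction columns scored as precision 0 and `P + R = 0` as `F1 = 0`. Test
frames are *not* balanced — only training is — so per-class test counts are
unequal, as they are in practice.

## The synthetic generator

Real vocalization corpora cannot be bundled, so the package generates
labeled synthetic vocalizations with exactly the structure the features
exploit: species-specific frequency bands (harmonic stacks with a
fundamental drawn per syllable, harmonics clipped to the band, geometrically
decaying amplitudes), species-dependent syllable/gap durations (activity
patterns), slow amplitude modulation, additive white noise at a configurable
SNR (default 25 dB), and truncated-normal vocalization durations. The 13
presets grade band overlap from well-separated (e.g. elephant vs dolphin)
to heavily overlapping (cat/dog/horse), so classification is good but not
trivially perfect, and their duration statistics follow published
field-recording spreads (means 1.45–4.55 s with large dispersions). Two
presets' published maxima are extreme outliers (one species reaches 54 s);
maxima are capped at 8 s to bound runtime, while means and SDs are kept.

What the generator does *not* emulate: environmental/colored noise,
reverberation, overlapping callers, within-species repertoire diversity
(different call types), or frequency modulation within syllables. A green
end-to-end test therefore establishes that the pipeline's machinery is
correct and that its decision rules behave as designed (voting helps,
vocalization-level beats frame-level, dual agreement beats single networks)
— not that any particular accuracy transfers to field recordings.

## Numerical choices and degenerate inputs

* `log10(0)` guarded by flooring energies at 1e-12.
* Strict `>` in every threshold comparison; all-equal inputs yield empty
  active sets, handled with warnings/flags rather than errors.
* Resampling identity (already at target rate) returns the input bit-exact.
* Multi-channel WAV input is averaged to mono; PCM 8/16/24/32-bit and
  float32 dialects are read, 16-bit PCM written.
* Single-frame aggregation yields a zero SD with a warning; clips shorter
  than one frame yield empty feature tables, flagged not raised.
* Seeds: every stochastic step (dataset generation, shuffles, balancing,
  weight init) derives child seeds below 2^31 from one master seed, and
  the caller's RNG state is always restored.

## Scaled-down defaults in the test suite

The full reference protocol (13 species × 50 clips, five 45/5 repeats,
1000-iteration training) costs tens of CPU-minutes. The package's
protocol-level tests run the same pipeline shape at reduced scale (13
species × 16 clips, 12/4 splits, capped solver iterations) and assert
directions and structure rather than absolute rates; the unit and oracle
tests cover the exact formulas at full precision.

## Known limitations

* The gammatone realization is the standard all-pole approximation; no
  level-dependent/nonlinear cochlear behavior is modeled.
* Frame-independent filtering (zero state per frame) means a filter's ring
  from one frame does not carry into the next; with 50% overlap the loss is
  small but it is a convention, pinned by tests, not a physical claim.
* No automatic segmentation of continuous field recordings into
  vocalizations: one file is one vocalization.
* The L-BFGS iteration count between stopping-rule checks is reported from
  the solver's gradient-evaluation count and is exact up to the chunk
  granularity.
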