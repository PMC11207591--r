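---
title: "Grip-force estimation from wireless sEMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grip-force estimation from wireless sEMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semgrip)
```

`semgrip` turns packetized wireless surface-EMG (sEMG) streams into
grip-force estimates in %MVC (percent of maximum voluntary contraction).
This vignette is the package's account of the science: the signal chain, the
model, the tunable parameters and their defaults, the numerical choices, and
what the synthetic-data tests do and do not demonstrate.

## The acquisition chain and its codec

Each wireless terminal digitizes one muscle channel at 1000 Hz with a 12-bit
ADC (4096 levels, 3.3 V reference).  The analog front end sits the
alternating µV-level sEMG on a 1.65 V (VCC/2) baseline after a two-stage
amplification of 45× × 25× = 1125×.  Data leave the terminal as fixed
116-byte frames — packet header (2 B), frame header (4 B), MAC address
(6 B), 50 two-byte samples (100 B), end-of-data flag (2 B), packet end
(2 B) — one frame every 50 ms, i.e. 20 packets/s × 50 samples = 1000 Hz.

The field sizes are fixed by that layout; the magic byte values, the sample
endianness and the frame-header semantics are not published, so the codec
pins configurable defaults (header `AA 55`, end flag `FF FF`, trailer
`0D 0A`, little-endian samples, the 4-byte frame header read as an unsigned
little-endian frame counter).  Any concrete firmware convention can be
expressed through `protocol_config()`; the round-trip and layout tests hold
for all of them.

Reconstruction (`reconstruct_streams()`) groups packets by MAC (one terminal
= one channel), orders by frame sequence, keeps the first copy of a
duplicated frame, and *reports* missing frame runs rather than filling them:
downstream segmentation is manual, and silently interpolated samples would
corrupt features.  Codes map to volts as `code/4095 × 3.3 − 1.65`; the
divisor 4095 (not 4096) makes full scale hit the reference voltage exactly.

## Preprocessing

Stages, in order, per channel (`preprocess_session()`):

1. **Segmentation** — half-open `[start, end)` slices at 0-based sample
   indices from manual annotations; contractions last ≥ 2 s in the intended
   protocol, so every segment comfortably exceeds the filter warm-up.
2. **Band-pass filtering** — Butterworth band-pass, prototype order 4,
   20–490 Hz at 1000 Hz sampling (the fundamental sEMG band), applied
   forward and backward.  The zero-phase realization uses odd-reflection
   padding of `3 × max(len(a), len(b))` samples and starts each pass in
   steady state for the edge level, so a constant baseline offset produces
   no start-up transient; the effective gain is the squared magnitude
   response, which `filter_gain_squared()` exposes as the analytic oracle
   the tests check against.
3. **Full-wave rectification** — elementwise absolute value.
4. **MVC normalization** — `x / sEMG_MVC × 100`, where `sEMG_MVC` is the
   maximum of the *rectified, filtered* MVC trial of the same subject and
   channel.  The reference stage is chosen so the normalized trial attains
   exactly 100% and the ratio is non-negative; no smoothing is applied
   before taking the peak.

Both the rectified-normalized and the filtered-unrectified version of every
segment are retained: rectification folds the spectrum, so spectral features
must read the unrectified signal while amplitude features read the
normalized one.

## Window features

Windows of 256 ms step by 56 ms (`floor((L − W)/S) + 1` windows per segment;
trailing partial windows are dropped).  Per window and channel:

| feature | definition | source stage |
|---|---|---|
| iEMG | `(1/N) Σ x_i` | rectified-normalized |
| RMS | `sqrt((1/N) Σ x_i²)` | rectified-normalized |
| WL | `Σ_{i=1}^{N−1} |x_{i+1} − x_i|` | rectified-normalized |
| SE | `−Σ p log₂ p`, amplitude histogram | rectified-normalized |
| MF | median frequency of the PSD | filtered |
| MPF | `Σ f·PSD / Σ PSD` | filtered |

Numerical choices worth stating:

- The iEMG definition keeps its 1/N factor, making it a mean absolute
  value; the upper index of WL runs to N−1 (an index of N would reach past
  the window).
- Shannon entropy of a continuous amplitude needs a probability model; we
  use an equal-width histogram over `[min(x), max(x)]`, default 64 bins,
  `0·log 0 := 0`, base-2 logarithm.  A constant window occupies one bin and
  has zero entropy by convention.
- The PSD is a single-taper Hann periodogram (one-sided,
  `|X|²/(rate · Σw²)`, interior bins doubled).  Welch averaging is not the
  default because a 256-sample window leaves too few sub-segments for
  stable averaging; the taper is switchable (`psd_method = "boxcar"`).
- Median frequency is the smallest grid frequency at which cumulative power
  reaches half the total, linearly interpolated inside the crossing bin.
  (A literal "half the integral of the PSD" has power units, not Hz; the
  implemented definition is the standard one the name denotes.)

## The bald eagle search

BES is a population metaheuristic for bounded continuous minimization with
three phases per iteration:

- **Select space**: `P_i,new = P_best + α·r·(P_mean − P_i)`, fresh
  `r ~ U(0,1)` per eagle.
- **Search prey** (spiral): `θ = a·π·rand`, `r = θ + R·rand`,
  `(xr, yr) = (r sin θ, r cos θ)`, normalized by the population maxima of
  `|xr|`, `|yr|`; candidate
  `P_i + x_i(P_i − P_mean) + y_i(P_i − P_{i+1})`, with `P_{i+1}` the next
  eagle's current position, wrapping cyclically at the population end.
- **Swoop** (hyperbolic): `r = θ`, `(xr, yr) = (r sinh θ, r cosh θ)`,
  normalized likewise; candidate
  `rand·P_best + x′_i(P_i − c1·P_mean) + y′_i(P_i − c2·P_best)`.

Design points that the original description leaves open, decided here:

- **Acceptance**: candidates replace an eagle only when they improve its
  fitness (greedy).  This guarantees a monotone best-so-far history —
  a testable invariant — and never loses a good candidate.
- **Defaults inside the stated ranges**: α = 2 from (1.5, 2], a = 10 from
  (5, 10], R = 1.5 from (0.5, 2), c1 = c2 = 2 from [1, 2]; all exposed in
  `bes_config()`.
- **Bounds**: hard clipping, the simplest deterministic repair.
- **Randomness**: one RNG, seeded once per run; draws are phase-major then
  eagle-major, so a seed fixes the whole trajectory bit-exactly.

On the 2-D sphere benchmark with population 10 and 30 iterations the
optimizer reaches fitness far below 1e−2 for every seed we tested; on 1-D
quadratics it matches a 1e−3-step grid minimum within 1e−2 in at least
18 of 20 seeds (both are acceptance-tested).

## The grip-force model

Features are split 70/30 (row-wise, seeded; a grouped split by session is
available via `stratify_by` — the modelling protocol does not state
subject-stratification, so plain row-wise is the default).  The Random
Forest regressor is delegated to the `randomForest` package
(`n_estimators → ntree`, `min_samples_leaf → nodesize`); the package's own
contribution is the tuning loop, fitness, metrics and pipeline.

The tuning fitness fits an RF on the training set and returns
`MSE(train) + MSE(test)`.  This is implemented exactly as specified, and it
knowingly leaks test information into hyperparameter selection; a
cross-validated variant (`cv_folds > 1`) is provided, off by default, for
leakage-free tuning.  BES searches the continuous relaxation of
`n_estimators ∈ [10, 500]`, `min_samples_leaf ∈ [1, 20]` (bounds are
configurable; the protocol does not print them), rounding to integers at
evaluation (ties half up).  Because the fitness is deterministic given the
split and seed, identical integer pairs are memoised — a pure runtime
optimization that changes no result.

Evaluation uses MAE, MSE and R² (`regression_metrics()`), defined exactly as
the printed formulas and tested against an independent loop-accumulated
oracle at 1e−12.

## The synthetic-data generator

Real recordings are unavailable, so `generate_session()` emulates the study
conditions end-to-end.  The signal model is the standard stochastic sEMG
surrogate: band-limited (20–490 Hz) Gaussian noise, amplitude-modulated by
activation.  Conditions, chosen once:

- Contraction amplitude `A(level) = mvc_rms_v · (level/100)^γ` with
  γ = 1.5 — between a linear and a strongly nonlinear EMG–force relation —
  and MVC-level RMS 0.30 V, which keeps ±4σ excursions inside the ±1.65 V
  ADC span.
- Channel gains (1, 0.85), emulating the differing activation of the two
  forearm muscles (ECRL and FCR) during grip.
- One MVC trial followed by task contractions at 100/80/60/40 %MVC, 3 s
  each, 200 ms raised-cosine on/off ramps, 1 s rests containing only the
  baseline and a white noise floor of 0.02 relative amplitude; an optional
  50 Hz line component is off by default.
- The continuous signal gets the 1.65 V baseline, 12-bit quantization, and
  packetization through the real protocol codec, one MAC per channel.

A default session yields 50 windows per contraction × 4 levels = 200
feature rows; the default pipeline uses two sessions (400 rows), matching
the scale of the intended experiment ("more than 200 data points", with a
window treated as a data point — whether the original protocol counted
windows or contractions is not stated, so the alternative reading is noted
here).  Rest gaps are short (1 s, not the 20 s anti-fatigue rests of a live
protocol) because rests carry no information for any downstream stage.

What the generator does *not* emulate: motor-unit firing structure,
fatigue-induced spectral compression over time, inter-subject variability,
electrode-placement and crosstalk effects, movement artifacts.  Passing
tests therefore demonstrate that the code implements the stated methods
faithfully and recovers force under the stated signal model — not that the
model attains any particular accuracy on real muscles.  The end-to-end
held-out R² (≥ 0.85 required, ≈ 0.99 observed on default sessions) is an
upper bound: synthetic amplitude maps to force much more cleanly than wet
data.

## Agreement analysis

For validating one acquisition system against a reference device on the
same muscle: both processed signals are envelope-smoothed (centered moving
average, default 100 ms — the window is not dictated by the protocol and is
configurable), lag-aligned by maximum cross-correlation, and compared by
the cross-correlation coefficient

`CCC = (n Σxy − Σx Σy) / sqrt((n Σx² − (Σx)²)(n Σy² − (Σy)²))`

and by the relative agreement of RMS features,
`(1 − |x − y|/y) × 100%`, with `y` the reference-system RMS — that role
assignment reproduces the published example cells exactly (e.g.
`(0.0535, 0.0486) → 89.92%`), which is how the unlabeled formula was
disambiguated.  Five of the eight published cells recompute exactly to two
decimals; three differ by 0.01, consistent with the original authors
computing from unrounded RMS values — documented here rather than matched.
CCC summaries report max, min, mean and the *sample* (n−1) standard
deviation, with a single-value set yielding sd 0 under a warning.

## Problem sizes and reproducibility

Defaults used by the shipped tests and the acceptance script: two synthetic
sessions (≈ 21 s of signal each, 400 windows), BES at population 10 ×
30 iterations for the headline tuning run, and a reduced 6 × 8 budget for
the ten-seed BES-versus-default comparison — sizes chosen so a full
reproduction runs in minutes on a single core while leaving every method
exercised at its published setting where one exists.  Every stochastic
stage (generator, split, RF, BES) takes an explicit seed; `run_grip_pipeline()`
threads one master seed through all of them, and the CLI writes a manifest
(config hash, seed, versions) sufficient to replay any run.

## Known limitations

- The codec's magic values and frame-header semantics are declared
  defaults, not reverse-engineered firmware constants.
- The train+test tuning fitness is faithful to the protocol but
  optimistic; use `cv_folds` for honest generalization estimates.
- Force labels are discrete levels (40–100 %MVC); the regressor
  interpolates between them but is never tested on continuous force.
- The synthetic generator's cleanliness inflates accuracy metrics relative
  to real recordings, as discussed above.
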