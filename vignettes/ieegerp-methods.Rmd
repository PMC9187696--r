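---
title: "Methods: synthetic iEEG evoked responses and cluster permutation statistics"
author: "ieegerp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic iEEG evoked responses and cluster permutation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `ieegerp`, the numerical choices
made at each stage, and the reasoning behind the less obvious design
decisions. Code chunks are illustrative and not evaluated when the
vignette is built.

## 1. The data model

A session is a continuous multichannel iEEG `Recording` (channels ×
samples, with a sampling rate, channel labels, and a cortical subregion
per channel) plus two `MarkerTrack`s on the same clock: note-onset times
and phrase-boundary times (boundaries are a subset of onsets — a phrase
ends *on* a note). The analysis unit is the peri-event **window**:
200 ms before to 600 ms after each marker. At the pipeline's working rate
of 256 Hz that is

* `preS  = floor(200 * 256 / 1000) = 51` samples before the marker,
* `postS = floor(600 * 256 / 1000) = 153` samples after,
* plus the marker sample itself → **205 samples**, with `relTime[52] = 0`.

Window centers are placed at `round(t * fs)` (0-based), so a marker is
never more than half a sample from its nominal time.

Three conditions are compared per subregion: `note_vs_reference`,
`phrase_vs_reference`, and `phrase_vs_note`. *Reference* windows are
sampled from inter-stimulus stretches (section 5).

## 2. The synthetic generator

Patient recordings cannot ship with a package, so every operating
characteristic is measured on synthetic sessions with known ground truth.
`generateSession(syntheticSessionSpec(...))` builds, per channel:

1. **Background noise** with a 1/f^α spectrum (default α = 1), produced by
   shaping white Gaussian noise in the frequency domain
   (`|H(f)| ∝ f^(−α/2)` above a 1 Hz knee, flat below it) and rescaling to
   a target SD (default 10 µV). The unit test checks the realized spectral
   slope by regression on a smoothed periodogram.
2. **Evoked responses**: at every note onset a note template, at every
   phrase boundary a phrase template (replacing, not adding to, the note
   template at that onset). Templates are sums of Gaussian components
   parameterized by latency (ms), amplitude (in units of the noise SD) and
   **width = FWHM** (ms). Defaults: a biphasic N1–P2-like note response
   (−1 at 100 ms, +0.8 at 200 ms) and a slower phrase response including a
   pre-boundary component at −150 ms and a late positivity near 500 ms.
3. **Spatial topography**: each subregion has a gain applied to the
   injected templates. The default gains alternate **+1 / −1 across
   channels within a region** (a dipolar pattern with near-zero spatial
   mean). This is deliberate: the pipeline applies an average reference,
   which exactly cancels any component that is spatially *uniform* across
   the montage. A generator that injected the same waveform with the same
   sign on all channels would produce data in which the evoked response is
   mathematically absent after referencing — realistic electrodes straddle
   dipolar sources and see both polarities, and the default topography
   reflects that.
4. **Interictal spikes** at Poisson times (default rate 0.033 Hz per
   channel), each an instance of the package's IED template scaled so its
   peak is `iedSnr` (default 5) noise SDs. Injected times per channel are
   returned as ground truth.

The marker schedule draws inter-onset intervals from a jittered mean IOI
(default 320 ms, matching fast classical piano music) and promotes a
spaced subset of onsets (default 8) to phrase boundaries.

### The IED template

The default template (`defaultIedTemplate`) is a triphasic
small–large–slow sequence of Gaussian lobes over 250 ms, normalized to
unit RMS. Its shape was chosen for two measurable properties rather than
visual fidelity alone:

* most of its energy lies **above the 1/f knee**, so it is nearly
  orthogonal to the smooth background and does not fire on noise
  (specificity on a clean fixture is part of the acceptance suite);
* its **peak-to-RMS ratio is ≈ 2.3**, so a spike whose *peak* is 5 noise
  SDs still yields a normalized correlation well above the 0.8 detection
  threshold (template-matching sensitivity degrades with peak/RMS, because
  the correlation is computed against the whole 250 ms support).

An earlier draft with a long low-amplitude slow wave failed both
properties: the slow wave both matched background fluctuations (false
positives) and diluted the correlation (peak/RMS ≈ 3 → misses at SNR 5).

## 3. Preprocessing

`preprocessRecording` applies, in order: bad-channel exclusion (robust
z-score of log channel RMS, threshold 5), 60 Hz notch (Q = 30), 1 Hz
high-pass and 250 Hz low-pass (4th-order Butterworth), average
re-referencing, and decimation to 256 Hz behind a 6th-order anti-alias
low-pass at 0.45 × the target rate.

All filters are **zero-phase** and are realized in the frequency domain:
the squared magnitude response |B(e^{iω})/A(e^{iω})|² of each Butterworth
cascade is evaluated on the FFT grid (Horner's rule on the polynomial
coefficients) and applied to the spectrum of the signal after ~2 s of
reflection padding at each end. This is numerically equivalent to
forward–backward IIR filtering but avoids edge transients and per-sample
state recursion, and it makes the "pulse stays put" property exact: the
unit tests verify both the magnitude response at probe frequencies (60 Hz
< 0.2 gain, passband > 0.95) and that a pulse's peak latency is unmoved.

Average referencing is applied *after* bad-channel exclusion so a broken
channel cannot leak into every other channel through the montage mean.

## 4. Markers

* `pickNoteOnsets` peak-picks an onset-strength envelope with a minimum
  inter-peak gap (greedy, strongest first) and discards peaks below a
  quantile of the retained strengths (`keepFraction`).
* Phrase boundaries annotated in *score* time are moved to *audio* time by
  classical dynamic time warping (`dtwAlign`: full DP table, steps
  diagonal/down/right, anchored at both ends) between score and audio
  feature sequences, then `mapPhraseBoundaries` reads each boundary's
  audio time off the warping path (averaging when a score frame maps to
  several audio frames). DTW is implemented directly because the package
  needs the full path, a pluggable local cost, and exactness against an
  exhaustive-path oracle for short sequences — all verified in tests.

## 5. Segmentation and reference windows

Reference windows must be far from any stimulus-locked activity.
`sampleReferenceWindows` draws candidate centers uniformly and accepts
those whose *whole window* is disjoint from every onset window. On sparse
schedules this succeeds outright (the acceptance suite asserts an
achieved overlap-relaxation of 0). On dense schedules (IOI ≈ 320 ms there
is simply no stimulus-free time), a strict requirement would deadlock, so
the sampler walks a **relaxation ladder**: it retries with the minimum
allowed center distance shrunk in steps of 10 %, up to a configurable cap
(`maxRelaxFrac`), records the relaxation actually used, and emits a
message. With the cap at 0 the dense case is an error, not a silent
degradation.

## 6. Statistics

### Per-timepoint test

At each of the 205 time points, the two groups of windows are compared
with a Mann–Whitney U statistic converted to a Z score using the
tie-corrected variance (the same normal approximation as
`stats::wilcox.test`). iEEG window amplitudes fail normality checks at
these sample sizes — the package ships `dagostinoPearson` (D'Agostino–
Pearson K², for n > 50) and falls back to Shapiro–Wilk below that, with
`chooseNormalityTest`/`assessNormality` exposing the diagnostics — which
is why the primary test is rank-based rather than a t-test.

The exactness of the U computation is tested against a brute-force
pairwise count, and the normal approximation against full enumeration of
the exact permutation null at n = 6 vs 6. One honest caveat found during
that comparison: at n = 6 the discrete exact null deviates from *any*
normal approximation by more than 0.01 in the mid-range (p ≈ 0.4–0.6);
agreement within 0.01 holds throughout the decision-relevant tail
(exact p ≤ 0.2), which is what the tests assert.

### Clusters and permutation

Contiguous runs of |Z| > `zThreshold(0.05)` = 1.96 with a consistent sign
form clusters; the cluster statistic is the sum of Z inside the run. The
familywise-corrected p-value of each observed cluster is the add-one
permutation p `(1 + b) / (1 + m)` of its |statistic| against the
**max-cluster-statistic** null from `m` random relabelings (default 200,
so the smallest attainable p is 1/201 ≈ 0.005).

### Bootstrap inside the permutation

Group sizes are unbalanced by two orders of magnitude (≈ 270 note windows
vs 8 phrase windows), so both groups are equalized by bootstrap
resampling to `resampleTo` windows (default 200). The order of operations
matters enormously:

* **Wrong:** bootstrap once, then permute labels over the resampled
  windows. The resampled groups contain *duplicated rows*; shuffling
  labels over rows that are copies of each other produces permuted
  "groups" far more similar to each other than the observed groups are,
  so the null distribution is too tight. On pure-noise sessions this
  scheme flagged a significant cluster in essentially every session —
  a catastrophic type-I failure.
* **Right (what the package does):** the observed statistic uses one
  seeded bootstrap draw per group; every permutation first shuffles the
  condition labels over the pooled *unique source windows* and then draws
  its own fresh bootstrap from each relabeled group. Exchangeability then
  holds at the level of the actual independent units (source windows),
  and the measured false-positive rate across 100 seeded null sessions
  sits at the nominal few percent.

Internally the per-permutation U statistics are computed by a weighted
formulation (per-column rank order precomputed once, bootstrap
multiplicities as weights, flattened cumulative sums), which is what makes
200 permutations × 205 time points fast. That shortcut is valid precisely
because the two groups' bootstrap draws come from disjoint source rows.

## 7. IED rejection

`detectIeds` slides the unit-RMS template over each channel and records
local maxima of the normalized cross-correlation above `rThreshold`
(default 0.8), merging detections closer than one template length.
`rejectWindows` then drops every window whose time span intersects any
detection's ± half-template interval, on *any* channel — epileptiform
activity is treated as a whole-montage artifact.

## 8. Integration across sessions

`integrateSessions` takes per-session `ClusterTestResult`s per subregion
and produces: per-timepoint counts of sessions having a *significant*
cluster covering that time point; shading intervals where the count
reaches `nLight` (≥ 6) and `nDark` (≥ 10) sessions — dark intervals are
by construction nested inside light ones; and a per-subregion summary
(number of significant clusters pooled over sessions, mean and population
SD of their p-values, rounded to 3 decimals, `NA` when a region has
none). The acceptance suite drives this with a fully constructed
12-session fixture so every count and every summary number has a
hand-computable value.

## 9. Problem sizes and runtime

The package's own validation sizes are chosen to keep the full suite
within minutes on one CPU while leaving no stage untested at realistic
rates: sessions of **90 s at 512 Hz** (decimated to 256 Hz), **2
subregions × 2 channels**, ≈ 280 note onsets and 8 phrase boundaries per
session, 200 permutations, bootstrap size 200. Operating characteristics
use 100 null sessions (type-I), 50 injected-response sessions (power and
extent accuracy), and 20 injected spikes (IED recall). These are the
package's choices; all sizes are arguments and scale up without code
changes.

## 10. Limitations

* The normal approximation to U is used even at the bootstrap-equalized
  n = 200, where it is excellent; but the per-timepoint test ignores
  temporal autocorrelation *within* a window — that dependence is handled
  only at the cluster level, which is the standard trade-off of
  cluster-based permutation testing (inference is on clusters, not on
  individual time points or exact boundaries).
* The generator's noise is stationary Gaussian 1/f^α; real iEEG has
  nonstationarities (sleep/wake, electrode drift) the pipeline is not
  tested against.
* The IED detector is single-template; real discharge morphology varies
  by patient and site, and a production deployment would fit
  patient-specific templates.
* DTW here aligns generic feature sequences; no audio front end (onset
  strength from spectral flux, chroma) is included.
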