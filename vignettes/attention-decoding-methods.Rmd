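---
title: "Decoding auditory attention with boosted temporal response functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding auditory attention with boosted temporal response functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aadtrf)
```

## The model

When a listener attends to one of several concurrent talkers, low-frequency
EEG tracks the temporal envelope of the attended speech more strongly than
that of ignored speech. `aadtrf` models this tracking with temporal response
functions (TRFs): linear filters over a grid of time lags relating a
stimulus feature $x(k)$ to EEG channels $y_i(k)$.

The **forward** (encoding) model predicts EEG from the feature,

$$\hat y_i(k) = \sum_{l = l_1}^{l_2} h_{l,i}\, x(k - l),$$

and the **backward** (decoding) model reconstructs the feature from all
channels,

$$\hat x(k) = \sum_{i = 1}^{n_{ch}} \sum_{l = l_1}^{l_2} h_{l,i}\, y_i(k + l),$$

both with zero-padding outside the trial. Attention is decoded by
correlating the reconstruction with the candidate streams (Pearson $\rho$):
a decision window is classified as attended whenever
$\rho_{att} > \rho_{ign}$, exact ties counting as incorrect.

## Estimation: sparse boosting on a Hamming basis

TRFs are estimated by greedy coordinate boosting with a mean-absolute-error
objective. The kernel is parameterized as a weighted sum of Hamming windows
(width 50 ms, one centered on every lag-grid element; at the 50 Hz analysis
rate each window spans three 20-ms grid points), which enforces temporal
smoothness at the scale of the P1/N1/P2 components. Each boosting step adds
$\pm\delta$ to the single (basis function, channel) weight that most reduces
the training MAE; the step size $\delta$ defaults to 0.005 target-SD units.
Training data are split into contiguous inner partitions (default 4; the
scaled-down test configurations use 2): each partition serves once as inner
validation, fitting stops once validation MAE has not improved for
`patience` steps (default 20), the kernel at the validation minimum is kept,
and kernels are averaged across partitions. Weights never selected remain
exactly zero, so kernels are sparse, and every returned kernel is exactly
representable in its basis.

Ties between equally good candidate steps are broken deterministically
(lowest channel index, then lowest basis index, `+` before `-`), so fits are
bit-reproducible. A constant (degenerate) regression target yields a zero
kernel with a warning rather than an error.

### What kernel recovery can and cannot mean

A deconvolution estimator can only identify the kernel within the stimulus'
excited band. Speech-like envelopes (syllabic pulses smoothed over ~150 ms)
carry almost no power near the 25-Hz Nyquist of the 50-Hz lag grid, so
alternating-sign kernel components are invisible through them: fits can
reach prediction $\rho > 0.999$ while coefficient-space recovery saturates
near $\rho \approx 0.86$. The kernel-recovery acceptance test therefore uses
a white-noise feature — the standard persistent-excitation input — and the
package makes no claim that envelope-driven TRFs are identified outside the
stimulus band.

## Preprocessing

EEG passes a fixed, asserted chain: group rereferencing (scalp channels to
their common average, cEEGrid channels to linked L4/R4), 50-Hz FIR notch,
0.1–40 Hz bandpass, a pluggable artifact-removal slot, 1–20 Hz bandpass,
resampling to 50 Hz, and per-channel z-scoring within the trial. Filters are
linear-phase Hamming windowed-sinc designs applied forward and backward
(zero net group delay); transition bandwidths follow the
`min(max(0.25 f, 2 Hz), room)` convention of the common EEG toolchains and
determine the filter length (3.3 / transition bandwidth). Stimulus features
take the same 1–20 Hz / 50 Hz / z-score path through `prepare_feature()`.

Design notes:

* The artifact slot is a documented no-op by default. The manual ICA
  component selection used on real recordings is irreproducible by
  construction, and the synthetic data contain no ocular artifacts; a custom
  function can be plugged in for real data.
* Normalization is per channel *per trial* (the alternative, per session,
  would leak amplitude information across CV folds).
* Applying a symmetric FIR forward and backward squares its magnitude
  response; stated attenuations hold with margin in steady state. Edge
  transients of length ~filter length are inherent to the zero-padding
  policy and are excluded when responses are measured.

## Stimulus features

Audio is decomposed by a bank of 4th-order gammatone filters (128 bands by
default, ERB-rate spaced between 80 and 15000 Hz; magnitudes half-wave
rectified, smoothed, and decimated to 1000 Hz). The **acoustic envelope** is
the across-band sum of magnitudes. **Acoustic onsets** apply an
edge-detection operator per band: compress
($\log(1 + kx)/\log(1 + k)$, $k = 100$, so unit steps give unit-order
edges), subtract a 10-ms-delayed 30-Hz-lowpassed copy, half-wave rectify,
and sum across bands. Published edge-detector constants vary, so delay,
lowpass and compression are exposed as tunables. The derivative-based onset
variant is deliberately out of scope. Synthetic envelopes may bypass the
filterbank and enter at `prepare_feature()`.

## The synthetic world

Because the study's recordings are not public, the package states a
generative world in `synthesize_session()`:

* **Envelopes** are gamma-renewal pulse trains (shape 2, mean inter-onset
  250 ms — a ~4 Hz syllable rate) with gamma-distributed amplitudes,
  convolved with a 150-ms raised-cosine window and modulated by a slow
  positive drift. They are nonnegative with dominant power below 10 Hz.
* **Response kernels** have P1/N1/P2 Gaussian bumps at 40/100/180 ms
  (amplitudes 0.6/−1.0/0.7, widths 15/25/35 ms), truncated to exact zero
  beyond four widths.
* **Trials** (180 s by default) mix the attended stream through the
  attended kernel and the competing stream through the ignored kernel
  scaled by `attention_gain` (default 0.5 — no numeric attended:ignored
  ratio is published, this is a stated choice matching the qualitative
  contrast of attended vs ignored TRFs). Three conditions: sustained
  attention (SustAC, 8 trials), switching attention (SwitAC, 8 trials; two
  switches drawn from U(35,55) s and U(125,145) s), and a conversation
  condition (ConvAC, 9 trials; a two-talker front conversation in
  alternating turns vs one side talker). A control stream is generated but
  never mixed into the EEG.
* **Noise** is 1/f (exponent 1), spatially mixed across channels by a
  seeded smooth random matrix, scaled so the realized kernel-response SNR
  matches `snr_db` (default 0 dB) exactly per trial. cEEGrid channels carry
  6 dB weaker signal topography than scalp channels, reflecting the weaker
  around-the-ear effects reported for that montage.
* Raw simulation runs at 500 Hz and is pushed through the real
  preprocessing chain, so preprocessing is exercised on realistic input.

Every generator is a pure function of (configuration, seed).

What a green test on this world does establish: the estimator, CV
bookkeeping, classification and statistics behave correctly on data with
the assumed structure. What it does not establish: performance on real EEG,
whose artifacts, nonstationarities and inter-subject variability the
generator deliberately does not model.

## Evaluation

All performance metrics use leave-one-trial-out cross-validation within a
condition. Backward decoders are fitted on the schedule-spliced attended
feature of the training trials; the held-out trial's reconstruction is
computed once, split into consecutive non-overlapping decision windows
(default grid 1.1, 2.2, 4.4, 8.8, 17.5, 35, 178 s — geometric doubling
between the published endpoints), and correlated with the attended, ignored
and control features. SwitAC windows straddling an attention switch are
excluded (mixed-label segments are undefined), and the 178-s full-trial
window is dropped for SwitAC. Cross-condition generalization fits on all
trials of one condition and classifies another at a 35-s window;
same-condition requests are redirected to within-condition CV. The ConvAC
attended feature is the summed front-conversation envelope (turn-taking
makes overlap rare); the side talker serves as the ignored stream.

The sliding optimal-lag analysis fits short-lag TRFs for 78 windows of
45 ms, stepped 15 ms over −600..600 ms. Windows are defined in continuous
time: the 20-ms grid taps whose lag falls inside a window are used (2–3
taps). Forward-model correlations are averaged across electrodes, giving
one estimate per window (per montage group and stream).

## Statistics

Group-level attended-vs-ignored TRF contrasts use mass-univariate t tests
(pooled-variance independent-samples by default, matching the reported
choice; a paired variant is available) after smoothing TRFs with a Gaussian
kernel along the lag axis. The 50-ms "width" of that kernel is interpreted
as FWHM (switchable to SD), with partial-window renormalization at the lag
edges. Multiple comparisons are controlled by threshold-free cluster
enhancement (exponents E = 0.5, H = 2, step dh = max|t|/100 — the standard
defaults, not restated in the source) with a max-statistic permutation null
(label exchange or sign flips), $p = (1 + \#\{null \ge obs\}) / (1 + n_{perm})$.
TFCE adjacency is along the lag axis only: synthetic sessions carry no
electrode geometry, so channel adjacency is not assumed. The stored TFCE
map is the nonnegative enhancement magnitude (positive and negative t
enhanced separately; signs live in the t map). Scalar metrics use paired t
tests with Benjamini–Hochberg adjustment.

## Numerical and scaling choices

* Decision thresholds, tolerances and band checks in the test suite are the
  stated acceptance values; simulation sizes are scaled down (fewer/shorter
  trials, fewer channels, reduced decoder lag ranges) purely for the
  single-CPU time budget. Sizes that carry the statistics — the 600-s
  recovery fit, ≥ 200 null decisions, n = 24 groups, 200 null simulations,
  all 78 scan windows — are kept.
* The full ±1 s lag range is supported and used by default in
  `boosting_fit()`; scaled test configurations restrict it (e.g. −0.2..0.6 s)
  since the synthetic kernels have no support outside that range.
* Session serialization uses a directory container (JSON metadata +
  full-precision CSV arrays) in place of HDF5, for which no R binding is
  available in the supported environment; the round-trip is lossless. EDF
  export is inherently 16-bit quantized.
* Permutation p-values are bounded below by 1/(1 + n_perm); FWER control
  follows from exchangeability, not asymptotics.

## Known limitations

* No artifact modelling or removal; real-data use requires plugging an
  artifact stage into the chain.
* Backward decoding weights all channels; no channel selection or
  regularized spatial filtering beyond what boosting's sparsity provides.
* The conversation condition's mixture-as-attended-feature choice is an
  interpretation; per-talker streams are retained so alternatives can be
  evaluated.
* Band-resolved (spectrogram) TRFs and linguistic features are out of
  scope.
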