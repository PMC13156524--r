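# aadtrf

Auditory attention decoding from multichannel EEG with boosted temporal
response functions (TRFs).

In a multi-talker ("cocktail party") scene, low-frequency EEG tracks the
amplitude envelope of the speech a listener attends more faithfully than
that of ignored speech. `aadtrf` implements the full analysis chain used to
quantify that effect and to decode attention from it:

* **Stimulus features** — gammatone filterbank (ERB-spaced, 128 bands,
  80–15000 Hz), acoustic envelope (across-band magnitude sum) and acoustic
  onsets (per-band edge detection), each bandpassed 1–20 Hz, downsampled to
  50 Hz and z-scored.
* **EEG preprocessing** — a fixed, asserted chain: rereferencing (scalp
  common average; cEEGrid around-the-ear array to linked L4/R4), 50-Hz
  notch, 0.1–40 Hz and 1–20 Hz zero-phase Hamming windowed-sinc FIR
  bandpasses, resampling to 50 Hz, per-channel z-scoring.
* **TRF estimation** — forward (encoding) models
  `y_i(k) = Σ_l h_{l,i} x(k−l)` and backward (decoding) models
  `x(k) = Σ_i Σ_l h_{l,i} y_i(k+l)`, estimated by greedy sparse boosting
  (mean-absolute-error objective, validation-based selective stopping) on a
  basis of 50-ms Hamming windows over lags up to −1..1 s.
* **Attention evaluation** — leave-one-trial-out cross-validation,
  Pearson-correlation classification over decision windows (1.1–178 s),
  cross-condition generalization, and a 78-window sliding optimal-lag scan
  (45-ms windows, 15-ms steps, −600..600 ms).
* **Statistics** — Gaussian TRF smoothing (50-ms FWHM), mass-univariate t
  maps, threshold-free cluster enhancement (E = 0.5, H = 2) with
  max-statistic permutation control, Benjamini–Hochberg adjustment, paired
  t tests.
* **Synthetic sessions** — a seeded generator emulating three two-talker
  listening protocols (sustained, switching and conversation attention)
  with speech-like envelopes, P1/N1/P2 response kernels, attenuated ignored
  responses and spatially correlated 1/f noise at exact SNR, so the entire
  pipeline is testable without any recordings.

See `vignettes/attention-decoding-methods.Rmd` for the model, the generative
world, and every numerical design choice.

## Worked example

Simulate a small sustained-attention session, preprocess it, and decode
attention with leave-one-trial-out cross-validated backward TRFs:

```r
library(aadtrf)

cfg <- sim_config(n_scalp_channels = 4, n_ceegrid_channels = 0, fs_raw = 200,
                  trial_duration = 60,
                  trial_counts = c(SustAC = 4, SwitAC = 0, ConvAC = 0),
                  switch_window_1 = c(15, 25), switch_window_2 = c(35, 45),
                  snr_db = 5, attention_gain = 0.5, seed = 1)
session <- preprocess_session(synthesize_session(cfg))
session
#> <aad_session> 4 trials (SustAC: 4), preprocessed

cv <- decision_window_curve(session, "SustAC", lengths = c(2.2, 8.8, 35),
                            lag_range = c(-0.2, 0.6),
                            cfg = boost_config(partitions = 2))
cv
#> <aad_curve> SustAC
#>  window_s   n  accuracy
#>       2.2 108 0.9444444
#>       8.8  24 1.0000000
#>      35.0   4 1.0000000

cv$kernels[[1]]
#> <trf_kernel> backward, 41 lags [-0.2, 0.6] s @ 50 Hz, 4 channels
```

Each row of the curve is one decision-window length: `n` decisions (here,
non-overlapping windows across the four held-out trials) and the fraction in
which the reconstructed envelope correlated more strongly with the attended
than with the ignored stream. Accuracy grows with window length — 2.2-s
windows already decode at 94%, full 35-s windows perfectly — because the
Pearson correlation stabilizes over longer segments. At `attention_gain = 1`
(no attended/ignored asymmetry) the same pipeline stays at chance, and the
test suite verifies both calibrations.

The full pipeline (simulate → preprocess → fit → evaluate → export CSVs and
a manifest) runs from a single config:

```r
report <- run_pipeline(run_config(overrides = list(seed = 42, output_dir = "out")))
```

or from the command line:

```sh
Rscript -e 'aadtrf::aad_cli()' run --config config.json --seed 42 --out results/
Rscript -e 'aadtrf::aad_cli()' simulate --out session_dir/ --seed 7
```

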