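---
title: "Environment-aware noise reduction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environment-aware noise reduction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the method

Listeners using hearing-assistive devices, cochlear implants in particular,
lose far more intelligibility in background noise than normal-hearing
listeners. A single "one size fits all" denoiser helps, but a denoiser
specialized to the *current* noise type helps more. The system implemented
here therefore couples three components:

1. **A noise classifier (NC).** A feed-forward network over 13
   mel-frequency cepstral coefficients per frame, with three 100-unit
   logistic hidden layers and a softmax output over the noise classes.
   Per-frame posteriors are averaged over the utterance; the argmax of the
   mean posterior is the predicted class and its value is the routing
   confidence.
2. **Deep denoising autoencoders (DDAE).** Five-weight-layer networks with
   ReLU hidden units and a linear output that regress noisy log-power-spectrum
   (LPS) frames onto clean ones. One *noise-independent* (NI) model is trained
   on mixtures of every class; *noise-dependent* (ND) variants specialize it.
3. **Knowledge transfer.** An ND variant is not a separate network: starting
   from the NI parameters, exactly one weight layer is retrained on
   matched-noise data. The deployed system stores one full NI model plus one
   `(W, b)` pair per class — the `TransferStore` — and composes the ND model
   on demand. All other layers are shared bit-for-bit, which
   `count_system_parameters()` turns into the headline footprint reduction.

At enhancement time the pipeline is: STFT → (MFCC → classify → route) →
LPS denoising by the routed model → magnitude via `exp(lps/2)` → inverse
STFT using the *unmodified noisy phase* → waveform. If the routing
confidence falls below the threshold (default 0.9), the NI model is used;
this makes misclassification degrade gracefully toward the generalist model.

## Signal representation

LPS features are `log(max(|STFT|^2, floor))` with a periodic 512-sample
(32 ms) Hann window, 256-sample hop and a 512-point FFT at 16 kHz — standard
speech-enhancement framing; none of these values is prescribed by the
method itself, and all are configurable through `stft_config()`. The log
floor (`1e-12`) is the only guard against `-Inf`; the features module
guarantees no non-finite value ever leaves it. Synthesis applies the window
a second time and normalizes by the accumulated squared window, so the
analysis–synthesis roundtrip is exact to floating point away from the first
and last half-frame. The noisy phase is reused verbatim; no phase
estimation is attempted.

LPS frames are z-scored per frequency bin before entering any network (the
statistics are computed from the noisy training material, stored with the
model, applied to both input and target, and inverted on output). Without
this, training of small networks on raw LPS — whose per-bin dynamic ranges
differ by orders of magnitude — stalls. MFCCs use a 26-filter triangular
mel bank and an orthonormal DCT-II, 13 coefficients including c0.

## Training

Both networks train with minibatch Adam (batch 128) under exact
backpropagation; gradient correctness is verified against central
differences in the test suite. The classifier minimizes softmax
cross-entropy (learning rate 1e-3, 50 epochs by default); the denoiser
minimizes per-frame squared error averaged over frames, the standard DDAE
loss. Fine-tuning a single layer uses a per-layer trainable mask: masked
layers are *bit-identical* before and after training — this conservation
property, not an approximation of it, is what makes the transfer store
sound, and it is asserted exactly in the tests. Fine-tuning defaults are
deliberately gentle (10 epochs, learning rate 1e-4, one tenth of base
training): the adaptation is a small correction of an already-good model.
Every stochastic step (initialization, shuffling, subsampling) takes an
explicit seed, and package code restores the caller's RNG state.

## Which layer to substitute

The substituted layer is a configuration knob (`substituted_index`,
`layer_sweep()` scores every choice). The default is layer 3, the middle
weight layer of the default five-layer denoiser: in the package's own
sweeps on the synthetic corpus, middle-layer substitution gave the most
robust matched-noise adaptation — mean STOI change positive and the worst
per-utterance change smallest in magnitude — while substituting layer 2
produced larger per-utterance excursions for a similar mean. The
`r_to_layer()` helper documents the alternative "count from the top"
indexing (`L - r`) used when the trainable layer is written `W^(L-r)`.

## Parameter accounting

With `C` noise classes, explicit deployment needs `C + 1` full denoisers
(plus the classifier); the transfer scheme needs one denoiser plus `C`
copies of one layer. With all five weight layers of equal size the ratio
tends to `(5 + 12) / (5 * 13) = 17/65 ≈ 0.26` for twelve classes — about a
quarter. The default denoiser width is 256 (`ddae_default_dims()`): a bank
of thirteen such models holds about 4.3 million parameters, the scale at
which this scheme was designed to operate, and the default transfer system
reduces the footprint by roughly 73%. The classifier can be counted on both
sides or excluded from both (`include_nc`); it is never counted on one side
only, which keeps the ratio conservative.

## The synthetic corpus

No recorded speech or noise ships with the package; everything is generated:

* **Speech-like utterances** — additive harmonic synthesis with a
  piecewise-random fundamental (100–250 Hz), three formant-like resonances,
  a low-pass spectral tilt, syllable-rate (2–6 Hz) amplitude modulation and
  a weak aspiration floor. This reproduces the gross structure that both
  STOI and an LPS denoiser respond to: harmonicity, formant peaks, and
  strong slow envelope modulation.
* **Twelve noise classes** — sirens and alarms (tonal sweeps), jackhammer
  and squeaky-toy impulses, low/high two-talker babble, cafeteria babble,
  fan hum (harmonic comb), speech-shaped noise, low-frequency rumble, and
  two composite mixtures. The bank is constructed so that mean log-spectra
  of distinct classes correlate below 0.95 and a trivial nearest-centroid
  classifier already exceeds 90% — i.e. the classification task is honest
  but solvable, and a perfect classifier score reflects the method, not an
  accident of the fixture.
* **Exact SNR mixing** — clean speech is RMS-normalized to 0.05 (keeping
  peaks clear of clipping at −10 dB SNR), noise is truncated from sample 0,
  and the scaling gain is computed in closed form, so every mixture's
  realized SNR matches its nominal SNR to well below 1e-6 dB. Default SNR
  grids: train {−10, −7, −4, −1, 1, 4, 7, 10} dB, test {−6, −3, 0, 3, 6} dB.
* **Reproducibility** — a corpus is its manifest: per-entry seeds derive
  arithmetically from one master seed, and resolving an entry twice yields
  bit-identical audio, so corpora are never stored.

What the generator does *not* emulate: linguistic content, speaker
variability, reverberation, recording channels, or non-stationary real-world
noise statistics. Passing results on this corpus demonstrate that the
machinery — routing, transfer, reconstruction, accounting — behaves as
designed, not that any particular intelligibility gain transfers to real
recordings.

## Evaluation

* **STOI** is implemented in the package (classic variant: 10 kHz analysis,
  silent-frame removal at a 40 dB dynamic range, 15 one-third-octave bands
  from 150 Hz, 384 ms segments, −15 dB clipping) and exposed as
  `eval_stoi()`. Its contract — self-score 1, degradation ordering,
  monotonicity in SNR — is property-tested.
* **PESQ** is a standardized ITU metric and is only ever *consumed*:
  `eval_pesq()` validates its contract and dispatches to a backend
  registered via `options(eanr.pesq_backend = ...)`; without one it fails
  loudly rather than approximating. Sweep and scoring tables carry an
  `NA` PESQ column in that case.
* **Word correct rate** (`wcr()`) is the listening-test utility:
  `100 * n_correct / n_total`.
* **Layer separability** (`layer_separability()`) quantifies, per layer, how
  well the trained denoiser's activations separate clean-input from
  noisy-input frames, using a two-class silhouette on raw activations with
  seeded subsampling (default cap 2000 frames per population). A 2-D
  embedding can be attached for plots but never feeds the score: a visual
  overlap argument is not assertable, a silhouette is.

## Numerical choices and degenerate inputs

Softmax rows are computed with max subtraction; posteriors sum to one
within 1e-9. Argmax ties break to the lowest class id. Zero-power signals
are rejected by the mixer ("degenerate input") rather than propagated as
NaN. Zero, constant and clipped signals pass through the feature chain
without producing a single non-finite value. Training raises an error on a
non-finite loss instead of returning a broken model. An all-false trainable
mask and zero training epochs are both exact no-ops, which gives the
transfer machinery a testable identity element.

## Problem sizes used in the shipped tests

The test suite trains miniature models so the full suite stays fast: the
classifier check uses 10 training and 5 held-out clips per class at 30
epochs; the denoiser study uses six noise classes, a [257, 128×4, 257]
model, 40 training mixtures per class over four SNRs and 24 matched test
mixtures at 0 dB. These sizes are the package's chosen fixture scale;
`scripts/acceptance.R` runs the classifier experiment at its full size
(20 + 10 clips per class, 50 epochs).

## Known limitations

* The clean/noisy separability profile of the trained denoiser *decreases
  monotonically* with depth on the synthetic corpus: the first hidden layer
  inherits the large clean-versus-noisy offset present in the LPS input,
  and deeper layers progressively merge the two populations as they
  denoise. The often-reported picture in which separation *peaks* at an
  interior layer does not reproduce at this fixture scale and architecture;
  the package records the profile (seeds fixed) and the corresponding test
  states the expected interior peak plainly, so the discrepancy is visible
  rather than hidden.
  The choice of substituted layer is therefore justified here by the sweep
  (STOI under substitution), not by the separability profile.
* STOI on synthetic harmonic "speech" is meaningful for *comparisons*
  (enhanced vs noisy, ND vs NI) but its absolute values should not be read
  as intelligibility predictions for human speech.
* The confidence measure is the simplest calibrated statistic (maximum of
  the frame-averaged posterior); no open-set detection is attempted beyond
  the threshold rule.
* Everything runs on CPU; the networks are small by design — the point of
  the transfer scheme is a small deployable footprint, not scale.
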