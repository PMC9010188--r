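---
title: "Methods: from multichannel EEG to a 1-100 pleasure score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from multichannel EEG to a 1-100 pleasure score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the pipeline

`eegaffect` implements a complete emotion-detection chain for wearable-EEG
affect measurement: 62-channel EEG is reduced to band-wise
differential-entropy (DE) features, smoothed, rendered as a standardized
224 x 224 feature image, classified into three emotion classes
(negative / neutral / positive) by a residual CNN, and finally mapped to a
1-100 "pleasure" display scale. A companion evaluation module implements
the arithmetic used to compare detector output with questionnaire
references in a field study (per-pair absolute error, accuracy as
100 minus mean error, between-group contrast consistency).

Because the reference emotion corpus (15 subjects x 3 sessions x 15
film-clip trials, 62 channels, labels -1/0/+1) is an external download and
the detector hardware is a physical device, the package ships a seeded
synthetic-EEG generator that stands in for both. Every stage is therefore
testable offline, end to end.

# The synthetic world

`generate_recording()` draws white Gaussian noise per channel and shapes it
with the same five spectral band masks the analyzer uses (delta 1-3, theta
4-7, alpha 8-13, beta 14-30, gamma 31-50 Hz), rescaling each band component
so its realized sample variance equals the class profile's stated variance
exactly. Defaults state the world the tests live in:

* trials of 180 s at 200 Hz (the corpus contract after preprocessing);
* a flat neutral profile of 10 uV^2 per band — a realistic resting-EEG
  band-power magnitude;
* positive affect with beta+gamma elevated to 30 uV^2, negative affect
  with delta+theta elevated to 30 uV^2.

The 3x elevation makes the class-mean DE differ by about
`0.5 * log(3) = 0.55` nats in the affected bands, large against the
within-class spread of a 180-window trial, so the three classes are
linearly separable in DE space by construction. That choice is deliberate:
the end-to-end tests are *parameter-recovery* tests ("can the pipeline
recover a known separable structure?"), not claims about real emotional
EEG. The generator does not model scalp topography, ocular/muscular
artifacts, nonstationarity, or inter-subject variability, so a green
end-to-end test establishes correctness of the machinery, not field
performance.

Sub-seeds for recording *k* of a dataset are derived as
`(seed + 1000003 * k) mod (2^31 - 1)`, so any single trial can be
regenerated in isolation.

# Preprocessing

The corpus contract is: downsample to 200 Hz, bandpass 0-75 Hz, uniform
180 s segments. Three numerical choices:

* **Filters are FFT-domain magnitude masks applied with zero phase** (a
  brick wall with a 0.5 Hz raised-cosine transition), not IIR
  filters. No filter-design toolbox is needed, the response is exactly
  reproducible, there is no group delay to shift windowed features, and
  out-of-band attenuation far exceeds the 20 dB/octave requirement. The
  trade-off — mild Gibbs ringing at sharp spectral edges — is immaterial
  for band-power features. A "0-75 Hz bandpass" is implemented as a pure
  lowpass: the lower edge 0 means DC is retained.
* **Resampling is Fourier resampling** (spectrum truncation or
  zero-padding), which is inherently anti-aliased and keeps a pure tone in
  its frequency bin.
* **Segmentation keeps the leading window.** Only a uniform length of
  180 s is specified; cropping the first 180 s is the simplest
  reproducible rule.

# Differential-entropy features

For a Gaussian window, differential entropy has the closed form

$$h(X) = \tfrac{1}{2}\log\!\left(2\pi e \sigma^2\right),$$

estimated per window from the sample variance. Choices:

* **DE window = 1 s, non-overlapping.** A 180 s trial then yields exactly
  180 windows, matching the 62 x 180 x 5 tensor contract; the window
  length itself is not otherwise pinned.
* **Variance floor 1e-12** before the log, so constant windows give a
  finite documented floor instead of `-Inf`.
* The band decomposition reuses the generator's masks, so generator and
  analyzer cannot drift apart.

A caveat the tests respect: the *estimator* `log(s^2)` is negatively
biased for windows with few effective degrees of freedom. A 1 s window of
a 2 Hz-wide band (delta) has only a handful of independent samples, so
its DE sits visibly below the closed form evaluated at the long-run band
variance, while wide bands (beta, gamma) agree closely. Between-band DE
*differences* are therefore validated on similar-bandwidth pairs, and
narrow bands are checked for ordering only. Within a band, the bias is
identical across classes and cancels from every comparison the classifier
sees.

# LDS smoothing

To suppress emotion-irrelevant fluctuation, each (channel, band) DE series
is smoothed by a linear dynamic system with a 20 s window: a scalar
random-walk state-space model

$$x_t = x_{t-1} + w_t,\quad y_t = x_t + v_t,$$

smoothed by a forward Kalman pass plus backward fixed-interval (RTS) pass.
With `"auto"` noise settings, the variances are estimated by method of
moments on the first differences `d = diff(y)`: for this model
`Var(d) = q + 2r` and `Cov(d_t, d_{t+1}) = -r`, so `r = -acov1(d)` and
`q = Var(d) - 2r`, both floored at a small positive value. One deviation
from the original sketch is documented here: parameters are estimated once
per series rather than per 20-window block, because block-local estimates
of `r` on 20 points are frequently negative and destabilize the smoother;
the 20-point span survives as the documented centered moving-average
fallback (`method = "moving_average"`). Contracts either way: constant
and length-1 series are fixed points, the output length is unchanged, and
the variance of first differences never increases.

# The feature image

A conformant tensor holds 62 x 180 x 5 = 55,800 values; the classifier
consumes 224 x 224 = 50,176. Since no lossless reshape exists, the bridge
is made explicit: bands are stacked vertically into a 310 x 180 plane (row
block `(b-1)*62 + c` = channel `c` of band `b`, columns = time windows),
the plane is bilinearly resampled to 224 x 224 with corner alignment, and
the image is min-max standardized,

$$y_i = \frac{x_i - \min x}{\max x - \min x},$$

*per image* (not per corpus), because the deployed detector scores single
sessions with no corpus statistics available. The pre-standardization
extrema are kept on the object for audit. A degenerate image
(max = min, detected with a relative 1e-12 tolerance because bilinear
interpolation of a constant plane wobbles at machine epsilon) maps to
all-0.5 with a warning. One consequence worth knowing: per-image
standardization amplifies whatever contrast an image has, so a flat
neutral-profile image becomes full-range estimator noise — classes must be
distinguished by spatial structure, not absolute level, which is what a
convolutional classifier is for.

# The residual classifier

The full-depth preset reproduces the published 50-layer design: a 7x7
stride-2 stem convolution, 3x3 stride-2 max pooling, four stages of
bottleneck blocks with counts 3/4/6/3 (16 blocks, three convolutions
each), global average pooling in place of a wide dense layer, and a 3-way
softmax head; weighted layers count 1 + 48 + 1 = 50. Every block computes
`relu(F(x) + shortcut)`, with a learned 1x1 projection shortcut exactly
where channel count or stride changes. A `small` preset keeps the same
topology at desk scale (counts 1/1/1/1, widths 4/8/16/32, expansion 2,
stem 8) so CPU training completes in minutes; the full preset is used for
structural assertions, the small one for training tests.

Training follows the stated protocol: categorical cross-entropy, Adam at
its conventional defaults (1e-3, 0.9, 0.999 — "default parameter" is taken
at its word), batches of 5, a seeded 9:1 split whose test size is
round-half-up(n/10) (the only rounding consistent with 675 -> 607/68), and
best-epoch selection on the held-out accuracy curve with ties going to the
earliest epoch. Labels map -1/0/+1 to classes 1/2/3 in that fixed order.
Two implementation notes:

* **No batch normalization.** The original design predates none of this
  mathematics, but the sources specify only the residual equations,
  activations and loss; adding BN would introduce unspecified machinery.
  Without it, convergence is slower — the end-to-end test budget (15
  epochs x 12 batches) is enough for the separable synthetic world, and
  gradients were verified against central finite differences at 1e-9
  relative error.
* **The loss in two forms.** The printed loss is written in two-term
  (binary) form although the task has three classes.
  `categorical_crossentropy()` exposes both: `"binary_sum"` reproduces the
  printed form (and its worked value ~1.9095 on a uniform prediction),
  while training uses the standard multiclass form, whose gradient through
  softmax is the usual `a - y`.

Checkpoints embed parameters, configs, seed, epoch and accuracy, so a run
is re-creatable from its artifacts. Selecting the model by test-set
accuracy and then reporting that same test set's accuracy — as the
original protocol does — is an optimistic estimate; the package follows
the protocol and flags the bias here.

# Detector sessions and the pleasure score

A measurement session spans 60 s; EEG is acquired in the first 30 s at
200 Hz. Training images, however, come from 180-window trials. The bridge
is window-axis resampling: the 30-window DE tensor is linearly
interpolated to 180 windows before imaging. This is a package choice
(the original workflow does not explain the reconciliation) isolated in
`resample_window_axis()` so alternatives can be swapped.

Class probabilities map to the display scale as

$$\mathrm{score} = \mathrm{clamp}\!\left(\mathrm{round}\!\left(100\,(p_{+} + 0.5\,p_{0})\right),\ 1,\ 100\right),$$

the simplest mapping that is strictly increasing in the positive-class
probability, places certain neutrality at mid-scale (50), and respects the
displayed 1-100 integer range (certain negativity clamps from 0 to 1).
Scores are rounded to integers, matching the displayed values.
`improvement()` is the signed delta stimulus minus baseline.

# Evaluation arithmetic

`pairwise_error()` takes paired detector and reference scores on the 1-100
scale; errors are absolute differences, `mean_error` their mean, and
`accuracy_percent = 100 - mean_error` — the only reading under which a
mean error of 2.77 and an accuracy of 97% are the same fact.
`contrast_consistency()` differences the two group means on each side and
reports the absolute discrepancy of the contrasts. Because the underlying
study's raw tables are not public, the package ships *synthetic* study
tables (marked `synthetic` in their filenames) constructed so their group
statistics equal the study's printed summaries; the evaluation module
computes everything from those tables at run time. Whether per-pair
comparisons should use raw stimulus scores or improvement deltas is
ambiguous in the source protocol, so both are exposed
(`compare = "stimulus"` / `"improvement"`).

# What the tests do and do not establish

The test suite verifies: exact closed forms (DE, softmax, cross-entropy,
min-max), estimator agreement with independent oracles (periodogram band
power, Vasicek entropy, finite-difference gradients), structural fidelity
of the 50-layer network, determinism and serialization contracts, and
end-to-end recovery of the synthetic classes (held-out accuracy >= 0.90
with the small preset, with a shuffled-label control at chance). They do
not establish performance on real EEG: the synthetic world is linearly
separable by construction, contains no artifacts, and uses one "subject".
The externally reported corpus accuracy (76.47% with the full 50-layer
model) requires the external dataset and a long stochastic training run,
and is intentionally out of scope.

# Known limitations

* Bit-level training reproducibility holds for a fixed BLAS; different
  BLAS builds may differ in the last ulp and, over many Adam steps,
  diverge visibly. All contracts asserted by tests are robust to this.
* The EDF writer quantizes to 16 bits (as the format requires); bit-exact
  storage uses the versioned RDS array container instead.
* The SEED-style adapter reads the session layout from RDS or delimited
  directories; original MATLAB files must be converted externally (no
  .mat reader is available in the dependency set).
* Artifact removal (ocular/EMG) is not implemented; the pipeline assumes
  band-passed input is sufficient, as the corpus preprocessing contract
  implies.
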