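---
title: "Estimating and comparing receptive fields from calcium event trains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing receptive fields from calcium event trains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(astrorf)
```

## The problem

Astrocytes in sensory cortex produce calcium events that are, for a subset
of subcellular loci, reliably linked to the sensory stimulus. Whether those
loci are *feature-selective* — whether they respond preferentially to
particular spectrotemporal patterns in a natural sound, the way auditory
neurons do — is a question about receptive fields, asked of a signal that
is sparse, binary (event onsets), trial-structured and slow.

`astrorf` implements the full chain needed to answer it for
ultrasonic-vocalization (USV) stimuli: stimulus preprocessing, a
second-order Maximum Noise Entropy (MNE) encoding model fitted to
trial-averaged event trains, shuffle-based significance, receptive-field
feature extraction, and population-level comparison of feature subspaces
via principal angles. A synthetic-data module generates USV-like stimuli
and event rasters from *known* encoding models, so every stage of the
chain is testable end to end without any recorded data.

## Stimulus representation

The stimulus waveform (250 kHz sampling in the USV regime) is converted to
a power spectral density spectrogram with 4096-sample Hann windows and 50%
overlap, giving a temporal resolution of 8.1920 ms and a frequency
resolution of 61.035 Hz. The frequency axis is restricted to the 45–110
kHz vocalization band and averaged into 28 linearly spaced bins. For each
time bin `t` (from the 28th onward) the model's stimulus is the 28 × 28
patch covering bins `t-27 … t` across the 28 frequency bins, flattened
row-major into a 784-vector. PCA reduces these to K = 128 coordinates.

Numerical choices made here, and why:

* **Hann taper and PSD scaling.** Standard practice for power spectral
  estimates; the window is exposed through `compute_spectrogram()`.
* **Mean (not sum) aggregation of FFT bins** into the 28 linear bins,
  keeping units comparable if band edges leave unequal bin counts.
* **Leading edge dropped, not padded.** The first 27 time bins yield no
  patch; fabricating stimulus history would bias the earliest responses,
  and a silent stimulus lead makes the loss immaterial.
* **Raw PSD by default** with an optional `log(power + eps)` compression
  (`eps = 1e-12` relative to the maximum); both modes are recorded in the
  spectrogram object.
* **PCA is fit on the analyzed stimulus's own patches**, matching the
  single-stimulus experimental design rather than a held-out corpus.

## Responses

Event onsets are detected per trial at the first bin where the
fluorescence excursion reaches 10% of its peak (per contiguous
above-baseline excursion), then binarized into a trials × bins raster.
The regression target `y(t)` is the across-trial mean of the binary
raster — a per-bin event probability estimate in [0, 1] — paired with the
reduced patch whose window *ends* at `t`.

The train/test split is the first 70% versus last 30% of rows, and the
train block is cut into 3 contiguous folds (remainder bins to the earliest
folds). Contiguous blocks, rather than random rows, are deliberate:
adjacent rows share 27 of their 28 stimulus columns, so random splits
would leak stimulus history between train and test.

Reduced stimulus coordinates are standardized to unit variance per
component (train-block standard deviations) before fitting
(`align_responses(scale = TRUE)`). Raw PCA coordinates of PSD patches span
many orders of magnitude, which stalls any first-order optimizer started
at zero; standardization makes the optimization well conditioned without
changing the model class. All fitted parameters are mapped back through
the inverse scaling when features are extracted, so reported features are
in the unscaled spectrotemporal space.

## The encoding model

The MNE model gives the event probability for a reduced stimulus `s` as

$$P(\mathrm{event}\mid s) = \frac{1}{1 + \exp(a + s\cdot h + s^\top J s)}$$

with scalar `a`, linear kernel `h` and symmetric quadratic kernel `J`. At
its optimum on binary targets the model's expected mean rate,
event-triggered average and event-triggered covariance match their
empirical counterparts; the gradient components of the cross-entropy
objective in `a` and `h` are exactly the first two of those moment
mismatches, which the test suite exploits.

Fitting minimizes the average cross-entropy between `y` and the predicted
probabilities — with fractional, trial-averaged targets this is the
trial-summed Bernoulli likelihood up to a constant — plus a small ridge
penalty (`ridge = 1e-4` by default) on `h` and `J` that keeps the problem
well posed when the parameter count `1 + K + K(K+1)/2` exceeds the number
of training rows. Only the upper triangle of `J` is optimized, so symmetry
is structural. The optimizer is L-BFGS run in rounds of 10 iterations;
each cross-validation fold selects the round with the best held-out
unpenalized loss (3 rounds of patience), and the final model is refit on
the whole training block for the mean best round count. Early stopping is
the main regularizer: fully converged fits visibly inflate the noise
eigenvalues of `J`. A non-finite loss aborts with an error naming the step
budget.

### Evaluation and significance

Performance is the cosine similarity between predictions and the true
trial-averaged response on the held-out 30% (raw vectors by default;
`cosine_similarity(center = TRUE)` is available). Significance comes from
a shuffle null: the training responses are permuted over rows (the test
pairing untouched), the model is refit with the identical optimizer
budget, and the unshuffled test stimuli are predicted; 200 shuffles is the
default, and `evaluate_mne()` warns when configured below that, since the
null becomes coarse. The p-value is reported both as the literal
proportion of null similarities at or above the observed one and under the
`(r+1)/(n+1)` convention; the significance flag uses the literal
proportion at α = 0.05.

### Features

Receptive-field features are the linear kernel `h` and the eigenvectors of
`J`, back-projected through the PCA basis into the time–frequency plane.
An eigenvalue > 0 increases the exponent and therefore *decreases* event
probability (inhibitory); < 0 is excitatory. Eigenvector sign is fixed by
making the largest-magnitude element of the back-projected map positive;
numerically zero eigenvalues are not candidates.

No published criterion exists for calling individual features significant,
so the package states its own convention and records it in the output: the
shuffled fits are reused as a null, each null `J` is eigendecomposed and
its sorted eigenvalues pooled per rank, and a feature is significant when
its eigenvalue falls outside the central 95% band of its rank's null
distribution (the linear feature analogously via the norm of `h` against
the upper null quantile). Eigen-analysis and the null comparison happen in
the coordinates the model was fitted in (the standardized ones when
scaling is on) — rank-matching is calibrated there, whereas undoing the
scaling first lets the smallest-variance PCA components dominate the
sorted spectrum.

## Comparing features

Each feature map's modulation power spectrum is the squared magnitude of
its 2-D DFT, zero-frequency centred, with axes in cycles/s and cycles/kHz.
No window or padding is applied by default (features are already compact);
a padding factor is exposed. The unnormalized DFT convention means
`sum(power) = 784 * sum(map^2)`.

Feature sets are inspected in a 2-D embedding (`embed_features()`). The
default backend is PCA — deterministic and sufficient for the separation
checks in the test suite; a seeded UMAP backend (via the `uwot` package)
is available when installed. Event-property vectors (duration, area, rise
time, fall time, circularity; intensity measures excluded to avoid
indicator-expression artifacts) are z-scored per property, embedded, and
density-clustered with a Gaussian mixture whose component count is
BIC-selected (`mclust`); the noise label −1 is reserved in the interface.

## Subspace comparison

Pooled per population, the flattened significant features form a matrix
whose column space is orthonormalized by pivoted QR (numerically dependent
columns dropped at relative tolerance 1e-10, the retained rank recorded).
The k-th principal angle between two subspaces is the recursive maximum
cosine between unit vectors orthogonal to the previously selected
directions; the package computes it from the singular values of
$Q_a^\top Q_b$, with one refinement: for the small-angle half of the
spectrum the sine-based formulation (singular values of
$Q_b - Q_a Q_a^\top Q_b$) is used, because the arc-cosine of a near-unit
singular value cannot resolve angles below about 1e-4 degrees. The literal
recursive maximization is kept in the test suite as an independent oracle.
The "full stimulus space" in population comparisons is the span of the
retained PCA basis — the subspace the features inhabit by construction;
comparing in the full 784-dimensional ambient space is available as an
option by supplying a different basis.

## Synthetic data: what it emulates, and what it does not

`generate_usv_stimulus()` reproduces the *layout* of the experimental
stimulus: segments of 8 s of vocalization padded by 1 s of silence on each
side, a 20 s silent lead for baseline estimation, 250 kHz sampling, energy
confined to 45–110 kHz. Within segments it synthesizes 2–6
frequency-modulated sweeps per second (random start frequency, extent up
to 30 kHz, 30–150 ms duration, linear or sinusoidal FM, Hann envelopes,
fixed RMS) — qualitative mouse-USV statistics, with no claim of
bioacoustic fidelity and no attempt at real USV phonology.

Ground-truth encoding models are built from Gabor-like localized
time–frequency maps (localized features make recovery checks legible),
projected into the PCA space and orthonormalized by Gram–Schmidt so true
principal angles are exactly 0 or 90 degrees by construction. Eigenvalues
are calibrated against the actual patch ensemble so the quadratic term has
a chosen standard deviation (default 2.5), keeping probabilities inside
(0, 1) regardless of stimulus units. The default baseline event
probability is 0.3 per 8.192 ms bin, kept at or below 0.3 so rasters
resemble sparse calcium event trains; real per-bin event rates for
astrocyte functional units are not well characterized, so this default is
a plausible placeholder exposed in the configuration. Rasters are
independent Bernoulli draws per trial and bin — deliberately free of the
slow indicator kinetics, bursting, adaptation and correlated noise of real
recordings. Passing tests therefore demonstrate that the *analysis chain*
is correct and well calibrated under its own assumptions, not that real
astrocyte data will satisfy those assumptions.

## Problem sizes used by the test suite

The test and acceptance suites run a band-scaled stimulus regime — 25 kHz
sampling, a 4.5–11 kHz band, 512-sample FFT windows — which preserves the
entire analysis geometry (28 frequency bins, 28-bin windows, 784-dim
patches) at desk-scale cost. Sizes chosen for the deeper checks:

* parameter recovery: 6 segments (~5,800 stimulus bins), K = 16, one
  planted quadratic feature, 20 trials;
* shuffle-null calibration: 100 stimulus-independent units, K = 6, 360
  bins, 50 shuffles per unit;
* subspace recovery: 10 segments (~9,800 bins), two populations of two
  units each sharing one of two feature directions, 20 trials, 20
  shuffles per unit for the feature-significance null, pooling each
  unit's dominant significant feature (one feature is planted per unit).

## Known limitations

* The shuffle null permutes away the temporal autocorrelation of the
  trial-averaged response; fits to real (autocorrelated) targets have
  systematically broader `J` spectra than shuffled fits, so the
  eigenvalue-null convention is anti-conservative for weakly stimulus-
  locked units. Early stopping mitigates but does not remove this.
* Trial-averaged targets discard across-trial variability; no spike- or
  event-history terms are modeled.
* The embedding and clustering stages are exploratory plumbing around
  established libraries; their hyperparameters are package defaults, not
  calibrated values.
* The pipeline's structured container is an RDS file; portable delimited
  text is exported alongside for every table.
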