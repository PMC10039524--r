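---
title: "Methods: spiral-wave analysis, complexity, and snapshot synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spiral-wave analysis, complexity, and snapshot synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Disinhibited cortical tissue (4-aminopyridine with raised K+ and lowered
Mg2+) produces propagating waves on high-density multi-electrode arrays
(HD-MEAs): planar waves travelling in one direction and spiral waves
rotating around a fixed locus, the centre of mass.  `spiralmea` implements
the full analysis chain for such recordings: delta-band (1-4 Hz)
zero-phase filtering, artifact removal, 1-ms snapshot extraction,
instantaneous-phase and vector-field analysis, centre-of-mass and
winding-number estimation, participation-ratio (PR) and Levina-Bickel
(LBMLE) complexity, distance-dependent correlations, and a convolutional
adversarial model that synthesises activity snapshots.  Because raw slice
recordings are not publicly deposited, the package carries a seeded
phenomenological simulator that every downstream stage is validated
against.

# Coordinate conventions

One convention is used everywhere.  Rows increase downward, columns
rightward, indices are 1-based; channel order is column-major over the
grid.  Physical positions are `x = (col-1)*pitch`, `y = (row-1)*pitch`
(42 um pitch by default).  Angles are measured counter-clockwise in the
flipped-y frame (`theta = atan2(-(row-r0), col-c0)`), so figures drawn
with row 1 at the top look conventional.  The winding number traverses its
circle counter-clockwise in raw array coordinates; under this pairing a
spiral with positive arm count (counter-clockwise rotation) has winding
`+m`, so positive winding means CCW and negative means CW.

# The simulator and its stated world

A spiral wave is `v = A(rho) * E * T(rho) * cos(2 pi f t - m theta + k rho)
+ noise` with

* `A(rho) = amplitude * rho / (rho + dip_radius)` — the amplitude dip at
  the rotation core.  `dip_radius = 200` um makes the dip pronounced
  enough that the disk/annulus criterion (below) detects it reliably over
  background activity.
* `E` — a seeded log-normal envelope (Gaussian-correlated field, 200 um
  correlation length, log-SD 0.2), the "domains" of stronger and weaker
  participation seen in slice recordings.
* `T(rho) = exp(-(rho/R)^4 / 2)` with `R = 550` um — a flat-top spatial
  cut-off.  Real waves occupy a delimited domain around their core; without
  a cut-off the activity-weighted centre of mass of a near-uniform field
  sits at the grid centre, not at the rotation core, and no centre
  estimator could recover the programmed centre.  The quartic (rather than
  Gaussian) profile keeps the 250-500 um annulus at full amplitude — so
  the core dip remains measurable — while removing the far-field mass that
  would bias the centre.
* defaults `amplitude = 100` uV, `f` in the delta band, additive white
  noise SD 10 uV (10% of amplitude; extracellular recordings under a
  pro-epileptiform solution are far from clean).  The window slightly
  exceeds the programmed rotations (`duration = (cycles + 0.1)/f`), the
  way manually segmented waves include margins; this also keeps the cycle
  count away from the knife edge of its `floor`.

Planar waves are `A cos(2 pi f t - k (x cos a + y sin a))` plus the same
noise.  Baseline activity is a stationary Gaussian field with 150 um
spatial correlation (Gaussian kernel, generated on a 3-sigma padded grid so
opposite array edges are *not* wrap-around neighbours) and AR(1) temporal
correlation (0.15 s).  The 150 um scale — local co-activation over a few
cell diameters — gives baseline 6-snapshot stacks a pooled-SVD PR of about
22 on the full 64 x 64 grid, which brackets the planar rank-2 floor from
above and the richer spiral images from below, reproducing the ordering
reported for real tissue (spiral > baseline > planar).  Datasets
concatenate events over a continuous baseline background (waves ride on
background, as in slices), with 5 s gaps by default (about 7 events/min at
2.5 s mean durations); durations are truncated-normal (mean 2.52 s, SD
1.0 s, floor 0.6 s).

What the simulator does *not* emulate: multi-singularity interactions
(saddle waves), meandering cores, biophysical waveform shapes, electrode
drift, or the heavy-tailed broadband noise of real electrodes.  A green
recovery test therefore establishes that the estimators are correct on
coherent rotating fields with domain structure and realistic noise — not
that they would segment arbitrary slice recordings without threshold
adjustment.

# Preprocessing decisions

* The second-order Butterworth band-pass is designed from the analog
  prototype by bilinear transform (no DSP package ships with this R
  installation) and applied forward and backward with odd-reflection
  padding and steady-state initial conditions, giving zero group delay.
  The design was verified against an independent frequency-response oracle
  and, during development, against `scipy.signal`.
* Artifact replacement (samples with |v| > 200 uV) uses the per-channel
  mean over *non-artifact* samples; computing it over all samples would
  let the artifact contaminate its own replacement.  The all-samples
  variant remains available (`use_all_samples = TRUE`).  Filtering runs
  before artifact removal by default, matching the order the procedure is
  usually described in; both orders are trivially composable from the two
  functions.
* 1-ms snapshots are bin averages (not decimation), avoiding aliasing from
  the native 7.7 kHz rate.  With non-integer samples-per-bin the bins
  differ by one sample, so the stack mean equals the raw mean exactly only
  for integer division — the property is asserted in that case only.
* The band table implements delta as 0.1-4 Hz (a 4 Hz low-pass needs a
  small high-pass edge for numerical stability); the wave pipeline itself
  filters at 1-4 Hz.

# Wave identification

The published criteria were applied by visual inspection; the automation
and all thresholds here are package choices, config-exposed in
`wave_thresholds()`:

* (i) *broad phases*: mean per-frame circular resultant of phases over the
  electrodes within 12 grid units of the centre, threshold 0.4.  The
  restriction to the neighbourhood of the centre matters: far outside the
  active domain, phases follow the spatially coherent background and would
  mask the broad distribution of the wave itself.
* (ii) *rotation*: |median winding number| >= 1 on a circle of a quarter
  of the grid width (shrunk to fit), phases interpolated on the unit
  circle so wrapping is respected.
* (iii) *core dip*: mean |v| in a disk of 3 grid units below 0.8 of the
  6-12-unit annulus.
* (iv) *distance-dependent correlations*: negative, significant
  (p < 0.05) slope of binned mean correlation against electrode distance.
  The regression is weighted by bin pair count: over a short band-limited
  window the sparsest long-distance bins carry only a handful of
  effectively independent pairs and their means fluctuate wildly.

Criteria are evaluated about the *rotation core*: the centre of mass
(squared weights, robust to diffuse background mass) refined to the local
minimum of the smoothed time-averaged amplitude surface (`refine_core()`),
since the dip marks the core.  Both the Eqs-style centre of mass and the
refined core are reported.  The default centre-of-mass weights are |a|
(the "mass" reading of the formula — signed oscillatory voltage can sum to
zero); `signed` and `squared` are options.

Segmentation thresholds the array-mean amplitude envelope at the baseline
median + 3 MAD, where "baseline" statistics come from the lower half of
the envelope distribution so a high wave duty cycle cannot inflate the
threshold.  Excursions of at least 0.5 s (gaps < 0.25 s merged) are
classified individually.  Cycle counting fits the unwrapped-phase slope
over the central 80% of the window (analytic-signal edges are unreliable)
and floors `advance/2pi + 0.05`; the 0.05 guards the floor against
numerical jitter exactly at integer boundaries.  Vector fields use the
standard phase-gradient velocity `v = -(dphi/dt) grad(phi)/|grad(phi)|^2`
with mild complex-domain smoothing (sigma 1 grid unit) of the phase maps;
the planar-alignment statistic samples the central 70% of the window.

# Complexity

The decomposition behind the published PR values is ambiguous (6 snapshots
per wave, yet N-channel spectra and PR values far above the rank of a
6-sample covariance), so three labelled conventions are implemented:
pooled per-frame spatial SVD (default; defined for any frame count),
channel covariance (the only mode defined on arbitrary channel subsets,
hence used by `pr_vs_channel_count()`), and the uncentred snapshot Gram
matrix.  Every result records its mode.  LBMLE averages the k-NN
maximum-likelihood estimator over k = 5..15 (the estimator's standard
usage; no k is published) and, for wave segments, treats each 1-ms frame
as one point: frame-scale stochasticity then contributes to the estimate,
as it does in recorded segments.

A known limitation, deliberately not patched: the simulator's waves are
temporally coherent (a single rotation frequency), so their intrinsic
dimensionality is small and essentially independent of how many channels
or how many snapshots are analysed.  PR-versus-channel-count saturates
within a few channels instead of growing like sqrt(N) over hundreds of
channels, and pooled-SVD PR grows linearly in the snapshot count k (pooling
k near-identical spectra multiplies PR by k exactly), so dividing by
sqrt(N) or sqrt(k) does not produce the plateau reported for real
recordings, whose waves are high-dimensional.  The package computes and
reports both normalisations faithfully; the corresponding stabilisation
checks are expected to fail on synthetic data and are analysed rather than
forced.

# The adversarial snapshot model

No autodiff library is available for R in this environment, so the model
is self-contained: im2col convolutions, nearest-neighbour upsampling,
ReLU/leaky-ReLU/tanh activations, manual backprop, and Adam.  The
generator has a dense projection to a 4 x 4 seed map followed by six
hidden convolution + ReLU layers (upsampling interleaved until the target
size) and a tanh output; the discriminator has eight hidden convolution +
leaky-ReLU layers (stride-2 until a 4 x 4 map) and a tanh head.
Published choices kept as defaults: Adam, discriminator learning rate
2e-4, generator learning rate 1e-3, 10,000 iterations at full scale,
latent Gaussian noise with mean 0 and SD 25, 64 x 64 x 6 items built from
six evenly spaced snapshots per wave, each item rescaled to [-1, 1] with
the transform recorded.

Implementation decisions that are ours:

* the tanh discriminator head is mapped to a probability
  `p = (h + 1)/2` (clipped at 1e-6) before the log loss — a tanh output
  cannot feed `log D(x)` directly;
* the generator minimises the non-saturating surrogate `-E[log D(G(z))]`,
  which shares the minimax fixed point but has usable early gradients;
* Adam's beta1 is 0.5 (standard for adversarial training; 0.9 was
  unstable at every scale tried);
* the generator's input layer is initialised with gain `1/noise_sd` so
  that SD-25 latents produce O(1) activations instead of saturating the
  tanh output from the first step; output heads use gain 0.5;
* training begins with 60 discriminator-only warm-up updates so the
  generator faces a competent critic (and a meaningful gradient) from its
  first step; `d_every` can further throttle the discriminator;
* the discriminator stack is half the generator's width by default — a
  wide critic memorises small training sets and starves the generator;
* latent length defaults to 100 (unpublished), kernel 3, and layer widths
  follow standard deep-convolutional practice, all config-exposed;
* the generator emits 6-plane volumes; each plane is one snapshot.

The desk-scale profile used by tests and the acceptance script trains
16 x 16 single-plane items for a few hundred iterations; the full-scale
configuration exists but is not exercised by the test suite (one CPU).
Sample evaluation (`frechet_distance()`, `inception_style_score()`) works
against any pluggable feature embedding or classifier; no pretrained
network is downloaded or bundled.

# Numerical choices

Analytic signals use the FFT Hilbert weights (DC and Nyquist untouched).
Degenerate traces (zero variance) get phase 0 and a flag.  Random fields
are generated on 3-sigma padded grids to keep them stationary and free of
periodic wrap-around.  Spectra are clamped at zero before PR; an all-zero
spectrum is an error, not a zero.  LBMLE lifts exact duplicate points to
an infinitesimal distance.  The Frechet distance symmetrises and clamps
eigenvalues, adding diagonal jitter (with a warning) only if the cross
matrix is numerically non-PSD.  All stochastic stages draw their seeds
deterministically from a global seed and a stage label (`derive_seed()`),
and seeded generators restore the caller's RNG state.

# File formats

No HDF5 bindings are installed for R in this environment, so recordings
live in a plain-text container: a directory with `voltage.csv`
(channels x time) and `meta.json` (sampling rate, units, provenance, and
the full electrode layout), schema-validated on read.  Event tables and
ground truth are CSV/JSON; model checkpoints are a single JSON file
(architecture plus flat parameter arrays); pipeline configurations
serialise to JSON (no YAML parser is available).  `run_pipeline()` drives
simulate → preprocess → detect → complexity → (optional) adversarial
training from one configuration and emits a manifest with md5 checksums;
identical configurations reproduce identical checksums.
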