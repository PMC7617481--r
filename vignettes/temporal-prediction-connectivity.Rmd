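---
title: "Temporal prediction, Dale-constrained recurrence, and V1-like lateral connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal prediction, Dale-constrained recurrence, and V1-like lateral connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lateralpred)
```

## The model

`lateralpred` implements a normative account of lateral (recurrent)
connectivity in primary visual cortex: a single-layer recurrent network is
trained to predict the next frame of naturalistic movies from the current
and preceding frames, and the connectivity motifs that emerge among its
hidden units are compared with those measured between V1 neurons.

The state equation is

$$\mathbf{s}[t] = f\!\left(W_{in}\,\mathbf{u}[t] + W_{rec}\,\mathbf{s}[t-1] + \mathbf{b}_{rec}\right),
\qquad \hat{\mathbf{v}}[t] = W_{out}\,\mathbf{s}[t] + \mathbf{b}_{out},$$

with $f$ the ReLU, $\mathbf{u}[t]$ the flattened grayscale frame, and
$\hat{\mathbf{v}}[t]$ the predicted next frame. Dale's law is enforced in
the forward pass by re-parameterising every recurrent weight as
$w \leftarrow \pm|w|$ according to its presynaptic unit's fixed
excitatory/inhibitory label (90% / 10% of hidden units; 2,332 and 260 at
the full scale of 2,592 units on 36×36-pixel frames). Training minimises
the summed squared prediction error plus an L1 wiring cost over all three
weight matrices,

$$E = \sum_n\sum_t \left\lVert \hat{\mathbf{v}}_n[t] - \mathbf{v}_n[t+1] \right\rVert_2^2
  + \lambda\left(\lVert W_{in}\rVert_1 + \lVert W_{rec}\rVert_1 + \lVert W_{out}\rVert_1\right),$$

by Adam, with gradients propagated through the full recurrence
(`train_network()`; the analytic backward pass is checked against finite
differences in the test suite). Biases are not regularised — the loss as
written penalises weights only. Alternative objectives share the
architecture: denoising (3 dB input corruption), inpainting (eight random
8×8 masks per frame), and a sparse autoencoder (an additional
$\lambda_{act}\sum\lVert \mathbf{s}\rVert_1$ activity term); all three
reconstruct the *current* frame. A prediction-span variant widens the
readout to emit one frame per requested offset.

### Initialisation and constraint handling

The published description leaves initialisation open. We draw $W_{in}$ and
$W_{out}$ uniformly at scale $1/\sqrt{\text{fan-in}}$. For $W_{rec}$ we use
$1/\text{fan-in}$: under the sign constraint a column's weights all share
one sign, so the *sum* of magnitudes (not the root-mean-square) sets the
recurrent gain, and the smaller scale keeps the expected gain below one at
initialisation. The constraint is applied inside every forward pass (a
re-parameterisation, not a post-hoc projection), so the sign law holds at
every checkpoint by construction; the raw parameters carry a free sign
whose gradient follows the chain rule through $|w|$.

### First frames and targets

The hidden state starts at zero, and with offset $k$ the usable clip
shortens to $T-k$ prediction steps, so every target frame exists. During
training, Gaussian noise at 6 dB SNR is added to the *input* copy of each
clip (the prediction target stays clean); validation errors are computed on
clean inputs. SNR is defined as
$10\log_{10}(\mathrm{var(signal)}/\mathrm{var(noise)})$ over the whole
clip — the power definition is not printed in the source description, and
variance over all pixels and frames is the natural choice for zero-mean
clips.

## The synthetic movie corpus

Wildlife footage is not shipped; `generate_movie_corpus()` builds a
surrogate with the properties the model needs:

* **bandpass spatial statistics** — each frame's amplitude spectrum lives
  inside a retina-like annulus (default 0.02–0.25 cycles/pixel) with a
  1/f-like falloff; the precise cut-offs of the original preprocessing are
  cited to prior work rather than printed, so the defaults are chosen to
  sit well inside the Nyquist limit of a 36-pixel (or 16-pixel) patch;
* **locally coherent, globally heterogeneous motion** — two texture layers
  drift at independent velocities (0.5–2 pixels/frame) and are blended by
  smooth static masks. A single rigidly translating texture turned out to
  be a degenerate surrogate: with one global motion per clip the optimal
  predictor is a global Fourier phase shift, spatially localised receptive
  fields are never favoured, and the downstream physiology has nothing to
  measure. Real footage is only *locally* rigid — different surfaces move
  differently — and the two-layer blend restores exactly that property;
* **in-band generator noise** refreshed every frame, so that even a
  zero-drift clip has frame-to-frame variability.

Everything downstream of the generator treats clips identically whether
they are synthetic or user-supplied, so a real movie corpus can be
substituted wherever a list of `movie_clip` objects is accepted. What the
surrogate does *not* emulate — sharp edges and occlusions, luminance
nonstationarity, camera shake, object-level content — bounds what passing
tests show: they demonstrate that the pipeline recovers the
temporal-prediction connectivity phenomena under movie-like second-order
statistics, not that the specific published effect sizes transfer.

## Desk-scale study conditions

All of the package's own analyses run on a reduced profile
(`scaled_profile()` + `scaled_corpus_params()`): 16×16-pixel patches, 512
hidden units (10% inhibitory), 2,000 synthetic clips of 50 frames (1,800
train / 200 validation), batches of 50 clips, 30 epochs, Adam at learning
rate $10^{-3}$. The published learning rate of $10^{-4}$ belongs to a far
longer full-scale run; at desk scale it converges too slowly to be useful,
and $10^{-3}$ reaches a stable validation plateau in minutes on one CPU.
Epoch count and batch size are not printed in the source description and
are recorded here as the package's choices. The L1 strength keeps its
published default $\lambda = 10^{-6}$; `hyperparameter_sweep()` reproduces
the selection procedure (validation MSE over a $\lambda$ grid) at any
scale. The desk corpus rescales the bandpass band so the *cycles per
patch* match the full-scale configuration (0.72–9 cycles/patch, i.e.
0.045–0.45 cycles/pixel at 16 px); without this rescaling the 16-pixel
patches are dominated by sub-cycle luminance gradients that carry no
orientation structure.

## In-silico physiology

* **Receptive fields** (`response_weighted_average()`): responses to
  25,000 white-noise frames presented as one continuous sequence — the
  recurrent state is carried across frames, not reset, matching continuous
  presentation; the alternative is not stated in the source. The RWA is
  normalised by the summed response, making it invariant to response
  rescaling. The spatiotemporal variant stacks the past 7 frames;
  `temporal_summary()` reduces it to a normalised per-lag power profile
  and its centre of mass.
* **Gabor parameterisation** (`fit_gabor()`): Levenberg–Marquardt least
  squares with centroid/Fourier-peak initialisation and five jittered
  restarts. `rf_size` is the geometric mean of the fitted envelope sigmas
  (the source's "size" is not defined); inclusion requires
  `rf_size >= 0.5` px and fit correlation `>= 0.7`.
* **Tuning** (`grating_battery()`): drifting sinusoids over 6 log-spaced
  spatial frequencies (0.03–0.5 cycles/pixel), 5 log-spaced temporal
  frequencies (0.02–0.25 cycles/frame) and 16 directions — the printed
  ranges with a grid density of our choosing. The first 10 frames of each
  presentation are discarded as onset transient (whether the printed
  "mean response across 50 frames" includes onset is unstated; discarding
  makes preferred-stimulus estimates less initialisation-dependent). OSI
  and DSI use the standard contrast ratios; classification uses strict
  inequalities, so a DSI of exactly 0.8 counts as weakly selective under
  the stricter scheme. The modulation ratio fits a free-phase sinusoid at
  the known stimulus frequency and is reported only when that fit
  correlates with the trace above 0.9.
* **Connectivity** (`threshold_connections()`): edges where the absolute
  recurrent weight strictly exceeds the 95th percentile (linear
  interpolation) over all ordered pairs of included units, zero weights
  included in the pool. Absolute weight is used so that inhibitory edges
  are detectable. Rows are postsynaptic and columns presynaptic,
  consistent with the state equation. Degrees convert to pixels at
  6°/pixel (from the printed 15° = 2.5 px); short range is < 2.5 px, long
  range 5–9.17 px.
* **Visual-space normalisation** (`normalize_visual_space()`): translate
  the postsynaptic centre to the origin, rotate by $\theta - \pi/2$. After
  this rotation the preferred-orientation axis is vertical, so co-axial
  means $|y| > |x|$; for direction analyses the preferred direction maps
  onto $+x$ and "ahead" means $x > 0$. The printed matrices do not fix the
  axis semantics; these choices make the quadrant analyses reproducible
  and are arguments, not constants.
* **Statistics**: the Cochran–Armitage trend z (two-sided; integer
  scores) is written out directly and cross-checked in the tests against
  both `stats::prop.trend.test` and a permutation oracle;
  `shuffle_control()` permutes recurrent weights among the ordered pairs
  of the analysis subset (exactly preserving the weight multiset) and is
  used only for connectivity analyses, never for responses.
* **Perturbations**: ablation replaces selected E→E edges with the median
  connected E→E weight. Tuning windows for the ablation classes follow the
  profile bin conventions (co-tuned < 22.5°, orthogonal > 67.5°,
  co/anti-tuned within 22.5° of the same or opposite direction). The
  silhouette analysis presents three grating classes offset by 0°, 11.25°
  and 22.5°, sweeps the base orientation around the circle, and scores
  time-averaged hidden vectors in the full hidden space (per-frame points
  and 2-D embeddings are display choices, not the statistic); stimulus
  noise uses the same SNR machinery at the quoted 0 and −9.5 dB levels.
* **Prediction-error units**: a unit is `pure_PE` (strict) when, for some
  stimulus condition, it responds on the deviant frame at ≥ 5 deviant
  positions while staying at or below machine zero on the matching frames
  of both controls — rectified units can be exactly silent, so "no
  response" is implemented as ≤ machine epsilon. The loose criterion
  requires the deviant response to strictly exceed three times the larger
  control response at the same number of positions. The "any condition"
  reading of the ambiguous quantifier is implemented. One frame per
  pattern element is assumed in the oddball sequences (the per-element
  duration is not printed).
* **Neural fitting** (`fit_ln()`): activity → first `min(200, rank)`
  training-set principal components → Lasso over 40 log-spaced strengths
  in $[10^{-5}, 10^1]$, selected by mean validation CC$_{norm}$ across
  k = 5 folds (k is not printed; 5 is the conventional default) → a
  rectified sigmoid $\max(0, a/(1+e^{(c-x)/b}) + d)$ by nonlinear least
  squares, with a linear-only fallback when the sigmoid degrades
  validation CC$_{norm}$ beyond a small tolerance. CC$_{max}$ uses the
  signal-power formulation
  $\mathrm{CC}_{max} = \sqrt{\mathrm{SP}/\mathrm{var}(\bar y)}$ with
  $\mathrm{SP} = (\mathrm{var}(\sum_i y_i) - \sum_i \mathrm{var}(y_i)) / (N(N-1))$
  — the cited estimator family includes two variants and this one is exact
  on constructed decompositions, which the tests exploit. Neurons with
  non-positive estimated signal power (noise-to-signal ratio ≥ 60, or
  undefined) are excluded.

## What the desk-scale experiments show

At the reduced scale the package reproduces the qualitative phenomena:
training roughly halves the next-frame error of the persistence baseline
(copying the current frame) and clearly beats the untrained network; a
subpopulation of units becomes orientation- and direction-selective to
drifting gratings; among selective excitatory pairs, connection
probability is highest for similar orientation preferences and lowest for
orthogonal ones, and the weight-shuffle control flattens that profile;
ablating co-tuned connections degrades next-frame prediction more than
ablating the same number of orthogonally tuned connections; and
bar-stimulus ablation deficits correlate with stimulus size while
dot-stimulus deficits do not. At this scale the like-to-like probability
bias is a weak effect: it is present under the packaged study seed but
its sign can flip across training realizations, whereas the ablation
asymmetry and the bar/dot contrast were directionally consistent across
every seed we examined. Treat the desk-scale motif as a demonstration
that the pipeline can detect the effect, not as evidence about its
universality at this network size.

One desk-scale limitation deserves emphasis. After roughly a thousand
optimiser steps the learned input filters are oriented but still curved
and spatially distributed, so the published receptive-field inclusion
criteria (Gabor fit r ≥ 0.7, size ≥ 0.5 px) retain only a few percent of
units — far from the published ~70%. The criteria, the Gabor fitting and
the spatial analyses that depend on fitted centres (co-axial versus
co-orthogonal sectors, ahead/opposite densities, range classes) are all
implemented and validated against planted ground truth and constructed
geometry, but the trained desk-scale model itself does not yet populate
them; tuning-gated analyses (the like-to-like motif, ablation classes) do
not require fitted centres and are measured on the trained model
directly. The published headline numbers (CC$_{norm}$ tables,
connectivity scores, unit-type percentages, prediction-error prevalences)
belong to the full-scale model trained on real footage and real
recordings and are not reproduced here; `scripts/acceptance.R` recomputes
the desk-scale quantities from scratch on every run, and the test suite
asserts only the directional and calibration properties listed above.

## Numerical choices and degenerate inputs

Percentiles use R's default linear interpolation; thresholding is strict,
so an all-equal weight matrix yields an empty graph. Ties in preferred
gratings are broken by first index and flagged. Zero-response units have
undefined receptive fields and are flagged rather than silently dropped;
all-zero maps fail the Gabor fit with `fit_r = NA` and are excluded by the
criteria. OSI/DSI with zero denominators, CC$_{norm}$ with zero-variance
predictions, and trend tests with degenerate margins all return flagged
`NA`/unit p-values rather than errors. Training aborts with a diagnostic
when the loss stops being finite. All randomness flows through explicit
integer seeds; generators restore the caller's RNG state.

## Known limitations

The surrogate corpus has stationary Gaussian texture statistics; effect
sizes measured on it need not transfer to natural movies. The desk-scale
model is 2× overcomplete (512 units on 256 pixels) rather than the
published ratio, and its training length is set by CPU budget, not by
convergence of the connectivity score. The reference connectivity profiles
shipped under `inst/extdata/` are synthetic stand-ins with the qualitative
published shapes, intended to exercise `connectivity_score()`; real
digitised profiles can be supplied in the same CSV schema. The LN stage is
exercised on synthetic reference neurons with a known noise decomposition,
not on recorded spike trains.
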