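---
title: "Methods: terminal segmentation, receptive-field mapping, and optomotor quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: terminal segmentation, receptive-field mapping, and optomotor quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymotion)
```

`flymotion` implements the computational chain used to characterize
direction-selective motion processing in the fly visual system: automated
extraction of T4/T5 axon terminals from two-photon calcium movies,
reverse-correlation estimation of spatiotemporal receptive fields (STRFs),
flash and moving-bar response metrics, optomotor turning quantification on
a spherical treadmill, and synapse-table summarization from a proofread
connectome. Because every stage is exercised on synthetic data with
planted ground truth, this vignette describes both the analysis models and
the forward models that generate the test data, and is explicit about what
the recovery tests do and do not establish.

## The forward model: LN neurons and rendered movies

The synthetic generator simulates neurons as linear–nonlinear (LN)
cascades. The linear stage is separable: a spatial Gaussian receptive
field (center in screen degrees, width `rf_sigma`) sampled at the stimulus
bar centers, and a biphasic temporal filter (`biphasic_filter()`) with a
fast positive ON lobe and a delayed negative OFF lobe, the shape seen in
medulla feedback neurons. The drive then passes through a threshold-linear
rectifier `max(x - threshold, 0)` and a single-exponential
calcium-indicator kernel (default τ = 0.25 s, a GCaMP6f-like decay; the
indicator model is a package choice since no specific kinetics are
prescribed by the measurements it emulates), plus optional Gaussian noise.

Two simplifications are deliberate:

* **Moving-edge/bar drive.** For motion stimuli the per-epoch drive is an
  idealized raised-cosine transient timed to the moment the edge front
  crosses the receptive-field center, with amplitude
  `gain × direction_modulation × contrast_modulation`. The full 2-D screen
  convolution is computed only for ternary noise. Direction/contrast
  selectivity indices depend only on per-epoch peak ratios, so this
  idealization is exactly what those recovery targets need, at a fraction
  of the cost.
* **Direction tuning shape.** The forward model uses a raised cosine:
  modulation 1 at the preferred direction and `1 − dsi_true` at the null,
  so the planted `dsi_true` is, by construction, the DSI that the
  measurement formula `(PD − ND)/PD` should report. The analysis side
  never assumes this shape — DSI recovery is therefore a non-circular
  check — but tuning *width* is not a recovery target for the same reason.

Angles are counterclockwise with 0° = rightward motion, everywhere. The
screen is 80° azimuth × 55° elevation at 1°/cell. Defaults of
15 Hz acquisition and 0.5 µm/px sit inside typical two-photon operating
ranges; pixel size is a required parameter of the segmentation because it
converts cluster pixel counts into the micrometer² area constraint.

Movies place disjoint square terminal footprints on the pixel grid and
render `F = baseline_f0 · (1 + dF/F) + noise` on terminal pixels and a
(configurable, darker) background level elsewhere, clipped at zero —
fluorescence cannot be negative, which also means model gains must keep
dF/F above −1 for exact round-trips. Continuous noise stimuli integrate
much more drive than a single edge transient, so the pipeline rescales the
gain when rendering noise-block movies of the same neurons.

## dF/F and baselines

`compute_dff()` subtracts a background signal, then computes
`(F − F0)/F0` with one of three baseline conventions: the mean of a
non-stimulus epoch before stimulation (the default for terminal
segmentation data), the whole-trace mean, or the mean over gray
interleaves of a noise stimulus. The conventions genuinely differ on
responsive traces (a step trace is the test case) and agree on constant
ones. Traces are linearly interpolated for resampling (`resample_trace()`;
10 Hz before cross-fly averaging, or edge-value-holding extrapolation to
20 Hz for receptive-field mapping). Trial averaging follows the hierarchy
repeats → ROIs within fly → flies, so each fly contributes equally to
population means regardless of its ROI count.

## Automated terminal segmentation

The segmentation chain is:

1. **Foreground**: the movie's time-mean image is Gaussian-filtered
   (σ = 1.5 px) and thresholded by Otsu's method. Otsu is computed over a
   256-equal-width-bin histogram spanning the observed range, with ties
   broken toward the lowest qualifying bin edge — fixed binning makes the
   threshold reproducible across float inputs, and the implementation is
   verified against an exhaustive search over all cuts.
2. **Background guard**: the mean of the non-foreground region is the
   background signal, and foreground pixels whose baseline does not exceed
   it by more than three standard errors of a background time-mean are
   dropped. Smoothing inevitably bleeds bright structure into neighboring
   mask pixels; those pixels carry no signal of their own, and their dF/F
   would be a division by approximately zero.
3. **Responsiveness**: after trial-averaging the responses to the
   four-direction ON/OFF edge epochs, pixels must show a peak above
   mean + k·SD of the full trial-averaged trace (k = 2, or 3 when the
   pixels feed receptive-field mapping). The SD is taken after trial
   averaging; on white-noise-only traces this filter is intentionally
   weak (a long noise trace almost always peaks above 2 SD), which is why
   the background guard above matters.
4. **Selectivity**: per pixel, PD is the direction with the largest peak
   response at the preferred contrast, ND its 180° opposite; PC/NC are the
   analogous contrasts. DSI = (PD − ND)/PD and CSI = (PC − NC)/PC, with
   negative ND/NC peaks clipped at zero so both indices live in [0, 1];
   pixels with non-positive PD or PC are dropped and counted. The frame of
   the PD-epoch peak becomes the pixel's response-timing feature.
5. **Clustering**: within each (contrast class, layer) group, pixels are
   clustered by average-linkage agglomerative clustering on
   `(x, y, time_weight × t_pd_peak)`. Mixing pixel coordinates and frame
   indices in one Euclidean distance needs a weight; the default
   `time_weight = 1` (one frame ≡ one pixel) is exposed in configuration
   and is the largest single reconstruction uncertainty in the package.
   Candidate cut heights are exactly the dendrogram merge heights (the
   partition is piecewise constant between them, so nothing else needs
   scanning); the chosen height maximizes the number of clusters with area
   in 1–6.5 µm², and **ties go to the largest height**. The coarsest of
   the equally-good partitions keeps terminals whole; cutting at the
   smallest tied height instead fragments a terminal-sized block into one
   in-range fragment plus debris and reports the fragment's centroid.
   Out-of-range clusters are discarded. Layer labels (A–D, the four
   direction-specific lobula-plate strata) come from a user-supplied
   region mask, since synthetic data has no anatomy; the area optimization
   runs per (contrast, layer) group, which is one of two readings of the
   original procedure and is flagged as an interpretation.
6. **Matching**: cluster masks are saved and re-applied to later
   recordings of the same cells by pixel identity, with a report of mask
   pixels falling outside the later recording's foreground.

## Receptive fields by reverse correlation

The stimulus is ternary white noise: 12 bars of 5° × 60°, each switching
independently among contrast −1, 0, +1 with equal probability at 20 Hz,
for 500 s. The STRF is the response-weighted stimulus average over a 2 s
window (40 lags):

$$STRF[\tau, b] = \frac{1}{T-\tau}\sum_{t=\tau+1}^{T} r_t\, s_{t-\tau, b},$$

with the response mean-centered first. Normalization is per lag — each lag
divides by its own term count — which matches the printed estimator; a
fixed divisor would differ by less than `n_lags/T`. Validity is assessed
by convolving the STRF with the stimulus and squaring the Pearson
correlation between prediction and measured response over the region where
a full window exists (the first 2 s are discarded to avoid edge effects);
"R²" is taken as squared Pearson correlation, the standard reading where
no other definition is given. STRFs with R² < 0.26 are discarded — the
threshold is adopted as-is from the original pipeline's visually chosen
gate — and survivors are averaged with R² weights, optionally after
shifting each STRF along the bar axis so its peak bar is centered
(population averaging of aligned receptive fields). Only pixels with
CSI > 0.5 feed STRF estimation, which removes values never, rows only.

The temporal filter is extracted either as the time course at the
maximal-|weight| bar (default, consistent with the spatial slice used for
width fitting) or as the mean over bars; the phrase "averaging along the
time axis" admits both readings and the mode switch records each without
guessing intent. The ON peak is the lag of maximal positive correlation.
The spatial profile at the lag of the global |weight| maximum is fit with
a Gaussian in degree coordinates and FWHM = 2√(2 ln 2)·σ is reported;
profiles at or below one bar width are flagged sub-resolution.

What recovery can and cannot target: reverse correlation of a calcium
signal estimates the *effective* filter of the whole cascade, including
the indicator kernel. `strf_ground_truth()` therefore exposes the
temporal filter convolved with the calcium kernel (times the bar-sampled
spatial Gaussian) as the comparison object. Recovery of the raw membrane
filter is not claimed and not tested. Likewise the ≥ 0.9 prediction-R²
recovery level holds in the linear regime (rectifier disabled); with
half-wave rectification at zero the best achievable linear prediction of
the rectified response caps near R² ≈ 0.73 for Gaussian drive, so
rectified configurations are tested for the 0.26 gate, not for 0.9.

## Flash and tuning metrics

Flash steps are peak-minus-baseline differences over 2 s windows around
light onset/offset; time-to-peak is measured from onset within the ON
epoch. The decay constant comes from a least-squares fit of `A·e^{bt}`
over the window ending 3 s after onset and is reported only when
negative. The fit is anchored at the post-onset peak by default — the
decaying segment is what the exponential describes; "the response 3 s
after the onset" is ambiguous about the start, so onset-anchoring is also
available.

Direction tuning uses the circular resultant
`L_dir = |Σ R(θ_k) e^{iθ_k} / Σ R(θ_k)|`; its magnitude is 1 minus the
circular variance, its angle the preferred direction. Negative responses
are clipped to zero before the vector sum, since the circular-variance
interpretation needs non-negative weights.

## Optomotor behavior

Yaw traces (120 Hz) are signed so that turning with the stimulus is
positive; responses to leftward epochs are sign-inverted and pooled with
rightward ones before per-fly trial averaging. Flies with mean forward
speed < 3 mm/s, or with negative mean signed yaw over the motion windows
("turning against the stimulus", operationalized as that sign), are
rejected with logged reasons. For single edges (0.75 s at 192°/s) the
declining phase is the OLS slope over 0.45–0.75 s after motion onset. For
paired edges (2 × 0.75 s or 2 × 0.5 s at 240°/s, back to back, 1.5 s dark
between epochs), per fly: V_peak is the mean of the 8 highest
trial-averaged instantaneous velocities over the first edge [0, D], and
V_lowest the mean of the 8 lowest over the first 0.25 s of the second
edge — a window consistent with both printed epoch variants. Percent
recovery = (V_peak − V_lowest)/V_peak × 100, computed per fly before any
cross-fly statistics. The first-edge V_peak window is read as [0, D]; the
printed parenthetical that could be read as two alternative windows is
taken to list the two epoch-duration variants instead, and that decision
is recorded rather than asserted as authorial intent. Group differences
use two-tailed pooled-variance Student's t tests against two genetic
controls, significant only when both comparisons reject.

The simulated cohorts drive yaw as direction × (kernel summed over edge
onsets) + noise. The control kernel is a compact-support raised-cosine
bump (0.1 s latency, 0.5 s width) — it genuinely returns to zero inside
the dark interleave, so noiseless control recovery is exactly 100%. The
"silenced" kernel shares the rise but decays with a long exponential tail
(τ = 1.5 s), producing sustained turning, recovery far below 100%, and a
shallower declining-phase slope. Latency and width were chosen once as
behaviorally plausible values and are parameters of `turning_kernel()`.

## Connectome summaries

Synapse tables (pre/post type and cell id, count, proofread flag) are
filtered by removing rows with a missing proofread flag first, then rows
with fewer than 3 synapses. Per reference cell, the percentage of its
synapses with each partner type is computed in each direction; the
summary is mean ± SEM across reference cells. Partner types connected to
fewer than 70% of reference cells (≥, configurable — the original rule
does not print the boundary case) are hidden from the display table but
**kept in every cell's normalization**: the displayed percentages describe
each cell's full synaptic budget, not a renormalized subset. The fixture
generator plants exact partner percentages plus sub-threshold and
unproofread rows, so the filters' effect is testable to rounding error.

## Numerical choices and degenerate inputs

* Otsu on constant input, empty movies, misaligned responses, and
  zero-variance predictions raise informative errors (or return 0 with a
  warning where the quantity has a natural value).
* Gaussian and exponential fits run through `nls` with closed-form
  starts (log-linear for decays, moment-based for spatial profiles);
  zero-residual fits keep the best iterate, divergent fits return NA with
  a diagnostic rather than stopping a batch.
* Cluster ids are assigned after sorting by (contrast class, layer,
  centroid), so partitions are invariant to pixel input order.
* All generators take explicit seeds and restore the caller's RNG state;
  identical seeds give bit-identical stimuli, movies, traces and tables.

## Problem sizes and what the tests show

The bundled analyses and tests run at the study's native stimulus scales
(500 s of 20 Hz noise for receptive fields; 48 × 48 px movies with 20
planted 2.25 µm² terminals; cohorts of 8–10 flies at 120 Hz; synapse
tables of tens of rows), sizes at which the full suite completes in a few
minutes on one core. Passing recovery tests show that the estimators
invert the package's own forward models under realistic noise — they do
not certify performance on real recordings, where motion artifacts,
neuropil contamination, non-Gaussian noise, overlapping terminals and
anatomical layer assignment (all outside this package's scope, and the
first two explicitly delegated upstream) add failure modes the generator
does not emulate.
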