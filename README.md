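# flymotion

Analysis pipeline for motion vision in the fly: two-photon calcium
imaging of direction-selective neurons, optomotor behavior on a spherical
treadmill, and connectome synapse-count summaries — with a synthetic-data
generator that plants known ground truth so every stage can be validated
end to end without any recordings.

## Who this is for

Labs quantifying T4/T5-pathway physiology and behavior face a standard
chain of computations: turn fluorescence movies into dF/F, find axon
terminals automatically, score direction and contrast selectivity, map
receptive fields against white noise, and reduce treadmill turning traces
to interpretable statistics. `flymotion` implements that chain as tested,
seeded, composable R functions, and pairs each estimator with a forward
model so the whole pipeline can be checked by parameter recovery.

## The core computations

**Terminal segmentation.** Foreground pixels come from Otsu-thresholding
the Gaussian-smoothed (σ = 1.5 px) mean image. Responsive pixels (peak >
mean + k·SD of the trial-averaged trace, k ∈ {2, 3}) are scored per pixel:

    DSI = (PD − ND) / PD        CSI = (PC − NC) / PC

with PD/ND the peak dF/F in the preferred direction and its 180°
opposite, PC/NC the analogous contrasts. Pixels are then grouped by
average-linkage hierarchical clustering on (x, y, t_peak), cutting the
dendrogram at the merge height that maximizes the number of clusters
with area in 1–6.5 µm² — the size of single T4/T5 axon terminals.

**Receptive fields.** Against ternary white noise (12 bars, 5°, contrasts
{−1, 0, 1} at 20 Hz, 500 s), the spatiotemporal receptive field is the
response-weighted stimulus average over a 2 s window,

    STRF[τ, b] = 1/(T − τ) · Σ_t  r_t · s[t − τ, b],

validated by convolving it with the stimulus and squaring the Pearson
correlation with the measured response (discard below R² = 0.26), then
averaged across cells with R² weights. The temporal filter's ON-peak
latency and the FWHM of a Gaussian fit to the spatial profile
(FWHM = 2√(2 ln 2)·σ) summarize each field.

**Tuning.** The circular resultant
`L_dir = |Σ R(θₖ)e^{iθₖ} / Σ R(θₖ)|` gives tuning sharpness (1 − circular
variance) and preferred angle.

**Behavior.** Signed yaw traces are pooled across mirror-symmetric
stimuli, flies failing QC (forward speed < 3 mm/s, turning against the
stimulus) are rejected, and for paired-edge stimuli each fly's

    % recovery = (V_peak − V_lowest) / V_peak × 100

measures how completely turning returns toward zero between two edges
(V_peak: mean of the 8 highest velocities during the first edge;
V_lowest: mean of the 8 lowest in the early second edge). Groups are
compared with two-tailed Student's t tests against two genetic controls.

**Connectome.** Synapse tables are filtered (proofread rows only,
≥ 3 synapses), and per-cell partner percentages are summarized as
mean ± SEM, displaying partners connected to ≥ 70% of reference cells
while keeping all partners in each cell's normalization.

## Worked example

Plant 20 model-neuron terminals (2.25 µm² each) in a noisy movie
responding to ON/OFF edges in four directions, then recover them:

```r
library(flymotion)

sim  <- simulate_terminal_recording(n_terminals = 20, noise_sigma = 20,
                                    seed = 1)
feats <- pixel_selectivity(sim$movie, k_sd = 2)
seg   <- cluster_terminals(feats, pixel_size = 0.5,
                           area_range = c(1, 6.5))
length(seg$clusters)
#> [1] 20
range(vapply(seg$clusters, function(cl) cl$area_um2, 0))
#> [1] 1.75 2.25
```

All 20 planted terminals are recovered as clusters inside the allowed
area range (at this noise level one cluster loses two edge pixels, hence
the 1.75 µm² minimum); centroids land within 0.32 px of the planted
positions. Receptive-field recovery for a neuron with a planted 15° FWHM
from 500 s of ternary noise:

```r
tn   <- make_ternary_noise(12, 20, 500, seed = 1)
m    <- neuron_model(rf_sigma = 15 / (2 * sqrt(2 * log(2))),
                     temporal_filter = biphasic_filter(20),
                     rectifier_threshold = -Inf, gain = 2)
resp <- simulate_ln_response(m, tn)$response
s    <- reverse_correlate(resp, tn)
strf_prediction_r2(s, tn, resp)
#> [1] 0.9505565
spatial_fwhm(s, bar_width = 5)$fwhm
#> [1] 15.51902
```

The estimated field predicts the response with R² = 0.95 and the spatial
width is recovered to 0.5° of the planted 15°. The numbered drivers under
`analysis/` run the full study — simulation, segmentation, receptive
fields, behavior, connectome — and write their tables under `results/`;
stage 4, for instance, prints

```
control1  10/10 flies pass QC, recovery 100.7 +/- 0.1 %
control2  10/10 flies pass QC, recovery 100.6 +/- 0.1 %
silenced  10/10 flies pass QC, recovery 30.4 +/- 0.2 %
silenced vs both controls: p = 1.3e-36 / 1.4e-36 -> significant
```

(recoveries can exceed 100% by a whisker when noise pushes V_lowest
slightly negative)

showing that the fast-decaying (control) kernel recovers fully between
paired edges while the sustained kernel does not — the behavioral
signature of slowed response decline.

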