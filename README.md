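# ringbump

Circular population-vector analytics and plastic ring-attractor
simulation for the *Drosophila* head-direction system.

The fly's compass lives in the ellipsoid body: EPG head-direction
neurons tile the donut-shaped neuropil in 16 angular wedges, and their
population activity forms a single "bump" whose angular position
encodes heading. Visual ring (ER) neurons inhibit every wedge, and
plasticity at ER→EPG synapses tethers the bump to visual landmarks at
an arbitrary, fly-specific offset. This package implements the
analysis and modelling stack for studying that tethering:

- **Synthetic data** — seeded generators for walking behavior
  (Ornstein–Uhlenbeck rotational velocity), 16-wedge fluorescence
  sessions (von Mises bump, photobleaching, arena-light background,
  indicator delay), optogenetic pairing protocols (8 locations × 5
  repeats), branched neuron skeletons and annular neuropil meshes.
- **Preprocessing** — cross-correlation motion correction, wedge-ROI
  extraction, the log-domain detrend
  `ŷ_k = exp(β₂ t + β₁ log y_bg + β₀)`, z-scoring with temporal
  (σ = 100 ms) and circular spatial (σ = π/16 rad) smoothing, and
  behavior alignment with the −200 ms shift.
- **Bump analytics** — the population vector average
  `PVA_t = (1/16) Σ_k y_{k,t} e^{iπk/8}`, bump–cue offsets
  `o_t = ∠ e^{i(∠PVA_t − ∠cue_t)}`, the mean offset vector
  `Ō = (1/T) Σ_t e^{i o_t}` whose length `‖Ō‖ ∈ [0, 1]` measures
  tethering (1 − circular variance), remapping error
  `(|∠Ō₀| + |∠e^{i(∠Ō_π − π)}|)/2`, heading-aligned profiles, lag
  scans, binned statistics and opto-response matrices.
- **Plasticity model** — a 32-unit rate-model ring attractor with
  velocity-integrating drive and plastic inhibitory visual input under
  *presynaptically*-gated (`ΔW_ji = ε a_j (r* − r_i)`) or
  *postsynaptically*-gated (`ΔW_ji = ε r_i (a* − a_j)`) learning, plus
  the closed-loop/dark/closed-loop recall and opto-pairing experiment
  drivers that discriminate the two rules.
- **Connectome geometry** — PCA ring coordinate frames for neuropil
  meshes, local center-of-mass corrections, iterative convex-hull
  peeling, and Dijkstra cable distances between synapse classes on
  weighted skeleton graphs (SWC in, candidates within a 10 μm
  Euclidean radius).

## Worked example

Simulate a six-minute closed-loop session with a known bump–cue offset
of π/3 ≈ 1.047 rad, push it through the full preprocessing chain, and
recover the offset:

```r
library(ringbump)

cfg <- synthConfig(seed = 1, duration = 360, bumpCueOffset = pi/3)
beh <- genWalk(cfg, "closed_loop")
roi <- genImaging(beh, cfg)
roi
#> RoiSession (raw): 16 x 3600 volumes @ 10 Hz

det  <- detrendSession(roi)
norm <- normalizeSmooth(det$session)
al   <- alignBehavior(norm, beh, shift = -0.2)
o    <- bumpCueOffset(pvaSeries(al$roi), cueAngle(al$behavior))
o
#> OffsetSummary: 3598 timepoints, mean angle 1.054 rad, vector length 0.989
```

The recovered mean offset (1.054 rad) matches the configured π/3 to
well under half a wedge, and the vector length 0.989 says the offset
was near-constant throughout — a tightly tethered bump. The detrend
coefficients recover the generator's photobleaching rate
(β₂ ≈ −0.0022 s⁻¹ against a 1/300 s⁻¹ forward model that also couples
the background artifact):

```r
round(det$fit@coefficients[1:3, ], 5)
#>          beta0   beta1    beta2
#> roi_01 0.02264 0.43402 -0.00211
#> roi_02 0.04697 0.42293 -0.00221
#> roi_03 0.05438 0.44656 -0.00219
```

A single recall experiment — train the plastic network in closed loop,
run it through darkness, return to closed loop:

```r
r <- runDarkRecallExperiment(seed = 2, rule = "presynaptic")
r$vectorLengths
#>       cl1      dark       cl2
#> 0.6799600 0.7422534 0.6724342
r$deltaOffset
#> [1] 0.3331776
```

The offset change across the dark period (0.33 rad, about one wedge
and a half) is far below the π/2 chance level: the presynaptically
gated network stored its visual map through darkness, because with no
ER activity its learning rule cannot touch the weights.
`darkStabilityExperiment()` repeats this paired across seeds and rules
and shows the postsynaptically gated variant loses the map.

## Package layout

| Area | Files |
| --- | --- |
| S4 classes and accessors | `R/AllClasses.R`, `R/AllGenerics.R` |
| Synthetic data | `R/synth-config.R`, `R/synth-generate.R` |
| Preprocessing | `R/preprocess.R` |
| Bump analytics | `R/pva.R`, `R/profiles.R` |
| Ring-attractor model | `R/model.R`, `R/experiments.R` |
| Connectome geometry | `R/connectome.R`, `R/skeleton.R` |
| File formats (TSV/JSON/SWC/OBJ) | `R/io.R` |

The methods vignette (`vignettes/ring-attractor-analytics.Rmd`)
documents the model, its assumptions, every tunable parameter and the
design decisions in detail.
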