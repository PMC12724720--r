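---
title: "Head-direction bump analytics and gated inhibitory plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head-direction bump analytics and gated inhibitory plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringbump)
```

# The scientific problem

The *Drosophila* ellipsoid body hosts a ring attractor: EPG
head-direction neurons arranged in 16 angular wedges carry a single
bump of activity whose position encodes the fly's heading. GABAergic
visual ring (ER) neurons synapse onto every wedge, and plasticity at
those inhibitory synapses binds visual landmarks to headings at an
arbitrary per-fly offset. The package provides (i) the circular
statistics used to quantify that binding in wedge-resolved calcium
imaging, (ii) the imaging preprocessing that precedes them, (iii) a
ring-attractor network with two candidate gated plasticity rules, and
(iv) the connectome geometry used to relate synapse positions on
skeletons to the ring. Everything runs on synthetic data generated
in-package, so every claim here is reproducible from a seed.

# Circular statistics

All angles are wrapped to $[-\pi, \pi)$ through the complex
exponential, $\mathrm{wrap}(x) = \operatorname{Arg} e^{ix}$; there is
no ad-hoc modulo arithmetic anywhere, so wrapped sums, differences and
means are consistent across the package.

The population vector average at time $t$ is
$$\overline{PV}_t = \frac{1}{16}\sum_{k=1}^{16} y_{k,t}\, e^{i\pi k/8},$$
with wedge $k$ fixed at angle $\pi k/8$ (wedge 16 at $2\pi \equiv 0$).
Its angle decodes the bump position and its modulus the bump strength.
Z-scored (hence possibly negative) fluorescence feeds the sum
unchanged — no clipping. The bump–cue offset is
$o_t = \operatorname{Arg} e^{i(\angle\overline{PV}_t - \angle
\mathrm{ref}_t)}$ with the cue as reference in closed loop and the
ball angle in darkness; its mean resultant vector
$\bar O = \frac1T\sum_t e^{i o_t}$ has length
$\lVert\bar O\rVert = 1 - \text{circular variance}$: exactly 1 when
the offset never changes, exactly 0 when offsets are spread uniformly.
Both identities are asserted as tests and recomputed by the acceptance
script.

The remapping error after enforcing offsets of 0 and $\pi$ in two
pairing sessions is
$$\tfrac12\left(|\angle\bar O_0| +
  |\operatorname{Arg} e^{i(\angle\bar O_\pi - \pi)}|\right),$$
which has the useful analytic property that an offset *unchanged* by
pairing scores exactly $\pi/2$ whatever its value — the no-plasticity
reference point — verified on a 64-angle grid in the tests.

One derived fact worth recording: for a peak-normalised von Mises
wedge profile the raw PVA magnitude is *not* monotone in the
concentration $\kappa$ (broad bumps carry more total mass; the
magnitude peaks near $\kappa \approx 2$ on 16 wedges). What grows
strictly with $\kappa$ is the profile's resultant length — magnitude
relative to total mass — and that is the property the test suite
asserts.

# Imaging preprocessing

The chain is motion correction → wedge extraction → detrend →
z-score/smooth → behavior alignment, matching how wedge imaging is
processed in practice.

**Motion correction** estimates integer-pixel rigid shifts at the peak
of the spatial cross-correlation, computed by FFT with periodic
boundaries (raw, unnormalised correlation). The reference image is
built from a one-tenth subset of frames in three steps: temporal
average, per-frame alignment to it, re-average. Sub-pixel registration
is deliberately out of scope: shifts are whole pixels.

**Wedge extraction** assigns each annulus pixel the phase
$\operatorname{atan2}(y - c_y,\, x - c_x)$ about the inner ROI's
center of mass and bins phases into 16 equal wedges centred on the
wedge angles; an empty wedge is an error naming the wedge.

**Detrending** fits, per wedge,
$\log \tilde y_k(t) = \beta_2 t + \beta_1 \log y_{bg}(t) + \beta_0 +
\epsilon(t)$ by least squares. The exponential term absorbs
photobleaching and slow drift; the background regressor absorbs
arena-light artifacts. The detrended trace is the *linear-domain*
residual $\tilde y_k - \hat y_k$ — the subtraction happens after
exponentiating the fit, not in log space. This is why raw sessions
must be strictly positive, and why the synthetic generator floors raw
fluorescence at $10^{-6}$.

**Normalisation** z-scores each wedge (sample variance), then smooths
in time with a Gaussian kernel of $\sigma = 0.1$ s (about one imaging
volume at the 10 Hz default) and across wedges with a Gaussian of
$\sigma = \pi/16$ rad (half a wedge). The spatial kernel wraps across
the wedge-16/wedge-1 seam: the ellipsoid body is a ring, so a circular
kernel is the only defensible topology. Kernels are normalised to sum
1, so spatial smoothing preserves the per-volume total. Z-scoring
precedes smoothing.

**Alignment** shifts the behavioral series by −200 ms (rounded to
whole volumes — the delay is about two volumes, and sub-volume
resampling would manufacture information), trims both series to common
support, and can rotate heading/cue so 0 rad matches the 0 rad wedge.
On generator data the lag scan peaks at the configured indicator
delay, closing the loop between generator and analysis conventions.

# The synthetic-data generators

The generators define the study conditions; their defaults are fixed
once and the tests run against them.

* Walking: rotational velocity is a stationary Ornstein–Uhlenbeck
  process, exact discretisation, with correlation time 0.8 s and
  stationary s.d. 1.0 rad/s. These are placeholders for real fly
  walking statistics (which the package does not ship); they produce
  rotational speeds spanning 0 to beyond $\pi$ rad/s, the range over
  which bump statistics are usually binned. Heading is the wrapped
  cumulative integral (this is a class invariant, checked on
  construction).
* Fluorescence: per wedge, a peak-normalised von Mises bump
  ($\kappa = 3$, a bump about a quarter of the ring wide at half
  maximum) rides on a bleaching baseline
  ($\tau_{bleach} = 300$ s), an arena-light background artifact
  (slow positive oscillation, gain 0.3) and Gaussian noise
  (amplitude/noise = 10 by default). Fluorescence reports heading at a
  0.2 s indicator delay. In darkness the bump–cue offset additionally
  performs a Brownian walk at 0.3 rad/$\sqrt{\mathrm{s}}$; dark drift
  is only characterised qualitatively in vivo, so the rate is a free
  knob with a plausible default.
* Pairing protocols: 8 locations × 5 repeats = 40 events, clockwise
  (decreasing ring angle), 2 s flashes, 1.8 s stimulation, 0.2 s
  shutter-open tail; the cue of every event equals the stimulated
  wedge's angle plus the enforced offset. A no-cue variant models
  stimulation in darkness.
* Anatomy: skeletons grow as seeded 3-D trees with exact edge-length
  weights; meshes sample a torus with known plane and center so the
  PCA ring frame has a ground truth.

What the generators deliberately do **not** emulate: pixel-level
imaging (beyond small frame stacks for registration tests), indicator
kinetics beyond a fixed delay, z-drift that is not monotone, real
walking trajectories, and multi-bump or split-bump regimes. Passing
tests therefore validate the *computations*, not the biology of any
particular fly.

# The ring-attractor model

The published simulation this module re-creates defers its host
network to earlier modelling work and specifies only the deltas: a
thin-bar visual drive as a von Mises with $\kappa = 15$, uniform
velocity noise $v = v_{actual} + 0.4\max|v_{actual}|\,\sigma$ with
$\sigma \sim U(-0.5, 0.5)$, zero visual drive in darkness, and a swept
learning rate. The host network here is therefore a standard rate
model, fully specified so results are reproducible:

$$\tau \dot r = -r + f\!\Big(\tfrac{1}{N}\big(g_{exc}\cos\Delta\theta
  - g_{inh}\big) r + \tfrac{g_{vel}}{N} v \sin\Delta\theta\, r
  - g_{vis}\,\widetilde{W^\top a} + I_0\Big)$$

with $N = 32$ EPG units, $f$ threshold-linear saturating at
$r_{max} = 1$, Euler integration at the behavior sampling interval
(0.1 s), $\tau = 0.2$ s, $g_{exc} = 10$, $g_{inh} = 5$, $I_0 = 0.15$.
The sine kernel implements velocity integration; its gain
$g_{vel} = 2.02$ was calibrated once so a constant 1 rad/s drive moves
the decoded bump 10.0 rad in 10 s, and frozen. EPG preferred angles
are offset half a unit so that averaging adjacent pairs lands exactly
on the 16 analysis wedge angles, making the simulated output
drop-in-compatible with the imaging analytics (no preprocessing is
applied to simulated data).

**Balanced visual inhibition.** $\widetilde{W^\top a}$ denotes the ER
inhibition centred on its ring average. Only the spatial *contrast* of
the learned weights steers the bump; a weight matrix saturated
uniformly at $w_{max}$ has no effect. This choice resolves a real
tension: the raw subtractive drive either extinguishes the bump when
weights saturate (which the postsynaptically gated rule produces after
darkness) or, if the network is made robust to that, loses the ability
to capture the bump after remapping. Treating uniform inhibitory tone
as balanced by the recurrent loop keeps the network functional in both
regimes. The gain $g_{vis} = 2$ sets the strength of the contrast
term.

**Plasticity.** Weights $W$ (ER × EPG, inhibition magnitudes clipped
to $[0, 0.4]$) update each step:

* presynaptic gating: $\Delta W_{ji} = \epsilon\, a_j (r^* - r_i)$ —
  an active ER unit depresses synapses onto bump-active EPGs and
  potentiates the rest; with $a \equiv 0$ (darkness) **nothing
  changes**, which is the mechanism of dark recall.
* postsynaptic gating: $\Delta W_{ji} = \epsilon\, r_i (a^* - a_j)$ —
  EPG activity alone drives potentiation in darkness, eroding the
  stored map.

Gating thresholds default to $r^* = 0.5\,r_{max}$ and $a^* = 0.1$; the
learning rate default is $\epsilon = 0.015$ per step. These four
numbers were chosen together so that (i) closed-loop experience carves
a coherent offset-aligned trough within about two minutes, (ii) a
single 40-event pairing bout — each ER unit is strongly active for
roughly 90 steps — both erases the previous trough
($\epsilon r^* \cdot 90 > w_{max}$) and carves the enforced one, and
(iii) capture of the bump by a freshly carved trough outruns
re-carving at the stale offset. These requirements genuinely compete:
map formation from scratch favours a weak visual force, antipodal
capture after pairing favours a strong one. At the chosen operating
point both succeed on most seeds; occasional runs that fail to remap
(or tether weakly in a first-ever session) parallel the animal-to-animal
variability seen in such experiments, and the discriminating
statistics are framed as paired comparisons across seeds for exactly
that reason.

**Experiments.** Both drivers first give the network a phase of
closed-loop experience with plasticity intact, mirroring the ≥10 min
of closed-loop exposure an animal has before imaging; the configured
$\epsilon$ then governs the analysed sessions, so $\epsilon = 0$
models acute blockade in an animal that already has a stored offset —
which is what makes the no-plasticity remapping error land at exactly
$\pi/2$. Pairing is simulated by clamping the network bump to the
stimulated wedge for the 1.8 s stimulation of each event while the
event's cue drives the ER bank (the optogenetic stand-in; a modelling
choice, not a claim about photostimulation biophysics). Analysed
phases default to 360 s — the six-minute sessions typical of such
recordings — because the slow Brownian-style dark drift of the offset
needs the full session length to express; the recall/stability runs at
these sizes complete in well under a minute each.

# Connectome geometry

The ring frame comes from PCA on mesh vertices: origin at the
centroid (the center of the annulus), first two axes spanning the ring
plane, third giving depth; each axis is oriented so its
largest-magnitude loading is positive, making repeated fits
bit-identical. Points get radius $\sqrt{c_1^2 + c_2^2}$, phase
$\operatorname{atan2}(c_2, c_1)$ and depth $c_3$; a point exactly at
the origin reports phase 0 with an explicit flag. Because the first
two principal directions of a near-isotropic annulus are degenerate,
phase is reproducible only up to the fitted axes — radius, |depth| and
all pairwise distances are the rigid-motion invariants the tests
assert.

Local centring subtracts, per phase window, the mesh's local mean
radius and depth from synapse coordinates; empty windows merge with
their nearest non-empty neighbour (logged). Convex-hull peeling
deletes hull vertices for exactly 20 iterations by default, stopping
early (with a message) below 3 points; collinear degenerate sets peel
by their extreme points.

Cable distance attaches synapses to their nearest skeleton node after
subdividing edges to ≤ 0.5 μm (bounding attachment error; the
upsampling resolution is otherwise unspecified upstream), then takes
the Dijkstra minimum over candidates of the target class within a
10 μm Euclidean radius measured synapse-coordinate to
synapse-coordinate. Queries with no candidate return an explicit `NA`,
never an infinity, and profiles count them separately. The
implementation rides on igraph; tests check it against a hand-written
Floyd–Warshall oracle on random trees.

# Numerical choices and degenerate inputs

* Wrapping always via $\operatorname{Arg} e^{ix}$, with the single
  boundary value $+\pi$ mapped to $-\pi$.
* Sample (n−1) variance everywhere a variance is taken; s.e.m. is
  sample s.d. over $\sqrt n$; across-fly aggregation is hierarchical
  (within fly first).
* The wrapped first difference of the PVA angle drops the boundary
  frame in lag scans.
* Zero-variance ROIs, empty wedges, non-positive raw fluorescence,
  all-zero frames, unattached query synapses, and lag grids outside
  the data support are errors, not warnings.
* Raw generator fluorescence is floored at $10^{-6}$ so the log-domain
  detrend is always defined.
* Determinism: every stochastic function takes a seed and restores the
  caller's RNG state; equal seeds give bitwise-equal output.

# Known limitations

* The host network is one concrete realisation of the referenced
  model family; only the gating truth table, the $\kappa = 15$ visual
  drive, the velocity-noise prescription and dark = zero drive are
  constrained from outside. Conclusions about the *rules* (dark
  invariance vs erosion) are robust to host details; absolute offsets
  and time constants are not.
* Map formation from scratch can tether weakly on trajectories with
  long fast-rotation excursions; the paired experiment designs absorb
  this.
* The detrend model is fit per ROI independently and assumes the
  background couples multiplicatively in the log domain; the generator
  couples it additively, so recovered $\beta_1$ is an effective, not a
  generative, coefficient. $\beta_2$ recovery is exact in the
  noiseless case and biased below 4% at amplitude-to-noise 10 (the
  log of noisy positive data is slightly biased; the tests pool the
  16 per-ROI estimates).
* Motion correction is integer-pixel and periodic; large non-rigid
  deformations are out of scope.

# Problem sizes

The shipped tests and acceptance checks run at: 1,000-timepoint offset
series for the circular identities; $10^6$ draws for the chance-level
Monte Carlo; 1,000 random 16×12 matrices for the PVA oracle; 200
random trees of up to 50 nodes for the cable-distance oracle; 300 s
sessions for bleach-rate recovery; ten seeded 3 × 360 s
closed-loop/dark/closed-loop runs per rule for the rule
discrimination; and one 360 s session for end-to-end offset recovery.
The full suite completes in about a minute on one core.
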