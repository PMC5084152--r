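---
title: "Quantifying axonal mitochondrial transport with mitotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axonal mitochondrial transport with mitotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotrack)
```

## The problem

Neurons move mitochondria along their axons on microtubules, driven by
kinesin (anterograde) and dynein (retrograde) motors. Disrupted mitochondrial
transport accompanies ALS, Parkinson's and Alzheimer's disease, so
quantifying it reproducibly matters. The practical observable is a 4-D
fluorescence stack: mitochondria labelled with a mitochondrially targeted
fluorophore, imaged as z-stacks (xyz) every 1-2 seconds for a few minutes,
typically with axon bundles confined to parallel microfluidic grooves so
that transport happens along one known axis.

`mitotrack` turns such a stack into per-mitochondrion 3-D trajectories and
classifies every trajectory timepoint into one of four motion states:

* **ST** (stationary): no net movement and no motility;
* **DP** (dynamic pause): no net displacement but sustained oscillation,
  the signature of a motor tug-of-war with balanced teams — much
  shorter-lived than ST (typically under ~15 s) and more likely to convert
  into a run;
* **AR / RR** (anterograde / retrograde running): smooth runs at roughly
  1 um/s.

The package has three layers: a tracker (enhancement, segmentation,
IMM-Kalman linking), a motion-pattern analyzer (transient-velocity
decomposition + classification), and a synthetic-data simulator that makes
every stage testable without microscope data.

## The transient-velocity decomposition

A trajectory is a series of positions $p_i$ (um) sampled every $\Delta t$
seconds. Framewise velocity is the forward difference
$v_i = (p_i - p_{i-1})/\Delta t$. Over a sliding window of $N$ points
(default $N = 16$, i.e. 24 s at $\Delta t = 1.5$ s) centred on timepoint
$i$ ($N/2$ points before, $N/2 - 1$ after), each coordinate is regressed
against time by ordinary least squares. The slope vector is the **sustained
velocity**: the short-term average velocity, insensitive to oscillation.
Its projection onto the anterograde axis gives the signed sustained speed;
its magnitude, the sustained speed.

The **transient speed** measures motility that produces no net movement:

$$v^{transient}_i = \frac{1}{N} \sum_{j \in \text{window}}
  \left| \operatorname{proj}_{\hat a}\!\left(v^{sustain}_i - v_j\right) \right|$$

the mean magnitude of the framewise-velocity deviations from the sustained
velocity, projected onto the anterograde axis $\hat a$. It is exactly zero
on a constant-velocity track and large for an oscillating one.

Two numerical choices deserve explanation:

* **Why a magnitude at all.** The plain mean of OLS residual velocities is
  identically ~0 (residuals cancel), so a literal mean-of-deviations is
  degenerate; the mean *magnitude* is the meaningful motility measure, and
  on the alternating square-wave test case (positions hopping 0 ↔ 0.3 um
  each frame) it evaluates to ~0.19 um/s while the sustained slope is the
  closed form $d/(85\,\Delta t) \approx 0.002$ um/s — exactly the DP
  signature.
* **Why the axis projection.** With isotropic localisation noise
  $\sigma = 0.05$ um and $\Delta t = 1.5$ s, the framewise velocity noise is
  $\sqrt 2 \sigma / \Delta t \approx 0.047$ um/s per axis. The mean *3-D
  Euclidean norm* of pure-noise deviations is then ~0.075 um/s — above the
  0.05 um/s state threshold, which would relabel every truly stationary
  timepoint as DP. The 1-D projection has a noise floor of ~0.037 um/s,
  below threshold, and loses nothing physical: in groove geometry transport
  is along the axon. The 3-D norm is still reported
  (`transient_speed_3d`) for diagnostics.

Classification applies one threshold $\theta$ (default 0.05 um/s) to both
components: ST if both are below $\theta$; DP if only the sustained speed
is; otherwise AR or RR by the sign of the signed sustained speed (an exact
zero with super-threshold off-axis speed is assigned RR; it is logged as
physically anomalous in groove geometry). The default $\theta$ is not
arbitrary: when speed distributions are fitted for experimental groups of
differing motility, the fitted curves cross near 0.05 um/s, and
`find_intersection_threshold()` re-derives it from data — the crossing of
two fitted log-normal densities located by bisection to $10^{-4}$ um/s.

Window edges (fewer than $N/2$ points before or $N/2 - 1$ after) are
flagged invalid rather than analysed with shrunken windows, keeping the
estimator's variance uniform across reported timepoints. Gap-interpolated
samples participate but are flagged, and a configurable cutoff can
invalidate windows with too many of them.

## The tracker

**Enhancement.** Each volume is mapped to a particle-probability (PP) map:
centre-surround Haar responses (inner box mean minus surround shell mean,
surround twice the inner size) at window scales bracketing the expected
diameter (default 7 px, valid 5-13 px), combined by voxel-wise maximum and
rescaled to [0, 1] with a 1st/99th-percentile clamp. Box windows shrink in
z by the pixel/z-step ratio because axial sampling (0.5-1 um) is much
coarser than lateral (~0.2 um). The raw (unclamped) response is kept
alongside the map: the clamp flattens bright cores into plateaus of 1.0,
which cannot be peak-picked. Denoising uses a feature-preserving non-local
means: patch similarity is measured on the intensity patch concatenated
with the PP patch, so particle voxels preferentially average with other
particle voxels and peaks survive smoothing. The filtering strength ties to
a robust noise estimate (MAD of the in-plane Laplacian). The implementation
box-filters squared-difference volumes per search offset, making cost
independent of patch size (~1.4 s per 256x256x5 volume).

**Segmentation.** The PP map is thresholded (default 0.5, per-frame
overrides replace interactive tuning) and small components are removed
(minimum volume a fraction of $(d/2)^3$). Markers are local maxima of the
raw Haar response inside the mask with minimum separation $d/2$; a
marker-controlled watershed on inverted intensity then grows exactly one
region per marker, so segmentation can neither split nor merge particles —
the detection count equals the marker count by construction, an invariant
the tests assert. Detections carry intensity-weighted centroids in um.

**Tracking.** Each track runs an interacting-multiple-model filter over
three motion models sharing a 10-dimensional state (position, velocity,
acceleration, intensity): random walk, constant velocity, constant
acceleration. The model-transition matrix defaults to 0.90 self / 0.05
cross (mildly sticky, configurable); measurement noise defaults to half a
pixel. Assignments are globally optimal one-to-one (shortest augmenting
path) under a cost of Mahalanobis position distance plus a normalised
intensity/volume mismatch, gated at 4 um — a little over twice the largest
per-frame run displacement, because a newborn track predicts with zero
velocity. Unmatched detections open tentative tracks (confirmed after 2
consecutive hits); unmatched tracks coast up to 3 frames then terminate.
A greedy cost-ordered linking step joins track fragments across dropouts
(ties broken by earliest start frame for determinism) and removes tracks
shorter than a minimum length; linked gaps are linearly interpolated and
flagged.

## The simulator: what it emulates, what it does not

`generate_dataset()` realises the four-state model: a first-order Markov
chain per particle (per-frame transition matrix), ST anchored in place, DP
an AR(1) oscillation about an anchor (coefficient -0.5, so steps alternate
direction like a balanced tug-of-war; stationary sd = the configured
amplitude, default 0.3 um), runs at a per-segment speed drawn from
N(1.0, 0.1) um/s. Dwell times echo the biology: ST ~90 s, DP ~12 s (under
the ~15 s typical bound), runs ~15 s, and DP exits prefer the running
states. The paper-scale acquisition (1.5 s/frame, 5 z-slices, ~0.2 um/px)
is the default calibration. Rendering sums anisotropic Gaussian blobs
(sigma 0.3 um lateral / 0.6 um axial) on a constant background with
exponential photobleaching and Poisson shot noise (Gaussian and noiseless
options exist for analytic tests). Particles sit on parallel groove lines;
the default groove spacing (10 um) is half the physical microgroove pitch,
scaled down to suit the 51-um synthetic field.

Collisions are resolved by *stalling*: a mover whose step would bring it
within the minimum spacing of a neighbour (or a field edge) stops at the
limit, as a motor does at an obstruction. An earlier clamping scheme that
pushed neighbours produced rigid lockstep chains and instantaneous
direction reversals — kinematics no tracker (and no mitochondrion) should
be expected to follow.

A green test on this world therefore establishes: correct decomposition
arithmetic, state recovery at realistic noise, detection-count
conservation, and identity-safe tracking at enforced spacing. It does
*not* establish performance on real data with fission/fusion events,
elongated or overlapping mitochondria, focus drift, or SNR below ~3 —
none of which the simulator emulates (fission/fusion is explicitly out of
scope, as is morphological classification).

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `mito_diameter_px` | 7 | px | Haar scales + marker separation; valid 5-13 |
| `segmentation_threshold` | 0.5 | — | on the [0,1] PP map; per-frame overrides |
| `clustering_threshold_speed` | 0.05 | um/s | state threshold; re-derivable from data |
| `window_size` | 16 | frames | must be $2^k$; 24 s at 1.5 s/frame |
| `gating_distance` | 4 | um | ~2x max per-frame run displacement |
| `max_gap` | 3 | frames | coasting length before termination |
| `min_track_length` | 8 | frames | fragments below this are trimmed |

## Degenerate inputs and tie-breaks

Constant volumes produce an all-zero PP map (response range below machine
epsilon) and pass through the denoiser unchanged. Zero markers produce an
empty label map and zero detections. Trajectories shorter than the window
yield an all-invalid state series with a warning, not an error. Equal
assignment costs resolve deterministically (augmenting-path order); equal
linking costs resolve by earliest start frame. The AR/RR tie at exactly
zero signed speed goes to RR.

## Known limitations

* The Haar/NLM enhancement follows the described intent of the original
  filter chain, not a line-by-line port (the upstream filter internals are
  published separately); constants were chosen for testability and are
  exposed as arguments.
* Intensity is carried in the Kalman state *and* the assignment cost; a
  config switch can exclude it from the cost (`feature_weight = 0`).
* Elongated mitochondria are represented by their centroid only.
* The TIFF layer reads/writes uncompressed baseline grayscale TIFF
  (8/16-bit unsigned, 32-bit float) with this package's JSON metadata or
  minimal OME-XML; compressed or tiled files from other writers are out of
  scope.
* Speed-distribution fitting defaults to a log-normal (positive,
  right-skewed support); a KDE fallback exists for distributions the
  log-normal fits poorly.
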