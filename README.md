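# mitotrack

Tracking and motion-state analysis of axonal mitochondria in 4-D (xyz-t)
fluorescence microscopy.

Neurons ship mitochondria along axonal microtubules using opposing motor
teams (kinesin anterograde, dynein retrograde); defects in this transport
accompany ALS, Parkinson's and Alzheimer's disease. Given a time-lapse
z-stack of fluorescently labelled mitochondria — typically axon bundles
confined to parallel microfluidic grooves, imaged every 1-2 s for a few
minutes — `mitotrack`:

1. **detects** mitochondria per frame (multi-scale Haar centre-surround
   particle enhancement, feature-preserving non-local-means denoising,
   marker-controlled watershed, so the region count always equals the
   marker count);
2. **links** detections into 3-D trajectories with an
   interacting-multiple-model (IMM) Kalman tracker over random-walk /
   constant-velocity / constant-acceleration motion models, globally
   optimal frame-to-frame assignment, and fragment linking;
3. **classifies** every trajectory timepoint into four motion states in a
   2-D speed space. Over a sliding window of N = 16 points the positions
   are fit by least squares: the slope is the *sustained velocity*
   v<sup>sus</sup> (short-term average velocity), and the *transient speed*

   v<sup>trans</sup><sub>i</sub> = (1/N) Σ<sub>j</sub> | proj<sub>â</sub>(v<sup>sus</sup><sub>i</sub> − v<sub>j</sub>) |,&emsp;v<sub>j</sub> = (p<sub>j</sub> − p<sub>j−1</sub>)/Δt

   measures motility without net movement (â is the anterograde axis).
   With threshold θ = 0.05 µm/s on both components: **ST** (stationary)
   if both are sub-threshold, **DP** (dynamic pause — the tug-of-war
   oscillation state) if only the sustained speed is, otherwise **AR** or
   **RR** by the sign of the signed sustained speed.

A synthetic-data module simulates the four-state motion model (runs at
~1 µm/s, dynamic pauses < 15 s, long stationary phases) and renders it
with a Gaussian PSF, background, shot noise and photobleaching, so the
entire pipeline is testable with no microscope data. Reporting utilities
build kymographs, fit speed distributions (log-normal or KDE), estimate
the state threshold from the intersection of two fitted distributions, and
summarise state proportions per experimental group.

## Worked example

```r
library(mitotrack)

# 1. simulate a small acquisition: 12 mitochondria, 60 frames (90 s)
ds <- generate_dataset(
  n_particles = 12, n_frames = 60, seed = 42,
  metadata = acquisition_metadata(pixel_size_xy = 0.2, z_step = 1,
                                  frame_interval = 1.5, n_frames = 60,
                                  n_z = 5, height = 128, width = 128))

# 2. track it (enhancement -> segmentation -> IMM tracking)
cfg <- pipeline_config()
tracks <- track_sequence(ds$sequence, cfg)
length(tracks)
#> [1] 12

# 3. classify motion states and pool the proportions
series <- lapply(tracks, analyze_trajectory, config = cfg, dt = 1.5)
round(state_proportions(series), 3)
#>    ST    DP    AR    RR
#> 0.704 0.111 0.094 0.091

# 4. same analysis on the simulator's ground-truth trajectories
truth_series <- lapply(truth_trajectories(ds$truth, 1.5),
                       analyze_trajectory, config = cfg, dt = 1.5)
round(state_proportions(truth_series), 3)
#>    ST    DP    AR    RR
#> 0.683 0.128 0.096 0.093
```

The tracker recovers all 12 particles, and the state proportions measured
from its tracks agree with those measured from the ground-truth positions
to within ~2 percentage points: about 70% of mitochondria-timepoints are
stationary, ~11% in dynamic pause, and ~9% running in each direction —
the composition the default transition matrix is designed to produce.

Trajectories round-trip through a plain CSV schema
(`write_trajectories()` / `read_trajectories()`), so the motion analyzer
also works on tracks produced by external trackers. Image stacks are read
and written as multi-page TIFF / OME-TIFF (`read_image_sequence()`,
`write_image_sequence()`).

## Command line

```sh
inst/cli/mitotrack simulate --out stack.tif --truth truth.csv --n-particles 50 --seed 1
inst/cli/mitotrack track    --input stack.tif --out tracks.csv
inst/cli/mitotrack analyze  --tracks tracks.csv --out states.csv --frame-interval 1.5
inst/cli/mitotrack report   --states states.csv --out summary.csv
```

## Documentation

`vignettes/mitotrack-methods.Rmd` describes the model and its assumptions,
the parameters that matter (with units and defaults), what the simulator
does and does not emulate, numerical choices, and known limitations.
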