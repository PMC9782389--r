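# imudecomp

Separating the error sources of IMU-based body-segment orientation
estimation.

## The problem

Inertial measurement units (IMUs) strapped to the pelvis, thighs and
shanks make lower-body motion analysis possible outside the lab, but their
segment-orientation estimates carry three distinct error sources:

1. **Body-frame definition** — the sensor-body calibration (a neutral pose
   plus a sagittal calibration movement) defines each segment's anatomical
   frame differently than marker-based conventions do.
2. **Soft tissue artefact (STA)** — the skin-mounted sensor moves relative
   to the underlying bone, both slowly (skin sliding coupled to joint
   flexion) and fast (oscillations at impacts).
3. **Orientation filter** — the sensor-fusion algorithm (here a
   gradient-descent Madgwick MARG filter, gain β = 0.043) drifts and is
   disturbed by linear accelerations and magnetic-field distortions.

`imudecomp` implements a decomposition that quantifies each source
*separately*, using an optoelectronic system as reference and a rigid
marker cluster (RMC) that couples four optical markers rigidly to each
IMU. Six body-frame series are built per segment — three IMU
sensor-calibrated body frames (IMU-scbfA/B/C, one per calibration
movement), the IMU and RMC series re-aligned to the marker-calibrated body
frame via a static trial (IMU-mcbf, RMC-mcbf), and the anatomical-landmark
frame itself (AL-mcbf) — and compared pairwise:

| # | frames              | isolates                      |
|---|---------------------|-------------------------------|
| 1–3 | IMU-scbf(A–C) vs IMU-mcbf | body-frame definition   |
| 4 | RMC-mcbf vs AL-mcbf | soft tissue artefact          |
| 5 | IMU-mcbf vs RMC-mcbf | orientation filter           |
| 6 | IMU-mcbf vs AL-mcbf | filter + STA                  |
| 7–9 | IMU-scbf(A–C) vs AL-mcbf | total error            |

Each comparison is summarized by the root-mean-square over time of the
smallest rotation angle between the two frames (RMSD, degrees), averaged
over repetitions per subject, then mean ± SD across subjects.

Because the real study dataset is not shipped, the package includes a
fully ground-truthed synthetic generator: stylized squat / jump / gait /
kick kinematics with exact analytic angular velocities, configurable STA
injection, marker synthesis at 250 Hz and raw IMU synthesis
(gyroscope/accelerometer/magnetometer) at 500 Hz, so every pipeline stage
is testable against known truth.

## Worked example

Generate a one-subject synthetic dataset (squat trial, realistic sensor
noise, a 15° injected calibration error), run the full pipeline, and look
at the decomposition:

```r
library(imudecomp)
library(dplyr)

gen <- generate_dataset("demo_ds", movements = "squat", subjects = 1,
                        base_cfg = synthetic_config(), mounting_error_deg = 15,
                        seed = 3)
res <- run_pipeline(gen$manifests[1])

tidy(res$results) |>
  filter(segment == "thigh_r") |>
  select(comparison, error_source, rmsd_deg, max_deg)
#> # A tibble: 9 x 4
#>   comparison error_source             rmsd_deg max_deg
#> 1          1 frame definition A          13.3    13.3
#> 2          2 frame definition B          13.4    13.4
#> 3          3 frame definition C          15.0    15.0
#> 4          4 soft tissue artefact         4.41    7.22
#> 5          5 orientation filter           1.49    2.79
#> 6          6 orientation filter + STA     3.80    6.17
#> 7          7 total A                     13.6    14.7
#> 8          8 total B                     13.7    14.7
#> 9          9 total C                     15.3    16.3
```

Reading the output: comparison #3 recovers the injected 15° frame error
exactly (the plank calibration C involves no knee flexion and so no STA in
this simulation, while the squat and thigh-rise movements behind A/B are
themselves STA-contaminated, biasing them to ~13°); #4 reports the soft
tissue artefact the generator injected (flexion-coupled, peaking above 7°
at deep knee flexion); #5 is the Madgwick filter error under the
configured noise and bias. #6 combines filter and STA; for independently
injected errors it follows the root-sum-square √(#4² + #5²) (verified in
the test suite), while in this trial the flexion-coupled parts of the two
sources are correlated, so #6 lands slightly below it. `autoplot()` on
`res$results` draws the per-sample angle series; `aggregate_errors()`
produces the trial × segment × comparison group summary across subjects.

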