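---
title: "Separating body-frame, soft-tissue and filter errors in IMU motion analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating body-frame, soft-tissue and filter errors in IMU motion analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imudecomp)
```

## The decomposition

An IMU on a body segment estimates the segment's orientation through three
fallible steps, and this package quantifies each step's error separately
against an optoelectronic reference. The instrument that makes the
separation possible is the rigid marker cluster (RMC): a rigid mount that
carries both the IMU and four optical markers, so the optical cluster
frame (RMC-sf) and the IMU sensor frame (IMU-sf) are the same physical
frame by construction. Everything is expressed as unit rotation
quaternions: q_A^B denotes the orientation of frame B relative to frame A,
vectors map as v_A = q ⊗ v_B ⊗ q*, and frames chain by right-
multiplication, q_A^C = q_A^B ⊗ q_B^C.

Per segment and trial, six body-frame series are assembled relative to the
optical global frame (GRF):

* **IMU-scbfA/B/C** — the filter output q_t(IRF→IMU-sf), re-referenced to
  GRF through the hand-eye (compass) yaw, then right-composed with one of
  three sensor-body calibrations (bow + thigh rise, squat, inclined
  plank).
* **IMU-mcbf**, **RMC-mcbf** — the IMU and RMC sensor series right-
  composed with the *inverse* of the static-trial alignment, the
  time-average over the static trial of qrel(AL-mcbf_t, sensor_t). By
  construction both coincide with the anatomical frame during the static
  trial, so any later divergence is error accrued by that sensing route.
* **AL-mcbf** — the anatomical-landmark frame built from bony-landmark
  markers (ISB conventions: X anterior, Y proximal, Z to the subject's
  right).

The nine pairwise comparisons in `comparison_table()` then isolate the
sources: #1–3 share the identical filter series in both operands, so the
filter error cancels exactly and only the two constant calibrations
differ — the frame-definition error, constant over time (the pipeline
asserts per-sample constancy within 1e-6°). #4 uses only optical data on
both sides, calibrated to the same body frame, so it measures the relative
motion between skin-mounted cluster and bone landmarks — the STA. #5
shares the rigid IMU/RMC mount, so no STA or frame-definition difference
survives and only the filter error remains. #6–9 combine sources. The
error metric is the smallest rotation angle, θ = 2·arccos(|w|), of the
relative quaternion per sample, summarized as RMSD over the trial window;
aggregation is mean over repetitions per subject, then mean and SD
(n−1) across subjects.

## Pipeline parameters

| parameter | default | meaning |
|---|---|---|
| `filter.beta` | 0.043 | Madgwick gradient-descent gain (dimensionless); the value used for the decomposition and deliberately not re-tuned |
| warm-up | 5 s | filter convergence window excluded from all RMSD windows |
| low-pass | 4th order, 8 Hz | zero-phase Butterworth on all marker trajectories |
| rates | 500 / 250 Hz | IMU / marker sampling; IMU is down-sampled by 2 after integer-lag synchronization, leaving a worst-case phase error of half a marker period, 0.002 s |
| HJC regression | (−0.19, −0.30, ±0.36)·IAD | hip joint centre as fractions of inter-ASIS distance in the pelvis frame |

The orientation filter is the MARG form of the gradient-descent algorithm:
the quaternion rate from the gyroscope minus β times the normalized
gradient of the stacked gravity and magnetic-field objectives, with the
magnetic reference flattened to (b_x, 0, b_z) each step so magnetic
disturbances can only corrupt heading. First-order integration at 500 Hz;
with β = 0 the update is exactly gyro integration (a test covers the
closed form). Initialization is a TRIAD solution from the mean
accelerometer and magnetometer over the first static second — every trial
in the protocol begins static, so `q0 = "auto"` is safe; the IMU-only mode
(`use_mag = FALSE`) exists for sensitivity studies. A zero-norm
accelerometer or magnetometer sample drops that term for the step rather
than poisoning the state.

Static-trial averaging of quaternions is the component-wise arithmetic
mean after sign-continuity enforcement, renormalized — the literal reading
of the alignment formulas. In the static-trial dispersion regime (well
under 30°, guarded by a warning) this agrees with the Markley eigenvector
mean to far better than 0.1°; the eigenvector method serves as the
independent oracle in the tests, never as the implementation. The same
duality holds for the cluster pose: production code solves Davenport's
q-method (largest eigenvector of the 4×4 attitude-profile matrix), and the
Kabsch SVD solution is the test oracle.

Two conventions need stating because the source formulas are ambiguous
about them. First, the static alignment produces q_AL-mcbf^sensor, and the
body-frame series is sensor_t ⊗ (q_AL-mcbf^sensor)⁻¹ — the only
composition under which IMU-mcbf coincides with AL-mcbf during the static
trial, which is what makes comparisons #5 and #6 meaningful. Second, the
functional flexion axis has a sign ambiguity (flexion vs extension
rotation); it is resolved by a per-segment sign declared in the trial
manifest stating whether the calibration movement's initial rotation
phase is about the rightward or leftward mediolateral axis (e.g. the
shank initially rotates leftward in a squat while the thigh rotates
rightward).

## The synthetic world

The generator emulates the nine-trial football protocol (squat, squat
jumps, walk/run/sprint, kicks) plus the three calibration movements, the
compass trial and the static trial, for any number of subjects and
repetitions. Design choices:

* **Kinematics** are products of elementary rotations about body-fixed
  axes with raised-cosine and enveloped-sinusoid angle profiles, so the
  body-frame angular velocity is analytic (for q = q1 ⊗ q2, ω = R(q2)ᵀω1 +
  ω2) and the emitted gyroscope is exact, not differentiated. Gait is
  treadmill-style (no forward travel) and knee angles oscillate
  symmetrically about neutral — stylized, but with realistic frequency
  content, amplitudes and impact events. Linear acceleration comes from
  five-point finite differences of the sensor trajectory; the squat jump's
  flight phase is exactly ballistic, so the accelerometer reads near zero
  in flight.
* **STA** enters as skin_t = bone_t ⊗ δ_t with δ_t a rotation about the
  mediolateral axis of gain × adjacent-joint flexion (skin sliding) plus
  an exponentially damped 15 Hz oscillation (τ = 0.05 s) at each impact.
  Landmark markers ride the bone and cluster markers ride the skin, which
  realizes exactly the assumption that the landmark frames approximate
  bone; `landmark_sta_frac` adds a fraction of the STA to the landmarks to
  study that approximation.
* **The injected frame-definition error** (`mounting_error_deg`) is
  modelled as the calibration movement's rotation plane deviating from the
  sagittal plane by an internal/external rotation about the longitudinal
  axis. A physical sensor mounting rotation would be *recovered* by a
  functional calibration on a perfectly executed movement and produce no
  frame error at all; only an execution/anatomy deviation of the movement
  axis itself can generate the constant frame-definition error that
  comparison #1 measures, so that is what the parameter injects. A
  separate `mount_deg` applies a benign random physical mounting.
* **Magnetics**: homogeneous unit field with 67° dip; the hand-eye yaw
  equals the declination (default 12°). An optional localized dipole
  reproduces the magnetic-disturbance failure mode.
* **Noise defaults** (gyro 0.005 rad/s, accel 0.05 m/s², mag 0.003 a.u.,
  gyro bias SD 0.002 rad/s, markers 0.2 mm) are consumer-MEMS-plus-
  optical-lab scale. Under these defaults and full-intensity movements the
  decomposition lands in the ranges reported for real football movements
  (frame definition ≈ 11–19°, STA ≈ 2–9°, filter ≈ 0.3–3°): the frame and
  STA channels are quantitatively realistic, while the filter channel is
  cleaner than reality because the magnetic environment is nearly ideal
  and sensor calibration residuals are small.

What passing tests on this world show — and do not show. They show the
*pipeline algebra* is right: each comparison isolates exactly the injected
source, recoveries are quantitative (frame errors within fractions of a
degree, STA at its closed-form RMS within 2%), and independent sources
compose as a root sum of squares. They do not certify real-data accuracy:
real STA is not a pure flexion-coupled rotation, real magnetic
environments are dirtier, marker gaps and relabelling do not occur here
(gap filling is deliberately refused — it belongs to the capture
software), and real calibration movements are executed imperfectly in ways
richer than a single tilted axis.

## Numerical choices and degenerate inputs

Quaternions are kept unit-norm after every product; series are
sign-continuous (consecutive dot products ≥ 0) before any averaging or
differentiation. Constant quaternions are serialized with w ≥ 0.
Degenerate frames (collinear axes, collinear cluster markers, a vertical
compass, a flexion axis within 10° of the longitudinal axis, non-static
calibration windows, missing markers/gaps) are hard errors naming the
offending input, not silent repairs. The functional-axis rate threshold
adapts to gentle movements (half the peak rate, capped at 0.5 rad/s) so a
slow calibration is usable while a static window is still rejected. The
marker low-pass uses reflective padding of 2 s so the zero-phase IIR
transient settles below numerical noise at the window edges.

Problem sizes in the shipped tests and acceptance script are desk-scale by
choice: trials of 4–14 s, one to three subjects, single repetitions —
enough for every recovery check to operate far from its tolerance while
the whole suite runs in minutes.

## Known limitations

The sensor-body calibration error model captures one mechanism
(movement-plane deviation); between-subject variability of real
calibrations is broader. The arithmetic quaternion mean is only valid in
the low-dispersion regime it is guarded for. The synchronizer assumes a
shared dynamic event and breaks ties by cross-correlation peak, which is
ambiguous for strictly periodic motion — use an aperiodic event (as the
mechanical sync peak in the protocol provides). C3D ingestion is not
implemented; marker data enters through the documented CSV dialect.
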