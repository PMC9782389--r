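# Constant alignment quaternions: sensor-body calibrations A-C (neutral-pose
# longitudinal axis + sagittal-movement flexion axis), the hand-eye (compass)
# rotation between the optical GRF and the filter's IRF, the static-trial
# marker-calibrated alignments, and IMU/marker time alignment.

#' Sensor-body calibration result
#'
#' Holds the constant rotation from the IMU sensor frame to a body frame:
#' q_IMU-sf^IMU-scbf for methods A/B/C, or q_AL-mcbf^sensor for the
#' static-trial marker-calibrated alignment (`method = "mcbf"`).
#'
#' @param q Unit quaternion.
#' @param method `"A"`, `"B"`, `"C"` or `"mcbf"`.
#' @param segment Segment label.
#' @return A `body_cal` list.
#' @export
body_cal <- function(q, method, segment = NA_character_) {
  stopifnot(method %in% c("A", "B", "C", "mcbf"))
  structure(list(q = qnormalize(q), method = method, segment = segment),
            class = "body_cal")
}

#' Segment longitudinal axis from a static neutral pose
#'
#' In the neutral pose each segment's longitudinal axis is assumed parallel
#' to gravity, so the unit mean accelerometer direction over the window is
#' the body Y axis in sensor coordinates.
#'
#' @param rec An `imu_record` restricted to the static window.
#' @param max_gyro_rms Static guard, rad/s.
#' @return Unit 3-vector (sensor frame), pointing up.
#' @export
longitudinal_axis_static <- function(rec, max_gyro_rms = 0.05) {
  gy <- imu_gyro(rec)
  if (sqrt(mean(gy^2)) > max_gyro_rms) {
    stop("window is not static: gyro RMS exceeds threshold", call. = FALSE)
  }
  a <- unname(colMeans(imu_accel(rec)))
  a / sqrt(sum(a^2))
}

#' Flexion (mediolateral) axis from a sagittal-plane movement
#'
#' Dominant gyroscope rotation axis over the movement window: samples below
#' the rate threshold are discarded, the remaining unit angular-velocity
#' vectors are sign-aligned to the majority direction, averaged with
#' magnitude weights and normalized; the component along the longitudinal
#' axis is projected out. The overall sign must point to the subject's
#' right (flexion positive by the right-hand rule): `sign` states whether
#' the movement's initial rotation phase is about the rightward (+1) or
#' leftward (-1) mediolateral axis, a property of the calibration movement
#' declared per segment in the trial manifest.
#'
#' @param rec An `imu_record` restricted to the movement window.
#' @param long_axis Unit longitudinal axis (sensor frame).
#' @param min_rate Discard samples with |omega| below this, rad/s.
#' @param sign +1 or -1, see Details.
#' @return Unit 3-vector (sensor frame).
#' @export
flexion_axis_functional <- function(rec, long_axis, min_rate = 0.5, sign = 1) {
  w <- imu_gyro(rec)
  rate <- sqrt(rowSums(w^2))
  # adapt the threshold to gentle movements, but insist on real rotation
  thr <- min(min_rate, 0.5 * max(rate))
  keep <- rate >= thr
  if (sum(keep) < 10 || max(rate) < 0.05) {
    stop("insufficient rotation in window for functional calibration", call. = FALSE)
  }
  u <- w[keep, , drop = FALSE] / rate[keep]
  # sign-align each unit axis to the movement's initial rotation direction
  ref <- u[1, ]
  s <- base::sign(u %*% ref)
  s[s == 0] <- 1
  axis <- unname(colSums(u * drop(s) * rate[keep]))
  axis <- axis / sqrt(sum(axis^2))
  axis <- axis - sum(axis * long_axis) * long_axis
  n <- sqrt(sum(axis^2))
  if (n < 1e-6) stop("flexion axis collinear with longitudinal axis", call. = FALSE)
  sign * axis / n
}

#' Build a sensor-body calibration from the two functional axes
#'
#' Y = longitudinal axis; Z = flexion axis orthogonalized against Y;
#' X = Y x Z. Returns q_IMU-sf^IMU-scbf.
#'
#' @param long_axis,flexion_axis Unit 3-vectors in the sensor frame.
#' @param method Calibration movement, `"A"`, `"B"` or `"C"`.
#' @param segment Segment label.
#' @return A `body_cal`.
#' @export
build_sensor_body_cal <- function(long_axis, flexion_axis, method, segment = NA_character_) {
  ang <- acos(pmin(1, abs(sum(long_axis * flexion_axis)))) * 180 / pi
  if (ang < 10) stop("degenerate calibration: axes within 10 deg of collinear", call. = FALSE)
  y <- long_axis / sqrt(sum(long_axis^2))
  z <- flexion_axis - sum(flexion_axis * y) * y
  z <- z / sqrt(sum(z^2))
  x <- .cross_rows(matrix(y, 1), matrix(z, 1))[1, ]
  # triad = body axes in sensor coords -> quaternion q_sf^body
  body_cal(qfrom_axes(x, y, z), method = method, segment = segment)
}

#' Hand-eye (compass) calibration between GRF and IRF
#'
#' Both the optical global frame and the filter's earth frame share the
#' gravity vertical, so the unknown is a single heading angle. A compass
#' with a marker at each end is laid along magnetic north; the yaw rotation
#' mapping the IRF north axis (+X by convention) onto the measured compass
#' heading in GRF is q_GRF^IRF, averaged over the trial.
#'
#' @param ms A `marker_set` with the two compass markers; the first marker
#'   is the north end.
#' @param markers Length-2 marker names, `c(south/tail, north/tip)` order
#'   reversed: the axis runs from `markers[1]` to `markers[2]` and points
#'   magnetic north.
#' @param max_tilt_deg Reject a compass axis further than this from
#'   horizontal.
#' @return Unit quaternion q_GRF^IRF (pure yaw about GRF +Z).
#' @export
hand_eye_from_compass <- function(ms, markers = c("COMPASS1", "COMPASS2"),
                                  max_tilt_deg = 10) {
  .check_gaps(ms, markers)
  axis <- marker_xyz(ms, markers[2]) - marker_xyz(ms, markers[1])
  a <- unname(colMeans(axis))
  a <- a / sqrt(sum(a^2))
  tilt <- abs(90 - acos(pmin(1, abs(a[3]))) * 180 / pi)
  if (tilt > max_tilt_deg) {
    stop("compass axis is not horizontal: heading undefined", call. = FALSE)
  }
  heading <- atan2(a[2], a[1]) * 180 / pi
  qfrom_axis_angle(c(0, 0, 1), heading)
}

#' Static-trial marker-calibrated alignment
#'
#' The mean over the static trial of qrel(body_t, sensor_t), i.e. the
#' constant q_AL-mcbf^sensor whose inverse, right-applied to the sensor
#' series, yields a marker-calibrated body-frame series (IMU-mcbf or
#' RMC-mcbf) that coincides with AL-mcbf during the static trial.
#'
#' @param body_series `quat_series` GRF -> AL-mcbf over the static trial.
#' @param sensor_series `quat_series` GRF -> IMU-sf or RMC-sf, time-aligned
#'   with `body_series`.
#' @param segment Segment label.
#' @return A `body_cal` with `method = "mcbf"` holding q_AL-mcbf^sensor.
#' @export
static_frame_alignment <- function(body_series, sensor_series, segment = NA_character_) {
  if (nrow(body_series) != nrow(sensor_series)) {
    stop("frame mismatch: series lengths differ", call. = FALSE)
  }
  rel <- qmul(qinv(qs_matrix(body_series)), qs_matrix(sensor_series))
  q <- qmean(quat_series(body_series$time, rel))
  body_cal(q, method = "mcbf", segment = segment)
}

#' Apply a marker-calibrated alignment to a sensor series
#'
#' Right-multiplies each sample by the inverse of q_AL-mcbf^sensor, turning
#' a GRF -> sensor-frame series into the GRF -> IMU-mcbf / RMC-mcbf series.
#'
#' @param sensor_series `quat_series` GRF -> IMU-sf or RMC-sf.
#' @param cal A `body_cal` with `method = "mcbf"`.
#' @param to Output frame label (`"IMU-mcbf"` or `"RMC-mcbf"`).
#' @return A `quat_series` GRF -> `to`.
#' @export
apply_mcbf_alignment <- function(sensor_series, cal, to = "IMU-mcbf") {
  stopifnot(inherits(cal, "body_cal"), cal$method == "mcbf")
  qs_rebuild(sensor_series, qmul(qs_matrix(sensor_series), qinv(cal$q)), to = to)
}

#' Estimate the integer-sample lag between IMU and marker streams
#'
#' Cross-correlates the IMU gyroscope rate magnitude (decimated to the
#' marker rate) with the angular-rate magnitude differentiated from the
#' optical cluster series. The residual bound after nearest-sample
#' alignment is half the marker sample period.
#'
#' @param imu An `imu_record` (500 Hz nominal).
#' @param rmc_series `quat_series` GRF -> RMC-sf (250 Hz nominal).
#' @param max_lag Search range, marker samples.
#' @return A list `sync_result`: `lag` (marker samples; positive when the
#'   IMU stream leads), `residual_bound` (s).
#' @export
estimate_sync_offset <- function(imu, rmc_series, max_lag = 250) {
  f_imu <- 1 / qs_dt(imu)
  f_mk <- 1 / qs_dt(rmc_series)
  factor <- round(f_imu / f_mk)
  g <- sqrt(rowSums(imu_gyro(imu)^2))
  g <- g[seq(1, length(g), by = factor)]
  r <- qs_angular_rate(rmc_series)$rate
  n <- min(length(g), length(r))
  g <- g[seq_len(n)] - mean(g[seq_len(n)])
  r <- r[seq_len(n)] - mean(r[seq_len(n)])
  if (stats::sd(g) < 1e-9 || stats::sd(r) < 1e-9) {
    stop("insufficient excitation for synchronization", call. = FALSE)
  }
  max_lag <- min(max_lag, n - 2L)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    # shift the marker signal by l samples relative to the IMU signal
    if (l >= 0) sum(g[seq_len(n - l)] * r[seq_len(n - l) + l])
    else sum(g[seq_len(n + l) - l] * r[seq_len(n + l)])
  }, numeric(1))
  structure(list(lag = lags[which.max(cc)], residual_bound = 1 / (2 * round(f_mk))),
            class = "sync_result")
}

#' Down-sample a quaternion series by an integer factor
#'
#' Keeps every `factor`-th sample after an optional integer lag shift;
#' timestamps are rewritten onto the target clock starting at `t0`.
#'
#' @param qs A `quat_series` (e.g. 500 Hz filter output).
#' @param factor Integer decimation factor (500 -> 250 Hz: 2).
#' @param lag Integer shift in input samples applied before decimation.
#' @param t0 First output timestamp; defaults to the shifted first input
#'   timestamp.
#' @return A `quat_series` at the reduced rate.
#' @export
downsample_series <- function(qs, factor = 2, lag = 0, t0 = NULL) {
  if (factor != round(factor) || factor < 1) {
    stop("decimation factor must be a positive integer", call. = FALSE)
  }
  idx <- seq(1 + max(0, lag), nrow(qs), by = factor)
  if (lag < 0) idx <- idx[idx - lag <= nrow(qs)]
  m <- qs_matrix(qs)[idx, , drop = FALSE]
  tt <- qs$time[idx]
  if (!is.null(t0)) tt <- t0 + (tt - tt[1])
  fr <- qs_frames(qs)
  quat_series(tt, m, from = fr[1], to = fr[2])
}
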