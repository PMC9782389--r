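# IMU streams. An imu_record is a tibble: time, gyro_x..z (rad/s),
# accel_x..z (m/s^2), mag_x..z (normalized a.u.), with attribute sensor_id.

#' Construct an IMU record
#'
#' @param time Timestamps (s), uniform; nominal rate 500 Hz.
#' @param gyro,accel,mag n x 3 matrices: angular rate (rad/s), specific
#'   force (m/s^2), magnetic field (arbitrary units).
#' @param sensor_id Sensor label.
#' @return An `imu_record` tibble.
#' @export
imu_record <- function(time, gyro, accel, mag, sensor_id = NA_character_) {
  n <- length(time)
  stopifnot(nrow(gyro) == n, nrow(accel) == n, nrow(mag) == n)
  if (n > 2L) {
    dt <- diff(time)
    if ((max(dt) - min(dt)) > 1e-6 * stats::median(dt) * n) {
      # tolerate accumulated float error, reject genuine jitter
      if ((max(dt) - min(dt)) > 1e-4 * stats::median(dt)) {
        stop("non-uniform IMU timestamps", call. = FALSE)
      }
    }
  }
  out <- tibble::tibble(time = time,
                        gyro_x = gyro[, 1], gyro_y = gyro[, 2], gyro_z = gyro[, 3],
                        accel_x = accel[, 1], accel_y = accel[, 2], accel_z = accel[, 3],
                        mag_x = mag[, 1], mag_y = mag[, 2], mag_z = mag[, 3])
  attr(out, "sensor_id") <- sensor_id
  class(out) <- c("imu_record", class(out))
  out
}

#' Extract one channel triad of an IMU record as a matrix
#' @param rec An `imu_record`.
#' @return n x 3 numeric matrix.
#' @export
imu_gyro <- function(rec) as.matrix(rec[, c("gyro_x", "gyro_y", "gyro_z")])

#' @rdname imu_gyro
#' @export
imu_accel <- function(rec) as.matrix(rec[, c("accel_x", "accel_y", "accel_z")])

#' @rdname imu_gyro
#' @export
imu_mag <- function(rec) as.matrix(rec[, c("mag_x", "mag_y", "mag_z")])

#' IMU sensor-calibration parameters
#'
#' Per-triad bias, scale and misalignment; corrected = misalignment %*%
#' diag(scale) %*% (raw - bias) per sample.
#'
#' @param gyro_bias,accel_bias Length-3 biases (rad/s, m/s^2).
#' @param gyro_scale,accel_scale Length-3 scale factors, each in (0.5, 2).
#' @param gyro_align,accel_align 3 x 3 near-identity alignment matrices.
#' @return An `imu_cal` list.
#' @export
imu_cal <- function(gyro_bias = c(0, 0, 0), accel_bias = c(0, 0, 0),
                    gyro_scale = c(1, 1, 1), accel_scale = c(1, 1, 1),
                    gyro_align = diag(3), accel_align = diag(3)) {
  stopifnot(all(gyro_scale > 0.5), all(gyro_scale < 2),
            all(accel_scale > 0.5), all(accel_scale < 2))
  for (A in list(gyro_align, accel_align)) {
    if (abs(det(A)) < 1e-6) stop("singular misalignment matrix", call. = FALSE)
  }
  structure(list(gyro_bias = gyro_bias, accel_bias = accel_bias,
                 gyro_scale = gyro_scale, accel_scale = accel_scale,
                 gyro_align = gyro_align, accel_align = accel_align),
            class = "imu_cal")
}

#' Apply a sensor calibration to a raw IMU record
#'
#' Compensates offsets, scale factors and triad misalignment per channel;
#' the magnetometer is additionally normalized per sample (the orientation
#' filter only uses its direction).
#'
#' @param rec An `imu_record`.
#' @param cal An `imu_cal`.
#' @return Calibrated `imu_record`.
#' @export
apply_imu_calibration <- function(rec, cal) {
  stopifnot(inherits(cal, "imu_cal"))
  g <- sweep(imu_gyro(rec), 2, cal$gyro_bias) %*% diag(cal$gyro_scale) %*% t(cal$gyro_align)
  a <- sweep(imu_accel(rec), 2, cal$accel_bias) %*% diag(cal$accel_scale) %*% t(cal$accel_align)
  m <- imu_mag(rec)
  nm <- sqrt(rowSums(m^2))
  ok <- nm > 1e-12
  m[ok, ] <- m[ok, , drop = FALSE] / nm[ok]
  imu_record(rec$time, g, a, m, sensor_id = attr(rec, "sensor_id"))
}

#' Estimate a simplified static sensor calibration
#'
#' From a static window: gyro biases are the channel means, the accelerometer
#' scale is set so the mean specific force has magnitude g, misalignment is
#' left at identity. Intended as the desk-scale stand-in for a full
#' multi-position rate-table calibration; externally supplied `imu_cal`
#' parameters can be used instead.
#'
#' @param rec A static `imu_record` (gyro RMS < `max_gyro_rms` rad/s).
#' @param max_gyro_rms Static-detection guard, rad/s.
#' @param g Gravitational acceleration, m/s^2.
#' @return An `imu_cal`.
#' @export
estimate_static_cal <- function(rec, max_gyro_rms = 0.02, g = 9.81) {
  gy <- imu_gyro(rec)
  if (sqrt(mean(gy^2)) > max_gyro_rms) {
    stop("window is not static: gyro RMS exceeds threshold", call. = FALSE)
  }
  amean <- colMeans(imu_accel(rec))
  s <- g / sqrt(sum(amean^2))
  imu_cal(gyro_bias = unname(colMeans(gy)), accel_scale = rep(s, 3))
}
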