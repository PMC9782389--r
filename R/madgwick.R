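# Gradient-descent (Madgwick) MARG orientation filter. The state quaternion
# is q_IRF^S: the sensor frame expressed in the IMU reference frame (IRF),
# an earth frame with Z up (gravity) and X along magnetic north (the
# horizontal component of the measured field). v_IRF = q (x) v_S (x) q*.

#' Orientation-filter configuration
#'
#' @param beta Filter gain (dimensionless). Default 0.043.
#' @param q0 Initial quaternion, or `"auto"` for an accelerometer +
#'   magnetometer TRIAD solution over the first static second.
#' @param warmup Convergence window (s) to exclude from error metrics.
#' @param use_mag Include the magnetometer (MARG) correction term; when
#'   `FALSE` only gravity corrects the gyro integration (IMU mode) and the
#'   heading is defined by `q0`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(beta = 0.043, q0 = "auto", warmup = 5, use_mag = TRUE) {
  stopifnot(beta >= 0, warmup >= 0)
  structure(list(beta = beta, q0 = q0, warmup = warmup, use_mag = use_mag),
            class = "filter_config")
}

#' One Madgwick MARG update step
#'
#' First-order integration of the gyro rate of change minus `beta` times the
#' normalized gradient of the combined gravity + magnetic-field objective.
#' The magnetic reference is flattened to (bx, 0, bz) from the current
#' estimate each step. With `beta = 0` the update is pure gyro integration;
#' a zero-norm accel or mag sample drops that correction term for the step.
#'
#' @param q Current unit quaternion q_IRF^S.
#' @param gyro Length-3 angular rate, rad/s (sensor frame).
#' @param accel Length-3 specific force, m/s^2.
#' @param mag Length-3 magnetic field, a.u.
#' @param dt Step, s.
#' @param beta Filter gain.
#' @param use_mag Include the magnetometer term.
#' @return Updated unit quaternion.
#' @export
madgwick_step <- function(q, gyro, accel, mag, dt, beta = 0.043, use_mag = TRUE) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  qdot <- 0.5 * qmul_raw(q, c(0, gyro))
  if (beta > 0) {
    grad <- c(0, 0, 0, 0)
    an <- sqrt(sum(accel^2))
    if (an > 1e-12) {
      a <- accel / an
      # objective: R(q)^T (0,0,1) - a  (third row of R)
      f <- c(2 * (x * z - w * y) - a[1],
             2 * (w * x + y * z) - a[2],
             1 - 2 * (x^2 + y^2) - a[3])
      # J^T f, J = d f / d (w,x,y,z)
      grad <- grad + c(-2 * y * f[1] + 2 * x * f[2],
                        2 * z * f[1] + 2 * w * f[2] - 4 * x * f[3],
                       -2 * w * f[1] + 2 * z * f[2] - 4 * y * f[3],
                        2 * x * f[1] + 2 * y * f[2])
    }
    mn <- sqrt(sum(mag^2))
    if (use_mag && mn > 1e-12) {
      m <- mag / mn
      h <- qrotate(q, m)                       # field in IRF
      bx <- sqrt(h[1]^2 + h[2]^2); bz <- h[3]
      fb <- c(bx * (1 - 2 * y^2 - 2 * z^2) + 2 * bz * (x * z - w * y) - m[1],
              2 * bx * (x * y - w * z) + 2 * bz * (w * x + y * z) - m[2],
              2 * bx * (x * z + w * y) + bz * (1 - 2 * x^2 - 2 * y^2) - m[3])
      grad <- grad + c(
        -2 * bz * y * fb[1] + (-2 * bx * z + 2 * bz * x) * fb[2] + 2 * bx * y * fb[3],
         2 * bz * z * fb[1] + (2 * bx * y + 2 * bz * w) * fb[2] + (2 * bx * z - 4 * bz * x) * fb[3],
        (-4 * bx * y - 2 * bz * w) * fb[1] + (2 * bx * x + 2 * bz * z) * fb[2] + (2 * bx * w - 4 * bz * y) * fb[3],
        (-4 * bx * z + 2 * bz * x) * fb[1] + (-2 * bx * w + 2 * bz * y) * fb[2] + 2 * bx * x * fb[3])
    }
    gn <- sqrt(sum(grad^2))
    if (gn > 1e-12) qdot <- qdot - beta * grad / gn
  }
  q <- q + qdot * dt
  q / sqrt(sum(q^2))
}

# unnormalized Hamilton product for scalar quaternions (internal hot path)
qmul_raw <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' TRIAD orientation from one accelerometer/magnetometer sample pair
#'
#' Builds q_IRF^S from the mean specific force (gravity, IRF +Z) and mean
#' magnetic field (horizontal component = IRF +X) over a static window.
#'
#' @param accel,mag Length-3 mean accelerometer / magnetometer vectors.
#' @return Unit quaternion q_IRF^S.
#' @export
triad_init <- function(accel, mag) {
  zs <- accel / sqrt(sum(accel^2))            # IRF Z axis in sensor coords
  mh <- mag - sum(mag * zs) * zs              # horizontal field
  nh <- sqrt(sum(mh^2))
  if (nh < 1e-9) stop("magnetic field parallel to gravity: heading undefined", call. = FALSE)
  xs <- mh / nh                               # IRF X axis in sensor coords
  ys <- .cross_rows(matrix(zs, 1), matrix(xs, 1))[1, ]
  # columns of M are IRF axes in sensor coords; R(q) = t(M)
  qfrom_matrix(t(cbind(xs, ys, zs)))
}

#' Run the orientation filter over an IMU record
#'
#' Produces the time-varying sensor orientation q_t(IRF -> IMU-sf) at the
#' record's own rate, sign-continuous.
#'
#' @param rec A calibrated `imu_record`.
#' @param cfg A `filter_config`.
#' @return A `quat_series` from `"IRF"` to `"IMU-sf"`.
#' @export
run_orientation_filter <- function(rec, cfg = filter_config()) {
  n <- nrow(rec)
  dt <- qs_dt(rec)
  if (n * dt <= cfg$warmup) stop("record shorter than the filter warm-up window", call. = FALSE)
  gy <- imu_gyro(rec); ac <- imu_accel(rec); mg <- imu_mag(rec)
  if (identical(cfg$q0, "auto")) {
    k <- min(n, max(2L, round(1 / dt)))       # first static second
    q <- triad_init(colMeans(ac[seq_len(k), , drop = FALSE]),
                    colMeans(mg[seq_len(k), , drop = FALSE]))
  } else {
    q <- qnormalize(cfg$q0)
  }
  out <- matrix(0, n, 4)
  out[1, ] <- q
  for (i in seq_len(n - 1L)) {
    q <- madgwick_step(q, gy[i, ], ac[i, ], mg[i, ], dt,
                       beta = cfg$beta, use_mag = cfg$use_mag)
    out[i + 1L, ] <- q
  }
  enforce_continuity(quat_series(rec$time, out, from = "IRF", to = "IMU-sf"))
}
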