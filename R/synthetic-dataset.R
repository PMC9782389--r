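# From ground-truth kinematics to measurements: soft-tissue artefact
# injection, marker trajectories (250 Hz) and raw IMU signals (500 Hz),
# with exact ground truth carried alongside.

#' Default synthetic skeleton and instrumentation geometry
#'
#' Segment lengths, landmark and rigid-marker-cluster local coordinates
#' (mm, in the segment anatomical frame: X anterior, Y up, Z right; cluster
#' coordinates in the sensor frame), and sensor mounting positions. The
#' skeleton's hip joint centres sit exactly at the regression location used
#' by [hip_joint_center()], so anatomical-landmark frames coincide with
#' bone frames in the error-free world.
#'
#' @return A named list of geometry constants.
#' @export
default_geometry <- function() {
  list(
    pelvis_height_mm = 1000,
    inter_asis_mm = 240,
    hjc_frac = c(-0.19, -0.30, 0.36),
    thigh_length_mm = 420,
    shank_length_mm = 400,
    landmarks = list(
      pelvis = list(LASIS = c(0, 0, -120), RASIS = c(0, 0, 120),
                    LPSIS = c(-150, 0, -50), RPSIS = c(-150, 0, 50)),
      thigh_r = list(RMEP = c(0, -420, -55), RLEP = c(0, -420, 55),
                     RTHIGH = c(-60, -210, 0)),
      thigh_l = list(LMEP = c(0, -420, 55), LLEP = c(0, -420, -55),
                     LTHIGH = c(-60, -210, 0)),
      shank_r = list(RMMAL = c(0, -400, -45), RLMAL = c(0, -400, 45),
                     RSHANK = c(40, -200, 0)),
      shank_l = list(LMMAL = c(0, -400, 45), LLMAL = c(0, -400, -45),
                     LSHANK = c(40, -200, 0))),
    rmc_local = list(RMC1 = c(70, 50, 35), RMC2 = c(-68, 48, 15),
                     RMC3 = c(-70, -52, 30), RMC4 = c(66, -46, 12)),
    sensor_offset = list(pelvis = c(-130, -20, 0),
                         thigh_l = c(30, -200, -60), thigh_r = c(30, -200, 60),
                         shank_l = c(30, -180, -50), shank_r = c(30, -180, 50)),
    sta_axis = c(0, 0, 1),
    impact_disp_mm = 6)
}

#' Inject soft tissue artefact onto a bone orientation series
#'
#' The skin-mounted cluster rotates relative to the bone by
#' delta_t = R(axis, sta_gain * flexion(t) + impact transients): a
#' low-frequency component proportional to the adjacent joint's flexion
#' (skin sliding) plus an exponentially damped oscillation at each impact.
#' Returns skin_t = bone_t (x) delta_t and the injected STA angle series
#' qangle(delta_t).
#'
#' @param time Timestamps (s).
#' @param bone_q n x 4 bone orientation matrix (GRF -> bone).
#' @param flexion_deg Adjacent-joint flexion angle series (deg).
#' @param cfg A `synthetic_config` (uses `sta_gain`, `impact_deg`,
#'   `impact_freq_hz`, `impact_tau`).
#' @param events Impact event times (s).
#' @param flexion_dot Flexion rate (deg/s); needed when `omega_bone` is
#'   supplied.
#' @param omega_bone n x 3 exact bone angular velocity (rad/s, body frame);
#'   when given, the exact skin angular velocity is returned too.
#' @param axis STA rotation axis in the body frame.
#' @return List: `q_skin` (n x 4), `sta_deg` (n), and `omega_skin`
#'   (n x 3) when `omega_bone` was supplied.
#' @export
inject_sta <- function(time, bone_q, flexion_deg, cfg, events = numeric(0),
                       flexion_dot = NULL, omega_bone = NULL, axis = c(0, 0, 1)) {
  imp <- p_impacts(events, cfg$impact_deg, cfg$impact_freq_hz, cfg$impact_tau)(time)
  theta <- cfg$sta_gain * flexion_deg + imp$v           # deg
  d2r <- pi / 180
  half <- theta * d2r / 2
  dq <- cbind(cos(half), sin(half) %o% (axis / sqrt(sum(axis^2))))
  out <- list(q_skin = qmul(bone_q, dq), sta_deg = abs(theta))
  if (!is.null(omega_bone)) {
    if (is.null(flexion_dot)) stop("flexion_dot required with omega_bone", call. = FALSE)
    theta_dot <- (cfg$sta_gain * flexion_dot + imp$d) * d2r
    n <- nrow(dq)
    omega_skin <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      omega_skin[i, ] <- qrotate(qinv(dq[i, ]), omega_bone[i, ])
    }
    out$omega_skin <- omega_skin + theta_dot %o% axis
    out
  } else out
}

# skin kinematics for every segment of a trial
.skin_motion <- function(motion, cfg, geometry) {
  out <- list()
  for (s in SEGMENTS) {
    m <- motion[[s]]
    events <- motion$recipe$impacts[[s]] %||% numeric(0)
    out[[s]] <- inject_sta(motion$time, m$q, m$flexion_deg, cfg, events = events,
                           flexion_dot = m$flexion_dot, omega_bone = m$omega,
                           axis = geometry$sta_axis)
  }
  out
}

# vertical impact displacement (mm) shared by the cluster markers and the IMU
.impact_disp <- function(time, events, geometry, cfg) {
  if (!length(events)) return(list(v = numeric(length(time)), d = numeric(length(time))))
  p_impacts(events, geometry$impact_disp_mm, cfg$impact_freq_hz, cfg$impact_tau)(time)
}

#' Synthesize the optical marker set for one trial
#'
#' Anatomical-landmark markers ride the bone poses (optionally with a
#' fraction of the segment STA); rigid-cluster markers ride the skin poses
#' composed with the sensor mounting. Output at 250 Hz with optional white
#' position noise.
#'
#' @param motion Output of [generate_segment_motion()].
#' @param cfg A `synthetic_config`.
#' @param mounts Named list of mounting quaternions (skin -> sensor frame)
#'   per segment; identity when omitted.
#' @param geometry See [default_geometry()].
#' @param skin Precomputed [inject_sta()] results per segment (internal reuse).
#' @return A `marker_set` at 250 Hz.
#' @export
synthesize_marker_set <- function(motion, cfg, mounts = NULL,
                                  geometry = default_geometry(), skin = NULL) {
  if (is.null(skin)) skin <- .skin_motion(motion, cfg, geometry)
  if (is.null(mounts)) mounts <- stats::setNames(rep(list(qidentity()), 5), SEGMENTS)
  idx <- seq(1, length(motion$time), by = 2)
  time <- motion$time[idx]
  positions <- list()
  for (s in SEGMENTS) {
    m <- motion[[s]]
    q_land <- if (cfg$landmark_sta_frac > 0) {
      sub <- inject_sta(motion$time, m$q, m$flexion_deg,
                        within_cfg_gain(cfg, cfg$landmark_sta_frac),
                        events = motion$recipe$impacts[[s]] %||% numeric(0),
                        axis = geometry$sta_axis)
      sub$q_skin[idx, , drop = FALSE]
    } else m$q[idx, , drop = FALSE]
    org <- m$origin[idx, , drop = FALSE]
    for (nm in names(geometry$landmarks[[s]])) {
      r <- geometry$landmarks[[s]][[nm]]
      positions[[nm]] <- org + qrotate(q_land, matrix(r, 1)[rep(1, length(idx)), ])
    }
    # cluster markers on the skin + mounting
    qsk <- skin[[s]]$q_skin[idx, , drop = FALSE]
    qsens <- qmul(qsk, matrix(mounts[[s]], 1)[rep(1, length(idx)), ])
    disp <- .impact_disp(time, motion$recipe$impacts[[s]] %||% numeric(0), geometry, cfg)
    base <- org + qrotate(qsk, matrix(geometry$sensor_offset[[s]], 1)[rep(1, length(idx)), ])
    base[, 3] <- base[, 3] + disp$v
    for (k in names(geometry$rmc_local)) {
      nm <- paste0(toupper(s), "_", k)
      positions[[nm]] <- base + qrotate(qsens, matrix(geometry$rmc_local[[k]], 1)[rep(1, length(idx)), ])
    }
  }
  if (cfg$marker_noise_mm > 0) {
    for (nm in names(positions)) {
      positions[[nm]] <- positions[[nm]] +
        matrix(stats::rnorm(3 * length(idx), 0, cfg$marker_noise_mm), ncol = 3)
    }
  }
  marker_set(time, positions)
}

within_cfg_gain <- function(cfg, frac) {
  cfg$sta_gain <- cfg$sta_gain * frac
  cfg$impact_deg <- cfg$impact_deg * frac
  cfg
}

# homogeneous earth field in GRF (+ optional dipole disturbance), unit norm
.mag_field_grf <- function(cfg, pos_mm = NULL) {
  d2r <- pi / 180
  b_irf <- c(cos(cfg$mag_dip_deg * d2r), 0, -sin(cfg$mag_dip_deg * d2r))
  he <- qfrom_axis_angle(c(0, 0, 1), cfg$mag_declination_deg)
  b <- qrotate(he, b_irf)
  if (is.null(cfg$mag_disturbance) || is.null(pos_mm)) {
    matrix(b, nrow = if (is.null(pos_mm)) 1 else nrow(pos_mm), ncol = 3, byrow = TRUE)
  } else {
    dist <- cfg$mag_disturbance
    r <- sweep(pos_mm, 2, dist$position) / dist$radius_mm
    rn <- sqrt(rowSums(r^2))
    rhat <- r / rn
    mhat <- dist$moment / sqrt(sum(dist$moment^2))
    dot <- rhat %*% mhat
    dip <- dist$strength * (3 * rhat * drop(dot) -
                            matrix(mhat, nrow(pos_mm), 3, byrow = TRUE)) / rn^3
    sweep(dip, 2, b, "+")
  }
}

#' Synthesize raw IMU signals for one trial
#'
#' Gyroscope: exact skin angular velocity in the sensor frame plus bias and
#' white noise. Accelerometer: specific force (sensor linear acceleration
#' minus gravity) from five-point finite differences of the sensor
#' trajectory, expressed in the sensor frame. Magnetometer: the (optionally
#' dipole-disturbed) earth field in the sensor frame.
#'
#' @inheritParams synthesize_marker_set
#' @param biases Named list of length-3 gyro biases (rad/s) per segment;
#'   drawn from `cfg$gyro_bias` when omitted (a length-3 vector in `cfg` is
#'   used directly, a scalar is an SD).
#' @return A list per segment: `rec` (the `imu_record`), `q_true`
#'   (`quat_series` IRF -> IMU-sf ground truth), `bias`.
#' @export
synthesize_imu_signals <- function(motion, cfg, mounts = NULL, biases = NULL,
                                   geometry = default_geometry(), skin = NULL) {
  if (is.null(skin)) skin <- .skin_motion(motion, cfg, geometry)
  if (is.null(mounts)) mounts <- stats::setNames(rep(list(qidentity()), 5), SEGMENTS)
  time <- motion$time
  n <- length(time)
  dt <- time[2] - time[1]
  he <- qfrom_axis_angle(c(0, 0, 1), cfg$mag_declination_deg)
  out <- list()
  for (s in SEGMENTS) {
    m <- motion[[s]]
    if (is.null(biases)) {
      bias <- if (length(cfg$gyro_bias) == 3) cfg$gyro_bias else stats::rnorm(3, 0, cfg$gyro_bias)
    } else bias <- biases[[s]]
    qsk <- skin[[s]]$q_skin
    mount <- mounts[[s]]
    qsens <- qmul(qsk, matrix(mount, 1)[rep(1, n), ])
    # gyro: skin angular velocity re-expressed through the mounting
    Rm <- qto_matrix(mount)
    gyro <- skin[[s]]$omega_skin %*% Rm          # R(mount)^T omega (row form)
    # sensor trajectory (m) and specific force
    disp <- .impact_disp(time, motion$recipe$impacts[[s]] %||% numeric(0), geometry, cfg)
    p <- m$origin + qrotate(qsk, matrix(geometry$sensor_offset[[s]], 1)[rep(1, n), ])
    p[, 3] <- p[, 3] + disp$v
    p <- p / 1000
    acc_grf <- .fd2(p, dt)
    acc_grf[, 3] <- acc_grf[, 3] + 9.81
    accel <- t(vapply(seq_len(n), function(i) qrotate(qinv(qsens[i, ]), acc_grf[i, ]),
                      numeric(3)))
    # magnetometer
    b_grf <- .mag_field_grf(cfg, pos_mm = if (is.null(cfg$mag_disturbance)) NULL else
                              m$origin)
    if (nrow(b_grf) == 1) b_grf <- b_grf[rep(1, n), , drop = FALSE]
    mag <- t(vapply(seq_len(n), function(i) qrotate(qinv(qsens[i, ]), b_grf[i, ]),
                    numeric(3)))
    gyro <- sweep(gyro, 2, bias, "+")
    if (cfg$gyro_noise > 0) gyro <- gyro + matrix(stats::rnorm(3 * n, 0, cfg$gyro_noise), ncol = 3)
    if (cfg$accel_noise > 0) accel <- accel + matrix(stats::rnorm(3 * n, 0, cfg$accel_noise), ncol = 3)
    if (cfg$mag_noise > 0) mag <- mag + matrix(stats::rnorm(3 * n, 0, cfg$mag_noise), ncol = 3)
    rec <- imu_record(time, gyro, accel, mag, sensor_id = s)
    q_true <- quat_series(time, qmul(matrix(qinv(he), 1)[rep(1, n), ], qsens),
                          from = "IRF", to = "IMU-sf")
    out[[s]] <- list(rec = rec, q_true = q_true, bias = bias)
  }
  out
}

# five-point central second derivative per column; endpoints padded
.fd2 <- function(p, dt) {
  n <- nrow(p)
  out <- matrix(0, n, ncol(p))
  i <- 3:(n - 2)
  out[i, ] <- (-p[i - 2, ] + 16 * p[i - 1, ] - 30 * p[i, ] + 16 * p[i + 1, ] - p[i + 2, ]) /
    (12 * dt^2)
  out[1:2, ] <- out[rep(3, 2), ]
  out[(n - 1):n, ] <- out[rep(n - 2, 2), ]
  out
}

#' Synthesize the compass trial marker set
#'
#' Two static markers laid along magnetic north (heading =
#' `mag_declination_deg` in GRF), 1 m apart.
#'
#' @param cfg A `synthetic_config`.
#' @return A `marker_set` with markers `COMPASS1` (south end) and
#'   `COMPASS2` (north end) at 250 Hz.
#' @export
synthesize_compass <- function(cfg) {
  time <- seq(0, cfg$duration - 1 / 250, by = 1 / 250)
  d2r <- pi / 180
  dir <- c(cos(cfg$mag_declination_deg * d2r), sin(cfg$mag_declination_deg * d2r), 0)
  n <- length(time)
  p1 <- matrix(c(0, 0, 100), n, 3, byrow = TRUE) - matrix(500 * dir, n, 3, byrow = TRUE)
  p2 <- matrix(c(0, 0, 100), n, 3, byrow = TRUE) + matrix(500 * dir, n, 3, byrow = TRUE)
  if (cfg$marker_noise_mm > 0) {
    p1 <- p1 + matrix(stats::rnorm(3 * n, 0, cfg$marker_noise_mm), ncol = 3)
    p2 <- p2 + matrix(stats::rnorm(3 * n, 0, cfg$marker_noise_mm), ncol = 3)
  }
  marker_set(time, list(COMPASS1 = p1, COMPASS2 = p2))
}

#' Simulate one complete trial in memory
#'
#' Ground-truth kinematics, STA injection, marker set and IMU records for
#' one trial, reproducible from `cfg$seed`.
#'
#' @param cfg A `synthetic_config`.
#' @param mounts,biases Optional per-segment mounting quaternions / gyro
#'   biases (drawn from the seed when omitted).
#' @param geometry See [default_geometry()].
#' @return A list: `motion`, `skin`, `markers`, `imu`, `mounts`, `cfg`.
#' @export
simulate_trial <- function(cfg, mounts = NULL, biases = NULL,
                           geometry = default_geometry()) {
  set.seed(cfg$seed)
  if (is.null(mounts)) {
    mounts <- lapply(stats::setNames(SEGMENTS, SEGMENTS), function(s) {
      ax <- stats::rnorm(3)
      qfrom_axis_angle(ax, cfg$mount_deg)
    })
  }
  motion <- generate_segment_motion(cfg, geometry)
  skin <- .skin_motion(motion, cfg, geometry)
  markers <- synthesize_marker_set(motion, cfg, mounts, geometry, skin = skin)
  imu <- synthesize_imu_signals(motion, cfg, mounts, biases, geometry, skin = skin)
  list(motion = motion, skin = skin, markers = markers, imu = imu,
       mounts = mounts, cfg = cfg)
}
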