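static_rec <- function(accel, n = 500, gnoise = 0, anoise = 0) {
  t <- seq(0, by = 0.002, length.out = n)
  imu_record(t, matrix(rnorm(3 * n, 0, gnoise), n, 3),
             matrix(accel, n, 3, byrow = TRUE) + matrix(rnorm(3 * n, 0, anoise), n, 3),
             matrix(c(0.4, 0, -0.9), n, 3, byrow = TRUE))
}

gyro_rec <- function(gyro, dt = 0.002) {
  n <- nrow(gyro)
  t <- seq(0, by = dt, length.out = n)
  imu_record(t, gyro, matrix(c(0, 0, 9.81), n, 3, byrow = TRUE),
             matrix(c(0.4, 0, -0.9), n, 3, byrow = TRUE))
}

test_that("the longitudinal axis is the unit mean gravity direction", {
  expect_equal(longitudinal_axis_static(static_rec(c(0, 0, 9.81))), c(0, 0, 1))
  tilted <- qrotate(qinv(qfrom_axis_angle(c(1, 0, 0), 30)), c(0, 0, 9.81))
  ax <- longitudinal_axis_static(static_rec(tilted))
  expect_equal(acos(sum(ax * c(0, 0, 1))) * 180 / pi, 30, tolerance = 1e-9)
  set.seed(14)
  noisy <- longitudinal_axis_static(static_rec(c(0, 0, 9.81), n = 1000, anoise = 0.2))
  expect_lt(acos(pmin(1, sum(noisy * c(0, 0, 1)))) * 180 / pi, 0.3)
  moving <- static_rec(c(0, 0, 9.81), gnoise = 0.5)
  expect_error(longitudinal_axis_static(moving), "not static")
})

test_that("the functional flexion axis is recovered and sign-aligned", {
  t <- seq(0, 4, by = 0.002)
  g <- cbind(0, 0.1 * sin(2 * pi * t), 0)
  ax <- flexion_axis_functional(gyro_rec(g), c(0, 0, 1))
  expect_equal(ax, c(0, 1, 0), tolerance = 1e-9)
  # flex/extend cycles: alternate-sign samples collapse onto one axis
  g2 <- g * rep_len(c(1, -1), nrow(g))
  ax2 <- flexion_axis_functional(gyro_rec(g2), c(0, 0, 1))
  expect_equal(abs(ax2[2]), 1, tolerance = 1e-9)
  # the longitudinal component is projected out
  g3 <- cbind(0, sin(2 * pi * t), 0.3 * sin(2 * pi * t))
  ax3 <- flexion_axis_functional(gyro_rec(g3), c(0, 0, 1))
  expect_lt(abs(ax3[3]), 1e-12)
  expect_error(flexion_axis_functional(gyro_rec(g * 0.01), c(0, 0, 1)),
               "insufficient")
})

test_that("sensor-body calibration builds an orthonormal right-handed triad", {
  cal <- build_sensor_body_cal(c(0, 1, 0), c(0, 0, 1), "B", "thigh_r")
  expect_equal(cal$q, qidentity())
  cal2 <- build_sensor_body_cal(c(0, 1, 0), c(0.1, 0, 0.995), "A")
  R <- qto_matrix(cal2$q)
  expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-10)
  expect_equal(R[, 2], c(0, 1, 0))
  expect_error(build_sensor_body_cal(c(0, 1, 0), c(0, 0.999, 0.04), "C"),
               "degenerate")
})

test_that("the functional calibration recovers a known sensor mounting", {
  # squat-like flexion seen through a 25 deg mounting rotation
  mount <- qfrom_axis_angle(c(1, 2, 0.5), 25)
  t <- seq(0, 4, by = 0.002)
  rate <- 1.5 * sin(2 * pi * t / 4)          # rad/s about body z
  gyro <- t(vapply(rate, function(r) qrotate(qinv(mount), c(0, 0, r)), numeric(3)))
  long <- qrotate(qinv(mount), c(0, 1, 0))
  flex <- flexion_axis_functional(gyro_rec(gyro), long)
  cal <- build_sensor_body_cal(long, flex, "B")
  # composing the mounting with the calibration returns the body frame
  expect_lt(qangle(qrel(cal$q, qinv(mount))), 2)
})

test_that("hand-eye calibration is the compass heading yaw", {
  t <- seq_len(50) / 250
  mk <- function(dir) {
    marker_set(t, list(COMPASS1 = matrix(-500 * dir, 50, 3, byrow = TRUE),
                       COMPASS2 = matrix(500 * dir, 50, 3, byrow = TRUE)))
  }
  expect_equal(hand_eye_from_compass(mk(c(1, 0, 0))), qidentity())
  q35 <- hand_eye_from_compass(mk(c(cos(35 * pi / 180), sin(35 * pi / 180), 0)))
  expect_equal(qangle(q35), 35, tolerance = 1e-9)
  expect_equal(qrotate(q35, c(1, 0, 0))[2], sin(35 * pi / 180), tolerance = 1e-9)
  expect_error(hand_eye_from_compass(mk(c(0, 0, 1))), "horizontal")
})

test_that("static-trial alignment recovers constant sensor-to-body offsets", {
  set.seed(15)
  t <- seq_len(500) / 250
  body <- quat_series(t, rand_quat(1), from = "GRF", to = "AL-mcbf")
  expect_equal(static_frame_alignment(body, body)$q, qidentity())

  off <- qfrom_axis_angle(c(0.3, 1, 0.1), 12)
  sens <- quat_series(t, qmul(qs_matrix(body), matrix(off, 1)[rep(1, 500), ]),
                      from = "GRF", to = "RMC-sf")
  cal <- static_frame_alignment(body, sens)
  expect_equal(qangle(cal$q), 12, tolerance = 1e-9)
  aligned <- apply_mcbf_alignment(sens, cal, to = "RMC-mcbf")
  expect_lt(max(qangle(qmul(qinv(qs_matrix(body)), qs_matrix(aligned)))), 1e-6)

  # 0.5 deg jitter on 500 samples: alignment within 0.1 deg of the offset
  jitter <- t(vapply(1:500, function(i) {
    qmul(qmul(qs_matrix(body)[i, ], off), qfrom_axis_angle(rnorm(3), rnorm(1, 0, 0.5)))
  }, numeric(4)))
  cal2 <- static_frame_alignment(body, quat_series(t, jitter))
  expect_lt(qangle(qrel(cal2$q, off)), 0.1)
  expect_error(static_frame_alignment(body, sens[1:10, ]), "mismatch")
})

test_that("synchronization is exact on constructed shifts and bounded at 2 ms", {
  cfg <- noise_free_cfg("squat_jump", duration = 5, seed = 16)
  sim <- simulate_trial(cfg)
  rec <- sim$imu$thigh_r$rec
  q_rmc <- cluster_frame(sim$markers, rmc_geometry("thigh_r"))
  m <- qs_matrix(q_rmc); n <- nrow(m)
  for (d in c(0L, 17L, 130L)) {
    shifted <- if (d > 0) rbind(m[rep(1, d), ], m[1:(n - d), ]) else m
    sr <- estimate_sync_offset(rec, quat_series(q_rmc$time, shifted,
                                                from = "GRF", to = "RMC-sf"))
    expect_identical(sr$lag, d)
    expect_identical(sr$residual_bound, 0.002)
  }
  flat <- quat_series(q_rmc$time, matrix(qidentity(), n, 4, byrow = TRUE))
  expect_error(estimate_sync_offset(static_rec(c(0, 0, 9.81), n = 2 * n), flat),
               "excitation")
})

test_that("down-sampling halves the rate and preserves integrated orientation", {
  t500 <- seq(0, 4 - 0.002, by = 0.002)
  ang <- 2 * pi * 2 * t500               # 2 Hz rotation
  m <- t(vapply(ang, function(a) qfrom_axis_angle(c(0, 0, 1), a * 180 / pi),
                numeric(4)))
  s <- quat_series(t500, m, from = "IRF", to = "IMU-sf")
  down <- downsample_series(s, 2)
  expect_equal(nrow(down), length(t500) / 2)
  expect_equal(qs_dt(down), 0.004)
  direct <- t(vapply(ang[seq(1, length(ang), 2)],
                     function(a) qfrom_axis_angle(c(0, 0, 1), a * 180 / pi), numeric(4)))
  expect_lt(max(qangle(qmul(qinv(qs_matrix(down)), direct))), 0.05)
  expect_error(downsample_series(s, 1.5), "integer")
})
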