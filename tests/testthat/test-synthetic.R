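test_that("trial simulation is deterministic under a fixed seed", {
  cfg <- synthetic_config(movement = "walk", duration = 2, static_lead = 1, seed = 33)
  a <- simulate_trial(cfg)
  b <- simulate_trial(cfg)
  expect_identical(a$markers, b$markers)
  expect_identical(a$imu$thigh_r$rec, b$imu$thigh_r$rec)
  expect_identical(a$mounts, b$mounts)
})

test_that("zero intensity collapses to the static pose", {
  cfg <- noise_free_cfg("squat", intensity = 0, duration = 2, static_lead = 1)
  m <- generate_segment_motion(cfg)
  for (s in c("pelvis", "thigh_r", "shank_l")) {
    expect_lt(max(abs(m[[s]]$omega)), 1e-9, label = s)
    expect_lt(max(qangle(qmul(qinv(m[[s]]$q[1, ]), m[[s]]$q))), 1e-9, label = s)
  }
})

test_that("the squat flexion profile is periodic at the requested cadence", {
  cfg <- noise_free_cfg("squat", duration = 8, static_lead = 0.5, cadence_hz = 0.5)
  m <- generate_segment_motion(cfg)
  flex <- m$thigh_r$flexion_deg
  t <- m$time
  on <- t >= 0.5
  period <- 2 / (1 / 500)                  # 2 s in samples
  x <- flex[on]
  expect_gt(stats::cor(x[1:(length(x) - period)], x[(period + 1):length(x)]), 0.999)
  expect_gte(min(flex), 0)
})

test_that("emitted angular velocity is consistent with the orientation series", {
  for (mv in c("squat", "walk", "kick")) {
    cfg <- noise_free_cfg(mv, duration = 6, static_lead = 1, intensity = 0.8)
    m <- generate_segment_motion(cfg)
    for (s in c("thigh_r", "shank_r")) {
      # numerical derivative of q matches the analytic omega within 0.1 % RMS
      w_num <- qs_angular_rate(quat_series(m$time, m[[s]]$q))
      w_ana <- sqrt(rowSums(m[[s]]$omega^2))
      mid <- 50:(length(m$time) - 50)
      rel <- sqrt(mean((w_num$rate[mid] - w_ana[mid])^2)) / max(w_ana)
      expect_lt(rel, 0.001, label = paste(mv, s))
    }
  }
})

test_that("STA injection matches its closed forms", {
  cfg <- synthetic_config(sta_gain = 0.3, impact_deg = 0)
  t <- seq(0, 10 - 0.002, by = 0.002)
  n <- length(t)
  bone <- matrix(qidentity(), n, 4, byrow = TRUE)
  # zero gains: skin == bone
  cfg0 <- synthetic_config(sta_gain = 0, impact_deg = 0)
  out0 <- inject_sta(t, bone, rep(30, n), cfg0)
  expect_equal(out0$q_skin, bone)
  expect_equal(out0$sta_deg, rep(0, n))
  # sinusoidal flexion F = 20 deg, gain 0.3: RMS = g F / sqrt(2) within 1 %
  flex <- 20 * sin(2 * pi * t)
  out <- inject_sta(t, bone, flex, cfg)
  expect_equal(sqrt(mean(out$sta_deg^2)), 0.3 * 20 / sqrt(2), tolerance = 0.01)
  expect_equal(out$sta_deg, qangle(qmul(qinv(bone), out$q_skin)), tolerance = 1e-9)
  # impact: decaying transient with the configured time constant
  cfgi <- synthetic_config(sta_gain = 0, impact_deg = 5, impact_tau = 0.05)
  oi <- inject_sta(t, bone, rep(0, n), cfgi, events = 2)
  peak1 <- max(oi$sta_deg[t >= 2 & t < 2.1])
  peak2 <- max(oi$sta_deg[t >= 2.1 & t < 2.2])
  expect_gt(peak1, 3)
  expect_equal(peak2 / peak1, exp(-0.1 / 0.05), tolerance = 0.3)
  expect_lt(max(oi$sta_deg[t > 2.6]), 0.01)
})

test_that("cluster markers recover the skin pose and noise spreads distances", {
  cfg <- noise_free_cfg("squat", duration = 2, static_lead = 0.5, mount_deg = 0)
  sim <- simulate_trial(cfg)
  q_rmc <- cluster_frame(sim$markers, rmc_geometry("shank_r"))
  idx <- seq(1, length(sim$motion$time), by = 2)
  err <- qangle(qmul(qinv(qs_matrix(q_rmc)), sim$motion$shank_r$q[idx, ]))
  expect_lt(max(err), 1e-6)

  cfgn <- synthetic_config(movement = "static", duration = 2, static_lead = 0.5,
                           marker_noise_mm = 0.5, seed = 4)
  simn <- simulate_trial(cfgn)
  d <- sqrt(rowSums((marker_xyz(simn$markers, "PELVIS_RMC1") -
                     marker_xyz(simn$markers, "PELVIS_RMC2"))^2))
  # distance between two markers with iid sigma = 0.5 mm noise spreads ~ sqrt(2) sigma
  expect_gt(stats::sd(d), 0.3)
  expect_lt(stats::sd(d), 1.2)
})

test_that("synthetic IMU signals obey static, rotational and free-fall physics", {
  cfg <- noise_free_cfg("static", duration = 2, static_lead = 1, mount_deg = 0)
  sim <- simulate_trial(cfg)
  rec <- sim$imu$pelvis$rec
  expect_lt(max(abs(imu_gyro(rec))), 1e-9)
  expect_equal(sqrt(rowSums(imu_accel(rec)^2)), rep(9.81, nrow(rec)), tolerance = 1e-6)
  expect_lt(max(apply(imu_mag(rec), 2, stats::sd)), 1e-9)

  # integrating the emitted gyro reproduces the emitted orientation
  cfg2 <- noise_free_cfg("walk", duration = 9, static_lead = 1, seed = 5)
  sim2 <- simulate_trial(cfg2)
  rec2 <- sim2$imu$shank_l$rec
  qt <- sim2$imu$shank_l$q_true
  # midpoint exponential integration of the emitted gyro
  gy <- imu_gyro(rec2)
  n2 <- nrow(gy)
  q <- qs_matrix(qt)[1, ]
  worst <- 0
  for (i in seq_len(n2 - 1)) {
    wmid <- (gy[i, ] + gy[i + 1, ]) / 2
    a <- sqrt(sum(wmid^2)) * 0.002
    q <- qmul(q, if (a > 0) qfrom_axis_angle(wmid, a * 180 / pi) else qidentity())
    worst <- max(worst, qangle(qrel(q, qs_matrix(qt)[i + 1, ])))
  }
  expect_lt(worst, 0.1)

  # free fall: specific force near zero during the flight phase
  cfg3 <- noise_free_cfg("squat_jump", duration = 4, static_lead = 1, intensity = 1)
  sim3 <- simulate_trial(cfg3)
  recj <- sim3$imu$pelvis$rec
  t <- recj$time
  fly <- t > 1 + 0.8 + 0.25 + 0.1 & t < 1 + 0.8 + 0.25 + 2 * 2.5 / 9.81 - 0.1
  expect_lt(max(sqrt(rowSums(imu_accel(recj)[fly, ]^2))), 0.3)
})

test_that("the STA and filter error sources stay separable in the simulator", {
  # comparison #4 depends on the STA amplitude, not on the IMU noise;
  # checked at the decomposition level with marker-only frames
  run4 <- function(gain) {
    cfg <- synthetic_config(movement = "walk", duration = 4, static_lead = 1,
                            sta_gain = gain, impact_deg = 0, marker_noise_mm = 0,
                            mount_deg = 0, seed = 6)
    sim <- simulate_trial(cfg)
    idx <- seq(1, length(sim$motion$time), by = 2)
    al <- quat_series(sim$markers$time, sim$motion$thigh_r$q[idx, ],
                      from = "GRF", to = "AL-mcbf")
    rmc <- cluster_frame(sim$markers, rmc_geometry("thigh_r"))
    rmc_m <- apply_mcbf_alignment(rmc, body_cal(qidentity(), "mcbf"), to = "RMC-mcbf")
    compare_frames(rmc_m, al, comparison = 4L)$rmsd_deg
  }
  r_lo <- run4(0.05); r_hi <- run4(0.15)
  expect_gt(r_hi / r_lo, 2.5)
})

test_that("datasets regenerate byte-identically from the same seed", {
  withr::with_tempdir({
    cfg <- synthetic_config(duration = 2, static_lead = 1)
    generate_dataset("d1", movements = "walk", base_cfg = cfg,
                     durations = list(movement = 2, calibA = 8, calibB = 5,
                                      calibC = 6, neutral = 2, compass = 1,
                                      static = 2), seed = 77)
    generate_dataset("d2", movements = "walk", base_cfg = cfg,
                     durations = list(movement = 2, calibA = 8, calibB = 5,
                                      calibC = 6, neutral = 2, compass = 1,
                                      static = 2), seed = 77)
    f1 <- list.files("d1", recursive = TRUE)
    expect_identical(f1, list.files("d2", recursive = TRUE))
    for (f in f1) {
      expect_identical(unname(tools::md5sum(file.path("d1", f))),
                       unname(tools::md5sum(file.path("d2", f))), label = f)
    }
    man <- read_manifest(file.path("d1", "manifest_S01.yaml"))
    expect_s3_class(man, "trial_manifest")
    expect_equal(length(man$trials), 7L)
  })
})
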