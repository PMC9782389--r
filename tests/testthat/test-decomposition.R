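const_series <- function(q, n = 100, from = "GRF", to = "IMU-sf") {
  quat_series(seq_len(n) / 250, matrix(q, n, 4, byrow = TRUE), from = from, to = to)
}

test_that("sensor-body composition right-multiplies per sample", {
  s <- const_series(qidentity(), from = "IRF")
  calI <- body_cal(qidentity(), "A")
  expect_equal(qs_matrix(compose_scbf(s, calI)), qs_matrix(s))
  cal90 <- body_cal(qfrom_axis_angle(c(1, 0, 0), 90), "B")
  out <- compose_scbf(s, cal90)
  expect_equal(unique(qangle(qmul(qinv(qs_matrix(s)), qs_matrix(out)))), 90)
  expect_equal(attr(out, "to"), "IMU-scbfB")

  set.seed(17)
  sr <- quat_series(1:50 / 250, rand_quat(50), from = "IRF", to = "IMU-sf")
  calq <- rand_quat()
  comp <- qs_matrix(compose_scbf(sr, body_cal(calq, "C")))
  for (i in c(1, 25, 50)) {
    expect_lt(max(abs(qto_matrix(comp[i, ]) -
                      qto_matrix(qs_matrix(sr)[i, ]) %*% qto_matrix(calq))), 1e-10)
  }
  expect_error(compose_scbf(s, body_cal(qidentity(), "mcbf")), "mismatch")
})

test_that("hand-eye re-expression left-multiplies and commutes with composition", {
  s <- const_series(qidentity(), from = "IRF")
  expect_equal(qs_matrix(express_in_grf(s, qidentity())), qs_matrix(s))
  q35 <- qfrom_axis_angle(c(0, 0, 1), 35)
  out <- express_in_grf(s, q35)
  expect_equal(unique(qangle(qs_matrix(out))), 35)
  expect_equal(attr(out, "from"), "GRF")

  set.seed(18)
  sr <- quat_series(1:30 / 250, rand_quat(30), from = "IRF", to = "IMU-sf")
  cal <- body_cal(rand_quat(), "A")
  a <- qs_matrix(compose_scbf(express_in_grf(sr, q35), cal))
  b <- qs_matrix(express_in_grf(compose_scbf(sr, cal), q35))
  expect_lt(max(qangle(qmul(qinv(a), b))), 1e-10)
  expect_error(express_in_grf(out, q35), "mismatch")
})

test_that("frame comparison yields the smallest-angle RMSD", {
  a <- const_series(qidentity(), n = 2500, to = "IMU-mcbf")
  expect_equal(compare_frames(a, a)$rmsd_deg, 0)

  b10 <- const_series(qfrom_axis_angle(c(0, 1, 0), 10), n = 2500, to = "AL-mcbf")
  cmp <- compare_frames(a, b10, comparison = 6L)
  expect_equal(cmp$rmsd_deg, 10, tolerance = 1e-9)
  expect_equal(cmp$max_deg, 10, tolerance = 1e-9)
  expect_equal(cmp$error_source, "orientation filter + STA")

  # sinusoidal 8 deg axis-angle difference: RMSD -> 8/sqrt(2) at 10 s
  t <- seq(0, 10 - 0.004, by = 1 / 250)
  ang <- 8 * sin(2 * pi * 1.3 * t)
  mb <- t(vapply(ang, function(x) qfrom_axis_angle(c(0, 0, 1), x), numeric(4)))
  bs <- quat_series(t, mb, from = "GRF", to = "AL-mcbf")
  as <- quat_series(t, matrix(qidentity(), length(t), 4, byrow = TRUE),
                    from = "GRF", to = "IMU-mcbf")
  expect_equal(compare_frames(as, bs)$rmsd_deg, 8 / sqrt(2), tolerance = 0.01)
  # rmsd is the exact RMS of the angle series and never exceeds the max
  got <- compare_frames(as, bs)
  expect_equal(got$rmsd_deg, sqrt(mean(got$angle[[1]]$angle_deg^2)))
  expect_lte(got$rmsd_deg, got$max_deg)
  expect_error(compare_frames(const_series(qidentity(), n = 50), bs), "mismatch")
})

test_that("run_table1 produces the nine pairings and flags missing frames", {
  s <- const_series(qidentity())
  frames <- list("IMU-scbfA" = s, "IMU-scbfB" = s, "IMU-scbfC" = s,
                 "IMU-mcbf" = s, "RMC-mcbf" = s, "AL-mcbf" = s)
  out <- run_table1(frames, segment = "pelvis", trial = "squat")
  expect_equal(nrow(out), 9L)
  expect_equal(out$comparison, 1:9)
  expect_true(all(out$rmsd_deg == 0))
  expect_equal(out$frame1[4], "RMC-mcbf")
  expect_equal(out$frame2[4], "AL-mcbf")
  expect_error(run_table1(frames[-4]), "IMU-mcbf")
})

test_that("run_table1 isolates an injected constant frame-definition error", {
  set.seed(19)
  base <- quat_series(1:200 / 250, rand_quat(200), from = "GRF", to = "IMU-sf")
  delta <- qfrom_axis_angle(c(0, 1, 0), 15)
  truth_cal <- rand_quat()
  frames <- list(
    "IMU-scbfA" = compose_scbf(base, body_cal(qmul(truth_cal, delta), "A")),
    "IMU-scbfB" = compose_scbf(base, body_cal(truth_cal, "B")),
    "IMU-scbfC" = compose_scbf(base, body_cal(truth_cal, "C")),
    "IMU-mcbf" = apply_mcbf_alignment(base, body_cal(qinv(truth_cal), "mcbf")),
    "RMC-mcbf" = apply_mcbf_alignment(base, body_cal(qinv(truth_cal), "mcbf"), to = "RMC-mcbf"),
    "AL-mcbf" = quat_series(base$time,
                            qmul(qs_matrix(base), matrix(truth_cal, 1)[rep(1, 200), ]),
                            from = "GRF", to = "AL-mcbf"))
  out <- run_table1(frames)
  expect_equal(out$rmsd_deg[1], 15, tolerance = 1e-6)
  expect_lt(out$rmsd_deg[4], 1e-8)
  expect_lt(out$rmsd_deg[5], 1e-8)
  expect_lt(out$max_deg[1] - out$rmsd_deg[1], 1e-9)   # constant over time
})

test_that("aggregation follows repetitions-then-subjects with n-1 STD", {
  one <- dplyr::bind_rows(lapply(1:5, function(r) {
    compare_frames(const_series(qidentity()),
                   const_series(qfrom_axis_angle(c(1, 0, 0), 7), to = "AL-mcbf"),
                   comparison = 4L, segment = "pelvis", trial = "squat",
                   subject = "S01", repetition = r)
  }))
  class(one) <- c("frame_comparison", class(one))
  agg <- aggregate_errors(one)
  expect_equal(agg$mean_rmsd_deg, 7, tolerance = 1e-9)
  expect_equal(agg$sd_rmsd_deg, 0)
  expect_true(agg$single_subject)

  two <- dplyr::bind_rows(
    compare_frames(const_series(qidentity()),
                   const_series(qfrom_axis_angle(c(1, 0, 0), 4), to = "AL-mcbf"),
                   comparison = 4L, segment = "pelvis", trial = "squat", subject = "S01"),
    compare_frames(const_series(qidentity()),
                   const_series(qfrom_axis_angle(c(1, 0, 0), 6), to = "AL-mcbf"),
                   comparison = 4L, segment = "pelvis", trial = "squat", subject = "S02"))
  class(two) <- c("frame_comparison", class(two))
  agg2 <- aggregate_errors(two)
  expect_equal(agg2$mean_rmsd_deg, 5, tolerance = 1e-9)
  expect_equal(agg2$sd_rmsd_deg, sqrt(2), tolerance = 1e-9)
  expect_error(aggregate_errors(two[0, ]), "no comparison")
})

test_that("the independence ratio behaves like root-sum-square", {
  expect_equal(independence_check(3, 4, 5), 1)
  expect_equal(independence_check(0, 4, 4), 1)
  expect_warning(r <- independence_check(0, 0, 0), "undefined")
  expect_true(is.na(r))
})

test_that("tidiers and plots expose the results", {
  s <- const_series(qidentity())
  frames <- list("IMU-scbfA" = s, "IMU-scbfB" = s, "IMU-scbfC" = s,
                 "IMU-mcbf" = s, "RMC-mcbf" = s, "AL-mcbf" = s)
  out <- run_table1(frames, segment = "pelvis", trial = "squat", subject = "S01")
  td <- tidy(out)
  expect_false("angle" %in% names(td))
  gl <- glance(out)
  expect_equal(gl$n_comparisons, 9L)
  p <- ggplot2::autoplot(out, comparisons = 4:6)
  expect_s3_class(p, "ggplot")
  p2 <- ggplot2::autoplot(aggregate_errors(out))
  expect_s3_class(p2, "ggplot")
})
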