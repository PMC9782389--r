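# Synthetic segment kinematics for the nine-trial football protocol plus the
# three calibration movements. Motions are stylized parametric profiles
# (raised-cosine bumps and enveloped sinusoids about the sagittal axis) --
# chosen for realistic frequency content, impacts and amplitudes, not for
# physiological fidelity. Orientations are products of elementary rotations
# about body-fixed axes, so the body-frame angular velocity is analytic:
# for q = q1 (x) q2, omega = R(q2)^T omega1 + omega2.

# ---- scalar time profiles: p(t) returns list(v = value, d = derivative) ----

p_zero <- function() function(t) list(v = numeric(length(t)), d = numeric(length(t)))

p_sum <- function(...) {
  ps <- list(...)
  function(t) {
    v <- numeric(length(t)); d <- numeric(length(t))
    for (p in ps) { r <- p(t); v <- v + r$v; d <- d + r$d }
    list(v = v, d = d)
  }
}

p_scale <- function(p, k) function(t) { r <- p(t); list(v = k * r$v, d = k * r$d) }

# raised-cosine bump 0 -> A -> 0 on [t0, t1]
p_bump <- function(t0, t1, A) {
  Tw <- t1 - t0
  function(t) {
    u <- (t - t0) / Tw
    on <- u >= 0 & u <= 1
    v <- ifelse(on, A * 0.5 * (1 - cos(2 * pi * u)), 0)
    d <- ifelse(on, A * pi / Tw * sin(2 * pi * u), 0)
    list(v = v, d = d)
  }
}

# enveloped sinusoid A sin(2 pi f (t - t0)) from t0, ramping over `ramp` s
p_sine <- function(t0, f, A, ramp = 1) {
  function(t) {
    tt <- t - t0
    on <- tt >= 0
    e <- ifelse(tt < ramp, 0.5 * (1 - cos(pi * tt / ramp)), 1)
    de <- ifelse(tt < ramp, 0.5 * pi / ramp * sin(pi * tt / ramp), 0)
    s <- sin(2 * pi * f * tt); c <- cos(2 * pi * f * tt)
    v <- ifelse(on, A * e * s, 0)
    d <- ifelse(on, A * (de * s + e * 2 * pi * f * c), 0)
    list(v = v, d = d)
  }
}

# repeated raised-cosine cycles A/2 (1 - cos(2 pi f (t - t0))) from t0
p_cycles <- function(t0, f, A) {
  function(t) {
    tt <- t - t0
    on <- tt >= 0
    v <- ifelse(on, A * 0.5 * (1 - cos(2 * pi * f * tt)), 0)
    d <- ifelse(on, A * pi * f * sin(2 * pi * f * tt), 0)
    list(v = v, d = d)
  }
}

# exponentially damped sinusoid transients at event times (impacts)
p_impacts <- function(events, A, f = 15, tau = 0.05) {
  function(t) {
    v <- numeric(length(t)); d <- numeric(length(t))
    for (te in events) {
      tt <- t - te
      on <- tt >= 0
      e <- exp(-pmax(0, tt) / tau)
      s <- sin(2 * pi * f * tt); c <- cos(2 * pi * f * tt)
      v <- v + ifelse(on, A * e * s, 0)
      d <- d + ifelse(on, A * e * (2 * pi * f * c - s / tau), 0)
    }
    list(v = v, d = d)
  }
}

# ---- configuration ----

#' Synthetic trial configuration
#'
#' Defines one simulated trial: the movement family, its intensity, the
#' soft-tissue-artefact model, IMU noise/bias, magnetic environment and the
#' injected calibration error. Defaults emulate a realistic capture with a
#' consumer MEMS IMU; `seed` fixes all randomness.
#'
#' @param movement One of `"static"`, `"squat"`, `"squat_jump"`, `"walk"`,
#'   `"run"`, `"sprint"`, `"kick"`, `"calibA"`, `"calibB"`, `"calibC"`,
#'   `"compass"`.
#' @param intensity Fraction in 0..1 scaling amplitudes and cadence.
#' @param duration Movement duration (s), after the static lead.
#' @param cadence_hz Override the movement family's cyclic cadence (squat
#'   and gait families); `NULL` keeps the family default.
#' @param static_lead Static seconds preceding the movement (filter
#'   initialization and warm-up).
#' @param sta_gain Low-frequency STA: degrees of skin rotation per degree
#'   of adjacent joint flexion.
#' @param impact_deg High-frequency STA: amplitude (deg) of the damped
#'   oscillation triggered at impact events.
#' @param impact_freq_hz,impact_tau Impact transient frequency (Hz) and
#'   decay time constant (s).
#' @param landmark_sta_frac Fraction of the segment STA applied to the
#'   anatomical-landmark markers (0 = landmarks ride the bone).
#' @param gyro_noise,accel_noise,mag_noise White noise SDs (rad/s, m/s^2,
#'   a.u.).
#' @param gyro_bias Length-3 gyro bias (rad/s) or a single SD from which
#'   per-axis biases are drawn.
#' @param marker_noise_mm Marker position noise SD (mm).
#' @param mounting_error_deg Injected body-frame definition error: the
#'   calibration movement's flexion axis deviates from the bone mediolateral
#'   axis by this internal/external rotation (deg).
#' @param mount_deg Magnitude (deg) of the benign random physical mounting
#'   rotation of each sensor cluster (recovered by the calibrations).
#' @param mag_declination_deg Heading of magnetic north in GRF (the
#'   hand-eye yaw).
#' @param mag_dip_deg Magnetic inclination (downward dip).
#' @param mag_disturbance Optional list `(position, moment, strength,
#'   radius_mm)` adding a localized dipole to the homogeneous field.
#' @param seed Integer seed fixing all randomness of the trial.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(movement = "squat", intensity = 1, duration = 10,
                             static_lead = 6, cadence_hz = NULL,
                             sta_gain = 0.08, impact_deg = 2.5,
                             impact_freq_hz = 15, impact_tau = 0.05,
                             landmark_sta_frac = 0,
                             gyro_noise = 0.005, accel_noise = 0.05,
                             mag_noise = 0.003, gyro_bias = 0.002,
                             marker_noise_mm = 0.2,
                             mounting_error_deg = 0, mount_deg = 10,
                             mag_declination_deg = 12, mag_dip_deg = 67,
                             mag_disturbance = NULL, seed = 1L) {
  if (!movement %in% c("static", "squat", "squat_jump", "walk", "run", "sprint",
                       "kick", "calibA", "calibB", "calibC", "compass")) {
    stop("unknown movement: ", movement, call. = FALSE)
  }
  stopifnot(duration > 0, intensity >= 0, intensity <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

SEGMENTS <- c("pelvis", "thigh_l", "thigh_r", "shank_l", "shank_r")

# neutral orientation of every segment frame (X ant, Y up, Z right) in the
# Z-up GRF (X anterior, Y left)
q_neutral <- function() qfrom_matrix(matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, byrow = TRUE))

# movement recipe: per-joint angle profiles (deg), pelvis height (mm),
# impact event times per segment, flexion signs for functional calibration
movement_recipe <- function(cfg) {
  s0 <- cfg$static_lead; i <- cfg$intensity; dur <- cfg$duration
  zero <- p_zero()
  hip_r <- hip_l <- knee_r <- knee_l <- lumbar <- zero
  height <- zero; impacts <- list(); signs <- c(pelvis = 1, thigh_l = 1, thigh_r = 1,
                                               shank_l = 1, shank_r = 1)
  windows <- list(movement = c(s0, s0 + dur))
  switch(cfg$movement,
    static = , compass = NULL,
    squat = {
      f <- cfg$cadence_hz %||% 0.4
      ncyc <- max(1, round(dur * f)); f <- ncyc / dur
      knee_r <- knee_l <- p_cycles(s0, f, 90 * i)
      hip_r <- hip_l <- p_cycles(s0, f, 70 * i)
      lumbar <- p_cycles(s0, f, 25 * i)
      height <- p_cycles(s0, f, -250 * i)
    },
    squat_jump = {
      v0 <- 1 + 1.5 * i                       # take-off speed m/s
      tf <- 2 * v0 / 9.81
      t_push <- s0 + 0.8; t_fly <- t_push + 0.25; t_land <- t_fly + tf
      knee_r <- knee_l <- p_sum(p_bump(s0, t_fly, 95 * i),
                                p_bump(t_land, t_land + 0.6, 70 * i))
      hip_r <- hip_l <- p_sum(p_bump(s0, t_fly, 75 * i),
                              p_bump(t_land, t_land + 0.6, 50 * i))
      lumbar <- p_bump(s0, t_fly, 20 * i)
      height <- jump_height_profile(s0, v0)
      impacts <- rep(list(t_land), 5); names(impacts) <- SEGMENTS
    },
    walk = , run = , sprint = {
      f <- cfg$cadence_hz %||% c(walk = 0.9, run = 1.3, sprint = 1.7)[[cfg$movement]]
      Ah <- 15 + 30 * i; Ak <- 20 + 45 * i
      hip_r <- p_sine(s0, f, Ah); hip_l <- p_scale(p_sine(s0, f, Ah), -1)
      knee_r <- p_sine(s0, f, Ak); knee_l <- p_scale(p_sine(s0, f, Ak), -1)
      lumbar <- p_sine(s0, 2 * f, 3)
      height <- p_sine(s0, 2 * f, 15 + 20 * i)
      if (cfg$movement != "walk") {
        strikes_r <- s0 + seq(0.75 / f, dur - 0.1, by = 1 / f)
        strikes_l <- s0 + seq(0.25 / f, dur - 0.1, by = 1 / f)
        impacts <- list(pelvis = c(strikes_r, strikes_l),
                        thigh_l = strikes_l, thigh_r = strikes_r,
                        shank_l = strikes_l, shank_r = strikes_r)
      }
    },
    kick = {
      t_plant <- s0 + 0.8; t_ball <- s0 + 1.25
      hip_l <- p_bump(s0 + 0.2, s0 + 1.6, 25 * i)
      knee_l <- p_bump(s0 + 0.2, s0 + 1.4, 35 * i)
      hip_r <- p_sum(p_scale(p_bump(s0 + 0.3, s0 + 1.1, 30 * i), -1),
                     p_bump(s0 + 0.9, s0 + 2.1, 80 * i))
      knee_r <- p_bump(s0 + 0.5, s0 + 1.5, 85 * i)
      lumbar <- p_bump(s0 + 0.7, s0 + 2.1, 15 * i)
      height <- p_bump(s0 + 0.5, s0 + 1.7, -80 * i)
      impacts <- list(pelvis = c(t_plant, t_ball),
                      thigh_l = t_plant, shank_l = t_plant,
                      thigh_r = t_ball, shank_r = t_ball)
    },
    calibA = {
      # bow (pelvis), then simultaneous thigh rises (thighs + shanks)
      t1 <- c(s0, s0 + 3); t2 <- c(s0 + 3.5, s0 + 7)
      lumbar <- p_bump(t1[1], t1[2], 50)
      hip_r <- hip_l <- p_sum(p_bump(t1[1], t1[2], 30), p_bump(t2[1], t2[2], 70))
      knee_r <- knee_l <- p_bump(t2[1], t2[2], 110)
      signs[c("shank_l", "shank_r")] <- -1
      windows <- list(pelvis = t1, thigh = t2, shank = t2, movement = c(s0, t2[2]))
    },
    calibB = {
      knee_r <- knee_l <- p_bump(s0, s0 + 4, 90)
      hip_r <- hip_l <- p_bump(s0, s0 + 4, 60)
      lumbar <- p_bump(s0, s0 + 4, 25)
      height <- p_bump(s0, s0 + 4, -250)
      signs[c("shank_l", "shank_r")] <- -1
      windows <- list(pelvis = c(s0, s0 + 4), thigh = c(s0, s0 + 4),
                      shank = c(s0, s0 + 4), movement = c(s0, s0 + 4))
    },
    calibC = {
      # inclined plank: straight-body pitch
      lumbar <- hip_r <- hip_l <- p_bump(s0, s0 + 5, 35)
      windows <- list(pelvis = c(s0, s0 + 5), thigh = c(s0, s0 + 5),
                      shank = c(s0, s0 + 5), movement = c(s0, s0 + 5))
    })
  list(hip_r = hip_r, hip_l = hip_l, knee_r = knee_r, knee_l = knee_l,
       lumbar = lumbar, height = height, impacts = impacts, signs = signs,
       windows = windows)
}

# piecewise vertical pelvis profile for the squat jump (mm)
jump_height_profile <- function(s0, v0, depth = 0.35) {
  g <- 9.81
  t_push <- s0 + 0.8; tp <- 0.25; a <- v0 / tp
  t_fly <- t_push + tp; tf <- 2 * v0 / g; t_land <- t_fly + tf; tl <- 0.25
  h_push <- -depth + 0.5 * a * tp^2
  h_land <- h_push                             # returns at -v0
  function(t) {
    v <- numeric(length(t)); d <- numeric(length(t))
    crouch <- t >= s0 & t < t_push
    u <- (t - s0) / 0.8
    v[crouch] <- -depth * 0.5 * (1 - cos(pi * u[crouch]))
    d[crouch] <- -depth * pi / 1.6 * sin(pi * u[crouch])
    push <- t >= t_push & t < t_fly
    tt <- t - t_push
    v[push] <- -depth + 0.5 * a * tt[push]^2
    d[push] <- a * tt[push]
    fly <- t >= t_fly & t < t_land
    tt <- t - t_fly
    v[fly] <- h_push + v0 * tt[fly] - 0.5 * g * tt[fly]^2
    d[fly] <- v0 - g * tt[fly]
    land <- t >= t_land & t < t_land + tl
    tt <- t - t_land
    al <- v0 / tl
    v[land] <- h_land - v0 * tt[land] + 0.5 * al * tt[land]^2
    d[land] <- -v0 + al * tt[land]
    after <- t >= t_land + tl
    v[after] <- h_land - 0.5 * v0 * tl
    list(v = 1000 * v, d = 1000 * d)           # m -> mm
  }
}

#' Generate ground-truth segment kinematics for one trial
#'
#' Bone orientation, exact body-frame angular velocity, segment-origin
#' trajectory and the adjacent-joint flexion angle for each of the five
#' segments, at 500 Hz.
#'
#' @param cfg A `synthetic_config`.
#' @param geometry Skeleton geometry, see [default_geometry()].
#' @return A list with `time` (s), `recipe` (profiles/windows/impacts) and
#'   one entry per segment: `q` (n x 4, GRF -> bone), `omega` (n x 3 rad/s,
#'   body frame), `origin` (n x 3 mm, GRF), `flexion_deg`,
#'   `flexion_dot` (deg/s).
#' @export
generate_segment_motion <- function(cfg, geometry = default_geometry()) {
  fs <- 500
  time <- seq(0, cfg$static_lead + cfg$duration - 1 / fs, by = 1 / fs)
  rec <- movement_recipe(cfg)
  qn <- q_neutral()
  d2r <- pi / 180

  # injected frame-definition error: calibration movements rotate about an
  # axis internally rotated from the bone mediolateral axis
  delta <- if (cfg$movement %in% c("calibA", "calibB", "calibC")) cfg$mounting_error_deg else 0
  axis <- c(sin(delta * d2r), 0, cos(delta * d2r))   # rot about Y applied to Z

  hip_r <- rec$hip_r(time); hip_l <- rec$hip_l(time)
  knee_r <- rec$knee_r(time); knee_l <- rec$knee_l(time)
  lumbar <- rec$lumbar(time); height <- rec$height(time)

  seg_angle <- list(
    pelvis = lumbar,
    thigh_r = hip_r, thigh_l = hip_l,
    shank_r = list(v = hip_r$v - knee_r$v, d = hip_r$d - knee_r$d),
    shank_l = list(v = hip_l$v - knee_l$v, d = hip_l$d - knee_l$d))
  flexion <- list(pelvis = lumbar, thigh_r = knee_r, thigh_l = knee_l,
                  shank_r = knee_r, shank_l = knee_l)

  n <- length(time)
  out <- list(time = time, recipe = rec, config = cfg)

  # orientations and body angular velocities
  qs <- list()
  for (s in SEGMENTS) {
    th <- seg_angle[[s]]
    half <- th$v * d2r / 2
    qrot <- cbind(cos(half), sin(half) %o% axis)     # n x 4 rotation about `axis`
    qseg <- qmul(matrix(qn, 1)[rep(1, n), ], qrot)
    omega <- (th$d * d2r) %o% axis                   # exact: fixed body axis
    qs[[s]] <- list(q = qseg, omega = omega)
  }

  # kinematic chain positions (mm, GRF)
  g <- geometry
  p_pelvis <- cbind(0, 0, g$pelvis_height_mm + height$v)
  origins <- list(pelvis = p_pelvis)
  for (side in c("l", "r")) {
    hjc_local <- g$hjc_frac * c(1, 1, if (side == "r") 1 else -1) * g$inter_asis_mm
    p_hip <- p_pelvis + qrotate(qs$pelvis$q, matrix(hjc_local, 1)[rep(1, n), ])
    origins[[paste0("thigh_", side)]] <- p_hip
    p_knee <- p_hip + qrotate(qs[[paste0("thigh_", side)]]$q,
                              matrix(c(0, -g$thigh_length_mm, 0), 1)[rep(1, n), ])
    origins[[paste0("shank_", side)]] <- p_knee
  }

  for (s in SEGMENTS) {
    out[[s]] <- list(q = qs[[s]]$q, omega = qs[[s]]$omega,
                     origin = origins[[s]],
                     flexion_deg = flexion[[s]]$v, flexion_dot = flexion[[s]]$d)
  }
  out
}
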