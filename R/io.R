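# Canonical CSV interchange formats, the YAML trial manifest, and the
# on-disk dataset writer.

IMU_HEADER <- c("time_s", "gyro_x", "gyro_y", "gyro_z",
                "accel_x", "accel_y", "accel_z", "mag_x", "mag_y", "mag_z")

#' Read / write the IMU CSV dialect
#'
#' Columns `time_s, gyro_x..z (rad/s), accel_x..z (m/s^2), mag_x..z (a.u.)`.
#' Reading validates the header and timestamp uniformity.
#'
#' @param path File path.
#' @return `read_imu_csv`: an `imu_record`.
#' @export
read_imu_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!identical(names(df), IMU_HEADER)) {
    stop("malformed IMU CSV header in ", path, ": expected ",
         paste(IMU_HEADER, collapse = ","), call. = FALSE)
  }
  dt <- diff(df$time_s)
  if (length(dt)) {
    bad <- which(abs(dt - stats::median(dt)) > 1e-4 * stats::median(dt))
    if (length(bad)) {
      stop(sprintf("non-uniform IMU timestamps in %s near sample %d (t = %.6f s)",
                   path, bad[1] + 1L, df$time_s[bad[1] + 1L]), call. = FALSE)
    }
  }
  imu_record(df$time_s,
             as.matrix(df[, c("gyro_x", "gyro_y", "gyro_z")]),
             as.matrix(df[, c("accel_x", "accel_y", "accel_z")]),
             as.matrix(df[, c("mag_x", "mag_y", "mag_z")]),
             sensor_id = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_imu_csv
#' @param rec An `imu_record`.
#' @export
write_imu_csv <- function(rec, path) {
  df <- tibble::as_tibble(rec)
  names(df)[names(df) == "time"] <- "time_s"
  readr::write_csv(df[, IMU_HEADER], path, progress = FALSE)
  invisible(path)
}

#' Read / write the marker CSV dialect
#'
#' Columns `time_s` plus `<NAME>_x_mm, <NAME>_y_mm, <NAME>_z_mm` per marker;
#' empty cells are gaps (NaN).
#'
#' @param path File path.
#' @param expected Optional marker names that must be present.
#' @return `read_marker_csv`: a `marker_set`.
#' @export
read_marker_csv <- function(path, expected = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "time_s") stop("marker CSV must start with time_s: ", path, call. = FALSE)
  nms <- unique(sub("_[xyz]_mm$", "", names(df)[-1]))
  if (!is.null(expected)) {
    miss <- setdiff(expected, nms)
    if (length(miss)) stop("markers missing from ", path, ": ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- df
  names(out)[1] <- "time"
  class(out) <- c("marker_set", class(out))
  out
}

#' @rdname read_marker_csv
#' @param ms A `marker_set`.
#' @export
write_marker_csv <- function(ms, path) {
  df <- tibble::as_tibble(ms)
  names(df)[names(df) == "time"] <- "time_s"
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a trial manifest
#'
#' The YAML manifest declares, per subject: the trial files, each trial's
#' role (neutral / calibA-C / compass / static / movement), analysis
#' windows, calibration movement windows and flexion signs, and the
#' segment list. Paths are resolved relative to the manifest's directory.
#'
#' @param path Manifest YAML path.
#' @return A `trial_manifest` list.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  m$root <- dirname(normalizePath(path))
  roles <- vapply(m$trials, function(tr) tr$role, character(1))
  for (role in c("neutral", "static", "compass")) {
    if (sum(roles == role) != 1) {
      stop("manifest must declare exactly one ", role, " trial", call. = FALSE)
    }
  }
  for (tr in m$trials) {
    for (p in c(unlist(tr$imu), tr$markers)) {
      if (!file.exists(file.path(m$root, p))) {
        stop("manifest references missing file: ", p, call. = FALSE)
      }
    }
  }
  structure(m, class = "trial_manifest")
}

.signif9 <- function(x) if (is.numeric(x)) signif(x, 9) else x

#' Write a dataset of synthetic trials to disk
#'
#' Generates the full per-subject trial battery -- neutral pose,
#' calibration movements A/B/C, compass, static trial and the requested
#' movement trials with repetitions -- with per-subject randomized sensor
#' mountings, gyro biases and injected calibration errors, and writes the
#' CSV files, a YAML manifest per subject and a ground-truth JSON.
#' Fully reproducible from `seed`.
#'
#' @param out_dir Output directory (created).
#' @param movements Character vector of movement trials (any of squat,
#'   squat_jump, walk, run, sprint, kick).
#' @param subjects,reps Number of subjects / repetitions per movement.
#' @param base_cfg Template `synthetic_config`; per-trial fields
#'   (movement, duration, seed) are overridden internally.
#' @param intensities Named intensity per movement (defaults per family).
#' @param mounting_error_deg Injected frame-definition error; recycled over
#'   subjects.
#' @param durations Named list of durations per role.
#' @param seed Master seed.
#' @return Invisibly, the manifest paths and the ground-truth list.
#' @export
generate_dataset <- function(out_dir, movements = "squat", subjects = 1, reps = 1,
                             base_cfg = synthetic_config(), intensities = NULL,
                             mounting_error_deg = 12, durations = NULL, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  dur <- utils::modifyList(list(neutral = 3, calibA = 8, calibB = 5, calibC = 6,
                                compass = 3, static = 3, movement = 8),
                           durations %||% list())
  def_int <- c(squat = 1, squat_jump = 1, walk = 0.3, run = 0.6, sprint = 1, kick = 1)
  mounting_error_deg <- rep(mounting_error_deg, length.out = subjects)
  manifests <- character(0)
  truth <- list()
  for (si in seq_len(subjects)) {
    subj <- sprintf("S%02d", si)
    sdir <- file.path(out_dir, subj)
    dir.create(sdir, showWarnings = FALSE)
    mounts <- lapply(stats::setNames(SEGMENTS, SEGMENTS), function(s) {
      qfrom_axis_angle(stats::rnorm(3), base_cfg$mount_deg)
    })
    biases <- lapply(stats::setNames(SEGMENTS, SEGMENTS), function(s) {
      if (length(base_cfg$gyro_bias) == 3) base_cfg$gyro_bias
      else stats::rnorm(3, 0, base_cfg$gyro_bias)
    })
    subj_truth <- list(mounting_error_deg = mounting_error_deg[si],
                      mounts = mounts, biases = biases,
                      hand_eye_yaw_deg = base_cfg$mag_declination_deg,
                      sta = list())
    trials <- list()

    emit <- function(id, role, movement, duration, intensity = 1, repetition = NULL) {
      cfg <- base_cfg
      cfg$movement <- movement
      cfg$duration <- duration
      cfg$intensity <- intensity
      cfg$mounting_error_deg <- mounting_error_deg[si]
      cfg$seed <- sample.int(2^30, 1)
      if (movement == "compass") {
        ms <- synthesize_compass(cfg)
        mpath <- file.path(subj, paste0("markers_", id, ".csv"))
        write_marker_csv(ms, file.path(out_dir, mpath))
        tr <- list(id = id, role = role, markers = mpath)
      } else {
        sim <- simulate_trial(cfg, mounts = mounts, biases = biases)
        mpath <- file.path(subj, paste0("markers_", id, ".csv"))
        write_marker_csv(sim$markers, file.path(out_dir, mpath))
        ipaths <- list()
        for (s in SEGMENTS) {
          ip <- file.path(subj, paste0("imu_", id, "_", s, ".csv"))
          write_imu_csv(sim$imu[[s]]$rec, file.path(out_dir, ip))
          ipaths[[s]] <- ip
        }
        w <- sim$motion$recipe$windows
        tr <- list(id = id, role = role, movement = movement,
                   markers = mpath, imu = ipaths,
                   window = c(cfg$static_lead, cfg$static_lead + duration))
        if (role %in% c("calibA", "calibB", "calibC")) {
          tr$static_window <- c(0.5, cfg$static_lead - 0.5)
          tr$movement_windows <- list(
            pelvis = w$pelvis %||% w$movement,
            thigh_l = w$thigh %||% w$movement, thigh_r = w$thigh %||% w$movement,
            shank_l = w$shank %||% w$movement, shank_r = w$shank %||% w$movement)
          tr$flexion_signs <- as.list(sim$motion$recipe$signs)
        }
        if (!is.null(repetition)) tr$repetition <- repetition
        if (role == "movement") {
          win <- tr$window
          idx <- sim$markers$time >= win[1] & sim$markers$time <= win[2]
          subj_truth$sta[[id]] <<- lapply(stats::setNames(SEGMENTS, SEGMENTS), function(s) {
            sta <- sim$skin[[s]]$sta_deg[seq(1, length(sim$motion$time), by = 2)][idx]
            list(rms_deg = sqrt(mean(sta^2)), max_deg = max(sta))
          })
        }
      }
      trials[[length(trials) + 1L]] <<- tr
    }

    emit("neutral", "neutral", "static", dur$neutral)
    emit("calibA", "calibA", "calibA", dur$calibA)
    emit("calibB", "calibB", "calibB", dur$calibB)
    emit("calibC", "calibC", "calibC", dur$calibC)
    emit("compass", "compass", "compass", dur$compass)
    emit("static", "static", "static", dur$static)
    for (mv in movements) {
      int <- if (!is.null(intensities) && !is.null(intensities[[mv]])) {
        intensities[[mv]]
      } else def_int[[mv]]
      for (r in seq_len(reps)) {
        emit(paste0(mv, "_", r), "movement", mv, dur$movement, intensity = int,
             repetition = r)
      }
    }
    man <- list(subject = subj, segments = as.list(SEGMENTS),
                trials = trials)
    mpath <- file.path(out_dir, paste0("manifest_", subj, ".yaml"))
    yaml::write_yaml(man, mpath)
    manifests <- c(manifests, mpath)
    truth[[subj]] <- subj_truth
  }
  tj <- rapply(truth, .signif9, how = "replace")
  jsonlite::write_json(tj, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifests = manifests, truth = truth))
}
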