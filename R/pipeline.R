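# End-to-end pipeline: sensor calibration -> orientation filter -> hand-eye
# -> sensor-body calibrations A-C -> static marker-calibrated alignments ->
# the six body-frame series -> the nine comparisons -> aggregation.

.window_qs <- function(qs, window) {
  keep <- qs$time >= window[1] & qs$time <= window[2]
  fr <- qs_frames(qs)
  quat_series(qs$time[keep], qs_matrix(qs)[keep, , drop = FALSE],
              from = fr[1], to = fr[2])
}

.window_rec <- function(df, window) {
  df[df$time >= window[1] & df$time <= window[2], ]
}

.trial_by_role <- function(manifest, role) {
  hit <- Filter(function(tr) tr$role == role, manifest$trials)
  if (!length(hit)) stop("manifest has no ", role, " trial", call. = FALSE)
  hit
}

# process one recorded trial: filter each sensor, hand-eye to GRF,
# down-sample onto the marker clock, build optical frames
.process_trial <- function(tr, manifest, hand_eye, cals_imu, fcfg, segments, sync = TRUE) {
  root <- manifest$root
  ms <- lowpass_markers(read_marker_csv(file.path(root, tr$markers)))
  geom <- default_geometry()
  out <- list()
  for (s in segments) {
    rec <- read_imu_csv(file.path(root, tr$imu[[s]]))
    rec <- apply_imu_calibration(rec, cals_imu[[s]])
    q_imu <- run_orientation_filter(rec, fcfg)               # IRF -> IMU-sf, 500 Hz
    q_imu <- express_in_grf(q_imu, hand_eye)
    rmc_geom <- lapply(default_geometry()$rmc_local, identity)
    names(rmc_geom) <- paste0(toupper(s), "_", names(rmc_geom))
    q_rmc <- cluster_frame(ms, rmc_geom)                     # GRF -> RMC-sf, 250 Hz
    factor <- round(qs_dt(q_rmc) / qs_dt(q_imu))
    lag <- 0L
    if (sync) {
      sr <- tryCatch(estimate_sync_offset(rec, q_rmc),
                     error = function(e) NULL)
      if (!is.null(sr)) lag <- sr$lag
    }
    q_imu <- downsample_series(q_imu, factor = factor, lag = -lag * factor,
                               t0 = NULL)
    n <- min(nrow(q_imu), nrow(q_rmc))
    q_imu <- qs_rebuild(q_rmc[seq_len(n), ], qs_matrix(q_imu)[seq_len(n), , drop = FALSE],
                        from = "GRF", to = "IMU-sf")
    q_al <- segment_frame(ms, s)
    out[[s]] <- list(imu_sf = q_imu,
                     rmc_sf = .head_qs(q_rmc, n),
                     al = .head_qs(q_al, n),
                     rec = rec)
  }
  out$markers <- ms
  out
}

.head_qs <- function(qs, n) {
  fr <- qs_frames(qs)
  quat_series(qs$time[seq_len(n)], qs_matrix(qs)[seq_len(n), , drop = FALSE],
              from = fr[1], to = fr[2])
}

#' Run the full error-decomposition pipeline for one subject
#'
#' Executes, from a trial manifest: the simplified IMU sensor calibration
#' (neutral trial), the orientation filter, IMU/marker synchronization and
#' down-sampling, marker-frame construction, the hand-eye (compass)
#' calibration, the three sensor-body calibrations, the static-trial
#' marker-calibrated alignments and, per movement trial, the nine frame
#' comparisons.
#'
#' @param manifest Path to a manifest YAML or a `trial_manifest`.
#' @param fcfg A `filter_config`.
#' @param out_dir Optional directory: results CSV and an aggregate JSON
#'   summary are written there.
#' @param verbose Print stage progress.
#' @return A list: `results` (`frame_comparison` tibble over all movement
#'   trials x segments), `summary` (`error_summary`), `hand_eye`,
#'   `body_cals`, `mcbf_cals`.
#' @export
run_pipeline <- function(manifest, fcfg = filter_config(), out_dir = NULL,
                         verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  root <- manifest$root
  segments <- unlist(manifest$segments)
  say <- function(...) if (verbose) message(sprintf(...))

  # 1. simplified IMU-sensor calibration from the neutral (static) trial
  say("[%s] sensor calibration", manifest$subject)
  ntr <- .trial_by_role(manifest, "neutral")[[1]]
  cals_imu <- lapply(stats::setNames(segments, segments), function(s) {
    estimate_static_cal(read_imu_csv(file.path(root, ntr$imu[[s]])))
  })

  # 2. hand-eye calibration from the compass trial
  say("[%s] hand-eye calibration", manifest$subject)
  ctr <- .trial_by_role(manifest, "compass")[[1]]
  hand_eye <- hand_eye_from_compass(
    lowpass_markers(read_marker_csv(file.path(root, ctr$markers))))

  # 3. sensor-body calibrations A-C from the calibration movements
  body_cals <- list()
  for (role in c("calibA", "calibB", "calibC")) {
    say("[%s] %s", manifest$subject, role)
    tr <- .trial_by_role(manifest, role)[[1]]
    method <- sub("calib", "", role)
    for (s in segments) {
      rec <- apply_imu_calibration(read_imu_csv(file.path(root, tr$imu[[s]])),
                                   cals_imu[[s]])
      long <- longitudinal_axis_static(.window_rec(rec, unlist(tr$static_window)))
      mw <- unlist(tr$movement_windows[[s]])
      sgn <- tr$flexion_signs[[s]] %||% 1
      flex <- flexion_axis_functional(.window_rec(rec, mw), long, sign = sgn)
      body_cals[[method]][[s]] <- build_sensor_body_cal(long, flex, method, segment = s)
    }
  }

  # 4. static-trial marker-calibrated alignments (IMU and RMC)
  say("[%s] static alignments", manifest$subject)
  st <- .trial_by_role(manifest, "static")[[1]]
  stp <- .process_trial(st, manifest, hand_eye, cals_imu, fcfg, segments, sync = FALSE)
  win <- unlist(st$window)
  mcbf_cals <- lapply(stats::setNames(segments, segments), function(s) {
    al <- .window_qs(stp[[s]]$al, win)
    list(imu = static_frame_alignment(al, .window_qs(stp[[s]]$imu_sf, win), segment = s),
         rmc = static_frame_alignment(al, .window_qs(stp[[s]]$rmc_sf, win), segment = s))
  })

  # 5. movement trials: six frames and nine comparisons per segment
  results <- list()
  for (tr in .trial_by_role(manifest, "movement")) {
    say("[%s] trial %s", manifest$subject, tr$id)
    prc <- .process_trial(tr, manifest, hand_eye, cals_imu, fcfg, segments)
    win <- unlist(tr$window)
    for (s in segments) {
      imu_sf <- .window_qs(prc[[s]]$imu_sf, win)
      rmc_sf <- .window_qs(prc[[s]]$rmc_sf, win)
      al <- .window_qs(prc[[s]]$al, win)
      frames <- list(
        "IMU-scbfA" = compose_scbf(imu_sf, body_cals$A[[s]]),
        "IMU-scbfB" = compose_scbf(imu_sf, body_cals$B[[s]]),
        "IMU-scbfC" = compose_scbf(imu_sf, body_cals$C[[s]]),
        "IMU-mcbf" = apply_mcbf_alignment(imu_sf, mcbf_cals[[s]]$imu, to = "IMU-mcbf"),
        "RMC-mcbf" = apply_mcbf_alignment(rmc_sf, mcbf_cals[[s]]$rmc, to = "RMC-mcbf"),
        "AL-mcbf" = al)
      results[[length(results) + 1L]] <-
        run_table1(frames, segment = s, trial = tr$movement %||% tr$id,
                   subject = manifest$subject,
                   repetition = tr$repetition %||% NA_integer_)
    }
  }
  results <- dplyr::bind_rows(results)
  class(results) <- c("frame_comparison", class(results))
  summary <- aggregate_errors(results)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    flat <- dplyr::select(results, -"angle")
    flat <- dplyr::mutate(flat, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, 9)))
    readr::write_csv(flat, file.path(out_dir, paste0("results_", manifest$subject, ".csv")),
                     progress = FALSE)
    jsonlite::write_json(
      rapply(list(summary = as.list(summary)), .signif9, how = "replace"),
      file.path(out_dir, paste0("summary_", manifest$subject, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  list(results = results, summary = summary, hand_eye = hand_eye,
       body_cals = body_cals, mcbf_cals = mcbf_cals)
}

#' Run the pipeline over several subjects and aggregate
#'
#' @param manifests Character vector of manifest paths.
#' @param fcfg A `filter_config`.
#' @param out_dir Optional output directory.
#' @param verbose Print stage progress.
#' @return A list: `results` (all subjects), `summary` (cross-subject
#'   aggregate).
#' @export
run_study <- function(manifests, fcfg = filter_config(), out_dir = NULL,
                      verbose = FALSE) {
  runs <- lapply(manifests, run_pipeline, fcfg = fcfg, out_dir = out_dir,
                 verbose = verbose)
  results <- dplyr::bind_rows(lapply(runs, `[[`, "results"))
  class(results) <- c("frame_comparison", class(results))
  list(results = results, summary = aggregate_errors(results))
}
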