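# The error decomposition itself: composing sensor-calibrated body frames,
# re-expressing filter output in the optical global frame, the nine frame
# comparisons, and the RMSD aggregation that separates the error sources.

COMPARISON_TABLE <- tibble::tibble(
  comparison = 1:9,
  frame1 = c("IMU-scbfA", "IMU-scbfB", "IMU-scbfC", "RMC-mcbf", "IMU-mcbf",
             "IMU-mcbf", "IMU-scbfA", "IMU-scbfB", "IMU-scbfC"),
  frame2 = c("IMU-mcbf", "IMU-mcbf", "IMU-mcbf", "AL-mcbf", "RMC-mcbf",
             "AL-mcbf", "AL-mcbf", "AL-mcbf", "AL-mcbf"),
  error_source = c("frame definition A", "frame definition B", "frame definition C",
                   "soft tissue artefact", "orientation filter",
                   "orientation filter + STA", "total A", "total B", "total C"))

#' The nine frame comparisons
#'
#' Pairings of the six per-segment body-frame series and the error source
#' each difference isolates.
#'
#' @return A tibble with columns `comparison`, `frame1`, `frame2`,
#'   `error_source`.
#' @export
comparison_table <- function() COMPARISON_TABLE

#' Compose a sensor series with a sensor-body calibration
#'
#' Per-sample right-multiplication: q_t(IRF -> IMU-scbf) =
#' q_t(IRF -> IMU-sf) (x) q(IMU-sf -> IMU-scbf).
#'
#' @param sensor_series `quat_series` IRF (or GRF) -> IMU-sf.
#' @param cal A `body_cal` with method A, B or C.
#' @return A `quat_series` to `"IMU-scbfA"`/`B`/`C`.
#' @export
compose_scbf <- function(sensor_series, cal) {
  stopifnot(inherits(cal, "body_cal"))
  if (!cal$method %in% c("A", "B", "C")) {
    stop("frame mismatch: compose_scbf needs a movement calibration (A/B/C)", call. = FALSE)
  }
  qs_rebuild(sensor_series, qmul(qs_matrix(sensor_series), cal$q),
             to = paste0("IMU-scbf", cal$method))
}

#' Re-express an IRF-referenced series in the optical global frame
#'
#' Per-sample left-multiplication by the hand-eye quaternion:
#' q_t(GRF -> F) = q_GRF^IRF (x) q_t(IRF -> F).
#'
#' @param series `quat_series` from `"IRF"`.
#' @param hand_eye Unit quaternion q_GRF^IRF.
#' @return The series re-referenced to `"GRF"`.
#' @export
express_in_grf <- function(series, hand_eye) {
  fr <- qs_frames(series)
  if (!is.na(fr[1]) && fr[1] != "IRF") {
    stop("frame mismatch: series is not IRF-referenced", call. = FALSE)
  }
  qs_rebuild(series, qmul(matrix(hand_eye, 1)[rep(1, nrow(series)), ], qs_matrix(series)),
             from = "GRF")
}

#' Compare two frame series by their smallest rotation angle
#'
#' Per sample, the rotation quaternion between the two frames and its
#' smallest rotation angle in degrees; summarized by the root-mean-square
#' difference (RMSD) and the maximum over the window.
#'
#' @param a,b `quat_series` of equal length sharing a reference frame.
#' @param comparison Optional comparison id (1..9).
#' @param segment,trial,subject,repetition Optional labels carried through.
#' @return A one-row `frame_comparison` tibble: `comparison`, `frame1`,
#'   `frame2`, `error_source`, labels, `rmsd_deg`, `max_deg`, `n`, and a
#'   list column `angle` holding the per-sample tibble (`time`,
#'   `angle_deg`).
#' @export
compare_frames <- function(a, b, comparison = NA_integer_, segment = NA_character_,
                           trial = NA_character_, subject = NA_character_,
                           repetition = NA_integer_) {
  if (nrow(a) != nrow(b)) stop("frame mismatch: series lengths differ", call. = FALSE)
  fa <- qs_frames(a); fb <- qs_frames(b)
  if (!is.na(fa[1]) && !is.na(fb[1]) && fa[1] != fb[1]) {
    stop("frame mismatch: series have different reference frames", call. = FALSE)
  }
  ang <- qangle(qmul(qinv(qs_matrix(a)), qs_matrix(b)))
  src <- if (!is.na(comparison)) COMPARISON_TABLE$error_source[comparison] else NA_character_
  out <- tibble::tibble(
    comparison = comparison,
    frame1 = fa[2], frame2 = fb[2], error_source = src,
    subject = subject, trial = trial, repetition = repetition, segment = segment,
    rmsd_deg = sqrt(mean(ang^2)), max_deg = max(ang), n = length(ang),
    angle = list(tibble::tibble(time = a$time, angle_deg = ang)))
  class(out) <- c("frame_comparison", class(out))
  out
}

#' Run all nine frame comparisons for one segment and trial
#'
#' @param frames Named list of six time-aligned `quat_series` (GRF-referenced):
#'   `IMU-scbfA`, `IMU-scbfB`, `IMU-scbfC`, `IMU-mcbf`, `RMC-mcbf`,
#'   `AL-mcbf`.
#' @param segment,trial,subject,repetition Labels carried into the result.
#' @param check_constancy Assert that the frame-definition comparisons
#'   (1-3) are constant over time within `constancy_tol_deg` (they compare
#'   two constant rotations of the same underlying series).
#' @param constancy_tol_deg Tolerance for the constancy self-check, degrees.
#' @return A `frame_comparison` tibble with nine rows.
#' @export
run_table1 <- function(frames, segment = NA_character_, trial = NA_character_,
                       subject = NA_character_, repetition = NA_integer_,
                       check_constancy = TRUE, constancy_tol_deg = 1e-6) {
  need <- unique(c(COMPARISON_TABLE$frame1, COMPARISON_TABLE$frame2))
  missing <- setdiff(need, names(frames))
  if (length(missing)) {
    stop("missing frame series: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  res <- purrr::pmap(COMPARISON_TABLE[, c("comparison", "frame1", "frame2")],
                     function(comparison, frame1, frame2) {
                       r <- compare_frames(frames[[frame1]], frames[[frame2]],
                                           comparison = comparison, segment = segment,
                                           trial = trial, subject = subject,
                                           repetition = repetition)
                       r$frame1 <- frame1
                       r$frame2 <- frame2
                       r
                     })
  out <- dplyr::bind_rows(res)
  if (check_constancy) {
    for (i in 1:3) {
      a <- out$angle[[i]]$angle_deg
      if (max(a) - min(a) > constancy_tol_deg) {
        warning(sprintf("comparison #%d varies by %.2e deg over time; expected constant",
                        i, max(a) - min(a)), call. = FALSE)
      }
    }
  }
  class(out) <- c("frame_comparison", class(out))
  out
}

#' Aggregate comparison RMSDs across repetitions and subjects
#'
#' Per subject, the mean RMSD over repetitions; then the cross-subject mean
#' and standard deviation (n - 1 denominator) per trial x segment x
#' comparison. With a single subject the STD is reported as 0 and flagged.
#'
#' @param results A `frame_comparison` tibble (any number of rows).
#' @return An `error_summary` tibble: `trial`, `segment`, `comparison`,
#'   `error_source`, `n_subjects`, `mean_rmsd_deg`, `sd_rmsd_deg`,
#'   `mean_max_deg`, `single_subject`.
#' @export
aggregate_errors <- function(results) {
  if (nrow(results) == 0) stop("no comparison results to aggregate", call. = FALSE)
  per_subject <- results |>
    dplyr::group_by(.data$subject, .data$trial, .data$segment, .data$comparison,
                    .data$error_source) |>
    dplyr::summarise(rmsd_deg = mean(.data$rmsd_deg),
                     max_deg = mean(.data$max_deg), .groups = "drop")
  out <- per_subject |>
    dplyr::group_by(.data$trial, .data$segment, .data$comparison, .data$error_source) |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     mean_rmsd_deg = mean(.data$rmsd_deg),
                     sd_rmsd_deg = ifelse(dplyr::n() > 1, stats::sd(.data$rmsd_deg), 0),
                     mean_max_deg = mean(.data$max_deg),
                     .groups = "drop") |>
    dplyr::mutate(single_subject = .data$n_subjects == 1L)
  class(out) <- c("error_summary", class(out))
  out
}

#' Root-sum-square independence diagnostic
#'
#' Ratio of a combined error RMSD to the root-sum-square of its components;
#' near 1 when the component errors are independent.
#'
#' @param sta_rmsd,filter_rmsd,combined_rmsd RMSDs in degrees, all >= 0.
#' @return The ratio combined / sqrt(sta^2 + filter^2); `NA` with a warning
#'   when the denominator is zero.
#' @export
independence_check <- function(sta_rmsd, filter_rmsd, combined_rmsd) {
  stopifnot(all(c(sta_rmsd, filter_rmsd, combined_rmsd) >= 0))
  denom <- sqrt(sta_rmsd^2 + filter_rmsd^2)
  if (denom == 0) {
    warning("zero component errors: independence ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  combined_rmsd / denom
}
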