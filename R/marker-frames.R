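# Optoelectronic frames: anatomical-landmark body frames (AL-mcbf) for
# pelvis, thighs and shanks following ISB segment conventions (X anterior,
# Y proximal/up, Z to the subject's right), and rigid-marker-cluster sensor
# frames (RMC-sf). Marker positions are mm in the global camera frame (GRF,
# Z up), nominally 250 Hz.
#
# A marker_set is a tibble: time plus <NAME>_x_mm, <NAME>_y_mm, <NAME>_z_mm
# per marker. NaN cells mark gaps; gap filling is deliberately refused here
# (it belongs to the capture software), so gaps must be resolved upstream.

#' Construct a marker set
#'
#' @param time Timestamps (s), 250 Hz nominal.
#' @param positions Named list of n x 3 matrices (mm, GRF), one per marker.
#' @return A `marker_set` tibble.
#' @export
marker_set <- function(time, positions) {
  stopifnot(is.list(positions), length(positions) > 0)
  cols <- list(time = time)
  for (nm in names(positions)) {
    p <- positions[[nm]]
    stopifnot(nrow(p) == length(time), ncol(p) == 3)
    cols[[paste0(nm, "_x_mm")]] <- p[, 1]
    cols[[paste0(nm, "_y_mm")]] <- p[, 2]
    cols[[paste0(nm, "_z_mm")]] <- p[, 3]
  }
  out <- tibble::as_tibble(cols)
  class(out) <- c("marker_set", class(out))
  out
}

#' Marker names present in a marker set
#' @param ms A `marker_set`.
#' @return Character vector of marker labels.
#' @export
marker_names <- function(ms) {
  unique(sub("_[xyz]_mm$", "", setdiff(names(ms), "time")))
}

#' Extract one marker trajectory as an n x 3 matrix (mm)
#' @param ms A `marker_set`.
#' @param name Marker label.
#' @return n x 3 matrix.
#' @export
marker_xyz <- function(ms, name) {
  cols <- paste0(name, c("_x_mm", "_y_mm", "_z_mm"))
  if (!all(cols %in% names(ms))) stop("unknown marker: ", name, call. = FALSE)
  as.matrix(ms[, cols])
}

.check_gaps <- function(ms, markers = marker_names(ms)) {
  for (nm in markers) {
    p <- marker_xyz(ms, nm)
    bad <- !stats::complete.cases(p)
    if (any(bad)) {
      idx <- range(which(bad))
      stop(sprintf("gap in marker %s between t = %.3f s and t = %.3f s; fill gaps upstream",
                   nm, ms$time[idx[1]], ms$time[idx[2]]), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Zero-phase low-pass filter marker trajectories
#'
#' Fourth-order Butterworth, applied forward and backward (zero phase lag)
#' per coordinate, with reflective endpoint padding. Defaults follow the
#' conventional motion-capture recommendation of 8 Hz for marker noise
#' reduction.
#'
#' @param ms A gap-free `marker_set`.
#' @param fc Cut-off frequency, Hz.
#' @param order Butterworth order per pass.
#' @return Filtered `marker_set`.
#' @export
lowpass_markers <- function(ms, fc = 8, order = 4) {
  .check_gaps(ms)
  fs <- 1 / stats::median(diff(ms$time))
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  pad <- min(nrow(ms) - 1L, ceiling(2 * fs))   # 2 s settle for the IIR transient
  out <- ms
  for (col in setdiff(names(ms), "time")) {
    x <- ms[[col]]
    # reflect about the endpoints to suppress filter edge transients
    xe <- c(2 * x[1] - x[(pad + 1):2], x,
            2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)])
    y <- signal::filtfilt(bf, xe)
    out[[col]] <- y[(pad + 1):(pad + length(x))]
  }
  out
}

#' Least-squares rigid rotation of a marker cluster
#'
#' Per-sample optimal rotation from the cluster's local frame to GRF,
#' solved with Davenport's q-method (largest eigenvector of the 4 x 4
#' attitude-profile matrix). The RMC local frame is the IMU sensor frame by
#' construction, so the result is q_t(GRF -> RMC-sf).
#'
#' @param ms A gap-free `marker_set` holding the cluster markers.
#' @param geometry Named list of length-3 local coordinates (mm), names
#'   matching markers in `ms`.
#' @param rigid_tol_mm Warn when the per-sample rigid-body residual RMS
#'   exceeds this (mm).
#' @return A `quat_series` from `"GRF"` to `"RMC-sf"`.
#' @export
cluster_frame <- function(ms, geometry, rigid_tol_mm = 5) {
  nms <- names(geometry)
  if (length(nms) < 3) stop("need at least 3 cluster markers", call. = FALSE)
  .check_gaps(ms, nms)
  L <- do.call(rbind, geometry[nms])                  # k x 3 local coords
  Lc <- sweep(L, 2, colMeans(L))
  if (qr(Lc)$rank < 2) stop("degenerate cluster geometry: collinear markers", call. = FALSE)
  traj <- lapply(nms, function(nm) marker_xyz(ms, nm))
  n <- nrow(ms); k <- length(nms)
  out <- matrix(0, n, 4)
  worst <- 0
  P <- matrix(0, k, 3)
  for (t in seq_len(n)) {
    for (j in seq_len(k)) P[j, ] <- traj[[j]][t, ]
    Pc <- sweep(P, 2, colMeans(P))
    B <- t(Pc) %*% Lc                                 # maps local -> global
    K <- matrix(0, 4, 4)
    K[1, 1] <- B[1, 1] + B[2, 2] + B[3, 3]
    K[1, 2:4] <- c(B[3, 2] - B[2, 3], B[1, 3] - B[3, 1], B[2, 1] - B[1, 2])
    K[2:4, 1] <- K[1, 2:4]
    K[2:4, 2:4] <- B + t(B) - diag(3) * K[1, 1]
    ev <- eigen(K, symmetric = TRUE)
    q <- ev$vectors[, 1]
    if (q[1] < 0) q <- -q
    out[t, ] <- q
    res <- Pc - Lc %*% t(qto_matrix(q))
    worst <- max(worst, sqrt(mean(rowSums(res^2))))
  }
  if (worst > rigid_tol_mm) {
    warning(sprintf("cluster rigid-body residual up to %.1f mm exceeds %.1f mm",
                    worst, rigid_tol_mm), call. = FALSE)
  }
  enforce_continuity(quat_series(ms$time, out, from = "GRF", to = "RMC-sf"))
}

#' Hip joint centre from pelvis markers
#'
#' Regression location of the hip joint centre as fixed fractions of the
#' inter-ASIS distance, expressed in the pelvis anatomical frame relative
#' to the mid-ASIS point (Bell-style coefficients: posterior 0.19, distal
#' 0.30, lateral 0.36), then mapped back to GRF per sample.
#'
#' @param ms A `marker_set` with LASIS, RASIS, LPSIS, RPSIS.
#' @param side `"L"` or `"R"`.
#' @param coef Regression fractions `c(x = -0.19, y = -0.30, z = 0.36)` of
#'   inter-ASIS distance in the pelvis frame (X anterior, Y up, Z right);
#'   the z fraction is negated for the left side.
#' @return n x 3 matrix of HJC positions (mm, GRF).
#' @export
hip_joint_center <- function(ms, side = c("R", "L"),
                             coef = c(x = -0.19, y = -0.30, z = 0.36)) {
  side <- match.arg(side)
  .check_gaps(ms, c("LASIS", "RASIS", "LPSIS", "RPSIS"))
  qp <- pelvis_frame(ms)
  la <- marker_xyz(ms, "LASIS"); ra <- marker_xyz(ms, "RASIS")
  mid_asis <- (la + ra) / 2
  iad <- sqrt(rowSums((ra - la)^2))
  local <- cbind(coef["x"], coef["y"], if (side == "R") coef["z"] else -coef["z"]) # nolint
  offset <- qrotate(qs_matrix(qp), local[rep(1, nrow(ms)), , drop = FALSE] * iad)
  unname(mid_asis + offset)
}

.seg_frame_series <- function(time, xs, ys, zs, to) {
  n <- nrow(xs)
  out <- matrix(0, n, 4)
  for (t in seq_len(n)) out[t, ] <- qfrom_axes(xs[t, ], ys[t, ], zs[t, ])
  enforce_continuity(quat_series(time, out, from = "GRF", to = to))
}

.unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Pelvis anatomical frame (ISB)
#'
#' Z along LASIS -> RASIS; X anterior in the plane spanned by the ASIS
#' midpoint and the PSIS midpoint, orthogonal to Z; Y = Z x X (up).
#'
#' @param ms A `marker_set` with the four pelvis markers.
#' @return A `quat_series` from `"GRF"` to `"AL-mcbf"`.
#' @export
pelvis_frame <- function(ms) {
  .check_gaps(ms, c("LASIS", "RASIS", "LPSIS", "RPSIS"))
  la <- marker_xyz(ms, "LASIS"); ra <- marker_xyz(ms, "RASIS")
  lp <- marker_xyz(ms, "LPSIS"); rp <- marker_xyz(ms, "RPSIS")
  z <- .unit_rows(ra - la)
  v <- (la + ra) / 2 - (lp + rp) / 2
  x <- .unit_rows(v - rowSums(v * z) * z)
  y <- .cross_rows(z, x)
  .seg_frame_series(ms$time, x, y, z, "AL-mcbf")
}

#' Thigh anatomical frame (ISB)
#'
#' Y from the epicondyle midpoint toward the hip joint centre; Z lateral
#' from the epicondyle line (medial -> lateral, sign chosen so Z points to
#' the subject's right); X = Y x Z anterior.
#'
#' @param ms A `marker_set` with the epicondyle markers of `side`.
#' @param side `"L"` or `"R"`.
#' @param hjc n x 3 matrix of hip joint centre positions (mm, GRF); computed
#'   from the pelvis markers when `NULL`.
#' @return A `quat_series` from `"GRF"` to `"AL-mcbf"`.
#' @export
thigh_frame <- function(ms, side = c("R", "L"), hjc = NULL) {
  side <- match.arg(side)
  .check_gaps(ms, paste0(side, c("MEP", "LEP")))
  mep <- marker_xyz(ms, paste0(side, "MEP"))
  lep <- marker_xyz(ms, paste0(side, "LEP"))
  if (is.null(hjc)) hjc <- hip_joint_center(ms, side)
  mid <- (mep + lep) / 2
  y <- .unit_rows(hjc - mid)
  z0 <- if (side == "R") lep - mep else mep - lep    # points subject-right
  x <- .unit_rows(.cross_rows(y, .unit_rows(z0)))
  z <- .cross_rows(x, y)
  .seg_frame_series(ms$time, x, y, z, "AL-mcbf")
}

#' Shank anatomical frame (ISB)
#'
#' Y from the malleoli midpoint toward the epicondyle midpoint; Z lateral
#' from the malleoli line; X = Y x Z anterior.
#'
#' @inheritParams thigh_frame
#' @return A `quat_series` from `"GRF"` to `"AL-mcbf"`.
#' @export
shank_frame <- function(ms, side = c("R", "L")) {
  side <- match.arg(side)
  .check_gaps(ms, paste0(side, c("MEP", "LEP", "MMAL", "LMAL")))
  mep <- marker_xyz(ms, paste0(side, "MEP"))
  lep <- marker_xyz(ms, paste0(side, "LEP"))
  mm <- marker_xyz(ms, paste0(side, "MMAL"))
  lm <- marker_xyz(ms, paste0(side, "LMAL"))
  y <- .unit_rows((mep + lep) / 2 - (mm + lm) / 2)
  z0 <- if (side == "R") lm - mm else mm - lm
  x <- .unit_rows(.cross_rows(y, .unit_rows(z0)))
  z <- .cross_rows(x, y)
  .seg_frame_series(ms$time, x, y, z, "AL-mcbf")
}

#' Anatomical frame for any supported segment
#'
#' Dispatches to [pelvis_frame()], [thigh_frame()] or [shank_frame()].
#'
#' @param ms A `marker_set`.
#' @param segment One of `"pelvis"`, `"thigh_l"`, `"thigh_r"`, `"shank_l"`,
#'   `"shank_r"`.
#' @return A `quat_series` from `"GRF"` to `"AL-mcbf"`.
#' @export
segment_frame <- function(ms, segment) {
  switch(segment,
         pelvis = pelvis_frame(ms),
         thigh_l = thigh_frame(ms, "L"),
         thigh_r = thigh_frame(ms, "R"),
         shank_l = shank_frame(ms, "L"),
         shank_r = shank_frame(ms, "R"),
         stop("unknown segment: ", segment, call. = FALSE))
}
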