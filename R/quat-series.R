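# Timestamped quaternion series. The user-facing container is a tibble with
# columns time, qw, qx, qy, qz and attributes "from"/"to" carrying the frame
# labels (GRF, IRF, IMU-sf, RMC-sf, AL-mcbf, IMU-mcbf, RMC-mcbf,
# IMU-scbfA/B/C). All series verbs are data-frame-first so they pipe.

#' Construct a quaternion series
#'
#' @param time Numeric vector of timestamps (s), strictly increasing and
#'   uniformly spaced.
#' @param q Length-4 quaternion (recycled) or n x 4 matrix of row quaternions
#'   (w, x, y, z).
#' @param from,to Frame labels, e.g. `"GRF"`, `"IMU-sf"`.
#' @return A `quat_series` tibble with columns `time, qw, qx, qy, qz`.
#' @export
quat_series <- function(time, q, from = NA_character_, to = NA_character_) {
  m <- .q_as_mat(q)
  if (nrow(m) == 1L) m <- m[rep(1L, length(time)), , drop = FALSE]
  if (nrow(m) != length(time)) stop("time and quaternion lengths differ", call. = FALSE)
  if (length(time) == 0L) stop("empty series", call. = FALSE)
  if (length(time) > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  }
  m <- m / sqrt(rowSums(m^2))
  out <- tibble::tibble(time = time, qw = m[, 1], qx = m[, 2], qy = m[, 3], qz = m[, 4])
  attr(out, "from") <- from
  attr(out, "to") <- to
  class(out) <- c("quat_series", class(out))
  out
}

#' Extract the n x 4 quaternion matrix from a series
#' @param qs A `quat_series` tibble.
#' @return n x 4 numeric matrix (w, x, y, z).
#' @export
qs_matrix <- function(qs) {
  as.matrix(qs[, c("qw", "qx", "qy", "qz")])
}

qs_frames <- function(qs) c(attr(qs, "from") %||% NA_character_, attr(qs, "to") %||% NA_character_)

qs_rebuild <- function(qs, m, from = NULL, to = NULL) {
  quat_series(qs$time, m,
              from = from %||% attr(qs, "from") %||% NA_character_,
              to = to %||% attr(qs, "to") %||% NA_character_)
}

#' Sampling interval of a uniform series
#' @param qs A `quat_series` (or any tibble with a `time` column).
#' @return Median sampling interval in seconds.
#' @export
qs_dt <- function(qs) stats::median(diff(qs$time))

#' Enforce sign continuity along a quaternion series
#'
#' q and -q encode the same rotation; averaging and interpolation need a
#' consistent sign. Flips signs so consecutive quaternions have non-negative
#' dot products. Rotations are unchanged.
#'
#' @param qs A `quat_series` tibble.
#' @return The series with continuous signs.
#' @export
enforce_continuity <- function(qs) {
  if (nrow(qs) == 0L) stop("empty series", call. = FALSE)
  m <- qs_matrix(qs)
  flip <- cumprod(c(1, sign(rowSums(m[-nrow(m), , drop = FALSE] *
                                    m[-1, , drop = FALSE]) + .Machine$double.eps)))
  qs_rebuild(qs, m * flip)
}

#' Mean rotation of a quaternion series
#'
#' Component-wise arithmetic mean after sign-continuity enforcement,
#' renormalized to unit norm. Intended for the low-dispersion static-trial
#' regime; warns when the series spreads more than `max_dispersion_deg`
#' about its mean.
#'
#' @param qs A `quat_series` tibble.
#' @param max_dispersion_deg Dispersion warning threshold, degrees.
#' @return Unit quaternion (length 4), canonical sign (w >= 0).
#' @export
qmean <- function(qs, max_dispersion_deg = 30) {
  if (nrow(qs) == 0L) stop("empty series", call. = FALSE)
  m <- qs_matrix(enforce_continuity(qs))
  q <- unname(colMeans(m))
  q <- q / sqrt(sum(q^2))
  disp <- max(qangle(qmul(qinv(m), q)))
  if (disp > max_dispersion_deg) {
    warning(sprintf("quaternion dispersion %.1f deg exceeds %.1f deg; mean may be unreliable",
                    disp, max_dispersion_deg), call. = FALSE)
  }
  if (q[1] < 0) q <- -q
  q
}

#' Body-frame angular velocity of a quaternion series
#'
#' Finite-difference angular velocity (rad/s) expressed in the series'
#' target (body) frame, from the relative rotation between consecutive
#' samples. Used for IMU/marker synchronization.
#'
#' @param qs A `quat_series` tibble.
#' @return Tibble `time, wx, wy, wz, rate` (rate = |omega| rad/s).
#' @export
qs_angular_rate <- function(qs) {
  m <- qs_matrix(enforce_continuity(qs))
  n <- nrow(m)
  if (n < 3L) stop("series too short for differentiation", call. = FALSE)
  # central differences: the rate at sample i from the rotation i-1 -> i+1
  lo <- m[c(1, 1:(n - 1)), , drop = FALSE]
  hi <- m[c(2:n, n), , drop = FALSE]
  span <- qs$time[c(2:n, n)] - qs$time[c(1, 1:(n - 1))]
  dq <- qmul(qinv(lo), hi)
  ang <- 2 * acos(pmin(1, abs(dq[, 1])))          # rad
  sn <- sqrt(pmax(0, 1 - dq[, 1]^2))
  ax <- dq[, 2:4, drop = FALSE]
  ok <- sn > 1e-12
  ax[ok, ] <- ax[ok, , drop = FALSE] / sn[ok]
  ax[!ok, ] <- 0
  ax <- ax * sign(dq[, 1])                        # q and -q same rotation
  w <- ax * (ang / span)
  tibble::tibble(time = qs$time, wx = w[, 1], wy = w[, 2], wz = w[, 3],
                 rate = sqrt(rowSums(w^2)))
}
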