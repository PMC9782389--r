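# Scalar-first Hamilton quaternions. q_A^B holds the orientation of frame B
# relative to frame A: v_A = q %q% v_B %q% q*, and chains right-to-left,
# q_A^C = q_A^B (x) q_B^C. All functions accept either a length-4 numeric
# (w, x, y, z) or an n x 4 matrix of row quaternions and are vectorised
# over rows.

.q_as_mat <- function(q) {
  if (is.matrix(q)) {
    if (ncol(q) != 4L) stop("quaternions must have 4 components", call. = FALSE)
    q
  } else {
    if (length(q) != 4L) stop("quaternions must have 4 components", call. = FALSE)
    matrix(q, nrow = 1L)
  }
}

.q_shape <- function(out, a, b = NULL) {
  vec_in <- !is.matrix(a) && (is.null(b) || !is.matrix(b))
  if (vec_in && nrow(out) == 1L) drop(out) else out
}

.q_check_finite <- function(..., what = "quaternion") {
  for (q in list(...)) {
    if (!all(is.finite(q))) stop("non-finite ", what, " input", call. = FALSE)
  }
}

#' Identity quaternion
#' @return Numeric vector `c(1, 0, 0, 0)`.
#' @export
qidentity <- function() c(1, 0, 0, 0)

#' Normalize quaternions to unit norm
#' @param q Length-4 numeric or n x 4 matrix (w, x, y, z rows).
#' @return Same shape as `q`, each quaternion scaled to unit norm.
#' @export
qnormalize <- function(q) {
  m <- .q_as_mat(q)
  .q_check_finite(m)
  n <- sqrt(rowSums(m^2))
  if (any(n < 1e-12)) stop("cannot normalize zero quaternion", call. = FALSE)
  .q_shape(m / n, q)
}

#' Hamilton product of quaternions
#'
#' Composes rotations: if `a` is q_A^B and `b` is q_B^C, the product is
#' q_A^C. The result is renormalized.
#'
#' @param a,b Length-4 numeric or n x 4 matrices; a single row recycles
#'   against a matrix.
#' @return Product quaternion(s), unit norm.
#' @export
qmul <- function(a, b) {
  am <- .q_as_mat(a); bm <- .q_as_mat(b)
  .q_check_finite(am, bm)
  if (nrow(am) == 1L && nrow(bm) > 1L) am <- am[rep(1L, nrow(bm)), , drop = FALSE]
  if (nrow(bm) == 1L && nrow(am) > 1L) bm <- bm[rep(1L, nrow(am)), , drop = FALSE]
  if (nrow(am) != nrow(bm)) stop("length mismatch in qmul", call. = FALSE)
  w <- am[, 1] * bm[, 1] - am[, 2] * bm[, 2] - am[, 3] * bm[, 3] - am[, 4] * bm[, 4]
  x <- am[, 1] * bm[, 2] + am[, 2] * bm[, 1] + am[, 3] * bm[, 4] - am[, 4] * bm[, 3]
  y <- am[, 1] * bm[, 3] - am[, 2] * bm[, 4] + am[, 3] * bm[, 1] + am[, 4] * bm[, 2]
  z <- am[, 1] * bm[, 4] + am[, 2] * bm[, 3] - am[, 3] * bm[, 2] + am[, 4] * bm[, 1]
  out <- cbind(w, x, y, z, deparse.level = 0)
  out <- out / sqrt(rowSums(out^2))
  .q_shape(out, a, b)
}

#' Quaternion inverse (conjugate for unit quaternions)
#' @inheritParams qnormalize
#' @return Inverse quaternion(s).
#' @export
qinv <- function(q) {
  m <- .q_as_mat(q)
  .q_check_finite(m)
  out <- cbind(m[, 1], -m[, 2], -m[, 3], -m[, 4], deparse.level = 0)
  .q_shape(out, q)
}

#' Rotate a 3-vector by a quaternion
#'
#' Computes v' = q (x) v (x) q*: the coordinates of `v` (given in the
#' quaternion's target frame) re-expressed in its source frame.
#'
#' @param q Unit quaternion (length 4) or n x 4 matrix.
#' @param v Length-3 numeric or n x 3 matrix of row vectors.
#' @return Rotated vector(s), same shape logic as inputs.
#' @export
qrotate <- function(q, v) {
  qm <- .q_as_mat(q)
  vm <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  if (ncol(vm) != 3L) stop("vectors must have 3 components", call. = FALSE)
  .q_check_finite(qm, vm, what = "qrotate")
  if (nrow(qm) == 1L && nrow(vm) > 1L) qm <- qm[rep(1L, nrow(vm)), , drop = FALSE]
  if (nrow(vm) == 1L && nrow(qm) > 1L) vm <- vm[rep(1L, nrow(qm)), , drop = FALSE]
  w <- qm[, 1]; qv <- qm[, 2:4, drop = FALSE]
  # v' = v + 2 w (qv x v) + 2 qv x (qv x v)
  t1 <- 2 * .cross_rows(qv, vm)
  out <- vm + w * t1 + .cross_rows(qv, t1)
  if (!is.matrix(v) && !is.matrix(q)) drop(out) else out
}

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1], deparse.level = 0)
}

#' Quaternion from an orthonormal axis triad
#'
#' Builds the quaternion whose rotation matrix has columns `x`, `y`, `z`
#' (the child frame's axes expressed in the parent frame). The triad is
#' re-orthogonalized internally; the returned sign is canonical (w >= 0).
#'
#' @param x,y,z Unit 3-vectors, right-handed within 1e-6.
#' @return Unit quaternion, w >= 0.
#' @export
qfrom_axes <- function(x, y, z) {
  R <- cbind(x, y, z, deparse.level = 0)
  if (!all(is.finite(R))) stop("non-finite axis input", call. = FALSE)
  if (abs(det(R)) < 1e-6) stop("degenerate frame: collinear or zero axes", call. = FALSE)
  # polar re-orthogonalization via SVD
  s <- svd(R)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) stop("degenerate frame: left-handed triad", call. = FALSE)
  qfrom_matrix(R)
}

#' Quaternion from / to a rotation matrix
#'
#' @param R 3 x 3 rotation matrix (columns = child axes in parent frame).
#' @return `qfrom_matrix`: unit quaternion with w >= 0;
#'   `qto_matrix`: 3 x 3 rotation matrix.
#' @export
qfrom_matrix <- function(R) {
  # Shepperd's method: pick the most stable of the four branches
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > max(R[1, 1], R[2, 2], R[3, 3])) {
    w <- sqrt(1 + tr) / 2
    q <- c(w,
           (R[3, 2] - R[2, 3]) / (4 * w),
           (R[1, 3] - R[3, 1]) / (4 * w),
           (R[2, 1] - R[1, 2]) / (4 * w))
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3L + 1L; k <- j %% 3L + 1L
    s <- sqrt(1 + R[i, i] - R[j, j] - R[k, k]) * 2
    qv <- numeric(3)
    qv[i] <- s / 4
    qv[j] <- (R[j, i] + R[i, j]) / s
    qv[k] <- (R[k, i] + R[i, k]) / s
    q <- c((R[k, j] - R[j, k]) / s, qv)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' @rdname qfrom_matrix
#' @param q Unit quaternion (length 4).
#' @export
qto_matrix <- function(q) {
  q <- qnormalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Quaternion from axis and angle
#' @param axis Length-3 axis (normalized internally).
#' @param angle_deg Rotation angle in degrees.
#' @return Unit quaternion.
#' @export
qfrom_axis_angle <- function(axis, angle_deg) {
  axis <- unname(axis) / sqrt(sum(axis^2))
  half <- unname(angle_deg) * pi / 360
  c(cos(half), sin(half) * axis)
}

#' Smallest rotation angle of a quaternion, in degrees
#'
#' theta = 2 arccos(min(1, |w|)), in 0..180 degrees; sign-invariant, so
#' `qangle(q) == qangle(-q)`.
#'
#' @inheritParams qnormalize
#' @return Angle(s) in degrees.
#' @export
qangle <- function(q) {
  m <- .q_as_mat(q)
  .q_check_finite(m)
  n <- sqrt(rowSums(m^2))
  ang <- 2 * acos(pmin(1, abs(m[, 1]) / n)) * 180 / pi
  if (is.matrix(q)) ang else ang[1]
}

#' Relative rotation between two frames sharing a reference
#'
#' For `qa` = q_G^A and `qb` = q_G^B (same reference frame G), returns
#' q_A^B = qinv(qa) (x) qb.
#'
#' @param qa,qb Unit quaternions or n x 4 matrices relative to the same
#'   reference frame.
#' @return Relative quaternion(s).
#' @export
qrel <- function(qa, qb) qmul(qinv(qa), qb)
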