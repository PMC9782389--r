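# Independent oracles used across the suite. These deliberately avoid the
# package's own conversion routines.

# Rodrigues rotation matrix from axis-angle
rodrigues <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotation matrix directly from quaternion components (textbook formula,
# written out independently of qto_matrix)
rot_from_quat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
         3, byrow = TRUE)
}

rand_quat <- function(n = 1) {
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m / sqrt(rowSums(m^2))
}

# Kabsch/SVD optimal rotation mapping local coords L onto observed P
kabsch <- function(P, L) {
  Pc <- sweep(P, 2, colMeans(P)); Lc <- sweep(L, 2, colMeans(L))
  s <- svd(t(Pc) %*% Lc)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Markley eigenvector mean of row quaternions
markley_mean <- function(m) {
  v <- eigen(crossprod(m), symmetric = TRUE)$vectors[, 1]
  if (v[1] < 0) -v else v
}

# angle between two quaternions ignoring sign, via the dot product
quat_angle_between <- function(a, b) {
  2 * acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}

noise_free_cfg <- function(movement = "squat", ...) {
  synthetic_config(movement = movement, gyro_noise = 0, accel_noise = 0,
                   mag_noise = 0, gyro_bias = c(0, 0, 0), marker_noise_mm = 0,
                   sta_gain = 0, impact_deg = 0, ...)
}

rmc_geometry <- function(segment) {
  g <- default_geometry()$rmc_local
  names(g) <- paste0(toupper(segment), "_", names(g))
  g
}

# rebuild a quat_series after data-frame subsetting (which drops attributes)
as_qs <- function(df, from, to) {
  quat_series(df$time, as.matrix(df[, c("qw", "qx", "qy", "qz")]),
              from = from, to = to)
}
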