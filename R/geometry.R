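# Small geometry helpers shared across modules.

#' Unit vectors on a sphere by the golden-section spiral
#'
#' Deterministic, nearly uniform point set used by the accessibility sampler.
#'
#' @param n number of points.
#' @return an `n x 3` matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Convert a (not necessarily unit) quaternion to a rotation matrix
#' @param q numeric length-4; normalized internally.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Optimal superposition (Kabsch) of two coordinate sets
#'
#' @param x,y `n x 3` matrices, rows in correspondence; `x` is rotated onto `y`.
#' @return list with `R` (rotation), `t` (translation), `rmsd`.
#' @keywords internal
kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.vector(R %*% cx)
  fit <- sweep(x0 %*% t(R), 2, cy, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fit - y)^2))))
}

#' Apply a rigid transform to coordinates
#' @keywords internal
apply_rigid <- function(xyz, R, t) {
  sweep(xyz %*% t(R), 2, t, "+")
}

# Best-fit plane of >= 3 points: returns centroid and unit normal (smallest
# principal direction).
plane_fit <- function(xyz) {
  ctr <- colMeans(xyz)
  s <- svd(sweep(xyz, 2, ctr))
  n <- s$v[, 3]
  list(centroid = ctr, normal = n / sqrt(sum(n^2)))
}

# Angle (deg) at vertex b for points a-b-c.
angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Acute angle (deg) between two plane normals.
plane_angle_deg <- function(n1, n2) {
  cosang <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
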