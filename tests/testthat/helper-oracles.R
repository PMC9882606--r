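# Independent oracles: kept deliberately separate from the implementation
# paths they check.

# accessibility oracle: Fibonacci-lattice directions (a different
# construction from the implementation's spiral) at 10x density, averaged
# over several random orientations so lattice artefacts cancel
sasa_oracle <- function(atoms, probe = 1.4, n_points = 19200, seed = 99,
                        n_rot = 5) {
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- hotphore:::vdw_radius(atoms$element) + probe
  n <- nrow(atoms)
  i_pt <- seq_len(n_points)
  gold <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * i_pt - 1) / n_points
  phi <- 2 * pi * i_pt / gold
  lattice <- cbind(
    sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z
  )
  set.seed(seed)
  total <- matrix(0, n, 1)
  for (k in seq_len(n_rot)) {
    q <- stats::rnorm(4)
    pts <- lattice %*% t(hotphore:::quat_to_rot(q / sqrt(sum(q^2))))
    for (i in seq_len(n)) {
      sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
      acc <- rep(TRUE, n_points)
      for (j in seq_len(n)[-i]) {
        d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
          (sp[, 3] - xyz[j, 3])^2
        acc <- acc & d2 >= rad[j]^2
      }
      total[i] <- total[i] + 4 * pi * rad[i]^2 * mean(acc)
    }
  }
  as.vector(total / n_rot)
}

# numeric grid integration of the product of two Gaussian mixtures
grid_overlap_oracle <- function(xa, ra, xb, rb, p = 2.7, spacing = 0.1,
                                margin = 3) {
  all_pts <- rbind(xa, xb)
  lo <- apply(all_pts, 2, min) - margin
  hi <- apply(all_pts, 2, max) + margin
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dens <- function(xs, rs) {
    al <- hotphore:::gaussian_alpha(rs, p)
    rho <- numeric(nrow(grid))
    for (i in seq_len(nrow(xs))) {
      d2 <- (grid[, 1] - xs[i, 1])^2 + (grid[, 2] - xs[i, 2])^2 +
        (grid[, 3] - xs[i, 3])^2
      rho <- rho + p * exp(-al[i] * d2)
    }
    rho
  }
  sum(dens(xa, ra) * dens(xb, rb)) * spacing^3
}

# connected components of the threshold graph by breadth-first search
brute_force_clusters <- function(xyz, cutoff) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  labels <- rep(NA_integer_, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (!is.na(labels[s])) next
    comp <- comp + 1L
    queue <- s
    labels[s] <- comp
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(d[v, ] <= cutoff & is.na(labels))
      labels[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  labels
}

rigid_jitter <- function(xyz, R, t) hotphore:::apply_rigid(xyz, R, t)

random_rotation <- function() {
  q <- stats::rnorm(4)
  hotphore:::quat_to_rot(q / sqrt(sum(q^2)))
}
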