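# Rigid-body alignment of a conformer to a pharmacophore under a Gaussian
# shape + typed-feature ("color") overlap objective, with Tanimoto scoring.
#
# Each heavy atom / feature is a spherical Gaussian p*exp(-alpha r^2) whose
# exponent is chosen so the isolated-atom integral equals the hard-sphere
# volume (4/3) pi r^3 -- possible only for amplitude p > 1. Set overlap is
# the first-order sum of pairwise product integrals; higher-order
# intersection corrections are neglected.

gaussian_alpha <- function(radius, p) {
  pi * (3 * p / (4 * pi * radius^3))^(2 / 3)
}

#' Closed-form overlap volume of two atomic Gaussians
#'
#' `V_ij = p^2 (pi/(a_i+a_j))^{3/2} exp(-a_i a_j d^2 / (a_i+a_j))`, symmetric
#' in the two atoms.
#'
#' @param xyz_i,xyz_j positions (length-3).
#' @param r_i,r_j radii (Angstrom).
#' @param p Gaussian amplitude.
#' @return overlap volume in A^3.
#' @export
gaussian_pair_overlap <- function(xyz_i, xyz_j, r_i = 1.7, r_j = 1.7, p = 2.7) {
  ai <- gaussian_alpha(r_i, p)
  aj <- gaussian_alpha(r_j, p)
  d2 <- sum((xyz_i - xyz_j)^2)
  p^2 * (pi / (ai + aj))^1.5 * exp(-ai * aj * d2 / (ai + aj))
}

# vectorized all-pairs overlap between two sets (matrices + radius vectors)
pair_overlap_matrix <- function(xa, ra, xb, rb, p) {
  aa <- gaussian_alpha(ra, p)
  ab <- gaussian_alpha(rb, p)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  asum <- outer(aa, ab, "+")
  p^2 * (pi / asum)^1.5 * exp(-outer(aa, ab) * d2 / asum)
}

#' First-order Gaussian overlap volume of two sets
#'
#' Sum of all pairwise overlaps. For color overlap only same-type pairs count
#' (ring-ring, donor-donor, acceptor-acceptor); a dual-role feature matches
#' either role, counted once per pair.
#'
#' @param a,b lists with elements `xyz` (n x 3 matrix), `radius` (vector),
#'   and optionally `kind`, `donor`, `acceptor` for color sets.
#' @param p Gaussian amplitude.
#' @param color if `TRUE`, restrict to type-compatible pairs.
#' @return overlap volume in A^3 (0 with a warning when a set is empty).
#' @export
overlap_volume <- function(a, b, p = 2.7, color = FALSE) {
  if (nrow(a$xyz) == 0 || nrow(b$xyz) == 0) {
    warning("overlap_volume: empty set", call. = FALSE)
    return(0)
  }
  v <- pair_overlap_matrix(a$xyz, a$radius, b$xyz, b$radius, p)
  if (color) {
    ring <- outer(a$kind == "ring", b$kind == "ring")
    don <- outer(a$donor, b$donor)
    acc <- outer(a$acceptor, b$acceptor)
    v <- v * (ring | don | acc)
  }
  sum(v)
}

shape_set <- function(xyz, radius) {
  list(xyz = xyz, radius = rep_len(radius, nrow(xyz)))
}

color_set <- function(feats, radius) {
  keep <- feats$kind %in% c("ring", "donor", "acceptor")
  f <- feats[keep, , drop = FALSE]
  list(
    xyz = as.matrix(f[, c("x", "y", "z")]),
    radius = rep_len(radius, nrow(f)),
    kind = f$kind, donor = f$donor, acceptor = f$acceptor
  )
}

# shape + color sets of a pharmacophore: atom-like features (carbon, donor,
# acceptor) define shape; ring centroids + donors/acceptors define color
phore_sets <- function(phore, params) {
  f <- phore$features
  at <- f[f$kind != "ring", , drop = FALSE]
  list(
    shape = shape_set(as.matrix(at[, c("x", "y", "z")]), params$shape_radius),
    color = color_set(f, params$color_radius)
  )
}

conformer_sets_for <- function(cs, conf, params) {
  a <- cs$atoms[cs$atoms$conf == conf & cs$atoms$element != "H", , drop = FALSE]
  feats <- cs$features
  feats <- if (is.null(feats)) {
    perceive_ligand_features(cs, conf)
  } else {
    feats[feats$conf == conf, , drop = FALSE]
  }
  list(
    shape = shape_set(as.matrix(a[, c("x", "y", "z")]), params$shape_radius),
    color = color_set(feats, params$color_radius)
  )
}

transform_set <- function(set, R, t) {
  out <- set
  out$xyz <- apply_rigid(set$xyz, R, t)
  out
}

tanimoto <- function(vab, vaa, vbb) {
  if (vaa + vbb - vab <= 0) {
    return(0)
  }
  max(0, min(1, vab / (vaa + vbb - vab)))
}

#' Align a conformer to a pharmacophore
#'
#' Multi-start local optimization over the 6 rigid degrees of freedom
#' maximizing `V_AB(shape) + color_weight * V_AB(color)`. Starts are the 4
#' proper inertial-axis flips plus `n_random_starts` seeded random rotations,
#' each refined by a derivative-free simplex over a unit quaternion and a
#' translation. Ties between starts break by start index, so the result is
#' deterministic under a fixed seed.
#'
#' @param cs a `conformer_set`.
#' @param phore a `pharmacophore`.
#' @param conf conformer index within `cs`.
#' @param params an [hp_params()] list.
#' @return a `phore_alignment`: rotation `R` and translation `t` mapping
#'   query into the template frame, overlap volumes, `T_shape`, `T_color`,
#'   `S_combo = (T_shape + T_color)/2`, start diagnostics, `converged`.
#' @export
align_to_pharmacophore <- function(cs, phore, conf = 1L, params = hp_params()) {
  tmpl <- phore_sets(phore, params)
  qry <- conformer_sets_for(cs, conf, params)
  if (nrow(qry$shape$xyz) == 0) stop("conformer has no heavy atoms", call. = FALSE)
  if (nrow(tmpl$shape$xyz) == 0) stop("pharmacophore has no features", call. = FALSE)
  p <- params$gaussian_p
  w <- params$color_weight

  vaa_s <- overlap_volume(tmpl$shape, tmpl$shape, p)
  vbb_s <- overlap_volume(qry$shape, qry$shape, p)
  vaa_c <- if (nrow(tmpl$color$xyz)) overlap_volume(tmpl$color, tmpl$color, p, color = TRUE) else 0
  vbb_c <- if (nrow(qry$color$xyz)) overlap_volume(qry$color, qry$color, p, color = TRUE) else 0
  has_color <- nrow(tmpl$color$xyz) > 0 && nrow(qry$color$xyz) > 0

  ctr_q <- colMeans(qry$shape$xyz)
  ctr_t <- colMeans(tmpl$shape$xyz)
  q0 <- sweep(qry$shape$xyz, 2, ctr_q)
  qc0 <- if (has_color) sweep(qry$color$xyz, 2, ctr_q) else NULL

  objective <- function(par) {
    R <- quat_to_rot(par[1:4])
    t <- par[5:7]
    qs <- qry$shape
    qs$xyz <- sweep(q0 %*% t(R), 2, t, "+")
    val <- overlap_volume(qs, tmpl$shape, p)
    if (has_color) {
      qc <- qry$color
      qc$xyz <- sweep(qc0 %*% t(R), 2, t, "+")
      val <- val + w * overlap_volume(qc, tmpl$color, p, color = TRUE)
    }
    -val
  }

  starts <- alignment_starts(q0, tmpl$shape$xyz, ctr_t, params)
  best <- NULL
  n_eval <- 0L
  for (s in seq_along(starts)) {
    st <- starts[[s]]
    fit <- stats::optim(c(st$q, st$t), objective,
      method = "Nelder-Mead",
      control = list(reltol = params$opt_tol, maxit = 2000)
    )
    n_eval <- n_eval + fit$counts[1]
    if (is.null(best) || fit$value < best$value - 1e-12) {
      best <- fit
      best$start <- s
    }
  }

  R <- quat_to_rot(best$par[1:4])
  t_full <- as.vector(best$par[5:7]) - as.vector(R %*% ctr_q)
  qs <- transform_set(qry$shape, R, t_full)
  vab_s <- overlap_volume(qs, tmpl$shape, p)
  vab_c <- if (has_color) {
    overlap_volume(transform_set(qry$color, R, t_full), tmpl$color, p, color = TRUE)
  } else {
    0
  }
  t_shape <- tanimoto(vab_s, vaa_s, vbb_s)
  t_color <- if (has_color) tanimoto(vab_c, vaa_c, vbb_c) else 0

  structure(
    list(
      R = R, t = t_full,
      V_AB = vab_s, V_AA = vaa_s, V_BB = vbb_s,
      V_AB_color = vab_c, V_AA_color = vaa_c, V_BB_color = vbb_c,
      T_shape = t_shape, T_color = t_color,
      S_combo = (t_shape + t_color) / 2,
      conf = conf, name = cs$name,
      phore = phore$provenance,
      starts = length(starts), best_start = best$start,
      n_eval = n_eval,
      converged = best$convergence == 0
    ),
    class = "phore_alignment"
  )
}

alignment_starts <- function(q0, tmpl_xyz, ctr_t, params) {
  # principal axes of both point clouds
  ax_q <- svd(q0)$v
  if (det(ax_q) < 0) ax_q[, 3] <- -ax_q[, 3]
  t0 <- sweep(tmpl_xyz, 2, ctr_t)
  ax_t <- svd(t0)$v
  if (det(ax_t) < 0) ax_t[, 3] <- -ax_t[, 3]
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  starts <- lapply(flips, function(f) {
    R <- ax_t %*% diag(f) %*% t(ax_q)
    list(q = rot_to_quat(R), t = ctr_t)
  })
  if (params$n_random_starts > 0) {
    set.seed(params$seed)
    for (i in seq_len(params$n_random_starts)) {
      q <- stats::rnorm(4)
      starts[[length(starts) + 1L]] <- list(q = q / sqrt(sum(q^2)), t = ctr_t)
    }
  }
  starts
}

rot_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s, (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

#' Best alignment over all conformers of a molecule
#'
#' @inheritParams align_to_pharmacophore
#' @return the `phore_alignment` with the highest combo score.
#' @export
align_best_conformer <- function(cs, phore, params = hp_params()) {
  fits <- lapply(
    seq_len(cs$n_conf),
    function(i) align_to_pharmacophore(cs, phore, conf = i, params = params)
  )
  scores <- vapply(fits, function(f) f$S_combo, double(1))
  fits[[which.max(scores)]]
}

#' @export
print.phore_alignment <- function(x, ...) {
  cat(sprintf(
    "<phore_alignment> %s conf %d vs %s: T_shape %.3f T_color %.3f S_combo %.3f\n",
    x$name, x$conf, x$phore$source_id, x$T_shape, x$T_color, x$S_combo
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an alignment into a one-row tibble
#'
#' @param x a `phore_alignment`.
#' @param ... unused.
#' @export
tidy.phore_alignment <- function(x, ...) {
  tibble::tibble(
    name = x$name, conf = x$conf, template = x$phore$source_id,
    T_shape = x$T_shape, T_color = x$T_color, S_combo = x$S_combo,
    V_AB = x$V_AB, converged = x$converged, best_start = x$best_start
  )
}

#' @rdname tidy.phore_alignment
#' @export
glance.phore_alignment <- function(x, ...) {
  tibble::tibble(
    S_combo = x$S_combo, starts = x$starts, n_eval = x$n_eval,
    converged = x$converged
  )
}
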