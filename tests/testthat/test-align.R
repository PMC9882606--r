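# Gaussian overlap volumes and rigid alignment.

test_that("pair overlap: symmetry, closed form at d = 0, decay to zero", {
  set.seed(2)
  for (i in 1:5) {
    a <- stats::rnorm(3)
    b <- stats::rnorm(3, sd = 2)
    expect_equal(
      gaussian_pair_overlap(a, b, 1.7, 1.2),
      gaussian_pair_overlap(b, a, 1.2, 1.7)
    )
  }
  p <- 2.7
  al <- hotphore:::gaussian_alpha(1.7, p)
  expect_equal(
    gaussian_pair_overlap(c(0, 0, 0), c(0, 0, 0), 1.7, 1.7, p),
    p^2 * (pi / (2 * al))^1.5
  )
  expect_lt(gaussian_pair_overlap(c(0, 0, 0), c(0, 0, 500), 1.7, 1.7), 1e-12)
})

test_that("volume-matching exponent reproduces the hard-sphere volume", {
  # isolated-atom Gaussian integral == (4/3) pi r^3 by construction
  for (r in c(1.0, 1.7, 2.2)) {
    al <- hotphore:::gaussian_alpha(r, 2.7)
    expect_equal(2.7 * (pi / al)^1.5, 4 / 3 * pi * r^3, tolerance = 1e-12)
  }
})

test_that("pair and set overlaps match grid integration", {
  set.seed(21)
  xi <- c(0, 0, 0)
  xj <- c(1.2, 1.0, 1.0) # ~1.86 A apart
  v <- gaussian_pair_overlap(xi, xj, 1.7, 1.7)
  v_grid <- grid_overlap_oracle(rbind(xi), 1.7, rbind(xj), 1.7)
  expect_lt(abs(v - v_grid) / v_grid, 0.01)

  xa <- matrix(stats::runif(15, 0, 4), ncol = 3)
  xb <- matrix(stats::runif(15, 0, 4), ncol = 3)
  v_set <- overlap_volume(
    list(xyz = xa, radius = rep(1.7, 5)),
    list(xyz = xb, radius = rep(1.7, 5))
  )
  v_set_grid <- grid_overlap_oracle(xa, rep(1.7, 5), xb, rep(1.7, 5))
  expect_lt(abs(v_set - v_set_grid) / v_set_grid, 0.05)
})

test_that("self-overlap Tanimoto is exactly 1 and empty sets warn", {
  set.seed(3)
  xa <- matrix(stats::rnorm(12), ncol = 3)
  s <- list(xyz = xa, radius = rep(1.7, 4))
  vaa <- overlap_volume(s, s)
  expect_equal(hotphore:::tanimoto(vaa, vaa, vaa), 1)
  expect_warning(
    v0 <- overlap_volume(list(xyz = matrix(0, 0, 3), radius = numeric()), s),
    "empty"
  )
  expect_equal(v0, 0)
})

test_that("a randomly transformed probe aligns back onto its pharmacophore", {
  phore <- toy_phore()
  probe <- make_probe_ligand(phore)
  set.seed(17)
  moved <- transform_conformer_set(probe, random_rotation(), c(25, -10, 8))
  fit <- align_to_pharmacophore(moved, phore, params = fast_align_params())
  expect_gte(fit$S_combo, 0.99)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  back <- rigid_jitter(as.matrix(moved$atoms[, c("x", "y", "z")]), fit$R, fit$t)
  orig <- as.matrix(probe$atoms[, c("x", "y", "z")])
  expect_lt(sqrt(mean(rowSums((back - orig)^2))), 0.1)
})

test_that("scores are invariant to rigid pre-transformation of the query", {
  phore <- toy_phore()
  probe <- make_probe_ligand(phore)
  fit0 <- align_to_pharmacophore(probe, phore, params = fast_align_params())
  set.seed(23)
  moved <- transform_conformer_set(probe, random_rotation(), c(-40, 13, 2))
  fit1 <- align_to_pharmacophore(moved, phore, params = fast_align_params())
  expect_lt(abs(fit0$S_combo - fit1$S_combo), 1e-3)
  expect_lt(abs(fit0$T_shape - fit1$T_shape), 1e-3)
})

test_that("adding a far-away atom to the query lowers the shape Tanimoto", {
  phore <- toy_phore()
  probe <- make_probe_ligand(phore)
  fit0 <- align_to_pharmacophore(probe, phore, params = fast_align_params())
  bigger <- probe
  bigger$atoms <- dplyr::bind_rows(
    probe$atoms,
    tibble::tibble(
      conf = 1L, atom_id = max(probe$atoms$atom_id) + 1L, element = "C",
      x = probe$atoms$x[1] + 30, y = 0, z = 0
    )
  )
  fit1 <- align_to_pharmacophore(bigger, phore, params = fast_align_params())
  expect_lt(fit1$T_shape, fit0$T_shape)
})

test_that("a featureless query scores zero color against a typed template", {
  phore <- toy_phore()
  fit <- align_to_pharmacophore(decoy_blob(1), phore, params = fast_align_params())
  expect_equal(fit$T_color, 0)
  expect_gte(fit$T_shape, 0)
  expect_lte(fit$S_combo, 0.5)
})

test_that("tidy and glance summarise an alignment", {
  phore <- toy_phore()
  fit <- align_to_pharmacophore(make_probe_ligand(phore), phore,
    params = fast_align_params()
  )
  td <- tidy(fit)
  expect_equal(nrow(td), 1)
  expect_true(all(c("T_shape", "T_color", "S_combo") %in% names(td)))
  expect_true(glance(fit)$converged)
})
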