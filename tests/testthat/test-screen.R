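# Receptor-frame placement, interaction scoring, library ranking.

test_that("placement applies the alignment transform exactly", {
  fx <- toy_fixture()
  phore <- toy_phore()
  probe <- make_probe_ligand(phore)
  set.seed(5)
  moved <- transform_conformer_set(probe, random_rotation(), c(30, 0, -12))
  fit <- align_to_pharmacophore(moved, phore, params = fast_align_params())
  pose <- place_in_receptor(fit, moved, fx$structure)
  manual <- rigid_jitter(as.matrix(moved$atoms[, c("x", "y", "z")]), fit$R, fit$t)
  expect_lt(max(abs(as.matrix(pose$atoms[, c("x", "y", "z")]) - manual)), 1e-6)
  # pseudo-molecule pose superposes the pharmacophore features
  feat <- as.matrix(
    dplyr::filter(phore$features, kind != "ring")[, c("x", "y", "z")]
  )
  expect_lt(max(abs(as.matrix(pose$atoms[, c("x", "y", "z")]) - feat)), 1e-2)
})

test_that("placement refuses a receptor the template was not extracted from", {
  phore <- toy_phore()
  probe <- make_probe_ligand(phore)
  fit <- align_to_pharmacophore(probe, phore, params = fast_align_params())
  other <- msi_fixture()$structure
  expect_error(place_in_receptor(fit, probe, other), "provenance")
})

test_that("interaction score: isolated ligand, clash, ideal hydrogen bond", {
  fx <- toy_fixture()
  st <- fx$structure
  far <- tibble::tibble(element = "C", x = 500, y = 500, z = 500)
  s <- interaction_score(far, st)
  expect_equal(s$score, 0)
  expect_equal(s$clash_count, 0L)

  prot1 <- dplyr::filter(tibble::as_tibble(st), chain_class == "protein")[1, ]
  clashing <- tibble::tibble(
    element = "C", x = prot1$x + 1.0, y = prot1$y, z = prot1$z
  )
  expect_gte(interaction_score(clashing, st)$clash_count, 1L)

  # lone N...O pair at 2.9 A against a minimal receptor: one bond, score < 0
  tiny <- classify_chains(hotphore:::new_mol_structure(dplyr::bind_rows(
    hotphore:::atom_rows(
      hotphore:::carbonyl_residue(c(0, 0, 0), c(0, 0, -1)), "A", 1, "VAL"
    ),
    hotphore:::atom_rows(hotphore:::ideal_nucleotide("U"), "R", 1, "U")[1, ] |>
      dplyr::mutate(x = 50, y = 50, z = 50)
  ), "tiny"))
  lig <- tibble::tibble(element = "N", x = 0, y = 0, z = 2.9)
  s2 <- interaction_score(lig, tiny)
  expect_gte(s2$hbond_count, 1L)
  expect_lt(s2$score, 0)
})

test_that("screening ranks the pharmacophore probe above random decoys", {
  fx <- toy_fixture()
  phore <- toy_phore()
  ligands <- c(
    list(make_probe_ligand(phore)),
    lapply(1:5, decoy_blob)
  )
  hits <- screen_library(ligands, phore, fx$structure,
    params = fast_align_params()
  )
  expect_equal(hits$name[1], make_probe_ligand(phore)$name)
  expect_gte(hits$S_combo[1], 0.99)
})

test_that("duplicated molecules score identically with stable tie order", {
  phore <- toy_phore()
  ligands <- list(decoy_blob(3), decoy_blob(3))
  ligands[[1]]$name <- "first"
  ligands[[2]]$name <- "second"
  hits <- screen_library(ligands, phore, params = fast_align_params())
  expect_equal(hits$S_combo[1], hits$S_combo[2])
  expect_equal(hits$name, c("first", "second"))
})

test_that("a clash wall over the pocket empties the hit list, and removing it restores the hit", {
  fx_wall <- make_toy_complex(fixture_spec(
    n_buried = 1, n_exposed = 0, n_hbonds = 1, stacking_rings = 0,
    clash_wall = TRUE, seed = 31
  ))
  ph_wall <- extract_pharmacophores(fx_wall$structure)[[1]]
  probe <- make_probe_ligand(ph_wall)
  hits_wall <- screen_library(list(probe), ph_wall, fx_wall$structure,
    params = fast_align_params()
  )
  expect_equal(nrow(hits_wall), 0)

  no_wall <- classify_chains(hotphore:::new_mol_structure(
    dplyr::filter(tibble::as_tibble(fx_wall$structure), chain != "X"),
    attr(fx_wall$structure, "source_id")
  ))
  ph2 <- extract_pharmacophores(no_wall)[[1]]
  probe2 <- make_probe_ligand(ph2)
  hits_free <- screen_library(list(probe2), ph2, no_wall,
    params = fast_align_params()
  )
  expect_equal(nrow(hits_free), 1)
  expect_equal(hits_free$rank[1], 1L)
})

test_that("an empty ligand stream warns and returns an empty table", {
  expect_warning(
    hits <- screen_library(list(), toy_phore()),
    "empty"
  )
  expect_equal(nrow(hits), 0)
})
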