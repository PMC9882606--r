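# Molecule parsing, conformer generation, feature perception.

test_that("SMILES parse: benzene, salts, and failure modes", {
  m <- parse_ligand("c1ccccc1", name = "benzene")
  expect_equal(m$n_heavy_atoms, 6)
  expect_equal(m$n_aromatic_rings, 1)

  salt <- parse_ligand("c1ccccc1C(=O)[O-].[Na+]", name = "benzoate")
  expect_equal(salt$n_heavy_atoms, 9) # sodium stripped

  expect_error(parse_ligand("not_a_smiles"), "unparseable")
})

test_that("SDF input keeps its 3-D coordinates as conformer 0", {
  cs <- generate_conformers(parse_ligand("CCO", name = "ethanol"),
    n_max = 5, seed = 3
  )
  path <- withr::local_tempfile(fileext = ".sdf")
  write_conformers_sdf(cs, path)
  m <- parse_ligand(path)
  expect_false(is.null(m$conformers))
  a0 <- dplyr::filter(m$conformers$atoms, conf == 1)
  b0 <- dplyr::filter(cs$atoms, conf == 1)
  expect_equal(nrow(a0), nrow(b0))
  expect_lt(max(abs(a0$x - b0$x)), 1e-3)
})

test_that("rigid benzene gives one conformer; butane the anti/gauche family", {
  bz <- generate_conformers(parse_ligand("c1ccccc1", name = "benzene"),
    n_max = 50, seed = 5
  )
  expect_equal(bz$n_conf, 1L)

  bu <- generate_conformers(parse_ligand("CCCC", name = "butane"),
    n_max = 50, seed = 5
  )
  expect_gte(bu$n_conf, 2L)
  # retained conformers are mutually distinct at the dedup threshold
  if (bu$n_conf >= 2) {
    heavy <- function(k) {
      as.matrix(dplyr::filter(bu$atoms, conf == k, element != "H")[, c("x", "y", "z")])
    }
    for (i in seq_len(bu$n_conf - 1)) {
      for (j in (i + 1):bu$n_conf) {
        expect_gte(hotphore:::kabsch(heavy(i), heavy(j))$rmsd, 0.3)
      }
    }
  }
})

test_that("conformer generation is reproducible under a fixed seed", {
  a <- generate_conformers(parse_ligand("CCOC(=O)c1ccc(N)cc1", name = "bz"),
    n_max = 20, seed = 11
  )
  b <- generate_conformers(parse_ligand("CCOC(=O)c1ccc(N)cc1", name = "bz"),
    n_max = 20, seed = 11
  )
  expect_identical(a$atoms, b$atoms)
  expect_equal(a$n_conf, b$n_conf)
})

test_that("feature perception follows the chemistry rules", {
  bz <- generate_conformers(parse_ligand("c1ccccc1", name = "benzene"),
    n_max = 5, seed = 5
  )
  f <- perceive_ligand_features(bz, 1)
  expect_equal(sum(f$kind == "ring"), 1)
  expect_equal(sum(f$donor), 0)
  expect_equal(sum(f$acceptor), 0)

  ph <- generate_conformers(parse_ligand("c1ccc(O)cc1", name = "phenol"),
    n_max = 5, seed = 5
  )
  f <- perceive_ligand_features(ph, 1)
  expect_equal(sum(f$kind == "ring"), 1)
  expect_equal(sum(f$donor), 1) # the O-H oxygen donates...
  expect_equal(sum(f$acceptor), 1) # ...and accepts (dual role)

  ade <- generate_conformers(parse_ligand("Nc1ncnc2[nH]cnc12", name = "adenine"),
    n_max = 5, seed = 5
  )
  f <- perceive_ligand_features(ade, 1)
  expect_equal(sum(f$kind == "ring"), 2)
  expect_gte(sum(f$donor), 2) # exocyclic amine + ring NH
  expect_gte(sum(f$acceptor), 3) # N1/N3/N7-type ring nitrogens
})

test_that("features transform covariantly under rigid motion", {
  ph <- generate_conformers(parse_ligand("c1ccc(O)cc1", name = "phenol"),
    n_max = 5, seed = 5
  )
  f0 <- perceive_ligand_features(ph, 1)
  set.seed(8)
  R <- random_rotation()
  t <- c(3, -2, 7)
  moved <- ph
  moved$atoms[, c("x", "y", "z")] <-
    rigid_jitter(as.matrix(ph$atoms[, c("x", "y", "z")]), R, t)
  f1 <- perceive_ligand_features(moved, 1)
  expect_equal(
    as.matrix(f1[, c("x", "y", "z")]),
    rigid_jitter(as.matrix(f0[, c("x", "y", "z")]), R, t),
    tolerance = 1e-6, ignore_attr = TRUE
  )
})
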