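# Hydrogen-bond detection, polar reversion, clustering, extraction,
# stacking annotation.

# small hand-built complex: one guanine, protein partners at prescribed
# geometry, optional explicit hydrogen on the guanine N1
hb_testbed <- function(partner_dist = 2.9, partner = "NZ", with_h = FALSE,
                       h_angle = 165, water = FALSE) {
  nt <- hotphore:::ideal_nucleotide("G")
  rna <- hotphore:::atom_rows(nt, "R", 1, "G")
  o6 <- as.numeric(nt[match("O6", nt$atom), c("x", "y", "z")])
  n7 <- as.numeric(nt[match("N7", nt$atom), c("x", "y", "z")])
  dir <- (o6 - n7) / sqrt(sum((o6 - n7)^2))
  rows <- list(rna)
  if (partner == "NZ") {
    rows <- c(rows, list(hotphore:::atom_rows(
      hotphore:::lys_residue(o6 + partner_dist * dir, dir), "A", 21, "LYS"
    )))
  }
  if (with_h) {
    n1 <- as.numeric(nt[match("N1", nt$atom), c("x", "y", "z")])
    ctr <- colMeans(as.matrix(nt[1:6, c("x", "y", "z")]))
    u <- (n1 - ctr) / sqrt(sum((n1 - ctr)^2))
    # acceptor along a direction making the requested angle at N1 via H
    hpos <- n1 + 1.0 * u
    th <- (180 - h_angle) * pi / 180
    perp <- c(-u[2], u[1], 0)
    adir <- cos(th) * u + sin(th) * perp
    apos <- n1 + 2.9 * adir
    rows <- c(rows, list(
      tibble::tibble(
        model = 1L, chain = "R", resno = 1L, resname = "G", insert = "",
        atom = "H1", element = "H", x = hpos[1], y = hpos[2], z = hpos[3],
        occ = 1
      ),
      hotphore:::atom_rows(
        hotphore:::carbonyl_residue(apos, adir), "A", 94, "VAL"
      )
    ))
  }
  if (water) {
    n3 <- as.numeric(nt[match("N3", nt$atom), c("x", "y", "z")])
    ctr <- colMeans(as.matrix(nt[1:6, c("x", "y", "z")]))
    u <- (n3 - ctr) / sqrt(sum((n3 - ctr)^2))
    wpos <- n3 + 2.8 * u
    rows <- c(rows, list(
      tibble::tibble(
        model = 1L, chain = "W", resno = 501L, resname = "HOH", insert = "",
        atom = "O", element = "O", x = wpos[1], y = wpos[2], z = wpos[3],
        occ = 1
      ),
      hotphore:::atom_rows(
        hotphore:::carbonyl_residue(wpos + 2.9 * u, u, "GLY"), "A", 50, "GLY"
      )
    ))
  }
  classify_chains(hotphore:::new_mol_structure(dplyr::bind_rows(rows), "hb"))
}

test_that("direct hydrogen bonds follow the distance criterion", {
  hb <- detect_hbonds(hb_testbed(partner_dist = 2.9))
  direct <- dplyr::filter(hb, kind == "direct")
  expect_true(any(direct$rna_atom == "O6" & direct$partner_atom == "NZ"))

  hb_far <- detect_hbonds(hb_testbed(partner_dist = 4.2))
  expect_false(any(hb_far$rna_atom == "O6" & hb_far$partner_atom == "NZ"))
})

test_that("the D-H...A angle gates bonds only when the hydrogen is present", {
  hb <- detect_hbonds(hb_testbed(partner = "none", with_h = TRUE, h_angle = 165))
  expect_true(any(hb$rna_atom == "N1" & hb$partner_atom == "O"))
  expect_gte(hb$angle[hb$rna_atom == "N1" & hb$partner_atom == "O"][1], 120)

  hb_bent <- detect_hbonds(hb_testbed(partner = "none", with_h = TRUE, h_angle = 80))
  expect_false(any(hb_bent$rna_atom == "N1" & hb_bent$partner_atom == "O"))
})

test_that("a bridging water records a water-mediated bond, and the flag disables it", {
  st <- hb_testbed(partner = "none", water = TRUE)
  hb <- detect_hbonds(st)
  wm <- dplyr::filter(hb, kind == "water_mediated")
  expect_true(any(wm$rna_atom == "N3"))
  hb_off <- detect_hbonds(st, params = hp_params(include_waters = FALSE))
  expect_false(any(hb_off$kind == "water_mediated"))
})

test_that("polar atoms not in hydrogen bonds revert to carbon features", {
  fx <- toy_fixture() # adenine 101 with N6 (donor) and N1 (acceptor) planted
  map <- build_interaction_map(fx$structure)
  phore <- toy_phore()
  f <- phore$features
  promoted <- f$atom[f$kind %in% c("donor", "acceptor")]
  expect_setequal(promoted, fx$truth$hbond_atoms$atom)
  carbons <- f$atom[f$kind == "carbon"]
  expect_true(all(c("N3", "N7") %in% carbons)) # unbonded polar -> carbon
  expect_false(any(c("N3", "N7") %in% promoted))
  # every promoted feature traces to a qualifying bond in the map
  for (nm in promoted) {
    expect_true(nm %in% map$hbonds$rna_atom)
  }
})

test_that("an atom bonded as donor and as acceptor yields one dual-role feature", {
  map <- build_interaction_map(toy_fixture()$structure)
  # duplicate the N6 bond with the opposite role
  extra <- map$hbonds[map$hbonds$rna_atom == "N6", ][1, ]
  extra$rna_donor <- FALSE
  extra$rna_acceptor <- TRUE
  map$hbonds <- dplyr::bind_rows(map$hbonds, extra)
  feats <- revert_nonbonding_polar(map)
  n6 <- dplyr::filter(feats, atom == "N6")
  expect_equal(nrow(n6), 1)
  expect_true(n6$donor && n6$acceptor)
})

test_that("single-linkage clusters match brute-force components on random sets", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50
    xyz <- matrix(stats::runif(3 * n, 0, 30), ncol = 3)
    feats <- tibble::tibble(
      kind = sample(c("ring", "carbon"), n, replace = TRUE),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = 1.7,
      nx = NA_real_, ny = NA_real_, nz = NA_real_,
      donor = FALSE, acceptor = FALSE, chain = "R",
      resno = seq_len(n), insert = "", resname = "A",
      atom = paste0("F", seq_len(n))
    )
    cutoff <- 4.5
    got <- cluster_features(feats, cutoff)
    labels <- brute_force_clusters(xyz, cutoff)
    expected <- split(seq_len(n), labels)
    expected <- Filter(function(i) any(feats$kind[i] == "ring"), expected)
    got_sets <- lapply(got, function(f) sort(match(f$atom, feats$atom)))
    exp_sets <- lapply(expected, function(i) sort(i))
    expect_setequal(
      unname(vapply(got_sets, paste, "", collapse = ",")),
      unname(vapply(exp_sets, paste, "", collapse = ","))
    )
  }
})

test_that("stacked rings cluster together, distant groups apart, and count is monotone in cutoff", {
  ring_feat <- function(x, z, resno) {
    tibble::tibble(
      kind = "ring", x = x, y = 0, z = z, radius = 1,
      nx = 0, ny = 0, nz = 1, donor = FALSE, acceptor = FALSE,
      chain = "R", resno = resno, insert = "", resname = "A", atom = "ring6"
    )
  }
  stacked <- dplyr::bind_rows(ring_feat(0, 0, 1), ring_feat(0.5, 3.6, 2))
  expect_length(cluster_features(stacked, 4.5), 1)
  distant <- dplyr::bind_rows(ring_feat(0, 0, 1), ring_feat(12, 0, 2))
  expect_length(cluster_features(distant, 4.5), 2)

  set.seed(42)
  n <- 30
  feats <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    ring_feat(stats::runif(1, 0, 40), stats::runif(1, 0, 10), i)
  }))
  counts <- vapply(
    c(1, 2, 4, 8, 16),
    function(ct) length(cluster_features(feats, ct)), double(1)
  )
  expect_true(all(diff(counts) <= 0))
})

test_that("extraction output is deterministic across repeated runs", {
  st <- toy_fixture()$structure
  p1 <- extract_pharmacophores(st)[[1]]
  p2 <- extract_pharmacophores(st)[[1]]
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(p1, f1)
  write_pharmacophore(p2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("two distant buried bases give two pharmacophores; none gives zero", {
  fx2 <- make_toy_complex(fixture_spec(
    n_buried = 2, n_exposed = 0, n_hbonds = 0, stacking_rings = 0, seed = 13
  ))
  ph2 <- extract_pharmacophores(fx2$structure)
  expect_length(ph2, 2)

  fx0 <- make_toy_complex(fixture_spec(
    n_buried = 0, n_exposed = 2, n_hbonds = 0, stacking_rings = 0, seed = 14
  ))
  expect_message(
    ph0 <- extract_pharmacophores(fx0$structure),
    "no deeply buried base"
  )
  expect_length(ph0, 0)
})

test_that("pharmacophore JSON round-trips", {
  phore <- toy_phore()
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(phore, path)
  back <- read_pharmacophore(path)
  expect_equal(back$features$kind, phore$features$kind)
  expect_equal(back$features$x, phore$features$x, tolerance = 1e-12)
  expect_equal(back$provenance$source_id, phore$provenance$source_id)
})

test_that("stacking partners require parallel geometry within range", {
  fx <- toy_fixture()
  phore <- toy_phore()
  st <- annotate_stacking_partners(fx$structure, phore)
  expect_setequal(st$resno, fx$truth$stacking_resno)

  # perpendicular ring at 8 A is not a stacking partner
  ring_xyz <- dplyr::filter(phore$features, kind == "ring")[1, ]
  ctr <- as.numeric(ring_xyz[, c("x", "y", "z")])
  nrm <- as.numeric(ring_xyz[, c("nx", "ny", "nz")])
  perp <- hotphore:::phe_residue(ctr + c(8, 0, 0), c(1, 0, 0), 0)
  st2 <- classify_chains(hotphore:::new_mol_structure(dplyr::bind_rows(
    tibble::as_tibble(fx$structure),
    hotphore:::atom_rows(perp, "A", 300, "PHE")
  ), attr(fx$structure, "source_id")))
  st_far <- annotate_stacking_partners(st2, phore)
  expect_false(300 %in% st_far$resno)
})
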