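# Structure parsing, writing, chain classification, nucleobase annotation.

test_that("PDB round-trip preserves atoms, names and coordinates", {
  st <- toy_fixture()$structure
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_file(st, path)
  st2 <- read_complex(path)
  expect_equal(nrow(st2), nrow(st))
  expect_equal(st2$atom, st$atom)
  expect_equal(st2$resname, st$resname)
  expect_lt(max(abs(as.matrix(st2[, c("x", "y", "z")]) -
    as.matrix(st[, c("x", "y", "z")]))), 1e-3)
  expect_gte(length(unique(st2$chain)), 2)
})

test_that("the same structure read from PDB and mmCIF agrees", {
  st <- toy_fixture()$structure
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  write_pdb_file(st, pdb)
  write_cif_file(st, cif)
  a <- read_complex(pdb)
  b <- read_complex(cif, format = "mmcif")
  expect_equal(nrow(a), nrow(b))
  expect_lt(max(abs(as.matrix(a[, c("x", "y", "z")]) -
    as.matrix(b[, c("x", "y", "z")]))), 1e-3)
})

test_that("an NMR-style ensemble differing by rotation loads as two models", {
  st <- toy_fixture()$structure
  set.seed(11)
  R <- random_rotation()
  t <- c(5, -3, 2)
  rotated <- dplyr::mutate(tibble::as_tibble(st), model = 2L)
  xyz <- rigid_jitter(as.matrix(rotated[, c("x", "y", "z")]), R, t)
  rotated$x <- xyz[, 1]; rotated$y <- xyz[, 2]; rotated$z <- xyz[, 3]
  ens <- hotphore:::new_mol_structure(
    dplyr::bind_rows(tibble::as_tibble(st), rotated), "ens"
  )
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_file(ens, path)
  st2 <- read_complex(path)
  expect_equal(attr(st2, "n_models"), 2L)
  m1 <- as.matrix(dplyr::filter(st2, model == 1)[, c("x", "y", "z")])
  m2 <- as.matrix(dplyr::filter(st2, model == 2)[, c("x", "y", "z")])
  expect_lt(hotphore:::kabsch(m2, m1)$rmsd, 1e-3)
})

test_that("unreadable or inconsistent files give informative errors", {
  expect_error(read_complex("no/such/file.pdb"), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", bad)
  expect_error(read_complex(bad), "parse")
})

test_that("chains classify as rna, protein and water by residue content", {
  st <- toy_fixture()$structure
  cls <- dplyr::distinct(tibble::as_tibble(st), chain, chain_class)
  expect_setequal(cls$chain_class[cls$chain == "R"], "rna")
  expect_setequal(cls$chain_class[cls$chain == "A"], "protein")

  wat <- tibble::tibble(
    model = 1L, chain = "W", resno = 1:3, resname = "HOH", insert = "",
    atom = "O", element = "O", x = c(0, 5, 9), y = 0, z = 0, occ = 1
  )
  st2 <- classify_chains(hotphore:::new_mol_structure(
    dplyr::bind_rows(tibble::as_tibble(st), wat), "w"
  ))
  expect_equal(unique(st2$chain_class[st2$chain == "W"]), "water")
})

test_that("classification is order-independent", {
  st <- toy_fixture()$structure
  set.seed(1)
  shuffled <- classify_chains(hotphore:::new_mol_structure(
    tibble::as_tibble(st)[sample(nrow(st)), ], "shuf"
  ))
  orig <- dplyr::distinct(tibble::as_tibble(st), chain, chain_class) |>
    dplyr::arrange(chain)
  new <- dplyr::distinct(tibble::as_tibble(shuffled), chain, chain_class) |>
    dplyr::arrange(chain)
  expect_equal(new$chain, orig$chain)
  expect_equal(new$chain_class, orig$chain_class)
})

test_that("a structure without protein or RNA records a warning attribute", {
  st <- toy_fixture()$structure
  rna_only <- classify_chains(hotphore:::new_mol_structure(
    dplyr::filter(tibble::as_tibble(st), chain == "R"), "rna_only"
  ))
  expect_match(attr(rna_only, "classification_warning"), "lacks")
  expect_error(extract_pharmacophores(rna_only), "lacks")
})

test_that("nucleobase annotation follows the canonical chemistry tables", {
  st <- msi_fixture()$structure
  ann <- annotate_nucleobases(st)
  by_res <- stats::setNames(ann, vapply(ann, function(a) as.character(a$resno), ""))

  g <- by_res[["107"]]
  expect_length(g$rings, 2)
  don <- g$polar$atom[g$polar$donor]
  acc <- g$polar$atom[g$polar$acceptor]
  expect_setequal(don, c("N1", "N2"))
  expect_setequal(acc, c("O6", "N3", "N7"))

  u <- by_res[["104"]]
  expect_length(u$rings, 1)
  expect_setequal(u$polar$atom[u$polar$acceptor], c("O2", "O4"))

  # polar atoms never overlap backbone atoms
  for (a in ann) {
    expect_length(intersect(a$polar$atom, a$backbone_atoms), 0)
  }
})

test_that("abasic residues are skipped with a message", {
  st <- toy_fixture()$structure
  abasic <- dplyr::filter(
    tibble::as_tibble(st),
    !(chain == "R" & resno == 102 & !hotphore:::is_rna_backbone_atom(atom))
  )
  st2 <- classify_chains(hotphore:::new_mol_structure(abasic, "abasic"))
  expect_message(ann <- annotate_nucleobases(st2), "incomplete")
  expect_false(102 %in% vapply(ann, function(a) a$resno, integer(1)))
})

test_that("ring centroids equal the analytic vertex mean for planar rings", {
  u <- hotphore:::ideal_nucleotide("U")
  st <- classify_chains(hotphore:::new_mol_structure(
    hotphore:::atom_rows(u, "R", 1, "U"), "hex"
  ))
  ann <- annotate_nucleobases(st)
  ring_xyz <- as.matrix(u[match(ann[[1]]$rings[[1]], u$atom), c("x", "y", "z")])
  expect_lt(max(abs(ann[[1]]$centroids[[1]] - colMeans(ring_xyz))), 1e-9)
  expect_equal(sum(ann[[1]]$normals[[1]]^2), 1, tolerance = 1e-9)
})

test_that("highest-occupancy alternate location wins, ties by identifier", {
  lines <- c(
    "ATOM      1  N   ALA A   1      0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N   ALA A   1      1.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1      2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA  ALA A   1      3.000   0.000   0.000  0.50  0.00           C",
    "END"
  )
  # altloc column 17
  substr(lines[1], 17, 17) <- "A"
  substr(lines[2], 17, 17) <- "B"
  substr(lines[3], 17, 17) <- "B"
  substr(lines[4], 17, 17) <- "A"
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  st <- read_complex(path)
  expect_equal(nrow(st), 2)
  expect_equal(st$x[st$atom == "N"], 1.0) # higher occupancy
  expect_equal(st$x[st$atom == "CA"], 3.0) # tie -> altloc A
})
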