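# Library building, selectivity profiling, distances, MDS embedding.

test_that("library build deduplicates by provenance and logs outcomes", {
  fx <- toy_fixture()
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "one.pdb")
  p2 <- file.path(dir, "two.pdb")
  write_pdb_file(fx$structure, p1)
  file.copy(p1, p2) # same content, different file stem -> distinct provenance
  fx2 <- make_toy_complex(fixture_spec(
    n_buried = 1, n_exposed = 0, n_hbonds = 1, stacking_rings = 0,
    bases = "G", seed = 23
  ))
  p3 <- file.path(dir, "three.pdb")
  write_pdb_file(fx2$structure, p3)

  lib <- suppressMessages(
    build_library(c(p1, p2, p1, p3), dedup = FALSE)
  )
  # p1 read twice gives identical provenance -> one survives; p2 is a copy
  # under a different source id -> separate entry
  expect_equal(length(lib), 3L)
  expect_true(any(lib$log$status == "dedup_provenance"))
})

test_that("identical-geometry entries collapse under the similarity dedup", {
  phore <- toy_phore()
  shifted <- phore
  shifted$features <- dplyr::mutate(shifted$features, x = x + 50)
  shifted$provenance$source_id <- "translated_copy"
  lib <- build_library(list(phore, shifted), params = fast_align_params())
  expect_equal(length(lib), 1L)
  expect_true(any(lib$log$status == "dedup_similarity"))
})

test_that("a failing input is logged, and all-failing inputs error", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.pdb")
  writeLines("garbage", bad)
  fx <- toy_fixture()
  good <- file.path(dir, "good.pdb")
  write_pdb_file(fx$structure, good)
  lib <- suppressMessages(build_library(c(bad, good), dedup = FALSE))
  expect_equal(length(lib), 1L)
  expect_true(any(lib$log$status == "error"))
  expect_error(build_library(bad), "failed")
})

test_that("library round-trips through a directory with manifest", {
  lib <- build_library(list(toy_phore(), msi_phore()), dedup = FALSE)
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  back <- read_library(dir)
  expect_setequal(names(back$entries), names(lib$entries))
  expect_error(read_library(withr::local_tempdir()), "manifest")
})

test_that("a probe's profile peaks at its source pharmacophore", {
  lib <- build_library(list(toy_phore(), msi_phore()), dedup = FALSE)
  probe <- make_probe_ligand(toy_phore())
  prof <- profile_compound(probe, lib, params = fast_align_params())
  src_id <- grep("toy", prof$scores$entry, value = TRUE)
  expect_equal(prof$scores$entry[1], src_id)
  expect_equal(sum(prof$histogram$count), length(lib))
  expect_true(all(prof$scores$S_combo >= 0 & prof$scores$S_combo <= 1))
  expect_s3_class(autoplot(prof), "ggplot")
})

test_that("duplicate library entries (dedup off) score equally", {
  phore <- toy_phore()
  dup <- phore
  dup$provenance$source_id <- "dup_copy"
  lib <- build_library(list(phore, dup), dedup = FALSE)
  prof <- profile_compound(decoy_blob(4), lib, params = fast_align_params())
  expect_equal(prof$scores$S_combo[1], prof$scores$S_combo[2], tolerance = 1e-6)
  expect_true(all(prof$scores$T_color == 0)) # featureless query: shape only
})

test_that("pharmacophore distances: zero self, symmetric, translation-blind", {
  phore <- toy_phore()
  shifted <- phore
  shifted$features <- dplyr::mutate(shifted$features, y = y + 30)
  shifted$provenance$source_id <- "shifted"
  other <- msi_phore()
  lib <- build_library(list(phore, shifted, other), dedup = FALSE)
  D <- pairwise_distance_matrix(lib, params = fast_align_params())
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  ids <- rownames(D)
  i <- grep("toy", ids)[1]
  j <- grep("shifted", ids)
  expect_lt(D[i, j], 0.02) # translation removed by alignment
})

test_that("exact planar distances embed with vanishing stress", {
  set.seed(6)
  pts <- matrix(stats::runif(20), ncol = 2)
  D <- as.matrix(stats::dist(pts))
  m <- mds_embed(D)
  expect_lt(m$stress, 1e-6)
  E <- as.matrix(stats::dist(as.matrix(m$coords[, c("x", "y")])))
  expect_lt(max(abs(E - D)), 1e-4)
})

test_that("three equidistant points embed as an equilateral triangle", {
  D <- matrix(1, 3, 3) - diag(3)
  m <- mds_embed(D)
  E <- stats::dist(as.matrix(m$coords[, c("x", "y")]))
  expect_lt(max(E) - min(E), 1e-6)
})

test_that("majorization never increases stress and beats the classical start", {
  set.seed(9)
  n <- 20
  M <- matrix(stats::runif(n * n), n, n)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  m <- mds_embed(D)
  expect_true(all(diff(m$trace) <= 1e-9))
  expect_lte(m$stress, m$trace[1]) # trace[1] is the classical-MDS stress
  expect_error(mds_embed(D[1:2, 1:2]), "at least 3")
  expect_s3_class(autoplot(m), "ggplot")
  expect_equal(glance(m)$n, n)
})
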