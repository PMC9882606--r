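# Shared fixtures, built once per test run.

.fx_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fx_cache[[key]])) assign(key, force(expr), envir = .fx_cache)
  .fx_cache[[key]]
}

toy_fixture <- function() {
  cached("toy", make_toy_complex(
    fixture_spec(n_buried = 1, n_exposed = 2, n_hbonds = 2,
                 stacking_rings = 1, seed = 7)
  ))
}

toy_phore <- function() {
  cached("toy_phore", extract_pharmacophores(toy_fixture()$structure)[[1]])
}

msi_fixture <- function() cached("msi", make_msi1_like_complex())

msi_phore <- function() {
  cached("msi_phore", extract_pharmacophores(msi_fixture()$structure)[[1]])
}

# parameters for alignment-heavy checks where the optimum is easy to find
fast_align_params <- function() hp_params(n_random_starts = 2)

# rigidly transform a conformer set (atoms + features)
transform_conformer_set <- function(cs, R, t) {
  out <- cs
  out$atoms[, c("x", "y", "z")] <-
    hotphore:::apply_rigid(as.matrix(cs$atoms[, c("x", "y", "z")]), R, t)
  if (!is.null(cs$features) && nrow(cs$features)) {
    out$features[, c("x", "y", "z")] <-
      hotphore:::apply_rigid(as.matrix(cs$features[, c("x", "y", "z")]), R, t)
    nrm <- as.matrix(cs$features[, c("nx", "ny", "nz")])
    ok <- stats::complete.cases(nrm)
    nrm[ok, ] <- nrm[ok, , drop = FALSE] %*% t(R)
    out$features[, c("nx", "ny", "nz")] <- nrm
  }
  out
}

# a rigid featureless decoy blob (distinct geometry from any base)
decoy_blob <- function(seed, n = 9) {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, sd = 2.5), ncol = 3)
  hotphore:::new_conformer_set(
    name = paste0("decoy", seed), smiles = NA_character_,
    atoms = tibble::tibble(
      conf = 1L, atom_id = seq_len(n), element = "C",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    ),
    features = tibble::tibble(
      conf = integer(), kind = character(), x = double(), y = double(),
      z = double(), nx = double(), ny = double(), nz = double(),
      donor = logical(), acceptor = logical()
    )
  )
}
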