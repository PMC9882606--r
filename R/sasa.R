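# Solvent-accessible surface area by Shrake-Rupley point sampling.

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples points on the solvent-expanded sphere of each heavy atom along a
#' deterministic golden-section spiral and counts the fraction not occluded by
#' any neighbouring atom's expanded sphere. Hydrogens are ignored. Van der
#' Waals radii come from a fixed Bondi table (C 1.70, N 1.55, O 1.52, P/S
#' 1.80 Angstrom; unknown elements fall back to carbon).
#'
#' @param atoms a data frame with columns `x`, `y`, `z`, `element` (a
#'   `mol_structure` model works directly). Hydrogen rows are dropped.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 1920).
#' @param subset optional logical or integer index (into the heavy-atom rows)
#'   restricting which atoms get an area; occluders still count. Used when
#'   only one residue's accessibility is needed.
#' @return a tibble: the heavy-atom rows evaluated, plus an `area` column
#'   (A^2), with attributes `probe` and `n_points` recording the parameters.
#' @export
compute_sasa <- function(atoms, probe = 1.4, n_points = 1920, subset = NULL) {
  stopifnot(probe > 0, n_points >= 12)
  atoms <- tibble::as_tibble(atoms)
  atoms <- dplyr::filter(atoms, .data$element != "H")
  n <- nrow(atoms)
  if (n == 0) stop("compute_sasa: no heavy atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- vdw_radius(atoms$element) + probe
  pts <- sphere_points(n_points)

  eval_idx <- if (is.null(subset)) seq_len(n) else seq_len(n)[subset]
  area <- rep(NA_real_, n)
  for (i in eval_idx) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad[i] + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      # strict inequality: a point exactly on a twin atom's surface stays
      # accessible for one of the two copies
      acc <- acc & dj2 >= rad[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  out <- dplyr::mutate(atoms, area = area)
  if (!is.null(subset)) out <- out[eval_idx, , drop = FALSE]
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  out
}

#' Burial fraction of a nucleobase
#'
#' Compares the solvent-accessible area of the base (non-backbone heavy)
#' atoms in the full complex against the same atoms with every non-RNA atom
#' removed: `b = 1 - A_base(complex) / A_base(RNA alone)`, clamped to
#' `[0, 1]`. If the base is inaccessible even in the free RNA the fraction is
#' defined as 0 with a warning.
#'
#' @param structure a classified `mol_structure`.
#' @param base one annotation from [annotate_nucleobases()].
#' @param model_index model to evaluate.
#' @param probe,n_points passed to [compute_sasa()].
#' @return a list with `b`, `area_complex`, `area_free` (A^2).
#' @export
base_burial <- function(structure, base, model_index = 1L, probe = 1.4,
                        n_points = 1920) {
  atoms <- model_atoms(structure, model_index)
  complex_sasa <- compute_sasa(atoms, probe = probe, n_points = n_points)
  a_complex <- complex_sasa |>
    dplyr::filter(
      .data$chain == base$chain, .data$resno == base$resno,
      .data$insert == base$insert, .data$atom %in% base$base_atoms
    ) |>
    dplyr::pull("area") |>
    sum()

  rna_only <- dplyr::filter(atoms, .data$chain_class == "rna")
  free_sasa <- compute_sasa(rna_only, probe = probe, n_points = n_points)
  a_free <- free_sasa |>
    dplyr::filter(
      .data$chain == base$chain, .data$resno == base$resno,
      .data$insert == base$insert, .data$atom %in% base$base_atoms
    ) |>
    dplyr::pull("area") |>
    sum()

  if (a_free <= 0) {
    warning("base ", base$chain, base$resno,
      " has zero accessible area in the free RNA; burial set to 0",
      call. = FALSE
    )
    b <- 0
  } else {
    b <- min(1, max(0, 1 - a_complex / a_free))
  }
  list(b = b, area_complex = a_complex, area_free = a_free)
}
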