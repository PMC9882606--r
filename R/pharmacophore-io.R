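# Pharmacophore serialization: versioned JSON, and a pseudo-molecule SDF for
# visualization (ring member carbons as C, donors as N, acceptors as O).

#' Write a pharmacophore to JSON
#'
#' Versioned schema: `format_version`, `provenance` (source id, model,
#' chains, residues, extraction parameters), `features` (kind, position,
#' radius, optional normal, role flags, parent atom).
#'
#' @param phore a `pharmacophore`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pharmacophore <- function(phore, path) {
  obj <- list(
    format_version = 1L,
    provenance = phore$provenance,
    parameters = unclass(phore$params),
    features = phore$features
  )
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA, na = "null",
    pretty = TRUE
  )
  invisible(path)
}

#' Read a pharmacophore from JSON
#'
#' @param path path written by [write_pharmacophore()].
#' @return a `pharmacophore`.
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported pharmacophore format in ", path, call. = FALSE)
  }
  params <- obj$parameters
  class(params) <- "hp_params"
  feats <- tibble::as_tibble(obj$features)
  feats$insert <- as.character(feats$insert %||% rep("", nrow(feats)))
  feats$insert[is.na(feats$insert)] <- ""
  new_pharmacophore(
    features = feats,
    provenance = obj$provenance,
    params = params
  )
}

#' Pseudo-molecule of a pharmacophore
#'
#' Encodes the pharmacophore as a rigid molecule-like object: carbon features
#' (ring member atoms and reverted polar atoms) become C atoms, donors N,
#' acceptors O, with the typed color features copied over. Aligning this
#' probe back onto its source pharmacophore scores a combo Tanimoto of ~1;
#' it is the construction behind probe ligands and pharmacophore-vs-
#' pharmacophore distances.
#'
#' @param phore a `pharmacophore`.
#' @param name molecule name (default from provenance).
#' @return a `conformer_set` with a single conformer.
#' @export
phore_pseudo_molecule <- function(phore, name = NULL) {
  f <- phore$features
  atomish <- dplyr::filter(f, .data$kind != "ring")
  element <- dplyr::case_when(
    atomish$donor ~ "N",
    atomish$acceptor ~ "O",
    TRUE ~ "C"
  )
  atoms <- tibble::tibble(
    conf = 1L, atom_id = seq_len(nrow(atomish)), element = element,
    x = atomish$x, y = atomish$y, z = atomish$z
  )
  color <- dplyr::filter(f, .data$kind %in% c("ring", "donor", "acceptor")) |>
    dplyr::transmute(
      conf = 1L, kind = .data$kind, x = .data$x, y = .data$y, z = .data$z,
      nx = .data$nx, ny = .data$ny, nz = .data$nz,
      donor = .data$donor, acceptor = .data$acceptor
    )
  new_conformer_set(
    name = name %||% paste0(
      phore$provenance$source_id, "_m",
      phore$provenance$model_index, "_c", phore$provenance$cluster %||% 1L
    ),
    smiles = NA_character_,
    atoms = atoms,
    features = color
  )
}

#' Write a pharmacophore pseudo-molecule as SDF
#'
#' A bond-less V2000 record for visualization in standard viewers.
#'
#' @param phore a `pharmacophore`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pharmacophore_sdf <- function(phore, path) {
  mol <- phore_pseudo_molecule(phore)
  write_conformers_sdf(mol, path)
}
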