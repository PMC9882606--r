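# Reading, writing and classifying protein-RNA complex structures.
#
# A structure is a tidy atom table (one row per atom per model) of class
# "mol_structure": columns model, chain, chain_class, resno, resname, insert,
# atom, element, x, y, z, occ. Attributes: source_id, n_models.

new_mol_structure <- function(atoms, source_id) {
  atoms <- tibble::as_tibble(atoms)
  structure(atoms,
    class = c("mol_structure", class(atoms)),
    source_id = source_id,
    n_models = length(unique(atoms$model))
  )
}

#' Load a protein-RNA complex structure
#'
#' Parses a PDB or mmCIF file into a tidy atom table. All models of an NMR
#' ensemble are retained (one set of rows per model), ordered waters are kept,
#' alternate locations are resolved to the highest-occupancy copy (ties broken
#' by altloc identifier), and hydrogens are kept when present. Coordinates are
#' in Angstrom in the file frame; no re-orientation is applied.
#'
#' @param path path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @return a `mol_structure` tibble with chains classified (see
#'   [classify_chains()]).
#' @export
read_complex <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("structure file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
    } else {
      bio3d::read.cif(path, verbose = FALSE)
    },
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
        conditionMessage(e),
        call. = FALSE
      )
    }
  )
  at <- pdb$atom
  n_atom <- nrow(at)
  if (is.null(n_atom) || n_atom == 0) {
    stop("no atom records parsed from '", path, "'", call. = FALSE)
  }
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * n_atom) {
    stop("inconsistent ensemble in '", path, "': ", ncol(xyz) / 3,
      " coordinates per model for ", n_atom, " atoms",
      call. = FALSE
    )
  }
  n_models <- nrow(xyz)

  element <- trimws(at$elesy)
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    # fall back on the leading letter(s) of the atom name
    guess <- sub("^[0-9']*", "", trimws(at$elety[missing_el]))
    element[missing_el] <- substr(guess, 1, 1)
  }

  alt <- trimws(at$alt)
  alt[is.na(alt)] <- ""
  occ <- at$o
  occ[is.na(occ)] <- 1

  base <- tibble::tibble(
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = at$resno,
    resname = trimws(at$resid),
    insert = ifelse(is.na(at$insert), "", trimws(at$insert)),
    atom = normalize_atom_name(at$elety),
    element = toupper(element),
    occ = occ,
    alt = alt
  )

  rows <- lapply(seq_len(n_models), function(m) {
    co <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    dplyr::mutate(base,
      model = m, x = co[, 1], y = co[, 2], z = co[, 3],
      .before = 1
    )
  })
  atoms <- dplyr::bind_rows(rows)

  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in '", path, "'", call. = FALSE)
  }

  # resolve altlocs (keep highest occupancy, tie -> first altloc id) while
  # preserving the file's atom order
  atoms <- atoms |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$model, .data$chain, .data$resno, .data$insert, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-"alt", -".ord")

  src <- sub("\\.(pdb|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  classify_chains(new_mol_structure(atoms, source_id = src))
}

#' Classify chains as protein, RNA, water, or other
#'
#' A chain is `rna` if at least half of its residues are standard (or common
#' modified) ribonucleotides, `protein` if at least half are standard amino
#' acids, `water` if its residues are HOH/WAT, and `other` otherwise.
#' Classification is deterministic and independent of atom order. If the
#' structure lacks a protein or an RNA chain a warning is recorded in the
#' `classification_warning` attribute (pharmacophore extraction refuses to run
#' on such structures).
#'
#' @param structure a `mol_structure`.
#' @return the structure with a `chain_class` column.
#' @export
classify_chains <- function(structure) {
  res <- structure |>
    dplyr::filter(.data$model == min(.data$model)) |>
    dplyr::distinct(.data$chain, .data$resno, .data$insert, .data$resname)
  cls <- res |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(
      frac_rna = mean(is_rna_resname(.data$resname)),
      frac_prot = mean(is_protein_resname(.data$resname)),
      frac_wat = mean(is_water_resname(.data$resname))
    ) |>
    dplyr::mutate(chain_class = dplyr::case_when(
      .data$frac_wat >= 0.5 ~ "water",
      .data$frac_rna >= 0.5 ~ "rna",
      .data$frac_prot >= 0.5 ~ "protein",
      TRUE ~ "other"
    )) |>
    dplyr::select("chain", "chain_class")

  atoms <- dplyr::select(tibble::as_tibble(structure), -dplyr::any_of("chain_class"))
  atoms <- dplyr::left_join(atoms, cls, by = "chain") |>
    dplyr::relocate("chain_class", .after = "chain")
  out <- new_mol_structure(atoms, source_id = attr(structure, "source_id"))
  if (!any(cls$chain_class == "rna") || !any(cls$chain_class == "protein")) {
    attr(out, "classification_warning") <-
      "structure lacks a protein chain and/or an RNA chain"
  }
  out
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(
    "<mol_structure> ", attr(x, "source_id"), ": ",
    attr(x, "n_models"), " model(s), ",
    length(unique(x$chain)), " chain(s), ",
    nrow(x) / attr(x, "n_models"), " atoms/model\n",
    sep = ""
  )
  NextMethod()
}

model_atoms <- function(structure, model_index = 1L) {
  if (!model_index %in% structure$model) {
    stop("model ", model_index, " not present (", attr(structure, "n_models"),
      " model(s))",
      call. = FALSE
    )
  }
  dplyr::filter(tibble::as_tibble(structure), .data$model == model_index)
}

#' Annotate nucleobase chemistry of RNA residues
#'
#' For every nucleotide in the RNA chains of one model, identifies the
#' aromatic ring atom sets (one ring for pyrimidines, two for purines),
#' their centroids and unit normals, the polar base atoms with donor/acceptor
#' capability from a fixed per-base lookup (A, G, C, U; common modified bases
#' map to their parent), and the backbone atom names. Residues with incomplete
#' base rings (e.g. abasic sites) are skipped with a message.
#'
#' @param structure a classified `mol_structure`.
#' @param model_index model to annotate (default 1).
#' @return a list of nucleobase annotations, each a list with elements
#'   `chain`, `resno`, `insert`, `resname`, `parent`, `rings` (list of atom
#'   name vectors), `centroids`, `normals`, `polar` (tibble of atom/donor/
#'   acceptor), `backbone_atoms`, `base_atoms`.
#' @export
annotate_nucleobases <- function(structure, model_index = 1L) {
  atoms <- model_atoms(structure, model_index)
  rna <- dplyr::filter(atoms, .data$chain_class == "rna")
  if (nrow(rna) == 0) {
    stop("structure has no RNA chain to annotate", call. = FALSE)
  }
  keys <- dplyr::distinct(rna, .data$chain, .data$resno, .data$insert, .data$resname)
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    res_atoms <- dplyr::filter(
      rna, .data$chain == k$chain, .data$resno == k$resno,
      .data$insert == k$insert
    )
    parent <- rna_parent_base(k$resname)
    if (is.na(parent)) {
      # non-standard residue: try to match purine, then pyrimidine ring names
      parent <- if (all(.base_rings$A$ring5 %in% res_atoms$atom)) "A" else "U"
    }
    rings <- .base_rings[[parent]]
    have <- vapply(rings, function(r) all(r %in% res_atoms$atom), logical(1))
    if (!all(have)) {
      message(
        "skipping ", k$resname, " ", k$chain, k$resno,
        ": incomplete base ring (abasic or disordered)"
      )
      next
    }
    centroids <- list(); normals <- list()
    for (rn in names(rings)) {
      xyz <- as.matrix(res_atoms[match(rings[[rn]], res_atoms$atom), c("x", "y", "z")])
      pf <- plane_fit(xyz)
      centroids[[rn]] <- pf$centroid
      normals[[rn]] <- pf$normal
    }
    polar_tab <- .base_polar[[parent]]
    if (is.na(rna_parent_base(k$resname))) {
      # element-based fallback for unmapped residues: base N/O treated as
      # donor+acceptor candidates
      cand <- res_atoms |>
        dplyr::filter(
          !is_rna_backbone_atom(.data$atom),
          .data$element %in% c("N", "O")
        )
      polar_tab <- data.frame(atom = cand$atom, donor = TRUE, acceptor = TRUE)
    }
    polar <- tibble::as_tibble(polar_tab) |>
      dplyr::filter(.data$atom %in% res_atoms$atom)
    pos <- res_atoms[match(polar$atom, res_atoms$atom), c("x", "y", "z")]
    polar <- dplyr::bind_cols(polar, pos)
    bb <- intersect(res_atoms$atom, .rna_backbone)
    base_atoms <- setdiff(
      res_atoms$atom[res_atoms$element != "H"],
      c(bb, grep("^H", res_atoms$atom, value = TRUE))
    )
    out[[length(out) + 1L]] <- list(
      chain = k$chain, resno = k$resno, insert = k$insert,
      resname = k$resname, parent = parent,
      rings = rings, centroids = centroids, normals = normals,
      polar = polar, backbone_atoms = bb, base_atoms = base_atoms
    )
  }
  out
}

#' Write a structure to a PDB file
#'
#' Minimal fixed-width PDB writer (ATOM/HETATM, MODEL/ENDMDL, element column).
#' Used by the synthetic-complex generator; output parses with any standard
#' PDB reader.
#'
#' @param structure a `mol_structure`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_file <- function(structure, path) {
  atoms <- tibble::as_tibble(structure)
  models <- sort(unique(atoms$model))
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (m in models) {
    a <- dplyr::filter(atoms, .data$model == m)
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    rec <- ifelse(is_water_resname(a$resname), "HETATM", "ATOM  ")
    name4 <- vapply(a$atom, function(nm) {
      if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    }, character(1))
    lines <- sprintf(
      "%s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, seq_len(nrow(a)), name4, "", substr(a$resname, 1, 3),
      substr(a$chain, 1, 1), a$resno, substr(paste0(a$insert, " "), 1, 1),
      a$x, a$y, a$z, a$occ, 0, substr(a$element, 1, 2)
    )
    writeLines(lines, con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure to a minimal mmCIF file
#'
#' Emits a single `atom_site` loop covering all models (`pdbx_PDB_model_num`).
#'
#' @inheritParams write_pdb_file
#' @return `path`, invisibly.
#' @export
write_cif_file <- function(structure, path) {
  atoms <- tibble::as_tibble(structure)
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9_]", "_", attr(structure, "source_id") %||% "struct")),
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  rec <- ifelse(is_water_resname(atoms$resname), "HETATM", "ATOM")
  ins <- ifelse(atoms$insert == "", "?", atoms$insert)
  body <- sprintf(
    "%s %d %s \"%s\" . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s \"%s\" %d",
    rec, seq_len(nrow(atoms)), atoms$element, atoms$atom, atoms$resname,
    atoms$chain, atoms$resno, ins, atoms$x, atoms$y, atoms$z, atoms$occ, 0,
    atoms$resno, atoms$resname, atoms$chain, atoms$atom, atoms$model
  )
  writeLines(c(hdr, body, "#"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
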