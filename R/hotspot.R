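# Hotspot pharmacophore extraction: burial selection, hydrogen-bond
# collection, polar reversion, spatial clustering.

#' Detect intermolecular hydrogen bonds between RNA and protein
#'
#' Geometric criterion on heavy atoms: a donor-capable atom on one side
#' within `hbond_dist` (default 3.5 A) of an acceptor-capable atom on the
#' other. When the donor hydrogen is present in the structure (NMR models)
#' the D-H...A angle must also reach `hbond_angle` (default 120 deg); without
#' explicit hydrogens the distance criterion alone applies. With
#' `include_waters`, an ordered water oxygen within `hbond_dist` of both an
#' RNA polar atom and a protein polar atom records a water-mediated bond.
#'
#' @param structure a classified `mol_structure`.
#' @param model_index model to analyse.
#' @param params an [hp_params()] list.
#' @return a tibble, one row per bond: RNA atom identity, partner identity,
#'   `distance`, `angle` (NA without explicit H), `kind`
#'   (`direct`/`water_mediated`), and the RNA atom's role flags
#'   `rna_donor`/`rna_acceptor` in that bond.
#' @export
detect_hbonds <- function(structure, model_index = 1L, params = hp_params()) {
  atoms <- model_atoms(structure, model_index)
  rna_pol <- rna_polar_atoms(atoms)
  prot_pol <- protein_polar_atoms(atoms)
  empty <- tibble::tibble(
    rna_chain = character(), rna_resno = integer(), rna_insert = character(),
    rna_resname = character(), rna_atom = character(),
    partner_chain = character(), partner_resno = integer(),
    partner_resname = character(), partner_atom = character(),
    distance = double(), angle = double(), kind = character(),
    rna_donor = logical(), rna_acceptor = logical()
  )
  if (nrow(rna_pol) == 0 || nrow(prot_pol) == 0) {
    return(empty)
  }
  hydro <- dplyr::filter(atoms, .data$element == "H")

  pairs <- tidyr::crossing(
    r = seq_len(nrow(rna_pol)),
    p = seq_len(nrow(prot_pol))
  )
  rx <- as.matrix(rna_pol[pairs$r, c("x", "y", "z")])
  px <- as.matrix(prot_pol[pairs$p, c("x", "y", "z")])
  d <- sqrt(rowSums((rx - px)^2))
  keep <- d <= params$hbond_dist & d > 0.1
  bonds <- empty

  for (idx in which(keep)) {
    r <- rna_pol[pairs$r[idx], ]
    p <- prot_pol[pairs$p[idx], ]
    as_donor <- r$donor && p$acceptor &&
      donor_angle_ok(r, p, hydro, params$hbond_angle)
    as_acceptor <- r$acceptor && p$donor &&
      donor_angle_ok(p, r, hydro, params$hbond_angle)
    if (!as_donor && !as_acceptor) next
    ang <- donor_angle(if (as_donor) r else p, if (as_donor) p else r, hydro)
    bonds <- dplyr::bind_rows(bonds, tibble::tibble(
      rna_chain = r$chain, rna_resno = r$resno, rna_insert = r$insert,
      rna_resname = r$resname, rna_atom = r$atom,
      partner_chain = p$chain, partner_resno = p$resno,
      partner_resname = p$resname, partner_atom = p$atom,
      distance = d[idx], angle = ang, kind = "direct",
      rna_donor = as_donor, rna_acceptor = as_acceptor
    ))
  }

  if (isTRUE(params$include_waters)) {
    wat <- dplyr::filter(
      atoms, .data$chain_class == "water" | is_water_resname(.data$resname),
      .data$element == "O"
    )
    for (w in seq_len(nrow(wat))) {
      wxyz <- as.numeric(wat[w, c("x", "y", "z")])
      dr <- sqrt((rna_pol$x - wxyz[1])^2 + (rna_pol$y - wxyz[2])^2 +
        (rna_pol$z - wxyz[3])^2)
      dp <- sqrt((prot_pol$x - wxyz[1])^2 + (prot_pol$y - wxyz[2])^2 +
        (prot_pol$z - wxyz[3])^2)
      near_r <- which(dr <= params$hbond_dist)
      if (length(near_r) == 0 || !any(dp <= params$hbond_dist)) next
      for (ri in near_r) {
        r <- rna_pol[ri, ]
        bonds <- dplyr::bind_rows(bonds, tibble::tibble(
          rna_chain = r$chain, rna_resno = r$resno, rna_insert = r$insert,
          rna_resname = r$resname, rna_atom = r$atom,
          partner_chain = wat$chain[w], partner_resno = wat$resno[w],
          partner_resname = wat$resname[w], partner_atom = wat$atom[w],
          distance = dr[ri], angle = NA_real_, kind = "water_mediated",
          rna_donor = r$donor, rna_acceptor = r$acceptor
        ))
      }
    }
  }
  bonds
}

# polar atom tables -----------------------------------------------------

rna_polar_atoms <- function(atoms) {
  rna <- dplyr::filter(
    atoms, .data$chain_class == "rna",
    .data$element %in% c("N", "O")
  )
  if (nrow(rna) == 0) {
    return(dplyr::mutate(rna, donor = logical(0), acceptor = logical(0)))
  }
  parent <- rna_parent_base(rna$resname)
  donor <- acceptor <- rep(FALSE, nrow(rna))
  for (i in seq_len(nrow(rna))) {
    nm <- rna$atom[i]
    if (is_rna_backbone_atom(nm)) {
      j <- match(nm, .backbone_polar$atom)
      if (!is.na(j)) {
        donor[i] <- .backbone_polar$donor[j]
        acceptor[i] <- .backbone_polar$acceptor[j]
      }
    } else if (!is.na(parent[i])) {
      tab <- .base_polar[[parent[i]]]
      j <- match(nm, tab$atom)
      if (!is.na(j)) {
        donor[i] <- tab$donor[j]
        acceptor[i] <- tab$acceptor[j]
      }
    } else {
      donor[i] <- acceptor[i] <- TRUE # element-based fallback
    }
  }
  dplyr::mutate(rna, donor = donor, acceptor = acceptor) |>
    dplyr::filter(.data$donor | .data$acceptor)
}

protein_polar_atoms <- function(atoms) {
  prot <- dplyr::filter(
    atoms, .data$chain_class == "protein",
    .data$element %in% c("N", "O")
  )
  if (nrow(prot) == 0) {
    return(dplyr::mutate(prot, donor = logical(0), acceptor = logical(0)))
  }
  donor <- acceptor <- rep(FALSE, nrow(prot))
  bb <- .protein_polar$backbone
  for (i in seq_len(nrow(prot))) {
    nm <- prot$atom[i]
    j <- match(nm, bb$atom)
    if (!is.na(j)) {
      donor[i] <- bb$donor[j]
      acceptor[i] <- bb$acceptor[j]
      next
    }
    tab <- .protein_polar$sidechain[[prot$resname[i]]]
    if (!is.null(tab)) {
      j <- match(nm, tab$atom)
      if (!is.na(j)) {
        donor[i] <- tab$donor[j]
        acceptor[i] <- tab$acceptor[j]
      }
    }
  }
  dplyr::mutate(prot, donor = donor, acceptor = acceptor) |>
    dplyr::filter(.data$donor | .data$acceptor)
}

# explicit-H angle test: TRUE when no hydrogen is attached to the donor
donor_angle_ok <- function(don, acc, hydro, min_angle) {
  a <- donor_angle(don, acc, hydro)
  is.na(a) || a >= min_angle
}

donor_angle <- function(don, acc, hydro) {
  hs <- dplyr::filter(
    hydro, .data$chain == don$chain, .data$resno == don$resno,
    .data$insert == don$insert
  )
  if (nrow(hs) == 0) {
    return(NA_real_)
  }
  dxyz <- as.numeric(don[c("x", "y", "z")])
  dh <- sqrt((hs$x - dxyz[1])^2 + (hs$y - dxyz[2])^2 + (hs$z - dxyz[3])^2)
  hs <- hs[dh < 1.3, , drop = FALSE] # covalently attached
  if (nrow(hs) == 0) {
    return(NA_real_)
  }
  axyz <- as.numeric(acc[c("x", "y", "z")])
  max(vapply(seq_len(nrow(hs)), function(i) {
    angle_deg(dxyz, as.numeric(hs[i, c("x", "y", "z")]), axyz)
  }, double(1)))
}

#' Build the interaction map of a protein-RNA complex
#'
#' Collects the deeply buried bases (burial fraction `b >=
#' burial_threshold` *and* absolute buried area `>= min_buried_area`) and
#' every RNA atom participating in a qualifying intermolecular hydrogen bond.
#'
#' @inheritParams detect_hbonds
#' @return a list with `bases` (all annotated bases with burial statistics
#'   and a `hotspot` flag), `hbonds` (from [detect_hbonds()]),
#'   `annotations`, and `model_index`.
#' @export
build_interaction_map <- function(structure, model_index = 1L,
                                  params = hp_params()) {
  classes <- unique(structure$chain_class)
  if (!("rna" %in% classes) || !("protein" %in% classes)) {
    stop("interaction map requires both a protein and an RNA chain",
      call. = FALSE
    )
  }
  ann <- annotate_nucleobases(structure, model_index)
  atoms <- model_atoms(structure, model_index)

  # one SASA evaluation per context, shared across bases
  complex_sasa <- compute_sasa(atoms,
    probe = params$sasa_probe,
    n_points = params$sasa_points
  )
  free_sasa <- compute_sasa(
    dplyr::filter(atoms, .data$chain_class == "rna"),
    probe = params$sasa_probe, n_points = params$sasa_points
  )
  base_area <- function(sasa, b) {
    sasa |>
      dplyr::filter(
        .data$chain == b$chain, .data$resno == b$resno,
        .data$insert == b$insert, .data$atom %in% b$base_atoms
      ) |>
      dplyr::pull("area") |>
      sum()
  }
  bases <- purrr::map_dfr(ann, function(b) {
    a_cpx <- base_area(complex_sasa, b)
    a_free <- base_area(free_sasa, b)
    burial <- if (a_free <= 0) 0 else min(1, max(0, 1 - a_cpx / a_free))
    tibble::tibble(
      chain = b$chain, resno = b$resno, insert = b$insert,
      resname = b$resname, parent = b$parent,
      b = burial, area_complex = a_cpx, area_free = a_free,
      buried_area = a_free - a_cpx
    )
  })
  bases$hotspot <- bases$b >= params$burial_threshold &
    bases$buried_area >= params$min_buried_area

  hb <- detect_hbonds(structure, model_index, params)
  # cache residue atom tables and H-bonded atom positions for the revert step
  ann <- lapply(ann, function(b) {
    attr(b, "res_atoms") <- dplyr::filter(
      atoms, .data$chain == b$chain, .data$resno == b$resno,
      .data$insert == b$insert
    )
    b
  })
  xyz_cache <- list()
  for (i in seq_len(nrow(hb))) {
    key <- paste(hb$rna_chain[i], hb$rna_resno[i], hb$rna_insert[i], hb$rna_atom[i])
    if (is.null(xyz_cache[[key]])) {
      row <- dplyr::filter(
        atoms, .data$chain == hb$rna_chain[i],
        .data$resno == hb$rna_resno[i], .data$insert == hb$rna_insert[i],
        .data$atom == hb$rna_atom[i]
      )
      xyz_cache[[key]] <- as.numeric(row[1, c("x", "y", "z")])
    }
  }

  map <- list(
    bases = bases,
    hbonds = hb,
    annotations = ann,
    model_index = model_index
  )
  attr(map, "atom_xyz") <- xyz_cache
  map
}

#' Revert non-bonding polar atoms and assemble pharmacophore features
#'
#' For each hotspot base: the aromatic rings are kept (a ring feature at each
#' centroid plus carbon features at all base heavy atoms); base N/O atoms in
#' qualifying hydrogen bonds become donor/acceptor features carrying the RNA
#' atom's role in the bond (an atom bonded once as donor and once as acceptor
#' yields one dual-role feature); every other base N/O is reverted to a
#' carbon feature. RNA atoms outside hotspot bases (backbone or exposed
#' bases) contribute donor/acceptor features only when hydrogen-bonded.
#'
#' @param map result of [build_interaction_map()].
#' @param params an [hp_params()] list (feature radii).
#' @return a feature tibble: `kind` (ring/donor/acceptor/carbon), position,
#'   `radius`, ring normals, role flags, and parent atom/residue provenance.
#' @export
revert_nonbonding_polar <- function(map, params = hp_params()) {
  hb <- map$hbonds
  hb_key <- paste(hb$rna_chain, hb$rna_resno, hb$rna_insert, hb$rna_atom)
  feats <- list()

  add <- function(kind, xyz, radius, normal = c(NA, NA, NA), donor = FALSE,
                  acceptor = FALSE, chain, resno, insert, resname, atom) {
    xyz <- unname(xyz)
    normal <- unname(normal)
    tibble::tibble(
      kind = kind, x = xyz[1], y = xyz[2], z = xyz[3], radius = radius,
      nx = normal[1], ny = normal[2], nz = normal[3],
      donor = donor, acceptor = acceptor,
      chain = chain, resno = resno, insert = insert, resname = resname,
      atom = atom
    )
  }
  hb_role <- function(key) {
    rows <- hb[hb_key == key, , drop = FALSE]
    list(donor = any(rows$rna_donor), acceptor = any(rows$rna_acceptor))
  }

  hot <- dplyr::filter(map$bases, .data$hotspot)
  for (b in map$annotations) {
    is_hot <- any(hot$chain == b$chain & hot$resno == b$resno &
      hot$insert == b$insert)
    if (!is_hot) next
    for (rn in names(b$rings)) {
      feats[[length(feats) + 1L]] <- add(
        "ring", b$centroids[[rn]], params$color_radius, b$normals[[rn]],
        chain = b$chain, resno = b$resno, insert = b$insert,
        resname = b$resname, atom = rn
      )
    }
    polar_names <- b$polar$atom
    # all base heavy atoms participate in shape; polar ones may be promoted
    for (nm in b$base_atoms) {
      key <- paste(b$chain, b$resno, b$insert, nm)
      xyz <- base_atom_xyz(b, nm)
      if (nm %in% polar_names && key %in% hb_key) {
        role <- hb_role(key)
        feats[[length(feats) + 1L]] <- add(
          if (role$donor && role$acceptor) "donor" else if (role$donor) "donor" else "acceptor",
          xyz, params$shape_radius,
          donor = role$donor, acceptor = role$acceptor,
          chain = b$chain, resno = b$resno, insert = b$insert,
          resname = b$resname, atom = nm
        )
      } else {
        feats[[length(feats) + 1L]] <- add(
          "carbon", xyz, params$shape_radius,
          chain = b$chain, resno = b$resno, insert = b$insert,
          resname = b$resname, atom = nm
        )
      }
    }
  }

  # H-bonded RNA atoms not covered above (backbone, or exposed bases)
  covered <- if (length(feats)) {
    f <- dplyr::bind_rows(feats)
    paste(f$chain, f$resno, f$insert, f$atom)
  } else {
    character()
  }
  extra <- hb |>
    dplyr::distinct(
      .data$rna_chain, .data$rna_resno, .data$rna_insert,
      .data$rna_resname, .data$rna_atom
    )
  for (i in seq_len(nrow(extra))) {
    e <- extra[i, ]
    key <- paste(e$rna_chain, e$rna_resno, e$rna_insert, e$rna_atom)
    if (key %in% covered) next
    rows <- hb[hb_key == key, , drop = FALSE]
    # position from the bond table's source structure is not stored; callers
    # go through extract_pharmacophores() which passes atom coordinates in
    xyz <- attr(map, "atom_xyz")[[key]]
    if (is.null(xyz)) next
    feats[[length(feats) + 1L]] <- add(
      if (any(rows$rna_donor)) "donor" else "acceptor", xyz,
      params$shape_radius,
      donor = any(rows$rna_donor), acceptor = any(rows$rna_acceptor),
      chain = e$rna_chain, resno = e$rna_resno, insert = e$rna_insert,
      resname = e$rna_resname, atom = e$rna_atom
    )
  }

  if (length(feats) == 0) {
    return(empty_features())
  }
  dplyr::bind_rows(feats) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert, .data$kind, .data$atom)
}

base_atom_xyz <- function(ann, atom_name) {
  # annotation stores polar positions; ring/carbon atoms resolved lazily via
  # the cached residue table
  tab <- attr(ann, "res_atoms")
  if (!is.null(tab)) {
    i <- match(atom_name, tab$atom)
    return(as.numeric(tab[i, c("x", "y", "z")]))
  }
  i <- match(atom_name, ann$polar$atom)
  if (!is.na(i)) {
    return(as.numeric(ann$polar[i, c("x", "y", "z")]))
  }
  stop("atom position not cached: ", atom_name)
}

empty_features <- function() {
  tibble::tibble(
    kind = character(), x = double(), y = double(), z = double(),
    radius = double(), nx = double(), ny = double(), nz = double(),
    donor = logical(), acceptor = logical(), chain = character(),
    resno = integer(), insert = character(), resname = character(),
    atom = character()
  )
}

#' Single-linkage clustering of pharmacophore features
#'
#' Clusters are the connected components of the graph joining features whose
#' positions (ring centroids for rings, atom positions otherwise) lie within
#' `cutoff`. Clusters without a ring feature are discarded: backbone
#' hydrogen-bond atoms may join a cluster but cannot seed one. Cluster order
#' is by minimum residue number.
#'
#' @param features a feature tibble from [revert_nonbonding_polar()].
#' @param cutoff linkage cutoff in Angstrom.
#' @return a list of feature tibbles, one per surviving cluster.
#' @export
cluster_features <- function(features, cutoff = 4.5) {
  if (nrow(features) == 0) {
    return(list())
  }
  xyz <- as.matrix(features[, c("x", "y", "z")])
  memb <- if (nrow(features) == 1) {
    1L
  } else {
    stats::cutree(stats::hclust(stats::dist(xyz), method = "single"), h = cutoff)
  }
  clusters <- split(seq_len(nrow(features)), memb)
  clusters <- Filter(function(i) any(features$kind[i] == "ring"), clusters)
  ord <- order(vapply(clusters, function(i) min(features$resno[i]), double(1)))
  lapply(clusters[ord], function(i) features[i, ])
}

#' Extract hotspot pharmacophores from a protein-RNA complex
#'
#' Full pipeline: burial selection, hydrogen-bond collection, polar
#' reversion, and spatial clustering, yielding one minimal pharmacophore per
#' surviving cluster. A complex with no deeply buried base yields an empty
#' list (with a message), not an error.
#'
#' @inheritParams detect_hbonds
#' @return a list of `pharmacophore` objects; each holds `features` (tibble),
#'   `provenance` (source id, model, chains, hotspot residues), and the
#'   parameter snapshot.
#' @export
extract_pharmacophores <- function(structure, model_index = 1L,
                                   params = hp_params()) {
  if (!is.null(attr(structure, "classification_warning"))) {
    stop("cannot extract pharmacophores: ",
      attr(structure, "classification_warning"),
      call. = FALSE
    )
  }
  map <- build_interaction_map(structure, model_index, params)
  if (!any(map$bases$hotspot)) {
    message(
      "no deeply buried base in ", attr(structure, "source_id"),
      " model ", model_index, "; no pharmacophore extracted"
    )
    return(list())
  }
  features <- revert_nonbonding_polar(map, params)
  clusters <- cluster_features(features, cutoff = params$cluster_cutoff)
  hot <- dplyr::filter(map$bases, .data$hotspot)
  lapply(seq_along(clusters), function(i) {
    f <- clusters[[i]]
    res <- sort(unique(f$resno[f$kind == "ring"]))
    new_pharmacophore(
      features = f,
      provenance = list(
        source_id = attr(structure, "source_id"),
        model_index = model_index,
        chains = sort(unique(f$chain)),
        residues = res,
        cluster = i
      ),
      params = params
    )
  })
}

new_pharmacophore <- function(features, provenance, params) {
  structure(
    list(features = features, provenance = provenance, params = params),
    class = "pharmacophore"
  )
}

#' @export
print.pharmacophore <- function(x, ...) {
  p <- x$provenance
  cat(
    "<pharmacophore> ", p$source_id, " model ", p$model_index,
    " residues ", paste(p$residues, collapse = "+"), "\n",
    sep = ""
  )
  print(dplyr::count(x$features, .data$kind))
  invisible(x)
}

#' Annotate aromatic stacking partners of a pharmacophore
#'
#' Returns the protein aromatic sidechains (Phe/Tyr/Trp/His) whose ring
#' centroid lies within `stack_dist` of any pharmacophore ring centroid with
#' an inter-plane angle at most `stack_angle` degrees (coplanar either way
#' up), deduplicated per residue.
#'
#' @param structure the source `mol_structure`.
#' @param phore a `pharmacophore` extracted from it.
#' @param model_index model to analyse.
#' @param params an [hp_params()] list.
#' @return a tibble with `chain`, `resno`, `resname`, `min_dist`.
#' @export
annotate_stacking_partners <- function(structure, phore, model_index = 1L,
                                       params = hp_params()) {
  atoms <- model_atoms(structure, model_index)
  rings <- dplyr::filter(phore$features, .data$kind == "ring")
  if (nrow(rings) == 0) {
    return(tibble::tibble(
      chain = character(), resno = integer(),
      resname = character(), min_dist = double()
    ))
  }
  prot <- dplyr::filter(
    atoms, .data$chain_class == "protein",
    .data$resname %in% names(.protein_aromatic_rings)
  )
  keys <- dplyr::distinct(prot, .data$chain, .data$resno, .data$insert, .data$resname)
  hits <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    res_atoms <- dplyr::filter(
      prot, .data$chain == k$chain, .data$resno == k$resno,
      .data$insert == k$insert
    )
    for (ring_names in .protein_aromatic_rings[[k$resname]]) {
      if (!all(ring_names %in% res_atoms$atom)) next
      xyz <- as.matrix(res_atoms[match(ring_names, res_atoms$atom), c("x", "y", "z")])
      pf <- plane_fit(xyz)
      for (j in seq_len(nrow(rings))) {
        d <- sqrt(sum((pf$centroid - as.numeric(rings[j, c("x", "y", "z")]))^2))
        ang <- plane_angle_deg(pf$normal, as.numeric(rings[j, c("nx", "ny", "nz")]))
        if (d <= params$stack_dist && ang <= params$stack_angle) {
          hits[[length(hits) + 1L]] <- tibble::tibble(
            chain = k$chain, resno = k$resno, resname = k$resname, min_dist = d
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(
      chain = character(), resno = integer(),
      resname = character(), min_dist = double()
    ))
  }
  dplyr::bind_rows(hits) |>
    dplyr::group_by(.data$chain, .data$resno, .data$resname) |>
    dplyr::summarise(min_dist = min(.data$min_dist), .groups = "drop") |>
    dplyr::arrange(.data$chain, .data$resno)
}
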