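# Small-molecule handling: parsing, 3-D conformer generation (seeded
# distance-geometry embedding + force-field minimization via an RDKit helper
# script), and ligand pharmacophoric feature perception.

new_conformer_set <- function(name, smiles, atoms, features = NULL,
                              bonds = NULL, strain = NULL) {
  structure(
    list(
      name = name, smiles = smiles, atoms = tibble::as_tibble(atoms),
      features = features, bonds = bonds, strain = strain,
      n_conf = length(unique(atoms$conf))
    ),
    class = "conformer_set"
  )
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(
    "<conformer_set> ", x$name, ": ", x$n_conf, " conformer(s), ",
    sum(x$atoms$conf == x$atoms$conf[1] & x$atoms$element != "H"),
    " heavy atoms\n",
    sep = ""
  )
  invisible(x)
}

python_helper <- function() {
  path <- system.file("python", "embed_conformers.py", package = "hotphore")
  if (path == "") stop("embed_conformers.py not found in package", call. = FALSE)
  path
}

run_helper <- function(args) {
  out <- suppressWarnings(system2("python", c(python_helper(), args),
    stdout = TRUE, stderr = TRUE
  ))
  status <- attr(out, "status") %||% 0L
  if (status != 0) {
    stop("ligand helper failed: ", paste(out, collapse = " "), call. = FALSE)
  }
  jsonlite::fromJSON(out[length(out)])
}

#' Parse a small molecule from SMILES or SDF
#'
#' Sanitizes the molecule, strips salts to the largest fragment, and records
#' aromaticity. An SDF record with 3-D coordinates keeps them as conformer 0.
#'
#' @param input a SMILES string, a path to an SDF file, or SDF record text.
#' @param name molecule name (defaults to a SMILES-derived label or the SDF
#'   title).
#' @return an `hp_molecule`: name, canonical SMILES, heavy-atom and aromatic
#'   ring counts, and (for 3-D SDF input) the source coordinates.
#' @export
parse_ligand <- function(input, name = NULL) {
  is_sdf_text <- grepl("V2000|\\$\\$\\$\\$", input)
  is_file <- !is_sdf_text && nchar(input) < 500 && file.exists(input)
  sdf_path <- NULL
  if (is_sdf_text) {
    sdf_path <- tempfile(fileext = ".sdf")
    writeLines(input, sdf_path)
  } else if (is_file) {
    sdf_path <- input
  }
  info <- if (is.null(sdf_path)) {
    run_helper(c("parse", "--smiles", shQuote(input)))
  } else {
    run_helper(c("parse", "--sdf", sdf_path))
  }
  conf0 <- NULL
  if (!is.null(sdf_path) && isTRUE(info$has_3d)) {
    conf0 <- read_conformers_sdf(sdf_path, name = name)
  }
  structure(
    list(
      name = name %||% (if (!is.null(conf0)) conf0$name else info$canonical_smiles),
      smiles = info$canonical_smiles,
      n_heavy_atoms = info$n_heavy_atoms,
      n_aromatic_rings = info$n_aromatic_rings,
      n_rotatable_bonds = info$n_rotatable_bonds,
      conformers = conf0
    ),
    class = "hp_molecule"
  )
}

#' @export
print.hp_molecule <- function(x, ...) {
  cat(
    "<hp_molecule> ", x$name, ": ", x$smiles, " (", x$n_heavy_atoms,
    " heavy atoms, ", x$n_aromatic_rings, " aromatic rings)\n",
    sep = ""
  )
  invisible(x)
}

#' Generate low-energy 3-D conformers
#'
#' Seeded distance-geometry embedding (ETKDG) followed by MMFF94
#' minimization; conformers are sorted by energy and deduplicated at a
#' heavy-atom best-fit RMSD threshold, keeping the lower-energy member.
#' Deterministic under a fixed seed.
#'
#' @param mol an `hp_molecule` from [parse_ligand()], or a SMILES string.
#' @param n_max maximum conformers retained.
#' @param rmsd_dedup deduplication threshold in Angstrom.
#' @param seed integer seed for the embedding.
#' @param rotbond_limit refuse molecules with more rotatable bonds (embedding
#'   cost guard).
#' @return a `conformer_set` with explicit hydrogens, per-conformer strain
#'   (kcal/mol above the best conformer), and perceived features.
#' @export
generate_conformers <- function(mol, n_max = 200, rmsd_dedup = 0.5, seed = 1L,
                                rotbond_limit = 15) {
  if (is.character(mol)) mol <- parse_ligand(mol)
  stopifnot(inherits(mol, "hp_molecule"))
  if (mol$n_rotatable_bonds > rotbond_limit) {
    stop(
      "molecule ", mol$name, " has ", mol$n_rotatable_bonds,
      " rotatable bonds (limit ", rotbond_limit, ")",
      call. = FALSE
    )
  }
  out <- tempfile(fileext = ".sdf")
  run_helper(c(
    "embed", "--smiles", shQuote(mol$smiles), "--out", out,
    "--name", shQuote(mol$name), "--n-max", n_max,
    "--rmsd-dedup", rmsd_dedup, "--seed", as.integer(seed)
  ))
  cs <- read_conformers_sdf(out, name = mol$name)
  cs$smiles <- mol$smiles
  cs$features <- purrr::map_dfr(
    seq_len(cs$n_conf),
    function(i) perceive_ligand_features(cs, conf = i)
  )
  cs
}

#' Read a (multi-conformer) SDF into a conformer set
#'
#' All records must share the same atom order (conformers of one molecule).
#'
#' @param path SDF path.
#' @param name optional name override.
#' @return a `conformer_set`.
#' @export
read_conformers_sdf <- function(path, name = NULL) {
  sdfs <- ChemmineR::read.SDFset(path)
  n <- length(sdfs)
  atoms <- list()
  bonds <- NULL
  strain <- numeric(n)
  rings_prop <- NULL
  feat_prop <- NULL
  for (i in seq_len(n)) {
    sdf <- sdfs[[i]]
    ab <- ChemmineR::atomblock(sdf)
    el <- toupper(gsub("_.*$", "", rownames(ab)))
    atoms[[i]] <- tibble::tibble(
      conf = i, atom_id = seq_len(nrow(ab)), element = el,
      x = ab[, 1], y = ab[, 2], z = ab[, 3]
    )
    if (i == 1L) {
      bb <- tryCatch(ChemmineR::bondblock(sdf), error = function(e) NULL)
      bonds <- if (is.null(bb) || length(dim(bb)) != 2 || nrow(bb) == 0 ||
        ncol(bb) < 3) {
        tibble::tibble(a1 = integer(), a2 = integer(), order = integer())
      } else {
        tibble::tibble(
          a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
          order = as.integer(bb[, 3])
        )
      }
      db <- ChemmineR::datablock(sdf)
      if ("aromatic_rings" %in% names(db)) rings_prop <- db[["aromatic_rings"]]
      if ("hotphore_features" %in% names(db)) {
        feat_prop <- db[["hotphore_features"]]
      }
    }
    db <- ChemmineR::datablock(sdf)
    strain[i] <- if ("strain" %in% names(db)) as.numeric(db[["strain"]]) else 0
  }
  atoms <- dplyr::bind_rows(atoms)
  counts <- table(atoms$conf)
  if (length(unique(counts)) != 1) {
    stop("records in ", path, " differ in atom count", call. = FALSE)
  }
  features <- NULL
  if (!is.null(feat_prop) && nzchar(feat_prop)) {
    # typed features serialized by write_conformers_sdf (pseudo-molecules)
    rows <- strsplit(strsplit(feat_prop, ";")[[1]], ",")
    num <- function(s) suppressWarnings(as.numeric(s))
    features <- purrr::map_dfr(rows, function(r) {
      tibble::tibble(
        conf = 1L, kind = r[1],
        x = num(r[2]), y = num(r[3]), z = num(r[4]),
        nx = num(r[5]), ny = num(r[6]), nz = num(r[7]),
        donor = r[8] == "1", acceptor = r[9] == "1"
      )
    })
  }
  cs <- new_conformer_set(
    name = name %||% ChemmineR::sdfid(sdfs[[1]]),
    smiles = NA_character_, atoms = atoms, bonds = bonds, strain = strain,
    features = features
  )
  attr(cs, "aromatic_rings_prop") <- rings_prop
  cs
}

#' Write a conformer set as multi-record SDF
#'
#' @param cs a `conformer_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conformers_sdf <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in sort(unique(cs$atoms$conf))) {
    a <- dplyr::filter(cs$atoms, .data$conf == i)
    b <- cs$bonds
    writeLines(c(
      cs$name, "  hotphore", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), if (is.null(b)) 0L else nrow(b))
    ), con)
    writeLines(sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      a$x, a$y, a$z, substr(a$element, 1, 1)
    ), con)
    if (!is.null(b) && nrow(b) > 0) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2, b$order), con)
    }
    writeLines("M  END", con)
    fi <- cs$features
    if (!is.null(fi) && nrow(fi) > 0 && i == min(cs$atoms$conf)) {
      ser <- paste(vapply(seq_len(nrow(fi)), function(k) {
        paste(
          fi$kind[k],
          format(fi$x[k], digits = 12), format(fi$y[k], digits = 12),
          format(fi$z[k], digits = 12),
          format(fi$nx[k], digits = 12), format(fi$ny[k], digits = 12),
          format(fi$nz[k], digits = 12),
          as.integer(fi$donor[k]), as.integer(fi$acceptor[k]),
          sep = ","
        )
      }, character(1)), collapse = ";")
      writeLines(c("> <hotphore_features>", ser, ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Perceive pharmacophoric features of one conformer
#'
#' Ring features at aromatic ring centroids (with unit normals); donor
#' features at N/O heavy atoms bearing a polar hydrogen; acceptor features at
#' oxygens and at nitrogens without attached hydrogen (lone-pair bearing);
#' hydrophobe features at the centroids of connected aliphatic-carbon
#' clusters of three or more atoms. The typing rules mirror the nucleobase
#' tables so ligand and pharmacophore features are commensurable. Feature
#' positions transform covariantly with the conformer.
#'
#' @param cs a `conformer_set` (from [generate_conformers()] or
#'   [read_conformers_sdf()]; bond information required).
#' @param conf conformer index.
#' @return a feature tibble (`conf`, `kind`, position, normal, role flags).
#' @export
perceive_ligand_features <- function(cs, conf = 1L) {
  a <- dplyr::filter(cs$atoms, .data$conf == conf)
  if (nrow(a) == 0) stop("no conformer ", conf, call. = FALSE)
  b <- cs$bonds
  feats <- list()
  nbr <- function(i) {
    c(b$a2[b$a1 == i], b$a1[b$a2 == i])
  }
  n_h <- vapply(a$atom_id, function(i) {
    sum(a$element[match(nbr(i), a$atom_id)] == "H")
  }, double(1))

  # aromatic rings: from the RDKit-provided ring property when present,
  # otherwise planar 5/6-cycles of unsaturated atoms
  ring_sets <- list()
  prop <- attr(cs, "aromatic_rings_prop")
  if (!is.null(prop) && nzchar(prop)) {
    ring_sets <- lapply(
      strsplit(prop, ";")[[1]],
      function(s) as.integer(strsplit(s, ",")[[1]])
    )
  } else if (!is.null(b)) {
    ring_sets <- find_planar_rings(a, b)
  }
  for (ring in ring_sets) {
    xyz <- as.matrix(a[match(ring, a$atom_id), c("x", "y", "z")])
    pf <- plane_fit(xyz)
    feats[[length(feats) + 1L]] <- tibble::tibble(
      conf = conf, kind = "ring", x = pf$centroid[1], y = pf$centroid[2],
      z = pf$centroid[3], nx = pf$normal[1], ny = pf$normal[2],
      nz = pf$normal[3], donor = FALSE, acceptor = FALSE
    )
  }

  aromatic_atoms <- unique(unlist(ring_sets))
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    if (!el %in% c("N", "O")) next
    donor <- n_h[i] >= 1
    acceptor <- el == "O" || (el == "N" && n_h[i] == 0)
    if (!donor && !acceptor) next
    feats[[length(feats) + 1L]] <- tibble::tibble(
      conf = conf,
      kind = if (donor) "donor" else "acceptor",
      x = a$x[i], y = a$y[i], z = a$z[i],
      nx = NA_real_, ny = NA_real_, nz = NA_real_,
      donor = donor, acceptor = acceptor
    )
  }

  # hydrophobes: connected aliphatic carbons with no polar neighbour
  if (!is.null(b)) {
    aliph <- a$atom_id[a$element == "C" & !a$atom_id %in% aromatic_atoms]
    aliph <- Filter(function(i) {
      !any(a$element[match(nbr(i), a$atom_id)] %in% c("N", "O", "S", "P"))
    }, aliph)
    comp <- graph_components(aliph, b)
    for (grp in comp) {
      if (length(grp) < 3) next
      xyz <- as.matrix(a[match(grp, a$atom_id), c("x", "y", "z")])
      ctr <- colMeans(xyz)
      feats[[length(feats) + 1L]] <- tibble::tibble(
        conf = conf, kind = "hydrophobe", x = ctr[1], y = ctr[2], z = ctr[3],
        nx = NA_real_, ny = NA_real_, nz = NA_real_,
        donor = FALSE, acceptor = FALSE
      )
    }
  }

  if (length(feats) == 0) {
    return(tibble::tibble(
      conf = integer(), kind = character(), x = double(), y = double(),
      z = double(), nx = double(), ny = double(), nz = double(),
      donor = logical(), acceptor = logical()
    ))
  }
  dplyr::bind_rows(feats)
}

# fallback aromatic perception: 5/6-cycles, non-sp3 members, near-planar
find_planar_rings <- function(a, b) {
  heavy <- a$atom_id[a$element != "H"]
  adj <- lapply(stats::setNames(heavy, heavy), function(i) {
    nb <- c(b$a2[b$a1 == i], b$a1[b$a2 == i])
    intersect(nb, heavy)
  })
  rings <- list()
  seen <- character()
  dfs <- function(path) {
    tail_ <- path[length(path)]
    for (nb in adj[[as.character(tail_)]]) {
      if (nb == path[1] && length(path) >= 5) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!nb %in% path && length(path) < 6) {
        dfs(c(path, nb))
      }
    }
  }
  for (i in heavy) dfs(i)
  Filter(function(ring) {
    xyz <- as.matrix(a[match(ring, a$atom_id), c("x", "y", "z")])
    pf <- plane_fit(xyz)
    dev <- abs(sweep(xyz, 2, pf$centroid) %*% pf$normal)
    max(dev) < 0.15
  }, rings)
}

graph_components <- function(nodes, bonds) {
  if (length(nodes) == 0) {
    return(list())
  }
  comp <- list()
  left <- nodes
  while (length(left) > 0) {
    grp <- left[1]
    repeat {
      nb <- unique(c(
        bonds$a2[bonds$a1 %in% grp], bonds$a1[bonds$a2 %in% grp]
      ))
      nb <- intersect(nb, left)
      new <- setdiff(nb, grp)
      if (length(new) == 0) break
      grp <- c(grp, new)
    }
    comp[[length(comp) + 1L]] <- sort(grp)
    left <- setdiff(left, grp)
  }
  comp
}
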