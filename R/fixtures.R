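# Synthetic protein-RNA complexes with planted, known ground truth.
#
# Fixtures are geometric, not energetic: ideal planar bases, occluding
# shells of alanine-like residues tuned to a target burial, hydrogen-bond
# partners planted at canonical geometry, phenylalanine rings at stacking
# geometry. Every property a downstream stage should recover is recorded in
# the returned ground truth.

# ---- ideal nucleotide geometry ----------------------------------------

hexagon <- function(names, radius = 1.39, start_deg = 270) {
  ang <- (start_deg + 60 * (seq_along(names) - 1)) * pi / 180
  tibble::tibble(atom = names, x = radius * cos(ang), y = radius * sin(ang), z = 0)
}

# template of one nucleotide in its base plane (z = 0); includes exocyclic
# substituents, glycosidic C1' and a short lateral backbone tail
ideal_nucleotide <- function(parent) {
  radial <- function(tab, from, dist) {
    p <- as.numeric(tab[match(from, tab$atom), c("x", "y", "z")])
    u <- p / sqrt(sum(p^2))
    p + dist * u
  }
  if (parent %in% c("C", "U")) {
    ring <- hexagon(c("N1", "C2", "N3", "C4", "C5", "C6"))
    sub2 <- radial(ring, "C2", 1.23)
    sub4 <- radial(ring, "C4", if (parent == "C") 1.34 else 1.23)
    subs <- tibble::tibble(
      atom = c("O2", if (parent == "C") "N4" else "O4"),
      x = c(sub2[1], sub4[1]), y = c(sub2[2], sub4[2]), z = 0
    )
    glyc_from <- "N1"
    base <- dplyr::bind_rows(ring, subs)
  } else {
    ring6 <- hexagon(c("N1", "C2", "N3", "C4", "C5", "C6"), start_deg = 90)
    # fused five-ring on the C4-C5 edge, outside the hexagon
    c4 <- as.numeric(ring6[4, c("x", "y", "z")])
    c5 <- as.numeric(ring6[5, c("x", "y", "z")])
    mid <- (c4 + c5) / 2
    out <- mid / sqrt(sum(mid^2))
    s <- 1.39
    pcen <- mid + out * s / (2 * tan(pi / 5))
    r5 <- s / (2 * sin(pi / 5))
    th4 <- atan2(c4[2] - pcen[2], c4[1] - pcen[1])
    th5 <- atan2(c5[2] - pcen[2], c5[1] - pcen[1])
    step <- (th5 - th4)
    step <- step - 2 * pi * round(step / (2 * pi)) # wrap to (-pi, pi]
    # walk from C4 away from C5: N9, C8, N7
    th <- th4 - sign(step) * 2 * pi / 5 * 1:3
    five <- tibble::tibble(
      atom = c("N9", "C8", "N7"),
      x = pcen[1] + r5 * cos(th), y = pcen[2] + r5 * sin(th), z = 0
    )
    base <- dplyr::bind_rows(ring6, five)
    sub6 <- radial(ring6, "C6", if (parent == "A") 1.34 else 1.23)
    subs <- tibble::tibble(
      atom = if (parent == "A") "N6" else "O6",
      x = sub6[1], y = sub6[2], z = 0
    )
    if (parent == "G") {
      sub2 <- radial(ring6, "C2", 1.34)
      subs <- dplyr::bind_rows(subs, tibble::tibble(
        atom = "N2", x = sub2[1], y = sub2[2], z = 0
      ))
    }
    glyc_from <- "N9"
    base <- dplyr::bind_rows(base, subs)
  }
  # glycosidic carbon + short zig-zag backbone tail in the base plane
  gpos <- as.numeric(base[match(glyc_from, base$atom), c("x", "y", "z")])
  u <- gpos / sqrt(sum(gpos^2))
  t_perp <- c(-u[2], u[1], 0)
  bb_names <- c("C1'", "O4'", "C2'", "C3'", "O3'", "C4'", "C5'", "O5'", "P", "OP1", "OP2")
  bb <- purrr::map_dfr(seq_along(bb_names), function(k) {
    pos <- gpos + u * (1.47 + (k - 1) * 1.25) +
      t_perp * 0.5 * (k %% 2) + c(0, 0, 0.4 * ((k %/% 2) %% 2))
    tibble::tibble(atom = bb_names[k], x = pos[1], y = pos[2], z = pos[3])
  })
  dplyr::bind_rows(base, bb)
}

base_atom_names <- function(tab) tab$atom[!is_rna_backbone_atom(tab$atom)]

place_residue <- function(tab, R, t) {
  xyz <- apply_rigid(as.matrix(tab[, c("x", "y", "z")]), R, t)
  dplyr::mutate(tab, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
}

rnd_rot <- function() {
  q <- stats::rnorm(4)
  quat_to_rot(q / sqrt(sum(q^2)))
}

atom_rows <- function(tab, chain, resno, resname, element = NULL) {
  tibble::tibble(
    model = 1L, chain = chain, resno = as.integer(resno), resname = resname,
    insert = "", atom = tab$atom,
    element = element %||% substr(tab$atom, 1, 1),
    x = tab$x, y = tab$y, z = tab$z, occ = 1
  )
}

# alanine-like occluder residue along direction `dir` from `origin`
shell_residue <- function(origin, dir, radius) {
  dir <- dir / sqrt(sum(dir^2))
  t1 <- if (abs(dir[3]) < 0.9) c(-dir[2], dir[1], 0) else c(1, 0, 0)
  t1 <- t1 / sqrt(sum(t1^2))
  cb <- origin + radius * dir
  ca <- origin + (radius + 1.53) * dir
  tibble::tibble(
    atom = c("N", "CA", "C", "O", "CB"),
    x = c(ca[1] + 1.45 * t1[1], ca[1], ca[1] - 1.52 * t1[1], ca[1] - 1.52 * t1[1] + 1.23 * dir[1], cb[1]),
    y = c(ca[2] + 1.45 * t1[2], ca[2], ca[2] - 1.52 * t1[2], ca[2] - 1.52 * t1[2] + 1.23 * dir[2], cb[2]),
    z = c(ca[3] + 1.45 * t1[3], ca[3], ca[3] - 1.52 * t1[3], ca[3] - 1.52 * t1[3] + 1.23 * dir[3], cb[3])
  )
}

# phenylalanine sidechain ring (+ stub backbone) stacked parallel to a base
# ring: centroid at `centroid + offset`, plane normal along `normal`
phe_residue <- function(centroid, normal, offset_dist, lateral = c(0, 0, 0)) {
  normal <- normal / sqrt(sum(normal^2))
  ctr <- centroid + normal * offset_dist + lateral
  t1 <- if (abs(normal[3]) < 0.9) c(-normal[2], normal[1], 0) else c(1, 0, 0)
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(
    normal[2] * t1[3] - normal[3] * t1[2],
    normal[3] * t1[1] - normal[1] * t1[3],
    normal[1] * t1[2] - normal[2] * t1[1]
  )
  ang <- (0:5) * pi / 3
  ring <- tibble::tibble(
    atom = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    x = ctr[1] + 1.39 * (cos(ang) * t1[1] + sin(ang) * t2[1]),
    y = ctr[2] + 1.39 * (cos(ang) * t1[2] + sin(ang) * t2[2]),
    z = ctr[3] + 1.39 * (cos(ang) * t1[3] + sin(ang) * t2[3])
  )
  cg <- as.numeric(ring[1, c("x", "y", "z")])
  away <- (cg - ctr) / 1.39
  # backbone stub strung radially outward and bent along +normal, i.e. away
  # from whatever the ring is stacked against
  r_off <- c(1.5, 3.0, 4.0, 4.0, 5.0)
  n_off <- c(0, 0.8, 0.8, 1.6, 1.6)
  t_off <- c(0, 0, 1.2, -1.2, -1.2)
  stub <- tibble::tibble(
    atom = c("CB", "CA", "N", "C", "O"),
    x = cg[1] + away[1] * r_off + normal[1] * n_off + t1[1] * t_off,
    y = cg[2] + away[2] * r_off + normal[2] * n_off + t1[2] * t_off,
    z = cg[3] + away[3] * r_off + normal[3] * n_off + t1[3] * t_off
  )
  dplyr::bind_rows(ring, stub)
}

# lysine-like donor arm: NZ at `pos`, chain strung along `dir`
lys_residue <- function(pos, dir) {
  dir <- dir / sqrt(sum(dir^2))
  d <- c(0, 1.5, 3.0, 4.4, 5.8, 7.2, 8.4, 8.4)
  zoff <- c(0, 0.3, 0, 0.4, 0, 0.4, 0, 1.2)
  tibble::tibble(
    atom = c("NZ", "CE", "CD", "CG", "CB", "CA", "N", "C"),
    x = pos[1] + dir[1] * d,
    y = pos[2] + dir[2] * d,
    z = pos[3] + dir[3] * d + zoff
  ) |> dplyr::bind_rows(tibble::tibble(
    atom = "O",
    x = pos[1] + dir[1] * 9.6, y = pos[2] + dir[2] * 9.6,
    z = pos[3] + dir[3] * 9.6 + 1.2
  ))
}

# backbone-carbonyl acceptor arm: O at `pos`
carbonyl_residue <- function(pos, dir, resname = "VAL") {
  dir <- dir / sqrt(sum(dir^2))
  d <- c(0, 1.23, 2.7, 4.1, 4.1)
  zoff <- c(0, 0, 0.3, 0.3, 1.5)
  tab <- tibble::tibble(
    atom = c("O", "C", "CA", "N", "CB"),
    x = pos[1] + dir[1] * d, y = pos[2] + dir[2] * d,
    z = pos[3] + dir[3] * d + zoff
  )
  if (resname == "GLY") tab <- tab[tab$atom != "CB", ]
  tab
}

# ---- burial tuning ----------------------------------------------------

measure_burial <- function(all_atoms, base_sel, n_points) {
  a_cpx <- compute_sasa(all_atoms, n_points = n_points, subset = base_sel(all_atoms))
  rna <- dplyr::filter(all_atoms, .data$chain == "R")
  a_free <- compute_sasa(rna, n_points = n_points, subset = base_sel(rna))
  cf <- sum(a_cpx$area)
  fr <- sum(a_free$area)
  list(
    b = if (fr > 0) min(1, max(0, 1 - cf / fr)) else 0,
    buried_area = fr - cf, area_free = fr
  )
}

# choose shell directions occluding a spherical-cap complement so measured
# burial lands within 0.05 of target (verified at 4x production density)
tune_shell <- function(fixed_atoms, centroid, base_sel, target_b, open_dir,
                       seed_dirs, shell_radius = 6.2, verify_points = 7680) {
  mk_shell <- function(c0) {
    keep <- seed_dirs %*% open_dir <= c0
    dirs <- seed_dirs[keep, , drop = FALSE]
    if (nrow(dirs) == 0) {
      return(NULL)
    }
    res <- purrr::map_dfr(seq_len(nrow(dirs)), function(i) {
      dplyr::mutate(shell_residue(centroid, dirs[i, ], shell_radius), .res = i)
    })
    # drop residues clashing with existing atoms or putting polar atoms
    # near RNA polar atoms
    bad <- unique(unlist(lapply(split(res, res$.res), function(r) {
      dmin <- min(dist_point_set(
        as.matrix(r[, c("x", "y", "z")]),
        as.matrix(fixed_atoms[, c("x", "y", "z")])
      ))
      pol <- r[r$atom %in% c("N", "O"), ]
      rna_pol <- dplyr::filter(
        fixed_atoms, .data$chain == "R",
        .data$element %in% c("N", "O")
      )
      dpol <- if (nrow(rna_pol)) {
        min(dist_point_set(
          as.matrix(pol[, c("x", "y", "z")]),
          as.matrix(rna_pol[, c("x", "y", "z")])
        ))
      } else {
        Inf
      }
      if (dmin < 2.7 || dpol < 3.8) r$.res[1] else NULL
    })))
    res[!res$.res %in% bad, ]
  }
  lo <- -1
  hi <- 1
  best <- NULL
  if (target_b >= 0.99) {
    shell <- mk_shell(1)
    return(shell)
  }
  for (iter in 1:9) {
    c0 <- (lo + hi) / 2
    shell <- mk_shell(c0)
    atoms <- dplyr::bind_rows(
      fixed_atoms,
      if (!is.null(shell)) atom_rows(shell[, c("atom", "x", "y", "z")], "A", 900, "ALA")
    )
    m <- measure_burial(atoms, base_sel, verify_points)
    if (abs(m$b - target_b) <= 0.04) {
      return(shell)
    }
    best <- shell
    if (m$b > target_b) hi <- c0 else lo <- c0
  }
  best
}

dist_point_set <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# ---- public fixture API -----------------------------------------------

#' Specification of a synthetic protein-RNA complex
#'
#' @param n_buried,n_exposed number of deeply buried / solvent-exposed bases.
#' @param target_burial burial fraction aimed at for buried bases (verified
#'   within 0.05 at build time with 4x the production point density).
#' @param n_hbonds planted intermolecular hydrogen bonds on the first buried
#'   base (0-4); roles alternate through the base's polar atoms.
#' @param include_bridging_water plant one water-mediated bond.
#' @param stacking_rings phenylalanine rings planted at stacking geometry
#'   against the first buried base.
#' @param clash_wall cover the pocket with a wall of glycine CA atoms.
#' @param bases parent bases used cyclically (default A, G, U, C).
#' @param seed mandatory integer seed (site orientations).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_buried = 1, n_exposed = 2, target_burial = 0.9,
                         n_hbonds = 2, include_bridging_water = FALSE,
                         stacking_rings = 1, clash_wall = FALSE,
                         bases = c("A", "G", "U", "C"), seed) {
  if (missing(seed)) stop("fixture_spec: seed is mandatory", call. = FALSE)
  stopifnot(
    n_buried >= 0, n_exposed >= 0, target_burial >= 0, target_burial <= 1,
    n_hbonds >= 0
  )
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic protein-RNA complex with planted ground truth
#'
#' Builds an RNA chain of ideal-geometry nucleotides, occludes the
#' designated bases with shells of alanine-like residues tuned to the target
#' burial (verified at build time with an independent, denser point
#' sampling), plants hydrogen-bond partner atoms at canonical geometry,
#' optionally a bridging water, phenylalanine rings at stacking geometry,
#' and a clash wall over the pocket. Deterministic: the same spec and seed
#' reproduce the file byte for byte.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory; when given, writes
#'   `toy_<seed>.pdb` and `toy_<seed>_truth.json`.
#' @return list with `structure` (a classified `mol_structure`), `truth`
#'   (planted hotspot bases, hydrogen-bond atoms, stacking residues), and
#'   `paths` (when written).
#' @export
make_toy_complex <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n_bases <- spec$n_buried + spec$n_exposed
  if (n_bases == 0) stop("fixture needs at least one base", call. = FALSE)
  parents <- rep_len(spec$bases, n_bases)
  buried_flag <- c(rep(TRUE, spec$n_buried), rep(FALSE, spec$n_exposed))

  rna <- list()
  site_R <- list()
  for (i in seq_len(n_bases)) {
    tmpl <- ideal_nucleotide(parents[i])
    R <- rot_z(stats::runif(1, 0, 360))
    # sites spaced so a planted bond arm or backbone tail of one site can
    # never reach hydrogen-bond distance of another
    t <- c((i - 1) * 34, 0, 0)
    rna[[i]] <- atom_rows(place_residue(tmpl, R, t), "R", 100 + i, parents[i])
    site_R[[i]] <- list(R = R, t = t)
  }
  rna_atoms <- dplyr::bind_rows(rna)

  # sentinel protein residues far from every base so the complex always has
  # a classifiable protein chain, even with nothing planted
  sentinel <- purrr::map_dfr(1:3, function(k) {
    atom_rows(
      shell_residue(c(-30 - 6 * k, 40, 0), c(0, 1, 0), 3), "A", 90 + k, "ALA"
    )
  })

  protein <- list(sentinel)
  truth_hb <- tibble::tibble(
    resno = integer(), atom = character(), role = character(), kind = character()
  )
  water_atoms <- NULL
  next_res <- 1L

  add_prot <- function(tab, resname) {
    protein[[length(protein) + 1L]] <<- atom_rows(tab, "A", next_res, resname)
    next_res <<- next_res + 1L
  }

  # hydrogen-bond partners on the first buried base
  if (spec$n_buried > 0 && spec$n_hbonds > 0) {
    i <- 1L
    resno <- 100 + i
    tab <- .base_polar[[parents[i]]]
    res_atoms <- dplyr::filter(rna_atoms, .data$resno == !!resno)
    base_xyz <- as.matrix(
      res_atoms[!is_rna_backbone_atom(res_atoms$atom), c("x", "y", "z")]
    )
    ctr <- colMeans(base_xyz)
    for (k in seq_len(min(spec$n_hbonds, nrow(tab)))) {
      nm <- tab$atom[k]
      apos <- as.numeric(res_atoms[match(nm, res_atoms$atom), c("x", "y", "z")])
      dir_out <- (apos - ctr) / sqrt(sum((apos - ctr)^2))
      pos <- apos + 2.9 * dir_out
      if (tab$donor[k]) {
        add_prot(carbonyl_residue(pos, dir_out), "VAL")
        truth_hb <- dplyr::bind_rows(truth_hb, tibble::tibble(
          resno = resno, atom = nm, role = "donor", kind = "direct"
        ))
      } else {
        add_prot(lys_residue(pos, dir_out), "LYS")
        truth_hb <- dplyr::bind_rows(truth_hb, tibble::tibble(
          resno = resno, atom = nm, role = "acceptor", kind = "direct"
        ))
      }
    }
    if (isTRUE(spec$include_bridging_water)) {
      k <- min(spec$n_hbonds, nrow(tab)) + 1L
      if (k <= nrow(tab)) {
        nm <- tab$atom[k]
        apos <- as.numeric(res_atoms[match(nm, res_atoms$atom), c("x", "y", "z")])
        dir_out <- (apos - ctr) / sqrt(sum((apos - ctr)^2))
        wpos <- apos + 2.8 * dir_out
        water_atoms <- atom_rows(
          tibble::tibble(atom = "O", x = wpos[1], y = wpos[2], z = wpos[3]),
          "W", 501, "HOH"
        )
        add_prot(carbonyl_residue(wpos + 2.9 * dir_out, dir_out,
          resname = "GLY"
        ), "GLY")
        truth_hb <- dplyr::bind_rows(truth_hb, tibble::tibble(
          resno = resno, atom = nm, role = "water", kind = "water_mediated"
        ))
      }
    }
  }

  # stacking phenylalanines against the first buried base
  truth_stack <- integer(0)
  if (spec$n_buried > 0 && spec$stacking_rings > 0) {
    res_atoms <- dplyr::filter(rna_atoms, .data$resno == 101)
    rings <- .base_rings[[parents[1]]]
    ring_xyz <- as.matrix(
      res_atoms[match(rings[[length(rings)]], res_atoms$atom), c("x", "y", "z")]
    )
    pf <- plane_fit(ring_xyz)
    sides <- rep(c(-1, 1), length.out = spec$stacking_rings)
    lat <- list(c(0, 0, 0), c(0, 0, 0), c(2.5, 0, 0))
    for (s in seq_len(spec$stacking_rings)) {
      truth_stack <- c(truth_stack, next_res)
      add_prot(
        phe_residue(pf$centroid, pf$normal * sides[s], 3.8, lat[[min(s, 3)]]),
        "PHE"
      )
    }
  }

  planted <- dplyr::bind_rows(protein)
  fixed <- dplyr::bind_rows(rna_atoms, planted, water_atoms)

  # occlusion shells around buried bases
  seed_dirs <- sphere_points(128)
  shells <- list()
  for (i in which(buried_flag)) {
    resno <- 100 + i
    sel <- function(tab) {
      tab$chain == "R" & tab$resno == resno & !is_rna_backbone_atom(tab$atom)
    }
    res_atoms <- dplyr::filter(rna_atoms, .data$resno == !!resno)
    ctr <- colMeans(as.matrix(
      res_atoms[!is_rna_backbone_atom(res_atoms$atom), c("x", "y", "z")]
    ))
    open_dir <- as.numeric(rnd_rot() %*% c(0, 0, 1))
    shell <- tune_shell(
      dplyr::bind_rows(fixed, shells), ctr, sel, spec$target_burial, open_dir,
      seed_dirs
    )
    if (!is.null(shell) && nrow(shell)) {
      for (r in split(shell, shell$.res)) {
        shells[[length(shells) + 1L]] <- atom_rows(
          r[, c("atom", "x", "y", "z")], "A", 100 + next_res, "ALA"
        )
        next_res <- next_res + 1L
      }
    }
  }
  shells <- dplyr::bind_rows(shells)

  wall <- NULL
  if (isTRUE(spec$clash_wall) && spec$n_buried > 0) {
    res_atoms <- dplyr::filter(rna_atoms, .data$resno == 101)
    bx <- as.matrix(
      res_atoms[!is_rna_backbone_atom(res_atoms$atom), c("x", "y", "z")]
    )
    gx <- seq(min(bx[, 1]) - 3, max(bx[, 1]) + 3, by = 1.2)
    gy <- seq(min(bx[, 2]) - 3, max(bx[, 2]) + 3, by = 1.2)
    grid <- expand.grid(x = gx, y = gy)
    wall <- tibble::tibble(
      model = 1L, chain = "X", resno = 700L + seq_len(nrow(grid)),
      resname = "GLY", insert = "", atom = "CA", element = "C",
      x = grid$x, y = grid$y, z = max(bx[, 3]) + 2.0, occ = 1
    )
  }

  atoms <- dplyr::bind_rows(rna_atoms, planted, shells, water_atoms, wall)
  st <- classify_chains(new_mol_structure(
    atoms,
    source_id = sprintf("toy_%d", spec$seed)
  ))
  truth <- list(
    seed = spec$seed,
    hotspot_bases = tibble::tibble(
      resno = as.integer(100 + which(buried_flag)),
      parent = parents[buried_flag], target_b = spec$target_burial
    ),
    exposed_bases = as.integer(100 + which(!buried_flag)),
    hbond_atoms = truth_hb,
    stacking_resno = truth_stack,
    clash_wall = isTRUE(spec$clash_wall)
  )
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pdb <- file.path(dir, sprintf("toy_%d.pdb", spec$seed))
    js <- file.path(dir, sprintf("toy_%d_truth.json", spec$seed))
    write_pdb_file(st, pdb)
    jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(pdb = pdb, truth = js)
  }
  list(structure = st, truth = truth, paths = paths)
}

#' Probe ligand for a pharmacophore
#'
#' The pharmacophore's rigid pseudo-molecule (ring member carbons as C,
#' donors as N, acceptors as O), optionally written as SDF. Aligning the
#' probe to its source pharmacophore reaches a combo score of ~1 by
#' construction.
#'
#' @param phore a `pharmacophore`.
#' @param path optional SDF output path.
#' @return a `conformer_set`.
#' @export
make_probe_ligand <- function(phore, path = NULL) {
  cs <- phore_pseudo_molecule(phore)
  if (!is.null(path)) write_conformers_sdf(cs, path)
  cs
}

#' Synthetic reconstruction of the MSI1 RRM1-RNA binding-site topology
#'
#' A synthetic complex (not deposited coordinates) reproducing the reported
#' interaction pattern of the Musashi-1 RRM1 / RNA hotspot: adjacent bases
#' A106 and G107 stacked and deeply buried, three phenylalanine rings
#' (numbered 23, 65, 96) at stacking geometry, a lysine (21) sidechain
#' donating to G107 O6, and backbone carbonyls (valine 94, the
#' phenylalanine 96 stub) accepting from G107 N1/N2 and A106 N6 - four
#' intermolecular hydrogen bonds engaging four polar groups. No ordered
#' waters. Extraction at default parameters yields a single pharmacophore.
#'
#' @return list with `structure` (source id `MSI1_RRM1_synthetic`) and
#'   `truth` (hotspot bases, hydrogen-bond atoms, stacking residues).
#' @export
make_msi1_like_complex <- function() {
  a106 <- ideal_nucleotide("A")
  g107 <- ideal_nucleotide("G")
  u104 <- ideal_nucleotide("U")
  a105 <- ideal_nucleotide("A")
  u108 <- ideal_nucleotide("U")

  rna <- dplyr::bind_rows(
    atom_rows(place_residue(u104, rot_z(40), c(-26, 4, 0)), "R", 104, "U"),
    atom_rows(place_residue(a105, rot_z(160), c(-13, 2, 0)), "R", 105, "A"),
    atom_rows(place_residue(a106, diag(3), c(0, 0, 0)), "R", 106, "A"),
    atom_rows(place_residue(g107, rot_z(30), c(1.2, 0.6, 3.4)), "R", 107, "G"),
    atom_rows(place_residue(u108, rot_z(250), c(19, 8, 0)), "R", 108, "U")
  )

  ring6_a <- .base_rings$A$ring6
  a_atoms <- dplyr::filter(rna, .data$resno == 106)
  g_atoms <- dplyr::filter(rna, .data$resno == 107)
  pf_a <- plane_fit(as.matrix(
    a_atoms[match(ring6_a, a_atoms$atom), c("x", "y", "z")]
  ))
  pf_g <- plane_fit(as.matrix(
    g_atoms[match(.base_rings$G$ring6, g_atoms$atom), c("x", "y", "z")]
  ))
  a_ctr <- colMeans(as.matrix(
    a_atoms[!is_rna_backbone_atom(a_atoms$atom), c("x", "y", "z")]
  ))
  g_ctr <- colMeans(as.matrix(
    g_atoms[!is_rna_backbone_atom(g_atoms$atom), c("x", "y", "z")]
  ))

  xyz_of <- function(tab, nm) as.numeric(tab[match(nm, tab$atom), c("x", "y", "z")])

  protein <- list()
  add_prot <- function(tab, resno, resname) {
    protein[[length(protein) + 1L]] <<- atom_rows(tab, "A", resno, resname)
  }

  # stacking: Phe23 under A106, Phe65 over G107, Phe96 under A106 offset
  dn <- if (pf_a$normal[3] > 0) -1 else 1
  add_prot(phe_residue(pf_a$centroid, pf_a$normal * dn, 3.8), 23, "PHE")
  up <- if (pf_g$normal[3] > 0) 1 else -1
  add_prot(phe_residue(pf_g$centroid, pf_g$normal * up, 3.7), 65, "PHE")
  add_prot(phe_residue(pf_a$centroid, pf_a$normal * dn, 4.0, c(3.0, 0, 0)), 96, "PHE")

  # hydrogen bonds (heavy-atom geometry, no explicit hydrogens):
  #   Lys21 NZ -> G107 O6; Val94 O <- G107 N1 and N2; Phe96-stub O <- A106 N6
  o6 <- xyz_of(g_atoms, "O6")
  n7 <- xyz_of(g_atoms, "N7")
  d_o6 <- (o6 - n7) / sqrt(sum((o6 - n7)^2))
  add_prot(lys_residue(o6 + 2.9 * d_o6, d_o6), 21, "LYS")

  n1 <- xyz_of(g_atoms, "N1")
  n2 <- xyz_of(g_atoms, "N2")
  mid <- (n1 + n2) / 2
  axis <- (n2 - n1) / sqrt(sum((n2 - n1)^2))
  d_mid <- (mid - g_ctr)
  d_mid <- d_mid - sum(d_mid * axis) * axis # orthogonal to the N1-N2 line
  d_mid <- d_mid / sqrt(sum(d_mid^2))
  # carbonyl oxygen equidistant (2.9 A) from N1 and N2
  opos <- mid + d_mid * sqrt(2.9^2 - sum((n1 - mid)^2))
  add_prot(carbonyl_residue(opos, d_mid), 94, "VAL")

  n6 <- xyz_of(a_atoms, "N6")
  n1a <- xyz_of(a_atoms, "N1")
  d_n6 <- (n6 - n1a) / sqrt(sum((n6 - n1a)^2))
  add_prot(carbonyl_residue(n6 + 2.9 * d_n6, d_n6, resname = "GLY"), 92, "GLY")

  planted <- dplyr::bind_rows(protein)
  fixed <- dplyr::bind_rows(rna, planted)

  # occlude the stacked dinucleotide; deterministic orientation
  seed_dirs <- sphere_points(128)
  shells <- list()
  next_res <- 120L
  for (resno in c(106L, 107L)) {
    sel <- function(tab) {
      tab$chain == "R" & tab$resno == resno & !is_rna_backbone_atom(tab$atom)
    }
    ctr <- if (resno == 106L) a_ctr else g_ctr
    shell <- tune_shell(
      dplyr::bind_rows(fixed, shells), ctr, sel,
      target_b = 0.9, open_dir = c(0, 0, 1), seed_dirs
    )
    if (!is.null(shell) && nrow(shell)) {
      for (r in split(shell, shell$.res)) {
        shells[[length(shells) + 1L]] <- atom_rows(
          r[, c("atom", "x", "y", "z")], "A", next_res, "ALA"
        )
        next_res <- next_res + 1L
      }
    }
  }

  atoms <- dplyr::bind_rows(rna, planted, dplyr::bind_rows(shells))
  st <- classify_chains(new_mol_structure(atoms, source_id = "MSI1_RRM1_synthetic"))
  truth <- list(
    hotspot_bases = c(106L, 107L),
    hbond_atoms = tibble::tibble(
      resno = c(107L, 107L, 107L, 106L),
      atom = c("O6", "N1", "N2", "N6"),
      role = c("acceptor", "donor", "donor", "donor")
    ),
    stacking_resno = c(23L, 65L, 96L),
    n_polar_features = 4L
  )
  list(structure = st, truth = truth)
}
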