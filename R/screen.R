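# Receptor-frame placement of aligned conformers, clash detection, and a
# simplified interaction score for coarse ranking. The published-forcefield
# rescoring stage of the original workflow is out of scope: this score is a
# transparent capped Lennard-Jones plus hydrogen-bond bonus, intended for
# clash filtering and tie-breaking, not affinity prediction.

#' Place an aligned conformer into the receptor frame
#'
#' Applies the alignment's rigid transform to the conformer, putting the
#' ligand into the frame of the receptor the pharmacophore was extracted
#' from. Provenance is checked: aligning to pharmacophore X and placing into
#' receptor Y is an error.
#'
#' @param alignment a `phore_alignment`.
#' @param cs the `conformer_set` that was aligned.
#' @param receptor the source `mol_structure`.
#' @param params an [hp_params()] list.
#' @return a `placed_pose`: transformed ligand atoms plus
#'   `interaction_score`, `clash_count`, `hbond_count`.
#' @export
place_in_receptor <- function(alignment, cs, receptor, params = hp_params()) {
  if (!identical(alignment$phore$source_id, attr(receptor, "source_id"))) {
    stop(
      "provenance mismatch: alignment template from '",
      alignment$phore$source_id, "' but receptor is '",
      attr(receptor, "source_id"), "'",
      call. = FALSE
    )
  }
  a <- dplyr::filter(cs$atoms, .data$conf == alignment$conf)
  xyz <- apply_rigid(as.matrix(a[, c("x", "y", "z")]), alignment$R, alignment$t)
  pose_atoms <- dplyr::mutate(a, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  score <- interaction_score(pose_atoms, receptor,
    model_index = alignment$phore$model_index %||% 1L, params = params
  )
  structure(
    list(
      atoms = pose_atoms, alignment = alignment, name = cs$name,
      interaction_score = score$score, clash_count = score$clash_count,
      hbond_count = score$hbond_count
    ),
    class = "placed_pose"
  )
}

#' @export
print.placed_pose <- function(x, ...) {
  cat(sprintf(
    "<placed_pose> %s: score %.2f, %d clash(es), %d H-bond(s)\n",
    x$name, x$interaction_score, x$clash_count, x$hbond_count
  ))
  invisible(x)
}

#' Simplified protein-ligand interaction score
#'
#' Over all protein/ligand heavy-atom pairs within `interaction_cutoff`
#' (default 6 A): a 12-6 Lennard-Jones term on summed van der Waals radii
#' with the repulsive wall continued linearly below `0.6 sigma` (so a deep
#' clash is penalized finitely and monotonically), plus a `-1` unit bonus
#' per donor-acceptor heavy-atom pair meeting the hydrogen-bond distance
#' criterion. A pair closer than `(r_i + r_j) - clash_tol` counts as a
#' clash. Lower is better; an isolated ligand scores 0.
#'
#' @param pose_atoms ligand atom tibble (`element`, `x`, `y`, `z`) in the
#'   receptor frame.
#' @param receptor a `mol_structure`.
#' @param model_index receptor model.
#' @param params an [hp_params()] list.
#' @return list with `score`, `clash_count`, `hbond_count`.
#' @export
interaction_score <- function(pose_atoms, receptor, model_index = 1L,
                              params = hp_params()) {
  lig <- dplyr::filter(tibble::as_tibble(pose_atoms), .data$element != "H")
  prot <- model_atoms(receptor, model_index) |>
    dplyr::filter(.data$chain_class == "protein", .data$element != "H")
  if (nrow(lig) == 0 || nrow(prot) == 0) {
    return(list(score = 0, clash_count = 0L, hbond_count = 0L))
  }
  lx <- as.matrix(lig[, c("x", "y", "z")])
  px <- as.matrix(prot[, c("x", "y", "z")])
  d2 <- outer(rowSums(lx^2), rowSums(px^2), "+") - 2 * tcrossprod(lx, px)
  d <- sqrt(pmax(d2, 1e-12))
  sigma <- outer(vdw_radius(lig$element), vdw_radius(prot$element), "+")
  within <- d <= params$interaction_cutoff

  eps <- 0.1
  lj <- function(dd, ss) eps * ((ss / dd)^12 - 2 * (ss / dd)^6)
  dmin <- 0.6 * sigma
  # linear continuation below 0.6 sigma with matching value and slope
  slope <- eps * (-12 * (1 / 0.6)^12 / dmin + 12 * (1 / 0.6)^6 / dmin)
  e <- matrix(0, nrow(lig), nrow(prot))
  reg <- within & d >= dmin
  e[reg] <- lj(d[reg], sigma[reg])
  cap <- within & d < dmin
  e[cap] <- lj(dmin[cap], sigma[cap]) + slope[cap] * (d[cap] - dmin[cap])

  clash <- sum(d < sigma - params$clash_tol)

  # hydrogen bonds: ligand N/O vs protein polar atoms, distance criterion
  lig_pol <- lig$element %in% c("N", "O")
  prot_pol_tab <- protein_polar_atoms(model_atoms(receptor, model_index))
  key <- paste(prot$chain, prot$resno, prot$insert, prot$atom)
  pkey <- paste(
    prot_pol_tab$chain, prot_pol_tab$resno, prot_pol_tab$insert,
    prot_pol_tab$atom
  )
  prot_pol <- key %in% pkey
  hb <- which(outer(lig_pol, prot_pol) & d <= params$hbond_dist & d >= 2.2)
  hbond_count <- length(hb)

  list(
    score = sum(e) - 1.0 * hbond_count,
    clash_count = as.integer(clash),
    hbond_count = as.integer(hbond_count)
  )
}

#' Screen a ligand library against a pharmacophore
#'
#' For each molecule: aligns every conformer, keeps the best combo score,
#' places it into the receptor frame, drops clashing poses, and ranks by
#' combo score (ties by interaction score, then input order).
#'
#' @param ligands a list of `conformer_set`s.
#' @param phore a `pharmacophore`.
#' @param receptor the source `mol_structure` (optional; omit to skip
#'   placement and clash filtering).
#' @param params an [hp_params()] list.
#' @param top_n rows reported (default 100).
#' @return a tibble: `rank`, `name`, `conf`, `T_shape`, `T_color`,
#'   `S_combo`, `interaction_score`, `clash_count`, `hbond_count`.
#' @export
screen_library <- function(ligands, phore, receptor = NULL,
                           params = hp_params(), top_n = 100) {
  if (length(ligands) == 0) {
    warning("empty ligand stream", call. = FALSE)
    return(tibble::tibble(
      rank = integer(), name = character(), conf = integer(),
      T_shape = double(), T_color = double(), S_combo = double(),
      interaction_score = double(), clash_count = integer(),
      hbond_count = integer()
    ))
  }
  rows <- purrr::imap_dfr(ligands, function(cs, i) {
    fit <- align_best_conformer(cs, phore, params)
    row <- tidy(fit)[, c("name", "conf", "T_shape", "T_color", "S_combo")]
    if (!is.null(receptor)) {
      pose <- place_in_receptor(fit, cs, receptor, params)
      row$interaction_score <- pose$interaction_score
      row$clash_count <- pose$clash_count
      row$hbond_count <- pose$hbond_count
    } else {
      row$interaction_score <- NA_real_
      row$clash_count <- 0L
      row$hbond_count <- NA_integer_
    }
    row$input_order <- i
    row
  })
  rows <- dplyr::filter(rows, .data$clash_count == 0)
  rows <- dplyr::arrange(
    rows, dplyr::desc(.data$S_combo),
    .data$interaction_score, .data$input_order
  )
  rows <- dplyr::mutate(utils::head(rows, top_n), rank = dplyr::row_number(),
    .before = 1
  )
  dplyr::select(rows, -"input_order")
}
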