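# Run configuration: every tunable in one place, with precedence
# CLI flag > config file > defaults (resolved by hp_resolve_params).

#' Pipeline parameters
#'
#' Collects every tunable of the extraction / alignment / screening pipeline
#' with its default. Values are Angstrom unless noted.
#'
#' @param burial_threshold minimum burial fraction `b` for a hotspot base.
#' @param min_buried_area minimum absolute buried base area (A^2); guards
#'   against flagging tiny bases whose fractional burial is high but whose
#'   actual contact patch is small.
#' @param hbond_dist donor-acceptor heavy-atom distance cutoff.
#' @param hbond_angle minimum D-H...A angle in degrees, applied only when the
#'   donor hydrogen is present in the structure.
#' @param include_waters include ordered-water bridged hydrogen bonds.
#' @param cluster_cutoff single-linkage cutoff joining neighbouring features;
#'   stacked adjacent bases sit ~3.4-4.0 A apart, so a dinucleotide hotspot
#'   forms one cluster at the default.
#' @param stack_dist,stack_angle ring-centroid distance cutoff and maximum
#'   inter-plane angle (deg) for annotating aromatic stacking partners.
#' @param sasa_probe,sasa_points probe radius and sphere sample count for
#'   accessibility.
#' @param gaussian_p Gaussian amplitude (dimensionless, > 1 so the
#'   volume-matching exponent exists).
#' @param shape_radius uniform heavy-atom radius for shape overlap.
#' @param color_radius radius of typed color features.
#' @param n_random_starts extra random-rotation starts beyond the 4 inertial
#'   axis flips.
#' @param color_weight weight of color overlap in the alignment objective.
#' @param opt_tol relative convergence tolerance of the simplex optimizer.
#' @param clash_tol pair distance below `(r_i + r_j) - clash_tol` counts as a
#'   steric clash.
#' @param interaction_cutoff pair cutoff for the simplified interaction score.
#' @param dedup_threshold mutual combo-score threshold above which two library
#'   pharmacophores are considered duplicates.
#' @param hist_bins histogram bins for selectivity profiles (on `[0, 1]`).
#' @param n_conformers_max maximum conformers retained per molecule.
#' @param rmsd_dedup heavy-atom RMSD threshold for conformer deduplication.
#' @param seed integer seed for all stochastic stages.
#' @return a named list of class `hp_params`.
#' @export
hp_params <- function(burial_threshold = 0.75,
                      min_buried_area = 40,
                      hbond_dist = 3.5,
                      hbond_angle = 120,
                      include_waters = TRUE,
                      cluster_cutoff = 4.5,
                      stack_dist = 5.5,
                      stack_angle = 30,
                      sasa_probe = 1.4,
                      sasa_points = 1920,
                      gaussian_p = 2.7,
                      shape_radius = 1.7,
                      color_radius = 1.0,
                      n_random_starts = 8,
                      color_weight = 1.0,
                      opt_tol = 1e-6,
                      clash_tol = 0.4,
                      interaction_cutoff = 6.0,
                      dedup_threshold = 0.98,
                      hist_bins = 50,
                      n_conformers_max = 200,
                      rmsd_dedup = 0.5,
                      seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$gaussian_p > 1, p$shape_radius > 0, p$color_radius > 0)
  structure(p, class = "hp_params")
}

#' Resolve parameters from defaults, a config file, and overrides
#'
#' Precedence: explicit overrides (e.g. CLI flags) > `key = value` config
#' file > defaults. The resolved list records the provenance of each value.
#'
#' @param config_file optional path to a flat `key = value` file.
#' @param overrides named list of explicit settings.
#' @return an `hp_params` list with a `provenance` attribute.
#' @export
hp_resolve_params <- function(config_file = NULL, overrides = list()) {
  p <- hp_params()
  prov <- stats::setNames(rep("default", length(p)), names(p))
  if (!is.null(config_file)) {
    lines <- grep("^\\s*(#|$)", readLines(config_file), invert = TRUE, value = TRUE)
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      if (!key %in% names(p)) {
        warning("unknown config key: ", key, call. = FALSE)
        next
      }
      val <- trimws(paste(kv[-1], collapse = "="))
      p[[key]] <- if (is.logical(hp_params()[[key]])) as.logical(val) else as.numeric(val)
      prov[key] <- "config_file"
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(p)) stop("unknown parameter: ", key, call. = FALSE)
    p[[key]] <- overrides[[key]]
    prov[key] <- "override"
  }
  attr(p, "provenance") <- prov
  class(p) <- "hp_params"
  p
}

#' @export
print.hp_params <- function(x, ...) {
  cat("<hp_params>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
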