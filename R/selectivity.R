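# Pharmacophore libraries, compound selectivity profiles, and the 2-D map of
# pharmacophore space.

#' Build a pharmacophore library from many complexes
#'
#' Runs extraction on each input (model 1 only for ensembles by default),
#' then deduplicates: first by provenance identity (source, model, residue
#' set), then by mutual combo score at least `dedup_threshold` (the first
#' entry by sorted source id survives). Per-file failures are logged, not
#' fatal; if every input fails the error lists the per-file reasons.
#'
#' @param inputs character vector of structure paths, or a list of
#'   `pharmacophore` objects / `mol_structure`s.
#' @param params an [hp_params()] list.
#' @param all_models extract from every model of an ensemble.
#' @param dedup apply the similarity dedup pass (provenance dedup always
#'   runs).
#' @return a `phore_library`: list with `entries` (named pharmacophores) and
#'   `log` (tibble of per-input outcomes).
#' @export
build_library <- function(inputs, params = hp_params(), all_models = FALSE,
                          dedup = TRUE) {
  entries <- list()
  log_rows <- list()
  note <- function(input, status, detail = "") {
    log_rows[[length(log_rows) + 1L]] <<- tibble::tibble(
      input = input, status = status, detail = detail
    )
  }
  harvest <- function(structure, label) {
    models <- if (all_models) seq_len(attr(structure, "n_models")) else 1L
    for (m in models) {
      ph <- extract_pharmacophores(structure, model_index = m, params = params)
      if (length(ph) == 0) {
        note(label, "empty", paste("model", m, ": no buried base"))
      }
      for (p in ph) entries[[length(entries) + 1L]] <<- p
    }
  }
  for (inp in inputs) {
    if (inherits(inp, "pharmacophore")) {
      entries[[length(entries) + 1L]] <- inp
      note(inp$provenance$source_id, "ok", "pre-extracted")
    } else if (inherits(inp, "mol_structure")) {
      tryCatch(harvest(inp, attr(inp, "source_id")),
        error = function(e) note(attr(inp, "source_id"), "error", conditionMessage(e))
      )
    } else {
      tryCatch(harvest(read_complex(inp), inp),
        error = function(e) note(inp, "error", conditionMessage(e))
      )
    }
  }
  if (length(entries) == 0 && length(log_rows) > 0) {
    fl <- dplyr::bind_rows(log_rows)
    if (all(fl$status == "error")) {
      stop(
        "all library inputs failed:\n",
        paste(" ", fl$input, "->", fl$detail, collapse = "\n"),
        call. = FALSE
      )
    }
  }

  ids <- vapply(entries, function(p) {
    paste0(
      p$provenance$source_id, "_m", p$provenance$model_index, "_",
      paste(p$provenance$residues, collapse = "+")
    )
  }, character(1))
  keep <- !duplicated(ids)
  if (any(!keep)) {
    for (i in which(!keep)) note(ids[i], "dedup_provenance", "identical provenance")
  }
  entries <- entries[keep]
  ids <- ids[keep]
  ord <- order(ids)
  entries <- entries[ord]
  ids <- ids[ord]

  if (isTRUE(dedup) && length(entries) > 1) {
    drop <- rep(FALSE, length(entries))
    for (i in seq_along(entries)) {
      if (drop[i]) next
      for (j in seq_along(entries)) {
        if (j <= i || drop[j]) next
        s_ij <- phore_similarity(entries[[i]], entries[[j]], params)
        s_ji <- phore_similarity(entries[[j]], entries[[i]], params)
        if (min(s_ij, s_ji) >= params$dedup_threshold) {
          drop[j] <- TRUE
          note(ids[j], "dedup_similarity", sprintf(
            "duplicate of %s (S=%.3f)", ids[i], min(s_ij, s_ji)
          ))
        }
      }
    }
    entries <- entries[!drop]
    ids <- ids[!drop]
  }
  names(entries) <- ids
  log <- if (length(log_rows)) {
    dplyr::bind_rows(log_rows)
  } else {
    tibble::tibble(input = character(), status = character(), detail = character())
  }
  structure(list(entries = entries, log = log), class = "phore_library")
}

#' @export
print.phore_library <- function(x, ...) {
  cat("<phore_library> ", length(x$entries), " unique pharmacophore(s)\n", sep = "")
  invisible(x)
}

#' @export
length.phore_library <- function(x) length(x$entries)

# directed combo score of pharmacophore p aligned onto q
phore_similarity <- function(p, q, params = hp_params()) {
  probe <- phore_pseudo_molecule(p)
  align_to_pharmacophore(probe, q, conf = 1L, params = params)$S_combo
}

#' Write / read a library as a directory of JSON files plus manifest
#'
#' @param library a `phore_library`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(library$entries)) {
    write_pharmacophore(library$entries[[id]], file.path(dir, paste0(id, ".json")))
  }
  utils::write.table(
    data.frame(
      id = names(library$entries),
      file = paste0(names(library$entries), ".json")
    ),
    file.path(dir, "manifest.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}

#' @rdname write_library
#' @export
read_library <- function(dir) {
  manifest <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest)) stop("no manifest.tsv in ", dir, call. = FALSE)
  man <- utils::read.table(manifest, sep = "\t", header = TRUE)
  if (nrow(man) == 0) stop("empty library: ", dir, call. = FALSE)
  entries <- lapply(file.path(dir, man$file), read_pharmacophore)
  names(entries) <- man$id
  structure(
    list(entries = entries, log = tibble::tibble(
      input = man$id, status = "loaded", detail = ""
    )),
    class = "phore_library"
  )
}

#' Selectivity profile of a compound against a pharmacophore library
#'
#' Aligns every conformer against every library entry and keeps the best
#' combo score per entry, with a histogram of the score distribution.
#'
#' @param cs a `conformer_set`.
#' @param library a `phore_library`.
#' @param params an [hp_params()] list.
#' @param annotate named character vector marking entries of interest
#'   (e.g. `c(target = "msi1_m1_106+107")`).
#' @return a `selectivity_profile`: `scores` tibble (entry, `S_combo`,
#'   `T_shape`, `T_color`, best conformer, rank), histogram counts, compound
#'   id.
#' @export
profile_compound <- function(cs, library, params = hp_params(),
                             annotate = character()) {
  if (length(library$entries) == 0) stop("empty library", call. = FALSE)
  scores <- purrr::imap_dfr(library$entries, function(phore, id) {
    fit <- align_best_conformer(cs, phore, params)
    tibble::tibble(
      entry = id, conf = fit$conf, T_shape = fit$T_shape,
      T_color = fit$T_color, S_combo = fit$S_combo
    )
  })
  scores <- dplyr::arrange(scores, dplyr::desc(.data$S_combo))
  scores$rank <- seq_len(nrow(scores))
  scores$label <- if (length(annotate)) {
    names(annotate)[match(scores$entry, annotate)]
  } else {
    NA_character_
  }
  breaks <- seq(0, 1, length.out = params$hist_bins + 1)
  hist_counts <- as.integer(table(cut(scores$S_combo, breaks, include.lowest = TRUE)))
  structure(
    list(
      compound = cs$name, scores = scores,
      histogram = tibble::tibble(
        lower = breaks[-length(breaks)], upper = breaks[-1],
        count = hist_counts
      )
    ),
    class = "selectivity_profile"
  )
}

#' @export
print.selectivity_profile <- function(x, ...) {
  cat(
    "<selectivity_profile> ", x$compound, " vs ", nrow(x$scores),
    " pharmacophore(s); top: ", x$scores$entry[1],
    sprintf(" (S_combo %.3f)\n", x$scores$S_combo[1]),
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.selectivity_profile <- function(x, ...) x$scores

#' @export
glance.selectivity_profile <- function(x, ...) {
  tibble::tibble(
    compound = x$compound, n_entries = nrow(x$scores),
    best_entry = x$scores$entry[1], best_score = x$scores$S_combo[1],
    median_score = stats::median(x$scores$S_combo)
  )
}

#' All-versus-all pharmacophore distance matrix
#'
#' `d(P, Q) = 1 - (S(P->Q) + S(Q->P)) / 2`, where `S(P->Q)` is the combo
#' score of P's pseudo-molecule aligned onto Q. Averaging the two directions
#' enforces symmetry; the diagonal is 0 by construction. An alignment
#' failure records distance 1 with a flag.
#'
#' @param library a `phore_library`.
#' @param params an [hp_params()] list.
#' @return a symmetric matrix with entry ids as dimnames; failed pairs (if
#'   any) listed in the `failed` attribute.
#' @export
pairwise_distance_matrix <- function(library, params = hp_params()) {
  n <- length(library$entries)
  if (n < 2) stop("need at least 2 library entries", call. = FALSE)
  ids <- names(library$entries)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  failed <- character()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- tryCatch(
        {
          s_ij <- phore_similarity(library$entries[[i]], library$entries[[j]], params)
          s_ji <- phore_similarity(library$entries[[j]], library$entries[[i]], params)
          1 - (s_ij + s_ji) / 2
        },
        error = function(e) {
          failed <<- c(failed, paste(ids[i], ids[j]))
          1
        }
      )
      D[i, j] <- D[j, i] <- min(1, max(0, d))
    }
  }
  attr(D, "failed") <- failed
  D
}

#' Embed a distance matrix in 2-D by metric MDS
#'
#' Classical (Torgerson) scaling provides the initial configuration, refined
#' by stress majorization (SMACOF, uniform weights). Raw stress
#' `sum (d_ij - delta_ij)^2` never increases across majorization steps; the
#' loop stops when the relative improvement drops below `tol`. Coordinates
#' are centered at the origin.
#'
#' @param D symmetric distance matrix (zero diagonal).
#' @param dim embedding dimension (default 2).
#' @param seed stored for provenance; the algorithm is deterministic.
#' @param max_iter,tol majorization controls.
#' @return a `phore_map`: `coords` tibble (`id`, `x`, `y`), `stress` (raw),
#'   `stress_norm` (stress-1), iteration trace, and the input `D`.
#' @export
mds_embed <- function(D, dim = 2, seed = 1L, max_iter = 500, tol = 1e-12) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 points to embed", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric", call. = FALSE)
  X <- stats::cmdscale(D, k = dim)
  if (ncol(X) < dim) { # degenerate: pad with zeros
    X <- cbind(X, matrix(0, n, dim - ncol(X)))
  }
  edist <- function(X) {
    as.matrix(stats::dist(X))
  }
  raw_stress <- function(X) {
    E <- edist(X)
    sum((E[upper.tri(E)] - D[upper.tri(D)])^2)
  }
  trace <- numeric(0)
  s_old <- raw_stress(X)
  trace <- s_old
  for (it in seq_len(max_iter)) {
    E <- edist(X)
    ratio <- ifelse(E > 1e-12, D / E, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X_new <- B %*% X / n
    s_new <- raw_stress(X_new)
    X <- X_new
    trace <- c(trace, s_new)
    if (s_old - s_new < tol * max(s_old, 1e-300)) {
      s_old <- s_new
      break
    }
    s_old <- s_new
  }
  X <- sweep(X, 2, colMeans(X))
  denom <- sum(D[upper.tri(D)]^2)
  structure(
    list(
      coords = tibble::tibble(
        id = rownames(D) %||% as.character(seq_len(n)),
        x = X[, 1], y = if (dim >= 2) X[, 2] else 0
      ),
      stress = s_old,
      stress_norm = if (denom > 0) sqrt(s_old / denom) else 0,
      trace = trace, D = D, seed = seed
    ),
    class = "phore_map"
  )
}

#' @export
print.phore_map <- function(x, ...) {
  cat(sprintf(
    "<phore_map> %d points in 2-D; raw stress %.3g (normalized %.3g)\n",
    nrow(x$coords), x$stress, x$stress_norm
  ))
  invisible(x)
}

#' @export
tidy.phore_map <- function(x, ...) x$coords

#' @export
glance.phore_map <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$coords), stress = x$stress, stress_norm = x$stress_norm,
    iterations = length(x$trace) - 1L
  )
}
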