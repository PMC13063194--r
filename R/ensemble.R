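# Conformational-ensemble pipeline: featurize frames, reduce dimensionality,
# cluster with Gaussian mixtures, extract representative conformations by
# coordinate averaging, and rank conformers by total interaction energy.

#' Flatten trajectory coordinates into a frame-by-feature matrix
#'
#' @param trajectory Multi-frame atom tibble.
#' @param selection As in [rmsd()].
#' @param align Superpose every frame onto the first (over the selection)
#'   before flattening.
#' @return Numeric matrix, one row per frame, `3 * n_selected` columns.
#' @export
featurize <- function(trajectory, selection = "heavy", align = TRUE) {
  frames <- sort(unique(trajectory$frame))
  first <- dplyr::filter(trajectory, .data$frame == frames[1])
  idx <- select_atom_idx(first, selection)
  if (length(idx) == 0) abort("argument error: empty atom selection")
  ref <- coords_matrix(first)
  rows <- map(frames, function(f) {
    m <- coords_matrix(dplyr::filter(trajectory, .data$frame == f))
    if (align) m <- kabsch_superpose(m, ref, idx)$coords
    as.numeric(t(m[idx, , drop = FALSE]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- frames
  out
}

#' Drop invalid frames from a trajectory
#'
#' Removes frames with non-finite coordinates or with a topology (atom count
#' or atom-name sequence) different from the first valid frame.
#'
#' @param trajectory Multi-frame atom tibble.
#' @return The filtered trajectory, with attribute `dropped`: a tibble of
#'   removed frame indices and reasons.
#' @export
filter_frames <- function(trajectory) {
  frames <- sort(unique(trajectory$frame))
  ref_key <- NULL
  dropped <- list()
  keep <- logical(length(frames))
  for (i in seq_along(frames)) {
    s <- dplyr::filter(trajectory, .data$frame == frames[i])
    if (!all(is.finite(s$x) & is.finite(s$y) & is.finite(s$z))) {
      dropped[[length(dropped) + 1]] <-
        tibble(frame = frames[i], reason = "non-finite coordinates")
      next
    }
    key <- paste(s$elety, collapse = "|")
    if (is.null(ref_key)) ref_key <- key
    if (!identical(key, ref_key)) {
      dropped[[length(dropped) + 1]] <-
        tibble(frame = frames[i], reason = "topology mismatch")
      next
    }
    keep[i] <- TRUE
  }
  if (!any(keep)) abort("all frames dropped: no valid frames remain")
  out <- dplyr::filter(trajectory, .data$frame %in% frames[keep])
  attr(out, "dropped") <- if (length(dropped) > 0) {
    list_rbind(dropped)
  } else {
    tibble(frame = integer(), reason = character())
  }
  out
}

#' Reduce a feature matrix to a low-dimensional embedding
#'
#' `"linear_projection"` is principal-component projection ([prcomp]);
#' `"neighbor_graph_nonlinear"` is an isomap-style embedding: a symmetrised
#' k-nearest-neighbour graph, graph-geodesic distances, and classical
#' multidimensional scaling. Both are deterministic for fixed input; the seed
#' is recorded for provenance.
#'
#' @param matrix Frame-by-feature matrix from [featurize()].
#' @param method `"linear_projection"` or `"neighbor_graph_nonlinear"`.
#' @param n_dims Embedding dimensionality.
#' @param seed Integer, recorded as an attribute.
#' @param n_neighbors Neighbourhood size for the graph method.
#' @return Frame-by-`n_dims` matrix with attribute `seed`.
#' @export
reduce_dimensionality <- function(matrix,
                                  method = c(
                                    "linear_projection",
                                    "neighbor_graph_nonlinear"
                                  ),
                                  n_dims = 2, seed = 1, n_neighbors = 15) {
  method <- match.arg(method)
  n <- nrow(matrix)
  if (n_dims < 1 || n_dims >= ncol(matrix)) {
    abort("argument error: need 1 <= n_dims < feature count")
  }
  if (n < n_dims + 1) {
    abort("argument error: fewer frames than n_dims + 1")
  }
  emb <- if (method == "linear_projection") {
    p <- prcomp(matrix, center = TRUE, scale. = FALSE)
    p$x[, seq_len(n_dims), drop = FALSE]
  } else {
    d <- as.matrix(dist(matrix))
    k <- min(n_neighbors, n - 1)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1)]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
    g <- igraph::graph_from_adjacency_matrix(
      d * adj,
      mode = "undirected", weighted = TRUE
    )
    # bridge disconnected neighbourhood components with their closest pair
    comp <- igraph::components(g)
    while (comp$no > 1) {
      i1 <- which(comp$membership == 1)
      i2 <- which(comp$membership != 1)
      sub <- d[i1, i2, drop = FALSE]
      w <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      g <- igraph::add_edges(g, c(i1[w[1]], i2[w[2]]),
        weight = min(sub)
      )
      comp <- igraph::components(g)
    }
    geo <- igraph::distances(g)
    cmdscale(geo, k = n_dims)
  }
  rownames(emb) <- rownames(matrix)
  colnames(emb) <- paste0("dim", seq_len(ncol(emb)))
  attr(emb, "seed") <- seed
  emb
}

#' Fit a Gaussian mixture model to an embedding
#'
#' Wraps [mclust::Mclust()]. With `k = "auto"` the number of components is
#' chosen by the Bayesian information criterion over 1..`k_max` and the
#' criterion trace is kept.
#'
#' @param embedding Frame-by-dimension matrix from [reduce_dimensionality()].
#' @param k Integer number of clusters, or `"auto"`.
#' @param seed Integer seed for the EM initialisation.
#' @param k_max Upper end of the `k = "auto"` search range.
#' @return An object of class `"ensemble_fit"`: `labels` (1-based per-frame
#'   cluster index), `n_clusters`, `embedding`, `seed`, `responsibilities`,
#'   `criterion_trace` (BIC by k), and the underlying `model`.
#' @export
fit_gmm <- function(embedding, k = "auto", seed = 1, k_max = 8) {
  n <- nrow(embedding)
  if (!identical(k, "auto")) {
    if (k > n) abort("argument error: k exceeds the number of frames")
    if (k < 1) abort("argument error: k must be >= 1")
  }
  set.seed(seed)
  g <- if (identical(k, "auto")) seq_len(min(k_max, n - 1)) else k
  model <- Mclust(embedding, G = g, verbose = FALSE)
  if (is.null(model)) abort("mixture fit failed to converge for requested k")
  z <- model$z
  if (is.null(z)) z <- matrix(1, nrow = n, ncol = 1)
  trace <- NULL
  if (identical(k, "auto")) {
    bic <- model$BIC
    trace <- tibble(
      k = as.integer(rownames(bic)),
      bic = apply(matrix(bic, nrow = nrow(bic)), 1, max, na.rm = TRUE)
    )
  }
  structure(
    list(
      labels = as.integer(model$classification),
      n_clusters = model$G,
      embedding = embedding,
      seed = seed,
      responsibilities = z,
      criterion_trace = trace,
      model = model
    ),
    class = "ensemble_fit"
  )
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf(
    "Gaussian-mixture ensemble model: %d frames, %d clusters (seed %d)\n",
    length(x$labels), x$n_clusters, x$seed
  ))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @describeIn fit_gmm Per-frame tidy summary: frame, embedding coordinates,
#'   cluster label and assignment uncertainty.
#' @param x An `"ensemble_fit"` object.
#' @param ... Unused.
#' @export
tidy.ensemble_fit <- function(x, ...) {
  emb <- as_tibble(as.data.frame(x$embedding))
  mutate(emb,
    frame = as.integer(rownames(x$embedding) %||% seq_along(x$labels)),
    cluster = x$labels,
    uncertainty = 1 - apply(x$responsibilities, 1, max),
    .before = 1
  )
}

#' @describeIn fit_gmm One-row model summary.
#' @export
glance.ensemble_fit <- function(x, ...) {
  tibble(
    n_frames = length(x$labels),
    n_clusters = x$n_clusters,
    log_lik = x$model$loglik,
    bic = as.numeric(x$model$bic),
    seed = x$seed
  )
}

#' Representative conformation of each cluster by coordinate averaging
#'
#' For every cluster, member frames are (optionally) superposed onto the
#' first member and each atom's coordinates are averaged arithmetically.
#'
#' @param trajectory Multi-frame atom tibble the model was fitted on (same
#'   frame order as the embedding).
#' @param model An `"ensemble_fit"` object (or an integer vector of per-frame
#'   labels).
#' @param align Superpose member frames before averaging.
#' @param selection Fit selection used for the superposition.
#' @return Atom tibble with one pseudo-frame per cluster (`frame` = cluster
#'   index, column `cluster` added, `n_members` attribute per row).
#' @export
representative_conformations <- function(trajectory, model, align = TRUE,
                                         selection = "heavy") {
  labels <- if (inherits(model, "ensemble_fit")) model$labels else model
  frames <- sort(unique(trajectory$frame))
  if (length(labels) != length(frames)) {
    abort("label count does not match the number of frames")
  }
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- frames[labels == cl]
    if (length(members) == 0) {
      warn(sprintf("cluster %d is empty; skipped", cl))
      next
    }
    first <- dplyr::filter(trajectory, .data$frame == members[1])
    idx <- select_atom_idx(first, selection)
    mats <- map(members, function(f) {
      m <- coords_matrix(dplyr::filter(trajectory, .data$frame == f))
      if (align && length(members) > 1) {
        m <- kabsch_superpose(m, coords_matrix(first), idx)$coords
      }
      m
    })
    avg <- Reduce(`+`, mats) / length(mats)
    rep_str <- mutate(first,
      frame = cl, x = avg[, 1], y = avg[, 2], z = avg[, 3],
      cluster = cl, n_members = length(members)
    )
    out[[length(out) + 1]] <- rep_str
  }
  list_rbind(out)
}

#' Rank conformers by total interaction energy
#'
#' @param energies Named numeric vector or two-column data frame
#'   (`conformer`, `energy`) of total interaction energies in kcal/mol.
#' @return Tibble sorted ascending by energy (ties broken by conformer label)
#'   with logical columns `is_min` and `is_max`.
#' @export
rank_conformers <- function(energies) {
  if (is.data.frame(energies)) {
    tbl <- tibble(
      conformer = as.character(energies[[1]]),
      energy = as.numeric(energies[[2]])
    )
  } else {
    if (length(energies) == 0) abort("argument error: empty energy map")
    tbl <- tibble(
      conformer = names(energies) %||% as.character(seq_along(energies)),
      energy = as.numeric(energies)
    )
  }
  if (nrow(tbl) == 0) abort("argument error: empty energy map")
  tbl <- dplyr::arrange(tbl, .data$energy, .data$conformer)
  mutate(tbl,
    is_min = .data$energy == min(.data$energy) &
      row_number() == 1,
    is_max = .data$energy == max(.data$energy) &
      row_number() == n()
  )
}
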