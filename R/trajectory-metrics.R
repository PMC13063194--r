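# Superposition and trajectory descriptors: Kabsch least-squares fitting,
# RMSD time series, delta-RMSD over a window, per-residue RMSF.

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body transform (proper rotation + translation) minimising
#' the RMSD of `mobile[fit_selection, ]` onto `reference[fit_selection, ]`.
#'
#' @param mobile,reference Numeric n x 3 coordinate matrices in atom
#'   correspondence.
#' @param fit_selection Row indices used to determine the fit (default all).
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   and `coords`, the whole mobile set transformed.
#' @export
kabsch_superpose <- function(mobile, reference,
                             fit_selection = seq_len(nrow(mobile))) {
  if (length(fit_selection) < 3) {
    abort("numerical-degeneracy error: need at least 3 fit atoms")
  }
  m <- mobile[fit_selection, , drop = FALSE]
  r <- reference[fit_selection, , drop = FALSE]
  cm <- colMeans(m)
  cr <- colMeans(r)
  h <- crossprod(sweep(m, 2, cm), sweep(r, 2, cr))
  sv <- svd(h)
  if (sv$d[2] < 1e-10) {
    abort("numerical-degeneracy error: fit selection is collinear")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.numeric(rot %*% cm)
  coords <- sweep(tcrossprod(mobile, rot), 2, trans, "+")
  list(rotation = rot, translation = trans, coords = coords)
}

coords_matrix <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

select_atom_idx <- function(atoms, selection) {
  if (is.numeric(selection)) {
    return(as.integer(selection))
  }
  switch(selection,
    all = seq_len(nrow(atoms)),
    heavy_atoms = ,
    heavy = which(atoms$element != "H"),
    abort(sprintf("unknown selection '%s'", selection))
  )
}

#' Root-mean-square deviation between two frames
#'
#' @param frame,reference Single-frame atom tibbles in atom correspondence.
#' @param selection `"heavy"` (non-hydrogen, the default), `"all"`, or an
#'   integer index vector into the atom rows.
#' @param fit Superpose `frame` onto `reference` (over the selection) before
#'   measuring.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame, reference, selection = "heavy", fit = TRUE) {
  if (nrow(frame) != nrow(reference)) {
    abort("correspondence error: frames differ in atom count")
  }
  idx <- select_atom_idx(frame, selection)
  m <- coords_matrix(frame)
  r <- coords_matrix(reference)
  if (fit) {
    m <- kabsch_superpose(m, r, idx)$coords
  }
  sqrt(mean(rowSums((m[idx, , drop = FALSE] - r[idx, , drop = FALSE])^2)))
}

#' RMSD time series over a trajectory
#'
#' Per-frame RMSD against a fixed reference.
#'
#' @param trajectory Multi-frame atom tibble.
#' @param reference `"first_frame"` or a single-frame atom tibble.
#' @param selection,fit As in [rmsd()].
#' @return Tibble with `frame`, `time_ns`, `rmsd`.
#' @export
rmsd_series <- function(trajectory, reference = "first_frame",
                        selection = "heavy", fit = TRUE) {
  frames <- sort(unique(trajectory$frame))
  ref <- if (is.data.frame(reference)) {
    reference
  } else {
    dplyr::filter(trajectory, .data$frame == frames[1])
  }
  list_rbind(map(frames, function(f) {
    s <- dplyr::filter(trajectory, .data$frame == f)
    tibble(
      frame = f,
      time_ns = s$time_ns[1],
      rmsd = rmsd(s, ref, selection = selection, fit = fit)
    )
  }))
}

#' Spread of an RMSD series within a time window
#'
#' The difference between the highest and lowest RMSD value observed at times
#' `t_start <= t <= t_end`.
#'
#' @param series Tibble from [rmsd_series()].
#' @param t_start,t_end Window bounds in ns (inclusive).
#' @return max - min of the windowed values, in Angstrom.
#' @export
delta_rmsd <- function(series, t_start, t_end) {
  v <- series$rmsd[series$time_ns >= t_start & series$time_ns <= t_end]
  if (length(v) == 0) abort("argument error: window contains no frames")
  max(v) - min(v)
}

#' Per-residue root-mean-square fluctuation
#'
#' For every selected atom, the square root of the time-mean squared
#' displacement about its time-mean position, after per-frame superposition;
#' residue values are the mean over the residue's selected atoms. With
#' `fit_reference = "mean_structure"` frames are first aligned to the first
#' frame, the mean structure is computed, and frames are re-aligned to it.
#'
#' @param trajectory Multi-frame atom tibble.
#' @param selection As in [rmsd()].
#' @param fit_reference `"mean_structure"` or `"first_frame"`.
#' @param fit Set `FALSE` to skip superposition entirely.
#' @return Tibble with `chain`, `resno`, `insert`, `resid`, `rmsf`.
#' @export
rmsf <- function(trajectory, selection = "heavy",
                 fit_reference = c("mean_structure", "first_frame"),
                 fit = TRUE) {
  fit_reference <- match.arg(fit_reference)
  frames <- sort(unique(trajectory$frame))
  first <- dplyr::filter(trajectory, .data$frame == frames[1])
  if (length(frames) < 2) {
    warn("single-frame trajectory: RMSF is identically zero")
  }
  idx <- select_atom_idx(first, selection)
  mats <- map(frames, function(f) {
    coords_matrix(dplyr::filter(trajectory, .data$frame == f))
  })
  if (fit) {
    ref <- mats[[1]]
    mats <- map(mats, ~ kabsch_superpose(.x, ref, idx)$coords)
    if (fit_reference == "mean_structure" && length(frames) > 1) {
      mean_mat <- Reduce(`+`, mats) / length(mats)
      mats <- map(mats, ~ kabsch_superpose(.x, mean_mat, idx)$coords)
    }
  }
  n_atoms <- nrow(mats[[1]])
  mean_pos <- Reduce(`+`, mats) / length(mats)
  msf <- Reduce(`+`, map(mats, ~ rowSums((.x - mean_pos)^2))) / length(mats)
  atom_rmsf <- sqrt(msf)
  per_atom <- mutate(first[idx, ], rmsf_atom = atom_rmsf[idx])
  summarise(
    group_by(per_atom, .data$chain, .data$resno, .data$insert, .data$resid),
    rmsf = mean(.data$rmsf_atom), .groups = "drop"
  )
}
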