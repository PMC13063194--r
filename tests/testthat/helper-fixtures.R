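# Shared fixtures, all built in code at test time.

toy_complex <- function(seed = 1, n_res = 5, contact_distance = 4) {
  pep <- make_peptide(n_res)
  lig <- make_steroid_like_ligand()
  cx <- make_complex(pep, lig$ligand,
    contact_distance = contact_distance, seed = seed
  )
  cx$region_map <- lig$region_map
  cx
}

ligand_atoms <- function(structure, resid = "LIG") {
  dplyr::filter(structure, .data$resid == !!resid)
}

protein_atoms <- function(structure) {
  dplyr::filter(structure, .data$kind == "amino_acid")
}

# random parameterized atom cloud for backend tests; atoms are kept at least
# min_sep apart so r^-12 terms stay well conditioned
random_atoms <- function(n, seed, spread = 8, serial_start = 1L,
                         min_sep = 2.0) {
  set.seed(seed)
  q <- stats::runif(n, -0.5, 0.5)
  pos <- matrix(stats::runif(3, 0, spread), ncol = 3)
  while (nrow(pos) < n) {
    cand <- stats::runif(3, 0, spread)
    d <- sqrt(rowSums(sweep(pos, 2, cand)^2))
    if (min(d) >= min_sep) pos <- rbind(pos, cand)
  }
  tibble::tibble(
    frame = 1L, time_ns = 0,
    eleno = serial_start + seq_len(n) - 1L,
    elety = paste0("X", seq_len(n)),
    element = sample(c("H", "C", "N", "O", "S"), n, replace = TRUE),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    chain = "A", resno = 1L, insert = "", resid = "XXX",
    kind = "other", charge = q - mean(q)
  )
}

# apply a random rigid motion (rotation + translation) to an atom tibble
rigid_motion <- function(atoms, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  rot <- diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
  tr <- stats::rnorm(3, 0, 10)
  m <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rot)
  atoms$x <- m[, 1] + tr[1]
  atoms$y <- m[, 2] + tr[2]
  atoms$z <- m[, 3] + tr[3]
  atoms
}

# trajectory with a hydrogen bond planted in exactly n_present of n_total
# frames (donor: backbone N of residue 2; acceptor: ligand O17)
make_occupancy_trajectory <- function(n_present, n_total, seed = 1) {
  cx <- toy_complex(seed = seed)
  s <- cx$structure
  don <- dplyr::filter(s, .data$resno == 2, .data$elety == "N")$eleno
  acc <- dplyr::filter(s, .data$elety == "O17")$eleno
  on_frame <- plant_hbond(s, don, acc, 2.9, 165, direction = c(0, 0, 1))
  off_frame <- plant_hbond(s, don, acc, 3.6, 165, direction = c(0, 0, 1))
  frames <- lapply(seq_len(n_total), function(f) {
    base <- if (f <= n_present) on_frame else off_frame
    dplyr::mutate(base, frame = f, time_ns = (f - 1) * 0.1)
  })
  list(
    trajectory = dplyr::bind_rows(frames),
    don = don, acc = acc
  )
}

# a tiny hand-written PDB: 3 residues x 5 atoms
toy_pdb_text <- function() {
  pep <- make_peptide(3)
  write_pdb(pep)
}
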