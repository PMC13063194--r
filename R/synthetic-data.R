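# Synthetic fixtures: idealized polypeptides, a rigid fused-ring
# steroid-like ligand with three labelled regions, parameterized complexes,
# clustered trajectories with planted labels, planted hydrogen-bond
# geometries, and synthetic docking poses. Everything is deterministic per
# seed and every planted quantity is returned so tests can use it as an
# oracle.

# idealized backbone geometry (Angstrom / degrees)
.GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.530,
  ang_n_ca_c = 111.0, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, ang_n_ca_cb = 110.5
)

# NeRF-style internal-coordinate placement: X bonded to c, with
# |X-c| = bond, angle(X, c, b) = angle, dihedral(X, c, b, a) = dihedral
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d <- c(
    -bond * cos(ang),
    bond * sin(ang) * cos(dih),
    bond * sin(ang) * sin(dih)
  )
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Generate an idealized polyalanine peptide
#'
#' A chain of alanine-like residues (backbone N, CA, C, O plus CB) built from
#' idealized bond lengths and angles at fixed backbone dihedrals. The
#' geometry is chemically plausible, not energy-minimized.
#'
#' @param n_residues Number of residues (>= 1).
#' @param chain_geometry `"extended"` (beta-strand dihedrals) or `"helix"`.
#' @param chain Chain identifier.
#' @param seed Recorded in the `seed` attribute (the geometry itself is
#'   deterministic).
#' @return Single-frame atom tibble, 5 heavy atoms per residue.
#' @export
make_peptide <- function(n_residues, chain_geometry = c("extended", "helix"),
                         chain = "A", seed = 1) {
  chain_geometry <- match.arg(chain_geometry)
  if (n_residues < 1) abort("argument error: n_residues must be >= 1")
  tor <- if (chain_geometry == "extended") {
    c(phi = -140, psi = 135)
  } else {
    c(phi = -57, psi = -47)
  }
  g <- .GEOM
  n_pos <- ca_pos <- c_pos <- vector("list", n_residues)
  n_pos[[1]] <- c(0, 0, 0)
  ca_pos[[1]] <- c(g$n_ca, 0, 0)
  th <- (180 - g$ang_n_ca_c) * pi / 180
  c_pos[[1]] <- ca_pos[[1]] + g$ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(n_residues)[-1]) {
    n_pos[[i]] <- place_atom(
      n_pos[[i - 1]], ca_pos[[i - 1]], c_pos[[i - 1]],
      g$c_n, g$ang_ca_c_n, tor[["psi"]]
    )
    ca_pos[[i]] <- place_atom(
      ca_pos[[i - 1]], c_pos[[i - 1]], n_pos[[i]],
      g$n_ca, g$ang_c_n_ca, 180
    )
    c_pos[[i]] <- place_atom(
      c_pos[[i - 1]], n_pos[[i]], ca_pos[[i]],
      g$ca_c, g$ang_n_ca_c, tor[["phi"]]
    )
  }
  rows <- list()
  serial <- 1L
  for (i in seq_len(n_residues)) {
    # carbonyl O anti to the next amide N (or at the trans position for the
    # C-terminal residue); CB placed off the backbone plane
    o_ref <- if (i < n_residues) n_pos[[i + 1]] else NULL
    o <- if (!is.null(o_ref)) {
      place_atom(
        n_pos[[i]], ca_pos[[i]], c_pos[[i]], g$c_o, g$ang_ca_c_o,
        tor[["psi"]] + 180
      )
    } else {
      place_atom(
        n_pos[[i]], ca_pos[[i]], c_pos[[i]], g$c_o, g$ang_ca_c_o, tor[["psi"]] + 180
      )
    }
    cb <- place_atom(
      o, c_pos[[i]], ca_pos[[i]], g$ca_cb, g$ang_n_ca_cb, -122
    )
    names_i <- c("N", "CA", "C", "O", "CB")
    el_i <- c("N", "C", "C", "O", "C")
    pos_i <- list(n_pos[[i]], ca_pos[[i]], c_pos[[i]], o, cb)
    for (k in 1:5) {
      rows[[length(rows) + 1]] <- tibble(
        frame = 1L, time_ns = 0,
        eleno = serial, elety = names_i[k], element = el_i[k],
        x = pos_i[[k]][1], y = pos_i[[k]][2], z = pos_i[[k]][3],
        chain = chain, resno = i, insert = "", resid = "ALA",
        kind = "amino_acid", charge = NA_real_
      )
      serial <- serial + 1L
    }
  }
  out <- list_rbind(rows)
  attr(out, "seed") <- seed
  out
}

# regular polygon vertices fused onto an edge (p1, p2), interior on the +x
# side of the edge; returns the n - 2 new vertices
fuse_polygon <- function(p1, p2, n_sides) {
  s <- sqrt(sum((p2 - p1)^2))
  mid <- (p1 + p2) / 2
  apothem <- s / (2 * tan(pi / n_sides))
  circ <- s / (2 * sin(pi / n_sides))
  edge_dir <- (p2 - p1) / s
  out_dir <- c(edge_dir[2], -edge_dir[1]) # rotate -90: +x side for a vertical edge
  if (out_dir[1] < 0) out_dir <- -out_dir
  center <- mid + apothem * out_dir
  a1 <- atan2(p1[2] - center[2], p1[1] - center[1])
  a2 <- atan2(p2[2] - center[2], p2[1] - center[1])
  angles <- a1 + (2 * pi / n_sides) * seq_len(n_sides - 1)
  # walk around in the direction that does not immediately hit p2
  step <- 2 * pi / n_sides
  dir_sign <- if (abs(Arg(exp(1i * (a1 + step - a2)))) < 1e-6) -1 else 1
  angles <- a1 + dir_sign * step * seq_len(n_sides - 1)
  vs <- lapply(angles, function(a) center + circ * c(cos(a), sin(a)))
  keep <- vapply(vs, function(v) sqrt(sum((v - p2)^2)) > 0.2, logical(1))
  vs[keep]
}

#' Generate a rigid steroid-like ligand with a three-region map
#'
#' A planar fused-ring mimic of the steroid nucleus: three fused
#' six-membered rings and one five-membered ring (17 carbons), with a ketone
#' oxygen `O3` on the first ring and a hydroxyl oxygen `O17` on the last.
#' The region map assigns the first ring (plus `O3`) to region `i`, the
#' middle ring atoms to `ii`, and the remaining rings (plus `O17`) to `iii`.
#'
#' @param template Ligand template name; only `"steroid"` is defined.
#' @param chain,resno,resid Identifiers for the ligand residue.
#' @param serial_start First atom serial number.
#' @return List with `ligand` (atom tibble, 19 heavy atoms) and `region_map`
#'   (validated [load_region_map()] result).
#' @export
make_steroid_like_ligand <- function(template = "steroid", chain = "X",
                                     resno = 901, resid = "LIG",
                                     serial_start = 9001) {
  if (!identical(template, "steroid")) {
    abort(sprintf("unknown ligand template '%s'", template))
  }
  side <- 1.54
  hex_angles <- (c(30, 90, 150, 210, 270, 330)) * pi / 180
  ring_a <- lapply(hex_angles, function(a) side * c(cos(a), sin(a)))
  centers <- list(
    c(sqrt(3) * side, 0), c(2 * sqrt(3) * side, 0)
  )
  ring_b <- lapply(hex_angles, function(a) centers[[1]] + side * c(cos(a), sin(a)))
  ring_c <- lapply(hex_angles, function(a) centers[[2]] + side * c(cos(a), sin(a)))
  dedupe <- function(new, seen) {
    Filter(function(v) {
      all(vapply(seen, function(s) sqrt(sum((s - v)^2)) > 0.2, logical(1)))
    }, new)
  }
  atoms <- ring_a
  ring_b_new <- dedupe(ring_b, atoms)
  atoms <- c(atoms, ring_b_new)
  ring_c_new <- dedupe(ring_c, atoms)
  atoms <- c(atoms, ring_c_new)
  # five-membered ring fused on the rightmost vertical edge of ring C
  p1 <- centers[[2]] + side * c(cos(pi / 6), sin(pi / 6))
  p2 <- centers[[2]] + side * c(cos(-pi / 6), sin(-pi / 6))
  pent_new <- fuse_polygon(p1, p2, 5)
  pent_new <- dedupe(pent_new, atoms)
  atoms <- c(atoms, pent_new)
  n_c <- length(atoms)
  # substituent oxygens: O3 outward from the leftmost ring-A vertex, O17
  # outward from the rightmost pentagon vertex
  left_idx <- which.min(vapply(atoms, `[`, numeric(1), 1))
  right_idx <- which.max(vapply(atoms, `[`, numeric(1), 1))
  o3 <- atoms[[left_idx]] + 1.23 * c(-1, 0)
  o17 <- atoms[[right_idx]] + 1.43 * c(1, 0)
  xy <- do.call(rbind, c(atoms, list(o3, o17)))
  names_all <- c(paste0("C", seq_len(n_c)), "O3", "O17")
  el_all <- c(rep("C", n_c), "O", "O")
  lig <- tibble(
    frame = 1L, time_ns = 0,
    eleno = serial_start + seq_len(n_c + 2L) - 1L,
    elety = names_all, element = el_all,
    x = xy[, 1], y = xy[, 2], z = 0,
    chain = chain, resno = resno, insert = "", resid = resid,
    kind = "ligand", charge = NA_real_
  )
  n_a <- 6L
  ring_a_names <- paste0("C", 1:6)
  ring_b_names <- paste0("C", seq(7, 6 + length(ring_b_new)))
  rest_names <- setdiff(paste0("C", seq_len(n_c)), c(ring_a_names, ring_b_names))
  region_map <- load_region_map(list(
    i = c(ring_a_names, "O3"),
    ii = ring_b_names,
    iii = c(rest_names, "O17")
  ), ligand = lig)
  list(ligand = lig, region_map = region_map)
}

#' Assemble a parameterized synthetic protein-ligand complex
#'
#' Places the ligand at an exact closest-atom contact distance from a chosen
#' residue (along the outward direction from the peptide) and assigns
#' per-residue zero-sum partial charges, yielding a structure fully
#' parameterized for the built-in pairwise backend.
#'
#' @param peptide Atom tibble from [make_peptide()].
#' @param ligand Atom tibble from [make_steroid_like_ligand()].
#' @param contact_resno Residue number of the contact residue.
#' @param contact_distance Requested closest-atom distance (Angstrom).
#' @param charge_scale Half-width of the uniform distribution charges are
#'   drawn from before per-residue centering.
#' @param seed Integer seed for the charge draw.
#' @return List with `structure` (peptide + ligand atom tibble), `params`
#'   ([backend_params()]), `ligand_resid`, `contact` (resno and achieved
#'   distance) and `seed`.
#' @export
make_complex <- function(peptide, ligand, contact_resno = NULL,
                         contact_distance = 4, charge_scale = 0.25,
                         seed = 1) {
  resnos <- sort(unique(peptide$resno))
  contact_resno <- contact_resno %||% resnos[ceiling(length(resnos) / 2)]
  target <- dplyr::filter(peptide, .data$resno == contact_resno)
  if (nrow(target) == 0) abort("contact residue not found in peptide")
  p_cent <- colMeans(coords_matrix(peptide))
  r_cent <- colMeans(coords_matrix(target))
  l_cent <- colMeans(coords_matrix(ligand))
  # candidate approach directions: away from the peptide centroid, then the
  # thinnest principal axis of the chain (out of the backbone plane), then
  # the coordinate axes; the first clash-free placement wins
  u0 <- r_cent - p_cent
  pc3 <- eigen(stats::cov(coords_matrix(peptide)))$vectors[, 3]
  candidates <- list(u0, pc3, -pc3, c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  candidates <- Filter(function(v) sqrt(sum(v^2)) > 1e-3, candidates)
  lig <- NULL
  for (u in candidates) {
    u <- u / sqrt(sum(u^2))
    lig_at <- function(t) {
      shift <- r_cent + t * u - l_cent
      mutate(ligand,
        x = .data$x + shift[1], y = .data$y + shift[2], z = .data$z + shift[3]
      )
    }
    gap <- function(t) min_atom_distance(target, lig_at(t)) - contact_distance
    t_star <- tryCatch(
      stats::uniroot(gap, c(0.01, 500), tol = 1e-12)$root,
      error = function(e) NULL
    )
    if (is.null(t_star)) next
    cand <- lig_at(t_star)
    if (min_atom_distance(peptide, cand) >= 0.8) {
      lig <- cand
      break
    }
  }
  if (is.null(lig)) {
    abort("placement error: steric overlap along every candidate direction")
  }
  # renumber ligand serials after the peptide if they clash
  if (length(intersect(lig$eleno, peptide$eleno)) > 0) {
    lig$eleno <- max(peptide$eleno) + seq_len(nrow(lig))
  }
  combined <- bind_rows(peptide, lig)
  set.seed(seed)
  res_key <- paste(combined$chain, combined$resno, combined$insert)
  for (k in unique(res_key)) {
    idx <- which(res_key == k)
    q <- stats::runif(length(idx), -charge_scale, charge_scale)
    combined$charge[idx] <- q - mean(q)
  }
  list(
    structure = combined,
    params = backend_params(),
    ligand_resid = lig$resid[1],
    contact = list(
      resno = contact_resno,
      distance = min_atom_distance(target, lig)
    ),
    seed = seed
  )
}

#' Generate a clustered synthetic trajectory with planted labels
#'
#' Builds `n_clusters` center conformations by rigidly translating the ligand
#' along cluster-specific offset vectors whose minimum pairwise distance is
#' `separation * noise_sigma`, then draws frames as a center plus isotropic
#' Gaussian coordinate noise. Frames are deterministically shuffled and the
#' planted labels returned.
#'
#' @param complex Output of [make_complex()] (or an atom tibble).
#' @param n_frames Total number of frames.
#' @param n_clusters Number of planted clusters.
#' @param separation Center separation in multiples of `noise_sigma`.
#' @param noise_sigma Isotropic per-coordinate noise (Angstrom).
#' @param time_step_ns Frame spacing for the `time_ns` column.
#' @param seed Integer seed.
#' @return List with `trajectory` (multi-frame atom tibble), `labels`
#'   (planted cluster per frame, in frame order) and `manifest` (seed,
#'   offsets, noise level).
#' @export
make_clustered_trajectory <- function(complex, n_frames = 300, n_clusters = 3,
                                      separation = 8, noise_sigma = 0.1,
                                      time_step_ns = 0.1, seed = 1) {
  if (separation <= 0) abort("argument error: separation must be > 0")
  if (noise_sigma <= 0) abort("argument error: noise_sigma must be > 0")
  base <- if (is.data.frame(complex)) complex else complex$structure
  base <- dplyr::filter(base, .data$frame == min(base$frame))
  set.seed(seed)
  dirs <- matrix(stats::rnorm(3 * n_clusters), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  if (n_clusters > 1) {
    pd <- as.matrix(dist(dirs))
    scale <- separation * noise_sigma / min(pd[upper.tri(pd)])
  } else {
    scale <- 0
  }
  offsets <- dirs * scale
  labels <- rep(seq_len(n_clusters), length.out = n_frames)
  labels <- sample(labels)
  lig_rows <- base$kind == "ligand"
  n_atoms <- nrow(base)
  frames <- map(seq_len(n_frames), function(f) {
    s <- mutate(base, frame = f, time_ns = (f - 1) * time_step_ns)
    off <- offsets[labels[f], ]
    s$x[lig_rows] <- s$x[lig_rows] + off[1]
    s$y[lig_rows] <- s$y[lig_rows] + off[2]
    s$z[lig_rows] <- s$z[lig_rows] + off[3]
    noise <- matrix(stats::rnorm(3 * n_atoms, 0, noise_sigma), ncol = 3)
    s$x <- s$x + noise[, 1]
    s$y <- s$y + noise[, 2]
    s$z <- s$z + noise[, 3]
    s
  })
  list(
    trajectory = list_rbind(frames),
    labels = labels,
    manifest = list(
      seed = seed, n_clusters = n_clusters, separation = separation,
      noise_sigma = noise_sigma, offsets = offsets
    )
  )
}

#' Plant an exact hydrogen-bond geometry
#'
#' Adjusts coordinates so that the donor-acceptor distance and the
#' donor-H-acceptor angle take the requested values exactly: the donor stays
#' fixed, its hydrogen is placed (or created, named `HD1`) at 1.01 Angstrom
#' along an outward direction, and the acceptor atom is moved into the
#' donor-hydrogen plane at the position satisfying both constraints.
#'
#' @param structure Atom tibble.
#' @param donor_serial,acceptor_serial Atom serial numbers.
#' @param distance Donor-acceptor distance (Angstrom).
#' @param angle Donor-H-acceptor angle (degrees).
#' @param direction Optional unit 3-vector for the donor-hydrogen direction;
#'   default points away from the frame centroid. Choose a clear direction
#'   (e.g. `c(0, 0, 1)` for a planar structure) to avoid incidental contacts
#'   with other atoms.
#' @return The modified structure; attribute `planted` records the geometry.
#' @export
plant_hbond <- function(structure, donor_serial, acceptor_serial,
                        distance, angle, direction = NULL) {
  f <- min(structure$frame)
  s <- structure
  di <- which(s$frame == f & s$eleno == donor_serial)
  ai <- which(s$frame == f & s$eleno == acceptor_serial)
  if (length(di) != 1 || length(ai) != 1) {
    abort("donor or acceptor serial not found")
  }
  d_pos <- c(s$x[di], s$y[di], s$z[di])
  if (is.null(direction)) {
    cent <- colMeans(coords_matrix(dplyr::filter(s, .data$frame == f)))
    u <- d_pos - cent
    if (sqrt(sum(u^2)) < 1e-6) u <- c(1, 0, 0)
  } else {
    u <- as.numeric(direction)
  }
  u <- u / sqrt(sum(u^2))
  w <- c(-u[2], u[1], 0)
  if (sqrt(sum(w^2)) < 1e-6) w <- c(0, 1, 0)
  w <- w / sqrt(sum(w^2))
  r <- 1.01
  th <- angle * pi / 180
  disc <- r^2 * cos(th)^2 - r^2 + distance^2
  if (disc < 0) abort("infeasible hydrogen-bond geometry")
  srt <- r * cos(th) + sqrt(disc)
  if (srt <= 0) abort("infeasible hydrogen-bond geometry")
  h_pos <- d_pos + r * u
  phi <- pi - th
  a_pos <- h_pos + srt * (cos(phi) * u + sin(phi) * w)
  # reuse an existing hydrogen bonded to the donor, else create one
  frame_rows <- which(s$frame == f)
  hmask <- s$element[frame_rows] == "H" &
    sqrt((s$x[frame_rows] - d_pos[1])^2 + (s$y[frame_rows] - d_pos[2])^2 +
      (s$z[frame_rows] - d_pos[3])^2) <= 1.3
  if (any(hmask)) {
    hi <- frame_rows[which(hmask)[1]]
    s$x[hi] <- h_pos[1]
    s$y[hi] <- h_pos[2]
    s$z[hi] <- h_pos[3]
  } else {
    h_row <- s[di, ]
    h_row$eleno <- max(s$eleno) + 1L
    h_row$elety <- "HD1"
    h_row$element <- "H"
    h_row$x <- h_pos[1]
    h_row$y <- h_pos[2]
    h_row$z <- h_pos[3]
    h_row$charge <- ifelse(is.na(h_row$charge), NA_real_, 0)
    s <- bind_rows(s, h_row)
  }
  s$x[ai] <- a_pos[1]
  s$y[ai] <- a_pos[2]
  s$z[ai] <- a_pos[3]
  attr(s, "planted") <- list(
    donor_serial = donor_serial, acceptor_serial = acceptor_serial,
    distance = distance, angle = angle
  )
  s
}

#' Generate synthetic docking poses around named sites
#'
#' Creates rigid copies of the ligand jittered around the given binding-site
#' residues (or far from all of them for the `"unassigned"` label), with
#' caller-supplied docking scores, for exercising pose classification.
#'
#' @param structure Atom tibble containing the site residues.
#' @param ligand Ligand atom tibble (the copied rigid body).
#' @param plan Tibble with columns `site` (label or `"unassigned"`) and
#'   `score`, one row per pose.
#' @param sites Named list: site label -> residue tibble (`chain`, `resno`).
#' @param jitter Maximum random displacement (Angstrom) around the site
#'   center.
#' @param seed Integer seed.
#' @return Tibble of pose atoms (`pose_id`, `score`, ligand columns) with
#'   attribute `planted_sites`.
#' @export
make_docked_poses <- function(structure, ligand, plan, sites,
                              jitter = 1.0, seed = 1) {
  set.seed(seed)
  f <- min(structure$frame)
  s <- dplyr::filter(structure, .data$frame == f)
  centers <- map(sites, function(res) {
    at <- bind_rows(map(seq_len(nrow(res)), function(i) {
      residue_atoms(s, res$chain[i], res$resno[i], frame = f)
    }))
    colMeans(coords_matrix(at))
  })
  far <- colMeans(coords_matrix(s)) + c(500, 0, 0)
  l_cent <- colMeans(coords_matrix(ligand))
  out <- map(seq_len(nrow(plan)), function(i) {
    target <- if (plan$site[i] == "unassigned") {
      far
    } else {
      centers[[plan$site[i]]]
    }
    shift <- target + stats::runif(3, -jitter, jitter) - l_cent
    mutate(ligand,
      pose_id = sprintf("pose_%02d", i), score = plan$score[i],
      x = .data$x + shift[1], y = .data$y + shift[2], z = .data$z + shift[3]
    )
  })
  res <- list_rbind(out)
  attr(res, "planted_sites") <- plan$site
  res
}
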