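# Geometric hydrogen-bond detection: donor-acceptor distance plus the
# donor-H...acceptor angle, with trajectory occupancy and water bridges.
# Donor/acceptor typing is a standard chemical rule set: N and O bearing a
# covalently bonded hydrogen donate; N, O (and optionally S) accept.

#' Hydrogen-bond geometric criteria
#'
#' @param max_da_distance Maximum donor-acceptor distance (Angstrom),
#'   inclusive. Default 3.4.
#' @param angle_min,angle_max Accepted donor-H-acceptor angle window in
#'   degrees, both boundaries inclusive. Default 90-180.
#' @param shell Contact-enumeration shell (Angstrom) for
#'   [classify_contacts()]. Default 4.
#' @param s_accepts Whether sulfur counts as an acceptor.
#' @param bond_h_max Maximum covalent H-heavy distance (Angstrom) used to
#'   decide which hydrogens belong to a donor.
#' @return A list of class `"hbond_criteria"`.
#' @export
hbond_criteria <- function(max_da_distance = 3.4, angle_min = 90,
                           angle_max = 180, shell = 4.0,
                           s_accepts = FALSE, bond_h_max = 1.3) {
  if (!(angle_min > 0 && angle_min <= angle_max && angle_max <= 180)) {
    abort("require 0 < angle_min <= angle_max <= 180")
  }
  if (max_da_distance <= 0 || shell <= 0) abort("distances must be positive")
  structure(
    list(
      max_da_distance = max_da_distance, angle_min = angle_min,
      angle_max = angle_max, shell = shell, s_accepts = s_accepts,
      bond_h_max = bond_h_max
    ),
    class = "hbond_criteria"
  )
}

# numerical slack for the inclusive boundaries: an exactly planted 3.4 A /
# 90 deg geometry must be accepted despite floating-point representation
.HB_EPS <- 1e-9

angle_deg <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

# hydrogens covalently bonded to one heavy atom, searched in the whole frame
bonded_hydrogens <- function(frame_atoms, heavy, bond_h_max) {
  h <- dplyr::filter(frame_atoms, .data$element == "H")
  if (nrow(h) == 0) {
    return(h)
  }
  d <- sqrt((h$x - heavy$x)^2 + (h$y - heavy$y)^2 + (h$z - heavy$z)^2)
  h[d <= bond_h_max, ]
}

acceptor_elements <- function(criteria) {
  if (criteria$s_accepts) c("N", "O", "S") else c("N", "O")
}

# evaluate one directed donor -> acceptor candidate; NULL if rejected.
# `frame_has_h`: when the frame carries explicit hydrogens, a heavy atom
# without a bonded one is simply not a donor; only hydrogen-free structures
# degrade to distance-only detection.
hbond_candidate <- function(frame_atoms, donor, acceptor, criteria,
                            frame_has_h) {
  da <- sqrt((donor$x - acceptor$x)^2 + (donor$y - acceptor$y)^2 +
    (donor$z - acceptor$z)^2)
  if (da > criteria$max_da_distance + .HB_EPS) {
    return(NULL)
  }
  hs <- bonded_hydrogens(frame_atoms, donor, criteria$bond_h_max)
  if (nrow(hs) == 0) {
    if (frame_has_h) {
      return(NULL)
    }
    # no explicit hydrogens anywhere: distance-only detection, flagged
    return(tibble(
      donor_serial = donor$eleno, donor_name = donor$elety,
      donor_chain = donor$chain, donor_resno = donor$resno,
      donor_resid = donor$resid,
      hydrogen_serial = NA_integer_,
      acceptor_serial = acceptor$eleno, acceptor_name = acceptor$elety,
      acceptor_chain = acceptor$chain, acceptor_resno = acceptor$resno,
      acceptor_resid = acceptor$resid,
      da_distance = da, dha_angle = NA_real_, angle_checked = FALSE
    ))
  }
  ang <- map_dbl(seq_len(nrow(hs)), function(k) {
    angle_deg(
      c(donor$x, donor$y, donor$z),
      c(hs$x[k], hs$y[k], hs$z[k]),
      c(acceptor$x, acceptor$y, acceptor$z)
    )
  })
  ok <- ang >= criteria$angle_min - .HB_EPS & ang <= criteria$angle_max + .HB_EPS
  if (!any(ok)) {
    return(NULL)
  }
  best <- which(ok)[which.max(ang[ok])]
  tibble(
    donor_serial = donor$eleno, donor_name = donor$elety,
    donor_chain = donor$chain, donor_resno = donor$resno,
    donor_resid = donor$resid,
    hydrogen_serial = hs$eleno[best],
    acceptor_serial = acceptor$eleno, acceptor_name = acceptor$elety,
    acceptor_chain = acceptor$chain, acceptor_resno = acceptor$resno,
    acceptor_resid = acceptor$resid,
    da_distance = da, dha_angle = ang[best], angle_checked = TRUE
  )
}

#' Detect hydrogen bonds between two atom groups
#'
#' All donor-acceptor pairs across the two groups with a donor-acceptor
#' distance of at most `max_da_distance` and, when the donor carries an
#' explicit hydrogen, a donor-H-acceptor angle inside the accepted window.
#' Both boundaries are inclusive. Donors without explicit hydrogens are
#' reported with `dha_angle = NA` and `angle_checked = FALSE`. Both group
#' orders are scanned, so the result is symmetric in the arguments.
#'
#' @param structure Atom tibble (the frame of the groups; hydrogens are
#'   looked up here even if not part of either group).
#' @param group_a,group_b Disjoint atom tibbles.
#' @param criteria An [hbond_criteria()] object.
#' @return Tibble of bonds ordered by donor and acceptor serial, with a
#'   `bridging_water` column (`NA` for direct bonds).
#' @export
detect_hbonds <- function(structure, group_a, group_b,
                          criteria = hbond_criteria()) {
  f <- min(structure$frame)
  frame_atoms <- dplyr::filter(structure, .data$frame == f)
  frame_has_h <- any(frame_atoms$element == "H")
  acc_el <- acceptor_elements(criteria)
  pairs_for <- function(ga, gb) {
    donors <- dplyr::filter(ga, .data$element %in% c("N", "O"))
    acceptors <- dplyr::filter(gb, .data$element %in% acc_el)
    if (nrow(donors) == 0 || nrow(acceptors) == 0) {
      return(NULL)
    }
    out <- list()
    for (i in seq_len(nrow(donors))) {
      for (j in seq_len(nrow(acceptors))) {
        cand <- hbond_candidate(
          frame_atoms, donors[i, ], acceptors[j, ], criteria, frame_has_h
        )
        if (!is.null(cand)) out[[length(out) + 1]] <- cand
      }
    }
    if (length(out) == 0) NULL else list_rbind(out)
  }
  res <- bind_rows(pairs_for(group_a, group_b), pairs_for(group_b, group_a))
  if (nrow(res) == 0) {
    return(tibble(
      donor_serial = integer(), donor_name = character(),
      donor_chain = character(), donor_resno = integer(),
      donor_resid = character(), hydrogen_serial = integer(),
      acceptor_serial = integer(), acceptor_name = character(),
      acceptor_chain = character(), acceptor_resno = integer(),
      acceptor_resid = character(), da_distance = numeric(),
      dha_angle = numeric(), angle_checked = logical(),
      bridging_water = character()
    ))
  }
  res <- dplyr::distinct(
    res, .data$donor_serial, .data$acceptor_serial,
    .keep_all = TRUE
  )
  mutate(
    dplyr::arrange(res, .data$donor_serial, .data$acceptor_serial),
    bridging_water = NA_character_
  )
}

#' Detect water-bridged hydrogen bonds between two groups
#'
#' A water residue bridges the groups when it simultaneously satisfies the
#' hydrogen-bond criteria with at least one atom of each group. One record is
#' emitted per (group-a atom, group-b atom, water) combination, carrying the
#' water identity and the two water-side distances.
#'
#' @param structure Atom tibble.
#' @param group_a,group_b Disjoint atom tibbles.
#' @param waters Residue tibble of waters (`chain`, `resno`, `insert`) or
#'   `NULL` to use every water in the frame.
#' @param criteria An [hbond_criteria()] object.
#' @return Tibble with `bridging_water` set to `"chain:resno"` of the water.
#' @export
detect_water_bridges <- function(structure, group_a, group_b, waters = NULL,
                                 criteria = hbond_criteria()) {
  f <- min(structure$frame)
  s <- dplyr::filter(structure, .data$frame == f)
  if (is.null(waters)) {
    waters <- dplyr::filter(residue_table(s), .data$kind == "water")
  }
  empty <- tibble(
    donor_serial = integer(), acceptor_serial = integer(),
    donor_resid = character(), acceptor_resid = character(),
    da_distance = numeric(), dha_angle = numeric(),
    bridging_water = character(), dist_a_water = numeric(),
    dist_b_water = numeric()
  )
  if (nrow(waters) == 0) {
    return(empty)
  }
  out <- list()
  for (i in seq_len(nrow(waters))) {
    w <- residue_atoms(s, waters$chain[i], waters$resno[i], waters$insert[i],
      frame = f
    )
    ba <- detect_hbonds(s, group_a, w, criteria)
    if (nrow(ba) == 0) next
    bb <- detect_hbonds(s, group_b, w, criteria)
    if (nrow(bb) == 0) next
    wid <- sprintf("%s:%d", waters$chain[i], waters$resno[i])
    a_side <- unique(c(
      ba$donor_serial[ba$donor_serial %in% group_a$eleno],
      ba$acceptor_serial[ba$acceptor_serial %in% group_a$eleno]
    ))
    b_side <- unique(c(
      bb$donor_serial[bb$donor_serial %in% group_b$eleno],
      bb$acceptor_serial[bb$acceptor_serial %in% group_b$eleno]
    ))
    for (sa in a_side) {
      for (sb in b_side) {
        at_a <- s[s$eleno == sa, ][1, ]
        at_b <- s[s$eleno == sb, ][1, ]
        out[[length(out) + 1]] <- tibble(
          donor_serial = sa, acceptor_serial = sb,
          donor_resid = at_a$resid, acceptor_resid = at_b$resid,
          da_distance = NA_real_, dha_angle = NA_real_,
          bridging_water = wid,
          dist_a_water = min_atom_distance(at_a, w),
          dist_b_water = min_atom_distance(at_b, w)
        )
      }
    }
  }
  if (length(out) == 0) empty else list_rbind(out)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For every donor-acceptor pair observed in at least one frame, the
#' percentage of frames in which [detect_hbonds()] reports it.
#'
#' @param trajectory Multi-frame atom tibble.
#' @param group_a,group_b Atom tibbles identifying the groups (matched to
#'   each frame by atom serial).
#' @param criteria An [hbond_criteria()] object.
#' @return Tibble with `donor_serial`, `acceptor_serial`, `frames_present`,
#'   `frames_total`, `occupancy_percent`.
#' @export
hbond_occupancy <- function(trajectory, group_a, group_b,
                            criteria = hbond_criteria()) {
  frames <- sort(unique(trajectory$frame))
  if (length(frames) == 0) abort("argument error: empty trajectory")
  per_frame <- map(frames, function(f) {
    s <- dplyr::filter(trajectory, .data$frame == f)
    ga <- dplyr::filter(s, .data$eleno %in% group_a$eleno)
    gb <- dplyr::filter(s, .data$eleno %in% group_b$eleno)
    b <- detect_hbonds(s, ga, gb, criteria)
    if (nrow(b) == 0) {
      return(NULL)
    }
    mutate(
      dplyr::select(
        b, "donor_serial", "donor_name", "donor_resid",
        "acceptor_serial", "acceptor_name", "acceptor_resid"
      ),
      frame = f
    )
  })
  all <- list_rbind(per_frame[!map_lgl(per_frame, is.null)])
  if (is.null(all) || nrow(all) == 0) {
    return(tibble(
      donor_serial = integer(), acceptor_serial = integer(),
      frames_present = integer(), frames_total = integer(),
      occupancy_percent = numeric()
    ))
  }
  summarise(
    group_by(
      all, .data$donor_serial, .data$donor_name, .data$donor_resid,
      .data$acceptor_serial, .data$acceptor_name, .data$acceptor_resid
    ),
    frames_present = dplyr::n_distinct(.data$frame),
    frames_total = length(frames),
    occupancy_percent = 100 * .data$frames_present / length(frames),
    .groups = "drop"
  )
}

#' Default contact-classification rules
#'
#' Ordered rule table for [classify_contacts()]: hydrogen bonds are delegated
#' to [detect_hbonds()]; carbon-carbon contacts are labelled hydrophobic
#' (alkyl); everything else inside the shell falls back to van der Waals.
#' This is a deliberately simple, documented approximation of the interaction
#' typologies produced by commercial visualisation suites.
#'
#' @return A list of rules, each `list(type =, test = function(el_a, el_b))`.
#' @export
default_contact_rules <- function() {
  list(
    list(
      type = "hydrophobic (alkyl)",
      test = function(el_a, el_b) el_a == "C" && el_b == "C"
    ),
    list(
      type = "van der Waals",
      test = function(el_a, el_b) TRUE
    )
  )
}

#' Classify residue-ligand contacts within the interaction shell
#'
#' Every protein atom within `criteria$shell` of the ligand is labelled:
#' atoms participating in a detected hydrogen bond get `"hydrogen bond"`;
#' otherwise the first matching rule in `rules` applies.
#'
#' @param structure Atom tibble.
#' @param ligand Ligand atom tibble or residue name.
#' @param criteria An [hbond_criteria()] object.
#' @param rules Rule list as from [default_contact_rules()].
#' @return Tibble with `chain`, `resno`, `resid`, `elety`, `contact_type`,
#'   `distance` (closest ligand-atom distance).
#' @export
classify_contacts <- function(structure, ligand,
                              criteria = hbond_criteria(),
                              rules = default_contact_rules()) {
  f <- min(structure$frame)
  s <- dplyr::filter(structure, .data$frame == f)
  lig <- as_ligand(s, ligand, frame = f)
  prot <- dplyr::filter(
    s, .data$kind == "amino_acid", !.data$eleno %in% lig$eleno
  )
  if (nrow(prot) == 0) {
    return(tibble(
      chain = character(), resno = integer(), resid = character(),
      elety = character(), contact_type = character(), distance = numeric()
    ))
  }
  pm <- as.matrix(prot[, c("x", "y", "z")])
  lm <- as.matrix(lig[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * tcrossprod(pm, lm)
  d2[d2 < 0] <- 0
  dmin <- sqrt(apply(d2, 1, min))
  nearest <- apply(d2, 1, which.min)
  in_shell <- which(dmin <= criteria$shell + .HB_EPS)
  if (length(in_shell) == 0) {
    return(tibble(
      chain = character(), resno = integer(), resid = character(),
      elety = character(), contact_type = character(), distance = numeric()
    ))
  }
  hb <- detect_hbonds(s, prot, lig, criteria)
  hb_serials <- unique(c(hb$donor_serial, hb$acceptor_serial))
  rows <- map(in_shell, function(i) {
    atom <- prot[i, ]
    lig_el <- lig$element[nearest[i]]
    type <- if (atom$eleno %in% hb_serials) {
      "hydrogen bond"
    } else {
      matched <- "van der Waals"
      for (rule in rules) {
        if (rule$test(atom$element, lig_el)) {
          matched <- rule$type
          break
        }
      }
      matched
    }
    tibble(
      chain = atom$chain, resno = atom$resno, resid = atom$resid,
      elety = atom$elety, contact_type = type, distance = dmin[i]
    )
  })
  list_rbind(rows)
}
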