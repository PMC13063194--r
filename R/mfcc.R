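# Conjugate-cap fragmentation and per-residue interaction-energy
# decomposition. For a residue R_i with caps taken from its sequence
# neighbours, four auxiliary systems are assembled:
#   S1 = caps + R_i + ligand,  S2 = caps + R_i,
#   S3 = caps + ligand,        S4 = caps only,
# and the residue-ligand interaction energy is E_S1 - E_S2 - E_S3 + E_S4.
# The caps are byte-identical across the four systems, so for any
# pairwise-additive potential every cap term cancels algebraically and the
# combination equals the direct residue-ligand cross-pair sum.

#' Residue- and water-selection criteria for decomposition
#'
#' @param residue_cutoff Residues whose closest atom lies within this distance
#'   (Angstrom) of the ligand enter the decomposition (inclusive). Default 10.
#' @param water_cutoff Waters within this distance of a selected residue or of
#'   the ligand are treated as bridging waters. Default 2.5.
#' @return A list of class `"selection_criteria"`.
#' @export
selection_criteria <- function(residue_cutoff = 10, water_cutoff = 2.5) {
  if (residue_cutoff <= 0 || water_cutoff <= 0) {
    abort("selection cutoffs must be positive")
  }
  structure(
    list(residue_cutoff = residue_cutoff, water_cutoff = water_cutoff),
    class = "selection_criteria"
  )
}

#' Select binding-site residues around a ligand
#'
#' Amino-acid residues whose minimum inter-atomic distance to the ligand is at
#' most `criteria$residue_cutoff`, in chain order, annotated with that
#' distance.
#'
#' @param structure Atom tibble (single frame is used).
#' @param ligand Ligand atom tibble or residue name.
#' @param criteria A [selection_criteria()] object.
#' @return Tibble with columns `chain`, `resno`, `insert`, `resid`,
#'   `min_distance`.
#' @export
select_binding_residues <- function(structure, ligand,
                                    criteria = selection_criteria()) {
  f <- min(structure$frame)
  lig <- as_ligand(structure, ligand, frame = f)
  s <- dplyr::filter(structure, .data$frame == f)
  res <- dplyr::filter(residue_table(s), .data$kind == "amino_acid")
  lig_key <- paste(lig$chain, lig$resno, lig$insert)
  res <- dplyr::filter(
    res, !paste(.data$chain, .data$resno, .data$insert) %in% lig_key
  )
  if (nrow(res) == 0) {
    return(tibble(
      chain = character(), resno = integer(), insert = character(),
      resid = character(), min_distance = numeric()
    ))
  }
  res$min_distance <- map_dbl(seq_len(nrow(res)), function(i) {
    min_atom_distance(
      residue_atoms(s, res$chain[i], res$resno[i], res$insert[i], frame = f),
      lig
    )
  })
  dplyr::select(
    dplyr::filter(res, .data$min_distance <= criteria$residue_cutoff),
    -"kind"
  )
}

#' Select bridging waters near selected residues or the ligand
#'
#' Water residues whose closest atom lies within `criteria$water_cutoff` of
#' any selected residue or of the ligand, deduplicated and ordered by residue
#' number.
#'
#' @param structure Atom tibble.
#' @param residues Residue tibble as returned by [select_binding_residues()].
#' @param ligand Ligand atom tibble or residue name.
#' @param criteria A [selection_criteria()] object.
#' @return Tibble of water residues (`chain`, `resno`, `insert`, `resid`).
#' @export
select_bridging_waters <- function(structure, residues, ligand,
                                   criteria = selection_criteria()) {
  f <- min(structure$frame)
  s <- dplyr::filter(structure, .data$frame == f)
  lig <- as_ligand(structure, ligand, frame = f)
  waters <- dplyr::filter(residue_table(s), .data$kind == "water")
  if (nrow(waters) == 0) {
    return(dplyr::select(waters, -"kind"))
  }
  targets <- c(
    list(lig),
    map(seq_len(nrow(residues)), function(i) {
      residue_atoms(
        s, residues$chain[i], residues$resno[i], residues$insert[i],
        frame = f
      )
    })
  )
  keep <- map_lgl(seq_len(nrow(waters)), function(i) {
    w <- residue_atoms(
      s, waters$chain[i], waters$resno[i], waters$insert[i],
      frame = f
    )
    any(map_lgl(targets, ~ min_atom_distance(w, .x) <= criteria$water_cutoff))
  })
  dplyr::arrange(dplyr::select(waters[keep, ], -"kind"), .data$resno)
}

# ordered amino-acid residues of one chain (frame f) as a residue table
chain_aa_residues <- function(s, chain) {
  dplyr::filter(
    residue_table(s), .data$chain == !!chain, .data$kind == "amino_acid"
  )
}

# place a passivating hydrogen on `heavy` along the direction to `toward`
passivating_h <- function(heavy, toward, bond_length, serial) {
  u <- c(toward$x - heavy$x, toward$y - heavy$y, toward$z - heavy$z)
  u <- u / sqrt(sum(u^2))
  mutate(heavy,
    eleno = as.integer(serial), elety = "HCP", element = "H",
    x = heavy$x + bond_length * u[1],
    y = heavy$y + bond_length * u[2],
    z = heavy$z + bond_length * u[3],
    charge = ifelse(is.na(heavy$charge), NA_real_, 0)
  )
}

#' Build a conjugate-capped fragment for one residue
#'
#' The caps are the full sequence-adjacent residues, severed at their distal
#' backbone bonds; each severed bond is passivated with a hydrogen placed on
#' the original bond vector at 1.09 Angstrom from carbon or 1.01 Angstrom from
#' nitrogen. Chain termini yield a single cap on the existing side, and a
#' terminal cap whose distal bond does not exist needs no passivation.
#'
#' @param structure Atom tibble.
#' @param chain,resno,insert Identify the core residue R_i.
#' @return Atom tibble with an extra column `role` in
#'   `c("core", "cap_prev", "cap_next", "h_cap")`. Passivating hydrogens are
#'   named `HCP` and carry fresh serial numbers.
#' @export
build_capped_fragment <- function(structure, chain, resno, insert = "") {
  f <- min(structure$frame)
  s <- dplyr::filter(structure, .data$frame == f)
  core <- residue_atoms(s, chain, resno, insert, frame = f)
  if (core$kind[1] != "amino_acid") {
    abort(sprintf(
      "unsupported-residue error: %s is not a standard amino acid",
      core$resid[1]
    ))
  }
  if (!all(c("N", "CA", "C") %in% core$elety)) {
    abort("topology error: core residue lacks backbone atoms N, CA, C")
  }
  aa <- chain_aa_residues(s, chain)
  pos <- which(aa$resno == resno & aa$insert == insert)
  get_res <- function(i) {
    if (i < 1 || i > nrow(aa)) {
      return(NULL)
    }
    residue_atoms(s, aa$chain[i], aa$resno[i], aa$insert[i], frame = f)
  }
  prev <- get_res(pos - 1)
  nxt <- get_res(pos + 1)
  prev2 <- get_res(pos - 2)
  nxt2 <- get_res(pos + 2)
  next_serial <- max(s$eleno) + 1L
  h_caps <- list()
  if (!is.null(prev) && !is.null(prev2)) {
    # sever C(i-2)-N(i-1): passivate N of the previous-residue cap
    n_atom <- dplyr::filter(prev, .data$elety == "N")
    c_atom <- dplyr::filter(prev2, .data$elety == "C")
    if (nrow(n_atom) == 1 && nrow(c_atom) == 1) {
      h_caps <- c(h_caps, list(passivating_h(n_atom, c_atom, 1.01, next_serial)))
      next_serial <- next_serial + 1L
    }
  }
  if (!is.null(nxt) && !is.null(nxt2)) {
    # sever C(i+1)-N(i+2): passivate C of the next-residue cap
    c_atom <- dplyr::filter(nxt, .data$elety == "C")
    n_atom <- dplyr::filter(nxt2, .data$elety == "N")
    if (nrow(c_atom) == 1 && nrow(n_atom) == 1) {
      h_caps <- c(h_caps, list(passivating_h(c_atom, n_atom, 1.09, next_serial)))
      next_serial <- next_serial + 1L
    }
  }
  bind_rows(
    mutate(core, role = "core"),
    if (!is.null(prev)) mutate(prev, role = "cap_prev"),
    if (!is.null(nxt)) mutate(nxt, role = "cap_next"),
    if (length(h_caps) > 0) mutate(bind_rows(h_caps), role = "h_cap")
  )
}

#' Assemble the four auxiliary systems for one capped fragment
#'
#' @param fragment Output of [build_capped_fragment()].
#' @param ligand Ligand atom tibble.
#' @param waters Atom tibble of bridging-water atoms (all waters to include),
#'   or `NULL`.
#' @param water_policy `"all_systems"` places identical copies of the waters
#'   in S1-S4 (so a pairwise potential cancels them exactly and a quantum
#'   backend sees the bridging environment in every term); `"none"` omits
#'   them everywhere.
#' @return A list of class `"mfcc_systems"` with atom tibbles `S1`-`S4` and
#'   `included_waters`.
#' @export
assemble_systems <- function(fragment, ligand, waters = NULL,
                             water_policy = c("all_systems", "none")) {
  water_policy <- match.arg(water_policy)
  if (length(intersect(fragment$eleno, ligand$eleno)) > 0) {
    abort("assembly error: fragment and ligand share atom serial numbers")
  }
  caps <- dplyr::filter(fragment, .data$role %in% c("cap_prev", "cap_next", "h_cap"))
  core <- dplyr::filter(fragment, .data$role == "core")
  w <- if (water_policy == "all_systems" && !is.null(waters) && nrow(waters) > 0) {
    waters
  } else {
    NULL
  }
  strip <- function(x) dplyr::select(x, -dplyr::any_of("role"))
  sys <- list(
    S1 = bind_rows(strip(caps), strip(core), ligand, w),
    S2 = bind_rows(strip(caps), strip(core), w),
    S3 = bind_rows(strip(caps), ligand, w),
    S4 = bind_rows(strip(caps), w)
  )
  structure(
    c(sys, list(included_waters = w)),
    class = "mfcc_systems"
  )
}

#' Conjugate-cap combination of the four system energies
#'
#' Evaluates the backend on S1-S4 and returns `E_S1 - E_S2 - E_S3 + E_S4`,
#' the interaction energy between the core residue and the ligand. With a
#' pairwise-additive backend this equals the direct residue-ligand cross-pair
#' sum exactly, independent of the caps and of any waters present identically
#' in all four systems.
#'
#' @param systems An `"mfcc_systems"` object.
#' @param backend An [energy_backend()].
#' @return Interaction energy in kcal/mol.
#' @export
mfcc_interaction_energy <- function(systems, backend) {
  e <- map(c("S1", "S2", "S3", "S4"), function(nm) {
    tryCatch(backend$evaluate(systems[[nm]]), error = function(err) {
      abort(sprintf("backend failed on system %s: %s", nm, conditionMessage(err)))
    })
  })
  e[[1]] - e[[2]] - e[[3]] + e[[4]]
}

# nearest ligand region for a residue: region of the ligand atom closest to it
nearest_region_tag <- function(res_atoms, ligand, region_map) {
  d_by_atom <- map_dbl(seq_len(nrow(ligand)), function(j) {
    min_atom_distance(res_atoms, ligand[j, ])
  })
  nm <- ligand$elety[which.min(d_by_atom)]
  tag <- names(region_map)[map_lgl(region_map, ~ nm %in% .x)]
  if (length(tag) == 0) NA_character_ else tag[1]
}

# ligand atoms per region; unmapped atoms (e.g. hydrogens) follow their
# nearest mapped heavy atom so the regions partition the whole ligand
ligand_region_split <- function(ligand, region_map) {
  mapped <- map(region_map, ~ which(ligand$elety %in% .x))
  un <- setdiff(seq_len(nrow(ligand)), unlist(mapped))
  if (length(un) > 0) {
    mapped_idx <- unlist(mapped)
    for (j in un) {
      d <- sqrt((ligand$x[mapped_idx] - ligand$x[j])^2 +
        (ligand$y[mapped_idx] - ligand$y[j])^2 +
        (ligand$z[mapped_idx] - ligand$z[j])^2)
      host <- mapped_idx[which.min(d)]
      for (rg in names(mapped)) {
        if (host %in% mapped[[rg]]) mapped[[rg]] <- c(mapped[[rg]], j)
      }
    }
  }
  mapped
}

#' Per-residue interaction-energy decomposition of a binding site
#'
#' Runs the full conjugate-cap scheme for every selected residue: fragment
#' construction, assembly of the four auxiliary systems, and the energy
#' combination. With a pairwise-additive backend and a region map, the energy
#' is additionally attributed exactly to the ligand regions by restricting the
#' cross-pair sum to each region's ligand atoms; with a non-additive backend
#' the per-region columns are `NA` and only the nearest-region tag is
#' reported.
#'
#' @param structure Atom tibble.
#' @param ligand Ligand atom tibble or residue name.
#' @param backend An [energy_backend()].
#' @param criteria A [selection_criteria()] object.
#' @param region_map Optional [load_region_map()] result.
#' @param water_policy Passed to [assemble_systems()].
#' @return Tibble with one row per selected residue: `chain`, `resno`,
#'   `insert`, `resid`, `min_distance`, `energy`, `region_tag`, and (with a
#'   region map) `region_i`, `region_ii`, `region_iii`.
#' @export
decompose_site <- function(structure, ligand, backend,
                           criteria = selection_criteria(),
                           region_map = NULL,
                           water_policy = c("all_systems", "none")) {
  water_policy <- match.arg(water_policy)
  f <- min(structure$frame)
  s <- dplyr::filter(structure, .data$frame == f)
  lig <- as_ligand(s, ligand, frame = f)
  res <- select_binding_residues(s, lig, criteria)
  if (nrow(res) == 0) {
    return(mutate(res,
      energy = numeric(0), region_tag = character(0)
    ))
  }
  waters_tbl <- select_bridging_waters(s, res, lig, criteria)
  water_atoms <- if (nrow(waters_tbl) > 0) {
    bind_rows(map(seq_len(nrow(waters_tbl)), function(i) {
      residue_atoms(
        s, waters_tbl$chain[i], waters_tbl$resno[i], waters_tbl$insert[i],
        frame = f
      )
    }))
  } else {
    NULL
  }
  region_idx <- if (!is.null(region_map)) ligand_region_split(lig, region_map)
  rows <- map(seq_len(nrow(res)), function(i) {
    frag <- build_capped_fragment(s, res$chain[i], res$resno[i], res$insert[i])
    sys <- assemble_systems(frag, lig, water_atoms, water_policy)
    energy <- mfcc_interaction_energy(sys, backend)
    core <- dplyr::filter(frag, .data$role == "core")
    row <- res[i, ]
    row$energy <- energy
    row$region_tag <- if (!is.null(region_map)) {
      nearest_region_tag(core, lig, region_map)
    } else {
      NA_character_
    }
    if (!is.null(region_map)) {
      if (backend$pairwise_additive) {
        br <- map_dbl(region_idx, function(idx) {
          if (length(idx) == 0) {
            return(0)
          }
          interaction_energy_direct(core, lig[idx, ], attr_params(backend))
        })
      } else {
        br <- setNames(rep(NA_real_, 3), names(region_idx))
      }
      row$region_i <- br[["i"]]
      row$region_ii <- br[["ii"]]
      row$region_iii <- br[["iii"]]
    }
    row
  })
  list_rbind(rows)
}

# The pairwise backend closes over its params; recover them for the exact
# per-region cross sums. Falls back to defaults for hand-built backends.
attr_params <- function(backend) {
  env <- environment(backend$evaluate)
  if (!is.null(env) && "params" %in% names(env)) env$params else backend_params()
}

#' Radius-convergence profile of the decomposed energy
#'
#' Cumulative interaction energy as a function of the binding-site radius:
#' at radius r, the sum of energies of all residues whose closest atom lies
#' within r of the ligand.
#'
#' @param energies Decomposition tibble from [decompose_site()] (needs
#'   `min_distance` and `energy`).
#' @param radii Strictly increasing radii in Angstrom.
#' @return Tibble with columns `radius`, `cumulative_energy`, `n_residues`.
#' @export
radius_profile <- function(energies, radii) {
  if (is.unsorted(radii, strictly = TRUE)) {
    abort("argument error: radii must be strictly increasing")
  }
  tibble(
    radius = radii,
    cumulative_energy = map_dbl(radii, function(r) {
      sum(energies$energy[energies$min_distance <= r])
    }),
    n_residues = map_dbl(radii, function(r) {
      sum(energies$min_distance <= r)
    })
  )
}

#' Export the four auxiliary systems for an external engine
#'
#' Writes one PDB and one XYZ file per system (S1-S4) plus a JSON manifest
#' mapping each system to its files and expected atom count.
#'
#' @param systems An `"mfcc_systems"` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the manifest list.
#' @export
export_systems <- function(systems, dir, prefix = "fragment") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- map(c("S1", "S2", "S3", "S4"), function(nm) {
    atoms <- systems[[nm]]
    pdb <- file.path(dir, sprintf("%s_%s.pdb", prefix, nm))
    xyz <- file.path(dir, sprintf("%s_%s.xyz", prefix, nm))
    write_pdb(atoms, pdb)
    write_xyz(atoms, xyz)
    list(system = nm, pdb = pdb, xyz = xyz, n_atoms = nrow(atoms))
  })
  names(manifest) <- c("S1", "S2", "S3", "S4")
  jsonlite::write_json(
    manifest, file.path(dir, paste0(prefix, "_manifest.json")),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
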