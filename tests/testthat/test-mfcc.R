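test_that("binding-residue selection matches brute-force distances and is inclusive", {
  cx <- toy_complex(seed = 1)
  s <- cx$structure
  lig <- ligand_atoms(s)
  sel <- select_binding_residues(s, lig, selection_criteria(residue_cutoff = 10))
  # brute force over residues
  rt <- residue_table(s)
  rt <- rt[rt$kind == "amino_acid", ]
  brute <- vapply(seq_len(nrow(rt)), function(i) {
    min_atom_distance(residue_atoms(s, rt$chain[i], rt$resno[i]), lig)
  }, numeric(1))
  expect_equal(sel$resno, rt$resno[brute <= 10])
  expect_equal(sel$min_distance, brute[brute <= 10], tolerance = 1e-12)
  # far ligand selects nothing
  far <- dplyr::mutate(lig, x = x + 1000)
  expect_equal(nrow(select_binding_residues(s, far)), 0)
  # a residue exactly at the cutoff is included
  d4 <- sel$min_distance[1]
  expect_gt(nrow(dplyr::filter(
    select_binding_residues(s, lig, selection_criteria(residue_cutoff = d4)),
    resno == sel$resno[1]
  )), 0)
})

test_that("bridging-water selection honours the 2.5 A rule around residues and ligand", {
  cx <- toy_complex(seed = 2)
  s <- cx$structure
  lig <- ligand_atoms(s)
  mk_water <- function(serial, resno, pos) {
    tibble::tibble(
      frame = 1L, time_ns = 0, eleno = serial, elety = "O", element = "O",
      x = pos[1], y = pos[2], z = pos[3], chain = "W", resno = resno,
      insert = "", resid = "HOH", kind = "water", charge = 0
    )
  }
  lig_edge <- c(lig$x[1], lig$y[1], lig$z[1])
  w_near <- mk_water(5001L, 601L, lig_edge + c(2.4, 0, 0))
  w_far <- mk_water(5002L, 602L, lig_edge + c(200, 0, 0))
  sw <- dplyr::bind_rows(s, w_near, w_far)
  res <- select_binding_residues(sw, "LIG")
  waters <- select_bridging_waters(sw, res, "LIG")
  expect_equal(waters$resno, 601)
  # no waters at all
  expect_equal(nrow(select_bridging_waters(s, res, "LIG")), 0)
})

test_that("capped fragments carry full neighbours and exact passivation geometry", {
  pep <- make_peptide(5)
  frag <- build_capped_fragment(pep, "A", 3)
  expect_setequal(unique(frag$role), c("core", "cap_prev", "cap_next", "h_cap"))
  expect_equal(sum(frag$role == "core"), 5)
  expect_equal(sum(frag$role == "cap_prev"), 5)
  expect_equal(sum(frag$role == "cap_next"), 5)
  expect_equal(sum(frag$role == "h_cap"), 2)
  expect_false(anyDuplicated(frag$eleno) > 0)
  # passivating H bond lengths: 1.01 on the N side, 1.09 on the C side
  h <- dplyr::filter(frag, role == "h_cap")
  n_prev <- dplyr::filter(frag, role == "cap_prev", elety == "N")
  c_next <- dplyr::filter(frag, role == "cap_next", elety == "C")
  d_n <- min_atom_distance(h[1, ], n_prev)
  d_c <- min_atom_distance(h[2, ], c_next)
  expect_equal(d_n, 1.01, tolerance = 1e-6)
  expect_equal(d_c, 1.09, tolerance = 1e-6)
  # the H lies on the severed-bond vector: collinear with N(i-1) -> C(i-2)
  c_prev2 <- dplyr::filter(pep, resno == 1, elety == "C")
  v1 <- c(h$x[1] - n_prev$x, h$y[1] - n_prev$y, h$z[1] - n_prev$z)
  v2 <- c(c_prev2$x - n_prev$x, c_prev2$y - n_prev$y, c_prev2$z - n_prev$z)
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  expect_equal(cosang, 1, tolerance = 1e-9)
})

test_that("terminal residues get a single cap and no phantom passivation", {
  pep <- make_peptide(3)
  frag_n <- build_capped_fragment(pep, "A", 1)
  expect_equal(sum(frag_n$role == "cap_prev"), 0)
  expect_equal(sum(frag_n$role == "cap_next"), 5)
  # the i+1 cap of residue 1 is severed at C2-N3: one passivating H
  expect_equal(sum(frag_n$role == "h_cap"), 1)
  # middle residue of a 3-residue chain: caps are chain termini, no severed bonds
  frag_m <- build_capped_fragment(pep, "A", 2)
  expect_equal(sum(frag_m$role == "h_cap"), 0)
  expect_equal(nrow(frag_m), 15)
  expect_error(build_capped_fragment(pep, "A", 99), "not found")
})

test_that("fragment construction is deterministic", {
  pep <- make_peptide(6)
  f1 <- build_capped_fragment(pep, "A", 4)
  f2 <- build_capped_fragment(pep, "A", 4)
  expect_identical(f1, f2)
})

test_that("system assembly obeys the set identities and shares caps exactly", {
  cx <- toy_complex(seed = 4)
  lig <- ligand_atoms(cx$structure)
  frag <- build_capped_fragment(cx$structure, "A", 3)
  sys <- assemble_systems(frag, lig)
  expect_equal(nrow(sys$S1), nrow(sys$S2) + nrow(lig))
  expect_equal(nrow(sys$S3), nrow(sys$S4) + nrow(lig))
  caps <- dplyr::filter(frag, role != "core")
  for (nm in c("S1", "S2", "S3", "S4")) {
    in_sys <- dplyr::filter(sys[[nm]], eleno %in% caps$eleno)
    expect_equal(nrow(in_sys), nrow(caps))
    m1 <- as.matrix(dplyr::arrange(in_sys, eleno)[, c("x", "y", "z")])
    m2 <- as.matrix(dplyr::arrange(caps, eleno)[, c("x", "y", "z")])
    expect_identical(m1, m2) # byte-identical cap coordinates
  }
  # water copies appear identically in all four systems
  w <- random_atoms(3, seed = 9, serial_start = 7001L)
  w$resid <- "HOH"
  w$kind <- "water"
  sysw <- assemble_systems(frag, lig, waters = w, water_policy = "all_systems")
  for (nm in c("S1", "S2", "S3", "S4")) {
    expect_equal(sum(sysw[[nm]]$eleno %in% w$eleno), 3)
  }
  sys0 <- assemble_systems(frag, lig, waters = w, water_policy = "none")
  for (nm in c("S1", "S2", "S3", "S4")) {
    expect_equal(sum(sys0[[nm]]$eleno %in% w$eleno), 0)
  }
})

test_that("conjugate-cap combination matches the direct cross-pair oracle exactly", {
  for (seed in 1:10) {
    cx <- toy_complex(seed = seed)
    be <- pairwise_backend(cx$params)
    s <- cx$structure
    lig <- ligand_atoms(s)
    res <- select_binding_residues(s, lig)
    i <- (seed %% nrow(res)) + 1
    frag <- build_capped_fragment(s, res$chain[i], res$resno[i])
    sys <- assemble_systems(frag, lig)
    e_mfcc <- mfcc_interaction_energy(sys, be)
    e_direct <- interaction_energy_direct(
      dplyr::filter(frag, role == "core"), lig, cx$params
    )
    expect_lt(abs(e_mfcc - e_direct), 1e-8)
  }
})

test_that("identical waters in all four systems cancel from the combination", {
  cx <- toy_complex(seed = 6)
  be <- pairwise_backend(cx$params)
  lig <- ligand_atoms(cx$structure)
  frag <- build_capped_fragment(cx$structure, "A", 2)
  e_dry <- mfcc_interaction_energy(assemble_systems(frag, lig), be)
  for (n_w in c(1, 3, 6)) {
    w <- random_atoms(n_w, seed = 20 + n_w, spread = 10, serial_start = 8001L)
    w$x <- w$x + 12 # near, but not overlapping, the complex
    e_wet <- mfcc_interaction_energy(
      assemble_systems(frag, lig, waters = w, water_policy = "all_systems"), be
    )
    expect_lt(abs(e_wet - e_dry), 1e-8)
  }
})

test_that("ligand at astronomical distance decouples and energies shift rigidly", {
  cx <- toy_complex(seed = 7)
  be <- pairwise_backend(cx$params)
  s <- cx$structure
  lig <- dplyr::mutate(ligand_atoms(s), x = x + 1e6)
  frag <- build_capped_fragment(s, "A", 3)
  e_far <- mfcc_interaction_energy(assemble_systems(frag, lig), be)
  expect_lt(abs(e_far), 1e-5)
  # rigid motion of the whole complex leaves the interaction unchanged
  lig0 <- ligand_atoms(s)
  e0 <- mfcc_interaction_energy(assemble_systems(frag, lig0), be)
  moved <- rigid_motion(dplyr::bind_rows(frag, lig0), seed = 3)
  frag_m <- dplyr::filter(moved, eleno %in% frag$eleno)
  lig_m <- dplyr::filter(moved, eleno %in% lig0$eleno)
  e_m <- mfcc_interaction_energy(assemble_systems(frag_m, lig_m), be)
  expect_lt(abs(e_m - e0), 1e-8)
})

test_that("site decomposition conserves totals and exact region attribution", {
  cx <- toy_complex(seed = 5)
  be <- pairwise_backend(cx$params)
  dec <- decompose_site(cx$structure, "LIG", be, region_map = cx$region_map)
  expect_equal(nrow(dec), 5)
  expect_lt(
    max(abs(dec$region_i + dec$region_ii + dec$region_iii - dec$energy)),
    1e-9
  )
  all_res <- dplyr::filter(
    cx$structure, kind == "amino_acid",
    resno %in% dec$resno
  )
  e_total <- interaction_energy_direct(
    all_res, ligand_atoms(cx$structure), cx$params
  )
  expect_lt(abs(sum(dec$energy) - e_total), 1e-8)
  # empty selection yields an empty frame
  far <- dplyr::mutate(cx$structure, x = ifelse(resid == "LIG", x + 1e5, x))
  expect_equal(nrow(decompose_site(far, "LIG", be)), 0)
})

test_that("non-additive backends get region tags but no numeric breakdown", {
  cx <- toy_complex(seed = 8)
  fake <- energy_backend(
    function(atoms) {
      if (nrow(atoms) == 0) 0 else sum(atoms$x)^2 / 1e4
    },
    pairwise_additive = FALSE
  )
  dec <- decompose_site(cx$structure, "LIG", fake, region_map = cx$region_map)
  expect_true(all(is.na(dec$region_i)))
  expect_true(all(dec$region_tag %in% c("i", "ii", "iii")))
})

test_that("radius profiles are cumulative, conservative and match refiltering", {
  dec <- tibble::tibble(
    chain = "A", resno = 1:4, insert = "", resid = "ALA",
    min_distance = c(4.2, 2.0, 7.5, 9.9),
    energy = c(-5, -1, -2, 3)
  )
  prof <- radius_profile(dec, c(1, 3, 4.2, 8, 12))
  expect_equal(prof$cumulative_energy, c(0, -1, -6, -8, -5))
  expect_equal(prof$cumulative_energy[nrow(prof)], sum(dec$energy))
  # refiltering oracle on a generated decomposition
  cx <- toy_complex(seed = 9)
  be <- pairwise_backend(cx$params)
  d2 <- decompose_site(cx$structure, "LIG", be)
  radii <- seq(2, 10, by = 0.5)
  p2 <- radius_profile(d2, radii)
  oracle <- vapply(
    radii,
    function(r) sum(d2$energy[d2$min_distance <= r]), numeric(1)
  )
  expect_equal(p2$cumulative_energy, oracle)
  expect_error(radius_profile(dec, c(3, 2)), "strictly increasing")
})

test_that("system export writes PDB, XYZ and a consistent manifest", {
  cx <- toy_complex(seed = 2)
  frag <- build_capped_fragment(cx$structure, "A", 3)
  sys <- assemble_systems(frag, ligand_atoms(cx$structure))
  dir <- withr::local_tempdir()
  man <- export_systems(sys, dir, prefix = "r3")
  for (nm in c("S1", "S2", "S3", "S4")) {
    expect_true(file.exists(man[[nm]]$pdb))
    expect_true(file.exists(man[[nm]]$xyz))
    expect_equal(nrow(read_pdb(man[[nm]]$pdb)), man[[nm]]$n_atoms)
    expect_equal(
      as.integer(readLines(man[[nm]]$xyz, n = 1)),
      man[[nm]]$n_atoms
    )
  }
  js <- jsonlite::read_json(file.path(dir, "r3_manifest.json"))
  expect_equal(js$S2$n_atoms, nrow(sys$S2))
})
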