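planted_pair <- function(cx) {
  s <- cx$structure
  don <- dplyr::filter(s, resno == 2, elety == "N")$eleno
  acc <- dplyr::filter(s, elety == "O17")$eleno
  list(s = s, don = don, acc = acc)
}

count_planted <- function(structure, don, acc, criteria = hbond_criteria()) {
  hb <- detect_hbonds(
    structure,
    dplyr::filter(structure, kind == "amino_acid"),
    dplyr::filter(structure, kind == "ligand"),
    criteria
  )
  sum(hb$donor_serial == don & hb$acceptor_serial == acc)
}

test_that("planted geometries are detected with their exact distance and angle", {
  p <- planted_pair(toy_complex(seed = 1))
  ps <- plant_hbond(p$s, p$don, p$acc, 2.9, 165, direction = c(0, 0, 1))
  hb <- detect_hbonds(
    ps, dplyr::filter(ps, kind == "amino_acid"),
    dplyr::filter(ps, kind == "ligand")
  )
  expect_equal(nrow(hb), 1)
  expect_equal(hb$da_distance, 2.9, tolerance = 1e-6)
  expect_equal(hb$dha_angle, 165, tolerance = 1e-6)
  expect_true(hb$angle_checked)
  expect_true(is.na(hb$bridging_water))
})

test_that("distance and angle criteria reject geometry outside the window", {
  p <- planted_pair(toy_complex(seed = 1))
  # beyond the 3.4 A donor-acceptor maximum
  ps <- plant_hbond(p$s, p$don, p$acc, 3.5, 165, direction = c(0, 0, 1))
  expect_equal(count_planted(ps, p$don, p$acc), 0)
  # angle below the 90 degree minimum
  ps2 <- plant_hbond(p$s, p$don, p$acc, 2.9, 85, direction = c(0, 0, 1))
  expect_equal(count_planted(ps2, p$don, p$acc), 0)
})

test_that("both geometric boundaries are inclusive, and barely beyond is rejected", {
  p <- planted_pair(toy_complex(seed = 1))
  at <- function(d, a) {
    count_planted(
      plant_hbond(p$s, p$don, p$acc, d, a, direction = c(0, 0, 1)),
      p$don, p$acc
    )
  }
  expect_equal(at(3.4, 165), 1)
  expect_equal(at(2.9, 90), 1)
  expect_equal(at(3.4, 90), 1)
  expect_equal(at(3.4 + 1e-6, 90), 0)
  expect_equal(at(3.4, 90 - 1e-6), 0)
  expect_equal(at(2.9, 180), 1)
})

test_that("bond detection is symmetric in the group arguments", {
  p <- planted_pair(toy_complex(seed = 2))
  ps <- plant_hbond(p$s, p$don, p$acc, 3.0, 150, direction = c(0, 0, 1))
  ga <- dplyr::filter(ps, kind == "amino_acid")
  gb <- dplyr::filter(ps, kind == "ligand")
  h1 <- detect_hbonds(ps, ga, gb)
  h2 <- detect_hbonds(ps, gb, ga)
  expect_equal(h1, h2)
})

test_that("hydrogen-free structures degrade to flagged distance-only detection", {
  p <- planted_pair(toy_complex(seed = 3))
  ps <- plant_hbond(p$s, p$don, p$acc, 3.0, 150, direction = c(0, 0, 1))
  noh <- dplyr::filter(ps, element != "H")
  hb <- detect_hbonds(
    noh, dplyr::filter(noh, kind == "amino_acid"),
    dplyr::filter(noh, kind == "ligand")
  )
  planted_row <- dplyr::filter(
    hb, donor_serial == p$don, acceptor_serial == p$acc
  )
  expect_equal(nrow(planted_row), 1)
  expect_false(planted_row$angle_checked)
  expect_true(is.na(planted_row$dha_angle))
})

test_that("water bridges require the criteria on both sides", {
  p <- planted_pair(toy_complex(seed = 4))
  s <- p$s
  # place a water O midway between donor N and the ligand acceptor path
  don_at <- dplyr::filter(s, eleno == p$don)
  acc_at <- dplyr::filter(s, eleno == p$acc)
  mk_water <- function(pos, resno, serial) {
    tibble::tibble(
      frame = 1L, time_ns = 0, eleno = serial, elety = "O", element = "O",
      x = pos[1], y = pos[2], z = pos[3], chain = "W", resno = resno,
      insert = "", resid = "HOH", kind = "water", charge = 0
    )
  }
  # drop hydrogens so both sides run in distance-only mode with exact control
  s_noh <- dplyr::filter(s, element != "H")
  don_pos <- c(don_at$x, don_at$y, don_at$z)
  w_good <- mk_water(don_pos + c(0, 0, 2.8), 701L, 6001L)
  # move the acceptor to within range of the water
  ai <- which(s_noh$eleno == p$acc)
  s_noh$x[ai] <- w_good$x
  s_noh$y[ai] <- w_good$y
  s_noh$z[ai] <- w_good$z + 2.8
  sw <- dplyr::bind_rows(s_noh, w_good)
  br <- detect_water_bridges(
    sw, dplyr::filter(sw, kind == "amino_acid"),
    dplyr::filter(sw, kind == "ligand")
  )
  expect_gt(nrow(br), 0)
  expect_true(all(br$bridging_water == "W:701"))
  expect_true(any(br$donor_serial == p$don & br$acceptor_serial == p$acc))
  # water in range of only one side bridges nothing
  w_half <- mk_water(don_pos + c(0, 0, 200), 702L, 6002L)
  sw2 <- dplyr::bind_rows(s_noh, w_half)
  s_only <- dplyr::filter(sw2, resno != 701)
  expect_equal(nrow(detect_water_bridges(
    s_only, dplyr::filter(s_only, kind == "amino_acid"),
    dplyr::filter(s_only, kind == "ligand")
  )), 0)
  # no waters at all
  expect_equal(nrow(detect_water_bridges(
    s_noh, dplyr::filter(s_noh, kind == "amino_acid"),
    dplyr::filter(s_noh, kind == "ligand")
  )), 0)
})

test_that("occupancy equals the exact fraction of frames with the bond", {
  tr <- make_occupancy_trajectory(1, 4)
  occ <- hbond_occupancy(
    tr$trajectory,
    dplyr::filter(tr$trajectory, frame == 1, kind == "amino_acid"),
    dplyr::filter(tr$trajectory, frame == 1, kind == "ligand")
  )
  row <- dplyr::filter(occ, donor_serial == tr$don, acceptor_serial == tr$acc)
  expect_equal(row$occupancy_percent, 25)
  expect_equal(row$frames_present, 1)
  expect_equal(row$frames_total, 4)
  # always present -> 100
  tr2 <- make_occupancy_trajectory(5, 5)
  occ2 <- hbond_occupancy(
    tr2$trajectory,
    dplyr::filter(tr2$trajectory, frame == 1, kind == "amino_acid"),
    dplyr::filter(tr2$trajectory, frame == 1, kind == "ligand")
  )
  expect_equal(
    dplyr::filter(occ2, donor_serial == tr2$don)$occupancy_percent, 100
  )
  expect_error(hbond_occupancy(
    tr$trajectory[0, ], tr$trajectory, tr$trajectory
  ), "empty")
})

test_that("contacts inside the shell are typed and outside ignored", {
  cx <- toy_complex(seed = 5, contact_distance = 3.0)
  ct <- classify_contacts(cx$structure, "LIG")
  expect_true(all(ct$distance <= 4 + 1e-9))
  expect_true(all(ct$contact_type %in% c(
    "hydrogen bond", "hydrophobic (alkyl)", "van der Waals"
  )))
  # carbon-carbon contacts are hydrophobic
  cc <- dplyr::filter(ct, elety %in% c("CA", "CB", "C"))
  if (nrow(cc) > 0) {
    expect_true(all(cc$contact_type %in% c("hydrophobic (alkyl)", "hydrogen bond")))
  }
  # a planted hydrogen bond is delegated to the bond detector
  p <- planted_pair(cx)
  ps <- plant_hbond(cx$structure, p$don, p$acc, 3.0, 160, direction = c(0, 0, 1))
  ct2 <- classify_contacts(ps, "LIG")
  don_row <- dplyr::filter(ct2, resno == 2, elety == "N")
  expect_equal(don_row$contact_type, "hydrogen bond")
  # far ligand: nothing in the shell
  far <- dplyr::mutate(
    cx$structure, x = ifelse(resid == "LIG", x + 100, x)
  )
  expect_equal(nrow(classify_contacts(far, "LIG")), 0)
})
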