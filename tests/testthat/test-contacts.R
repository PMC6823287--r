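# Typed contact detection and context labelling.

test_that("hydrogen bonds respect the distance cutoff and MM/MS/SS classes", {
  # backbone N...O at 2.9 A across chains
  atom <- rbind(
    atoms_row("A", 1L, "GLY", "N", "N", 0, 0, 0),
    atoms_row("A", 1L, "GLY", "CA", "C", 1.45, 0, 0),
    atoms_row("B", 9L, "GLY", "O", "O", 0, 2.9, 0),
    atoms_row("B", 9L, "GLY", "CA", "C", 1.0, 3.9, 0))
  hb <- hydrogen_bonds(structure_from_atoms(atom))
  expect_equal(nrow(hb), 1)
  expect_identical(hb$type, "HBOND_MM")
  expect_equal(hb$distance, 2.9, tolerance = 1e-3)

  # 3.6 A: beyond the 3.5 cutoff
  atom$y[3] <- 3.6
  expect_equal(nrow(hydrogen_bonds(structure_from_atoms(atom))), 0)

  # side chain vs backbone gives MS
  atom2 <- rbind(
    stub_residue("A", 1L, "SER", "OG", "O", c(0, 0, 0), c(0, -1, 0)),
    atoms_row("A", 9L, "GLY", "O", "O", 0, 3.0, 0),
    atoms_row("A", 9L, "GLY", "CA", "C", 1.2, 4.0, 0))
  hb2 <- hydrogen_bonds(structure_from_atoms(atom2))
  expect_true("HBOND_MS" %in% hb2$type)
})

test_that("helix hydrogen bonds equal brute-force enumeration", {
  toy <- gen_toy_structure("ideal_helix", n = 12)
  st <- parse_toy(toy)
  hb <- hydrogen_bonds(st)
  expect_setequal(interaction_pair_keys(hb), brute_hbond_pairs(st$atom))
  # the planted truth from the generator matches too
  truth_keys <- with(toy$truth$hbonds,
                     paste(pmin(paste(chain_n, resno_n, sep = ":"),
                                paste(chain_o, resno_o, sep = ":")),
                           pmax(paste(chain_n, resno_n, sep = ":"),
                                paste(chain_o, resno_o, sep = ":"))))
  expect_setequal(interaction_pair_keys(hb), unique(truth_keys))
  # detectors are symmetric in their selections
  s1 <- atom_select(st, resno = 1:6); s2 <- atom_select(st, resno = 7:12)
  expect_setequal(interaction_pair_keys(hydrogen_bonds(st, s1, s2)),
                  interaction_pair_keys(hydrogen_bonds(st, s2, s1)))
})

test_that("salt bridges detect charged pairs within 6 A, strong at 4 A", {
  st <- parse_toy(gen_toy_structure("ion_pair", distance = 3.2))
  sb <- salt_bridges(st)
  expect_equal(nrow(sb), 1)
  expect_identical(sb$atom_a, "OD1")
  expect_identical(sb$atom_b, "NH1")
  expect_true(sb$strong)

  st2 <- parse_toy(gen_toy_structure("ion_pair", distance = 5.5))
  sb2 <- salt_bridges(st2)
  expect_equal(nrow(sb2), 1)
  expect_false(sb2$strong)

  expect_equal(nrow(salt_bridges(parse_toy(
    gen_toy_structure("ion_pair", distance = 6.5)))), 0)

  # Asp against an uncharged Ser at 3.0 A is not a salt bridge
  atom <- rbind(
    stub_residue("A", 1L, "ASP", "OD1", "O", c(0, 0, 0), c(0, -1, 0)),
    stub_residue("A", 5L, "SER", "OG", "O", c(3.0, 0, 0), c(1, 0, 0)))
  expect_equal(nrow(salt_bridges(structure_from_atoms(atom))), 0)
})

test_that("hydrophobic contacts need apolar side-chain carbons on both sides", {
  atom <- rbind(
    stub_residue("A", 1L, "LEU", "CD1", "C", c(0, 0, 0), c(0, -1, 0)),
    stub_residue("A", 5L, "ILE", "CD1", "C", c(4.0, 0, 0), c(1, 0, 0)),
    stub_residue("A", 9L, "SER", "OG", "O", c(0, 4.0, 0), c(0, 1, 0)))
  st <- structure_from_atoms(atom)
  hp <- hydrophobic_contacts(st)
  expect_equal(nrow(hp), 1)
  expect_setequal(c(hp$resid_a, hp$resid_b), c("LEU", "ILE"))

  # contact count equals the all-pairs oracle over side-chain carbons
  pick <- which(st$atom$resid %in% c("ALA", "VAL", "LEU", "ILE", "MET",
                                     "PHE", "TRP", "PRO", "TYR") &
                  st$atom$elesy == "C" &
                  !st$atom$elety %in% c("N", "CA", "C", "O", "OXT"))
  expect_setequal(interaction_pair_keys(hp),
                  brute_residue_pairs(st$atom, pick, pick, 5.0))
})

test_that("water bridges and ligand polar contacts match the planted pocket", {
  toy <- gen_toy_structure("pocket_with_ligand_and_waters")
  st <- parse_toy(toy)

  lp <- ligand_polar_contacts(st, "4IP")
  expect_setequal(unique(lp$resno_a), toy$truth$ligand_polar_resno)
  # carbon-only proximity does not count: no contact involves C atoms
  expect_false(any(grepl("^C", lp$atom_b)))

  wb <- water_bridges(st)
  expect_equal(nrow(wb), nrow(toy$truth$water_bridges))
  expect_setequal(wb$resno_a, toy$truth$water_bridges$resno)
  expect_setequal(wb$resno_w, toy$truth$water_bridges$water_resno)
  expect_false(toy$truth$nonbridging_water %in% wb$resno_w)
  # brute-force triple enumeration agrees
  expect_setequal(paste(wb$chain_a, wb$resno_a, wb$resno_w),
                  brute_water_bridges(st$atom))

  expect_error(ligand_polar_contacts(st, "XYZ"), "4IP")
})

test_that("all detectors are invariant under rigid motion", {
  toy <- gen_toy_structure("pocket_with_ligand_and_waters")
  a1 <- toy$atom
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  xyz <- as.matrix(a1[, c("x", "y", "z")]) %*% R
  a2 <- a1
  a2$x <- xyz[, 1] - 7; a2$y <- xyz[, 2] + 3; a2$z <- xyz[, 3] + 11
  s1 <- structure_from_atoms(a1); s2 <- structure_from_atoms(a2)
  expect_setequal(
    paste(water_bridges(s1)$resno_a, water_bridges(s1)$resno_w),
    paste(water_bridges(s2)$resno_a, water_bridges(s2)$resno_w))
  expect_setequal(interaction_pair_keys(ligand_polar_contacts(s1, "4IP")),
                  interaction_pair_keys(ligand_polar_contacts(s2, "4IP")))
})

test_that("shrinking a cutoff yields a subset and distances obey their cutoff", {
  st <- parse_toy(gen_toy_structure("ideal_helix", n = 12))
  hb35 <- hydrogen_bonds(st, cutoff = 3.5)
  hb32 <- hydrogen_bonds(st, cutoff = 3.2)
  expect_true(all(interaction_pair_keys(hb32) %in% interaction_pair_keys(hb35)))
  expect_true(all(hb35$distance <= 3.5))
  expect_true(all(hb32$distance <= 3.2))

  stp <- parse_toy(gen_toy_structure("pocket_with_ligand_and_waters"))
  lp30 <- ligand_polar_contacts(stp, "4IP", cutoff = 3.0)
  lp35 <- ligand_polar_contacts(stp, "4IP", cutoff = 3.5)
  expect_true(all(interaction_pair_keys(lp30) %in% interaction_pair_keys(lp35)))
})

test_that("context labels distinguish intra-segment, inter-segment, inter-chain", {
  fx <- role_fixture()
  ints <- fx$interactions
  ic <- ints[ints$chain_a != ints$chain_b, ]
  expect_true(all(ic$context == "INTER_CHAIN"))
  is_ <- ints[ints$chain_a == ints$chain_b &
                ints$seg_a != ints$seg_b, ]
  expect_true(all(is_$context == "INTER_SEGMENT"))
  expect_true(any(ints$context == "INTRA_SEGMENT"))

  # residues outside any named segment are kept as UNASSIGNED
  segs <- segment_map(name = "PH", chain = "A", start = 1L, end = 2L)
  toy <- parse_toy(gen_toy_structure("ideal_helix", n = 12))
  lab <- label_context(hydrogen_bonds(toy), segs)
  expect_true("UNASSIGNED" %in% c(lab$seg_a, lab$seg_b))
  expect_gt(nrow(lab), 0)
})
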