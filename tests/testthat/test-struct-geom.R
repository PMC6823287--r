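# PDB parsing, Shrake-Rupley SASA, relative accessibility, burial.

test_that("PDB parsing keeps one altloc, drops hydrogens, tags HET groups", {
  lines <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.60  0.00           C",
    "ATOM      3  CA BALA A   1      11.700   6.100  -5.200  0.40  0.00           C",
    "ATOM      4  C   ALA A   1      12.000   7.400  -4.500  1.00  0.00           C",
    "ATOM      5  O   ALA A   1      12.600   7.400  -3.400  1.00  0.00           O",
    "ATOM      6  H   ALA A   1      10.500   5.500  -7.000  1.00  0.00           H",
    "HETATM    7  O   HOH W 101      20.000  20.000  20.000  1.00  0.00           O",
    "HETATM    8  P1  4IP L 201       0.000   0.000   0.000  1.00  0.00           P",
    "END")
  p <- tempfile(fileext = ".pdb")
  writeLines(lines, p)
  st <- parse_structure(p)
  ca <- st$atom[st$atom$elety == "CA", ]
  expect_equal(nrow(ca), 1)                     # altloc resolved
  expect_equal(ca$x, 11.639)                    # occupancy 0.6 copy kept
  expect_false(any(st$atom$elesy == "H"))       # hydrogens dropped
  expect_true(st$atom$water[st$atom$resid == "HOH"])
  expect_true(st$atom$ligand[st$atom$resid == "4IP"])
  expect_equal(nrow(st$atom), 6)

  # the higher-occupancy altloc wins even when it is not 'A'
  lines_b <- sub("AALA A   1      11.639   6.071  -5.147  0.60",
                 "AALA A   1      11.639   6.071  -5.147  0.40", lines)
  lines_b <- sub("BALA A   1      11.700   6.100  -5.200  0.40",
                 "BALA A   1      11.700   6.100  -5.200  0.60", lines_b)
  writeLines(lines_b, p)
  st_b <- parse_structure(p)
  expect_equal(st_b$atom$x[st_b$atom$elety == "CA"], 11.700)

  writeLines(c("HETATM    1  O   HOH W 101       0.0     0.0     0.0  1.00  0.00           O",
               "END"), p)
  expect_error(parse_structure(p), "no ATOM")
})

test_that("an isolated carbon's SASA matches the analytic sphere area", {
  sasa <- shrake_rupley(data.frame(elesy = "C", x = 0, y = 0, z = 0,
                                   het = FALSE))
  expect_equal(sasa$atom_area, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.005)
})

test_that("a fully enclosed atom has zero accessible area", {
  st <- parse_toy(gen_toy_structure("enclosed_atom"))
  rsa <- relative_accessibility(shrake_rupley(st))
  expect_equal(rsa$area[rsa$number == 1], 0)
  expect_gt(rsa$area[rsa$number == 20], 100)    # distant atom fully exposed
})

test_that("per-atom areas agree with a high-resolution quadrature oracle", {
  atoms <- data.frame(
    elesy = c("C", "N", "O"),
    x = c(0, 1.8, 3.1), y = c(0, 0.7, -0.4), z = c(0, -0.5, 0.6),
    het = FALSE)
  got <- shrake_rupley(atoms)$atom_area
  want <- sasa_quadrature(atoms, n_points = 10000)
  expect_equal(got, want, tolerance = 0.02)
})

test_that("total SASA is invariant under rigid motion", {
  toy <- gen_toy_structure("ideal_helix", n = 8)
  a1 <- toy$atom
  th <- 0.73
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(a1[, c("x", "y", "z")]) %*% R
  a2 <- a1
  a2$x <- xyz[, 1] + 5.3; a2$y <- xyz[, 2] - 2.1; a2$z <- xyz[, 3] + 9.9
  t1 <- sum(shrake_rupley(a1)$atom_area)
  t2 <- sum(shrake_rupley(a2)$atom_area)
  expect_lt(abs(t1 - t2) / t1, 0.005)
})

test_that("adding an atom never increases any other atom's area", {
  base <- data.frame(elesy = c("C", "N"), x = c(0, 2.5), y = 0, z = 0,
                     het = FALSE)
  more <- rbind(base, data.frame(elesy = "O", x = 1.2, y = 1.8, z = 0,
                                 het = FALSE))
  a_base <- shrake_rupley(base)$atom_area
  a_more <- shrake_rupley(more)$atom_area[1:2]
  expect_true(all(a_more <= a_base + 1e-9))
})

test_that("relative accessibility spans the exposed and buried limits", {
  # a lone residue is (essentially) fully exposed relative to the reference
  lone <- structure_from_atoms(build_backbone(1, phi = -57, psi = -47))
  rsa <- relative_accessibility(shrake_rupley(lone))
  expect_gt(rsa$rsa, 80)

  helix <- structure_from_atoms(build_backbone(5, phi = -57, psi = -47))
  s <- shrake_rupley(helix)
  rsa5 <- relative_accessibility(s)
  want <- sasa_quadrature(s$atom, n_points = 10000)
  per_res <- tapply(want, s$atom$resno, sum)
  mid <- rsa5$area[rsa5$number == 3]
  expect_equal(mid, unname(per_res["3"]), tolerance = 0.02)

  # nonstandard residues are flagged, not scored
  st <- parse_toy(gen_toy_structure("pocket_with_ligand_and_waters"))
  r <- relative_accessibility(shrake_rupley(st, include_het = TRUE))
  expect_true(all(r$nonstandard[r$resname %in% c("4IP", "HOH")]))
  expect_true(all(is.na(r$rsa[r$nonstandard])))
})

test_that("burial is inclusive at the cutoff", {
  m <- data.frame(chain = "A", number = 1:3, insert = "",
                  resname = "ALA", area = 1,
                  rsa = c(7.0, 7.01, 3), nonstandard = FALSE)
  b <- buried_set(m)
  expect_setequal(b$number, c(1, 3))
  expect_equal(nrow(buried_set(m[0, ])), 0)
})

test_that("per-residue areas agree with an independent implementation", {
  toy <- gen_toy_structure("ideal_helix", n = 10)
  pdb <- tempfile(fileext = ".pdb")
  write_toy_structure(toy, pdb)
  st <- parse_structure(pdb)
  s <- shrake_rupley(st, n_points = 1920)
  mine <- relative_accessibility(s)

  py <- tempfile(fileext = ".py")
  out <- tempfile(fileext = ".tsv")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "import biotite.structure.io.pdb as pdbio",
    "import biotite.structure as struc",
    "arr = pdbio.PDBFile.read(sys.argv[1]).get_structure(model=1)",
    "sasa = struc.sasa(arr, probe_radius=1.4, point_number=5000,",
    "                  vdw_radii='Single')",
    "res = {}",
    "for rid, a in zip(arr.res_id, sasa):",
    "    res[int(rid)] = res.get(int(rid), 0.0) + float(a)",
    "with open(sys.argv[2], 'w') as fh:",
    "    for k in sorted(res):",
    "        fh.write(f'{k}\\t{res[k]}\\n')"), py)
  status <- system2("python", c(py, pdb, out), stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  ref <- utils::read.delim(out, header = FALSE,
                           col.names = c("number", "area"))
  merged <- merge(mine, ref, by = "number")
  expect_gt(nrow(merged), 5)
  rel <- abs(merged$area.x - merged$area.y) / pmax(merged$area.y, 1)
  expect_lt(max(rel), 0.05)
})
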