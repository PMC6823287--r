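# Toy coordinate generators with planted geometry, plus a PDB writer.

# place atom D given A-B-C, bond |CD|, angle B-C-D and torsion A-B-C-D (NeRF)
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + bond * (-cos(th) * bc + sin(th) * (cos(chi) * m + sin(chi) * n))
}

# poly-glycine backbone with fixed torsions (standard bond geometry)
build_backbone <- function(n, phi, psi, chain = "A", resno_start = 1L) {
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3)
  C <- matrix(0, n, 3); O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)[-1]) {
    N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], 1.329, 116.2, psi)
    CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
    C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
  }
  for (i in 1:n)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi + 180)
  do.call(rbind, lapply(1:n, function(i) data.frame(
    chain = chain, resno = resno_start + i - 1L, resid = "GLY",
    elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
    x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
    y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
    z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
    het = FALSE, stringsAsFactors = FALSE)))
}

atoms_row <- function(chain, resno, resid, elety, elesy, x, y, z, het = FALSE) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             elesy = elesy, x = x, y = y, z = z, het = het,
             stringsAsFactors = FALSE)
}

# residue from a key (side-chain) atom plus a collinear backbone stub
# pointing outward along unit vector u
stub_residue <- function(chain, resno, resid, key_name, key_elesy, p, u) {
  rbind(
    atoms_row(chain, resno, resid, key_name, key_elesy,
              p[1], p[2], p[3]),
    atoms_row(chain, resno, resid, "CA", "C",
              p[1] + 3.2 * u[1], p[2] + 3.2 * u[2], p[3] + 3.2 * u[3]),
    atoms_row(chain, resno, resid, "N", "N",
              p[1] + 4.4 * u[1], p[2] + 4.4 * u[2], p[3] + 4.4 * u[3]),
    atoms_row(chain, resno, resid, "C", "C",
              p[1] + 5.6 * u[1], p[2] + 5.6 * u[2], p[3] + 5.6 * u[3]),
    atoms_row(chain, resno, resid, "O", "O",
              p[1] + 6.9 * u[1], p[2] + 6.9 * u[2], p[3] + 6.9 * u[3]))
}

#' Format an atom table as PDB text
#'
#' @param atom Data frame with `chain`, `resno`, `resid`, `elety`, `elesy`,
#'   `x`, `y`, `z`, `het` columns.
#' @param header Optional REMARK lines (character vector).
#' @return Character vector of PDB lines (terminated by `END`).
#' @export
format_pdb <- function(atom, header = NULL) {
  lines <- sprintf(
    "%-6s%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atom$het, "HETATM", "ATOM"), seq_len(nrow(atom)),
    atom$elety, atom$resid, atom$chain, atom$resno,
    atom$x, atom$y, atom$z, 1.00, 0.00, atom$elesy)
  c(if (!is.null(header)) paste("REMARK 999", header), lines, "END")
}

# independent brute-force enumeration of backbone N...O pairs within cutoff
# (sequence separation >= 2 within a chain), used as planted truth
enumerate_backbone_hbonds <- function(atom, cutoff = 3.5) {
  don <- which(atom$elety == "N" & !atom$het)
  acc <- which(atom$elety == "O" & !atom$het)
  out <- NULL
  for (i in don) for (j in acc) {
    if (atom$chain[i] == atom$chain[j] &&
        abs(atom$resno[i] - atom$resno[j]) < 2L) next
    d <- sqrt(sum((c(atom$x[i], atom$y[i], atom$z[i]) -
                     c(atom$x[j], atom$y[j], atom$z[j]))^2))
    if (d <= cutoff)
      out <- rbind(out, data.frame(
        chain_n = atom$chain[i], resno_n = atom$resno[i],
        chain_o = atom$chain[j], resno_o = atom$resno[j], distance = d,
        stringsAsFactors = FALSE))
  }
  out %||% data.frame(chain_n = character(), resno_n = integer(),
                      chain_o = character(), resno_o = integer(),
                      distance = numeric())
}

icosahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
    c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
    c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(1 + phi^2)
}

#' Generate a toy structure with planted geometry
#'
#' Recipes:
#' \describe{
#'   \item{`ideal_helix`}{`n`-residue poly-glycine alpha helix (phi -57,
#'     psi -47); planted truth is the brute-force list of backbone N...O
#'     pairs within the H-bond cutoff (the i, i+4 helical ladder).}
#'   \item{`strand_pair`}{Two parallel extended strands; the inter-strand
#'     offset is scanned deterministically until at least two cross-strand
#'     N...O pairs land in H-bond range.}
#'   \item{`ion_pair`}{An Asp and an Arg side chain whose closest
#'     charged-atom pair (OD1...NH1) sits at exactly `distance` Angstrom.}
#'   \item{`enclosed_atom`}{A central carbon buried under a 12-vertex
#'     icosahedral shell of overlapping carbons (SASA exactly 0), plus one
#'     distant fully exposed carbon.}
#'   \item{`pocket_with_ligand_and_waters`}{A star-shaped pocket: a
#'     phosphoinositide-like HET group (code 4IP) with four planted direct
#'     polar contacts (Lys NZ 2.7, Arg NH1 2.7, Ser OG 2.8, Tyr OH 3.0
#'     Angstrom), two protein-water-ligand bridges and one non-bridging
#'     water.}
#' }
#'
#' @param recipe One of the recipe names above.
#' @param n Residues per chain for the backbone recipes (default 12).
#' @param distance Charged-atom distance for `ion_pair` (default 3.2).
#' @return List: `atom` (atom table), `pdb` (PDB text lines), `truth`
#'   (recipe-specific planted facts).
#' @export
gen_toy_structure <- function(recipe = c("ideal_helix", "strand_pair",
                                         "ion_pair", "enclosed_atom",
                                         "pocket_with_ligand_and_waters"),
                              n = 12, distance = 3.2) {
  recipe <- match.arg(recipe)
  if (recipe == "ideal_helix") {
    atom <- build_backbone(n, phi = -57, psi = -47)
    truth <- list(hbonds = enumerate_backbone_hbonds(atom))
  } else if (recipe == "strand_pair") {
    s1 <- build_backbone(n, phi = -139, psi = 135, chain = "A")
    dy <- NA
    for (try_dy in seq(3.8, 6.0, by = 0.05)) {
      s2 <- s1
      s2$y <- s2$y + try_dy
      hb <- enumerate_backbone_hbonds(rbind(s1, transform(s2, chain = "B")))
      hb <- hb[hb$chain_n != hb$chain_o & hb$distance >= 2.6, , drop = FALSE]
      if (nrow(hb) >= 2L) { dy <- try_dy; break }
    }
    s2 <- s1
    s2$chain <- "B"
    s2$y <- s2$y + dy
    s2$resno <- s2$resno
    atom <- rbind(s1, s2)
    truth <- list(offset = dy, hbonds = enumerate_backbone_hbonds(atom))
  } else if (recipe == "ion_pair") {
    d <- distance
    asp <- rbind(
      atoms_row("A", 1L, "ASP", "OD1", "O", 0, 0, 0),
      atoms_row("A", 1L, "ASP", "OD2", "O", -1.1, 1.9, 0),
      atoms_row("A", 1L, "ASP", "CG", "C", -0.8, 0.95, 0),
      atoms_row("A", 1L, "ASP", "CB", "C", -1.6, 2.2, 0),
      atoms_row("A", 1L, "ASP", "CA", "C", -3.0, 3.0, 0),
      atoms_row("A", 1L, "ASP", "N", "N", -3.9, 3.9, 0),
      atoms_row("A", 1L, "ASP", "C", "C", -4.0, 2.2, 0),
      atoms_row("A", 1L, "ASP", "O", "O", -5.2, 2.4, 0))
    arg <- rbind(
      atoms_row("A", 10L, "ARG", "NH1", "N", d, 0, 0),
      atoms_row("A", 10L, "ARG", "CZ", "C", d + 1.3, 0.4, 0),
      atoms_row("A", 10L, "ARG", "NH2", "N", d + 2.2, 1.3, 0),
      atoms_row("A", 10L, "ARG", "NE", "N", d + 2.0, -0.7, 0),
      atoms_row("A", 10L, "ARG", "CD", "C", d + 3.4, -0.9, 0),
      atoms_row("A", 10L, "ARG", "CG", "C", d + 4.4, -0.2, 0),
      atoms_row("A", 10L, "ARG", "CB", "C", d + 5.6, -0.8, 0),
      atoms_row("A", 10L, "ARG", "CA", "C", d + 7.0, -0.2, 0),
      atoms_row("A", 10L, "ARG", "N", "N", d + 7.8, 0.9, 0),
      atoms_row("A", 10L, "ARG", "C", "C", d + 7.9, -1.3, 0),
      atoms_row("A", 10L, "ARG", "O", "O", d + 9.0, -1.6, 0))
    atom <- rbind(asp, arg)
    truth <- list(min_charged_distance = d,
                  salt_bridge = d <= 6.0,
                  pair = c("A:1", "A:10"))
  } else if (recipe == "enclosed_atom") {
    shell <- icosahedron_vertices() * 2.0
    atom <- rbind(
      atoms_row("A", 1L, "GLY", "CA", "C", 0, 0, 0),
      do.call(rbind, lapply(seq_len(nrow(shell)), function(k)
        atoms_row("A", k + 1L, "GLY", "CA", "C",
                  shell[k, 1], shell[k, 2], shell[k, 3]))),
      atoms_row("A", 20L, "GLY", "CA", "C", 30, 0, 0))
    truth <- list(buried_resno = 1L, exposed_resno = 20L)
  } else {
    # pocket_with_ligand_and_waters
    prot <- rbind(
      stub_residue("A", 1L, "LYS", "NZ", "N", c(5.7, 0, 0), c(1, 0, 0)),
      stub_residue("A", 2L, "ARG", "NH1", "N", c(-5.7, 0, 0), c(-1, 0, 0)),
      stub_residue("A", 3L, "SER", "OG", "O", c(0, 5.8, 0), c(0, 1, 0)),
      stub_residue("A", 4L, "TYR", "OH", "O", c(0, -6.0, 0), c(0, -1, 0)),
      stub_residue("A", 5L, "ASN", "OD1", "O", c(0, 0, 8.7), c(0, 0, 1)),
      stub_residue("A", 6L, "GLN", "NE2", "N", c(0, 0, -8.6), c(0, 0, -1)),
      stub_residue("A", 7L, "GLU", "OE1", "O", c(20, 20, 22.9), c(0, 0, 1)))
    lig <- rbind(
      atoms_row("L", 501L, "4IP", "P1", "P", 0, 0, 0, het = TRUE),
      atoms_row("L", 501L, "4IP", "O1", "O", 3, 0, 0, het = TRUE),
      atoms_row("L", 501L, "4IP", "O2", "O", -3, 0, 0, het = TRUE),
      atoms_row("L", 501L, "4IP", "O3", "O", 0, 3, 0, het = TRUE),
      atoms_row("L", 501L, "4IP", "O4", "O", 0, -3, 0, het = TRUE),
      atoms_row("L", 501L, "4IP", "O5", "O", 0, 0, 3, het = TRUE),
      atoms_row("L", 501L, "4IP", "O6", "O", 0, 0, -3, het = TRUE),
      atoms_row("L", 501L, "4IP", "C1", "C", 1.5, 1.5, 1.5, het = TRUE))
    wat <- rbind(
      atoms_row("W", 601L, "HOH", "O", "O", 0, 0, 5.9, het = TRUE),
      atoms_row("W", 602L, "HOH", "O", "O", 0, 0, -5.8, het = TRUE),
      atoms_row("W", 603L, "HOH", "O", "O", 20, 20, 20, het = TRUE))
    atom <- rbind(prot, lig, wat)
    truth <- list(
      ligand_code = "4IP",
      ligand_polar_resno = c(1L, 2L, 3L, 4L),
      water_bridges = data.frame(resno = c(5L, 6L),
                                 water_resno = c(601L, 602L)),
      nonbridging_water = 603L)
  }
  list(atom = atom, pdb = format_pdb(atom, header = paste("recipe", recipe)),
       truth = truth)
}

#' Write a toy structure to a PDB file
#'
#' @param toy Output of [gen_toy_structure()].
#' @param path File path to write.
#' @return The path, invisibly.
#' @export
write_toy_structure <- function(toy, path) {
  writeLines(toy$pdb, path)
  invisible(path)
}
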