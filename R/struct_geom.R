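# Structure parsing, Shrake-Rupley solvent accessibility and burial flags.

#' Parse a PDB file into a heavy-atom structure table
#'
#' Reads PDB-format text (via bio3d), keeps the first model, resolves
#' alternate locations to the highest-occupancy copy (ties: altloc `A`),
#' drops hydrogens, and tags waters and ligands among the HETATM records.
#'
#' @param pdb_path Path to a PDB-format file.
#' @param model Model number to keep (default 1; only the first model is
#'   supported).
#' @return A `subspec_structure`: list with `atom`, a data frame with columns
#'   `chain`, `resno`, `insert`, `resid`, `elety` (atom name), `elesy`
#'   (element), `x`, `y`, `z`, `o` (occupancy), `het`, `water`, `ligand`.
#' @export
parse_structure <- function(pdb_path, model = 1) {
  if (model != 1) stop("only the first model is supported")
  pdb <- suppressWarnings(bio3d::read.pdb(pdb_path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (!any(at$type == "ATOM")) stop("no ATOM records in ", pdb_path)

  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # element: use the element column where present, else infer from atom name
  elesy <- toupper(at$elesy)
  miss <- is.na(elesy) | elesy == ""
  if (any(miss)) {
    guess <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                 gsub("^[0-9]+", "", at$elety[miss])), 1, 1))
    elesy[miss] <- guess
    warning("element inferred from atom name for ", sum(miss), " atoms")
  }
  at$elesy <- elesy
  at <- at[at$elesy != "H" & at$elesy != "D", , drop = FALSE]

  # altloc resolution: highest occupancy, tie broken by altloc letter
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno, at$insert), ,
           drop = FALSE]

  atom <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                     resid = at$resid, elety = at$elety, elesy = at$elesy,
                     x = at$x, y = at$y, z = at$z, o = at$o,
                     het = at$type == "HETATM",
                     stringsAsFactors = FALSE)
  atom$water <- atom$het & atom$resid %in% WATER_RESNAMES
  atom$ligand <- atom$het & !atom$water
  if (any(!is.finite(c(atom$x, atom$y, atom$z))))
    stop("non-finite coordinates in ", pdb_path)
  rownames(atom) <- NULL
  structure(list(atom = atom, path = pdb_path), class = "subspec_structure")
}

#' @export
print.subspec_structure <- function(x, ...) {
  a <- x$atom
  cat(sprintf("subspec_structure: %d atoms, %d chains (%s), %d waters, %d ligand atoms\n",
              nrow(a), length(unique(a$chain)),
              paste(unique(a$chain), collapse = ","),
              sum(a$water), sum(a$ligand)))
  invisible(x)
}

#' Select atom indices of a structure
#'
#' @param structure A `subspec_structure`.
#' @param chain,resno,resid,elety Optional filters (vectors).
#' @param het `NA` (default) keeps everything, `FALSE` protein only,
#'   `TRUE` HETATM only.
#' @param water,ligand Optional logical filters.
#' @return Integer vector of atom row indices.
#' @export
atom_select <- function(structure, chain = NULL, resno = NULL, resid = NULL,
                        elety = NULL, het = NA, water = NULL, ligand = NULL) {
  a <- structure$atom
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  if (!is.na(het)) keep <- keep & a$het == het
  if (!is.null(water)) keep <- keep & a$water == water
  if (!is.null(ligand)) keep <- keep & a$ligand == ligand
  which(keep)
}

# deterministic golden-spiral point set on the unit sphere
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

atom_radii <- function(atom, probe) {
  r <- VDW_RADII[atom$elesy]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r) + probe
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Places a deterministic golden-spiral point set on each atom's solvent
#' sphere (van der Waals radius + probe) and counts the fraction of points
#' outside every neighbouring sphere; the per-atom area is that fraction of
#' the full sphere area. No randomness is involved, so results are bit-stable
#' across runs.
#'
#' @param structure A `subspec_structure`, or a data frame of atoms
#'   (`elesy`, `x`, `y`, `z`).
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Quadrature points per atom (default 960).
#' @param include_het Include HETATM atoms as occluders and targets
#'   (default FALSE: protein heavy atoms only, the NACCESS convention of
#'   ignoring waters and ligands).
#' @return A `subspec_sasa`: list with `atom_area` (per input atom, Angstrom^2)
#'   and the `atom` table used.
#' @export
shrake_rupley <- function(structure, probe = 1.4, n_points = 960,
                          include_het = FALSE) {
  atom <- if (inherits(structure, "subspec_structure")) structure$atom
          else structure
  if (!isTRUE(include_het) && !is.null(atom$het))
    atom <- atom[!atom$het, , drop = FALSE]
  n <- nrow(atom)
  if (n < 1L) stop("no atoms to compute SASA for")
  xyz <- cbind(atom$x, atom$y, atom$z)
  radii <- atom_radii(atom, probe)
  pts <- golden_spiral_points(n_points)

  # neighbour lists from the full distance matrix (structures here are small)
  d2 <- as.matrix(stats::dist(xyz))^2
  rsum2 <- outer(radii, radii, "+")^2
  nb <- lapply(seq_len(n), function(i) {
    j <- which(d2[i, ] < rsum2[i, ])
    j[j != i]
  })

  area <- numeric(n)
  sphere <- 4 * pi * radii^2
  for (i in seq_len(n)) {
    p <- pts * radii[i]
    p <- cbind(p[, 1] + xyz[i, 1], p[, 2] + xyz[i, 2], p[, 3] + xyz[i, 3])
    exposed <- rep(TRUE, n_points)
    for (j in nb[[i]]) {
      if (!any(exposed)) break
      dj <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      exposed <- exposed & dj > radii[j]^2
    }
    area[i] <- sphere[i] * mean(exposed)
  }
  structure(list(atom_area = area, atom = atom, probe = probe,
                 n_points = n_points),
            class = "subspec_sasa")
}

#' Per-residue relative solvent accessibility
#'
#' Sums atom areas per residue and divides by the residue type's reference
#' maximum (all-atom, extended Gly-X-Gly tripeptide values). Residues without
#' a reference value (nonstandard) are flagged and get `NA` RSA.
#'
#' @param sasa A `subspec_sasa` from [shrake_rupley()].
#' @return Data frame `chain`, `number` (author residue number), `insert`,
#'   `resname`, `area` (Angstrom^2), `rsa` (percent), `nonstandard` flag.
#' @export
relative_accessibility <- function(sasa) {
  a <- sasa$atom
  key <- paste(a$chain, a$resno, a$insert, a$resid, sep = "|")
  first <- !duplicated(key)
  area <- tapply(sasa$atom_area, key, sum)[key[first]]
  out <- data.frame(chain = a$chain[first], number = a$resno[first],
                    insert = a$insert[first], resname = a$resid[first],
                    area = as.numeric(area), stringsAsFactors = FALSE)
  ref <- MAX_ASA[out$resname]
  out$rsa <- 100 * out$area / unname(ref)
  out$nonstandard <- is.na(ref)
  rownames(out) <- NULL
  out
}

#' Buried residues at an RSA cutoff
#'
#' @param rsa_map Data frame from [relative_accessibility()].
#' @param cutoff Percent RSA at or below which a residue is buried
#'   (default 7, inclusive).
#' @return Subset of `rsa_map` rows that are buried (nonstandard residues
#'   never qualify).
#' @export
buried_set <- function(rsa_map, cutoff = 7.0) {
  rsa_map[!is.na(rsa_map$rsa) & rsa_map$rsa <= cutoff, , drop = FALSE]
}
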