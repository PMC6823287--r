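# Typed residue-residue and residue-ligand contact detection: the
# interaction classes of protein-interaction calculators (PIC-style),
# implemented as pure distance criteria for reproducibility.

res_key <- function(atom, i) {
  paste(atom$chain[i], atom$resno[i], atom$insert[i], sep = ":")
}

# all atom pairs (ia x ib) within cutoff and in different residues,
# symmetric in the two selections; returns one row per atom pair
cross_pairs <- function(atom, ia, ib, cutoff) {
  empty <- data.frame(i = integer(), j = integer(), d = numeric())
  if (length(ia) == 0L || length(ib) == 0L) return(empty)
  A <- cbind(atom$x[ia], atom$y[ia], atom$z[ia])
  B <- cbind(atom$x[ib], atom$y[ib], atom$z[ib])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  hit <- which(d2 <= cutoff^2 + 1e-12, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty)
  i <- ia[hit[, 1]]; j <- ib[hit[, 2]]
  keep <- res_key(atom, i) != res_key(atom, j)
  i <- i[keep]; j <- j[keep]
  if (length(i) == 0L) return(empty)
  d <- sqrt(pmax(0, d2[hit][keep]))
  # canonical unordered orientation, then dedupe atom pairs
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  dup <- duplicated(paste(i, j))
  data.frame(i = i[!dup], j = j[!dup], d = d[!dup])
}

interaction_rows <- function(atom, i, j, d, type, strong = NA) {
  n <- length(i)
  strong <- rep(strong, length.out = n)
  type <- rep(type, length.out = n)
  data.frame(
    type = type,
    chain_a = atom$chain[i], resno_a = atom$resno[i],
    insert_a = atom$insert[i], resid_a = atom$resid[i],
    atom_a = atom$elety[i],
    chain_b = atom$chain[j], resno_b = atom$resno[j],
    insert_b = atom$insert[j], resid_b = atom$resid[j],
    atom_b = atom$elety[j],
    distance = d, strong = strong,
    chain_w = rep(NA_character_, n), resno_w = rep(NA_integer_, n),
    context = rep(NA_character_, n), seg_a = rep(NA_character_, n),
    seg_b = rep(NA_character_, n),
    stringsAsFactors = FALSE)
}

empty_interactions <- function() {
  interaction_rows(data.frame(chain = character(), resno = integer(),
                              insert = character(), resid = character(),
                              elety = character()),
                   integer(), integer(), numeric(), character())
}

# one interaction per residue pair per type, closest atoms recorded
collapse_residue_pairs <- function(ints) {
  if (nrow(ints) == 0L) return(ints)
  ra <- paste(ints$chain_a, ints$resno_a, ints$insert_a)
  rb <- paste(ints$chain_b, ints$resno_b, ints$insert_b)
  key <- paste(ints$type, pmin(ra, rb), pmax(ra, rb),
               ifelse(is.na(ints$resno_w), "", paste(ints$chain_w, ints$resno_w)))
  ord <- order(key, ints$distance)
  out <- ints[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

hb_atoms <- function(atom, idx, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  tab <- if (role == "donor") SIDECHAIN_DONORS else SIDECHAIN_ACCEPTORS
  bb <- if (role == "donor") atom$elety[idx] == "N" & atom$resid[idx] != "PRO"
        else atom$elety[idx] %in% c("O", "OXT")
  sc <- mapply(function(res, aty) aty %in% (tab[[res]] %||% character()),
               atom$resid[idx], atom$elety[idx])
  idx[(bb | sc) & !atom$het[idx]]
}

#' Detect hydrogen bonds between two selections
#'
#' Heavy-atom distance criterion (the model has no hydrogens): a donor
#' nitrogen/oxygen within `cutoff` of an acceptor oxygen/nitrogen, with
#' donor/acceptor capability tabulated per residue chemistry. Main
#' chain-main chain bonds within a chain additionally require a sequence
#' separation of at least 2 so covalently adjacent backbone atoms are not
#' reported. Bonds are classified `HBOND_MM` (both atoms backbone),
#' `HBOND_MS` (one), `HBOND_SS` (neither), one record per residue pair and
#' class, closest atoms kept.
#'
#' @param structure A `subspec_structure`.
#' @param sel_a,sel_b Atom index vectors (default: all protein atoms);
#'   the detector is symmetric in the two selections.
#' @param cutoff Donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @return Interaction data frame.
#' @export
hydrogen_bonds <- function(structure, sel_a = NULL, sel_b = NULL,
                           cutoff = 3.5) {
  atom <- structure$atom
  sel_a <- sel_a %||% atom_select(structure, het = FALSE)
  sel_b <- sel_b %||% atom_select(structure, het = FALSE)
  pairs <- rbind(
    cross_pairs(atom, hb_atoms(atom, sel_a, "donor"),
                hb_atoms(atom, sel_b, "acceptor"), cutoff),
    cross_pairs(atom, hb_atoms(atom, sel_b, "donor"),
                hb_atoms(atom, sel_a, "acceptor"), cutoff))
  if (nrow(pairs) > 0L)
    pairs <- pairs[!duplicated(paste(pairs$i, pairs$j)), , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty_interactions())
  bb_i <- atom$elety[pairs$i] %in% BACKBONE_ATOMS
  bb_j <- atom$elety[pairs$j] %in% BACKBONE_ATOMS
  type <- ifelse(bb_i & bb_j, "HBOND_MM",
                 ifelse(bb_i | bb_j, "HBOND_MS", "HBOND_SS"))
  keep <- !(type == "HBOND_MM" &
              atom$chain[pairs$i] == atom$chain[pairs$j] &
              abs(atom$resno[pairs$i] - atom$resno[pairs$j]) < 2L)
  ints <- interaction_rows(atom, pairs$i[keep], pairs$j[keep],
                           pairs$d[keep], type[keep])
  collapse_residue_pairs(ints)
}

charged_atoms <- function(atom, idx, tab) {
  sel <- mapply(function(res, aty) aty %in% (tab[[res]] %||% character()),
                atom$resid[idx], atom$elety[idx])
  idx[sel & !atom$het[idx]]
}

#' Detect salt bridges between two selections
#'
#' Side-chain charged-atom pairs (Asp/Glu carboxylate oxygens against
#' Lys/Arg/His nitrogens; histidine treated as chargeable) within `cutoff`.
#' One record per residue pair, closest atoms kept; pairs at or below
#' `strong_cutoff` carry `strong = TRUE`.
#'
#' @inheritParams hydrogen_bonds
#' @param cutoff Distance cutoff in Angstrom (default 6.0, the ionic
#'   interaction convention).
#' @param strong_cutoff Distance at or below which the bridge is flagged
#'   strong (default 4.0).
#' @return Interaction data frame.
#' @export
salt_bridges <- function(structure, sel_a = NULL, sel_b = NULL,
                         cutoff = 6.0, strong_cutoff = 4.0) {
  atom <- structure$atom
  sel_a <- sel_a %||% atom_select(structure, het = FALSE)
  sel_b <- sel_b %||% atom_select(structure, het = FALSE)
  pairs <- rbind(
    cross_pairs(atom, charged_atoms(atom, sel_a, ACIDIC_ATOMS),
                charged_atoms(atom, sel_b, BASIC_ATOMS), cutoff),
    cross_pairs(atom, charged_atoms(atom, sel_b, ACIDIC_ATOMS),
                charged_atoms(atom, sel_a, BASIC_ATOMS), cutoff))
  if (nrow(pairs) > 0L)
    pairs <- pairs[!duplicated(paste(pairs$i, pairs$j)), , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty_interactions())
  ints <- interaction_rows(atom, pairs$i, pairs$j, pairs$d, "SALT_BRIDGE",
                           strong = pairs$d <= strong_cutoff)
  collapse_residue_pairs(ints)
}

#' Detect hydrophobic contacts between two selections
#'
#' Side-chain carbon-carbon pairs between residues in the apolar set
#' (Ala, Val, Leu, Ile, Met, Phe, Trp, Pro, Tyr) within `cutoff`; one
#' record per residue pair with the minimum distance kept.
#'
#' @inheritParams hydrogen_bonds
#' @param cutoff Distance cutoff in Angstrom (default 5.0).
#' @return Interaction data frame.
#' @export
hydrophobic_contacts <- function(structure, sel_a = NULL, sel_b = NULL,
                                 cutoff = 5.0) {
  atom <- structure$atom
  sel_a <- sel_a %||% atom_select(structure, het = FALSE)
  sel_b <- sel_b %||% atom_select(structure, het = FALSE)
  pick <- function(idx) idx[atom$resid[idx] %in% HYDROPHOBIC_RESIDUES &
                              atom$elesy[idx] == "C" &
                              !atom$elety[idx] %in% c("N", "CA", "C", "O", "OXT") &
                              !atom$het[idx]]
  pairs <- cross_pairs(atom, pick(sel_a), pick(sel_b), cutoff)
  if (nrow(pairs) == 0L) return(empty_interactions())
  collapse_residue_pairs(
    interaction_rows(atom, pairs$i, pairs$j, pairs$d, "HYDROPHOBIC"))
}

#' Detect protein-water-ligand bridges
#'
#' A water bridge is a protein polar atom within `cutoff` of a water oxygen
#' that is itself within `cutoff` of a ligand oxygen/phosphorus atom. One
#' record per (protein residue, water, ligand residue), closest atoms kept;
#' the bridging water is recorded in `chain_w`/`resno_w`.
#'
#' @param structure A `subspec_structure` containing waters.
#' @param sel_protein Protein atom selection (default all protein atoms).
#' @param sel_ligand Ligand atom selection (default all ligand atoms).
#' @param cutoff Polar-contact distance in Angstrom (default 3.5).
#' @return Interaction data frame (`type = "WATER_BRIDGE"`).
#' @export
water_bridges <- function(structure, sel_protein = NULL, sel_ligand = NULL,
                          cutoff = 3.5) {
  atom <- structure$atom
  sel_protein <- sel_protein %||% atom_select(structure, het = FALSE)
  sel_ligand <- sel_ligand %||% atom_select(structure, ligand = TRUE)
  waters <- atom_select(structure, water = TRUE, elety = "O")
  polar <- sel_protein[atom$elesy[sel_protein] %in% c("N", "O") &
                         !atom$het[sel_protein]]
  lig <- sel_ligand[atom$elesy[sel_ligand] %in% c("O", "P")]
  pw <- cross_pairs(atom, polar, waters, cutoff)
  wl <- cross_pairs(atom, waters, lig, cutoff)
  if (nrow(pw) == 0L || nrow(wl) == 0L) return(empty_interactions())
  # orient: protein atom in i, water in j / water in i, ligand in j
  fix <- function(p, set) {
    swap <- !p$i %in% set
    tmp <- p$i[swap]; p$i[swap] <- p$j[swap]; p$j[swap] <- tmp
    p
  }
  pw <- fix(pw, polar); wl <- fix(wl, waters)
  out <- empty_interactions()
  for (w in intersect(pw$j, wl$i)) {
    prot <- pw[pw$j == w, , drop = FALSE]
    ligp <- wl[wl$i == w, , drop = FALSE]
    for (pi in seq_len(nrow(prot))) for (li in seq_len(nrow(ligp))) {
      row <- interaction_rows(atom, prot$i[pi], ligp$j[li],
                              max(prot$d[pi], ligp$d[li]), "WATER_BRIDGE")
      row$chain_w <- atom$chain[w]
      row$resno_w <- atom$resno[w]
      out <- rbind(out, row)
    }
  }
  collapse_residue_pairs(out)
}

#' Detect direct polar contacts between protein and a ligand
#'
#' Protein nitrogen/oxygen atoms within `cutoff` of ligand oxygen/phosphorus
#' atoms; one record per (protein residue, ligand atom) pair.
#'
#' @param structure A `subspec_structure`.
#' @param ligand_code HET code of the ligand (e.g. `"4IP"`, `"I3P"`).
#' @param cutoff Distance cutoff in Angstrom (default 3.5).
#' @param sel_protein Protein atom selection (default all protein atoms).
#' @return Interaction data frame (`type = "LIGAND_POLAR"`).
#' @export
ligand_polar_contacts <- function(structure, ligand_code, cutoff = 3.5,
                                  sel_protein = NULL) {
  atom <- structure$atom
  lig <- atom_select(structure, resid = ligand_code, ligand = TRUE)
  if (length(lig) == 0L)
    stop("ligand ", ligand_code, " not found; available HET codes: ",
         paste(unique(atom$resid[atom$ligand]), collapse = ", "))
  sel_protein <- sel_protein %||% atom_select(structure, het = FALSE)
  polar <- sel_protein[atom$elesy[sel_protein] %in% c("N", "O")]
  ligp <- lig[atom$elesy[lig] %in% c("O", "P")]
  pairs <- cross_pairs(atom, polar, ligp, cutoff)
  if (nrow(pairs) == 0L) return(empty_interactions())
  # orient protein first
  swap <- !pairs$i %in% polar
  tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
  ints <- interaction_rows(atom, pairs$i, pairs$j, pairs$d, "LIGAND_POLAR")
  # one record per (protein residue, ligand atom)
  key <- paste(ints$chain_a, ints$resno_a, ints$insert_a, ints$atom_b)
  ord <- order(key, ints$distance)
  out <- ints[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generic heavy-atom contacts between two selections
#'
#' Any heavy-atom pair within `cutoff` (default 4.5), one record per residue
#' pair; used for interface-membership robustness checks.
#'
#' @inheritParams hydrogen_bonds
#' @param cutoff Distance cutoff in Angstrom (default 4.5).
#' @return Interaction data frame (`type = "GENERIC_CONTACT"`).
#' @export
generic_contacts <- function(structure, sel_a = NULL, sel_b = NULL,
                             cutoff = 4.5) {
  atom <- structure$atom
  sel_a <- sel_a %||% atom_select(structure, het = FALSE)
  sel_b <- sel_b %||% atom_select(structure, het = FALSE)
  pairs <- cross_pairs(atom, sel_a, sel_b, cutoff)
  if (nrow(pairs) == 0L) return(empty_interactions())
  collapse_residue_pairs(
    interaction_rows(atom, pairs$i, pairs$j, pairs$d, "GENERIC_CONTACT"))
}

#' Build a segment map
#'
#' @param name Segment names (unique).
#' @param chain Chain of each segment.
#' @param start,end Author residue-number range (inclusive); `NA` means the
#'   whole chain (used to name partner chains, e.g. Arf6 or G-beta).
#' @return Data frame of class `subspec_segment_map`.
#' @export
segment_map <- function(name, chain, start = NA_integer_, end = NA_integer_) {
  stopifnot(!anyDuplicated(name))
  out <- data.frame(name = name, chain = chain,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  class(out) <- c("subspec_segment_map", "data.frame")
  out
}

segment_of <- function(seg, chain, resno) {
  vapply(seq_along(chain), function(k) {
    hit <- seg$chain == chain[k] &
      (is.na(seg$start) | (seg$start <= resno[k] & resno[k] <= seg$end))
    if (any(hit)) seg$name[which(hit)[1]] else "UNASSIGNED"
  }, "")
}

#' Label interactions with segment/chain context
#'
#' Adds `seg_a`, `seg_b` and `context`: `INTER_CHAIN` when the two residues
#' sit on different chains, `INTER_SEGMENT` when on the same chain but in
#' different named segments, `INTRA_SEGMENT` otherwise. Residues outside any
#' named segment are labelled `UNASSIGNED` but kept.
#'
#' @param interactions Interaction data frame from the detectors.
#' @param segments A `subspec_segment_map`.
#' @return The interactions with `seg_a`, `seg_b`, `context` filled in.
#' @export
label_context <- function(interactions, segments) {
  if (nrow(interactions) == 0L) return(interactions)
  interactions$seg_a <- segment_of(segments, interactions$chain_a,
                                   interactions$resno_a)
  interactions$seg_b <- segment_of(segments, interactions$chain_b,
                                   interactions$resno_b)
  interactions$context <- ifelse(
    interactions$chain_a != interactions$chain_b, "INTER_CHAIN",
    ifelse(interactions$seg_a != interactions$seg_b,
           "INTER_SEGMENT", "INTRA_SEGMENT"))
  interactions
}
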