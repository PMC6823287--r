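# Per-residue role records: direct interface roles ("interacts"),
# second-shell roles ("maintains"), conformer membership and
# conformer interaction differences.

rid <- function(chain, resno) paste(chain, resno, sep = ":")

residue_label <- function(resid, resno) {
  if (length(resno) == 0L) return(character())
  three <- paste0(substr(resid, 1, 1), tolower(substr(resid, 2, 3)))
  paste0(three, "-", resno)
}

# partner name of an interaction from the viewpoint of residue `side`
partner_name <- function(ints, side) {
  other_seg <- if (side == "a") ints$seg_b else ints$seg_a
  lig <- if (side == "a") ints$resid_b else ints$resid_a
  ifelse(ints$type %in% c("LIGAND_POLAR", "WATER_BRIDGE"), lig, other_seg)
}

#' Direct roles of DA-specific residues
#'
#' A residue has a direct role toward partner `P` when it appears in at least
#' one labelled interaction crossing into `P`: an `INTER_SEGMENT` or
#' `INTER_CHAIN` contact whose other side lies in segment/chain `P`, or a
#' ligand polar contact / water bridge to ligand `P`.
#'
#' @param da_residues Data frame `chain`, `resno` (optionally `resid` for
#'   labels) of DA-specific residues.
#' @param interactions Interaction data frame labelled by [label_context()]
#'   (ligand contacts and water bridges may be unlabelled).
#' @return Role data frame: `chain`, `resno`, `partner`, `role = "direct"`,
#'   `via = NA`, `types` (comma-separated interaction types).
#' @export
assign_direct_roles <- function(da_residues, interactions) {
  out <- data.frame(chain = character(), resno = integer(),
                    partner = character(), role = character(),
                    via = character(), types = character(),
                    stringsAsFactors = FALSE)
  if (nrow(interactions) == 0L) return(out)
  ids <- rid(da_residues$chain, da_residues$resno)
  for (side in c("a", "b")) {
    ch <- interactions[[paste0("chain_", side)]]
    rn <- interactions[[paste0("resno_", side)]]
    sel <- rid(ch, rn) %in% ids &
      (interactions$context %in% c("INTER_SEGMENT", "INTER_CHAIN") |
         interactions$type %in% c("LIGAND_POLAR", "WATER_BRIDGE"))
    # a ligand side of a ligand contact is not a protein residue role
    sel <- sel & !interactions$type %in% c("LIGAND_POLAR", "WATER_BRIDGE") |
      (sel & side == "a" &
         interactions$type %in% c("LIGAND_POLAR", "WATER_BRIDGE"))
    if (!any(sel)) next
    out <- rbind(out, data.frame(
      chain = ch[sel], resno = rn[sel],
      partner = partner_name(interactions[sel, , drop = FALSE], side),
      role = "direct", via = NA_character_,
      types = interactions$type[sel], stringsAsFactors = FALSE))
  }
  if (nrow(out) == 0L) return(out)
  key <- paste(out$chain, out$resno, out$partner)
  types <- tapply(out$types, key, function(t) paste(sort(unique(t)), collapse = ","))
  out <- out[!duplicated(key), , drop = FALSE]
  out$types <- as.character(types[paste(out$chain, out$resno, out$partner)])
  rownames(out) <- NULL
  out[order(out$chain, out$resno, out$partner), , drop = FALSE]
}

# all residues (not just DA-specific) with a direct interaction toward each
# partner, from a labelled interaction set
direct_contactors <- function(interactions) {
  all_res <- data.frame(chain = character(), resno = integer(),
                        partner = character(), stringsAsFactors = FALSE)
  if (nrow(interactions) == 0L) return(all_res)
  for (side in c("a", "b")) {
    ch <- interactions[[paste0("chain_", side)]]
    rn <- interactions[[paste0("resno_", side)]]
    sel <- interactions$context %in% c("INTER_SEGMENT", "INTER_CHAIN") |
      (side == "a" & interactions$type %in% c("LIGAND_POLAR", "WATER_BRIDGE"))
    if (!any(sel)) next
    all_res <- rbind(all_res, data.frame(
      chain = ch[sel], resno = rn[sel],
      partner = partner_name(interactions[sel, , drop = FALSE], side),
      stringsAsFactors = FALSE))
  }
  unique(all_res)
}

#' Second-shell ("maintains") roles of DA-specific residues
#'
#' A residue maintains the interaction with partner `P` when it is not itself
#' a direct contactor of `P` but has an intraprotein interaction (any type,
#' one hop) with a residue that is. Direct always wins: a residue directly
#' contacting `P` never also gets a second-shell role for `P`.
#'
#' @inheritParams assign_direct_roles
#' @param direct_roles Output of [assign_direct_roles()] for the same
#'   interaction set (used to enforce direct-wins).
#' @return Role data frame rows with `role = "second_shell"` and `via` set to
#'   the mediating residue (`chain:resno`).
#' @export
second_shell_roles <- function(da_residues, interactions, direct_roles) {
  contact <- direct_contactors(interactions)
  out <- data.frame(chain = character(), resno = integer(),
                    partner = character(), role = character(),
                    via = character(), types = character(),
                    stringsAsFactors = FALSE)
  if (nrow(contact) == 0L) return(out)
  intra <- interactions[!is.na(interactions$context) &
                          interactions$chain_a == interactions$chain_b, ,
                        drop = FALSE]
  if (nrow(intra) == 0L) return(out)
  edges <- rbind(
    data.frame(r = rid(intra$chain_a, intra$resno_a),
               v_chain = intra$chain_b, v_resno = intra$resno_b,
               stringsAsFactors = FALSE),
    data.frame(r = rid(intra$chain_b, intra$resno_b),
               v_chain = intra$chain_a, v_resno = intra$resno_a,
               stringsAsFactors = FALSE))
  direct_key <- paste(rid(direct_roles$chain, direct_roles$resno),
                      direct_roles$partner)
  contact_id <- rid(contact$chain, contact$resno)
  for (k in seq_len(nrow(da_residues))) {
    r_id <- rid(da_residues$chain[k], da_residues$resno[k])
    nb <- edges[edges$r == r_id, , drop = FALSE]
    if (nrow(nb) == 0L) next
    nb_id <- rid(nb$v_chain, nb$v_resno)
    hits <- contact[contact_id %in% nb_id, , drop = FALSE]
    for (p in unique(hits$partner)) {
      if (paste(r_id, p) %in% direct_key) next
      via <- rid(hits$chain, hits$resno)[hits$partner == p][1]
      out <- rbind(out, data.frame(
        chain = da_residues$chain[k], resno = da_residues$resno[k],
        partner = p, role = "second_shell", via = via,
        types = NA_character_, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Conformer membership of DA-specific residues
#'
#' For each conformer (a named, labelled interaction set), a residue
#' participates when it has at least one direct interdomain or interchain
#' role in that conformer.
#'
#' @inheritParams assign_direct_roles
#' @param conformer_interactions Named list of labelled interaction data
#'   frames, one per conformer.
#' @param structures Optional named list of `subspec_structure` objects with
#'   shared numbering; when given, every DA residue must exist in every
#'   structure, otherwise an error lists the unmatched residues.
#' @return Data frame: `chain`, `resno`, one logical column per conformer,
#'   plus `partners_<conformer>` strings recording the partner segments.
#' @export
conformer_membership <- function(da_residues, conformer_interactions,
                                 structures = NULL) {
  stopifnot(length(conformer_interactions) >= 2L,
            !is.null(names(conformer_interactions)))
  if (!is.null(structures)) {
    for (nm in names(structures)) {
      a <- structures[[nm]]$atom
      present <- rid(da_residues$chain, da_residues$resno) %in%
        unique(rid(a$chain, a$resno))
      if (!all(present))
        stop("residues missing from conformer ", nm, ": ",
             paste(rid(da_residues$chain, da_residues$resno)[!present],
                   collapse = ", "))
    }
  }
  out <- da_residues[, c("chain", "resno"), drop = FALSE]
  for (nm in names(conformer_interactions)) {
    ints <- conformer_interactions[[nm]]
    ints <- ints[!is.na(ints$context) &
                   ints$context %in% c("INTER_SEGMENT", "INTER_CHAIN") &
                   !ints$type %in% c("LIGAND_POLAR", "WATER_BRIDGE"), ,
                 drop = FALSE]
    roles <- assign_direct_roles(da_residues, ints)
    id <- rid(out$chain, out$resno)
    role_id <- rid(roles$chain, roles$resno)
    out[[nm]] <- id %in% role_id
    out[[paste0("partners_", nm)]] <- vapply(id, function(i)
      paste(sort(unique(roles$partner[role_id == i])), collapse = ","), "")
  }
  rownames(out) <- NULL
  out
}

#' Interaction differences between two conformers
#'
#' Interactions are collapsed to unique unordered residue pairs (ignoring
#' interaction type: a pair trading an H-bond for a hydrophobic contact is
#' not "lost"), filtered to pairs with at least one member in the selected
#' region segments, and differenced.
#'
#' @param interactions_1,interactions_2 Labelled interaction data frames of
#'   two conformers sharing residue numbering.
#' @param region Character vector of segment names (e.g. C-helix and hinge);
#'   must be non-empty.
#' @return List with `lost` (pairs present in 1, absent in 2) and `gained`
#'   data frames (`chain_a`, `resno_a`, `chain_b`, `resno_b`).
#' @export
conformer_diff <- function(interactions_1, interactions_2, region) {
  if (length(region) == 0L) stop("region selection must be non-empty")
  pairs_of <- function(ints) {
    if (nrow(ints) == 0L)
      return(data.frame(chain_a = character(), resno_a = integer(),
                        chain_b = character(), resno_b = integer(),
                        stringsAsFactors = FALSE))
    keep <- ints$seg_a %in% region | ints$seg_b %in% region
    ints <- ints[keep, , drop = FALSE]
    # canonical order: by chain, then numeric residue number
    first <- ints$chain_a < ints$chain_b |
      (ints$chain_a == ints$chain_b & ints$resno_a <= ints$resno_b)
    out <- data.frame(
      chain_a = ifelse(first, ints$chain_a, ints$chain_b),
      resno_a = ifelse(first, ints$resno_a, ints$resno_b),
      chain_b = ifelse(first, ints$chain_b, ints$chain_a),
      resno_b = ifelse(first, ints$resno_b, ints$resno_a),
      stringsAsFactors = FALSE)
    out <- out[!duplicated(paste(out$chain_a, out$resno_a,
                                 out$chain_b, out$resno_b)), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  p1 <- pairs_of(interactions_1)
  p2 <- pairs_of(interactions_2)
  k1 <- paste(p1$chain_a, p1$resno_a, p1$chain_b, p1$resno_b)
  k2 <- paste(p2$chain_a, p2$resno_a, p2$chain_b, p2$resno_b)
  list(lost = p1[!k1 %in% k2, , drop = FALSE],
       gained = p2[!k2 %in% k1, , drop = FALSE])
}

#' Render a role table
#'
#' One row per DA-specific residue, one column per partner category; cells
#' read "Interacts with ..." for direct roles, "Maintains ... interaction
#' (via ...)" for second-shell roles, and a residue with no role at all is
#' marked "Role unknown".
#'
#' @param da_residues Data frame `chain`, `resno`, optionally `resid`.
#' @param roles Combined role data frame ([assign_direct_roles()] +
#'   [second_shell_roles()] rows).
#' @param partners Optional partner column order (default: sorted unique
#'   partners in `roles`).
#' @return Data frame with `residue` labels and one text column per partner.
#' @export
render_role_table <- function(da_residues, roles, partners = NULL) {
  partners <- partners %||% sort(unique(roles$partner))
  lab <- if ("resid" %in% names(da_residues))
    residue_label(da_residues$resid, da_residues$resno)
  else rid(da_residues$chain, da_residues$resno)
  out <- data.frame(residue = lab, stringsAsFactors = FALSE)
  role_id <- if (nrow(roles)) rid(roles$chain, roles$resno) else character()
  for (p in partners) {
    out[[p]] <- vapply(seq_len(nrow(da_residues)), function(k) {
      r_id <- rid(da_residues$chain[k], da_residues$resno[k])
      rr <- roles[role_id == r_id & roles$partner == p, , drop = FALSE]
      if (nrow(rr) == 0L) return("")
      paste(ifelse(rr$role == "direct",
                   paste0("Interacts with ", p),
                   paste0("Maintains ", p, " interaction (via ", rr$via, ")")),
            collapse = "; ")
    }, "")
  }
  has_role <- if (length(partners))
    rowSums(out[, partners, drop = FALSE] != "") > 0 else rep(FALSE, nrow(out))
  out$note <- ifelse(has_role, "", "Role unknown")
  out
}
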