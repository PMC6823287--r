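# Selection of homologues by domain architecture, and redundancy removal.

#' Parse a domain-annotation table with companion sequences
#'
#' Reads a TSV of per-protein domain hits (columns `protein_id`, `domain`,
#' `start`, `end`, optional logical `fragment`) plus a FASTA file (or named
#' character vector) of full-length sequences, and assembles one annotation
#' record per protein. Coordinates are 1-based and inclusive.
#'
#' @param table_path Path to the TSV domain table (header required).
#' @param fasta Path to a FASTA file of full-length sequences, or a named
#'   character vector of sequences.
#' @return A list of `protein_annotation` objects (fields `protein_id`,
#'   `sequence`, `hits` data frame sorted by `start`, `fragment` flag), with
#'   attribute `missing_sequence` listing protein ids present in the table but
#'   absent from the FASTA.
#' @export
parse_domain_table <- function(table_path, fasta) {
  tab <- utils::read.delim(table_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("protein_id", "domain", "start", "end")
  if (!all(need %in% names(tab)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) == 0L) return(structure(list(), missing_sequence = character()))

  for (col in c("start", "end")) {
    bad <- grepl("\\D", tab[[col]]) | tab[[col]] == ""
    if (any(bad))
      stop(sprintf("non-integer '%s' at table line %d: '%s'",
                   col, which(bad)[1] + 1L, tab[[col]][which(bad)[1]]))
    tab[[col]] <- as.integer(tab[[col]])
  }
  bad <- tab$end < tab$start
  if (any(bad))
    stop(sprintf("end < start at table line %d (%s)",
                 which(bad)[1] + 1L, tab$protein_id[which(bad)[1]]))

  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readAAStringSet(fasta)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else {
    if (is.null(names(fasta))) stop("fasta must be a path or a named vector")
    fasta
  }

  frag_col <- if ("fragment" %in% names(tab))
    toupper(tab$fragment) %in% c("TRUE", "1", "YES") else rep(FALSE, nrow(tab))

  ids <- unique(tab$protein_id)
  missing <- setdiff(ids, names(seqs))
  anns <- lapply(setdiff(ids, missing), function(id) {
    rows <- tab$protein_id == id
    hits <- data.frame(domain_name = tab$domain[rows],
                       start = tab$start[rows], end = tab$end[rows],
                       stringsAsFactors = FALSE)
    hits <- hits[order(hits$start), , drop = FALSE]
    rownames(hits) <- NULL
    seq <- seqs[[id]]
    if (any(hits$end > nchar(seq)))
      stop(sprintf("hit end beyond sequence length for %s", id))
    structure(list(protein_id = id, sequence = seq, hits = hits,
                   fragment = any(frag_col[rows])),
              class = "protein_annotation")
  })
  structure(anns, missing_sequence = missing)
}

#' Define a domain-architecture query
#'
#' @param domain_order Character vector of domain names in N-to-C order.
#' @param domain_bounds Data frame with columns `domain_name`, `min_len`,
#'   `max_len` (per-domain length bounds from the Pfam seed-alignment
#'   extremes; no additional relaxation is applied to domain lengths).
#' @param linker_ref Numeric vector of reference inter-domain linker lengths
#'   (length = number of domains - 1).
#' @param n_ext_ref,c_ext_ref Reference lengths of the unannotated N- and
#'   C-terminal extensions.
#' @param relaxation Residues of slack allowed on linkers and terminal
#'   extensions (absolute difference from the reference), default 20.
#' @return An `architecture_query` object.
#' @export
architecture_query <- function(domain_order, domain_bounds, linker_ref,
                               n_ext_ref = 0, c_ext_ref = 0, relaxation = 20) {
  stopifnot(length(domain_order) >= 1, relaxation >= 0,
            length(linker_ref) == length(domain_order) - 1L)
  if (!all(domain_order %in% domain_bounds$domain_name))
    stop("domain_bounds must cover every domain in domain_order")
  if (any(domain_bounds$min_len > domain_bounds$max_len))
    stop("min_len > max_len in domain_bounds")
  structure(list(domain_order = domain_order, domain_bounds = domain_bounds,
                 linker_ref = as.numeric(linker_ref),
                 n_ext_ref = n_ext_ref, c_ext_ref = c_ext_ref,
                 relaxation = relaxation),
            class = "architecture_query")
}

#' Match one protein annotation against an architecture query
#'
#' A protein is accepted when its domain hits reproduce the query architecture
#' exactly (same domain names, same order, nothing extra), no two hits
#' overlap, each domain length falls within the seed-alignment bounds, and
#' every linker and terminal extension is within `relaxation` residues of the
#' query reference. Rejection is a result, not an error.
#'
#' @param ann A `protein_annotation`.
#' @param query An `architecture_query`.
#' @return A list with `accept` (logical) and `reason` (`NA` when accepted,
#'   else one of `FRAGMENT`, `EXTRA_DOMAIN`, `WRONG_ORDER`, `OVERLAP`,
#'   `PARTIAL_DOMAIN`, `LONG_INSERTION`, `LONG_EXTENSION`).
#' @export
match_architecture <- function(ann, query) {
  reject <- function(code) list(accept = FALSE, reason = code)
  if (isTRUE(ann$fragment)) return(reject("FRAGMENT"))
  hits <- ann$hits
  ord <- query$domain_order
  if (nrow(hits) > length(ord) || any(!hits$domain_name %in% ord))
    return(reject("EXTRA_DOMAIN"))
  if (!identical(hits$domain_name, ord))
    return(reject("WRONG_ORDER"))
  if (nrow(hits) > 1L &&
      any(hits$start[-1L] <= hits$end[-nrow(hits)]))
    return(reject("OVERLAP"))
  len <- hits$end - hits$start + 1L
  b <- query$domain_bounds[match(ord, query$domain_bounds$domain_name), ]
  if (any(len < b$min_len | len > b$max_len))
    return(reject("PARTIAL_DOMAIN"))
  if (nrow(hits) > 1L) {
    gaps <- hits$start[-1L] - hits$end[-nrow(hits)] - 1L
    if (any(abs(gaps - query$linker_ref) > query$relaxation))
      return(reject("LONG_INSERTION"))
  }
  n_ext <- hits$start[1L] - 1L
  c_ext <- nchar(ann$sequence) - hits$end[nrow(hits)]
  if (abs(n_ext - query$n_ext_ref) > query$relaxation ||
      abs(c_ext - query$c_ext_ref) > query$relaxation)
    return(reject("LONG_EXTENSION"))
  list(accept = TRUE, reason = NA_character_)
}

#' Run architecture selection over a set of annotations
#'
#' @param anns List of `protein_annotation` objects.
#' @param query An `architecture_query`.
#' @return A list with `accepted` (character vector of protein ids) and
#'   `rejected` (named character vector, protein id -> reason code).
#' @export
select_architecture <- function(anns, query) {
  res <- lapply(anns, match_architecture, query = query)
  ids <- vapply(anns, function(a) a$protein_id, "")
  acc <- vapply(res, function(r) r$accept, TRUE)
  list(accepted = ids[acc],
       rejected = stats::setNames(
         vapply(res[!acc], function(r) r$reason, ""), ids[!acc]))
}

#' Global-alignment percent identity between two sequences
#'
#' Aligns the sequences globally (Needleman-Wunsch with affine gaps, BLOSUM62,
#' gap opening 10, gap extension 0.5) and returns the fraction of identical
#' aligned residue pairs over the length of the shorter sequence. Dividing by
#' the shorter ungapped length means a sequence and the same sequence with a
#' few extra terminal residues still score 1.0, which is what redundancy
#' removal needs: near-identical database entries often differ only by
#' N/C-terminal extensions. `X` never counts as identical.
#'
#' @param seq_a,seq_b Amino-acid strings (non-empty).
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  ident <- sum(a == b & a != "-" & a != "X")
  ident / min(nchar(seq_a), nchar(seq_b))
}

#' Greedy sequence clustering at an identity cutoff
#'
#' CD-HIT-style greedy clustering: sequences are sorted by length descending
#' (ties broken by id, lexicographic), and each sequence joins the first
#' existing representative it exceeds the identity cutoff with (strict `>`),
#' otherwise it founds a new cluster.
#'
#' @param seqs Named character vector of sequences.
#' @param cutoff Identity cutoff in `(0, 1]`; membership requires
#'   identity strictly greater than `cutoff`. Default 0.90.
#' @return List with `representatives` (ids) and `members`, a data frame
#'   (`id`, `representative`) covering every input sequence.
#' @export
greedy_cluster <- function(seqs, cutoff = 0.90) {
  stopifnot(cutoff > 0, cutoff <= 1, !is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  reps <- character()
  assign <- character(length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    placed <- FALSE
    for (r in reps) {
      if (pairwise_identity(seqs[[id]], seqs[[r]]) > cutoff) {
        assign[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, id)
      assign[i] <- id
    }
  }
  list(representatives = reps,
       members = data.frame(id = ids, representative = assign,
                            stringsAsFactors = FALSE))
}
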