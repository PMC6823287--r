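# Alignment I/O, column mapping between combined and subfamily alignments,
# and column-to-reference residue numbering.

#' Read and validate an aligned FASTA file
#'
#' @param fasta Path to an aligned FASTA file, or a named character vector of
#'   aligned sequences (gap `-`; `.` is normalised to `-`; case folded to
#'   upper).
#' @return A `subspec_alignment`: list with `ids`, `seqs` (named uppercase
#'   aligned strings), `mat` (character matrix, rows = sequences), `n_cols`.
#' @export
read_alignment <- function(fasta) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readAAStringSet(fasta)
    stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else fasta
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(gsub(".", "-", seqs, fixed = TRUE))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment; offending ids: ",
         paste(names(seqs)[widths != stats::median(widths)], collapse = ", "))
  if (length(seqs) < 2L) stop("alignment needs at least 2 sequences")
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  structure(list(ids = names(seqs), seqs = seqs, mat = mat,
                 n_cols = unname(widths[1L])),
            class = "subspec_alignment")
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment A `subspec_alignment`.
#' @param path Output file path.
#' @export
write_alignment <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(alignment$seqs), path, width = 60L)
  invisible(path)
}

# ungapped residue index at each column of one aligned row (NA at gaps)
ungapped_index <- function(row_chars) {
  idx <- cumsum(row_chars != "-")
  idx[row_chars == "-"] <- NA_integer_
  idx
}

#' Map combined-alignment columns onto a subfamily alignment
#'
#' For every sequence shared between the two alignments, combined column `c`
#' is paired with the subfamily column holding the same ungapped residue of
#' that sequence. The per-column target is the majority vote across shared
#' sequences (support = agreeing fraction of voting sequences); a tie or a
#' column gapped in all shared sequences maps to `NA`. The mapping is forced
#' injective: if two combined columns claim the same target, the lower-support
#' claim is dropped.
#'
#' @param combined,subfamily `subspec_alignment` objects sharing >= 1 id.
#' @return Data frame `combined_col`, `target_col` (NA when unmapped),
#'   `support`.
#' @export
build_column_map <- function(combined, subfamily) {
  shared <- intersect(combined$ids, subfamily$ids)
  if (length(shared) == 0L) stop("no shared sequence ids between alignments")

  votes <- matrix(NA_integer_, nrow = length(shared), ncol = combined$n_cols)
  for (i in seq_along(shared)) {
    id <- shared[i]
    ci <- ungapped_index(combined$mat[id, ])
    si <- ungapped_index(subfamily$mat[id, ])
    pos <- match(ci, si)            # subfamily column per residue index
    votes[i, ] <- pos
  }

  target <- rep(NA_integer_, combined$n_cols)
  support <- rep(NA_real_, combined$n_cols)
  for (c in seq_len(combined$n_cols)) {
    v <- votes[, c]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    tab <- table(v)
    best <- max(tab)
    winners <- names(tab)[tab == best]
    support[c] <- best / length(v)
    if (length(winners) == 1L) target[c] <- as.integer(winners)
  }

  # enforce injectivity: on duplicate targets keep the best-supported column
  mapped <- which(!is.na(target))
  if (anyDuplicated(target[mapped])) {
    for (t in unique(target[mapped][duplicated(target[mapped])])) {
      claim <- mapped[target[mapped] == t]
      keep <- claim[which.max(support[claim])]
      target[setdiff(claim, keep)] <- NA_integer_
    }
  }
  data.frame(combined_col = seq_len(combined$n_cols),
             target_col = target, support = support)
}

#' Map an alignment column to a reference residue
#'
#' @param alignment A `subspec_alignment`.
#' @param seq_id Row to use as reference (e.g. the sequence extracted from a
#'   PDB entry).
#' @param column 1-based column index.
#' @param numbering_offset Added to the ungapped index to produce the
#'   reference numbering (e.g. PDB author numbering); default 0.
#' @return `NULL` if the reference row is gapped at that column, else a list
#'   with `seq_id`, `number`, `aa`.
#' @export
column_to_reference <- function(alignment, seq_id, column, numbering_offset = 0L) {
  if (!seq_id %in% alignment$ids) stop("unknown seq_id: ", seq_id)
  if (column < 1L || column > alignment$n_cols)
    stop("column out of range: ", column)
  row <- alignment$mat[seq_id, ]
  if (row[column] == "-") return(NULL)
  list(seq_id = seq_id,
       number = sum(row[seq_len(column)] != "-") + numbering_offset,
       aa = unname(row[column]))
}
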