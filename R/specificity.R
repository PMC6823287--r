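# Column conservation profiles and DA-specific classification.
#
# A column is "conserved" in a subfamily when >= 85% of its rows carry the
# same residue, or the same Clustal-X strong group (conservative
# substitution); "semi-conserved" when a weak group reaches 85%. Gaps count
# in every denominator: a gap is evidence of non-conservation, so columns
# with more than 15% gaps can never be conserved.

#' Per-column conservation profiles of an alignment
#'
#' @param alignment A `subspec_alignment`.
#' @return List of per-column profiles, each with residue `counts`, `n_rows`,
#'   `majority` residue (alphabetical tie-break), `f_res`, best strong-group
#'   fraction `f_grp` with `grp`, best weak-group fraction `f_weak` with
#'   `weak_grp`, and `gap_fraction`.
#' @export
profile_columns <- function(alignment) {
  mat <- alignment$mat
  n <- nrow(mat)
  strong <- group_members(STRONG_GROUPS)
  weak <- group_members(WEAK_GROUPS)
  lapply(seq_len(ncol(mat)), function(c) {
    col <- mat[, c]
    res <- col[col %in% AA1]
    counts <- table(factor(res, levels = AA1))
    top <- max(counts, 0L)
    majority <- if (top > 0L) names(counts)[counts == top][1L] else NA_character_
    grp_frac <- vapply(strong, function(g) sum(counts[g]), 0) / n
    weak_frac <- vapply(weak, function(g) sum(counts[g]), 0) / n
    list(counts = counts, n_rows = n,
         majority = majority, f_res = top / n,
         f_grp = max(grp_frac), grp = STRONG_GROUPS[which.max(grp_frac)],
         f_weak = max(weak_frac), weak_grp = WEAK_GROUPS[which.max(weak_frac)],
         gap_fraction = sum(col == "-") / n)
  })
}

#' Conservation status of one profiled column
#'
#' @param p One element of [profile_columns()] output.
#' @param threshold Conservation threshold, default 0.85 (inclusive).
#' @return One of `CONSERVED_RESIDUE`, `CONSERVED_GROUP`, `SEMI_CONSERVED`,
#'   `NOT_CONSERVED`.
#' @export
conserved_status <- function(p, threshold = 0.85) {
  if (p$f_res >= threshold) "CONSERVED_RESIDUE"
  else if (p$f_grp >= threshold) "CONSERVED_GROUP"
  else if (p$f_weak >= threshold) "SEMI_CONSERVED"
  else "NOT_CONSERVED"
}

# groups (strong) containing a residue
strong_groups_of <- function(aa) {
  STRONG_GROUPS[vapply(group_members(STRONG_GROUPS),
                       function(g) aa %in% g, TRUE)]
}

# ">50% same residue type" exclusion: the largest single-residue fraction in
# column p among residues sharing a strong group with aa. A column scattered
# over several type-mates (none above 50%) does not trigger the exclusion;
# a single dominating type-mate does.
type_fraction <- function(p, aa) {
  members <- unique(unlist(group_members(strong_groups_of(aa))))
  if (length(members) == 0L) return(0)
  max(p$counts[members]) / p$n_rows
}

#' Classify a mapped column pair as shared, DA-specific or nonspecific
#'
#' Implements the subfamily-specificity rules: a column is DA-specific to
#' side A when it is conserved (residue or strong group at `threshold`) in A
#' while B shows neither the same residue at > `cross_max`, nor the same
#' residue type (strong group of A's majority) at > `cross_max`, nor
#' semi-conservation of a weak group containing A's majority. Both sides
#' conserved with the same residue or overlapping strong groups is
#' shared-conserved; both candidate rules firing with different conserved
#' residues is DA-specific to both.
#'
#' @param pa,pb Profiles of the corresponding columns in subfamily A and B.
#' @param threshold Conservation threshold (default 0.85, inclusive).
#' @param cross_max Cross-family exclusion level (default 0.50, strict `>`
#'   triggers the exclusion).
#' @return List with `class` (one of `SHARED_CONSERVED`, `DA_SPECIFIC_A`,
#'   `DA_SPECIFIC_B`, `DA_SPECIFIC_BOTH`, `NONSPECIFIC`) and `rationale`.
#' @export
classify_position <- function(pa, pb, threshold = 0.85, cross_max = 0.50) {
  sa <- conserved_status(pa, threshold)
  sb <- conserved_status(pb, threshold)
  cons_a <- sa %in% c("CONSERVED_RESIDUE", "CONSERVED_GROUP")
  cons_b <- sb %in% c("CONSERVED_RESIDUE", "CONSERVED_GROUP")

  if (cons_a && cons_b) {
    same_res <- identical(pa$majority, pb$majority)
    grp_overlap <- pa$f_grp >= threshold && pb$f_grp >= threshold &&
      length(intersect(group_members(pa$grp)[[1]],
                       group_members(pb$grp)[[1]])) > 0L
    if (same_res || grp_overlap)
      return(list(class = "SHARED_CONSERVED",
                  rationale = if (same_res) "same residue conserved both sides"
                  else sprintf("overlapping strong groups %s/%s", pa$grp, pb$grp)))
  }

  excl <- function(p_self, p_other, side) {
    aa <- p_self$majority
    if (p_other$counts[aa] / p_other$n_rows > cross_max)
      return(sprintf("%s: same residue %s > %.0f%% in other subfamily",
                     side, aa, 100 * cross_max))
    if (type_fraction(p_other, aa) > cross_max)
      return(sprintf("%s: same residue type (%s group) > %.0f%% in other subfamily",
                     side, aa, 100 * cross_max))
    if (conserved_status(p_other, threshold) == "SEMI_CONSERVED" &&
        aa %in% group_members(p_other$weak_grp)[[1]])
      return(sprintf("%s: other subfamily semi-conserved in weak group %s containing %s",
                     side, p_other$weak_grp, aa))
    NULL
  }

  ex_a <- if (cons_a) excl(pa, pb, "A") else "A not conserved"
  ex_b <- if (cons_b) excl(pb, pa, "B") else "B not conserved"
  cand_a <- cons_a && is.null(ex_a)
  cand_b <- cons_b && is.null(ex_b)

  if (cand_a && cand_b)
    list(class = "DA_SPECIFIC_BOTH",
         rationale = sprintf("different residues conserved: %s (A) vs %s (B)",
                             pa$majority, pb$majority))
  else if (cand_a)
    list(class = "DA_SPECIFIC_A",
         rationale = sprintf("conserved %s in A; B excluded by none (%s)",
                             pa$majority, ex_b %||% "B conserved but excluded"))
  else if (cand_b)
    list(class = "DA_SPECIFIC_B",
         rationale = sprintf("conserved %s in B; A excluded by none (%s)",
                             pb$majority, ex_a %||% "A conserved but excluded"))
  else
    list(class = "NONSPECIFIC",
         rationale = paste(c(if (!is.null(ex_a)) ex_a, if (!is.null(ex_b)) ex_b),
                           collapse = "; "))
}

#' Classify all mapped column pairs of two subfamily alignments
#'
#' @param sa_a,sa_b Subfamily alignments (`subspec_alignment`).
#' @param column_map Data frame pairing columns of A with columns of B
#'   (`col_a`, `col_b`); rows with `NA` are skipped. When the two alignments
#'   are column-compatible (same width) the identity map is used by default.
#' @inheritParams classify_position
#' @return Data frame `col_a`, `col_b`, `class`, `rationale`.
#' @export
classify_alignment_pair <- function(sa_a, sa_b, column_map = NULL,
                                    threshold = 0.85, cross_max = 0.50) {
  if (is.null(column_map)) {
    if (sa_a$n_cols != sa_b$n_cols)
      stop("alignments differ in width; supply a column_map")
    column_map <- data.frame(col_a = seq_len(sa_a$n_cols),
                             col_b = seq_len(sa_a$n_cols))
  }
  pa <- profile_columns(sa_a)
  pb <- profile_columns(sa_b)
  keep <- !is.na(column_map$col_a) & !is.na(column_map$col_b)
  cm <- column_map[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(cm)), function(i)
    classify_position(pa[[cm$col_a[i]]], pb[[cm$col_b[i]]],
                      threshold, cross_max))
  data.frame(col_a = cm$col_a, col_b = cm$col_b,
             class = vapply(out, `[[`, "", "class"),
             rationale = vapply(out, `[[`, "", "rationale"),
             stringsAsFactors = FALSE)
}

#' Exclude columns whose reference residue is buried
#'
#' Buried positions sit in the domain core and maintain the fold; they are
#' set aside rather than interpreted functionally. Classes are retained on
#' the excluded rows for reporting.
#'
#' @param classes Data frame from [classify_alignment_pair()] (or any frame
#'   with a column identifying alignment columns via `col_a`).
#' @param burial Data frame with columns `number` (reference residue number)
#'   and `rsa` (percent relative accessibility), e.g. from
#'   [relative_accessibility()].
#' @param ref_map Function mapping an alignment column (`col_a`) to a
#'   reference residue number, or `NA`/`NULL` when unmapped — typically a
#'   closure over [column_to_reference()].
#' @param cutoff Burial cutoff in percent RSA (default 7, inclusive `<=`).
#' @return List with `retained` and `excluded` data frames (both carry
#'   `ref_number`, `rsa`), and `unmapped` — rows passing through with a
#'   warning flag because no reference residue covers them.
#' @export
apply_burial_filter <- function(classes, burial, ref_map, cutoff = 7.0) {
  nums <- vapply(classes$col_a, function(c) {
    r <- ref_map(c)
    if (is.null(r) || length(r) == 0L) NA_integer_
    else as.integer(if (is.list(r)) r$number else r)
  }, 1L)
  rsa <- burial$rsa[match(nums, burial$number)]
  classes$ref_number <- nums
  classes$rsa <- rsa
  unmapped <- is.na(nums) | is.na(rsa)
  buried <- !unmapped & rsa <= cutoff
  list(retained = classes[!buried & !unmapped, , drop = FALSE],
       excluded = classes[buried, , drop = FALSE],
       unmapped = classes[unmapped, , drop = FALSE])
}
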