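# Ground-truth-labelled synthetic inputs: subfamily alignment pairs with
# planted column classes, domain-annotation sets with planted defects, and
# toy coordinate files with planted geometry.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# residues sharing no Clustal-X strong or weak group with aa
unrelated_residues <- function(aa) {
  related <- unique(unlist(c(
    group_members(STRONG_GROUPS)[vapply(group_members(STRONG_GROUPS),
                                        function(g) aa %in% g, TRUE)],
    group_members(WEAK_GROUPS)[vapply(group_members(WEAK_GROUPS),
                                      function(g) aa %in% g, TRUE)])))
  setdiff(AA1, c(aa, related))
}

# pick k residues, no 3 of which share a strong group (keeps the column
# genuinely non-conserved at any threshold >= 0.75)
pick_scattered <- function(pool, k = 4) {
  repeat {
    cand <- sample(pool, k)
    ok <- all(vapply(group_members(STRONG_GROUPS),
                     function(g) sum(cand %in% g) < 3, TRUE))
    if (ok) return(cand)
  }
}

# residue pairs whose strong-group memberships are disjoint (so conserving
# one per subfamily yields a both-specific, not shared, column)
disjoint_pair <- function() {
  repeat {
    p <- sample(AA1, 2)
    ga <- unlist(group_members(strong_groups_of(p[1])))
    gb <- unlist(group_members(strong_groups_of(p[2])))
    if (length(intersect(c(p[1], ga), c(p[2], gb))) == 0L) return(p)
  }
}

plant_column <- function(n, main_res, level, filler_pool) {
  k_main <- ceiling(level * n)
  filler <- rep_len(filler_pool, n - k_main)
  sample(c(rep(main_res, k_main), filler))
}

#' Generate a labelled pair of subfamily alignments
#'
#' Builds two subfamily alignments (A and B) plus their row-stacked combined
#' alignment with a planted class per column. Defaults reproduce the study
#' conditions of the motivating PH-domain analysis: 88 sequences in
#' subfamily A (the ARNO-like set), 21 in subfamily B (the GRK2-like set),
#' 120 columns of which 16 are shared-conserved, 30 A-specific, 11
#' B-specific and 10 specific to both (so 40 columns are A-specific and 21
#' B-specific in total), the rest variable.
#'
#' Planted recipes are chosen so the intended class is recoverable exactly at
#' zero noise: specific columns conserve one residue on their side while the
#' other side cycles through residues unrelated to it (no shared strong or
#' weak group, under 50\% each); both-specific columns conserve residues with
#' disjoint strong-group memberships; variable columns cycle scattered
#' residues on both sides. Substitution noise replaces each cell by a
#' uniformly drawn residue with the given probability; gaps are inserted at
#' `gap_rate` after noise.
#'
#' @param n_seqs_a,n_seqs_b Sequences per subfamily (defaults 88 and 21).
#' @param classes Character vector of planted classes (one per column) from
#'   `SHARED_CONSERVED`, `DA_SPECIFIC_A`, `DA_SPECIFIC_B`,
#'   `DA_SPECIFIC_BOTH`, `VARIABLE`; default the 120-column mix above.
#' @param planted_level Conservation level of planted residues before noise
#'   (default 1.0; must be >= 0.85 or the planted class is unrecoverable by
#'   construction and an error is raised).
#' @param noise Per-cell substitution probability in `[0, 1]`.
#' @param gap_rate Per-cell gap probability (default 0).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return List: `sa_a`, `sa_b`, `csa` (`subspec_alignment`s; the combined
#'   alignment is the row-stack, column-compatible with both), and `truth`, a
#'   data frame `col`, `class`, `a_residues`, `b_residues` (comma-separated
#'   planted residue sets per side).
#' @export
gen_alignment_pair <- function(n_seqs_a = 88, n_seqs_b = 21,
                               classes = default_column_classes(),
                               planted_level = 1.0, noise = 0,
                               gap_rate = 0, seed = 1) {
  stopifnot(noise >= 0, noise <= 1, gap_rate >= 0, gap_rate <= 1)
  if (planted_level < 0.85 &&
      any(classes != "VARIABLE"))
    stop("planted_level < 0.85 makes planted conservation unrecoverable")
  with_seed(seed, {
    n_cols <- length(classes)
    A <- matrix("", n_seqs_a, n_cols)
    B <- matrix("", n_seqs_b, n_cols)
    truth <- data.frame(col = seq_len(n_cols), class = classes,
                        a_residues = "", b_residues = "",
                        stringsAsFactors = FALSE)
    for (c in seq_len(n_cols)) {
      cl <- classes[c]
      if (cl == "SHARED_CONSERVED") {
        r <- sample(AA1, 1)
        filler <- pick_scattered(unrelated_residues(r))
        A[, c] <- plant_column(n_seqs_a, r, planted_level, filler)
        B[, c] <- plant_column(n_seqs_b, r, planted_level, filler)
        truth$a_residues[c] <- r
        truth$b_residues[c] <- r
      } else if (cl == "DA_SPECIFIC_A" || cl == "DA_SPECIFIC_B") {
        r <- sample(AA1, 1)
        off <- pick_scattered(unrelated_residues(r))
        cons <- plant_column(if (cl == "DA_SPECIFIC_A") n_seqs_a else n_seqs_b,
                             r, planted_level, off)
        vari <- rep_len(off, if (cl == "DA_SPECIFIC_A") n_seqs_b else n_seqs_a)
        if (cl == "DA_SPECIFIC_A") {
          A[, c] <- cons; B[, c] <- vari
          truth$a_residues[c] <- r
          truth$b_residues[c] <- paste(off, collapse = ",")
        } else {
          B[, c] <- cons; A[, c] <- vari
          truth$b_residues[c] <- r
          truth$a_residues[c] <- paste(off, collapse = ",")
        }
      } else if (cl == "DA_SPECIFIC_BOTH") {
        p <- disjoint_pair()
        fa <- pick_scattered(unrelated_residues(p[1]))
        fb <- pick_scattered(unrelated_residues(p[2]))
        A[, c] <- plant_column(n_seqs_a, p[1], planted_level, fa)
        B[, c] <- plant_column(n_seqs_b, p[2], planted_level, fb)
        truth$a_residues[c] <- p[1]
        truth$b_residues[c] <- p[2]
      } else if (cl == "VARIABLE") {
        sa <- pick_scattered(AA1)
        sb <- pick_scattered(AA1)
        A[, c] <- rep_len(sa, n_seqs_a)
        B[, c] <- rep_len(sb, n_seqs_b)
        truth$a_residues[c] <- paste(sa, collapse = ",")
        truth$b_residues[c] <- paste(sb, collapse = ",")
      } else stop("unknown planted class: ", cl)
    }
    corrupt <- function(M) {
      if (noise > 0) {
        flip <- matrix(stats::runif(length(M)) < noise, nrow(M))
        M[flip] <- sample(AA1, sum(flip), replace = TRUE)
      }
      if (gap_rate > 0) {
        g <- matrix(stats::runif(length(M)) < gap_rate, nrow(M))
        M[g] <- "-"
      }
      M
    }
    A <- corrupt(A); B <- corrupt(B)
    to_aln <- function(M, prefix) {
      seqs <- stats::setNames(apply(M, 1, paste, collapse = ""),
                              paste0(prefix, seq_len(nrow(M))))
      read_alignment(seqs)
    }
    sa_a <- to_aln(A, "A")
    sa_b <- to_aln(B, "B")
    csa <- read_alignment(c(sa_a$seqs, sa_b$seqs))
    list(sa_a = sa_a, sa_b = sa_b, csa = csa, truth = truth)
  })
}

#' Default planted column-class mix
#'
#' The 120-column mix matching the headline counts of the motivating
#' analysis: 16 shared, 30 A-only, 11 B-only, 10 both-specific (40 total
#' A-specific, 21 total B-specific), 53 variable.
#'
#' @return Character vector of length 120.
#' @export
default_column_classes <- function() {
  c(rep("SHARED_CONSERVED", 16),
    rep("DA_SPECIFIC_A", 30),
    rep("DA_SPECIFIC_B", 11),
    rep("DA_SPECIFIC_BOTH", 10),
    rep("VARIABLE", 53))
}

random_seq <- function(n) paste(sample(AA1, n, replace = TRUE), collapse = "")

#' Generate a labelled domain-annotation set
#'
#' Produces clean Sec7+PH two-domain proteins matching the default query, one
#' defective entry per requested reason code (each violating exactly one
#' rule), and near-duplicate copies of the first clean entry (differing only
#' by a short N-terminal extension, identity 1.0 under the min-length
#' definition) for clustering tests.
#'
#' @param n_clean Number of clean entries (default 10).
#' @param defects Character vector of reason codes to plant (any of
#'   `OVERLAP`, `EXTRA_DOMAIN`, `WRONG_ORDER`, `PARTIAL_DOMAIN`,
#'   `LONG_INSERTION`, `LONG_EXTENSION`, `FRAGMENT`; default all seven).
#' @param n_redundant Near-duplicates of the first clean entry (default 2).
#' @param seed RNG seed.
#' @param dir Optional directory; when given, writes `hits.tsv`, `seqs.fa`
#'   and `truth.json` there.
#' @return List: `table` (domain-hit data frame), `seqs` (named sequences),
#'   `truth` (data frame `protein_id`, `expect` = `ACCEPT` or reason code,
#'   `redundant_with`), `query` (the matching `architecture_query`).
#' @export
gen_annotation_set <- function(n_clean = 10,
                               defects = c("OVERLAP", "EXTRA_DOMAIN",
                                           "WRONG_ORDER", "PARTIAL_DOMAIN",
                                           "LONG_INSERTION", "LONG_EXTENSION",
                                           "FRAGMENT"),
                               n_redundant = 2, seed = 1, dir = NULL) {
  query <- architecture_query(
    domain_order = c("Sec7", "PH"),
    domain_bounds = data.frame(domain_name = c("Sec7", "PH"),
                               min_len = c(180, 100), max_len = c(200, 130)),
    linker_ref = 8, n_ext_ref = 50, c_ext_ref = 30, relaxation = 20)

  with_seed(seed, {
    rows <- list(); seqs <- character(); truth <- list()
    add <- function(id, doms, seq, expect, frag = FALSE, red = NA_character_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        protein_id = id, domain = doms$domain, start = doms$start,
        end = doms$end, fragment = frag, stringsAsFactors = FALSE)
      seqs[id] <<- seq
      truth[[length(truth) + 1L]] <<- data.frame(
        protein_id = id, expect = expect, redundant_with = red,
        stringsAsFactors = FALSE)
    }
    make_clean <- function() {
      n_ext <- sample(40:60, 1); s_len <- sample(185:195, 1)
      linker <- sample(5:12, 1); p_len <- sample(105:125, 1)
      c_ext <- sample(20:40, 1)
      s1 <- n_ext + 1; e1 <- s1 + s_len - 1
      s2 <- e1 + linker + 1; e2 <- s2 + p_len - 1
      list(doms = data.frame(domain = c("Sec7", "PH"),
                             start = c(s1, s2), end = c(e1, e2)),
           len = e2 + c_ext)
    }
    for (i in seq_len(n_clean)) {
      g <- make_clean()
      add(sprintf("CLEAN%02d", i), g$doms, random_seq(g$len), "ACCEPT")
    }
    for (d in defects) {
      g <- make_clean()
      doms <- g$doms; len <- g$len; frag <- FALSE
      if (d == "OVERLAP") {
        # slide the PH hit left into Sec7, keeping its length and the
        # C-terminal extension unchanged so only the overlap rule fires
        delta <- doms$start[2] - (doms$end[1] - 5)
        doms$start[2] <- doms$start[2] - delta
        doms$end[2] <- doms$end[2] - delta
        len <- len - delta
      } else if (d == "EXTRA_DOMAIN") {
        doms <- rbind(doms[1, ],
                      data.frame(domain = "UNK", start = doms$end[1] + 2,
                                 end = doms$end[1] + 40),
                      doms[2, ])
        doms$start[3] <- doms$end[2] + 5
        doms$end[3] <- doms$start[3] + 110
        len <- doms$end[3] + 25
      } else if (d == "WRONG_ORDER") {
        doms$domain <- c("PH", "Sec7")
        doms$end[1] <- doms$start[1] + 110
        doms$start[2] <- doms$end[1] + 9
        doms$end[2] <- doms$start[2] + 189
        len <- doms$end[2] + 25
      } else if (d == "PARTIAL_DOMAIN") {
        doms$end[2] <- doms$start[2] + 59   # PH truncated below min_len
        len <- doms$end[2] + 25
      } else if (d == "LONG_INSERTION") {
        shift <- 95 - (doms$start[2] - doms$end[1] - 1)
        doms$start[2] <- doms$start[2] + shift
        doms$end[2] <- doms$end[2] + shift
        len <- len + shift
      } else if (d == "LONG_EXTENSION") {
        shift <- 120 - (doms$start[1] - 1)
        doms[, c("start", "end")] <- doms[, c("start", "end")] + shift
        len <- len + shift
      } else if (d == "FRAGMENT") {
        frag <- TRUE
      } else stop("unknown defect: ", d)
      add(paste0("DEF_", d), doms, random_seq(len), d, frag = frag)
    }
    for (r in seq_len(n_redundant)) {
      base_rows <- rows[[1]]
      ext <- r + 2L   # short N-terminal extension
      doms <- data.frame(domain = base_rows$domain,
                         start = base_rows$start + ext,
                         end = base_rows$end + ext)
      add(sprintf("REDUN%02d", r), doms,
          paste0(random_seq(ext), seqs[["CLEAN01"]]),
          "ACCEPT", red = "CLEAN01")
    }
    tab <- do.call(rbind, rows)
    truth <- do.call(rbind, truth)
    out <- list(table = tab, seqs = seqs, truth = truth, query = query)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(tab, file.path(dir, "hits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                                  file.path(dir, "seqs.fa"))
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           dataframe = "rows")
    }
    out
  })
}
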