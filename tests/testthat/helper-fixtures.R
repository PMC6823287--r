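# Fixtures built in code at test time.

parse_toy <- function(toy) {
  p <- tempfile(fileext = ".pdb")
  write_toy_structure(toy, p)
  parse_structure(p)
}

structure_from_atoms <- function(atom) {
  p <- tempfile(fileext = ".pdb")
  writeLines(format_pdb(atom), p)
  parse_structure(p)
}

write_annotation_files <- function(ann) {
  tf <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fa")
  utils::write.table(ann$table, tf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(ann$seqs), fa)
  list(table = tf, fasta = fa)
}

aln_from_rows <- function(...) {
  read_alignment(unlist(list(...)))
}

# single aligned column as an alignment (for profile/oracle work)
column_alignment <- function(chars) {
  read_alignment(stats::setNames(chars, paste0("s", seq_along(chars))))
}

# Two-chain role fixture: chain A carries a PH-like segment (residues 1-10)
# and a linker segment (11-20); chain B is a partner protein.
#   A:1 Lys NZ  -- 2.8 A -- B:50 Asp OD1   (inter-chain salt bridge/H-bond)
#   A:2 Ser OG  -- 2.9 A -- A:1 Lys NZ     (intraprotein: second shell to B)
#   A:3 Tyr OH  -- 3.0 A -- A:12 Gln OE1   (inter-segment, PH x linker)
#   A:4 Thr OG1 isolated                    (no role)
role_fixture <- function() {
  atom <- rbind(
    stub_residue("A", 1L, "LYS", "NZ", "N", c(0, 0, 0), c(0, -1, 0)),
    stub_residue("A", 2L, "SER", "OG", "O", c(2.9, 0, 0), c(1, 0, 0)),
    stub_residue("B", 50L, "ASP", "OD1", "O", c(0, 2.8, 0), c(0, 1, 0)),
    stub_residue("A", 3L, "TYR", "OH", "O", c(30, 0, 0), c(0, -1, 0)),
    stub_residue("A", 12L, "GLN", "OE1", "O", c(30, 3.0, 0), c(0, 1, 0)),
    stub_residue("A", 4L, "THR", "OG1", "O", c(60, 0, 0), c(0, -1, 0)))
  st <- structure_from_atoms(atom)
  segs <- segment_map(name = c("PH", "linker", "Arf6"),
                      chain = c("A", "A", "B"),
                      start = c(1L, 11L, NA), end = c(10L, 20L, NA))
  ints <- label_context(rbind(hydrogen_bonds(st), salt_bridges(st)), segs)
  list(structure = st, segments = segs, interactions = ints,
       da = data.frame(chain = "A", resno = c(1L, 2L, 3L, 4L),
                       resid = c("LYS", "SER", "TYR", "THR"),
                       stringsAsFactors = FALSE))
}

# Conformer fixture: n_pairs Ser OG ... Glu OE1 H-bonded pairs bridging a
# "hinge" segment (residues 1-50) and a "C-helix" segment (101-150); the
# second conformer displaces `displaced` Ser residues, breaking those pairs.
conformer_fixture <- function(n_pairs = 5, displaced = integer()) {
  rows <- list()
  for (i in seq_len(n_pairs)) {
    dz <- if (i %in% displaced) 50 else 0
    rows[[length(rows) + 1]] <-
      stub_residue("A", i, "SER", "OG", "O", c(10 * i, 0, dz), c(0, -1, 0))
    rows[[length(rows) + 1]] <-
      stub_residue("A", 100L + i, "GLU", "OE1", "O", c(10 * i, 2.9, 0),
                   c(0, 1, 0))
  }
  st <- structure_from_atoms(do.call(rbind, rows))
  segs <- segment_map(name = c("hinge", "C-helix"), chain = c("A", "A"),
                      start = c(1L, 101L), end = c(50L, 150L))
  label_context(hydrogen_bonds(st), segs)
}

# multinomial resampling oracle for planted-column recovery: rebuilds each
# column's residue vector from the truth recipe, applies iid substitution
# noise, and classifies with the package rule
oracle_recovery <- function(truth, n_a, n_b, noise, n_reps, seed) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sample_side <- function(res_str, n) {
    base <- rep_len(strsplit(res_str, ",")[[1]], n)
    flip <- stats::runif(n) < noise
    base[flip] <- sample(aa, sum(flip), replace = TRUE)
    base
  }
  expected <- ifelse(truth$class == "VARIABLE", "NONSPECIFIC", truth$class)
  hits <- 0L; total <- 0L
  for (rep in seq_len(n_reps)) {
    for (k in seq_len(nrow(truth))) {
      pa <- profile_columns(column_alignment(
        sample_side(truth$a_residues[k], n_a)))[[1]]
      pb <- profile_columns(column_alignment(
        sample_side(truth$b_residues[k], n_b)))[[1]]
      got <- classify_position(pa, pb)$class
      hits <- hits + (got == expected[k])
      total <- total + 1L
    }
  }
  hits / total
}

# recovery fraction measured through the generator itself
generator_recovery <- function(noise, n_runs, seed0, n_a = 88, n_b = 21) {
  hits <- 0L; total <- 0L
  for (r in seq_len(n_runs)) {
    g <- gen_alignment_pair(n_a, n_b, noise = noise, seed = seed0 + r)
    cls <- classify_alignment_pair(g$sa_a, g$sa_b)
    expected <- ifelse(g$truth$class == "VARIABLE", "NONSPECIFIC",
                       g$truth$class)
    hits <- hits + sum(cls$class == expected)
    total <- total + nrow(g$truth)
  }
  hits / total
}
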