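# Domain-architecture selection, pairwise identity, greedy clustering.

make_query <- function(relaxation = 20) {
  architecture_query(
    domain_order = c("Sec7", "PH"),
    domain_bounds = data.frame(domain_name = c("Sec7", "PH"),
                               min_len = c(150, 100), max_len = c(200, 130)),
    linker_ref = 8, n_ext_ref = 50, c_ext_ref = 30, relaxation = relaxation)
}

make_ann <- function(id, hits, seq_len, fragment = FALSE) {
  structure(list(protein_id = id,
                 sequence = paste(rep("A", seq_len), collapse = ""),
                 hits = hits, fragment = fragment),
            class = "protein_annotation")
}

test_that("domain tables parse into sorted per-protein annotations", {
  tf <- tempfile()
  writeLines(c("protein_id\tdomain\tstart\tend",
               "P1\tPH\t263\t380",
               "P1\tSec7\t60\t255"), tf)
  seqs <- c(P1 = paste(rep("A", 400), collapse = ""))
  anns <- parse_domain_table(tf, seqs)
  expect_length(anns, 1)
  expect_identical(anns[[1]]$hits$domain_name, c("Sec7", "PH"))
  expect_identical(anns[[1]]$hits$start, c(60L, 263L))

  writeLines("protein_id\tdomain\tstart\tend", tf)
  expect_length(parse_domain_table(tf, seqs), 0)

  writeLines(c("protein_id\tdomain\tstart\tend", "P1\tPH\t26x\t380"), tf)
  expect_error(parse_domain_table(tf, seqs), "line 2")

  writeLines(c("protein_id\tdomain\tstart\tend", "P1\tPH\t380\t263"), tf)
  expect_error(parse_domain_table(tf, seqs), "end < start")

  writeLines(c("protein_id\tdomain\tstart\tend", "P9\tPH\t1\t100"), tf)
  expect_identical(attr(parse_domain_table(tf, seqs), "missing_sequence"), "P9")
})

test_that("architecture matching applies the acceptance and rejection rules", {
  q <- make_query()
  clean <- make_ann("ok", data.frame(domain_name = c("Sec7", "PH"),
                                     start = c(51, 249), end = c(240, 360)),
                    seq_len = 390)
  expect_true(match_architecture(clean, q)$accept)

  extra <- make_ann("x", data.frame(domain_name = c("Sec7", "X", "PH"),
                                    start = c(51, 245, 300),
                                    end = c(240, 290, 410)), 440)
  expect_identical(match_architecture(extra, q)$reason, "EXTRA_DOMAIN")

  # 95-residue linker vs reference 8 exceeds the 20-residue relaxation
  long <- make_ann("l", data.frame(domain_name = c("Sec7", "PH"),
                                   start = c(51, 336), end = c(240, 447)),
                   480)
  expect_identical(match_architecture(long, q)$reason, "LONG_INSERTION")

  frag <- make_ann("f", clean$hits, 390, fragment = TRUE)
  expect_identical(match_architecture(frag, q)$reason, "FRAGMENT")
})

test_that("matching is order-sensitive in the query architecture", {
  q <- make_query()
  swapped_q <- architecture_query(
    domain_order = c("PH", "Sec7"), domain_bounds = q$domain_bounds,
    linker_ref = 8, n_ext_ref = 50, c_ext_ref = 30)
  ann <- make_ann("ok", data.frame(domain_name = c("Sec7", "PH"),
                                   start = c(51, 249), end = c(240, 360)),
                  390)
  expect_true(match_architecture(ann, q)$accept)
  expect_identical(match_architecture(ann, swapped_q)$reason, "WRONG_ORDER")
})

test_that("selection reason codes match the planted defect panel exactly", {
  ann <- gen_annotation_set(n_clean = 6, seed = 11)
  files <- write_annotation_files(ann)
  anns <- parse_domain_table(files$table, files$fasta)
  rep <- select_architecture(anns, ann$query)
  truth <- ann$truth
  expect_setequal(rep$accepted, truth$protein_id[truth$expect == "ACCEPT"])
  planted <- truth[truth$expect != "ACCEPT", ]
  expect_identical(unname(rep$rejected[planted$protein_id]), planted$expect)
})

test_that("pairwise identity uses the shorter ungapped length and is symmetric", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1.0)
  # terminal extensions do not break redundancy detection
  expect_equal(pairwise_identity("ACDEFG", "ACDEFGHH"), 1.0)
  expect_equal(pairwise_identity("KKKKKKKKKK", "KKKKKAKKKK"), 0.9)
  expect_equal(pairwise_identity("KKKKKKKKKK", "KKKKKAKKKK"),
               gotoh_identity("KKKKKKKKKK", "KKKKKAKKKK"))
  expect_error(pairwise_identity("", "ACD"), "non-empty")

  set.seed(42)
  for (k in 1:5) {
    a <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 30,
                      replace = TRUE), collapse = "")
    b <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 25,
                      replace = TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_equal(pairwise_identity(a, a), 1.0)
  }
  # X never counts as identical
  expect_equal(pairwise_identity("AXAXAX", "AXAXAX"), 0.5)
})

test_that("identity agrees with an independent affine-gap DP oracle", {
  pairs <- list(
    c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"),
    c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", "MKTAYIAKQRQISFVKSHFSRQLAERLGLIEVQ"),
    c("GGSSAAPPLLKKHH", "GGSSAAPPLLKKHHEEE"),
    c("WWWFFFYYYLLL", "WWWFFFYYYILL"))
  for (p in pairs)
    expect_equal(pairwise_identity(p[1], p[2]), gotoh_identity(p[1], p[2]),
                 tolerance = 1e-12)
})

test_that("greedy clustering removes redundancy at the strict 90% cutoff", {
  seqs <- c(a = "MKTAYIAKQRQISFVKSHFSRQ", b = "MKTAYIAKQRQISFVKSHFSRQ")
  cl <- greedy_cluster(seqs)
  expect_length(cl$representatives, 1)
  expect_identical(unique(cl$members$representative), cl$representatives)

  # all pairwise identities at or below the cutoff: everything representative
  dis <- c(a = "AAAAAAAAAA", b = "CCCCCCCCCC", c = "DDDDDDDDDD")
  expect_length(greedy_cluster(dis)$representatives, 3)

  # boundary is strict: exactly 90% identity does not cluster
  ten <- c(a = "KKKKKKKKKK", b = "KKKKKAKKKK")
  expect_length(greedy_cluster(ten, cutoff = 0.90)$representatives, 2)
})

test_that("cutoff 1.0 clusters only exact duplicates and sub/super-sequences", {
  seqs <- c(full = "MKTAYIAKQRQISFVKSHFSRQ",
            dup = "MKTAYIAKQRQISFVKSHFSRQ",
            sub = "MKTAYIAKQRQISFVKSH",       # reaches 1.0 by min-length rule
            other = "GGGGGGGGGGGGGGGGGGGGGG")
  # equal-length ties break lexicographically, so "dup" founds the cluster
  cl <- greedy_cluster(seqs, cutoff = 0.99)
  expect_setequal(cl$representatives, c("dup", "other"))
  m <- stats::setNames(cl$members$representative, cl$members$id)
  expect_identical(unname(m[c("full", "sub")]), c("dup", "dup"))
})

test_that("greedy clustering equals the exhaustive-matrix oracle", {
  set.seed(7)
  base <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40,
                       replace = TRUE), collapse = "")
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], k,
                      replace = TRUE)
    paste(ch, collapse = "")
  }
  seqs <- c(s1 = base, s2 = mutate(base, 1), s3 = mutate(base, 2),
            s4 = mutate(base, 15), s5 = mutate(base, 20),
            s6 = paste0("AAA", base))
  got <- greedy_cluster(seqs)
  want <- greedy_cluster_oracle(seqs)
  expect_setequal(got$representatives, want$representatives)
  m <- stats::setNames(got$members$representative, got$members$id)
  expect_identical(m[names(want$assign)], want$assign)
})
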