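test_that("alignment coverage is length over mean protein length", {
  hits <- tibble::tibble(aln_len = c(50L, 10L, 75L),
                         qlen = c(100L, 100L, 100L),
                         slen = c(100L, 100L, 50L))
  expect_equal(alignment_coverage(hits), c(50, 10, 100))
})

test_that("best-hit selection filters inclusively and keeps one hit per subject genome", {
  genes <- tibble::tibble(gene_id = c("q1", "s1", "s2", "s3"),
                          genome_id = c("A", "B", "B", "C"),
                          aa_seq = strrep("M", 100), annotation = "")
  hits <- tibble::tibble(
    query_id = c("q1", "q1", "q1"),
    subject_id = c("s1", "s2", "s3"),
    evalue = c(1e-5, 1e-3, 2e-3),
    bitscore = c(80, 50, 40),
    aln_len = c(100L, 100L, 9L), qlen = 100L, slen = 100L
  )
  out <- select_best_hits(hits, genes, evalue_cut = 1e-3, coverage_cut = 10)
  # s1 and s2 are both genome B: only the lower E-value survives;
  # s3 fails both the E-value cut (strictly above) and coverage (9.9 < 10)
  expect_equal(out$subject_id, "s1")

  # boundary: evalue == cut and coverage == cut both pass
  hits2 <- tibble::tibble(query_id = "q1", subject_id = "s3",
                          evalue = 1e-3, bitscore = 40,
                          aln_len = 10L, qlen = 100L, slen = 100L)
  expect_equal(nrow(select_best_hits(hits2, genes, 1e-3, 10)), 1L)

  empty <- hits[0, ]
  expect_equal(nrow(select_best_hits(empty, genes, 1e-3, 10)), 0L)
})

test_that("groups are connected components spanning at least two genomes", {
  genes <- tibble::tibble(
    gene_id = c("a1", "b1", "c1", "a2", "a3"),
    genome_id = c("A", "B", "C", "A", "A"),
    aa_seq = "M", annotation = c("polA", "polA", "", "", "")
  )
  mk <- function(q, s) tibble::tibble(query_id = q, subject_id = s,
                                      evalue = 1e-9, bitscore = 99,
                                      aln_len = 10L, qlen = 10L, slen = 10L,
                                      coverage = 100)
  # chain a1-b1-c1 plus a same-genome pair a2-a3
  hits <- dplyr::bind_rows(mk("a1", "b1"), mk("b1", "c1"), mk("a2", "a3"))
  groups <- build_groups(hits, genes)
  expect_equal(nrow(groups), 1L) # a2/a3 component has genome span 1
  expect_equal(groups$genome_span, 3L)
  expect_setequal(groups$members[[1]], c("a1", "b1", "c1"))
  expect_match(groups$annotations, "polA")

  expect_equal(nrow(build_groups(hits[0, ], genes)), 0L)
})

test_that("grouping is invariant to hit order", {
  fam <- NULL
  genes <- tibble::tibble(
    gene_id = sprintf("g%d", 1:6),
    genome_id = rep(c("A", "B", "C"), 2),
    aa_seq = "M", annotation = ""
  )
  mk <- function(q, s, e) tibble::tibble(query_id = q, subject_id = s,
                                         evalue = e, bitscore = 50,
                                         aln_len = 10L, qlen = 10L,
                                         slen = 10L, coverage = 100)
  hits <- dplyr::bind_rows(mk("g1", "g2", 1e-8), mk("g2", "g3", 1e-7),
                           mk("g4", "g5", 1e-6), mk("g5", "g6", 1e-9))
  g1 <- build_groups(hits, genes)
  g2 <- build_groups(hits[sample(nrow(hits)), ], genes)
  expect_equal(g1, g2)
  # disjoint membership
  expect_equal(anyDuplicated(unlist(g1$members)), 0L)
})

test_that("identical proteins in different genomes hit each other strongly", {
  prot <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                       100, replace = TRUE), collapse = "")
  genes <- tibble::tibble(
    gene_id = c("x1", "y1"), genome_id = c("X", "Y"),
    aa_seq = prot, annotation = ""
  )
  for (engine in c("external", "internal")) {
    hits <- compute_pairwise_hits(genes, engine = engine)
    expect_setequal(hits$query_id, c("x1", "y1")) # both directions
    expect_true(all(hits$evalue < 1e-20))
    expect_true(all(hits$aln_len >= 95)) # essentially full length
  }
})

test_that("unrelated random proteins produce no hit at E <= 1e-3", {
  set.seed(21)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  genes <- tibble::tibble(
    gene_id = c("x1", "y1"), genome_id = c("X", "Y"),
    aa_seq = replicate(2, paste(sample(aas, 100, TRUE), collapse = "")),
    annotation = ""
  )
  for (engine in c("external", "internal")) {
    hits <- compute_pairwise_hits(genes, engine = engine)
    filt <- select_best_hits(hits, genes, evalue_cut = 1e-3,
                             coverage_cut = 10)
    expect_equal(nrow(filt), 0L)
  }
})

test_that("internal and external engines agree on which planted pairs pass", {
  fam <- simulated_family(905, n_genomes = 3L, aa_identity = 0.6,
                          aa_len = 120L, genome_len = 3000L)
  edge_set <- function(engine) {
    hits <- compute_pairwise_hits(fam$genes, engine = engine)
    filt <- select_best_hits(hits, fam$genes, 1e-3, 10)
    sort(unique(vapply(seq_len(nrow(filt)), function(i) {
      paste(sort(c(filt$query_id[i], filt$subject_id[i])), collapse = "|")
    }, "")))
  }
  expect_equal(edge_set("internal"), edge_set("external"))
})

test_that("standard BLAST tabular output parses with and without length columns", {
  tab12 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-50\t180"),
             tab12)
  genes <- tibble::tibble(gene_id = c("q1", "s1"), genome_id = c("A", "B"),
                          aa_seq = strrep("M", 100))
  hits <- read_blast_tab(tab12, genes)
  expect_equal(hits$qlen, 100L)
  expect_equal(hits$evalue, 1e-50)
  expect_error(read_blast_tab(tab12), "no gene records")

  tab14 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-50\t180\t110\t120"),
             tab14)
  hits14 <- read_blast_tab(tab14)
  expect_equal(hits14$qlen, 110L)
  expect_equal(hits14$slen, 120L)
})
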