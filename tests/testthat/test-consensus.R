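test_that("aligning identical genes gives gap-free rows equal to the coding sequences", {
  nt <- "ATGAAAGTTCCGGACTAA"
  genes <- genes_from_nt(c(nt, nt))
  aln <- align_group(genes)
  expect_equal(unname(aln$rows), c(nt, nt))
  expect_equal(aln$source, "auto")
})

test_that("back-translation replaces residues by original codons and gaps by ---", {
  # proteins MKV / MV aligned as MKV / M-V
  row <- phagesig:::back_translate_row("M-V", "ATGGTT", "g2")
  expect_equal(row$core, "ATG---GTT")
  row2 <- phagesig:::back_translate_row("MKV", "ATGAAAGTTTAA", "g1")
  expect_equal(row2$core, "ATGAAAGTT")
  expect_equal(row2$tail, "TAA")
  expect_error(phagesig:::back_translate_row("MKV", "ATGAAA", "g3"),
               "disagree")
})

test_that("ungapping any auto-alignment row reproduces the coding sequence", {
  set.seed(31)
  for (s in c(906, 907)) {
    fam <- simulated_family(s, n_genomes = 3L, aa_identity = 0.6,
                            aa_len = 80L, genome_len = 3000L)
    aln <- align_group(fam$genes)
    for (id in aln$member_ids) {
      ungapped <- gsub("-", "", aln$rows[[id]], fixed = TRUE)
      expect_equal(ungapped, fam$genes$nt_seq[fam$genes$gene_id == id])
    }
  }
})

test_that("user alignments round-trip through FASTA and CLUSTAL", {
  genes <- genes_from_nt(c("ATGAAAGTTTAA", "ATGGTTTAA"))
  aln <- align_group(genes)
  fa <- withr::local_tempfile(fileext = ".fasta")
  cl <- withr::local_tempfile(fileext = ".aln")
  write_alignment(aln, fasta_path = fa, clustal_path = cl)

  from_fa <- load_user_alignment(fa, expected_members = genes$gene_id)
  from_cl <- load_user_alignment(cl, expected_members = genes$gene_id)
  expect_equal(from_fa$rows[aln$member_ids], aln$rows)
  expect_equal(from_cl$rows[aln$member_ids], aln$rows)
  expect_equal(from_fa$source, "user")

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), ragged)
  expect_error(load_user_alignment(ragged), "unequal")
  expect_error(load_user_alignment(fa, expected_members = "zz"), "unknown")
})

test_that("the IUPAC consensus is minimal with gap propagation", {
  mk <- function(...) phagesig:::new_codon_alignment(
    paste0("m", seq_along(c(...))), c(...))
  c1 <- iupac_consensus(mk("ACGT", "ACGT"))
  expect_equal(c1$consensus, "ACGT")
  expect_true(all(c1$conserved))

  c2 <- iupac_consensus(mk("AAAA", "AAAG"))
  expect_equal(c2$consensus, "AAAR")
  expect_equal(c2$conserved, c(TRUE, TRUE, TRUE, FALSE))

  c3 <- iupac_consensus(mk("AC-T", "ACGT"))
  expect_equal(c3$consensus, "AC-T")
  expect_false(c3$conserved[3])

  # ambiguous input bases widen the column and are never conserved
  c4 <- iupac_consensus(mk("AN", "AA"))
  expect_equal(c4$consensus, "AN")
  expect_equal(c4$conserved, c(TRUE, FALSE))
})

test_that("consensus minimality holds on random columns", {
  set.seed(32)
  for (i in 1:200) {
    col <- sample(c("A", "C", "G", "T"), sample(2:6, 1), replace = TRUE)
    aln <- phagesig:::new_codon_alignment(paste0("m", seq_along(col)), col)
    cons <- iupac_consensus(aln)
    covered <- phagesig:::iupac_set(cons$consensus)
    expect_setequal(covered, unique(col)) # exact cover, hence minimal
    expect_equal(cons$conserved, length(unique(col)) == 1L)
  }
})

test_that("conserved regions follow the anchor/window/flank rule", {
  mk_cons <- function(consensus) {
    structure(list(
      consensus = consensus,
      conserved = strsplit(consensus, "")[[1]] %in% c("A", "C", "G", "T")
    ), class = "consensus_seq")
  }
  # conserved block at 6..13 inside degenerate flanks: each anchor 6..12
  # pairs with furthest conserved base 13, plus 5-base flanks clipped at
  # the termini
  r <- extract_conserved_regions(mk_cons("RRRRRACGTACGTRRRRR"))
  expect_equal(nrow(r), 7L)
  expect_equal(r$start, 1:7)
  expect_true(all(r$stop == 18L))
  expect_equal(r$length, 18:12)
  expect_equal(r$seq[7], "CGTACGTRRRRR")

  # two conserved bases 22 apart, nothing between: outside the 19-base window
  far <- paste0("A", strrep("R", 21), "A")
  expect_equal(nrow(extract_conserved_regions(mk_cons(far))), 0L)

  # any candidate span covering a gap column is excluded
  gapped <- "ACGT-ACGT"
  expect_equal(nrow(extract_conserved_regions(mk_cons(gapped))), 0L)
})

test_that("unclipped regions are 12-30 long with >= 2 conserved bases and no gaps", {
  set.seed(33)
  for (i in 1:20) {
    fam <- NULL
    chars <- sample(c("A", "C", "G", "T", "R", "Y", "S", "W", "N"),
                    sample(60:160, 1), replace = TRUE,
                    prob = c(rep(0.17, 4), rep(0.07, 4), 0.04))
    consensus <- paste(chars, collapse = "")
    cons <- structure(list(
      consensus = consensus,
      conserved = chars %in% c("A", "C", "G", "T")
    ), class = "consensus_seq")
    regions <- extract_conserved_regions(cons)
    if (nrow(regions) == 0L) next
    L <- nchar(consensus)
    unclipped <- regions$start > 5L & regions$stop < L - 4L
    expect_true(all(regions$length[unclipped] >= 12 &
                      regions$length[unclipped] <= 30))
    for (k in seq_len(nrow(regions))) {
      span <- strsplit(regions$seq[k], "")[[1]]
      expect_gte(sum(span %in% c("A", "C", "G", "T")), 2L)
      expect_false("-" %in% span)
    }
  }
})
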