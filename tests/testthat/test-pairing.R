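tp <- thermo_params()

make_cands <- function(seqs, starts, orientation) {
  primer_properties(tibble::tibble(
    region_id = "R1", seq = seqs, start = as.integer(starts),
    stop = as.integer(starts + nchar(seqs) - 1L),
    length = nchar(seqs), orientation = orientation
  ), tp)
}

test_that("candidates violating any single screen are dropped", {
  base <- make_cands(c(strrep("N", 12),        # degeneracy 16M
                       "AAAAAGGGGG",           # clamp 5
                       "CTGCACCGACCT"),        # unremarkable
                     c(1, 20, 40), "forward")
  out <- screen_candidates(base, design_params())
  expect_equal(out$seq, "CTGCACCGACCT")
  att <- attr(out, "attrition")
  expect_equal(unname(att["degeneracy"]), 1L)
  expect_equal(unname(att["gc_clamp"]), 1L)

  # all screens at infinite ranges pass everything through
  loose <- design_params(degeneracy_max = Inf, clamp_max = 5L,
                         gc_min = 0, gc_max = 100, dg3_floor = -Inf,
                         max_run = 100L)
  expect_equal(nrow(screen_candidates(base, loose)), nrow(base))
})

test_that("pairing respects orientation, product size and the ranking rule", {
  fwd <- make_cands(c("TAGGGCCCTTACCTTTTT", "TTTTATATATTTTAATAT"),
                    c(101, 120), "forward")
  rev <- make_cands(c("TTAGTTAGGCAGGTGCTT"), 921, "reverse")
  params <- design_params(product_min = 50L, product_max = 2000L)
  pairs <- pair_primers(fwd, rev, params)
  # f at 101, r stopping at 938 gives an 838 bp product
  expect_true(all(pairs$product_size ==
                    pairs$rev_stop - pairs$fwd_start + 1L))
  expect_true(any(pairs$product_size == 838L))
  expect_true(all(pairs$fwd_start < pairs$rev_start))
  # ranked by ascending Tm difference
  expect_equal(pairs$delta_tm, sort(pairs$delta_tm))
  expect_equal(pairs$rank, seq_len(nrow(pairs)))

  expect_equal(nrow(pair_primers(fwd[0, ], rev, params)), 0L)
})

test_that("pairs out of product range or with long cross-dimers are excluded", {
  fwd <- make_cands("TAGGGCCCTTACCTTTTT", 101, "forward")
  rev_far <- make_cands("TTAGTTAGGCAGGTGCTT", 5000, "reverse")
  expect_equal(nrow(pair_primers(fwd, rev_far,
                                 design_params(product_max = 1000L))), 0L)
  # reverse primer is the exact reverse complement: cross-dimer run spans
  # the whole primer
  rev_dimer <- make_cands(reverse_complement("TAGGGCCCTTACCTTTTT"),
                          300, "reverse")
  pr <- pair_primers(fwd, rev_dimer, design_params())
  expect_equal(nrow(pr), 0L)
  pr_loose <- pair_primers(fwd, rev_dimer, design_params(max_run = 100L))
  expect_equal(pr_loose$cross_dimer_run, 18L)
})

test_that("every emitted pair re-passes screening and the cross-dimer test", {
  fam <- simulated_family(908, n_genomes = 3L, aa_identity = 0.75,
                          aa_len = 80L, genome_len = 3000L)
  params <- design_params(len_min = 16L, len_max = 24L,
                          product_min = 80L, product_max = 1000L)
  d <- design_primers(fam$genes, params, top_k = 20L)
  expect_gt(nrow(d$pairs), 0L)
  for (k in seq_len(nrow(d$pairs))) {
    pair <- d$pairs[k, ]
    for (side in c("fwd_", "rev_")) {
      cand <- pair[, startsWith(names(pair), side)]
      names(cand) <- sub(side, "", names(cand))
      expect_equal(nrow(screen_candidates(cand, params)), 1L)
    }
    expect_lte(max_complementary_run(pair$fwd_seq, pair$rev_seq),
               params$max_run)
  }
})

test_that("in-silico recovery is exact for consensus-derived pairs and flags mutations", {
  genes <- genes_from_nt(c(
    "ATGGCTCGTAAAGGCGAACTGGTTGATCTGACCCGTGAAATCGCTAAAGGTTAA",
    "ATGGCTCGTAAAGGCGAACTGGTTGATCTGACCCGTGAAATCGCTAAAGGTTAA",
    "ATGGCTCGTAAAGGCGAACTGGTTGATCTGACCCGTGAAATCGCTAAAGGTTAA"
  ))
  d <- design_primers(genes, design_params(len_min = 12L, len_max = 18L,
                                           product_min = 30L,
                                           product_max = 60L), top_k = 5L)
  expect_gt(nrow(d$pairs), 0L)
  rec <- in_silico_recovery(d$pairs[1, ], d$alignment)
  expect_true(all(rec$fwd_mismatches == 0L))
  expect_true(all(rec$rev_mismatches == 0L))
  expect_true(all(rec$amplicon_length == d$pairs$product_size[1]))

  # inject one substitution inside the forward site of member 2
  aln2 <- d$alignment
  row <- strsplit(aln2$rows[[2]], "")[[1]]
  site <- d$pairs$fwd_start[1]:d$pairs$fwd_stop[1]
  pos <- site[3]
  row[pos] <- setdiff(c("A", "C", "G", "T"), row[pos])[1]
  aln2$rows[[2]] <- paste(row, collapse = "")
  rec2 <- in_silico_recovery(d$pairs[1, ], aln2)
  expect_equal(rec2$fwd_mismatches[2], 1L)
  expect_equal(rec2$fwd_mismatches[-2], rep(0L, 2))
})

test_that("member amplicon lengths track member-specific indels", {
  # middle member lacks one codon relative to the others
  genes <- genes_from_nt(c(
    "ATGGCTCGTAAAGGCGAACTGGTTGATCTGACCCGTGAAATCGCTAAAGGTTAA",
    "ATGGCTCGTAAAGGCGAACTGGATCTGACCCGTGAAATCGCTAAAGGTTAA",
    "ATGGCTCGTAAAGGCGAACTGGTTGATCTGACCCGTGAAATCGCTAAAGGTTAA"
  ))
  d <- design_primers(genes, design_params(len_min = 12L, len_max = 16L,
                                           product_min = 30L,
                                           product_max = 60L), top_k = 10L)
  if (nrow(d$pairs) > 0) {
    rec <- in_silico_recovery(d$pairs[1, ], d$alignment)
    expect_true(all(rec$gap_in_site == FALSE))
    span_cols <- d$pairs$rev_stop[1] - d$pairs$fwd_start[1] + 1L
    for (m in seq_len(nrow(rec))) {
      span <- substr(d$alignment$rows[[rec$member_id[m]]],
                     d$pairs$fwd_start[1], d$pairs$rev_stop[1])
      gaps <- nchar(span) - nchar(gsub("-", "", span, fixed = TRUE))
      expect_equal(rec$amplicon_length[m], span_cols - gaps)
    }
  }
})
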