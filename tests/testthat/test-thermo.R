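tp <- thermo_params()

test_that("primer enumeration slides every window of every length", {
  region <- tibble::tibble(region_id = "R001", start = 101L, stop = 112L,
                           length = 12L, seq = "ACGTACGTACGT")
  cands <- enumerate_primers(region, 10L, 28L)
  fwd <- cands[cands$orientation == "forward", ]
  expect_equal(nrow(fwd), 3 + 2 + 1) # lengths 10, 11, 12
  expect_equal(nrow(cands), 12L)     # reverse orientation mirrors it
  expect_true(all(cands$start >= 101 & cands$stop <= 112))

  # window content matches a substring oracle
  for (k in which(cands$orientation == "forward")) {
    expect_equal(cands$seq[k],
                 substr("ACGTACGTACGT", cands$start[k] - 100,
                        cands$stop[k] - 100))
  }
  rev <- cands[cands$orientation == "reverse", ]
  for (k in seq_len(nrow(rev))) {
    expect_equal(rev$seq[k],
                 reverse_complement(substr("ACGTACGTACGT",
                                           rev$start[k] - 100,
                                           rev$stop[k] - 100)))
  }

  short <- tibble::tibble(region_id = "R002", start = 1L, stop = 9L,
                          length = 9L, seq = "ACGTACGTA")
  expect_equal(nrow(enumerate_primers(short, 10L, 28L)), 0L)
})

test_that("basic melting temperature follows the Wallace/Marmur rule", {
  expect_equal(unname(tm_basic("AAAATTTT")["mid"]), 16)
  expect_equal(unname(tm_basic("GGGGCCCC")["mid"]), 32)
  # 14-mer switches to the long-primer formula
  expect_equal(unname(tm_basic("ACGTACGTACGTAC")["mid"]),
               64.9 + 41 * (7 - 16.4) / 14)
})

test_that("salt-adjusted Tm reduces to the basic rule at 50 mM and is monotone in salt", {
  expect_equal(unname(tm_salt("AAAATTTT", tp)["mid"]), 16)
  expect_equal(unname(tm_salt("ACGTACGTACGTAC", tp)["mid"]),
               81.5 + 16.6 * log10(0.05) + 0.41 * 50 - 675 / 14)
  set.seed(41)
  for (i in 1:10) {
    s <- random_dna_str(sample(8:25, 1))
    lo <- tm_salt(s, thermo_params(na_conc = 0.01))["mid"]
    hi <- tm_salt(s, thermo_params(na_conc = 0.2))["mid"]
    expect_lt(lo, hi)
  }
})

test_that("nearest-neighbor Tm matches the independent oracle", {
  # smallest case: single AT stack plus initiation terms
  expect_equal(unname(tm_nn("AT", tp)["mid"]), oracle_tm_nn("AT"),
               tolerance = 1e-10)
  set.seed(42)
  for (i in 1:25) {
    s <- random_dna_str(sample(8:28, 1))
    expect_equal(unname(tm_nn(s, tp)["mid"]), oracle_tm_nn(s),
                 tolerance = 1e-8)
  }
  # a longer duplex is more stable
  for (i in 1:10) {
    s <- random_dna_str(sample(8:14, 1))
    expect_gt(unname(tm_nn(paste0(s, s), tp)["mid"]),
              unname(tm_nn(s, tp)["mid"]))
  }
})

test_that("degenerate Tm triplets are ordered and collapse when non-degenerate", {
  set.seed(43)
  for (i in 1:20) {
    s <- random_iupac(sample(10:25, 1))
    for (f in list(tm_basic, function(x) tm_salt(x, tp),
                   function(x) tm_nn(x, tp))) {
      v <- f(s)
      expect_lte(v[["min"]], v[["mid"]])
      expect_lte(v[["mid"]], v[["max"]])
    }
    d <- random_dna_str(15)
    for (f in list(tm_basic, function(x) tm_salt(x, tp),
                   function(x) tm_nn(x, tp))) {
      v <- f(d)
      expect_equal(v[["min"]], v[["max"]])
    }
  }
})

test_that("3' stability sums the terminal stacks, most stable disambiguation", {
  # hand sum for a concrete 3' end AATAT: AA + AT + TA + AT
  nn <- phagesig:::load_nn_table(system.file("extdata",
                                             "nn_unified_1998.tsv",
                                             package = "phagesig"))
  hand <- unname(nn$dg37["AA"] + nn$dg37["AT"] + nn$dg37["TA"] +
                   nn$dg37["AT"])
  expect_equal(dg_3prime("GGGGGAATAT", tp), hand)
  expect_gt(dg_3prime("GGGGGAATAT", tp), -9) # weak A/T end passes
  expect_lt(dg_3prime("GGGGGGCGCG", tp), dg_3prime("GGGGGAATAT", tp))

  # degenerate end: most stable disambiguation, checked by enumeration
  set.seed(44)
  for (i in 1:20) {
    s <- paste0(random_dna_str(5), random_iupac(5, c("A", "C", "G", "T", "R", "Y", "S")))
    variants <- phagesig:::disambiguations(substr(s, 6, 10))
    by_enum <- min(vapply(variants, function(v) {
      dg_3prime(paste0("AAAAA", v), tp)
    }, 1))
    expect_equal(dg_3prime(s, tp), by_enum)
  }
})

test_that("substituting GC stacks into the 3' end lowers its free energy", {
  set.seed(45)
  for (i in 1:50) {
    s <- paste0(random_dna_str(10), "AATAT")
    stronger <- paste0(substr(s, 1, 10), "GCGCG")
    expect_lt(dg_3prime(stronger, tp), dg_3prime(s, tp))
  }
})

test_that("complementarity runs match known self-annealing cases", {
  expect_equal(max_complementary_run("GAATTC", "GAATTC"), 6) # palindrome
  expect_equal(max_complementary_run("AAAA", "AAAA"), 0)
  expect_equal(hairpin_run("GGGGAAAACCCC"), 4) # stem 4, loop AAAA
  expect_equal(hairpin_run("ACGT"), 0)         # too short for any loop
  # R/Y can pair under can-pair semantics (some disambiguation is WC)
  expect_equal(max_complementary_run("RRRR", "RRRR"), 0) # {A,G} vs {A,G}
  expect_equal(max_complementary_run("RRRR", "YYYY"), 4)
})

test_that("dg_min reports the most stable self-structure and 0 when none", {
  expect_equal(dg_min("AAAA", tp), 0)
  expect_lt(dg_min("GAATTC", tp), 0)
  nn <- phagesig:::load_nn_table(system.file("extdata",
                                             "nn_unified_1998.tsv",
                                             package = "phagesig"))
  # full palindrome duplex: dG of the 5 stacks of GAATTC
  ch <- strsplit("GAATTC", "")[[1]]
  expect_equal(dg_min("GAATTC", tp),
               unname(sum(nn$dg37[paste0(ch[-6], ch[-1])])))
})

test_that("screening predicates are pure and filtering twice is idempotent", {
  region <- tibble::tibble(region_id = "R1", start = 1L, stop = 30L,
                           length = 30L, seq = "ACGTRYGGCCAATTWSGATCKMACGTBDHV")
  cands <- primer_properties(enumerate_primers(region, 10L, 20L), tp)
  params <- design_params()
  once <- screen_candidates(cands, params)
  twice <- screen_candidates(once, params)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$seq, twice$seq)
  expect_equal(unname(attr(twice, "attrition")),
               rep(0L, length(attr(twice, "attrition"))))
})
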