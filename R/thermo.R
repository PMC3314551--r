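#' Primer thermodynamics and physicochemical screening
#'
#' Melting temperatures are computed three ways: the basic (Wallace/Marmur)
#' rule, a salt-adjusted form, and the unified nearest-neighbor (NN)
#' thermodynamic model. For degenerate primers each Tm is reported as a
#' `[min, mid, max]` triplet: the minimum and maximum come from the GC-extreme
#' disambiguations (every mixed base resolved towards A/T, respectively
#' towards G/C), which bound the pool's Tm because all three formulas are
#' monotone in GC count; mid is their mean. Free energies (3' end stability
#' and self-structure ΔG) take the most stable disambiguation, and
#' dimer/hairpin screening uses "can-pair" semantics (two codes pair if any
#' of their disambiguations are Watson-Crick complements) — all deliberately
#' conservative for degenerate pools.
#'
#' @name primer_thermo
NULL

#' Thermodynamic parameters
#'
#' @param na_conc monovalent cation concentration, mol/L (default 0.05 M).
#' @param primer_conc total oligo strand concentration, mol/L
#'   (default 2.5e-7 M = 250 nM).
#' @param nn_table path to the nearest-neighbor parameter TSV (columns `nn`,
#'   `dh_kcal`, `ds_cal`, `dg37_kcal`); defaults to the unified 1998
#'   parameter set shipped with the package.
#' @return list of class `thermo_params`.
#' @export
thermo_params <- function(na_conc = 0.05, primer_conc = 2.5e-7,
                          nn_table = NULL) {
  stopifnot(na_conc > 0, primer_conc > 0)
  if (is.null(nn_table)) {
    nn_table <- system.file("extdata", "nn_unified_1998.tsv",
                            package = "phagesig", mustWork = TRUE)
  }
  nn <- load_nn_table(nn_table)
  # 4x4 stack lookups by top-strand bases, for fast integer indexing
  bases <- c("A", "C", "G", "T")
  stack_mat <- function(v) {
    matrix(v[paste0(rep(bases, each = 4), rep(bases, 4))],
           4, 4, byrow = TRUE, dimnames = list(bases, bases))
  }
  structure(list(na_conc = na_conc, primer_conc = primer_conc, nn = nn,
                 dg_mat = stack_mat(nn$dg37), dh_mat = stack_mat(nn$dh),
                 ds_mat = stack_mat(nn$ds)),
            class = "thermo_params")
}

#' Load a nearest-neighbor parameter table
#'
#' The TSV lists the ten unique dinucleotide stacks plus the two duplex
#' initiation terms (`init_GC`, `init_AT`); the six reverse-complement
#' stacks are filled in automatically. Shipped as a plain-text file so
#' independent implementations can share one parameter source.
#'
#' @param path parameter TSV.
#' @return list with `dh`, `ds`, `dg37` named vectors over all 16 stacks
#'   and `init_GC`/`init_AT`.
#' @export
load_nn_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("nn", "dh_kcal", "ds_cal", "dg37_kcal") %in% names(tab)))
  dh <- stats::setNames(tab$dh_kcal, tab$nn)
  ds <- stats::setNames(tab$ds_cal, tab$nn)
  dg <- stats::setNames(tab$dg37_kcal, tab$nn)
  # a stack and its reverse complement share parameters
  for (x in setdiff(names(dh), c("init_GC", "init_AT"))) {
    rc <- reverse_complement(x)
    if (!rc %in% names(dh)) {
      dh[rc] <- dh[x]; ds[rc] <- ds[x]; dg[rc] <- dg[x]
    }
  }
  list(dh = dh, ds = ds, dg37 = dg)
}

.tm_triplet <- function(seq, f, ...) {
  ex <- gc_extremes(seq)
  lo <- f(ex$at, ...)
  hi <- f(ex$gc, ...)
  c(min = min(lo, hi), mid = mean(c(lo, hi)), max = max(lo, hi))
}

.base_counts <- function(seq) {
  n <- nchar(seq)
  gc <- n - nchar(gsub("[GC]", "", seq))
  c(gc = gc, at = n - gc, n = n)
}

tm_basic_concrete <- function(seq) {
  b <- .base_counts(seq)
  if (b["n"] < 14) {
    unname(2 * b["at"] + 4 * b["gc"])
  } else {
    unname(64.9 + 41 * (b["gc"] - 16.4) / b["n"])
  }
}

#' Basic melting temperature (Wallace/Marmur rule)
#'
#' `2(A+T) + 4(G+C)` for primers shorter than 14 nt; for 14 nt and longer,
#' `64.9 + 41 (nGC - 16.4) / N`.
#'
#' @param seq IUPAC primer string.
#' @return named numeric `[min, mid, max]` in deg C (all equal for
#'   non-degenerate primers).
#' @export
tm_basic <- function(seq) .tm_triplet(seq, tm_basic_concrete)

tm_salt_concrete <- function(seq, na_conc) {
  b <- .base_counts(seq)
  if (b["n"] < 14) {
    tm_basic_concrete(seq) - 16.6 * log10(0.05) + 16.6 * log10(na_conc)
  } else {
    unname(81.5 + 16.6 * log10(na_conc) + 0.41 * (100 * b["gc"] / b["n"]) -
             675 / b["n"])
  }
}

#' Salt-adjusted melting temperature
#'
#' The basic rule corrected for monovalent cation concentration; at the
#' reference 50 mM Na+ the short-primer correction vanishes. For 14 nt and
#' longer: `81.5 + 16.6 log10([Na+]) + 0.41 %GC - 675/N`.
#'
#' @param seq IUPAC primer string.
#' @param params a [thermo_params()].
#' @return named numeric `[min, mid, max]` in deg C.
#' @export
tm_salt <- function(seq, params = thermo_params()) {
  .tm_triplet(seq, tm_salt_concrete, na_conc = params$na_conc)
}

tm_nn_concrete <- function(seq, params) {
  bi <- match(strsplit(seq, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  n <- length(bi)
  stopifnot(n >= 2L, !anyNA(bi))
  st <- cbind(bi[-n], bi[-1])
  is_gc <- c(2L, 3L) # C, G
  init_rows <- ifelse(c(bi[1], bi[n]) %in% is_gc, "init_GC", "init_AT")
  dH <- sum(params$dh_mat[st]) + sum(params$nn$dh[init_rows])
  dS <- sum(params$ds_mat[st]) + sum(params$nn$ds[init_rows])
  R <- 1.987 # cal / (mol K)
  tm_K <- 1000 * dH / (dS + R * log(params$primer_conc / 4))
  unname(tm_K - 273.15 + 16.6 * log10(params$na_conc))
}

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm from the unified NN model:
#' `Tm(K) = 1000 dH / (dS + R ln(C_T/4))` with `R = 1.987` cal/(mol K),
#' dH/dS summed over dinucleotide stacks plus the two terminal initiation
#' terms, converted to deg C and salt-corrected by `+16.6 log10([Na+])`.
#'
#' @param seq IUPAC primer string, length >= 2.
#' @param params a [thermo_params()].
#' @return named numeric `[min, mid, max]` in deg C.
#' @export
tm_nn <- function(seq, params = thermo_params()) {
  .tm_triplet(seq, tm_nn_concrete, params = params)
}

#' 3' end stability
#'
#' Sum of nearest-neighbor ΔG(37 °C) over the four dinucleotide stacks
#' spanned by the five 3'-terminal bases. For degenerate primers the most
#' stable (most negative) disambiguation of the 3' end is taken. Primers
#' with ΔG >= -9 kcal/mol are conventionally considered acceptable for
#' pairing; an overly stable 3' end promotes mispriming and primer-dimer
#' extension.
#'
#' @param seq IUPAC primer string (5' to 3').
#' @param params a [thermo_params()].
#' @return ΔG in kcal/mol (a single number; shorter primers use the
#'   available stacks).
#' @export
dg_3prime <- function(seq, params = thermo_params()) {
  chars <- .check_iupac(.iupac_chars(seq))
  tail5 <- utils::tail(chars, 5L)
  .cpp_dg_run_min(.iupac_ints(tail5), .IUPAC_SETS_I, params$dg_mat)
}

#' Longest complementary run between two primers
#'
#' Slides `a` (5'->3') along the reverse of `b` over every ungapped offset
#' and returns the longest run of consecutive positions that can base-pair
#' (IUPAC can-pair semantics). `max_complementary_run(a, a)` is the
#' self-dimer run; forward vs reverse primer gives the cross-dimer run.
#' Dimers and hairpins must have fewer than five consecutive pairings to
#' pass screening.
#'
#' @param a,b IUPAC primer strings, both 5' to 3'.
#' @return integer, the maximum run length.
#' @export
max_complementary_run <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0L)
  xi <- .iupac_ints(.iupac_chars(a))
  yi <- rev(.iupac_ints(.iupac_chars(b)))
  .cpp_dimer_run(xi, yi, .CAN_PAIR_I)
}

#' Longest hairpin stem run
#'
#' Intramolecular pairing: the longest run of consecutive base pairs formed
#' between an upstream and a downstream segment of the same primer folded
#' back on itself, with a loop of at least `min_loop` unpaired bases
#' (default 3, the physical minimum).
#'
#' @param seq IUPAC primer string.
#' @param min_loop minimum loop length in bases.
#' @return integer, the maximum stem run length.
#' @export
hairpin_run <- function(seq, min_loop = 3L) {
  .cpp_hairpin_run(.iupac_ints(.iupac_chars(seq)), .CAN_PAIR_I,
                   as.integer(min_loop))
}

#' Minimum ΔG of primer self-structure
#'
#' The most negative nearest-neighbor ΔG(37 °C) over the maximal pairing
#' runs found by the self-dimer and hairpin searches, each run taken at its
#' most stable disambiguation. Reported for information; not filtered on by
#' default.
#'
#' @param seq IUPAC primer string.
#' @param params a [thermo_params()].
#' @param min_loop hairpin minimum loop.
#' @return ΔG in kcal/mol (0 when no pairing run of length >= 2 exists).
#' @export
dg_min <- function(seq, params = thermo_params(), min_loop = 3L) {
  .cpp_dg_min(.iupac_ints(.iupac_chars(seq)), .CAN_PAIR_I, .IUPAC_SETS_I,
              params$dg_mat, as.integer(min_loop))
}

#' Enumerate candidate primers from a conserved region
#'
#' Slides a window of every length in `[len_min, len_max]` one base at a
#' time across the region. Forward candidates take the consensus window as
#' written; reverse candidates store the reverse complement (so their
#' sequence reads 5' to 3' on the opposite strand). Start/stop stay in
#' consensus coordinates. Duplicates by (sequence, start, orientation) are
#' removed.
#'
#' @param regions region tibble from [extract_conserved_regions()] (one or
#'   more rows; needs `region_id`, `start`, `seq`).
#' @param len_min,len_max primer length range (defaults 10 and 28).
#' @return tibble of candidates: `region_id`, `seq`, `start`, `stop`,
#'   `length`, `orientation`.
#' @export
enumerate_primers <- function(regions, len_min = 10L, len_max = 28L) {
  stopifnot(len_min <= len_max)
  rid <- list(); sq <- list(); st <- list(); ln <- list()
  for (i in seq_len(nrow(regions))) {
    L <- nchar(regions$seq[i])
    if (L < len_min) next
    for (len in seq(len_min, min(len_max, L))) {
      offs <- seq_len(L - len + 1L) - 1L
      k <- length(sq) + 1L
      rid[[k]] <- rep.int(regions$region_id[i], length(offs))
      sq[[k]] <- substring(regions$seq[i], offs + 1L, offs + len)
      st[[k]] <- regions$start[i] + offs
      ln[[k]] <- rep.int(as.integer(len), length(offs))
    }
  }
  if (length(sq) == 0L) {
    return(tibble::tibble(region_id = character(), seq = character(),
                          start = integer(), stop = integer(),
                          length = integer(), orientation = character()))
  }
  fwd_seq <- unlist(sq); w_start <- as.integer(unlist(st))
  w_len <- unlist(ln); w_stop <- w_start + w_len - 1L
  out <- tibble::tibble(
    region_id = rep(unlist(rid), 2L),
    seq = c(fwd_seq, vapply(fwd_seq, reverse_complement, "",
                            USE.NAMES = FALSE)),
    start = rep(w_start, 2L),
    stop = rep(w_stop, 2L),
    length = rep(w_len, 2L),
    orientation = rep(c("forward", "reverse"), each = length(fwd_seq))
  )
  dplyr::distinct(out, .data$seq, .data$start, .data$orientation,
                  .keep_all = TRUE)
}

#' Compute the full property block for candidate primers
#'
#' @param candidates candidate tibble from [enumerate_primers()] (rows from
#'   several regions may be combined).
#' @param params a [thermo_params()].
#' @return the candidates with property columns appended: `degeneracy`,
#'   `gc_percent`, `gc_clamp`, `tm_basic_min/mid/max`, `tm_salt_min/mid/max`,
#'   `tm_nn_min/mid/max`, `dg_3prime`, `dg_min`, `self_dimer_run`,
#'   `hairpin_run`.
#' @export
primer_properties <- function(candidates, params = thermo_params()) {
  if (nrow(candidates) == 0L) {
    props <- tibble::tibble(
      degeneracy = numeric(), gc_percent = numeric(), gc_clamp = integer(),
      tm_basic_min = numeric(), tm_basic_mid = numeric(), tm_basic_max = numeric(),
      tm_salt_min = numeric(), tm_salt_mid = numeric(), tm_salt_max = numeric(),
      tm_nn_min = numeric(), tm_nn_mid = numeric(), tm_nn_max = numeric(),
      dg_3prime = numeric(), dg_min = numeric(),
      self_dimer_run = integer(), hairpin_run = integer()
    )
    return(dplyr::bind_cols(candidates, props))
  }
  # each unique primer sequence is evaluated once, then joined back
  uniq <- unique(candidates$seq)
  props <- dplyr::bind_cols(.props_cheap(uniq, params),
                            .props_structural(uniq, params))
  dplyr::bind_cols(candidates, props[match(candidates$seq, uniq), ])
}

# composition/Tm properties: cheap, vectorised across candidates; the
# scalar tm_* functions define the model, these mirror them exactly
.props_cheap <- function(uniq, params) {
  n <- nchar(uniq)
  spl <- strsplit(toupper(uniq), "", fixed = TRUE)
  for (ch in spl) .check_iupac(ch)
  ex <- gc_extremes(uniq)
  count_gc <- function(s) nchar(s) - nchar(gsub("[GC]", "", s))
  gc_lo <- count_gc(ex$at); gc_hi <- count_gc(ex$gc)
  basic_v <- function(gc) {
    ifelse(n < 14, 2 * (n - gc) + 4 * gc, 64.9 + 41 * (gc - 16.4) / n)
  }
  salt_v <- function(gc) {
    ifelse(n < 14,
           basic_v(gc) - 16.6 * log10(0.05) + 16.6 * log10(params$na_conc),
           81.5 + 16.6 * log10(params$na_conc) + 0.41 * (100 * gc / n) -
             675 / n)
  }
  tb_lo <- basic_v(gc_lo); tb_hi <- basic_v(gc_hi)
  ts_lo <- salt_v(gc_lo); ts_hi <- salt_v(gc_hi)
  tn_lo <- .tm_nn_v(ex$at, params); tn_hi <- .tm_nn_v(ex$gc, params)
  tail5 <- substring(uniq, pmax(1L, n - 4L), n)
  tibble::tibble(
    degeneracy = vapply(spl, function(ch) prod(.IUPAC_SIZE[ch]), 1),
    gc_percent = vapply(spl, function(ch) 100 * mean(.IUPAC_GCP[ch]), 1),
    gc_clamp = nchar(tail5) - nchar(gsub("[GCS]", "", tail5)),
    tm_basic_min = pmin(tb_lo, tb_hi), tm_basic_mid = (tb_lo + tb_hi) / 2,
    tm_basic_max = pmax(tb_lo, tb_hi),
    tm_salt_min = pmin(ts_lo, ts_hi), tm_salt_mid = (ts_lo + ts_hi) / 2,
    tm_salt_max = pmax(ts_lo, ts_hi),
    tm_nn_min = pmin(tn_lo, tn_hi), tm_nn_mid = (tn_lo + tn_hi) / 2,
    tm_nn_max = pmax(tn_lo, tn_hi)
  )
}

# vectorised NN Tm for concrete sequences, grouped by length
.tm_nn_v <- function(seqs, params) {
  out <- numeric(length(seqs))
  n <- nchar(seqs)
  R <- 1.987
  denom_const <- R * log(params$primer_conc / 4)
  salt <- 16.6 * log10(params$na_conc)
  for (l in unique(n)) {
    idx <- which(n == l)
    M <- matrix(match(unlist(strsplit(seqs[idx], "", fixed = TRUE)),
                      c("A", "C", "G", "T")), nrow = l)
    dH <- numeric(length(idx)); dS <- numeric(length(idx))
    for (k in seq_len(l - 1L)) {
      st <- cbind(M[k, ], M[k + 1L, ])
      dH <- dH + params$dh_mat[st]
      dS <- dS + params$ds_mat[st]
    }
    for (end in c(1L, l)) {
      gc_end <- M[end, ] %in% c(2L, 3L)
      dH <- dH + ifelse(gc_end, params$nn$dh[["init_GC"]],
                        params$nn$dh[["init_AT"]])
      dS <- dS + ifelse(gc_end, params$nn$ds[["init_GC"]],
                        params$nn$ds[["init_AT"]])
    }
    out[idx] <- 1000 * dH / (dS + denom_const) - 273.15 + salt
  }
  out
}

# self-structure properties: the expensive scans
.props_structural <- function(uniq, params) {
  tibble::tibble(
    dg_3prime = vapply(uniq, dg_3prime, 1, params = params),
    dg_min = vapply(uniq, dg_min, 1, params = params),
    self_dimer_run = vapply(uniq, function(s) max_complementary_run(s, s), 1L),
    hairpin_run = vapply(uniq, hairpin_run, 1L)
  )
}
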