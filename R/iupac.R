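#' IUPAC nucleotide ambiguity codes
#'
#' Utilities for degenerate DNA sequences written in the IUPAC one-letter
#' ambiguity alphabet (R = A/G, Y = C/T, S = G/C, W = A/T, K = G/T, M = A/C,
#' B/D/H/V = the three-base sets, N = any base). A degenerate primer written
#' with these codes stands for the pool of all exact sequences obtained by
#' disambiguating each position independently.
#'
#' @name iupac
NULL

# disambiguation sets, in fixed A<C<G<T order
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# set signature (e.g. "AG") -> code, for consensus building
.IUPAC_FROM_SET <- local({
  keys <- vapply(.IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(.IUPAC_SETS), keys)
})

.IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", `-` = "-"
)

.iupac_chars <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

.check_iupac <- function(chars, allow_gap = FALSE) {
  ok <- names(.IUPAC_SETS)
  if (allow_gap) ok <- c(ok, "-")
  bad <- setdiff(unique(chars), ok)
  if (length(bad) > 0L) {
    stop("non-IUPAC character(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(chars)
}

#' Disambiguation set of a single IUPAC code
#' @param code single IUPAC character.
#' @return character vector of the concrete bases the code stands for.
#' @keywords internal
iupac_set <- function(code) {
  s <- .IUPAC_SETS[[toupper(code)]]
  if (is.null(s)) stop("non-IUPAC character: ", code, call. = FALSE)
  s
}

#' Minimal IUPAC code covering a set of bases
#' @param bases character vector drawn from A, C, G, T.
#' @return single IUPAC character whose disambiguation set equals `bases`.
#' @keywords internal
iupac_code_for <- function(bases) {
  key <- paste(sort(unique(toupper(bases))), collapse = "")
  code <- .IUPAC_FROM_SET[[key]]
  if (is.null(code)) stop("not a base set: ", key, call. = FALSE)
  code
}

#' Reverse complement of an IUPAC DNA string
#'
#' Degenerate codes map to their IUPAC complements (R to Y, S to S, W to W,
#' K to M, B to V, D to H, N to N); gaps are preserved. The operation is an
#' involution: `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param seq DNA string over the IUPAC alphabet, optionally with `-` gaps.
#' @return the reverse-complemented string, same length.
#' @examples
#' reverse_complement("ACGT")
#' reverse_complement("CVCCTTGYTGRTTDC")
#' @export
reverse_complement <- function(seq) {
  chars <- .check_iupac(.iupac_chars(seq), allow_gap = TRUE)
  if (length(chars) == 0L) return("")
  paste(rev(unname(.IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Degeneracy of a degenerate primer
#'
#' The number of distinct exact sequences the written sequence encodes:
#' the product over positions of the size of each code's disambiguation set.
#'
#' @param seq IUPAC DNA string (no gaps).
#' @return positive integer (may be large; returned as double).
#' @examples
#' degeneracy("ACGT")             # 1
#' degeneracy("ACHGARGGYGARATHG") # 72
#' @export
degeneracy <- function(seq) {
  chars <- .check_iupac(.iupac_chars(seq))
  if (length(chars) == 0L) return(1)
  prod(.IUPAC_SIZE[chars])
}

#' Expected GC content of a degenerate primer
#'
#' Each position contributes the probability that a uniformly chosen
#' disambiguation is G or C (S contributes 1, R contributes 0.5, N 0.5, ...);
#' the mean over positions is returned as a percentage.
#'
#' @param seq IUPAC DNA string (no gaps).
#' @return percentage in `[0, 100]`.
#' @examples
#' gc_content("ACGT") # 50
#' gc_content("ACRT") # 37.5
#' @export
gc_content <- function(seq) {
  chars <- .check_iupac(.iupac_chars(seq))
  if (length(chars) == 0L) return(NA_real_)
  100 * mean(.IUPAC_GCP[chars])
}

#' GC clamp of a primer
#'
#' Counts, among the five 3'-terminal bases, the positions whose code
#' guarantees a G or C in every disambiguation (codes G, C and S). Screens
#' conventionally require no more than three.
#'
#' @param seq IUPAC primer string, 5' to 3'.
#' @return integer in `[0, 5]` (fewer if the primer is shorter than 5).
#' @export
gc_clamp <- function(seq) {
  chars <- .check_iupac(.iupac_chars(seq))
  tail3 <- utils::tail(chars, 5L)
  sum(tail3 %in% c("G", "C", "S"))
}

# TRUE iff some disambiguation of x Watson-Crick pairs some disambiguation of y
.CAN_PAIR <- local({
  codes <- names(.IUPAC_SETS)
  m <- matrix(FALSE, length(codes), length(codes), dimnames = list(codes, codes))
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  for (x in codes) for (y in codes) {
    m[x, y] <- any(wc[.IUPAC_SETS[[x]]] %in% .IUPAC_SETS[[y]])
  }
  m
})

# integer-coded views for the inner screening loops: codes indexed in
# names(.IUPAC_SETS) order, bases as 1..4 = A,C,G,T
.IUPAC_CODES <- names(.IUPAC_SETS)
.IUPAC_SIZE <- vapply(.IUPAC_SETS, length, 1)
.IUPAC_GCP <- vapply(.IUPAC_SETS, function(s) sum(s %in% c("G", "C")) / length(s), 1)
.CAN_PAIR_I <- unname(.CAN_PAIR)
.IUPAC_SETS_I <- lapply(.IUPAC_SETS, function(s) match(s, c("A", "C", "G", "T")))

.iupac_ints <- function(chars) {
  ix <- match(chars, .IUPAC_CODES)
  if (anyNA(ix)) {
    stop("non-IUPAC character(s): ",
         paste(unique(chars[is.na(ix)]), collapse = ", "), call. = FALSE)
  }
  ix
}

#' Can two IUPAC codes base-pair?
#'
#' TRUE when some disambiguation of `x` is the Watson-Crick complement of some
#' disambiguation of `y` ("can-pair" semantics, the conservative reading used
#' in dimer and hairpin screening of degenerate primers).
#'
#' @param x,y single IUPAC characters (vectorised).
#' @return logical vector.
#' @keywords internal
can_pair <- function(x, y) {
  .CAN_PAIR[cbind(toupper(x), toupper(y))]
}

#' IUPAC-aware sequence match
#'
#' Compares a degenerate primer to a concrete target site position by
#' position; a position matches when the target base is in the primer code's
#' disambiguation set.
#'
#' @param primer IUPAC string.
#' @param site concrete A/C/G/T string of the same length.
#' @return number of mismatching positions.
#' @keywords internal
iupac_mismatches <- function(primer, site) {
  p <- .iupac_chars(primer)
  s <- .iupac_chars(site)
  if (length(p) != length(s)) {
    stop("primer and site lengths differ (", length(p), " vs ", length(s), ")",
         call. = FALSE)
  }
  sum(!mapply(function(pc, sc) sc %in% .IUPAC_SETS[[pc]], p, s))
}

# GC-extreme disambiguations: the weakest (A/T-preferring, preference order
# A > T > C > G) and strongest (G/C-preferring, G > C > A > T) concrete
# sequences bounding a degenerate primer's Tm
.AT_EXTREME <- local({
  from <- "RYSWKMBDHVN"
  to <- paste(vapply(strsplit(from, "")[[1]], function(c) {
    p <- c("A", "T", "C", "G")
    p[p %in% .IUPAC_SETS[[c]]][1]
  }, ""), collapse = "")
  c(from = from, to = to)
})
.GC_EXTREME <- local({
  from <- "RYSWKMBDHVN"
  to <- paste(vapply(strsplit(from, "")[[1]], function(c) {
    p <- c("G", "C", "A", "T")
    p[p %in% .IUPAC_SETS[[c]]][1]
  }, ""), collapse = "")
  c(from = from, to = to)
})

#' Weakest and strongest disambiguations of a degenerate sequence
#' @param seq IUPAC string (vectorised).
#' @return list with `at` (A/T-preferring) and `gc` (G/C-preferring) concrete strings.
#' @keywords internal
gc_extremes <- function(seq) {
  list(
    at = chartr(.AT_EXTREME[["from"]], .AT_EXTREME[["to"]], toupper(seq)),
    gc = chartr(.GC_EXTREME[["from"]], .GC_EXTREME[["to"]], toupper(seq))
  )
}

#' All concrete disambiguations of a degenerate sequence
#'
#' Enumerates the full pool. Intended for short fragments (the 3'-terminal
#' five bases, dimer runs); the pool size is the sequence degeneracy.
#'
#' @param seq IUPAC string.
#' @param max_n guard against combinatorial explosion.
#' @return character vector of concrete sequences.
#' @keywords internal
disambiguations <- function(seq, max_n = 4096L) {
  chars <- .check_iupac(.iupac_chars(seq))
  if (length(chars) == 0L) return("")
  if (degeneracy(seq) > max_n) {
    stop("degeneracy exceeds ", max_n, "; refusing to enumerate", call. = FALSE)
  }
  sets <- lapply(chars, function(c) .IUPAC_SETS[[c]])
  do.call(paste0, rev(expand.grid(rev(sets), stringsAsFactors = FALSE)))
}
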