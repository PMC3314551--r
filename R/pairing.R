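#' Primer screening, pairing and in-silico recovery
#'
#' Candidates that survive the physicochemical screens are assembled into
#' forward/reverse pairs conforming to the product-size and cross-dimer
#' constraints, ranked by the difference in melting temperature between the
#' two primers (smallest first). Because primers are drawn from a consensus
#' built at a 100% identity threshold, every emitted pair is guaranteed to
#' match every gene in the alignment exactly; `in_silico_recovery()` verifies
#' that guarantee member by member.
#'
#' @name primer_pairing
NULL

#' Primer design parameters
#'
#' Ranges and thresholds for screening and pairing. Defaults: primer length
#' 10-28 nt, product size 50-4000 bp, degeneracy at most 512, GC content
#' unrestricted, GC clamp 0-3 (no more than three guaranteed G/C among the
#' five 3'-terminal bases), 3' end ΔG floor -9 kcal/mol, dimer/hairpin runs
#' shorter than 5 consecutive pairings, no ΔTm cap (pairs are ranked by ΔTm
#' instead), Tm ranges unrestricted, Tm method for pairing =
#' nearest-neighbor midpoint.
#'
#' @param len_min,len_max primer length range (nt).
#' @param product_min,product_max product size range (bp, on the consensus).
#' @param degeneracy_min,degeneracy_max allowed primer degeneracy.
#' @param gc_min,gc_max allowed GC percentage.
#' @param clamp_min,clamp_max allowed GC clamp count.
#' @param tm_min,tm_max allowed Tm range (deg C) for the chosen method
#'   (`NULL` = unrestricted).
#' @param tm_method which Tm triplet drives screening and ΔTm ranking:
#'   `"nn"`, `"salt"` or `"basic"` (midpoint used).
#' @param dg3_floor minimum (least negative allowed is no bound; primers
#'   with 3' ΔG below this are dropped) in kcal/mol.
#' @param max_run maximum allowed consecutive base pairings in self-dimer,
#'   cross-dimer and hairpin checks (default 4, i.e. fewer than five).
#' @param delta_tm_max optional cap on the pair's ΔTm (deg C).
#' @param thermo a [thermo_params()].
#' @return list of class `design_params`.
#' @export
design_params <- function(len_min = 10L, len_max = 28L,
                          product_min = 50L, product_max = 4000L,
                          degeneracy_min = 1, degeneracy_max = 512,
                          gc_min = 0, gc_max = 100,
                          clamp_min = 0L, clamp_max = 3L,
                          tm_min = NULL, tm_max = NULL,
                          tm_method = c("nn", "salt", "basic"),
                          dg3_floor = -9,
                          max_run = 4L,
                          delta_tm_max = Inf,
                          thermo = thermo_params()) {
  tm_method <- match.arg(tm_method)
  p <- list(len_min = len_min, len_max = len_max,
            product_min = product_min, product_max = product_max,
            degeneracy_min = degeneracy_min, degeneracy_max = degeneracy_max,
            gc_min = gc_min, gc_max = gc_max,
            clamp_min = clamp_min, clamp_max = clamp_max,
            tm_min = tm_min, tm_max = tm_max, tm_method = tm_method,
            dg3_floor = dg3_floor, max_run = max_run,
            delta_tm_max = delta_tm_max, thermo = thermo)
  for (nm in c("len", "product", "degeneracy", "gc", "clamp")) {
    if (p[[paste0(nm, "_min")]] > p[[paste0(nm, "_max")]]) {
      stop(nm, "_min exceeds ", nm, "_max", call. = FALSE)
    }
  }
  structure(p, class = "design_params")
}

.tm_mid_col <- function(params) paste0("tm_", params$tm_method, "_mid")

#' Screen candidate primers against the design parameters
#'
#' Applies every range/threshold screen to candidates whose properties have
#' been computed with [primer_properties()]. The screens are pure functions
#' of the property block, so screening twice is a no-op. Per-screen
#' attrition counts are attached as the `"attrition"` attribute.
#'
#' @param candidates candidates-with-properties tibble.
#' @param params a [design_params()].
#' @return the surviving rows, with attrition counts in
#'   `attr(, "attrition")`.
#' @export
screen_candidates <- function(candidates, params = design_params()) {
  screens <- c(
    .cheap_screens(candidates, params),
    list(
      dg_3prime = candidates$dg_3prime >= params$dg3_floor,
      self_dimer = candidates$self_dimer_run <= params$max_run,
      hairpin = candidates$hairpin_run <= params$max_run
    )
  )
  keep <- Reduce(`&`, screens)
  attrition <- vapply(screens, function(ok) sum(!ok), 1L)
  out <- candidates[keep, , drop = FALSE]
  attr(out, "attrition") <- attrition
  out
}

# the screens that only need composition/Tm properties
.cheap_screens <- function(candidates, params) {
  tmcol <- .tm_mid_col(params)
  list(
    length = candidates$length >= params$len_min &
      candidates$length <= params$len_max,
    degeneracy = candidates$degeneracy >= params$degeneracy_min &
      candidates$degeneracy <= params$degeneracy_max,
    gc_content = candidates$gc_percent >= params$gc_min &
      candidates$gc_percent <= params$gc_max,
    gc_clamp = candidates$gc_clamp >= params$clamp_min &
      candidates$gc_clamp <= params$clamp_max,
    tm = if (is.null(params$tm_min) && is.null(params$tm_max)) {
      rep(TRUE, nrow(candidates))
    } else {
      candidates[[tmcol]] >= (params$tm_min %||% -Inf) &
        candidates[[tmcol]] <= (params$tm_max %||% Inf)
    }
  )
}

.screen_cheap <- function(candidates, params) {
  screens <- .cheap_screens(candidates, params)
  list(keep = Reduce(`&`, screens),
       attrition = vapply(screens, function(ok) sum(!ok), 1L))
}

#' Pair forward and reverse primers
#'
#' Forms every (forward, reverse) combination with the forward upstream of
#' the reverse on the consensus, product size (inclusive of both primers)
#' within range, cross-dimer run within the allowed maximum, and both 3'
#' ends above the ΔG floor. Pairs are ranked by |Tm(forward) - Tm(reverse)|
#' ascending (using the configured Tm method's midpoint), ties broken by
#' the smaller product of degeneracies, then by coordinates.
#'
#' The candidate combination space can be very large for highly conserved
#' consensi, so the coordinate, product-size and ΔTm constraints are applied
#' on plain vectors first, the survivors are put in rank order, and the
#' cross-dimer scan (the only per-pair sequence computation) runs in that
#' order, stopping once `max_pairs` qualifying pairs have been emitted.
#' Because the cross-dimer screen only removes pairs, the emitted list is
#' identical to screening everything and then truncating.
#'
#' @param forwards,reverses screened candidate tibbles (orientation
#'   `"forward"` / `"reverse"` respectively) with properties.
#' @param params a [design_params()].
#' @param max_pairs emit at most this many ranked pairs (`Inf` = all).
#' @return tibble of pairs: forward/reverse columns prefixed `fwd_`/`rev_`,
#'   plus `product_size`, `delta_tm`, `cross_dimer_run`, `rank`. The number
#'   of coordinate/product/ΔTm-feasible combinations (before the
#'   cross-dimer screen and truncation) is in `attr(, "n_feasible")`.
#' @export
pair_primers <- function(forwards, reverses, params = design_params(),
                         max_pairs = Inf) {
  empty <- tibble::tibble(rank = integer(), fwd_seq = character(),
                          rev_seq = character(), fwd_start = integer(),
                          fwd_stop = integer(), rev_start = integer(),
                          rev_stop = integer(), product_size = integer(),
                          delta_tm = numeric(), cross_dimer_run = integer())
  attr(empty, "n_feasible") <- 0L
  if (nrow(forwards) == 0L || nrow(reverses) == 0L) return(empty)
  tmcol <- .tm_mid_col(params)
  nf <- nrow(forwards); nr <- nrow(reverses)
  f_ok <- forwards$dg_3prime >= params$dg3_floor
  r_ok <- reverses$dg_3prime >= params$dg3_floor

  # cheap feasibility pass over the full grid, chunked by forward primer
  r_idx_all <- which(r_ok)
  f_idx_all <- which(f_ok)
  acc_f <- vector("list", length(f_idx_all))
  acc_r <- vector("list", length(f_idx_all))
  for (a in seq_along(f_idx_all)) {
    fi <- f_idx_all[a]
    prod <- reverses$stop[r_idx_all] - forwards$start[fi] + 1L
    ok <- forwards$start[fi] < reverses$start[r_idx_all] &
      prod >= params$product_min & prod <= params$product_max
    if (is.finite(params$delta_tm_max)) {
      ok <- ok & abs(forwards[[tmcol]][fi] -
                       reverses[[tmcol]][r_idx_all]) <= params$delta_tm_max
    }
    ri <- r_idx_all[ok]
    acc_f[[a]] <- rep.int(fi, length(ri))
    acc_r[[a]] <- ri
  }
  keep_f <- unlist(acc_f); keep_r <- unlist(acc_r)
  n_feasible <- length(keep_f)
  if (n_feasible == 0L) return(empty)

  delta_tm <- abs(forwards[[tmcol]][keep_f] - reverses[[tmcol]][keep_r])
  deg_pool <- forwards$degeneracy[keep_f] * reverses$degeneracy[keep_r]
  ord <- order(delta_tm, deg_pool, forwards$start[keep_f],
               reverses$start[keep_r], forwards$stop[keep_f],
               reverses$stop[keep_r])

  # expensive cross-dimer screen, lazily in rank order
  n_cap <- if (is.finite(max_pairs)) as.integer(max_pairs) else length(ord)
  sel <- integer(n_cap); cross <- integer(n_cap); n_sel <- 0L
  for (k in ord) {
    run <- max_complementary_run(forwards$seq[keep_f[k]],
                                 reverses$seq[keep_r[k]])
    if (run <= params$max_run) {
      n_sel <- n_sel + 1L
      sel[n_sel] <- k
      cross[n_sel] <- run
      if (n_sel >= max_pairs) break
    }
  }
  if (n_sel == 0L) return(empty)
  sel <- sel[seq_len(n_sel)]; cross <- cross[seq_len(n_sel)]

  fwd <- dplyr::rename_with(forwards[keep_f[sel], ], ~ paste0("fwd_", .x))
  rev <- dplyr::rename_with(reverses[keep_r[sel], ], ~ paste0("rev_", .x))
  pairs <- dplyr::bind_cols(fwd, rev)
  pairs$product_size <- pairs$rev_stop - pairs$fwd_start + 1L
  pairs$delta_tm <- delta_tm[sel]
  pairs$cross_dimer_run <- cross
  pairs$rank <- seq_len(nrow(pairs))
  pairs <- dplyr::relocate(pairs, "rank")
  attr(pairs, "n_feasible") <- n_feasible
  pairs
}

#' Verify in-silico recovery of every group member
#'
#' For each member of the alignment, matches the forward primer against the
#' member's actual bases under the forward site columns and the reverse
#' primer against the reverse strand of the member's bases under the
#' reverse site columns (IUPAC-aware: a degenerate code matches any base in
#' its disambiguation set), and reports mismatch counts and the
#' member-specific amplicon length (which can differ from the consensus
#' product size by member indels). Pairs designed from a 100% identity
#' consensus must recover every member with zero mismatches.
#'
#' @param pair one-row tibble from [pair_primers()].
#' @param alignment the `codon_alignment` the design was run on.
#' @return tibble: `member_id`, `fwd_mismatches`, `rev_mismatches`,
#'   `amplicon_length`, `gap_in_site`.
#' @export
in_silico_recovery <- function(pair, alignment) {
  stopifnot(nrow(pair) == 1L)
  out <- lapply(alignment$member_ids, function(id) {
    row <- alignment$rows[[id]]
    fsite <- substring(row, pair$fwd_start, pair$fwd_stop)
    rsite <- substring(row, pair$rev_start, pair$rev_stop)
    gap <- grepl("-", fsite, fixed = TRUE) || grepl("-", rsite, fixed = TRUE)
    if (gap) {
      return(tibble::tibble(member_id = id, fwd_mismatches = NA_integer_,
                            rev_mismatches = NA_integer_,
                            amplicon_length = NA_integer_,
                            gap_in_site = TRUE))
    }
    span <- substring(row, pair$fwd_start, pair$rev_stop)
    tibble::tibble(
      member_id = id,
      fwd_mismatches = iupac_mismatches(pair$fwd_seq, fsite),
      rev_mismatches = iupac_mismatches(pair$rev_seq,
                                        reverse_complement(rsite)),
      amplicon_length = nchar(gsub("-", "", span, fixed = TRUE)),
      gap_in_site = FALSE
    )
  })
  dplyr::bind_rows(out)
}
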