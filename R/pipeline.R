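#' End-to-end primer design for a signature gene group
#'
#' Runs the full design chain on one group: codon-aware alignment (or a
#' user-supplied alignment), IUPAC consensus at 100% identity, conserved
#' region extraction, sliding-window primer enumeration, physicochemical
#' property computation, screening, Tm-matched pairing, and an in-silico
#' recovery check of every emitted pair against every member.
#'
#' @param genes gene tibble rows for the group members (>= 2), or `NULL`
#'   when `alignment` is given.
#' @param params a [design_params()].
#' @param alignment optional precomputed `codon_alignment` (e.g. from
#'   [load_user_alignment()]); skips the aligner.
#' @param top_k keep the best `top_k` pairs after ranking (default 100);
#'   `Inf` keeps all. Total counts are always recorded.
#' @param verify run [in_silico_recovery()] on every kept pair and attach
#'   the worst per-pair mismatch count (default TRUE).
#' @return object of class `primer_design`: list with `alignment`,
#'   `consensus`, `regions`, `candidates` (screened, with properties),
#'   `pairs` (ranked tibble, `max_mismatches` column when verified),
#'   `n_pairs_total` (coordinate/product/ΔTm-feasible combinations before
#'   the cross-dimer screen and truncation), `attrition`, `params`.
#' @export
design_primers <- function(genes = NULL, params = design_params(),
                           alignment = NULL, top_k = 100L, verify = TRUE) {
  if (is.null(alignment)) {
    if (is.null(genes) || nrow(genes) < 2L) {
      stop("primer design needs an alignment or at least 2 genes",
           call. = FALSE)
    }
    alignment <- align_group(genes)
  }
  cons <- iupac_consensus(alignment)
  regions <- extract_conserved_regions(cons)
  # clipped regions shorter than the minimum primer length are useless
  regions <- regions[regions$length >= params$len_min, , drop = FALSE]

  candidates <- enumerate_primers(regions, params$len_min, params$len_max)
  if (nrow(regions) == 0L || nrow(candidates) == 0L) {
    return(new_primer_design(alignment, cons, regions,
                             candidates = tibble::tibble(),
                             pairs = tibble::tibble(), n_pairs_total = 0L,
                             attrition = integer(), params = params))
  }
  # each unique primer sequence is tested once
  candidates <- dplyr::distinct(candidates, .data$seq, .data$start,
                                .data$orientation, .keep_all = TRUE)
  # composition/Tm screens are cheap, so they run first and the structural
  # scans (dimer/hairpin/ΔG) only touch the survivors; screen_candidates on
  # the full block afterwards is idempotent, and the attrition counts of
  # the pre-screen carry over
  uniq <- unique(candidates$seq)
  cheap <- .props_cheap(uniq, params$thermo)
  candidates <- dplyr::bind_cols(candidates,
                                 cheap[match(candidates$seq, uniq), ])
  pre <- .screen_cheap(candidates, params)
  candidates <- candidates[pre$keep, , drop = FALSE]
  uniq2 <- unique(candidates$seq)
  str_props <- .props_structural(uniq2, params$thermo)
  candidates <- dplyr::bind_cols(candidates,
                                 str_props[match(candidates$seq, uniq2), ])
  screened <- screen_candidates(candidates, params)
  attrition <- attr(screened, "attrition")
  attrition[names(pre$attrition)] <- attrition[names(pre$attrition)] +
    pre$attrition

  pairs <- pair_primers(screened[screened$orientation == "forward", ],
                        screened[screened$orientation == "reverse", ],
                        params, max_pairs = top_k)
  n_total <- attr(pairs, "n_feasible")
  if (verify && n_total > 0L) {
    pairs$max_mismatches <- vapply(seq_len(nrow(pairs)), function(i) {
      rec <- in_silico_recovery(pairs[i, ], alignment)
      if (any(rec$gap_in_site)) return(NA_integer_)
      max(rec$fwd_mismatches + rec$rev_mismatches)
    }, 1L)
  }
  new_primer_design(alignment, cons, regions, screened, pairs,
                    n_pairs_total = n_total, attrition = attrition,
                    params = params)
}

new_primer_design <- function(alignment, consensus, regions, candidates,
                              pairs, n_pairs_total, attrition, params) {
  structure(
    list(alignment = alignment, consensus = consensus, regions = regions,
         candidates = candidates, pairs = pairs,
         n_pairs_total = n_pairs_total, attrition = attrition,
         params = params),
    class = "primer_design"
  )
}

#' @export
print.primer_design <- function(x, ...) {
  cat("<primer_design>\n",
      "  members:        ", length(x$alignment$member_ids), "\n",
      "  consensus:      ", nchar(x$consensus$consensus), " columns, ",
      sum(x$consensus$conserved), " conserved\n",
      "  regions:        ", nrow(x$regions), "\n",
      "  candidates:     ", nrow(x$candidates), " (post-screen)\n",
      "  pairs:          ", x$n_pairs_total, " total, ",
      nrow(x$pairs), " kept\n", sep = "")
  invisible(x)
}

#' Tidy a primer design into its ranked pair table
#' @param x a `primer_design`.
#' @param ... unused.
#' @return the ranked pair tibble.
#' @export
tidy.primer_design <- function(x, ...) tibble::as_tibble(x$pairs)

#' One-row summary of a primer design
#' @param x a `primer_design`.
#' @param ... unused.
#' @return tibble with member, consensus, region, candidate and pair counts.
#' @export
glance.primer_design <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$alignment$member_ids),
    alignment_length = nchar(x$consensus$consensus),
    n_conserved_columns = sum(x$consensus$conserved),
    n_regions = nrow(x$regions),
    n_candidates = nrow(x$candidates),
    n_pairs = x$n_pairs_total,
    best_delta_tm = if (nrow(x$pairs) > 0) min(x$pairs$delta_tm) else NA_real_
  )
}

#' Plot a primer design
#'
#' Scatter of candidate pairs: consensus product size against the pair's
#' Tm difference, coloured by combined degeneracy.
#'
#' @param object a `primer_design`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.primer_design <- function(object, ...) {
  stopifnot(nrow(object$pairs) > 0)
  df <- dplyr::mutate(object$pairs,
                      pool_size = .data$fwd_degeneracy * .data$rev_degeneracy)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$product_size,
                                   y = .data$delta_tm,
                                   colour = .data$pool_size)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(trans = "log2",
                                    name = "pool size\n(fwd x rev degeneracy)") +
    ggplot2::labs(x = "product size on consensus (bp)",
                  y = expression(Delta * T[m] ~ ("°C")),
                  title = "Candidate primer pairs") +
    ggplot2::theme_minimal()
}

# ---- report writers ----

#' Write the signature gene group report and per-group FASTA files
#'
#' The group table mirrors the downloadable signature gene list: one row per
#' group with its genome span, member count, member ids and pooled
#' annotations. Per-group nucleotide and protein multi-FASTA files are
#' written alongside.
#'
#' @param groups group tibble from [build_groups()].
#' @param genes gene tibble.
#' @param out_dir output directory.
#' @return paths written, invisibly.
#' @export
write_group_report <- function(groups, genes, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- dplyr::mutate(groups,
                          members = vapply(.data$members, paste,
                                           "", collapse = ","))
  tsv <- file.path(out_dir, "signature_groups.tsv")
  readr::write_tsv(report, tsv, progress = FALSE)
  paths <- tsv
  for (i in seq_len(nrow(groups))) {
    members <- groups$members[[i]]
    sub <- genes[match(members, genes$gene_id), ]
    base <- file.path(out_dir, groups$group_id[i])
    write_fasta(stats::setNames(sub$nt_seq, sub$gene_id),
                paste0(base, "_nt.fasta"))
    write_fasta(stats::setNames(sub$aa_seq, sub$gene_id),
                paste0(base, "_aa.fasta"))
    paths <- c(paths, paste0(base, "_nt.fasta"), paste0(base, "_aa.fasta"))
  }
  invisible(paths)
}

#' Write the primer design reports
#'
#' Writes the alignment (aligned FASTA + CLUSTAL), the consensus, the
#' conserved region list and the ranked primer pair report as tab-delimited
#' files.
#'
#' @param design a `primer_design`.
#' @param out_dir output directory.
#' @param prefix file name prefix (e.g. the group id).
#' @return paths written, invisibly.
#' @export
write_design_report <- function(design, out_dir, prefix = "group") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, prefix)
  write_alignment(design$alignment,
                  fasta_path = paste0(base, "_alignment.fasta"),
                  clustal_path = paste0(base, "_alignment.aln"))
  write_fasta(stats::setNames(design$consensus$consensus,
                              paste0(prefix, "_consensus")),
              paste0(base, "_consensus.fasta"))
  readr::write_tsv(design$regions, paste0(base, "_regions.tsv"),
                   progress = FALSE)
  readr::write_tsv(design$pairs, paste0(base, "_primer_pairs.tsv"),
                   progress = FALSE)
  invisible(paste0(base, c("_alignment.fasta", "_alignment.aln",
                           "_consensus.fasta", "_regions.tsv",
                           "_primer_pairs.tsv")))
}

#' Identify signature genes across genome files and write reports
#'
#' Command-level wrapper: reads the genomes, runs the all-vs-all search and
#' grouping, and writes the group table and per-group FASTA files.
#'
#' @param genome_paths directory or vector of GenBank files.
#' @param out_dir output directory.
#' @param evalue_cut,coverage_cut filtering thresholds.
#' @param engine search engine.
#' @return the group tibble, invisibly; reports land in `out_dir`.
#' @export
cmd_identify <- function(genome_paths, out_dir, evalue_cut = 1e-3,
                         coverage_cut = 10,
                         engine = c("external", "internal")) {
  set <- read_genome_set(genome_paths)
  if (nrow(set$genomes) < 2L) {
    stop("signature gene identification needs at least 2 genomes",
         call. = FALSE)
  }
  groups <- identify_signature_genes(set$genes, evalue_cut, coverage_cut,
                                     engine = match.arg(engine))
  write_group_report(groups, set$genes, out_dir)
  invisible(groups)
}

#' Design primers for one signature gene group and write reports
#'
#' @param genome_paths directory or vector of GenBank files.
#' @param group_id group to design on (from [cmd_identify()]'s table), or
#'   `NULL` with `alignment_path` given.
#' @param out_dir output directory.
#' @param params a [design_params()].
#' @param alignment_path optional user-supplied alignment file.
#' @param evalue_cut,coverage_cut,engine grouping settings used to re-derive
#'   the group when `group_id` is given.
#' @param top_k pairs kept after ranking.
#' @return the `primer_design`, invisibly; reports land in `out_dir`.
#' @export
cmd_design <- function(genome_paths, group_id = NULL, out_dir,
                       params = design_params(), alignment_path = NULL,
                       evalue_cut = 1e-3, coverage_cut = 10,
                       engine = c("external", "internal"), top_k = 100L) {
  if (is.null(group_id) && is.null(alignment_path)) {
    stop("give either a group_id or an alignment_path", call. = FALSE)
  }
  if (!is.null(alignment_path)) {
    aln <- load_user_alignment(alignment_path)
    design <- design_primers(params = params, alignment = aln, top_k = top_k)
    prefix <- sub("\\.[^.]*$", "", basename(alignment_path))
  } else {
    set <- read_genome_set(genome_paths)
    groups <- identify_signature_genes(set$genes, evalue_cut, coverage_cut,
                                       engine = match.arg(engine))
    row <- groups[groups$group_id == group_id, ]
    if (nrow(row) == 0L) stop("no such group: ", group_id, call. = FALSE)
    members <- set$genes[match(row$members[[1]], set$genes$gene_id), ]
    if (nrow(members) < 2L) {
      stop("group ", group_id, " has fewer than 2 members", call. = FALSE)
    }
    design <- design_primers(members, params = params, top_k = top_k)
    prefix <- group_id
  }
  if (nrow(design$pairs) == 0L) {
    message("no primer pairs satisfy the constraints for ", prefix,
            "; empty report written")
  }
  write_design_report(design, out_dir, prefix = prefix)
  invisible(design)
}
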