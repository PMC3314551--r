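#' All-vs-all protein comparison and signature gene grouping
#'
#' Signature genes are homologous genes conserved among a chosen set of phage
#' genomes. They are found by an all-against-all protein similarity search
#' over the selected genomes, filtering hits on E-value and alignment
#' coverage, keeping each protein's best hit per subject genome, and taking
#' connected components of the resulting hit graph.
#'
#' @name homology
NULL

#' Compute all-vs-all pairwise protein hits
#'
#' Runs a local-alignment similarity search between every pair of proteins
#' from different records in `genes`. The external engine shells out to
#' `blastp` (all-vs-all, tabular output, E-value cut-off 10); the internal
#' engine is a Smith-Waterman search (BLOSUM62, gap open 11 / extend 1) with
#' Karlin-Altschul E-values using the gapped constants lambda = 0.267,
#' K = 0.041 and search space qlen x slen, so E-value cut-offs transfer
#' between engines. Self-hits (query == subject) are excluded; hits between
#' genes of the same genome are retained (paralogs are resolved at the
#' grouping stage).
#'
#' @param genes gene tibble with `gene_id`, `genome_id`, `aa_seq`.
#' @param engine `"external"` (blastp subprocess) or `"internal"`.
#' @param evalue_max report threshold (default 10, the precalculation
#'   cut-off; filtering to the working threshold happens in
#'   [select_best_hits()]).
#' @return tibble of hits: `query_id`, `subject_id`, `evalue`, `bitscore`,
#'   `aln_len`, `qlen`, `slen`.
#' @export
compute_pairwise_hits <- function(genes, engine = c("external", "internal"),
                                  evalue_max = 10) {
  engine <- match.arg(engine)
  stopifnot(nrow(genes) >= 2L)
  if (length(unique(genes$genome_id)) < 2L) {
    stop("need genes from at least 2 genomes", call. = FALSE)
  }
  hits <- switch(engine,
    external = blastp_all_vs_all(genes, evalue_max),
    internal = sw_all_vs_all(genes, evalue_max)
  )
  hits <- hits[hits$query_id != hits$subject_id & hits$evalue <= evalue_max, ]
  dplyr::arrange(hits, .data$query_id, .data$subject_id, .data$evalue)
}

blastp_all_vs_all <- function(genes, evalue_max) {
  for (tool in c("makeblastdb", "blastp")) {
    if (Sys.which(tool) == "") {
      stop("external search engine not found: `", tool,
           "` must be on PATH (or use engine = \"internal\")", call. = FALSE)
    }
  }
  tmp <- tempfile("blast")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  faa <- file.path(tmp, "prot.faa")
  write_fasta(stats::setNames(genes$aa_seq, genes$gene_id), faa)
  db <- file.path(tmp, "db")
  out <- file.path(tmp, "hits.tsv")
  res <- system2("makeblastdb",
                 c("-in", faa, "-dbtype", "prot", "-out", db),
                 stdout = FALSE, stderr = FALSE)
  if (res != 0) stop("makeblastdb failed", call. = FALSE)
  res <- system2("blastp",
                 c("-query", faa, "-db", db, "-evalue", format(evalue_max),
                   "-outfmt",
                   shQuote("6 qseqid sseqid pident length mismatch gapopen qstart qend sstart send evalue bitscore qlen slen"),
                   "-out", out),
                 stdout = FALSE, stderr = FALSE)
  if (res != 0) stop("blastp failed", call. = FALSE)
  hits <- read_blast_tab(out, genes)
  # keep only each query/subject pair's best HSP
  hits |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore)) |>
    dplyr::distinct(.data$query_id, .data$subject_id, .keep_all = TRUE)
}

#' Read BLAST tabular output
#'
#' Parses the standard 12-column tabular format (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`), plus `qlen` and
#' `slen` columns when present; when absent, protein lengths are looked up in
#' `genes`.
#'
#' @param path tabular output file.
#' @param genes optional gene tibble supplying protein lengths.
#' @return hit tibble as in [compute_pairwise_hits()].
#' @export
read_blast_tab <- function(path, genes = NULL) {
  cols12 <- c("query_id", "subject_id", "pident", "aln_len", "mismatch",
              "gapopen", "qstart", "qend", "sstart", "send", "evalue",
              "bitscore")
  if (file.size(path) == 0L) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          evalue = numeric(), bitscore = numeric(),
                          aln_len = integer(), qlen = integer(),
                          slen = integer()))
  }
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c(cols12, "qlen", "slen")[
                             seq_len(max(utils::count.fields(path, sep = "\t"),
                                         12L))],
                           fill = TRUE)
  tab <- tibble::as_tibble(raw)
  if (!"qlen" %in% names(tab) || anyNA(tab$qlen)) {
    if (is.null(genes)) {
      stop("BLAST table lacks qlen/slen columns and no gene records given",
           call. = FALSE)
    }
    len <- stats::setNames(nchar(genes$aa_seq), genes$gene_id)
    tab$qlen <- unname(len[tab$query_id])
    tab$slen <- unname(len[tab$subject_id])
  }
  tab[, c("query_id", "subject_id", "evalue", "bitscore", "aln_len",
          "qlen", "slen")]
}

# Smith-Waterman fallback with Karlin-Altschul statistics
sw_all_vs_all <- function(genes, evalue_max,
                          lambda = 0.267, K = 0.041) {
  n <- nrow(genes)
  aa <- Biostrings::AAStringSet(stats::setNames(genes$aa_seq, genes$gene_id))
  lens <- nchar(genes$aa_seq)
  out <- list()
  mat <- "BLOSUM62"
  for (i in seq_len(n)) {
    js <- setdiff(seq_len(n), i)
    if (length(js) == 0L) next
    aln <- Biostrings::pairwiseAlignment(
      aa[js], aa[[i]], type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1
    )
    score <- Biostrings::score(aln)
    alen <- Biostrings::nchar(aln)
    ev <- K * lens[i] * lens[js] * exp(-lambda * score)
    bits <- (lambda * score - log(K)) / log(2)
    keep <- ev <= evalue_max
    if (any(keep)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        query_id = genes$gene_id[i],
        subject_id = genes$gene_id[js][keep],
        evalue = ev[keep], bitscore = bits[keep], aln_len = alen[keep],
        qlen = lens[i], slen = lens[js][keep]
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          evalue = numeric(), bitscore = numeric(),
                          aln_len = integer(), qlen = integer(),
                          slen = integer()))
  }
  dplyr::bind_rows(out)
}

#' Alignment coverage of a pairwise hit
#'
#' Alignment length divided by the average of the query and subject protein
#' lengths, as a percentage: `100 * aln_len / ((qlen + slen) / 2)`.
#'
#' @param hits hit tibble (or any data frame with `aln_len`, `qlen`, `slen`).
#' @return numeric vector of coverages, one per hit.
#' @examples
#' alignment_coverage(data.frame(aln_len = 50, qlen = 100, slen = 100)) # 50
#' @export
alignment_coverage <- function(hits) {
  stopifnot(all(hits$qlen > 0), all(hits$slen > 0))
  100 * hits$aln_len / ((hits$qlen + hits$slen) / 2)
}

#' Filter hits and keep each protein's best hit per subject genome
#'
#' Drops hits with E-value above `evalue_cut` or coverage below
#' `coverage_cut` (both comparisons inclusive: `evalue <= cut` and
#' `coverage >= cut` pass). Among survivors, for each (query gene, subject
#' genome) only the best hit is kept: lowest E-value, ties broken by higher
#' bit score, then lexicographic subject id.
#'
#' @param hits hit tibble from [compute_pairwise_hits()].
#' @param genes gene tibble (supplies each subject's genome).
#' @param evalue_cut E-value threshold (case-study value 1e-3).
#' @param coverage_cut coverage threshold in percent (case-study value 10).
#' @return filtered hit tibble with a `coverage` column added.
#' @export
select_best_hits <- function(hits, genes, evalue_cut = 1e-3,
                             coverage_cut = 10) {
  stopifnot(evalue_cut >= 0, coverage_cut >= 0)
  if (nrow(hits) == 0L) {
    return(dplyr::mutate(hits, coverage = numeric(0)))
  }
  genome_of <- stats::setNames(genes$genome_id, genes$gene_id)
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(genome_of))
  if (length(unknown) > 0) {
    stop("hits reference unknown gene(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  hits |>
    dplyr::mutate(coverage = alignment_coverage(hits),
                  subject_genome = unname(genome_of[.data$subject_id])) |>
    dplyr::filter(.data$evalue <= evalue_cut,
                  .data$coverage >= coverage_cut) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore),
                   .data$subject_id) |>
    dplyr::distinct(.data$query_id, .data$subject_genome, .keep_all = TRUE) |>
    dplyr::select(-"subject_genome") |>
    dplyr::arrange(.data$query_id, .data$subject_id)
}

#' Integrate shared genes into signature gene groups
#'
#' Builds the undirected graph whose vertices are genes and whose edges are
#' the qualifying best hits, and reports its connected components as
#' signature gene groups. Components confined to a single genome are
#' discarded (a signature gene must span at least two genomes). Group ids are
#' assigned deterministically by each component's smallest member gene id;
#' the output is sorted by genome span (descending), then group id.
#'
#' @param filtered_hits output of [select_best_hits()].
#' @param genes gene tibble.
#' @return tibble of groups: `group_id`, `genome_span`, `n_members`,
#'   `members` (list column of gene ids), `annotations` (pooled, unique).
#' @export
build_groups <- function(filtered_hits, genes) {
  empty <- tibble::tibble(group_id = character(), genome_span = integer(),
                          n_members = integer(), members = list(),
                          annotations = character())
  if (nrow(filtered_hits) == 0L) return(empty)
  edges <- unique(t(apply(
    cbind(filtered_hits$query_id, filtered_hits$subject_id), 1L, sort
  )))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  comp <- igraph::components(g)
  membership <- split(names(comp$membership), comp$membership)
  genome_of <- stats::setNames(genes$genome_id, genes$gene_id)
  annot_of <- stats::setNames(genes$annotation, genes$gene_id)

  rows <- lapply(membership, function(members) {
    members <- sort(members)
    span <- length(unique(genome_of[members]))
    if (span < 2L) return(NULL)
    ann <- unique(annot_of[members])
    ann <- ann[!is.na(ann) & ann != ""]
    tibble::tibble(
      anchor = members[1], genome_span = span, n_members = length(members),
      members = list(members),
      annotations = paste(sort(ann), collapse = "; ")
    )
  })
  rows <- dplyr::bind_rows(rows[!vapply(rows, is.null, TRUE)])
  if (nrow(rows) == 0L) return(empty)
  rows <- dplyr::arrange(rows, .data$anchor)
  rows$group_id <- sprintf("SG%03d", seq_len(nrow(rows)))
  rows |>
    dplyr::arrange(dplyr::desc(.data$genome_span), .data$group_id) |>
    dplyr::select("group_id", "genome_span", "n_members", "members",
                  "annotations")
}

#' Identify signature gene groups across a set of genomes
#'
#' One-call pipeline: all-vs-all protein search, E-value/coverage filtering,
#' best-hit selection, and integration into signature gene groups.
#'
#' @param genes gene tibble covering at least two genomes.
#' @param evalue_cut,coverage_cut filtering thresholds (see
#'   [select_best_hits()]).
#' @param engine search engine (see [compute_pairwise_hits()]).
#' @param hits optional precomputed hit tibble (e.g. from
#'   [read_blast_tab()]); skips the search.
#' @return group tibble from [build_groups()].
#' @export
identify_signature_genes <- function(genes, evalue_cut = 1e-3,
                                     coverage_cut = 10,
                                     engine = c("external", "internal"),
                                     hits = NULL) {
  if (is.null(hits)) {
    hits <- compute_pairwise_hits(genes, engine = match.arg(engine))
  }
  best <- select_best_hits(hits, genes, evalue_cut, coverage_cut)
  build_groups(best, genes)
}
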