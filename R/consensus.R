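#' Codon-aware alignment, IUPAC consensus, and conserved regions
#'
#' Primer design works on the nucleotide level but alignment quality is far
#' better at the protein level, so a signature gene group is aligned as
#' proteins and each aligned residue is then replaced by its original codon
#' (back-translation), giving a codon-aware nucleotide alignment that
#' preserves every member's actual coding sequence. From that alignment an
#' IUPAC consensus at a 100% identity threshold is computed: a column is
#' conserved only when all members carry the same base, otherwise it gets
#' the minimal covering ambiguity code. Conserved regions — stretches
#' anchored by completely conserved bases — are the templates for primer
#' enumeration.
#'
#' @name consensus
NULL

new_codon_alignment <- function(member_ids, rows, source = "auto") {
  stopifnot(length(member_ids) == length(rows),
            length(unique(nchar(rows))) <= 1L)
  structure(
    list(member_ids = member_ids,
         rows = stats::setNames(rows, member_ids),
         source = source),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", length(x$member_ids), " members, ",
      if (length(x$rows) > 0) nchar(x$rows[[1]]) else 0L, " columns (",
      x$source, ")\n", sep = "")
  invisible(x)
}

#' Tidy a codon alignment into a tibble
#' @param x a `codon_alignment`.
#' @param ... unused.
#' @return tibble with `member_id` and `aligned_nt`.
#' @export
tidy.codon_alignment <- function(x, ...) {
  tibble::tibble(member_id = x$member_ids,
                 aligned_nt = unname(x$rows))
}

#' Align a signature gene group (protein alignment, back-translated)
#'
#' Aligns the member proteins with an external multiple aligner (`mafft`,
#' default settings) and converts each aligned protein row back to
#' nucleotides by replacing every residue with its original codon and every
#' gap with `---`. Ungapping any row therefore reproduces that member's
#' coding sequence exactly.
#'
#' @param genes gene tibble rows for the group members (needs `gene_id`,
#'   `nt_seq`, `aa_seq`).
#' @return a `codon_alignment`.
#' @export
align_group <- function(genes) {
  stopifnot(nrow(genes) >= 2L)
  for (i in seq_len(nrow(genes))) {
    aa_check <- suppressWarnings(translate_cds(genes$nt_seq[i]))
    if (!identical(aa_check, unname(genes$aa_seq[i]))) {
      stop("nt/aa sequences inconsistent for gene ", genes$gene_id[i],
           call. = FALSE)
    }
  }
  aligned_aa <- run_mafft(stats::setNames(genes$aa_seq, genes$gene_id))
  bt <- lapply(seq_len(nrow(genes)), function(i) {
    back_translate_row(aligned_aa[[genes$gene_id[i]]], genes$nt_seq[i],
                       genes$gene_id[i])
  })
  # terminal stop codons are not in the protein alignment; pad so rows stay
  # rectangular when some members lack one
  tail_w <- max(vapply(bt, function(b) nchar(b$tail), 1L))
  rows <- vapply(bt, function(b) {
    paste0(b$core, b$tail, strrep("-", tail_w - nchar(b$tail)))
  }, "")
  new_codon_alignment(genes$gene_id, rows, source = "auto")
}

run_mafft <- function(seqs) {
  if (Sys.which("mafft") == "") {
    stop("multiple aligner not found: `mafft` must be on PATH", call. = FALSE)
  }
  fin <- tempfile(fileext = ".faa")
  fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)))
  write_fasta(seqs, fin)
  res <- system2("mafft", c("--auto", "--anysymbol", "--quiet", fin),
                 stdout = fout, stderr = FALSE)
  if (res != 0 || !file.exists(fout)) stop("mafft failed", call. = FALSE)
  out <- read_fasta(fout)
  toupper(out[names(seqs)])
}

back_translate_row <- function(aligned_aa, nt_seq, gene_id) {
  aa_chars <- strsplit(aligned_aa, "", fixed = TRUE)[[1]]
  n_res <- sum(aa_chars != "-")
  extra <- nchar(nt_seq) - n_res * 3L
  if (!extra %in% c(0L, 3L)) {
    stop("aligned protein and coding sequence disagree for ", gene_id,
         call. = FALSE)
  }
  codons <- substring(nt_seq, seq(1, n_res * 3L, by = 3L),
                      seq(3, n_res * 3L, by = 3L))
  out <- character(length(aa_chars))
  out[aa_chars == "-"] <- "---"
  out[aa_chars != "-"] <- codons
  list(core = paste(out, collapse = ""),
       tail = substring(nt_seq, n_res * 3L + 1L, nchar(nt_seq)))
}

#' Load a user-supplied nucleotide alignment
#'
#' Accepts aligned FASTA or CLUSTAL format. Rows are taken verbatim (no
#' codon structure is assumed for user alignments); member ids are matched
#' by sequence name.
#'
#' @param path alignment file.
#' @param expected_members optional character vector; an error lists any
#'   alignment names not in this set.
#' @return a `codon_alignment` with `source = "user"`.
#' @export
load_user_alignment <- function(path, expected_members = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) {
    seqs <- read_clustal(path)
  } else {
    seqs <- toupper(read_fasta(path))
  }
  if (length(unique(nchar(seqs))) > 1L) {
    stop("alignment rows have unequal lengths in ", path, call. = FALSE)
  }
  if (!is.null(expected_members)) {
    unknown <- setdiff(names(seqs), expected_members)
    if (length(unknown) > 0) {
      stop("alignment contains unknown member name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  new_codon_alignment(names(seqs), unname(seqs), source = "user")
}

# interleaved CLUSTAL blocks: "<name>  <chunk>"; conservation lines (which
# start with whitespace), the header and blank lines are skipped
read_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)[-1]
  keep <- grepl("^\\S+\\s+\\S+\\s*$", lines)
  out <- list()
  for (ln in lines[keep]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    chunk <- gsub("[0-9]+$", "", parts[2]) # trailing residue counts
    out[[parts[1]]] <- paste0(out[[parts[1]]] %||% "", chunk)
  }
  if (length(out) == 0L) {
    stop("no sequences found in CLUSTAL file ", path, call. = FALSE)
  }
  toupper(unlist(out))
}

#' Write an alignment as aligned FASTA and CLUSTAL
#'
#' @param alignment a `codon_alignment`.
#' @param fasta_path,clustal_path output files (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_alignment <- function(alignment, fasta_path = NULL, clustal_path = NULL) {
  if (!is.null(fasta_path)) write_fasta(alignment$rows, fasta_path)
  if (!is.null(clustal_path)) {
    con <- file(clustal_path, "wt")
    on.exit(close(con))
    writeLines("CLUSTAL W multiple sequence alignment\n", con)
    width <- 60L
    L <- nchar(alignment$rows[[1]])
    name_w <- max(nchar(alignment$member_ids)) + 3L
    for (st in seq(1, L, by = width)) {
      for (id in alignment$member_ids) {
        writeLines(sprintf("%-*s%s", name_w, id,
                           substring(alignment$rows[[id]], st,
                                     min(st + width - 1L, L))), con)
      }
      writeLines("", con)
    }
  }
  invisible(c(fasta_path, clustal_path))
}

#' IUPAC consensus of a nucleotide alignment at 100% identity
#'
#' Per column: if any row carries a gap the consensus is `-`; otherwise the
#' consensus is the minimal IUPAC code whose disambiguation set equals the
#' set of bases observed in that column. A column is flagged conserved only
#' when that set has size one (code A, C, G or T). Ambiguous input bases
#' (e.g. N) widen the column's set; such columns are never conserved.
#'
#' @param alignment a `codon_alignment`.
#' @return object of class `consensus_seq`: list with `consensus` (string
#'   over IUPAC codes and `-`) and `conserved` (logical per column).
#' @export
iupac_consensus <- function(alignment) {
  stopifnot(length(alignment$rows) >= 1L)
  mat <- do.call(rbind, strsplit(unname(alignment$rows), "", fixed = TRUE))
  L <- ncol(mat)
  cons <- character(L)
  conserved <- logical(L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    if (any(col == "-")) {
      cons[j] <- "-"
      next
    }
    bases <- unique(unlist(lapply(unique(col), iupac_set)))
    cons[j] <- iupac_code_for(bases)
    conserved[j] <- length(bases) == 1L
  }
  structure(list(consensus = paste(cons, collapse = ""),
                 conserved = conserved),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat("<consensus_seq> ", nchar(x$consensus), " columns, ",
      sum(x$conserved), " conserved\n", sep = "")
  invisible(x)
}

#' Extract conserved regions from a consensus sequence
#'
#' A conserved region is anchored by at least two completely conserved bases
#' (A, C, G or T — no mixed codes) within 19 bases of each other. For each
#' conserved base at position `i`, the next 19 consensus positions are
#' scanned; if any conserved base is found there, the span from `i` to the
#' furthest such base is extracted together with 5 flanking bases on each
#' side (clipped at the consensus termini). Regions whose span contains a
#' gap column are excluded, and duplicate (start, stop) spans are removed.
#' Unclipped regions are therefore 12-30 bases long; overlapping regions
#' from successive anchors are all kept.
#'
#' @param cons a `consensus_seq`.
#' @param flank flanking bases added on each side (default 5).
#' @param window scan distance for the partner conserved base (default 19).
#' @return tibble of regions: `region_id`, `start`, `stop` (1-based inclusive
#'   consensus coordinates), `length`, `seq`.
#' @export
extract_conserved_regions <- function(cons, flank = 5L, window = 19L) {
  chars <- strsplit(cons$consensus, "", fixed = TRUE)[[1]]
  L <- length(chars)
  anchors <- which(cons$conserved)
  spans <- list()
  for (i in anchors) {
    in_window <- anchors[anchors > i & anchors <= i + window]
    if (length(in_window) == 0L) next
    j <- max(in_window)
    spans[[length(spans) + 1L]] <- c(max(1L, i - flank), min(L, j + flank))
  }
  empty <- tibble::tibble(region_id = character(), start = integer(),
                          stop = integer(), length = integer(),
                          seq = character())
  if (length(spans) == 0L) return(empty)
  spans <- unique(do.call(rbind, spans))
  seqs <- substring(cons$consensus, spans[, 1], spans[, 2])
  keep <- !grepl("-", seqs, fixed = TRUE)
  if (!any(keep)) return(empty)
  out <- tibble::tibble(
    start = as.integer(spans[keep, 1]), stop = as.integer(spans[keep, 2]),
    seq = seqs[keep]
  )
  out <- dplyr::arrange(out, .data$start, .data$stop)
  out$region_id <- sprintf("R%03d", seq_len(nrow(out)))
  out$length <- out$stop - out$start + 1L
  out[, c("region_id", "start", "stop", "length", "seq")]
}
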