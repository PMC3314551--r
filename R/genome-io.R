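#' Read an annotated phage genome
#'
#' Reads a genome plus its protein-coding gene annotations from either a
#' GenBank flat file (CDS features) or a FASTA genome paired with a TSV gene
#' table (columns `gene_id`, `start`, `stop`, `strand`, `annotation`).
#' Coordinates are 1-based inclusive throughout; minus-strand genes store the
#' reverse complement of the genomic slice as their coding sequence.
#'
#' Coding sequences are translated with the bacterial/plastid genetic code
#' (translation table 11), the convention for phage genomes. A terminal stop
#' codon is dropped from the protein; an internal stop raises a warning but
#' the record is retained, since public phage annotations vary in quality.
#'
#' @param path path to a GenBank file, or to a genome FASTA when
#'   `format = "fasta+table"`.
#' @param format `"genbank"` or `"fasta+table"`.
#' @param gene_table path to the TSV gene table (required for fasta+table).
#' @param genome_id identifier override; defaults to the LOCUS name (GenBank)
#'   or the FASTA record name.
#' @return list with `genome` (one-row tibble: genome_id, name, length,
#'   sequence) and `genes` (tibble of gene records: gene_id, genome_id, start,
#'   stop, strand, nt_seq, aa_seq, annotation).
#' @export
read_genome <- function(path, format = c("genbank", "fasta+table"),
                        gene_table = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "genbank") {
    parsed <- parse_genbank(path)
  } else {
    if (is.null(gene_table)) {
      stop("fasta+table format needs a `gene_table` TSV", call. = FALSE)
    }
    parsed <- parse_fasta_table(path, gene_table)
  }
  if (!is.null(genome_id)) {
    parsed$genome$genome_id <- genome_id
    if (nrow(parsed$genes) > 0) parsed$genes$genome_id <- genome_id
  }
  parsed$genes <- finish_gene_records(parsed$genes, parsed$genome)
  parsed
}

#' Read a directory or set of genome files
#'
#' Convenience wrapper: reads every `.gb`/`.gbk`/`.genbank` file and binds
#' the gene records of all genomes into one tibble.
#'
#' @param paths a directory or a character vector of GenBank files.
#' @return list with `genomes` (tibble, one row per genome) and `genes`
#'   (tibble over all genomes).
#' @export
read_genome_set <- function(paths) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE)
  }
  if (length(paths) == 0L) stop("no genome files found", call. = FALSE)
  parsed <- lapply(sort(paths), read_genome, format = "genbank")
  list(
    genomes = dplyr::bind_rows(lapply(parsed, `[[`, "genome")),
    genes = dplyr::bind_rows(lapply(parsed, `[[`, "genes"))
  )
}

# ---- GenBank flat file ----

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L) {
    stop("GenBank parse error in ", path, ": expected one LOCUS line, found ",
         length(locus_i), call. = FALSE)
  }
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i])), "\\s+")[[1]]
  genome_id <- locus[1]
  def_i <- grep("^DEFINITION", lines)
  name <- if (length(def_i) > 0) trimws(sub("^DEFINITION", "", lines[def_i[1]])) else genome_id

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1L) {
    stop("GenBank parse error in ", path, ": missing ORIGIN section", call. = FALSE)
  }
  seq_lines <- lines[(origin_i + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) {
    stop("GenBank parse error in ", path, ": empty sequence", call. = FALSE)
  }

  feat_i <- grep("^FEATURES", lines)
  genes <- tibble::tibble(
    gene_id = character(), genome_id = character(),
    start = integer(), stop = integer(), strand = character(),
    annotation = character()
  )
  if (length(feat_i) == 1L) {
    feat_lines <- lines[(feat_i + 1):(origin_i - 1)]
    genes <- parse_genbank_cds(feat_lines, genome_id, path)
  }
  list(
    genome = tibble::tibble(
      genome_id = genome_id, name = name,
      length = nchar(sequence), sequence = sequence
    ),
    genes = genes
  )
}

parse_genbank_cds <- function(feat_lines, genome_id, path) {
  # feature keys sit at column 6, qualifiers/continuations at column 22
  key_i <- grep("^ {5}\\S", feat_lines)
  recs <- list()
  for (k in seq_along(key_i)) {
    i <- key_i[k]
    end <- if (k < length(key_i)) key_i[k + 1] - 1L else length(feat_lines)
    key <- sub("^ +(\\S+).*$", "\\1", feat_lines[i])
    if (key != "CDS") next
    block <- feat_lines[i:end]
    # location may continue over lines until the first qualifier
    qual_start <- grep("^ +/", block)
    loc_end <- if (length(qual_start) > 0) qual_start[1] - 1L else length(block)
    loc <- gsub("\\s", "", paste(sub("^ +CDS", "", block[1]),
                                 paste(trimws(block[seq_len(loc_end)][-1]), collapse = "")))
    parsed_loc <- parse_gb_location(loc, path)
    quals <- parse_gb_qualifiers(block[seq_along(block) >= min(qual_start, Inf)])
    gene_id <- quals[["locus_tag"]] %||% quals[["gene"]] %||%
      paste0(genome_id, "_cds", length(recs) + 1L)
    annotation <- quals[["product"]] %||% quals[["note"]] %||% ""
    recs[[length(recs) + 1L]] <- tibble::tibble(
      gene_id = gene_id, genome_id = genome_id,
      start = parsed_loc$start, stop = parsed_loc$stop,
      strand = parsed_loc$strand, annotation = annotation
    )
  }
  if (length(recs) == 0L) {
    return(tibble::tibble(gene_id = character(), genome_id = character(),
                          start = integer(), stop = integer(),
                          strand = character(), annotation = character()))
  }
  dplyr::bind_rows(recs)
}

parse_gb_location <- function(loc, path) {
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  # join() of segments is collapsed to its outer span; partial markers dropped
  loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  loc <- gsub("[<>]", "", loc)
  nums <- as.integer(unlist(regmatches(loc, gregexpr("[0-9]+", loc))))
  if (length(nums) < 2L || anyNA(nums)) {
    stop("GenBank parse error in ", path, ": bad CDS location '", loc, "'",
         call. = FALSE)
  }
  list(start = min(nums), stop = max(nums), strand = strand)
}

parse_gb_qualifiers <- function(lines) {
  if (length(lines) == 0L) return(list())
  txt <- paste(trimws(lines), collapse = "\n")
  # continuation lines (no leading /) fold into the previous qualifier
  txt <- gsub("\n(?!/)", " ", txt, perl = TRUE)
  parts <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  parts <- parts[grepl("^/", parts)]
  out <- list()
  for (p in parts) {
    m <- regmatches(p, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?$', p))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || identical(a, "")) b else a

# ---- FASTA + gene table ----

parse_fasta_table <- function(path, gene_table) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) {
    stop("fasta+table mode expects exactly one genome record in ", path,
         call. = FALSE)
  }
  genome_id <- strsplit(names(seqs)[1], "\\s+")[[1]][1]
  tab <- readr::read_tsv(gene_table, show_col_types = FALSE, progress = FALSE)
  needed <- c("gene_id", "start", "stop", "strand")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0) {
    stop("gene table ", gene_table, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"annotation" %in% names(tab)) tab$annotation <- ""
  list(
    genome = tibble::tibble(
      genome_id = genome_id, name = names(seqs)[1],
      length = Biostrings::width(seqs)[1],
      sequence = as.character(seqs[[1]])
    ),
    genes = tibble::tibble(
      gene_id = as.character(tab$gene_id), genome_id = genome_id,
      start = as.integer(tab$start), stop = as.integer(tab$stop),
      strand = as.character(tab$strand), annotation = as.character(tab$annotation)
    )
  )
}

# slice coding sequences out of the genome and translate
finish_gene_records <- function(genes, genome) {
  if (nrow(genes) == 0L) {
    genes$nt_seq <- character()
    genes$aa_seq <- character()
    return(genes[, c("gene_id", "genome_id", "start", "stop", "strand",
                     "nt_seq", "aa_seq", "annotation")])
  }
  stopifnot(all(genes$start <= genes$stop), all(genes$strand %in% c("+", "-")))
  if (any(genes$stop > genome$length)) {
    bad <- genes$gene_id[genes$stop > genome$length]
    stop("gene(s) extend past genome end: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  slices <- substring(genome$sequence, genes$start, genes$stop)
  nt <- ifelse(genes$strand == "-",
               vapply(slices, reverse_complement, "", USE.NAMES = FALSE),
               slices)
  genes$nt_seq <- nt
  genes$aa_seq <- vapply(seq_len(nrow(genes)), function(i) {
    translate_cds(genes$nt_seq[i], gene_id = genes$gene_id[i])
  }, "")
  genes[, c("gene_id", "genome_id", "start", "stop", "strand",
            "nt_seq", "aa_seq", "annotation")]
}

#' Translate a coding sequence
#'
#' Standard codon translation under the bacterial/plastid code (table 11).
#' A terminal stop codon is dropped; internal stop codons are tolerated with
#' a warning (they appear as `*` in the protein).
#'
#' @param nt coding-strand DNA string; length must be a multiple of 3.
#' @param code NCBI translation table id (default `"11"`).
#' @param gene_id optional label used in warnings.
#' @return protein string.
#' @examples
#' translate_cds("ATGGCA") # "MA"
#' translate_cds("ATGTAA") # "M" (terminal stop dropped)
#' @export
translate_cds <- function(nt, code = "11", gene_id = NULL) {
  if (nchar(nt) %% 3 != 0) {
    stop("coding sequence length ", nchar(nt), " is not a multiple of 3",
         if (!is.null(gene_id)) paste0(" (", gene_id, ")"), call. = FALSE)
  }
  if (nchar(nt) == 0L) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode(code),
    no.init.codon = TRUE, # literal codon lookup, no initiator special-case
    if.fuzzy.codon = "solve"
  ))
  # drop terminal stop
  aa <- sub("\\*$", "", aa)
  if (grepl("*", aa, fixed = TRUE)) {
    warning("internal stop codon in translation",
            if (!is.null(gene_id)) paste0(" of ", gene_id),
            "; record retained", call. = FALSE)
  }
  aa
}

# ---- writers ----

#' Write a genome with gene annotations as a GenBank flat file
#'
#' Emits the minimal standard sections (LOCUS, DEFINITION, FEATURES with one
#' CDS per gene, ORIGIN). Round-trips through [read_genome()].
#'
#' @param genome one-row tibble as returned by [read_genome()].
#' @param genes gene tibble for this genome.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, genes, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w(sprintf("LOCUS       %s %d bp    DNA     linear   PHG", genome$genome_id,
            genome$length))
  w(sprintf("DEFINITION  %s", genome$name))
  w("FEATURES             Location/Qualifiers")
  w(sprintf("     source          1..%d", genome$length))
  if (nrow(genes) > 0) {
    for (i in seq_len(nrow(genes))) {
      loc <- sprintf("%d..%d", genes$start[i], genes$stop[i])
      if (genes$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      w(sprintf("     CDS             %s", loc))
      w(sprintf("                     /locus_tag=\"%s\"", genes$gene_id[i]))
      w(sprintf("                     /product=\"%s\"", genes$annotation[i]))
    }
  }
  w("ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1, nchar(s), by = 60)
  for (st in starts) {
    chunk <- substring(s, st, min(st + 59, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    w(sprintf("%9d %s", st, paste(blocks, collapse = " ")))
  }
  w("//")
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
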