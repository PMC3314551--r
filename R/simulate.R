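#' Synthetic phage genome sets with planted homologous gene families
#'
#' Generates small annotated phage-like genomes carrying orthologous gene
#' families at a controlled amino-acid identity, so that signature-gene
#' grouping and primer design can be exercised end to end with a known truth
#' set and no downloads. Each family descends from one random ancestral
#' coding sequence; every genome carries one ortholog per family, mutated
#' independently at nonsynonymous and synonymous sites so that the expected
#' pairwise protein identity between two orthologs matches `aa_identity`.
#' Intergenic DNA is random. The planted family membership is written to a
#' manifest TSV — the truth set for benchmarking.
#'
#' @param out_dir directory to write the GenBank files and manifest into
#'   (created if needed).
#' @param n_genomes number of genomes.
#' @param n_families number of planted orthologous families.
#' @param aa_identity target expected pairwise amino-acid identity between
#'   orthologs, in (0, 1].
#' @param genome_len genome length in bp (default 40000, a typical small
#'   podophage genome).
#' @param aa_len protein length of each family's ancestor, residues
#'   (default 250).
#' @param syn_rate per-codon probability of a synonymous codon swap in each
#'   lineage (default 0.5; adds nucleotide-level divergence beyond the
#'   protein-level target).
#' @param seed integer seed; output is fully reproducible from it.
#' @return list: `genome_paths` (GenBank files), `manifest_path`, `manifest`
#'   (tibble: family_id, genome_id, gene_id).
#' @export
generate_phage_set <- function(out_dir,
                               n_genomes = 4L, n_families = 6L,
                               aa_identity = 0.6, genome_len = 40000L,
                               aa_len = 250L, syn_rate = 0.5,
                               seed = 1L) {
  stopifnot(aa_identity > 0, aa_identity <= 1, n_families >= 1L,
            n_genomes >= 2L)
  set.seed(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  code <- Biostrings::getGeneticCode("11")
  aas <- setdiff(unique(code), "*")
  codons_of <- split(names(code), code)
  stops <- codons_of[["*"]]
  pick_codon <- function(aa) {
    cs <- codons_of[[aa]]
    cs[sample.int(length(cs), 1L)]
  }

  gene_nt_len <- (aa_len + 1L) * 3L # incl. stop codon
  min_spacer <- 100L
  if (n_families * (gene_nt_len + min_spacer) + min_spacer > genome_len) {
    stop("infeasible parameters: ", n_families, " genes of ", gene_nt_len,
         " bp do not fit in a ", genome_len, " bp genome", call. = FALSE)
  }

  # per-lineage substitution rate so that two independently mutated
  # orthologs agree at a fraction ~ aa_identity of residues
  p_ns <- 1 - sqrt(aa_identity)

  # ancestors: first residue fixed to M
  ancestors <- lapply(seq_len(n_families), function(f) {
    aa <- c("M", sample(aas, aa_len - 1L, replace = TRUE))
    list(aa = aa, codons = vapply(aa, pick_codon, ""))
  })

  mutate_lineage <- function(anc) {
    aa <- anc$aa
    codons <- anc$codons
    for (i in seq(2L, length(aa))) { # keep the start residue
      if (stats::runif(1) < p_ns) {
        aa[i] <- sample(setdiff(aas, aa[i]), 1L)
        codons[i] <- pick_codon(aa[i])
      } else if (stats::runif(1) < syn_rate) {
        codons[i] <- pick_codon(aa[i])
      }
    }
    paste0(paste(codons, collapse = ""), stops[sample.int(length(stops), 1L)])
  }

  random_dna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }

  manifest <- list()
  genome_paths <- character(n_genomes)
  for (g in seq_len(n_genomes)) {
    genome_id <- sprintf("SIMG%02d", g)
    # lay genes down left to right with random spacers
    slack <- genome_len - n_families * gene_nt_len - min_spacer
    spacers <- min_spacer + floor(stats::runif(n_families) *
                                    (slack / n_families - min_spacer))
    pos <- 1L
    genes <- list()
    seq_parts <- list()
    for (f in seq_len(n_families)) {
      sp <- as.integer(spacers[f])
      seq_parts[[length(seq_parts) + 1L]] <- random_dna(sp)
      pos <- pos + sp
      nt <- mutate_lineage(ancestors[[f]])
      strand <- sample(c("+", "-"), 1L)
      gene_id <- sprintf("%s_F%02d", genome_id, f)
      genes[[f]] <- tibble::tibble(
        gene_id = gene_id, genome_id = genome_id,
        start = pos, stop = pos + nchar(nt) - 1L, strand = strand,
        annotation = sprintf("planted family %02d protein", f)
      )
      seq_parts[[length(seq_parts) + 1L]] <-
        if (strand == "+") nt else reverse_complement(nt)
      pos <- pos + nchar(nt)
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        family_id = sprintf("F%02d", f), genome_id = genome_id,
        gene_id = gene_id
      )
    }
    seq_parts[[length(seq_parts) + 1L]] <- random_dna(genome_len - pos + 1L)
    sequence <- paste(unlist(seq_parts), collapse = "")
    genome <- tibble::tibble(
      genome_id = genome_id,
      name = sprintf("Synthetic phage %s (planted gene families)", genome_id),
      length = nchar(sequence), sequence = sequence
    )
    genome_paths[g] <- file.path(out_dir, paste0(genome_id, ".gb"))
    write_genbank(genome, dplyr::bind_rows(genes), genome_paths[g])
  }

  manifest <- dplyr::bind_rows(manifest)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path, progress = FALSE)
  list(genome_paths = genome_paths, manifest_path = manifest_path,
       manifest = manifest)
}
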