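# Small fixture builders used across test files.

# gene tibble straight from coding sequences (no genome file involved)
genes_from_nt <- function(nt, genome_ids = NULL, prefix = "g") {
  ids <- paste0(prefix, seq_along(nt))
  if (is.null(genome_ids)) genome_ids <- paste0("G", seq_along(nt))
  tibble::tibble(
    gene_id = ids, genome_id = genome_ids,
    start = 1L, stop = nchar(nt), strand = "+",
    nt_seq = nt,
    aa_seq = vapply(nt, function(s) suppressWarnings(translate_cds(s)), "",
                    USE.NAMES = FALSE),
    annotation = ""
  )
}

# one simulated family as a ready-to-design gene tibble (simulate -> read,
# members looked up through the manifest truth set)
simulated_family <- function(seed, n_genomes = 3L, aa_identity = 0.75,
                             aa_len = 100L, genome_len = 6000L) {
  dir <- file.path(tempdir(), sprintf("fam_s%d_%d", seed, n_genomes))
  sim <- generate_phage_set(dir, n_genomes = n_genomes, n_families = 1L,
                            aa_identity = aa_identity,
                            genome_len = genome_len, aa_len = aa_len,
                            seed = seed)
  set <- read_genome_set(dir)
  list(genes = set$genes[set$genes$gene_id %in% sim$manifest$gene_id, ],
       manifest = sim$manifest, dir = dir)
}

toy_genbank <- function(path, cds_line = "1..9",
                        seq = "atggcataac gatt") {
  writeLines(c(
    "LOCUS       TOY1 14 bp    DNA     linear   PHG",
    "DEFINITION  toy phage genome",
    "FEATURES             Location/Qualifiers",
    "     source          1..14",
    sprintf("     CDS             %s", cds_line),
    "                     /locus_tag=\"toy_001\"",
    "                     /product=\"toy protein\"",
    "ORIGIN",
    sprintf("%9d %s", 1, seq),
    "//"
  ), path)
  path
}
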