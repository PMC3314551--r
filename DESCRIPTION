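Package: phagesig
Title: Signature Gene Identification and Degenerate PCR Primer Design for Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies signature genes (homologous genes conserved across a
    user-selected set of phage genomes) from all-vs-all protein comparisons,
    builds codon-aware nucleotide alignments of each gene group, computes an
    IUPAC consensus at a 100% identity threshold, extracts conserved regions,
    and designs degenerate or non-degenerate PCR primer pairs with full
    physicochemical screening (degeneracy, GC content, GC clamp, three melting
    temperature methods including nearest-neighbor thermodynamics, 3' end
    stability, and primer-dimer/hairpin complementarity), pairing primers by
    minimal melting temperature difference. Includes a reproducible synthetic
    phage-genome simulator with planted homologous gene families for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
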