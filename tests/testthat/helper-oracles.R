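# Independent oracles, deliberately coded from scratch (no package
# internals) so the implementation and its checks share nothing but the
# published parameter file.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_can_pair <- function(x, y) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  any(comp[ORACLE_IUPAC[[x]]] %in% ORACLE_IUPAC[[y]])
}

# exhaustive O(n*m*offsets) scan of a against reverse(b)
oracle_dimer_run <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- rev(strsplit(b, "")[[1]])
  n <- length(x); m <- length(y)
  best <- 0L
  for (off in -(m - 1):(n - 1)) {
    run <- 0L
    for (i in seq_len(n)) {
      j <- i - off
      if (j >= 1 && j <= m && oracle_can_pair(x[i], y[j])) {
        run <- run + 1L
        best <- max(best, run)
      } else {
        run <- 0L
      }
    }
  }
  best
}

# brute force over all stem/loop splits: innermost pair (i, j) with
# j - i - 1 >= min_loop, extended outward while pairable
oracle_hairpin_run <- function(seq, min_loop = 3L) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  best <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i - 1 < min_loop) next
      run <- 0L
      while (i - run >= 1 && j + run <= n &&
             oracle_can_pair(x[i - run], x[j + run])) {
        run <- run + 1L
      }
      best <- max(best, run)
    }
  }
  best
}

# independent NN melting temperature for a concrete sequence, reading the
# same shipped parameter file but through its own table handling
oracle_tm_nn <- function(seq, na_conc = 0.05, primer_conc = 2.5e-7) {
  tab <- read.delim(system.file("extdata", "nn_unified_1998.tsv",
                                package = "phagesig"))
  rc <- function(s) {
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  dh <- ds <- c()
  for (i in seq_len(nrow(tab))) {
    dh[tab$nn[i]] <- tab$dh_kcal[i]
    ds[tab$nn[i]] <- tab$ds_cal[i]
    if (!grepl("init", tab$nn[i])) {
      dh[rc(tab$nn[i])] <- tab$dh_kcal[i]
      ds[rc(tab$nn[i])] <- tab$ds_cal[i]
    }
  }
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  stacks <- paste0(ch[-n], ch[-1])
  ends <- ifelse(c(ch[1], ch[n]) %in% c("G", "C"), "init_GC", "init_AT")
  H <- sum(dh[stacks]) + sum(dh[ends])
  S <- sum(ds[stacks]) + sum(ds[ends])
  1000 * H / (S + 1.987 * log(primer_conc / 4)) - 273.15 +
    16.6 * log10(na_conc)
}

random_iupac <- function(n, alphabet = names(ORACLE_IUPAC)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
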