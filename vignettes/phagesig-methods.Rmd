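---
title: "Signature genes and degenerate primers: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature genes and degenerate primers: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phagesig` couples two computations: finding homologous genes conserved
across a chosen set of phage genomes, and designing degenerate PCR primer
pairs that are guaranteed to match every member of such a gene group. This
vignette explains the underlying models, the tunable parameters and their
defaults, the numerical choices, and what the simulation-based tests do and
do not demonstrate.

## Homology grouping

All proteins from the selected genomes are compared all-against-all. The
default engine shells out to `blastp` (tabular output, report threshold
E = 10 so that later filtering never re-runs the search). The internal
engine exists so grouping works without external executables: it is a
Smith–Waterman local alignment (`Biostrings::pairwiseAlignment`, BLOSUM62,
gap open 11 / extend 1) whose raw score *S* is converted to an E-value with
the gapped Karlin–Altschul form E = K·m·n·e^(−λS), λ = 0.267, K = 0.041 and
search space m·n = qlen·slen. These constants match the external engine's
gapped defaults, so a user-chosen E-value cut-off means the same thing under
either engine; the test suite checks that both engines pass the same planted
ortholog pairs at E ≤ 10⁻³.

Hits are filtered inclusively on E-value (≤ cut) and on alignment coverage,
defined as the alignment length divided by the *mean* of query and subject
lengths, as a percentage. For each (query gene, subject genome) only the
best surviving hit is kept — lowest E-value, then higher bit score, then
lexicographic subject id, making the selection fully deterministic. Groups
are the connected components of the undirected graph of kept hits. Best
hits are treated directionally rather than as reciprocal-best: requiring
reciprocity silently shrinks group counts, and the most inclusive reading is
what "genes shared among multiple genomes" calls for. Components are
single-linkage, so paralogous genes from one genome can co-occur in a group;
a group is only emitted when its members span at least two genomes.

Two consequences of these definitions are worth knowing. First, at
permissive thresholds (E ≤ 10⁻³ with 10% coverage) a borderline chance hit
between two unrelated proteins occasionally slips through — E ≈ 10⁻³ means
exactly that — and single linkage then merges two families into one group.
The acceptance script reports the exact-recovery rate over ten simulated
genome sets; values slightly below 100% reflect this property of the
thresholds, not a defect of the grouping. Tightening either cut-off removes
such merges. Second, group ids are assigned by the lexicographically
smallest member gene id, so output order is stable across runs and input
orderings.

## Codon-aware consensus

Protein alignments are far more reliable than nucleotide alignments at the
divergence levels typical of phage gene families, but primers are
nucleotides. The pipeline therefore aligns member *proteins* (MAFFT,
default settings) and back-translates each aligned row by substituting
every residue with that member's own original codon and every gap with
`---`. Ungapping any row reproduces the member's coding sequence exactly —
a tested invariant. Terminal stop codons, which the protein alignment never
sees, are re-appended and padded so rows stay rectangular. Users can
substitute a manually curated alignment (aligned FASTA or CLUSTAL); user
rows are taken verbatim with no codon structure assumed.

The consensus is computed at a 100% identity threshold: each column gets
the minimal IUPAC code whose disambiguation set equals the set of observed
bases, and a column is *conserved* only when that set has size one. Any gap
in a column makes the whole column a gap. This is deliberately local: the
region extractor discards gapped spans anyway, and a local rule is easy to
test. Ambiguous input bases (N and friends) widen the column's set and can
never be conserved.

Conserved regions follow an anchor-and-window rule: for each conserved base,
the next 19 columns are scanned; if another conserved base occurs there, the
span to the *furthest* one is emitted with 5 flanking bases on each side.
Unclipped regions are therefore 12–30 nt. The scan restarts at every
conserved base and duplicates are removed, so overlapping regions from
successive anchors are all retained — uniqueness is enforced later at the
level of primer sequences, which is where it matters. Flanks are clipped at
the consensus termini; clipped regions shorter than the minimum primer
length are dropped since no window fits them.

## Thermodynamics

Three melting temperatures are reported per primer, using the standard
published forms:

* **basic**: 2(A+T) + 4(G+C) below 14 nt, else 64.9 + 41·(n_GC − 16.4)/N;
* **salt-adjusted**: the basic rule plus 16.6·log₁₀([Na⁺]/0.05) below
  14 nt, else 81.5 + 16.6·log₁₀[Na⁺] + 0.41·%GC − 675/N;
* **nearest-neighbor**: T_m(K) = 1000·ΔH / (ΔS + R·ln(C_T/4)) with
  R = 1.987 cal·mol⁻¹·K⁻¹, ΔH/ΔS summed over dinucleotide stacks plus two
  terminal initiation terms, converted to °C and corrected by
  +16.6·log₁₀[Na⁺].

The unified NN parameter set ships as a plain TSV
(`inst/extdata/nn_unified_1998.tsv`, ΔH in kcal/mol, ΔS in cal/(mol·K),
ΔG₃₇ in kcal/mol) so that the package implementation and the independent
oracle used in the tests share exactly one parameter source while sharing
no code. Defaults are [Na⁺] = 0.05 M and C_T = 250 nM, both overridable in
`thermo_params()`.

A degenerate primer is a pool, so each Tm is a `[min, mid, max]` triplet.
All three formulas are monotone in GC count, so the pool extremes are
attained by resolving every mixed base towards A/T (preference A > T > C >
G) respectively towards G/C (G > C > A > T); `mid` is the mean of the two.
This deterministic rule was chosen over enumerating the pool because pools
of degeneracy in the hundreds are routine and the extremes are exact under
monotonicity. Free energies go the other way: 3'-end ΔG and self-structure
ΔG take the *most stable* disambiguation (computed exactly by dynamic
programming over the pool, not per-stack bounds), and dimer/hairpin
screening uses "can-pair" semantics — two codes pair if any of their
disambiguations are Watson–Crick complements. All three choices are
conservative: a degenerate pool is screened by its worst member, so no
risky primer is emitted because its risk hides in one disambiguation.

Screening thresholds: GC clamp counts only guaranteed G/C (codes G, C, S)
among the five 3'-terminal bases, at most 3 by default with no minimum
enforced; 3' stability floor ΔG ≥ −9 kcal/mol over the last four stacks,
applied to both primers of a pair; self-dimer, cross-dimer and hairpin runs
must stay below 5 consecutive pairings; hairpin loops need at least 3
unpaired bases, the physical minimum, which the source descriptions leave
unstated. The "minimum ΔG" of a primer's self-structure is reported for
information but not filtered on by default, since no accepted threshold
exists for it; it is the most negative NN ΔG₃₇ over the maximal pairing
runs found by the dimer and hairpin scans. The run scans are implemented in
C++ (`src/screening.cpp`) because they are the inner loop of screening
thousands of windows; the test suite pins them to exhaustive brute-force R
oracles on hundreds of random degenerate sequences.

## Pairing

Feasible pairs require forward start < reverse start (both in consensus
coordinates; reverse candidates store the reverse complement of their
window, so their sequence reads 5'→3' on the opposite strand), a product
size — inclusive of both primer sites — within range, both 3' ends above
the ΔG floor, and a cross-dimer run within the limit. Pairs are ranked by
|ΔTm| (nearest-neighbor midpoints by default), ties by the smaller product
of degeneracies, then coordinates, a total deterministic order. Because a
highly conserved consensus can make the combination space enormous, the
cheap constraints are applied first on plain vectors and the cross-dimer
scan runs lazily in rank order until the requested number of pairs
(default 100) is emitted; as the scan only removes pairs, the output equals
screening everything and truncating. Per-member amplicon lengths are
reported alongside the consensus product size because member-specific
indels shift them.

The recovery guarantee is the design's central property: primers come from
a 100%-identity consensus of the members' own back-translated sequences, so
every disambiguation set at every position contains each member's base, and
`in_silico_recovery()` must find zero mismatches for every member. This is
what distinguishes consensus-of-actual-sequences design from
codon-usage-based consensus design, where reconstructed codons can fail to
match the real genes.

## The simulator

`generate_phage_set()` writes GenBank-format genomes carrying one ortholog
per planted family per genome. Each family has a random ancestral protein
(uniform residues, fixed start methionine, default 250 aa — a typical phage
gene); each lineage substitutes a residue with probability
p = 1 − √(identity), so two orthologs agree at an expected fraction
`identity` of sites, and additionally swaps synonymous codons with
probability 0.5 to add nucleotide-level divergence beyond the protein-level
target. Defaults — 4 genomes, 6 families, 60% amino-acid identity, 40 kb
genomes — mirror a small, diverged podophage-like study set; the realized
pairwise identities land within a few percentage points of the target
(tested at ±10). Intergenic DNA is uniform random; strands are random per
gene. Everything derives from one integer seed and is byte-reproducible.

What the simulator does *not* emulate: codon usage bias, GC skew,
insertions and deletions within families, overlapping genes, mosaic
(recombinant) gene histories, and annotation errors. Passing tests
therefore demonstrate correctness of the algorithms under controlled
homology, not robustness to mis-annotated or recombinant real genomes; the
recovery guarantee, however, holds for any alignment by construction,
including real ones.

## Problem sizes in the test suite

The suite exercises grouping at the default study conditions (4 genomes ×
6 families × 40 kb, ten seeds) and the recovery guarantee on fifty
simulated one-family groups of three genomes (80 aa genes, 4 kb genomes,
primer lengths 16–24, products 80–1000 bp) — sizes chosen so a full run
takes a few minutes while still covering hundreds of emitted pairs and
thousands of candidate windows. Two further checks reproduce a published
eight-genome case study (58 signature gene groups; a primase/helicase
primer pair with an 838 bp product) and require those public genomes to be
downloaded once into `inst/extdata/case_study/`; they fail with an
explanatory message until then, rather than passing vacuously.

## Known limitations

* Grouping quality is bounded by the annotation: no gene prediction is
  attempted, and unannotated genomes are only usable in FASTA + gene-table
  mode.
* The NN model omits mismatch and dangling-end corrections and divalent
  cations; Tm values are standard estimates, not calibrated predictions.
* Degenerate Tm extremes bound the pool but say nothing about its
  distribution; a pool with one extreme member is reported like a balanced
  one.
* In-silico recovery checks the primer sites on the group members only; no
  genome-wide specificity screen (against the rest of each genome, or other
  organisms) is performed.
* GenBank parsing covers the common single-interval and complement
  locations (joins collapse to their outer span) — enough for phage CDS
  records, not the full location grammar.
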