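---
title: "Methods: surveying fungal secretory peroxidase transcripts with peroxscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying fungal secretory peroxidase transcripts with peroxscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peroxscan)
```

`peroxscan` re-implements, as composable R functions, the computational
half of a transcript-level survey of fungal secretory peroxidases in
environmental samples: degenerate-primer amplicon pools are screened in
silico, translated, typed by catalytic residues, dereplicated, tabulated
and placed in bootstrapped neighbor-joining trees. This vignette
explains the models and conventions behind each stage, the defaults and
why they were chosen, what the synthetic-data generator does and does
not emulate, and the package's known limitations.

## In-silico PCR

A degenerate primer is a string over the IUPAC ambiguity codes plus
inosine (`I`). Each code denotes a base set; two positions *match* when
their sets intersect and *mismatch* when they are disjoint. Inosine
base-pairs promiscuously, so it is treated as a universal match (the
same set as `N`); in `expand_degenerate()` inosine positions stay
symbolic (emitted as `N`) and do not multiply the expansion count, which
therefore equals the product of the non-inosine code cardinalities.

`find_sites()` scans both strands ungapped. Two conventions are fixed
here because the wet-lab protocol implies but does not state them:

- **3'-anchor**: the two 3'-terminal primer positions must match
  exactly regardless of the mismatch tolerance. Taq extension requires
  a paired 3' end, and degenerate-primer surveys rely on this to
  suppress spurious products.
- **Default `max_mismatch = 0`**: no annealing tolerance is published
  for these primer sets, so the stringent default is used and the knob
  is exposed.

`amplify()` emits every convergent forward/reverse site combination
whose primer-inclusive length falls in the pair's size window, on the
strand defined by the forward primer. Product sizes are quoted from
gels, which include the primers, hence the primer-inclusive convention;
"~400 bp" and "~210 bp" are realized as windows of 300–500 bp
(class II, DyP) and 150–280 bp (UPO). Overlapping and nested products
are all reported — the size filter, not site pairing, decides.

## Translation and frame choice

Translation uses the standard genetic code only (the templates are
fungal nuclear mRNAs). A codon containing ambiguity codes translates to
a specific amino acid only when *every* concrete expansion encodes the
same residue (`GGN` → `G`), otherwise `X`. This is deliberately
conservative: a residue the data do not determine must not feed the
classifier.

The amplicon's reading frame is the forward primer's frame: these
primers were designed against protein motifs (e.g. the DyP forward
primer encodes `CPFAAHI`), so frame 0 of the product continues the
motif's codons. `choose_frame()` prefers frame 0 when it is free of
internal stops and otherwise falls back to the frame with the fewest
internal stops, which tolerates the occasional indel-bearing clone.

## Anchor mapping and classification

Catalytic positions are specified in **reference-sequence numbering**
(an `anchor_spec` names a reference protein and 1-based positions with
expected residues). Published discussions of these sites often quote
alignment-column numbers, but column numbers are artifacts of one
particular multiple alignment and cannot be reproduced without it;
reference numbering is stable and sufficient, because `map_anchors()`
aligns each query to the reference (global, affine gaps, BLOSUM62, gap
open 10, extend 0.5 — conventional protein-alignment defaults; the
original analysis names ClustalW without parameters) and reads off the
query residue in the anchor's column. Three outcomes are distinguished:
a residue letter, `GAP` (the query is deleted in that column), and
`ABSENT` (the anchor lies outside the aligned span of a partial query).
`GAP` and `ABSENT` both count as "residue not present": a clone that
does not cover the site carries no evidence for it.

Class II typing is the total 2×2 rule on the catalytic tryptophan and
the Mn-binding aspartate: Asp without Trp is MnP-like; Trp without Asp
is an **untypical LiP** — the residue alone cannot place a sequence in
the canonical LiP clade, so the upgrade to a canonical LiP call is
delegated to the phylogeny (a pipeline flag, applied only when the
query clusters inside a user-designated LiP reference clade); both
residues give VP-like (emitted for totality even though environmental
surveys may find none); neither gives GP-like. The Mn-binding anchor
accepts aspartate by default; `accept_glu = TRUE` widens it to any
acidic residue, since the homologous triad in versatile peroxidases is
acidic rather than strictly Asp.

DyP calls record the three H₂O₂-pocket residues (Arg, Leu, Phe in
3MM3-derived numbering) individually plus their conjunction
(`pocket_complete`). UPOs carry no known diagnostic residue in the
amplified region; they are grouped purely by partial-protein length,
66–74 aa (group I.1) versus 80–90 aa (group II), with everything else
`UNASSIGNED`. Both windows are configuration, not code.

`summarize_cohort()` prints integer-rounded percentages *and* their
denominators. Published headline percentages in this field are
ambiguous precisely because the denominator (all analyzed clones vs
DNA-unique vs protein-unique types) is usually implicit; the summary
therefore always states its own.

## Distances, neighbor-joining and bootstrap

Amino-acid distances are pairwise-deletion p-distances with Poisson
correction, *d* = −ln(1 − *p*), in substitutions per site (uniform
rates). Pairs sharing no gap-free column, or with *p* at or beyond a
saturation guard of 0.99, are flagged `UNDEFINED`; `nj_tree()` refuses
such matrices with a clear error rather than silently capping the
distance, so saturation surfaces instead of distorting topology.

`nj_tree()` is a from-scratch Saitou–Nei implementation with two
conventions stated explicitly because the method description leaves
them open: ties in the Q-criterion break to the lowest index pair, and
negative branch-length estimates clamp to 0. On additive matrices the
generating topology and all path lengths are recovered exactly (this is
asserted to 1e−9 in the tests, and the independent `ape::nj`
implementation serves as a cross-check oracle on random additive
matrices — it is never used as the implementation).

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the tree per replicate, and attaches to each internal edge of
the *original* tree the percentage of replicate trees containing the
same bipartition (supports annotate the reported tree, not a consensus).
Replicates whose resampled matrix contains undefined distances are
dropped from the denominator and counted in an attribute. 1,000
replicates with a 50% display threshold is the conventional setting;
the threshold is applied only at Newick rendering time.

## The synthetic-data generator

`generate_pools()` produces amplicon pools whose every record has a
known truth, emulating the structure of a real multi-site survey:

- **Reference panels are homologous.** Each family has a random
  scaffold protein; panel references are scaffold copies substituted at
  a per-residue divergence (default 0.12, a plausible within-family
  spread that keeps alignments unambiguous while making references
  clearly distinct). Catalytic residues are implanted at fixed
  positions in this synthetic numbering — deliberately decoupled from
  the real 171/175/329/354/356 coordinates, which belong to database
  proteins that are not reproduced here.
- **Amplicons carry real primer footprints.** A concrete, stop-free
  expansion of the forward primer plus one pad base (20 + 1 nt) keeps
  the core codons in frame 0; the reverse-complemented reverse-primer
  expansion closes the product. Translated lengths follow the published
  ranges — UPO group I.1 66–74 aa, group II 80–90 aa, DyP 128–144 aa,
  class II ~126–136 aa — which lands the products at ~210 bp (UPO) and
  ~400 bp (class II, DyP), inside the shipped size windows.
- **Environmental variants** are references mutated per nucleotide
  (default 2%, a modest divergence between environmental alleles and
  their nearest reference), with primer footprints and anchor codons
  preserved so the intended label remains the record's truth; indels
  are single whole codons (frame-preserving) and are suppressed when
  they would push a record out of its family's length window.
- **Duplicates and decoys.** A configurable fraction of records copies
  an earlier record — exactly, or as a synonymous re-encoding (same
  protein, freshly drawn codons), which reproduces the survey pattern
  of more unique DNA types than unique protein types. Decoys are random
  sequences verified to contain no primer site. Class II label mixes
  default to an MnP-dominated cohort with small untypical-LiP and GP
  fractions and no VP; DyP pocket residues are present with
  probabilities 0.98/0.98/0.91; UPO references split 0.8/0.2 between
  groups I.1 and II — all following the fractions such surveys report.

Everything is deterministic under the config seed, to the byte.

What the generator does **not** emulate: sequencing error (Sanger
clones are assumed clean), chimeric amplicons, codon-usage bias
(back-translation is uniform over synonymous codons), compositional
heterogeneity across sites, and real family phylogenetic depth (one
scaffold per family, not a gene tree). Passing tests on synthetic pools
therefore demonstrate the correctness of the pipeline's logic — primer
matching, frame handling, anchor mapping, rule tables, bookkeeping —
not the biological sensitivity of the primers or classifiers on real
environmental diversity.

## Numerical and interface conventions

- Coordinates are 1-based inclusive (the R/Bioconductor convention);
  `end − start + 1` equals the length.
- `U` is normalized to `T` on ingest (templates are cDNA); FASTA is
  written 60 columns wide, ids read to the first whitespace.
- Pairwise alignment delegates to `Biostrings::pairwiseAlignment`;
  percent identity counts identical gap-free columns over gap-free
  columns, which confines the comparison to the aligned overlap — the
  right convention for partial amplicons against full-length
  references. Best-reference ties break lexicographically by id.
- The progressive aligner builds an NJ guide tree from pairwise
  p-distances and merges profiles in agglomeration order with
  affine-gap profile–profile alignment (average-of-pairs BLOSUM62
  column scores). It is a minimal aligner for amplicon-scale inputs,
  not a general MSA engine.
- Activity conversion: one unit converts 1 µmol substrate per minute.
  The slope (ΔA min⁻¹) becomes a molar rate via ε and the path length,
  is scaled to the assay volume, from the aliquot to the whole extract,
  and normalized per gram dry matter. The dry-matter fraction is an
  explicit input (assays report per g DM but the extraction itself does
  not measure moisture); the default 1.0 means "per g fresh weight"
  and warns. Negative Mn-independent activities after laccase
  subtraction clamp to 0 with a flag, since negative activity is
  physically meaningless yet the subtraction can produce it.

## Problem sizes and determinism

The shipped tests and the acceptance script run the pipeline at
deliberately small scale — two to three sites, pools of 4–10 records
per family, bootstrap 10–1,000 replicates on 4-taxon alignments —
chosen so that the full suite exercises every stage, including two
complete pipeline runs compared byte for byte, in a couple of minutes.
All stochastic steps (simulation, bootstrap) consume seeds derived from
a single master seed; identical configuration reproduces identical
output files, and the run manifest records seed, parameters, package
version and per-file checksums.

## Known limitations

- No local (Smith–Waterman) alignment mode; queries are assumed to be
  amplicons of the targeted region, not arbitrary fragments.
- The untypical-LiP → canonical-LiP upgrade requires a user-designated
  reference clade; the package does not decide clade membership
  semantics itself.
- `UNDEFINED` distances abort tree building by design; extremely
  diverged pools need manual subsetting.
- The progressive aligner has no iterative refinement; for large or
  deeply diverged protein sets a dedicated MSA tool should be used and
  its aligned FASTA fed to the distance/tree functions directly.
- Richness tables map class II labels to the reporting vocabulary
  ("MnP short/unclassified", "MnP long", ...); separating short from
  long MnPs is a clade-level distinction that residue rules cannot
  make, so all MnP-like calls count as "MnP short/unclassified" unless
  the user relabels them from tree positions.
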