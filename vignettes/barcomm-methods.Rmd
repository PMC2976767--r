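---
title: "Methods: constrained barcode supermatrix phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained barcode supermatrix phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the models, algorithms and numerical choices behind
`barcomm`, in the spirit of a methods supplement: what is computed, under
which assumptions, and where a design was genuinely open, why it was
settled the way it was.

## The problem and the model

Given per-species sequences for up to three plastid barcode loci
(*rbcLa*, *matK*, *trnH-psbA*), a community taxonomy
(species → genus → family → order) and a reference order-level topology,
the package estimates a species-level phylogeny by maximum parsimony (MP)
on a concatenated supermatrix, **constrained** so that every retained tree
refines the ordinal backbone: the arrangement of orders is fixed a
priori, while relationships *within* orders are left to the sequence
data. This hybridises two traditions — supermatrix barcode phylogenetics,
which resolves shallow nodes well but can misplace deep lineages when
taxon sampling is sparse, and classification-derived trees, which get the
deep structure right but little else.

MP was chosen over likelihood deliberately: with barcode-scale data
(~0.5–0.8 kb per locus) and severe missingness at two of three loci,
parsimony with the full matrix in every addition replicate uses the data
more efficiently than bootstrapped likelihood searches, and the constraint
removes parsimony's main liability (long-branch misplacement of deep
lineages).

## Alignment strategies

Each locus gets the treatment its evolution warrants:

- **Global (rbcLa-like).** Coding, indel-free: one progressive alignment
  over all species. On equal-length indel-free input the optimum is the
  trivial stack with zero gap columns.
- **Back-translation (matK-like).** The reading frame of each sequence is
  the offset (0/1/2) minimising internal stop codons, ties to the lowest
  offset. Sequences whose best frame still exceeds 5% internal stops are
  excluded with a logged reason (a real *matK* read at plausible
  divergence stays far below this; crossing it signals a non-coding or
  frame-broken read). Translation uses the standard code; codons
  containing ambiguity translate to `X`, which aligns as a wildcard
  (score 0 against everything). Protein-level gaps map back onto
  nucleotides in whole codons; frame-offset flanks are padded with `?` so
  the block length is a multiple of three and no input base is lost.
- **Taxonomically partitioned (trnH-psbA-like).** The spacer is
  unalignable across distant families, so records are grouped by family
  (or order) and aligned within groups only. A group with a single
  species is omitted: a lone spacer sequence aligns with nothing and
  carries no comparative signal.

The progressive aligner itself is pairwise Needleman–Wunsch with affine
gaps (match +1, mismatch −1, gap open −2, extend −1; a length-*L* gap
costs *L*+1) generalised to frequency profiles, merged along a UPGMA
guide tree on 8-mer Jaccard distances. Gap penalties against a profile
column scale with its occupancy, so columns that are already mostly gaps
are cheap to gap again. Input order never matters: sequences are
processed in name order and the guide tree is deterministic. An external
aligner can be substituted by supplying pre-aligned blocks via
`new_alignment()`.

## Supermatrix and missing data

Blocks concatenate over the species union; absent cells are `?`. Both
`?` and `-` score as missing downstream — gaps are never coded as
characters. A species whose only data lie in partitioned spacer blocks is
excluded from the matrix: a family-local alignment fragment cannot place
a species against the rest of the community. One refinement: when *no*
global block exists at all (a spacer-only analysis, which is a legitimate
single-locus design), the rule would empty the matrix, so in that case
all species with data are kept. Internal coordinates are 0-based
half-open; NEXUS `charset` export converts to 1-based inclusive.

## Parsimony scoring

Tree length is the minimum number of substitutions summed over columns:
Fitch counting at binary nodes, Hartigan's generalisation at polytomies
(a hard polytomy is scored as such, not as its best resolution), with
IUPAC codes as partial state sets and `?`/`-` as the full set. The
scoring kernel (C++) receives site patterns with multiplicities. Patterns
whose cost is provably identical on every topology — all entries pure
bases or fully missing, and at most one state shared by two or more taxa
— contribute a closed-form constant (number of observed states minus
one) and are removed from the kernel; this is exact, not an
approximation, and typically removes a third to a half of the patterns
of a barcode supermatrix. Reported scores always include the constant.

## Constrained ratchet search

The constraint tree replaces each backbone tip by a polytomy of that
order's included species; orders without species are pruned.
Compatibility is defined on rooted clades: a candidate is admissible iff
every non-trivial constraint clade is a clade of the candidate. Rooted
semantics were chosen because the backbone supplies the root; it is also
the stricter reading, so nothing incompatible under the unrooted reading
is ever admitted.

The search is a classic parsimony ratchet:

1. A seeded random-addition tree: taxa in random order, each inserted at
   the compatible position of minimum length.
2. Hill-climbing over the SPR neighbourhood (which contains all NNI on a
   rooted binary tree), first-improvement, until a local optimum.
3. Per ratchet iteration, a random 25% of columns (`perturb_fraction`)
   are doubled in weight (`perturb_weight = 2`), the tree is re-optimised
   under the perturbed weights, then under the original weights; the
   result is accepted when not worse. Defaults (200 addition replicates,
   50 iterations) follow the published ratchet scheme; desk-scale
   analyses in the tests and acceptance script use 1–4 replicates and
   2–5 iterations, which already attain the exhaustive optimum on ≥95%
   of seeded 8-taxon instances.
4. All distinct trees at the best score are pooled (deduplicated by clade
   set), capped at `max_retained` (default 10,000) with first-found
   retention, since equally-parsimonious tree counts can explode.

Hill-climbing is exact-incremental: for each pruned subtree the remaining
tree's unit-cost Sankoff *down* and *context* vectors are computed once,
after which every regraft target is scored in O(4) per pattern; unit-cost
Sankoff equals Fitch counts on binary trees, and candidate moves are
restricted to the smallest constraint clade properly containing the
pruned tips (moves outside it cannot remain compatible) with a full
refinement check before acceptance. Every stochastic step draws from an
explicit seed; the same configuration reproduces the same trees byte for
byte.

## Consensus and supports

The 50% majority-rule consensus keeps clades with frequency strictly
above the threshold among the pooled equally-most-parsimonious trees;
node support is `round(100 × frequency)`. An extended variant
(`extended = TRUE`) greedily adds compatible minority clades by
descending frequency, and is off by default. Support is therefore *clade
frequency among retained MP trees*; a resampling-based ratchet support
(re-running the whole search per pseudo-replicate) was considered and
rejected as out of desk scale — the frequency estimator is the one
interpretation consistent with "support quantified on the majority-rule
tree of the ratchet's tree set".

## Evaluation metrics

- **Resolution** of a rooted tree with *n* tips and *I* internal nodes
  (root included) is `100·(I−1)/(n−2)`: 100 for fully binary, 0 for a
  star. No formula is canonical in the literature; this one is stated
  prominently because reported resolution percentages depend on it. The
  root is counted in *I* but is not a scored node for support bins.
- **Support bins** reproduce the conventional overlapping cumulative
  layout: `<50`, `≥50`, `[50,70)`, `≥70`, `[70,85)`, `≥85`, as
  percentages of scored internal nodes, so `<50 + >50 = 100` and
  `50–70 + >70 = >50` within rounding.
- **Monophyly**: a taxon is monophyletic iff the smallest clade
  containing all its tips contains no others; singletons are reported as
  such (trivially monophyletic).
- **Misplaced orders**: the species tree is contracted to one tip per
  order — monophyletic orders collapse to a tip; a non-monophyletic order
  is represented by the tip nearest its MRCA (fewest edges, ties
  alphabetical) and flagged inherently misplaced. The count is the
  complement of the maximum-cardinality order subset whose induced
  topologies agree with the backbone: exhaustive up to 12 orders, a
  seeded greedy removal/re-insertion heuristic with restarts beyond.
  The heuristic can overcount by missing a larger agreeing subset; it
  never undercounts below the true value on the exhaustive range.

## Barcode identification

Leave-one-out at the sequence level: each sequence queries all other
sequences of its marker; the match kernel is global alignment identity
over the shorter sequence (Biostrings `pid` type PID3), a deliberate
self-contained substitute for BLAST local alignment (an external BLAST
backend can be slotted in by replacing the kernel). A query is correct at
a rank iff *all* tied best hits share its taxon at that rank — ties
spanning species are species-level failures, the conservative and
deterministic convention. When a species has a single sequence it cannot
be species-correct (no conspecific exists to hit) but can still be
correct at coarser ranks; CI frequencies from single-sequence designs are
therefore lower bounds. Recovery×CI multiplies the recovery proportion by
CI and reports an integer percent, half away from zero.

## The simulator

`simulate_truth()` builds nested Yule-shaped trees per rank and glues
them so that order stems are deepest: with total height *H* (default
0.15 expected substitutions/site at the base rate), order crowns start at
0.55 *H*, family crowns at 0.30 *H*, genus crowns at 0.12 *H*. These
fractions make within-genus divergence ~1–2% at *rbcLa* rates and
order-level divergence ~10–20% at spacer rates, the ranges reported for
real plastid barcodes. Per-locus defaults: *rbcLa* 520 bp, JC69, rate
scale 0.6, no indels; *trnH-psbA* 450 bp, K2P (κ=2), rate 2.5, indels at
0.2 events per 100 sites per unit branch length with geometric lengths
(mean 2); *matK* 800 bp, K2P, rate 1.5. Substitutions use exact
transition probabilities (matrix exponential of the normalised rate
matrix) per branch. Roots of coding loci are drawn from sense codons in
frame 0 — a uniform root is ~5% stop codons in every frame, which would
defeat frame detection and corrupt the back-translation alignment.
Default dropout probabilities (0.10 / 0.08 / 0.30 for
rbcLa / trnH-psbA / matK) mirror typical per-species recovery failure
rates in plot-scale barcoding.

Discordance injection regrafts species from *monotypic* genera into a
foreign genus (same family preferred), at the midpoint of a random
member's terminal edge: each move renders exactly one genus
non-monophyletic, so `monophyly_report()` on the true tree matches the
injected count exactly. Donors are restricted to monotypic genera
because moving a species out of a larger genus would break two genera
per move and the count contract would be lost; configurations without
enough monotypic genera raise an error rather than silently changing the
contract.

What the simulator does **not** emulate: rate heterogeneity across sites
(no Γ), codon models, coalescent gene-tree discordance, sequencing error,
or partial reads. Passing the simulation-recovery tests therefore shows
that the pipeline recovers clean, clock-like signal under the stated
models — not that it is robust to every pathology of real chromatogram
data.

## Problem sizes and numerical conventions

The test suite verifies parsimony against an independent implementation
(phangorn) and exhaustive enumeration on 5–6 taxa (105/945 rooted
shapes, 100 seeded 20-column matrices), constrained-search optimality on
100 seeded 8-taxon two-order instances (225-tree constrained exhaustive
reference), and end-to-end recovery on ten seeded 60-species
communities (5 orders / 10 families / 20 genera, three loci, no
dropout), requiring ≥90% of true within-order clades in the constrained
consensus and zero misplaced orders. These sizes were chosen as the
smallest at which each property is non-trivially exercised.

Conventions worth knowing: ties in representative selection go to the
lexicographically smallest sample id; ties in frame selection to the
lowest offset; hill-climb improvements require a strict decrease (ties
never move, making termination certain); consensus thresholds are strict
(`frequency > 0.5`); percentages in recovery tables are rounded to one
decimal, Recovery×CI to integer percent half-away-from-zero; all
internal randomness flows from explicit integer seeds and never touches
the caller's RNG state.

## Known limitations

- TBR rearrangements are not implemented (NNI+SPR only); on highly
  homoplastic matrices the search can need more replicates to reach the
  optimum.
- The misplaced-order heuristic above 12 orders is approximate (exact
  below).
- The identification kernel is global identity, not BLAST; on length-
  variable spacers with large indels the two can rank hits differently.
- The supermatrix keeps IUPAC ambiguity as state sets but the simulator
  never generates ambiguity codes, so that path is exercised only by
  hand-built cases in the tests.
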