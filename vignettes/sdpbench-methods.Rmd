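---
title: "Methods: temporal benchmarking of functional-residue detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal benchmarking of functional-residue detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpbench)
```

## The question

Columns of a protein multiple sequence alignment (MSA) carry two classic
signals of functional importance: *full conservation* (a single residue type
tolerated by evolution) and *family-dependent conservation* — positions that
are conserved within functional subfamilies but differ between them, the
so-called specificity-determining positions (SDPs). Both are routinely used
to predict functional sites from sequence alone. Because public sequence
databases grow exponentially, a natural question is how that growth changes
what these detectors would have reported at different points in time.

`sdpbench` rebuilds the machinery needed to study this question at desk
scale: date-stamped *historical snapshots* of a family's MSA, five
sequence-based detectors, a structural evaluation statistic, and a
synthetic-family generator with planted ground truth so that every stage of
the pipeline can be verified without touching live databases. Real-data
retrieval (homolog searches, alignment, structure and binding-site lookup)
enters only through adapter interfaces: the pipeline consumes any aligned
FASTA plus a per-sequence date table, and a coordinate file plus binding
list.

## Historical snapshots

A *snapshot at year y* keeps exactly the sequences whose publication year is
at most *y* (`snapshot_at()`). Snapshots are therefore nested across years
by construction. Each snapshot is then made non-redundant
(`remove_redundancy()`): a greedy keep-first sweep in date order (ties by
sequence id) retains a sequence iff its identity to every previously kept
sequence is at most 0.95. Greedy keep-first is deterministic and the
standard practice where the filtering algorithm is not otherwise specified;
because the sweep order is the date order, snapshots of different years are
mutually consistent. Pairwise identity over a gapped alignment is defined as
identities divided by the number of columns where at least one of the two
sequences has a residue; gap-against-residue counts as a mismatch and
double-gap columns are excluded. This convention is stated so the filter is
bit-stable and testable.

Only snapshots with at least 15 sequences after redundancy removal are
*workable* (`workable()`); 10 is the conventional alternative threshold and
both are exposed in `benchmark_config()`. The default year grid is 1994 to
2014 in steps of two years.

One point was genuinely open: whether the identity filter should run before
or after the date restriction when retrieval order varies. We fix
date-ordered greedy filtering inside each snapshot; the alternative (filter
once at the final year, then subset) yields snapshots that are not
self-contained non-redundant sets and was rejected.

## The five detectors

All methods share one gap policy: the gap character is a 21st symbol for
entropy purposes, and any column with more than 50% gaps is *unscorable* —
reported with a missing score, never silently dropped.

**Fully conserved positions** (`conserved_positions()`). A column is
selected iff its non-gap residues are a single type *and* its gap fraction
is at most 10% (a column of one residue plus many gaps is not "fully
conserved"). The reported score is the 21-symbol Shannon entropy in bits;
selection corresponds to entropy zero after the gap cap.

**Xdet-like matrix correlation** (`xdet_scores()`). For each column, the
matrix of BLOSUM62 similarities between the residues of every sequence pair
at that column is compared with the matrix of overall sequence similarities
(mean BLOSUM62 score over shared non-gap columns) by Spearman rank
correlation with average-rank tie handling, over the upper-triangle pairs
where both are defined; pairs with a gap at the column are excluded. Columns
with correlation at or above 0.8 are selected. BLOSUM62 is a configurable
default; the method's description requires only "a standard substitution
matrix".

A structural property of this statistic is worth recording, because it
shapes every benchmark built on planted signals: for an idealized two-block
SDP (one residue per lineage) the positional matrix collapses into a few
exact tie blocks while the sequence-similarity matrix is effectively
continuous, so the Spearman correlation cannot exceed roughly
`sqrt(0.75) ~ 0.86` — the fraction of rank variance carried by the
within/between split — and whether a given column lands above or below 0.8
depends on luck in the ordering of the two residues' BLOSUM diagonals
relative to the lineage similarities. The 0.8 threshold therefore sits just
below the statistic's ceiling, and recall of planted SDPs at that threshold
is intrinsically volatile from family to family even under the strongest
clean signal, while precision stays high. This is a property of
rank-correlating a discrete pattern against a continuous one, not an
implementation artifact; the test suite asserts the oracle equivalence of
the correlation itself to 1e-12.

**Evolutionary-Trace-like ranks** (`et_scores()`). A neighbor-joining tree
is estimated from `1 - identity` distances and midpoint-rooted
(`build_tree()`); this replaces the original guide-tree dependence with a
deterministic, dependency-free construction, which suffices because the
benchmark only requires clade recovery on strongly separated subfamilies.
Cut levels are derived by splitting internal nodes in order of increasing
distance from the root (ties broken parents-first in traversal order):
level 1 is one group, level *l* has *l* groups, level *N* is all
singletons. The score of a column is the smallest level at which the column
is invariant (a single non-gap residue type; all-gap groups vacuously
invariant) within every group. Rank 1 is exactly full conservation; columns
with rank at most 2.0 are selected. We use the original integer-rank
formulation rather than later real-valued variants, which is the
formulation consistent with a "score 2.0 or better (lower)" selection rule.
Because the root level renders the fully conserved positions and those are
not SDPs, the *SDP set* of this method excludes rank-1 columns
(`selected_columns(tab, sdp_only = TRUE)`), while the score table's
`selected` flag remains the literal threshold comparison.

**TEA-O-like two-entropies score** (`teao_scores()`). For each column,
`H_global` is the 21-symbol entropy normalized by `log2(21)`, and
`H_within` is the mean over levels 2..N of the mean normalized within-group
entropy at that level. The score is the Euclidean distance from
`(H_global, H_within)` to the ideal SDP corner `(1, 0)`, scaled by
`1/sqrt(2)` into [0, 1]; columns scoring at most 0.3 are selected. The
corner-distance consensus is a reconstruction — the method's published
description names the two entropies and the 0.3 threshold but not the exact
consensus formula — so threshold semantics may differ from the original
tool. Two consequences follow directly from the normalization: a fully
conserved column scores exactly `1/sqrt(2) ~ 0.707`, and a score of 0.3 or
less requires `H_global >= 1 - 0.3*sqrt(2) ~ 0.58`, i.e. at least ~2.5 bits
of global diversity. Columns with a handful of residue types (the planted
SDPs of the generator) can never qualify, whereas highly scrambled columns
with low within-group entropy at deep levels can. Under the synthetic study
conditions this method therefore selects diffuse high-entropy columns far
from the binding pocket — an emergent behaviour consistent with this
method's published role as the outlier of the five.

**S3det-like correspondence analysis** (`s3det_like()`). The MSA is coded
as a binary sequence-by-(column, residue) indicator table (gap is not a
category; degenerate columns are left out) and decomposed by correspondence
analysis — the SVD of the standardized-residual matrix. Axes whose inertia
(squared singular value) exceeds the mean inertia are retained; retaining
by raw singular value instead keeps near-noise axes whose within-subfamily
scatter misleads the cluster-number selection, which is why the inertia
rule was adopted. Sequence coordinates on the retained axes are clustered
with k-means (10 restarts) for candidate counts 2..min(10, N-1); the count
with the highest mean silhouette wins, ties toward fewer clusters, and a
single cluster is reported when the best silhouette is below 0.25. Each
column is scored by the adjusted Rand index between the partition its
residues induce on the sequences (gapped sequences excluded) and the
*majority-residue coarsening* of the detected clusters — the coarsest
cluster-respecting reconstruction of the column. This lets a column whose
specificity divergence sits at a deeper split than the detected granularity
(e.g. one residue per basal lineage in a four-subfamily family) still score
1, while columns uncorrelated with the detected structure score near 0.
Columns scoring at least 0.8 are selected. The original tool's axis-count
and cluster-number procedure is unpublished in detail; the inertia,
silhouette and coarsening-ARI rules are this package's stated substitutes.

## Structural evaluation

Predictions are scored against a representative structure by the *relative
distance* statistic: the mean distance of the predicted residues to the
binding sites, divided by the mean distance of all residues to the same
sites (`relative_distance()`). Values below 1 mean the prediction is closer
to the binding region than chance. The residue-to-sites distance is the
minimum Euclidean distance to any binding residue's representative point —
the published definition averages "distance to the annotated binding
sites" without fixing the residue-to-site rule, and minimum-to-nearest is
the standard convention; averaging over all binding residues instead would
shift both numerator and denominator and is noted as the alternative.
Selections that map to no structure residue yield a missing ratio with
explicit n, never an imputed value. Per-year distributions are summarized
by five-number summaries with linear-interpolation quartiles
(`summarize_distribution()`), the convention fixed because boxplot figures
do not state one. Temporal series are reported relative to a reference year
(default 2014, `relative_series()`).

## The synthetic generator and its study conditions

The generator plants exactly the signals the detectors claim to find, under
conditions chosen once and used everywhere (tests, acceptance checks,
worked examples):

* **Tree** (`simulate_tree()`): four subfamilies of eight sequences.
  Subfamilies are star radiations — every leaf on a pendant branch of
  length 0.25 — because coalescent-shaped clades contain internal subclades
  that make the notion of "the" subfamily partition ill-defined for
  cluster-recovery tests. The between-subfamily backbone is a balanced
  hierarchy of depth 6.0 whose non-root splits sit at 70% of the remaining
  depth, so the deepest divergence is the root split: two basal lineages of
  two subfamilies each. Branch lengths are in expected substitutions per
  site at rate 1.
* **Site classes** (`site_class_profile()`, `evolve_family()`): 10 fully
  conserved columns, 10 SDPs, 180 neutral columns of 200. Neutral columns
  evolve by a uniform-replacement process (substitution events at rate 1.0
  per unit branch length, new residue uniform over 20); signal strength is
  controlled entirely by rate and depths, which is what the tests need — an
  empirical exchange matrix would add realism but no testable signal. At
  these depths neutral columns are scrambled between lineages (protecting
  the conservation detector from chance-conserved columns: the expected
  number of spuriously constant columns across a 20-family batch is well
  below one) while retaining within-subfamily coherence, so a realistic
  fraction of neutral columns are genuine subfamily markers. The default
  SDP flavour plants the residue change on the deepest split — one residue
  per basal lineage, constant within each subfamily — the classic pattern
  of specificity arising at an ancient duplication, and the pattern that a
  level-2 tree cut (ET rank 2) can recover; `sdp_residue_groups =
  "per-subfamily"` instead gives every subfamily its own residue. A second
  flavour, conserved-in-one-subfamily-only, is available per column.
* **Dates** (`assign_dates()`): publication years are i.i.d. draws from the
  geometric year distribution of an `accumulation_model()` (default growth
  1.4 per year over 1994-2014, roughly the observed growth of the protein
  databases), so cumulative counts are exponential in expectation and hit
  `n_final` exactly at the end year. Years are paired to sequences by
  similarity to an anchor sequence perturbed by noise (*discovery bias*,
  default strength 1.5): early database content clustered around
  well-studied organisms, and it is precisely this bias that makes early
  small alignments over-conserved — the phenomenon behind the several-fold
  excess of conserved positions in early-1990s snapshots. With unbiased
  pairing an early 15-sequence subset spans all subfamilies and shows no
  excess.
* **Redundancy** (`simulate_benchmark_data(redundancy_fraction = 0.15)`):
  15% of sequences get a near-clone (2% of neutral columns mutated, dated
  no earlier than the source), so the 95% filter has realistic work to do;
  clone mutations avoid planted columns so ground truth is preserved.
* **Structure** (`synth_structure()`): one representative point per column
  (a stand-in for the C-alpha; the published evaluation never names the
  atom). Binding columns sit inside a pocket of radius 5 Angstrom, near
  columns within 1.5 pocket radii of its centroid, and all other columns on
  a self-avoiding random walk kept at least 3 pocket radii away. In the
  bundled dataset the pocket is made of half the conserved columns and the
  near shell holds the SDPs plus the other conserved columns, encoding the
  biological expectation that catalytic/binding residues are conserved and
  specificity residues line the pocket's rim.

What the generator does *not* emulate: insertions and deletions (alignments
are generated aligned; gaps can only be injected synthetically), rate
heterogeneity across neutral sites, empirical amino-acid exchangeabilities,
database-side biases other than discovery order, and any correlation
between structural geometry and sequence evolution beyond the planted
placement. Passing tests therefore demonstrate that the implementations
recover planted signals under clean conditions and agree with independent
oracles — not that the methods perform at any particular level on real
families.

## Numerical choices and degenerate inputs

* Columns are 1-based everywhere, including the TSV outputs; structure
  residue numbering is 1-based (PDB convention).
* Entropy uses base-2 logs over 21 symbols; `0 * log(0)` terms are dropped.
* NJ trees occasionally carry tiny negative branch lengths; these are
  clamped to zero before midpoint rooting. Node-depth ties in the cut order
  are broken parents-first, then by traversal order, keeping the removed
  set ancestor-closed.
* Spearman correlations require at least 3 defined pairs and non-constant
  vectors; otherwise the column is unscorable.
* k-means uses a fixed seed from `benchmark_config(seed = )`; silhouette
  improvements below 1e-9 count as ties and keep the smaller count.
* An empty snapshot is valid (size 0); `workable()` gates analysis, and
  unworkable family-years appear in the records with missing values and
  explicit provenance counts rather than being dropped.
* Five-number summaries drop missing values and report the remaining n.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
families of 32 sequences by 200 columns: 20-family batches for
parameter-recovery checks, 50 families for the distance-discrimination
summary, 100 random structures for the normalization identity, and
oracle-equivalence suites of 50 small alignments (up to 8 sequences) plus
trees up to 12 leaves. These sizes were chosen as the smallest at which the
planted-signal regime is unambiguous; the pipeline itself has no hard-coded
size assumptions beyond the workability gate.

## Known limitations

* The Spearman ceiling discussed above makes threshold-based recall of the
  matrix-correlation method volatile near 0.8 under block-structured
  signals; its precision is unaffected.
* The TEA-O-like score's 0-0.3 selection band, combined with the 21-symbol
  normalization, is unreachable for low-diversity SDPs; whether the
  original tool's internal scaling behaves identically is unknown.
* The S3det-like cluster-number rule inherits silhouette's preference for
  compact, well-separated groups; families with genuinely hierarchical
  subfamily structure admit several defensible answers, and the detected
  granularity is whichever maximizes silhouette.
* Greedy keep-first redundancy removal is order-dependent in principle;
  monotone coverage along the timeline is guaranteed only for
  pre-redundancy snapshots and holds for post-redundancy counts as a
  statistical regularity, not a theorem.
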