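---
title: "Methods: comparative gene-content analysis with gcdollo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative gene-content analysis with gcdollo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcdollo)
```

## Scope

`gcdollo` implements a comparative gene-content pipeline of the kind used to
study metabolic reduction in euglenozoan protists (diplonemids, euglenids,
kinetoplastids): per-species KEGG Orthology (KO) annotation tables are turned
into a binary species-by-KO presence/absence matrix; gains and losses of each
KO are mapped onto a rooted species phylogeny by Dollo parsimony; repertoires
are compared across species groups (exclusive intersections, a convergent-loss
screen, unpaired t tests on repertoire sizes); species are embedded in 2D/3D
from pairwise Hamming distances with a seed-stability protocol; and
sequence-level candidate filters (taxonomic best-hit decontamination,
E-value/p-distance/splice-leader/domain-extension acceptance rules, and
centromeric-histone classification) reproduce the rule-based screens used for
divergent homologs. A synthetic-data module generates inputs with known truth
so every stage can be validated without any external sequence data.

The pipeline consumes the *outputs* of annotation and homology-search tools
(BlastKOALA-style KO tables, tabular BLAST/HMMER hits, alignments, Newick
trees); running those tools is out of scope.

## Presence/absence matrices

A cell is 1 iff at least one protein of the species was assigned the KO;
duplicate assignments collapse, so the construction is idempotent under record
duplication and row order. Each species carries a data-source flag
(`genome`/`transcriptome`) because absence from a transcriptome is weaker
evidence than absence from a genome; the flag is carried through the TSV
round-trip and drives the dropout generator.

KO-to-category maps are supplied as a two-column TSV (`ko`, semicolon path)
derived from a BRITE flat export; nothing is fetched online. A KO mapping to
several BRITE paths is counted **once per top-level category** (the level
below "Metabolism", e.g. "Amino acid metabolism") in category summaries. This
is a documented design choice: counting once per KO total would understate
categories for multifunctional enzymes, and the summaries here are per
category anyway.

## Group-level presence and repertoire statistics

A feature is present in a group when found in at least `min_present` member
species (default 2; 1 is appropriate for very small groups such as
Prokinetoplastina with its two free-living representatives plus
*Perkinsela*). Exclusive intersections follow UpSet semantics: each feature
present in at least one group contributes to exactly one subset — the exact
set of groups where it is present — so subset counts always sum to the number
of features present anywhere. Features present in zero groups are retained in
the matrix but excluded from intersection totals.

The convergent-loss screen returns features absent from *every* species of
both target lineages while present in at least `min_background = 3`
background species, the rule used to flag losses shared by kinetoplastids and
ciliates against a panel of free-living heterotrophic protists.

For repertoire-size comparisons, "unpaired t test" is read classically as
Student's pooled-variance test (the package default); Welch's correction is
available by flag and the choice is recorded in the output. No adjustment is
made for genome vs transcriptome completeness — the counts are of *unique*
KOs precisely to mitigate that difference — but the source flag is carried so
users can stratify. When both samples are constant the degenerate case is
handled in closed form (t = 0, p = 1 for equal means) because the standard
test refuses constant data. No multiple-testing correction is applied across
group comparisons.

## Dollo parsimony mapping

Dollo parsimony models a gene as gained at most once and lost arbitrarily
often. For a feature present in leaf set P, the unique minimum-loss
single-gain reconstruction places the gain at MRCA(P) and the losses at the
roots of the maximal subtrees below the gain that contain no presence leaf; a
branch is identified by its child node. `reconstruct_dollo()` computes this
directly from per-node presence-leaf counts; `dollo_brute_force()` is an
independent exhaustive search over all (gain node, loss set) scenarios used
to verify it — the two agree on every one of the 64 presence patterns of a
6-leaf tree.

**Outgroup handling.** The default mirrors gene-content software practice:
the outgroup is an ordinary leaf, and features whose inferred gain is the
root can be reported separately (their polarity is not resolved by the
ingroup). An "ambiguous-absence" analysis can instead be approximated by
excluding transcriptome-flagged species from a feature's reconstruction; by
default transcriptome absences are treated as absences, as unique-KO counting
effectively does.

**Identifiability.** Inference can only recover the *canonical* minimum-loss
representation of a pattern. If both leaves of a cherry lose a gene
independently, parsimony necessarily merges the two events into one loss on
the parent branch; if a leaf attached at the origin loses the gene, the
surviving MRCA is lower than the true origin. Simulations confirm both
directions of the sharp statement: on every feature whose simulated truth is
its own canonical form, recovery is exact, and on the rest the inference
explains the same leaf pattern with no more events than the truth. The
inferred gain is always a descendant-or-equal of the true origin (losses can
only pull the MRCA down), which the suite checks under internal-branch
losses.

## Hamming-distance embedding and seed stability

Distances are normalized Hamming (fraction of differing coordinates), which
on binary vectors equals squared Euclidean divided by the number of features
— the reason Euclidean and Hamming orderings behave similarly on such data,
with Hamming the natural choice. Embedding delegates to the UMAP
implementation in `uwot` with a precomputed distance matrix, single-threaded
and seeded, so a fixed seed reproduces coordinates bit-identically.

`sweep_parameters()` reproduces the settings screen: neighbors 2–18 crossed
with `min_dist` 0–0.9 in 0.1 steps (170 embeddings for a 19-species matrix);
`n_neighbors = 3`, `min_dist = 0` is the pipeline's default operating point.

Stability across seeds was originally judged by inspecting all embeddings
from 20 differently seeded runs. `stability_score()` quantifies that
judgement: each of 20 embeddings (seeds `base_seed + 0..19`, all recorded)
is partitioned by k-medoids (`cluster::pam`; medoids are data points, so
empty clusters cannot arise) and every pair of partitions is scored with the
adjusted Rand index. Defaults use `k_clusters = 6`, matching the six
repertoire clusters distinguishable in the 19-species analysis; benchmark
runs on synthetic blocks use the true block number. The mean and minimum
pairwise ARI are reported; a mean near 1 is the quantitative analogue of
"the clustering is stable".

## Sequence-level filters

* **Decontamination** (`classify_contaminant`): hits are sorted by
  descending bitscore with full tie-breaking (ascending E-value, then
  subject id), the top 20 retained, and the query excluded iff the bacterial
  fraction strictly exceeds 60%. For queries with fewer than 20 hits the
  denominator is the number of hits available — the published rule is silent
  there, and using the available count keeps the statistic a fraction of
  evidence actually seen. Queries with no hits are kept.
* **p-distance** (`p_distance`): mismatches over comparable columns with
  pairwise deletion of gap/ambiguous (`X`) columns, the default behavior of
  MEGA-style p-distances.
* **Acceptance profiles** (`filter_homolog_hit`): conjunctive rules —
  E-value at or below the ceiling for the search type, p-distance at or
  below its ceiling, splice-leader evidence if required, and hit coordinates
  extending beyond predicted conserved-domain borders if required (guards
  against calls driven by widespread domains, e.g. kinase domains). Shipped
  presets: `trypanothione` (BLAST 1e-20, p-dist 0.7), `prerc` (BLAST 1e-20,
  HMM 1e-5, p-dist 0.75), `kkt` (HMM 1e-5, p-dist 0.8, domain extension),
  `kkip7` (BLAST 1e-100, p-dist 0.65). Tightening any threshold can never
  turn a reject into an accept (tested as a property).
* **Splice-leader scan** (`sl_scan`): euglenozoan mRNAs receive a splice
  leader at their 5' end, so an SL suffix of length ≥ 12 nt anchored near a
  transcript's start evidences host origin. The scan checks both the given
  strand and the reverse complement (assemblers emit either orientation) and
  requires the match to start within a 30 nt window by default — the window
  is a package choice (transcript starts are ragged but an SL deep inside a
  transcript is not trans-splicing evidence), surfaced as a parameter.

## Histone H3 variant classification

Candidate centromeric histones (cenH3) are diagnosed on a pairwise alignment
to a canonical H3 by four criteria: at least one amino-acid insertion in
loop 1 of the histone fold; a divergent N-terminal tail; absence of the
conserved α1 glutamine; and a divergent histone fold. H3V-like variants show
the divergent tail and missing glutamine *without* a loop-1 insertion.
Canonical caH3/H3.3 shows none of the four (the pipeline does not attempt to
split caH3 from H3.3). The four cenH3 criteria are required conjunctively by
default — the natural reading of "satisfied the following criteria" — with an
any-3-of-4 relaxation by flag; outcomes are mutually exclusive and
exhaustive by construction.

"Divergent" is operationalized as identity below configurable thresholds:
tail < 0.5, fold < 0.75. These are package decisions (no published cutoffs
exist), chosen so that genuinely scrambled tails and substantially remodeled
folds trip them while ordinary inter-species variation does not; both appear
in every result object. Region coordinates default to standard H3 fold
annotation on the mature human H3.1 sequence (tail 1–44, α1 63–77 with Q68,
loop 1 78–84, fold 63–131) and are fully configurable for other references.

## Synthetic data: what it emulates and what it does not

`simulate_dollo_matrix()` draws, per feature, an origin node (uniform over
nodes by default; a root-only preset supports exact-recovery experiments)
and then loses the feature on each branch below the origin with a fixed
probability — exactly the generative process Dollo parsimony assumes, so the
truth satisfies the single-origin constraint by construction.
`apply_missingness()` adds transcriptome dropout: presences of
transcriptome-flagged species flip to absence independently (default rate in
examples: 0.2), emulating unexpressed genes; requesting dropout for a
genome-flagged species is an error. `simulate_hit_table()` makes ranked hit
tables whose top-20 bacterial fraction is controlled exactly;
`simulate_histones()` implants the cenH3/H3V features with fixed mutation
counts so the implanted classes deterministically satisfy the classifier's
default thresholds; `simulate_block_matrix()` produces block-structured
binary profiles (within-block distance ≈ 0.05, between ≈ 0.5 by default) for
stability benchmarks. All generators take explicit seeds and are
bit-reproducible; none keeps global random state.

The default tree fixture, `euglenozoa_tree()`, is the 19-taxon study
topology (18 euglenozoans plus the *Naegleria gruberi* outgroup) with
internal labels placed so the nodes discussed in the literature — the
kinetoplastid crown (N15), the post-Prokinetoplastina (N14) and
post-Neobodonida (N13) nodes, and the trypanosomatid crown (N11) — are
addressable; branch lengths are omitted because only topology matters to
Dollo mapping.

What the generators do **not** emulate: correlated loss across functionally
linked KOs (pathways are lost together in real data), annotation errors and
contamination in the KO tables themselves, rate variation across lineages,
and sequence evolution beyond the implanted histone features. Passing the
synthetic benchmarks therefore demonstrates correctness of the algorithms
under the model's assumptions, not robustness of the biological conclusions
to annotation noise.

## Numerical choices and problem sizes

Ties in category rankings break alphabetically; contaminant sorting is fully
tie-broken (bitscore, then E-value, then subject id) so results are
invariant to input order; the Hamming matrix forces an exactly zero
diagonal; degenerate t tests are handled in closed form. Validation runs use
sizes chosen to exercise the asymptotics while keeping the full suite fast:
all 64 patterns on a 6-leaf tree against the exhaustive oracle; 2,000–5,000
simulated features on the 19-taxon tree; 200 random group matrices for the
conservation property; 100 queries for the decontamination recount; 15
species in 3 blocks with 20 seeds for stability; 100 sequences per histone
class.

## Known limitations

Dollo parsimony cannot see convergent gains (e.g. lateral transfer) by
assumption; non-identifiable loss configurations are merged into their
canonical form as described above; transcriptome absences conflated with
loss can inflate loss counts (use the dropout generator to gauge
sensitivity, or the ambiguous-absence mode); UMAP coordinates are not
comparable across runs with different seeds except through the stability
protocol; and the divergence thresholds in the histone classifier are
heuristics to be tuned per dataset.
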