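---
title: "Methods: gene-family expansion after polyploidization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family expansion after polyploidization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polyflor` studies how a large plant gene family — flowering-time genes are
the motivating case — expands and is retained after whole-genome duplication
(WGD, polyploidization). The pipeline chains seven analysis stages, each
usable on its own, and a genome simulator that generates every input format
together with planted ground truth so that the full chain can be validated
without downloading genomes. This vignette explains the models and the
numerical choices behind each stage.

```{r setup, message = FALSE}
library(polyflor)
library(dplyr)
```

## Identification by domain architecture

Orthologs of a curated reference catalog (a FLOR-ID-style table of gene
symbols, functional categories, and protein sequences) are identified not by
sequence search but by *domain architecture*: the ordered tuple of domain
accessions along the protein, with same-accession hits merged when they
overlap or touch, and consecutive repeats collapsed. Reference genes sharing
an architecture form a *subtype*; a proteome protein is a candidate member
of a subtype when its architecture equals the subtype's architecture
exactly. Ordered-tuple equality is deliberately strict — domain order is
functionally meaningful — and a stricter criterion than unordered set
equality; the choice is documented here because either reading is defensible.

Candidates then pass a length filter: a candidate is kept when its protein
length lies within 90%–110% of its best reference gene's length, boundaries
inclusive. We read the filter's published phrasing ("more than 90% shorter
or more than 110% longer are filtered out") as defining this symmetric
retention window, the only reading under which the removed genes are the
extremes. The best reference within a subtype is the member with the highest
similarity score when a similarity table is available and the member of
nearest length otherwise, with ties broken by the smaller relative length
difference, then the lexicographically smallest symbol.

Domain coverage (fraction of candidate residues under at least one domain
hit, computed on interval unions) classifies candidates into
`multi_domain`, `single_high` (single-domain, coverage at least 0.5) and
`single_low` (below 0.5); single-domain low-coverage matches are the group
most prone to false positives in practice.

Reference genes without any domain hit cannot be matched by architecture;
they are grouped into one non-matchable "no-domain" subtype and reported
with a warning rather than silently dropped.

## Pairwise alignment engine

Two scoring schemes are used, matching the two jobs alignments do here.
Family alignment (`scoring_scheme()`, used by `global_align()`, the
progressive MSA and the Ks pipeline) is BLOSUM62 with gap opening 10,
extension 0.05 per gap position, and end gaps charged like internal gaps —
the classical multiple-alignment parameter set. Similarity *search*
(`search_scheme()`, used by `all_vs_all()` and internal conserved-pair
scoring) is BLOSUM62 with gap opening 11 and extension 1, the standard
protein-search gapping. The distinction matters: near-free gap extension is
right for aligning true homologs end to end, but in a database-style search
it lets unrelated proteins splice short matching fragments into
high-scoring chimeric alignments, destroying any score-significance
relationship. The dynamic programming
itself is delegated to `Biostrings::pairwiseAlignment`; the test suite
verifies its scores against a brute-force enumeration over all gapped
alignments for short sequences. Identity is reported per aligned column
that carries a residue in both rows; coverage is the aligned span over each
sequence's length, computed separately for query and subject.

The engine produces no E-values: a database E-value depends on database
size, which an internal all-vs-all engine cannot meaningfully reproduce.
Thresholds published as E-value cuts are honored directly when an external
(BLAST-style) similarity table is supplied; internally computed hits are
instead scored in bits via the standard Karlin–Altschul conversion for
gapped BLOSUM62 (`bits = (0.267·S − ln 0.041)/ln 2`) and retained at
bitscore ≥ 50, the customary rule of thumb approximating E < 1e−5 at
proteome scale.

`all_vs_all()` reports, per query, the best two non-self subjects (the
`max target sequences = 2` convention of duplication-pattern pipelines). A
shared-k-mer screen (at least 3 exact 5-mers in common, both parameters
adjustable, `min_shared_kmers = 0` disables it) restricts the quadratic
dynamic programming to plausible pairs; under the simulator's conditions a
true family pair at 70–80% identity over 300 residues shares on the order of
a hundred 5-mers, while unrelated proteins essentially never share three, so
the screen does not change which hits clear the score threshold.

## Conservation scoring

Families with at least three copies are aligned progressively: pairwise
global-alignment identities define distances (1 − identity), clusters are
joined by nearest-pair agglomeration (average linkage, ties broken by the
lexicographically smallest member id so the result is independent of input
order), and profiles are merged by global profile–profile alignment with
the same scoring scheme (column score = mean substitution score over
residue pairs; the inner loop is compiled C++).

The conservation score of a family is not given a published formula, so the
package defines it transparently: a column's score is the frequency of its
modal residue among non-gap symbols divided by the **total** number of rows
— gaps count against conservation — and the family score is the mean column
score as a percentage. A per-gene score (share of the gene's non-gap columns
carrying the modal residue) is computed against this implicit consensus
rather than against a designated best-match member; the published phrasing
is ambiguous between the two, and the consensus variant is both symmetric
and testable. Modal ties resolve to the alphabetically smallest residue for
determinism. Families are retained when the family score exceeds 50%
(strictly).

Length variation is profiled by a retention curve: for window half-widths
{0.01, 0.02, 0.05, 0.10, 0.15, 0.20, 0.25} the retained fraction of members
within `[(1−w)·ref, (1+w)·ref]` is recorded; curves are clustered by
complete-linkage agglomeration on Euclidean distance and the tree is cut at
k = 7 clusters, labeled 1..7 by ascending mean retention so cluster 1 is
always the most length-variable group. Identical curves always co-cluster;
when fewer than k distinct curves exist, each distinct curve keeps its own
cluster and fewer labels are used.

## Duplication classification

Genes are ranked 0..n−1 along each chromosome by start coordinate (strand is
ignored; ties break by end then id). Anchor pairs — qualifying similarity
hits between ranked genes — are chained per chromosome pair by dynamic
programming into strictly monotone chains (increasing on both rank axes, or
increasing/decreasing for inverted blocks) with consecutive anchors at most
`max_gap = 25` ranks apart; chains with at least `min_anchors = 5` anchors
are reported as collinear blocks, longest first, removing used anchors
before searching again. Ties prefer the `same` orientation and then the
lexicographically smallest anchor chain, which makes the output unique and
lets the tests compare it against exhaustive chain enumeration.

Each gene then receives exactly one duplication class with the precedence
`wgd_segmental` (anchored in any block) > `tandem` (a retained hit partner
at rank distance 1 on the same chromosome) > `proximal` (within 10 ranks) >
`dispersed` (any retained hit) > `singleton` (none); genes appearing only in
hits, without a gene model, are `unassigned`. The precedence and the
defaults follow the established collinearity tool's published conventions;
retaining only the top two subjects per query means a tandem array larger
than two may expose only its two closest members as partners, a consequence
we accept and state rather than work around.

## Microsynteny

For a focal gene, the flanking region holds the gene and up to 20 neighbors
per side (truncated at chromosome ends). Between two regions, conserved
pairs require identity > 60%, coverage > 60% on both sequences, and
E-value < 1e−10 (or the score surrogate internally), resolved one-to-one by
best score. Region statistics are computed on the span from the smallest
start to the largest end among member genes: the intergenic proportion is
one minus the union of gene spans over the region span (so genic +
intergenic = 1 exactly), and repeat density is the union of repeat features
intersected with the span, over the span. "Genes without collinearity"
counts members with no conserved partner in the partner region only, not
genome-wide — the narrower reading of an ambiguous phrase, chosen because
the statistic describes the region pair.

## Similarity networks

Nodes are proteins; an undirected edge requires qualifying hits in *both*
directions (reciprocity), with the same identity/coverage thresholds as the
conserved-pair criteria — the external network pipeline the convention
stems from does not publish its defaults, so the package reuses the one
threshold set already justified above, and documents this as its own
choice. Groups are connected components, identified by their smallest
member id; components with at least three members are "major" groups.
Per-group statistics (mean protein length, duplication-class distribution)
support the biological question of whether groups differ structurally.

## Synonymous distances (Ks)

Within-family protein alignments are back-translated to codon alignments
(residue → codon, gap → `---`; the CDS must translate to the aligned
protein, mismatches are hard errors naming the residue). Synonymous
distances use Nei–Gojobori (1986) counting: per-codon synonymous site
fractions (single-base neighbors, stop neighbors counted as nonsynonymous)
averaged over both sequences; multi-substitution codons resolved by
averaging over all minimal substitution pathways, excluding pathways that
traverse a stop codon (all pathways are used in the degenerate case where
every pathway is blocked); columns containing a gap or stop are skipped
pairwise, not listwise, to maximize usable sites per pair. The distance is
Jukes–Cantor corrected, `ks = −(3/4)·ln(1 − (4/3)·pS)`, reported as `NA`
with a reason (never an error) when `pS ≥ 3/4` or no synonymous sites
remain.

This closed-form counting estimator replaces maximum-likelihood codon
models (F3×4 and the like): it is dependency-free, exactly verifiable
against neighbor enumeration at desk scale, and adequate for the distances
of interest here (≲ 0.5); it is expected to differ from ML estimates by
small systematic amounts, mainly because it ignores transition/transversion
bias and codon-frequency structure.

## The genome simulator

`simulation_config()` defaults define the study conditions used throughout
the tests: 5 chromosomes × 200 ancestral genes of 300 codons, one WGD with
planted homeolog synonymous distance 0.2 and 30% fractionation loss, tandem
/ proximal / dispersed duplication probabilities 0.03 / 0.02 / 0.02 per
gene, 5% per-site amino-acid divergence per copy, repeat insertion in 20%
of intergenic flanks, and mean intergenic gaps of 2 kb. The gene and genome
sizes are chosen so that a full run (including internal all-vs-all
alignment) completes in minutes on one CPU while leaving enough homeolog
pairs (~700) for stable rate estimates; the duplication rates are at the
low end of what is reported for plant genomes so that planted classes stay
unambiguous.

Mechanics worth knowing when interpreting test results:

* **Synonymous divergence follows the genealogy.** WGD rounds are placed at
  depths of half their planted distance; along each branch every codon
  position mutates to a random synonymous single-base neighbor with
  probability `f · (3/4)(1 − e^{−4d/3})`, where `f` is the position's
  synonymous fraction — the Jukes–Cantor inversion that makes the planted
  distance the expected NG86 estimate between homeologs. Two-fold
  degenerate sites make the realized `pS` very slightly exceed the ideal
  value; the bias is a few percent, well inside the ±0.05 recovery band.
* **Amino-acid divergence is star-shaped.** Each copy independently
  replaces residues at the configured rate using nonsynonymous single-base
  neighbors (so the synonymous profile is not disturbed). Protein identity
  between copies is therefore ≈ (1 − rate)², uniform within a family,
  rather than tree-correlated — sufficient for identity-threshold behavior,
  not a model of protein evolution.
* **Indel-free by default.** Domain coordinates stay exact and alignments
  are trivially correct; optional truncation events (`truncation_rate`)
  create length-filter test cases instead.
* **Truth classes are structural.** After layout, a gene's planted class is
  derived from its final neighborhood with the same precedence the
  classifier uses (surviving homeolog > adjacent sibling > sibling within
  the proximal window > any sibling > none), so the truth table is the
  ideal classifier output and accuracy measures the pipeline, not a
  definition mismatch. Rare interactions (a tandem copy of a homeolog
  adopted as a block anchor) can still produce legitimate disagreements;
  they stay well under the 5% accuracy margin at the default rates.
* **Determinism.** A fixed seed yields byte-identical emitted files; the
  generator restores the caller's RNG state.

What the simulator does **not** emulate — real domain-architecture noise
(InterProScan disagreement between paralogs), alternative splicing, intron
structure, realistic repeat sequence models, correlated protein/synonymous
divergence, gene conversion between homeologs — bounds what green tests
mean: they validate the algorithms against a genome whose structure
satisfies the methods' assumptions, not the methods' robustness to
annotation noise in real genomes.

## Numerical and boundary conventions

* Coordinates are 1-based inclusive everywhere; interval arithmetic uses
  `IRanges` unions, so overlapping features never double-count.
* The identification length window is inclusive at both 90% and 110%;
  conservation filtering (>50%), conserved-pair identity/coverage (>60%)
  and the E-value cut (<1e−10) are strict, following the published
  phrasings.
* Proportions in the per-species summary are rounded half-up to two
  decimals (`round_half_up()`), the convention that reproduces published
  tables exactly; base R's half-to-even rounding does not.
* Proteome cleaning measures identity as matches over **all** alignment
  columns (gap columns included), so the default redundancy cutoff of 1.0
  removes exact duplicates only; the published pipeline used an external
  clustering tool without printing its threshold, so the default is the
  most conservative choice.
* Alignment scores from the compiled engine are single-precision; tests
  compare scores at 1e−5 tolerance.

## Problem sizes used by tests and the acceptance script

Unit tests run on genomes of 12–80 ancestral genes; the acceptance checks
use the full default conditions (1,000 ancestral genes, ~1,700 after WGD)
for identification, classification, and Ks recovery, 50 homeolog pairs of
300 codons for the planted-distance check, and a 150-gene genome with two
WGD rounds (planted distances 0.15 and 0.45) for the bimodality check.
These sizes give stable statistics (binomial fluctuations of retention and
accuracy are well inside the asserted margins) at a few minutes of compute.

## Known limitations

* Architecture matching is exact; a single lost or extra domain annotation
  excludes a candidate. Real annotation noise therefore depresses recall in
  ways the simulator does not measure.
* The score surrogate for E-values is calibrated for ~300-residue proteins;
  very short proteins can reach score 50 less easily.
* The progressive aligner is quadratic per merge and intended for families
  (tens of sequences), not whole proteomes.
* NG86 + Jukes–Cantor saturates near `pS = 3/4`; distances above ~1 are
  reported as `NA` rather than extrapolated.
* `run_full()` classifies duplications genome-wide but computes
  conservation and Ks only within identified families, mirroring the
  analysis design it implements.
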