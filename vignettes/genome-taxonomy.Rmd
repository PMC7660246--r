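---
title: "Genome-based genus demarcation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-based genus demarcation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Prokaryotic genera are increasingly delimited from whole genomes rather
than from 16S rRNA genes or phenotype. `genustax` implements one complete
route from per-genome protein (and optionally nucleotide) FASTA files to a
genus partition:

1. **Orthologous clusters (OCs).** All proteome pairs are compared with
   local alignment; reciprocal best hits (RBH) passing an identity /
   coverage / E-value filter become edges, and the connected components of
   the union graph over all genomes are the clusters. Clusters are
   classified core / accessory / unique, and single-copy core clusters
   (exactly one member per genome) feed the phylogeny.
2. **Similarity matrices.** Average amino-acid identity (AAI, mean percent
   identity over RBH ortholog pairs), fragment-based orthologous average
   nucleotide identity (ANI, reciprocal best 1020-bp fragment pairs), and
   the percentage of conserved proteins
   (POCP = (C1 + C2)/(T1 + T2) x 100, with `C_i` the one-way conserved
   counts and `T_i` the proteome sizes).
3. **Core-genome tree.** Single-copy core clusters are aligned
   (progressive profile MSA), trimmed by column gap fraction, concatenated
   into a supermatrix, converted to Kimura-corrected protein distances and
   summarised as a neighbor-joining tree; the patristic distance on that
   tree is the "evolutionary distance" used for demarcation.
4. **Metric comparison.** Inter- vs intra-clade value splits, Pearson
   cross-correlations between metrics, and Welch t-tests.
5. **Demarcation.** A pre-order traversal of the rooted tree emits each
   maximal clade in which (i) all pairwise patristic distances are at most
   `dist_max` (default 0.4 substitutions/site) and (ii) at least
   `aai_pass_fraction` (default 0.95) of the pairwise AAI values reach
   `aai_min` (default 70 %). Every genus is monophyletic by construction,
   and singleton genera are allowed.

A seeded pan-genome simulator generates inputs with known truth (tree,
genus labels, gene families, per-pair divergence) so that each stage is
testable without any external download.

## Alignment substrate

The aligner is an exact affine-gap Smith–Waterman (a gap of length L costs
`gap_open + L * gap_extend`), not a seed-and-extend heuristic. Protein
scoring uses BLOSUM62 with gap open 11 / extend 1 (the common defaults of
BLAST-family tools, which the upstream methods delegate to without stating
parameters); nucleotide scoring uses match +1 / mismatch −2 with gap open
5 / extend 2. Tracebacks are deterministic (diagonal, then up, then left,
with the start cell chosen in row-major scan order), so reruns are
byte-identical. Ambiguity codes (X/B/Z, N) are retained and scored but
never count as identity matches; `N` always scores as a mismatch —
identity estimates stay conservative.

E-values use the Karlin–Altschul closed form
`bits = (λS − ln K)/ln 2`, `E = m·n·2^(−bits)`, with gapped constants
λ = 0.267, K = 0.041 (BLOSUM62) and λ = 1.28, K = 0.46 (+1/−2
nucleotide). The effective search space is query length times the total
length of the compared proteome, matching per-proteome pairwise database
semantics. BLAST's finite-size edge corrections are deliberately omitted;
at the scales involved they move E-values by far less than the nine orders
of magnitude separating true orthologs from the 1e-5 ceiling.

All-vs-all search is made feasible by an exact shared k-mer prefilter
(k = 4, at least one shared word for proteins; k = 12 for nucleotide
fragments). The filter is a superset guarantee, not an approximation: a
hit able to pass the orthology filter (≥ 50 % identity over ≥ half of
both sequences) shares many exact 4-mers, and the unit tests verify that
prefiltered best-hit tables equal exhaustive ones on diverged simulated
proteomes.

## Orthology and pan-genome accounting

Filters are inclusive: identity ≥ 50 %, both coverages ≥ 50 %
(aligned span over full length, enforced on *both* sequences), E ≤ 1e-5
for clustering; identity ≥ 40 % for POCP conservation. Equal-score best
hits break ties by higher identity, longer alignment, then lexicographic
subject id.

Clusters are connected components of the RBH union graph. Tools in this
family often refine components further (e.g. by spectral partitioning);
components were chosen because they are deterministic, order-invariant and
exactly testable, at the cost of occasionally chaining paralogous
families. Orphan proteins become singleton unique clusters, so every gene
of every genome is accounted to exactly one of core / accessory / unique.
An outgroup genome participates in clustering and the tree (it is needed
for rooting) but is excluded from pan-genome accounting and from the
single-copy core *count*; the supermatrix uses clusters that are
single-copy across all genomes including the outgroup, since every row of
every partition must be present.

## Similarity metrics

* **AAI** averages identity over RBH pairs at E ≤ 1e-5 and coverage
  ≥ 50 % with *no identity floor* — AAI must remain computable below the
  50 % clustering threshold, where genus boundaries live. Pairs with no
  RBH orthologs yield a missing value (never 0), which propagates through
  correlations and histograms as NA.
* **ANI** cuts assemblies into consecutive non-overlapping 1020-bp
  windows (trailing remainder discarded), aligns fragments on both
  strands, keeps reciprocal best fragment pairs covering ≥ 70 % of both
  fragments, and averages their identities. Windows are taken on each
  contig's canonical strand (the lexicographically smaller of contig and
  reverse complement), which makes fragment coordinates — and therefore
  ANI — independent of assembly orientation.
* **POCP** counts one-way qualifying hits, not RBH, matching the original
  definition of the formula.

Identity statistics for a pair are computed once per unordered pair and
shared between directions, so all three metrics are symmetric by
construction.

## Core-genome phylogeny

The progressive MSA builds a UPGMA guide tree from 3-mer count distances
and merges profiles with affine-gap global alignment over
BLOSUM62-expected column scores; sequences are sorted lexicographically
first so the result does not depend on input order. This replaces a
general-purpose aligner deliberately: core orthologs are close to
full-length alignable, and an in-package aligner keeps the pipeline
dependency-free and exactly reproducible. Trimming keeps columns with gap
fraction ≤ 0.2 — a simple, auditable stand-in for heuristic "automated"
trimming modes.

Distances are Kimura-corrected protein distances
`d = −ln(1 − p − 0.2p²)`; saturated pairs (p ≥ 0.85) are capped at
d = 5 with a warning. The tree is Saitou–Nei neighbor joining with
negative branch estimates clamped to 0 (a simple clamp; the length is not
transferred to the sibling). Maximum-likelihood inference with partitioned
models is out of scope: demarcation needs relative distances and topology,
and NJ round-trips additive matrices exactly, which makes it testable to
1e-9. Rooting uses the midpoint of the outgroup's pendant edge when an
outgroup is given, otherwise midpoint rooting. Bootstrap support is not
computed.

"Evolutionary distance" is the patristic distance on this tree. The
pairwise Kimura distance matrix of the supermatrix is also available
(`distance_matrix()`), and on clean simulations the two are nearly
identical; the tree-based distance was chosen because the demarcation
threshold of 0.4 is a tree-scale quantity (the tree's branch lengths are
in substitutions per position).

## Demarcation choices

Two genuinely open points were resolved as follows:

* **The AAI criterion is a pass fraction, not a strict minimum.** A genus
  in which a single aberrant pair falls below 70 % AAI while ~97 % of
  pairs clear it should not be shattered; the default requires 95 % of
  non-missing pairs to pass. The distance criterion stays a strict
  maximum. With `aai_pass_fraction = 1` the rule reduces to strict
  all-pairs thresholds.
* **Greedy top-down maximal clades.** Among all ways to cover the tree
  with threshold-compliant monophyletic groups, the pre-order traversal
  emits the *coarsest* compliant clades — few, large genera. Tightening
  either threshold can only refine the partition (asserted as a property
  test), so the rule is monotone and deterministic.

`major_clades()` provides a reproducible stand-in for "the deepest n
clades" of a rooted tree: repeatedly split the largest remaining clade at
its root. It is used to label clades for the inter/intra histograms and
t-tests.

Statistical defaults: Pearson correlation (the conventional reading of an
unqualified r; Spearman is available via `method`), and the Welch
unequal-variance t-test (the safe default of R's `t.test`, which is also
the function the field uses). P-values below 2.2e-16 are printed with the
conventional `"<2.2e-16"` label while the numeric value is kept.

## The simulator: what it does and does not emulate

`simulate_pangenome()` draws an ancestral single-copy gene set i.i.d.
from a uniform residue model and evolves it along a known tree with
Poisson substitution counts per branch (uniform replacement over the 20
residues, so the expected identity at path divergence d is exactly
`100(e^{−d} + (1 − e^{−d})/20)`), Poisson gene gain (novel random genes)
and loss, and per-branch duplications. Nucleotide genomes are produced by
codon-encoding each protein (uniform synonymous codons, plus synonymous
wobble at rate 0.5 per site per unit branch length), joining genes with
random 50–200 bp spacers into 2–5 contigs, and reverse-complementing every
second contig.

Defaults are the package's study conditions: 3 genera × 4 genomes;
within-genus pairwise divergence 0.25 substitutions/site (leaf depth
0.125) and between-genus 0.75 (leaf depth 0.375), placing the two regimes
clearly on either side of the 70 % AAI / 0.4 distance boundaries; 100
core genes of 150–300 residues; gain 0.2 and loss 0.1 events per gene per
unit branch length and duplication probability 0.02 per gene per branch,
enough to produce accessory and unique gene content without destabilising
the core. All randomness flows from the single mandatory seed; identical
seeds give byte-identical FASTA output.

The uniform substitution model was chosen *because* it has a closed-form
expected identity, which turns end-to-end behaviour into analytic checks.
It does not emulate: realistic exchangeabilities or profile heterogeneity
(no WAG/LG), indels within genes, codon usage bias, rate variation across
sites, or horizontal transfer between non-sister lineages. Passing tests
therefore demonstrate the pipeline's correctness and calibration under a
clean, known-truth regime — not robustness to every artefact of real
assemblies (fragmented genes, contamination, annotation error).

## Numerical and determinism notes

* Thresholds are inclusive everywhere; the run log echoes the exact
  filter triples used.
* Cluster ids, genus ids and clade labels are assigned by deterministic
  orderings (lexicographically smallest member; traversal order), so
  reruns and permuted inputs give identical partitions.
* `run_all()` writes only plain TSV / FASTA / Newick; reruns are
  byte-identical apart from the log timestamp.
* Degenerate inputs have defined behaviour: empty FASTA, duplicate ids,
  internal stop codons, all-N contigs, leafless trees, all-gap overlaps,
  trimmed-away alignments, genomes absent from every cluster, and
  constant t-test samples all raise informative errors (or, for the
  t-test, return the exact degenerate statistics).

## Problem sizes used in the checks

The shipped tests exercise: exhaustive aligner-vs-reference comparisons up
to length 30 plus 500 longer random pairs; 50 random additive trees of
4–15 taxa for NJ round-trips; 50-gene two-genome simulations at d ∈
{0.05, 0.2, 0.5} for the closed-form identity check; ten seeds of the
full 12-genome study condition for planted-genus recovery; and 30-gene
6-genome configurations for exact core accounting (within the ≤ 0.3
substitutions/site regime where cluster recovery is exact). These sizes
were chosen as the smallest that still separate the regimes the thresholds
are meant to distinguish.

## Limitations

* Connected-component clustering can chain families through promiscuous
  paralogs at permissive thresholds (an optional stricter path is to
  raise `identity_min`).
* NJ branch lengths are method-of-moments estimates, not ML; very short
  internal branches can collapse to 0 after clamping.
* The E-value calibration is approximate (documented constants, no edge
  correction); it is used as a filter, not as a reported statistic.
* AAI below ~30 % identity rests on few, short RBH pairs and should be
  treated as qualitative.
* The demarcation thresholds themselves (70 % / 0.4) are inputs, not
  outputs: the package applies them and reports diagnostics, it does not
  re-derive them.
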