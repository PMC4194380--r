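---
title: "Functional phylogenomics of pathway profiles: models and methods"
author: "pathphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional phylogenomics of pathway profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathphylo)
```

# The question and the model

Prokaryotic cellular functions split into two broad evolutionary
regimes. Some metabolic pathways are clade-borne: acquired once and
inherited vertically, so their presence in a genome is predictable from
its phylogenetic neighbors. Others are dispersed across distant clades
by horizontal gene transfer, and phylogeny is a poor predictor of their
presence. `pathphylo` quantifies where a pathway sits on this spectrum
by treating it as a binary character — present (1) or absent (0) at each
tip of a rooted genome phylogeny — and measuring its fit to the tree.

The core statistic is the **parsimony score** $s$: the minimum number of
$0 \leftrightarrow 1$ changes along branches needed to produce the
observed tip pattern. `fitchScore()` computes it with the classical
two-state Fitch dynamic program; at multifurcating nodes the
generalized (Hartigan) majority recurrence is used, so the score remains
the exact minimum on non-binary trees (the test suite verifies this
against exhaustive enumeration of all internal labelings on small
trees, and against an independent Sankoff implementation).

Because $s$ grows mechanically with a character's frequency, it is
normalized into the **retention index**

$$RI = \frac{g - s}{g - m},$$

where $g$ is the maximum number of changes any tree could require (for
a binary character, the minority-state tip count) and $m$ the minimum
any tree could require (1 when both states occur, 0 for a constant
character). $RI = 1$ means perfect fit — the character delimits clades
exactly — while values near 0 indicate maximal homoplasy. Characters
are classified **consistent** when $RI > 0.9$ and **inconsistent** when
$RI < 0.7$ (strict comparisons; everything between is *intermediate*).

Two degenerate corners of the formula need conventions, which
`retentionIndex()` makes explicit rather than leaving 0/0 undefined:

* **constant characters** ($g = 0$): $RI$ is defined as 1 and the
  result is flagged `constant`, keeping downstream classification
  total;
* **$g = m$** (the minority is a single tip): the score is forced to
  its minimum and $RI$ is likewise 1.

Reported values are rounded half-up to two decimals
(`roundHalfUp()`), the convention used for printed retention indices;
full precision is kept internally.

# Ancestral states, dating, and gain/loss clocking

`fitchAncestral()` returns one most-parsimonious labeling of the
internal nodes: the bottom-up pass computes preliminary state sets, the
top-down pass assigns the root and lets every node inherit its parent's
state whenever its preliminary set allows. Ties at the root (both
states equally parsimonious) are resolved to **absent** by default — a
deliberately conservative choice about inferring ancient presence —
and are configurable to `present` or `majority`. The full set of
most-parsimonious reconstructions is *not* enumerated; one labeling is
what downstream event clocking and subtree drawing consume, and its
induced change count always equals the score (a tested invariant).

Node ages come from `assignNodeAges()`: each internal node's raw age is
its **mean path length** (MPL) to descendant tips, ages are clamped
bottom-up so no parent is younger than a child (clamping precedes
rescaling), and the result is rescaled linearly so the root sits at age
100 and extant tips at 0. This deliberately replaces rate-smoothing
dating programs: only the relative ordering of events matters to the
analyses built on top, not absolute ages, and MPL with clamping
preserves ordering while staying dependency-free and exactly
reproducible. Trees of zero total depth cannot be scaled and are
rejected.

`changeEvents()` then emits one gain or loss per edge whose endpoint
states differ, with the age interval `[child age, parent age]` and a
point age at the branch midpoint — the within-branch position of a
change is unidentifiable, so the midpoint is a declared convention, not
an estimate.

`reduceSubtree()` renders a pathway's history compactly: every maximal
clade whose tips all lack the pathway collapses into one tip (labeled
`<size>_absent_<first tip>`, branch length preserving the distance to
the clade's deepest original tip), nodes are colored red (gain) or blue
(loss) where their state differs from the parent's, and edges under
presence-state nodes are flagged green. The root is colored by its
state alone and excluded from the change count, since a root state is
not a change on any branch; consequently the number of non-root colored
nodes equals the parsimony score exactly.

# The surrounding pipeline

**Corpus QC** (`qcFilterGenomes()`): genomes with more than 1000
contigs (fragmented assemblies) or fewer than 400 predicted
protein-coding genes (likely incomplete) are discarded; both thresholds
are inclusive on the keep side and configurable via `qcConfig()`.

**Pathway profiles** (`loadPathwayReports()`): a pathway is present in
a genome iff some report row reaches confidence 70 (inclusive).
Duplicate rows collapse by maximum confidence because presence is an
existential claim. The pathway universe is the union observed across
the input files. Profiles live in a `PathwayProfiles` object — a
`SummarizedExperiment` with a 0/1 `presence` assay (pathways × genomes)
and the genome metadata as `colData`.

**Genus aggregation and clustering**: `aggregateByGenus()` ORs member
genomes into genus pan-genome profiles, damping uneven genus sampling.
`clusterProfiles()` clusters either axis with Manhattan distance (the
differing-entry count for binary vectors) and complete linkage by
default; only the distance is scientifically prescribed, and complete
linkage is the default of the heatmap tooling this machinery mirrors —
`single` and `average` are available. Items are sorted lexicographically
before clustering so results are invariant to input order.

**Annotation transfer** (`parseDomtbl()`, `filterHits()`): per-domain
HMMER output is aggregated per (query, family) pair; a hit survives iff
its whole-sequence e-value is strictly below `1e-3` *and* the merged
(possibly non-contiguous) aligned regions cover at least 50% of both
the HMM and the query. Coverage is computed on the union of domain
intervals — the filter is about total aligned extent, not the best
single domain. Per query, the surviving hit with the smallest e-value
wins; exact ties go to the lexicographically smallest family id, a
determinism rule the underlying search tools do not provide.
`validateCluster()` enforces the family-building rules (identity to
centroid and shortest/longest length ratio both strictly above 0.80),
and `mergeFamilyAnnotations()` takes field-wise unions across curated
members.

**GO enrichment** (`elimEnrichment()`): classic one-sided Fisher
(upper hypergeometric tail) per term, plus the *elim* decorrelation:
terms are tested leaf-ward first (decreasing longest-path depth, ties
by id), and a term whose elim p-value reaches 0.01 removes its
annotated genes from all its ancestors' tests, suppressing general
terms that are significant only through a specific child. Only `is_a`
edges are traversed. Reporting (`filterAndRank()`) keeps terms
annotated to strictly more than 10 background genes with elim
p ≤ 0.01 and ranks by elim p-value; this ranking is a documented
substitute for the heavier "weight" decorrelation algorithm, which is
out of scope. Whether genes or genomes are the sampling unit is an
open modelling question; this package pools **genes** of a taxon's
genomes as the study set against all genes of the retained corpus, and
any report should state that unit.

**Tree comparison**: `robinsonFoulds()` and `branchScore()` treat trees
as unrooted (a binary root's two child edges are one internal edge,
with summed length) and use non-trivial bipartitions only; the branch
score compares internal branches, mirroring comparisons against total
internal branch length.

# The synthetic corpus

No external data are required: `simulateYuleTree()` grows pure-birth
trees (uniformly chosen lineage splits at exponential waiting times;
extinction would add nothing testable here), and two character
generators emulate the two regimes:

* `simulateCharacterVertical()` runs a 2-state continuous-time Markov
  chain down every branch with exact exponential waiting times, so the
  **true event list** is known and parsimony's lower-bound property can
  be asserted per replicate. Defaults (`gainRate = 0.001`,
  `lossRate = 0.0075` per unit branch length, root state present) put
  roughly one loss event per character on a 200-tip Yule tree of total
  length ≈ 200 — the signature of a stably maintained, clade-borne
  pathway with few losses.
* `simulateCharacterScattered()` assigns presence to $k$ tips uniformly
  at random — the no-phylogenetic-signal limit of rampant horizontal
  transfer.

`assignGenera()` makes genera contiguous runs of tips in cladewise
order so genus aggregation has phylogenetic signal, and
`generateFixtureCorpus()` writes a complete file corpus (tree,
metadata, pathway reports, domtblout, gene-to-GO map, OBO stub) with
*planted* violations of every QC and filter clause, so filter contracts
can be checked exactly.

The regime-separation study in the test suite compares 50 vertical
characters against 50 frequency-matched scattered characters on a
200-tip tree at a fixed seed. Vertical characters are conditioned on
being variable at the tips (constant characters carry no information
about fit, and a real pathway universe contains only observed, variable
pathways); each scattered twin receives the same presence count. Under
the defaults the vertical mean RI exceeds the scattered mean by a wide
margin and the majorities fall on the consistent (> 0.9) and
inconsistent (< 0.7) sides respectively. Two caveats on what this does
and does not show: the scattered model is a stronger null than real HGT
(which transfers into related lineages too), and Yule trees lack the
extreme depth heterogeneity of real prokaryotic phylogenies — passing
these tests validates the statistics' behavior, not any claim about a
particular biological corpus.

# Problem sizes and numerical choices

The shipped checks use desk-scale corpora chosen as the smallest sizes
at which each property is informative: exhaustive parsimony oracles on
trees of up to 10 tips (1024 labelings), 500 reconstruction/clocking
replicates on a 100-tip tree, all 1225 tree pairs from 50 six-tip trees
for Robinson–Foulds, full hypergeometric enumeration up to a background
of 40, and the 200-tip regime study above. Branch lengths are
serialized with the shortest decimal representation that round-trips
exactly, so write–parse cycles are lossless; missing input branch
lengths default to 0 with a warning rather than an error, since Newick
dialects disagree about their legality.

# Known limitations

* One most-parsimonious reconstruction is reported, not the MPR set;
  gain/loss counts per *direction* (not their sum) can differ between
  equally parsimonious labelings, and the root tie rule biases ancient
  states toward absence by design.
* MPL dating is a monotone surrogate for divergence-time estimation;
  ages are comparable within a tree only.
* Unweighted parsimony ignores branch lengths; a pathway lost on a long
  branch counts the same as one lost on a short branch.
* The enrichment module implements classic Fisher and elim only; the
  "weight" algorithm and multiple-testing correction are intentionally
  absent.
* `part_of` and other non-`is_a` ontology edges are not traversed.
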