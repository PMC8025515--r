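---
title: "Comparing cancer-hallmark mapping schemes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cancer-hallmark mapping schemes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hallmarkConsensus)
```

# Overview

Published attempts to operationalise the ten hallmarks of cancer map
each hallmark onto Gene Ontology (GO) terms or pathway gene lists.
Because the schemes were curated by different groups against different
GO releases, they disagree — in which terms they select, in the gene
sets those terms induce, and in what downstream analyses conclude.
This package quantifies that disagreement and the consensus hiding in
it. This vignette explains each stage's model, its tunable parameters,
the numerical choices made, and what the synthetic data generator does
and does not emulate.

# Ontology representation and closure queries

An `OntologyGraph` stores a directed acyclic graph of terms with typed
child-to-parent edges (`is_a`, `part_of`). Obsolete terms are kept in
the term table — version comparison needs them — but carry no edges and
are refused as roots of closure queries. Validity is enforced on
construction: unique ids, closed edge set, no self edges, acyclicity
(the error message names one offending cycle).

Annotations are stored *direct-only*; the true-path rule (a gene
annotated to a term is implicitly annotated to every ancestor) is
applied at query time by `annotatedGenes()`, which unions the genes of
a term and all its descendants. Propagation-at-query keeps swapping
ontology versions cheap: the same annotation table can be interrogated
under any compatible graph.

Two traversal choices are deliberate:

* **Relations traversed default to `{is_a, part_of}`.** Descendant
  retrieval services commonly close over both; the set is a parameter
  (`relations`) everywhere it matters.
* **Multi-rooted graphs are allowed**, and namespace filtering is a
  query option rather than a structural constraint (enrichment defaults
  to `biological_process`).

Gene identifiers are opaque strings; no identifier translation is
attempted.

# Mapping schemes and hallmark gene sets

A `MappingScheme` is either ontology-based (hallmark → selected term
ids) or pathway-based (a flat gene list). The ten canonical hallmark
names are fixed; an alias table absorbs the spelling variants that
occur in published tables (plurals, "tumour/tumor",
"energetics/energetic"), and unresolvable names are an error naming the
offending row.

`buildHallmarkGeneSets()` unions `annotatedGenes()` over each
hallmark's selected terms. Selected terms that are obsolete or unknown
in the graph version in use are *skipped and reported* — never silently
dropped — because schemes frequently reference terms that later became
obsolete, and that bookkeeping is part of the analysis. Pathway
schemes, whose authors did not state pathway-to-hallmark assignments,
participate only through their gene-set union; inferring per-hallmark
splits for them would be an interpretation, not a reuse, of the
published mapping. To let a pathway scheme join per-hallmark consensus
counting, `convertPathwayScheme()` ingests a supplied
pathway-to-term correspondence table; the package never derives such a
correspondence itself.

# Consensus and divergence statistics

`termSelectionFrequency()` counts *schemes*, not hallmark slots: a term
one scheme maps to two hallmarks counts once for that scheme overall,
while the per-hallmark counts stay hallmark-scoped.
`uniqueTermFraction()` reports the percentage of a scheme's terms
selected by no other scheme, half-up rounded to one decimal for report
parity with common practice (R's default round-half-even would differ
in boundary cases).

**Consensus terms are hallmark-scoped.** A term selected by three
schemes *for three different hallmarks* is not a consensus term for any
hallmark. The published descriptions of the threshold disagree between
"three or more" and "more than three"; this package adopts ≥ 3 and
exposes `min_schemes` as a parameter. Because a term can reach
consensus in two hallmarks, `consensusTerms()` reports both tallies:
the number of unique consensus terms (`nUnique`) and the per-hallmark
total (`nPerHallmarkTotal`).

`exclusiveIntersections()` computes upset-style counts by exact
membership signature. The partition property — exclusive counts sum to
the size of the global union — is asserted on every call, not just in
tests.

# Prognostic-hallmark subgroups

Prognostic gene lists per cancer type are consumed as given (no
survival modelling). For each scheme, `prognosticHallmarkGenes()`
intersects them with the hallmark union, and `subgroupPartition()`
assigns every gene to the combination equal to its *exact* cancer-type
signature: a gene prognostic-hallmark in three cancers belongs to that
three-cancer subgroup only, not to any sub-combination. This reading of
"exclusively labelled" makes the subgroups a partition, which is what a
pairwise Jaccard comparison needs; the alternative (closed under
subsets) would double-count genes across rows of the comparison.
Subgroups under `min_size = 5` genes are dropped and logged. In
`pairwiseSchemeSimilarity()`, the row set is the union of retained
combinations across schemes, and a combination absent from one scheme
of a pair scores 0 — absence of a subgroup is itself disagreement.

The per-scheme totals of prognostic-hallmark genes are reported as the
union over cancers (each gene once), with the per-cancer breakdown
available alongside, since a gene prognostic in several cancers would
otherwise be multiply counted.

# Wang semantic similarity

For a term $A$, the semantic contribution of an ancestor $t$ is

$$S_A(A) = 1, \qquad
S_A(t) = \max\{\, w_e \cdot S_A(c) : c \text{ a child of } t
\text{ on a path to } A \,\}$$

with edge-type weights $w_{is\_a} = 0.8$ and $w_{part\_of} = 0.6$ — the
conventional contribution factors for this measure; they are
configurable because sources rarely print them. The similarity of two
terms sums their contributions over shared ancestors, normalised by the
two totals $SV = \sum_t S(t)$. Term sets are compared with the
best-match-average: each term's best counterpart similarity, averaged
over both directions.

Implementation notes: $S$ values are computed by one pass over the
ancestor closure in topological order (children before parents), which
is exact for DAGs and linear in the closure size; the test suite checks
it against an explicit all-paths enumeration. Terms in disjoint rooted
components share no ancestors and score 0 rather than raising an error
— comparing across namespaces is well-defined, just maximally
dissimilar. Terms unknown or obsolete in the graph version in use are
dropped with a warning before a set comparison (annotation-versus-
version drift is one of the things this package is for), and modules
enriched in fewer than three terms are excluded from the module
similarity matrix, since a best-match average over one or two terms is
dominated by single matches.

# Simplified co-expression analysis

The stage follows the weighted co-expression recipe at desk scale:
$\log_2(x + 1)$ transform; optional outlier removal by average-linkage
clustering of samples on Euclidean distance with a static cut;
unsigned adjacency $a_{ij} = |\mathrm{cor}_{ij}|^\beta$ (signed
transform available); topological overlap

$$TOM_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{u \ne i} a_{iu};$$

average-linkage clustering of $1 - TOM$ with a static cut; hub genes by
intramodular connectivity. Choices and defaults:

* **Single-block clustering with a static cut** (`cut_height = 0.995`,
  `min_module_size = 20`) replaces block-wise processing with dynamic
  tree cutting. The gene sets this stage receives are a few hundred
  prognostic-hallmark genes, where block-wise machinery adds nothing;
  the cut height and minimum size are explicit configuration. A
  consequence, documented deliberately: module *counts* from the full
  machinery on thousands of samples are not expected to reproduce here.
* **Soft power** `pickSoftThreshold()` scans powers 1–20, bins
  $\log_{10} k$, regresses log bin frequency on log mean connectivity,
  and accepts the smallest power whose slope-signed $R^2$ reaches
  `r2_cut = 0.8` (falling back to the best fit). For the planted-module
  fixtures in the tests a fixed $\beta = 6$ — the standard unsigned
  default — is used instead, because a 150–200-gene planted fixture is
  not scale-free and fitting it would be noise.
* **Hub ties are extended**: the top 5 genes per module by intramodular
  connectivity, plus any gene tied with the 5th value, so a module can
  legitimately have 6 hubs.
* **Enrichment** is a one-sided hypergeometric upper tail per
  biological-process term with at least one module gene after
  true-path propagation. The background defaults to the genes of the
  expression matrix. Significance uses the raw $p < 0.05$ rule that
  external enrichment services print by default, and the
  Benjamini–Hochberg adjusted value is always emitted alongside; the
  choice between them is the caller's, not silently made.
* Constant genes (zero variance) are dropped with a warning before
  correlation; average-linkage heights are monotonised against
  floating-point inversions before cutting.

# Ontology version diffing

`diffVersions()` builds the selected-terms-plus-first-neighbours
subgraph in each version and classifies every node of the union:
`shared_selected_both`, `shared_selected_only_old/new` (present in both
versions, selected by one side), `obsoleted_in_new` (selected by the
old side, obsolete or gone in the new version), `created_after_old`
(selected by the new side, unavailable in the old version), and
`neighbor_unselected`. Absence from a snapshot and creation after it
are treated as the same thing — a snapshot encodes availability, not
creation dates. Merged ids resolve through `alt_id` to their primary id
before classification; unresolvable ids are reported. Neighbours are
taken from each version's *active* graph (obsolete terms carry no
edges), which is the choice that makes the obsoleted category visible
as detached nodes. The classification is a partition (checked in
tests), and swapping the two versions swaps the directional categories
symmetrically. `annotationCountDrift()` counts genes per term with the
closure of each version, reporting `NA` — not zero — for terms missing
from a version.

# The synthetic study world

`syntheticWorld()` generates every input with known ground truth, so
the whole pipeline runs and can be scored without downloads:

* **Ontology**: a layered random DAG — each non-root draws a Poisson
  number of parents (mean 1.5, floor 1) from earlier terms, each edge
  `part_of` with probability 0.2. This mimics DAG *shape* (multiple
  parents, growing fan-out), not real GO topology statistics.
* **Version churn**: 5% of non-root terms obsoleted, 5% of terms
  added, 5% of edges rewired cycle-safely; all events recorded.
* **Annotations**: each gene draws direct terms biased toward deep
  terms (weight ∝ depth + 1), so true-path propagation is non-trivial;
  the second version's table adds 10% extra annotations (growth).
* **Schemes**: a planted per-hallmark consensus pool; each scheme draws
  Binomial(`terms_per_hallmark`, `overlap_p`) of its selection from the
  pool and the rest from scheme-private terms; coverage masks emulate
  schemes covering 8 of 10 hallmarks. Defaults: 4 schemes, 5 terms per
  hallmark, `overlap_p = 0.5`, coverage `10, 10, 8, 8`.
* **Prognostic table**: 17 cancer types; planted exact-signature
  combinations (sizes 8, 6, 10 over cancer pairs/triples) above the
  subgroup threshold, background genes prognostic per cancer at rate
  0.02 with signatures redrawn if they would collide with a planted
  combination.
* **Expression**: per module a latent sample profile; member genes load
  on it with loading $\sigma\sqrt{\rho/(1-\rho)}$ so the expected
  within-module Pearson correlation on the log scale equals
  $\rho$ (`within_cor = 0.8`); three modules of 50 genes plus
  background noise genes, 100 samples, exponentiated to an FPKM-like
  scale. One marker term per module annotates exactly the module's
  genes in both graph versions, giving enrichment a known right answer.

Every generator is a pure function of its parameters and a seed, and
the world derives one named sub-seed per component, so adding a
generator never changes existing draws. The default world is sized like
the real study materials (≈ 10 000 genes, ≈ 600 terms, 4 schemes, 17
cancer types, 100 samples). The test suite and the acceptance script
run the world at one-tenth gene/term scale, which this package treats
as its standard desk-scale configuration: every property being tested
(closure correctness, partition identities, planted-structure recovery)
is scale-free, and the statistical checks (module recovery, enrichment
ranking) are comfortably powered at 200 genes × 100 samples.

What passing tests on this world do **not** show: recovery of real GO
topology, realistic annotation sparsity patterns, FPKM mean–variance
relationships, or the module counts of the published analysis on
thousands of tumour samples (those depend on the full block-wise
machinery and an external enrichment service, and are deliberately out
of the acceptance scope; the stage is instead validated by
planted-structure recovery and structural invariants).

# Reproducibility choices

The pipeline (`runPipeline()`) takes a single declarative config with
no hidden defaults: every effective parameter is echoed into the
provenance record (tool version, config hash, input digests, version
labels, timestamp), every stage output carries the config hash in a
header comment, and two runs with identical inputs and parameters
produce byte-identical stage outputs. Optional stages skip loudly.
Ontology version labels are mandatory inputs throughout — none of the
published schemes recorded the release they were built against, and
making the version explicit everywhere is the design response.

# Known limitations

* The OBO reader covers the tag subset the analyses need (`is_a`,
  `relationship: part_of`, obsoletion, `alt_id`, `replaced_by`); it is
  not a general OBO 1.4 parser (no `regulates`, no cross-ontology
  links, no OWL).
* Pathway-to-term correspondence must be supplied; the package will not
  guess it.
* The co-expression stage is intentionally desk-scale; for
  thousands-of-genes networks use the full block-wise tooling and feed
  the resulting modules back into `moduleSimilarityMatrix()`.
* Semantic similarity assumes both term sets live in one graph version;
  comparing sets curated against different releases is exactly the
  situation the version-diff stage is meant to expose, not something
  the similarity score corrects for.
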