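---
title: "Methods: metapath HeteSim ranking and three-disease overlap analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metapath HeteSim ranking and three-disease overlap analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HeteSimKG)
```

HeteSimKG implements a comparative literature-based-discovery pipeline
over a heterogeneous knowledge graph of semantic triples: typed concept
nodes (UMLS-style semantic types such as `aapp` for
amino-acid/peptide/protein and `dsyn` for disease) joined by directed,
labelled relations, each edge carrying the identifiers of the articles
that assert it. The pipeline ranks AAPP source nodes against disease
target nodes with a deterministic HeteSim relevance measure, normalizes
and thresholds the rankings, quantifies three-way overlap, profiles
biological processes at the disease-pair intersections, and classifies
node evidence as direct or indirect. This vignette records the model, its
assumptions, and the design decisions that were genuinely open.

## The HeteSim relevance model

A *metapath signature* is the type-level shape of a connection: node
types `T0 … TL`, relations `R1 … RL`, and the direction each triple is
traversed. Candidate discovery treats triples as undirected ("search
depth" counts hops, not arrowheads); directions are preserved inside the
signature instead. Signatures are enumerated from *simple* instance paths
(no repeated node) — a path that revisits a node makes no progress from a
target toward a source and would admit degenerate cycles.

Given a signature, each step induces a reachability operator: the 0/1
typed adjacency restricted to the step's (type, relation, direction),
row-normalized. Rows with no matching edge stay zero — a random walker
with nowhere to go loses its mass, which is the behaviour that makes an
unmatched signature score 0 rather than error. For even path lengths the
source's forward and the target's backward walk distributions meet on the
midpoint type and the score is their cosine; odd lengths are first made
even by splitting the middle relation, one artificial midpoint per
middle-edge instance. Cosine normalization makes the measure symmetric
(`HeteSim(s, t | P)` equals `HeteSim(t, s | reverse(P))`) and bounds it
in `[0, 1]`, with 1 attained at self-relatedness under a palindromic
signature. Only the deterministic formulation is implemented; there is no
sampled approximation, so identical inputs give bit-identical rankings.

Aggregation involves two means, only one of which is forced by the
problem statement. Across several targets the package uses the exact
arithmetic mean of the per-target scores. Across the several signatures
connecting one (source, target) pair, the package also uses the
arithmetic mean; this is the symmetric choice, and it is isolated in one
place (`rankSources()`) so a different pooling rule could be substituted
without touching the HeteSim kernel. One consequence worth knowing: under
a per-signature mean, acquiring an extra *weak* signature can lower a
node's aggregate even though each signature's value is non-negative.
Monotonicity in the number of parallel paths holds *within* a signature —
adding a disjoint 2-hop path through the same intermediate type and
relation never decreases the score — and that is the controlled family
the test suite checks.

The matrix implementation (sparse operators, vectorized over sources) is
cross-checked against an independent brute-force oracle that enumerates
walk instances and accumulates meeting probabilities; the two agree to
1e-9 on hundreds of small random graphs in the acceptance suite.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `depth` | 2 hops | candidate-discovery horizon around a target |
| `maxLength` | 3 steps | maximum metapath length |
| `sourceType` | `"aapp"` | semantic type of ranked candidates |
| `topPct` | 1 % | top slice used for mapping and intersections |

Depth 2 / length 3 / AAPP / top 1% are the study settings the package is
built around; all are plain arguments. Path enumeration is implemented
for lengths up to 3 (joins over the directed-expansion edge table); this
covers the study design, and longer metapaths would change the method's
meaning, not just its cost.

## Normalization choices

Raw HeteSim scores are comparable only within one simulation (they depend
on the returned-node population), so per-disease tables are normalized
before any cross-disease statement:

* **z-scores** use the *population* standard deviation. The table is the
  complete population of returned nodes, not a sample from a larger one.
* **percentiles** use the Hazen definition `100 (r − 0.5) / n` with
  average ranks for ties: symmetric around 50, never exactly 0 or 100,
  and stable under relabeling. A single-row table gets z = 0,
  percentile 50; a zero-variance table gets all z = 0 with a warning
  rather than NaNs.
* **top 1%** takes `ceil(n · pct / 100)` nodes, ties at the threshold
  broken by ascending concept identifier, so the selection is a
  deterministic function of the table.
* **composite scores** are means of *raw* per-disease HeteSim scores, not
  of z or percentile — this preserves the convention that a node linked
  to a single disease has composite equal to its HeteSim score.

Venn percentages are rounded half away from zero to one decimal, the
rounding that reproduces the published three-disease shares from their
printed counts; the package keeps the one share that does *not* reproduce
(the ALS-exclusive 1.1%, which computes to 1.0%) flagged as inconsistent
rather than silently reconciled, and treats the GPT-4o F-measure row the
same way (printed 0.82; its printed precision/recall imply 0.81).

## Biological-process mapping

The original study mapped nodes to eight processes with ontology-backed
NLP plus a large language model. The package replaces that with a
deterministic, auditable stand-in: a per-category keyword lexicon matched
case-insensitively on word boundaries against node names, multi-label by
construction. The default lexicon is distilled from the category
definitions (mitosis/apoptosis for cell cycle regulation, cytokine and
microglia for inflammation, ion channels for synapse and
neurotransmission, …) and is replaceable configuration
(`processTaxonomy()`); the eight category labels are fixed. Counting is
per (node, category) *assignment*, since multi-label nodes make
node-level counting ill-defined.

Profiles are reported three ways: raw counts per disease-pair
intersection, per-intersection percentages (columns normalized to 100, to
adjust for intersections of very different sizes), and per-category
z-scores across intersections. The z-scores are computed on the
normalized percentages by default — standardizing counts would mostly
restate the size differences the normalization just removed — with
`zscoresOn = "counts"` available. With only three intersections the
population/sample distinction is material: population sd is used, and
zero-variance categories yield zero rows with a warning. A single
intersection is an error, not a degenerate answer.

## Evidence classification

A node's evidence for the targets is *direct* when a length-1 triple (in
either direction) reaches at least one target, *indirect* when the node
is only connected through intermediates within the search depth, and an
error when it is not connected at all — an unconnected node has no
evidence to classify. Evaluation treats *direct* as the positive class by
default (the choice is an argument), reports NA — never a silent 0 — for
ratios with zero denominators, and retains full precision internally
while rounding to 2 decimals for reporting.

## What the synthetic generator emulates

The generator (`generatorConfig()`, `generateKG()`) produces the study's
shape at desk scale: three disease targets with their real concept
identifiers, `n_aapp` AAPP nodes whose membership in the seven Venn
regions is drawn i.i.d. from `region_probs` (defaults patterned on the
published three-disease proportions, plus a small "none" mass),
per-membership relevance tiers, optional direct edges, and process labels
drawn from a fixed category distribution and embedded into node names as
keywords at `keyword_rate`.

Design decisions that were open, and why they were resolved this way:

* **Single pseudo-random stream, fixed order** (regions and tiers, then
  edges, then names/labels) so a configuration plus seed regenerates the
  fixture byte-identically across machines.
* **One intermediate type per membership.** All `k` bridge paths of one
  (node, disease) membership run through distinct intermediates of a
  single semantic type, so they condense into *one* metapath signature
  whose value grows like `sqrt(k / K)`. Spreading the paths over several
  types was considered and rejected: it adds several weaker signatures,
  and under the per-signature mean that *lowers* strong nodes' aggregates
  — the planted tier ordering inverts. The tier path counts
  (high/mid/low = 6/3/1) are spaced so the square-root growth separates
  tiers against the tier-independent length-3 signatures that any
  direct-edged node acquires.
* **Disease-dedicated bridge pools.** Each intermediate type's pool is
  partitioned three ways so a bridge node serves exactly one disease.
  This makes the set of AAPP nodes within 2 hops of a disease exactly its
  planted membership, which is what lets the pipeline's per-disease
  returned sets recover the planted Venn regions exactly. Real
  intermediates are of course shared between diseases; the dedication is
  a ground-truth-recovery device, not a claim about biology.
* **One simulation per disease.** `runPipeline()` ranks each disease with
  its own single-target simulation — mirroring the study, where each
  disease's returned-node count is a per-simulation output — and only
  then intersects, selects top slices, and aggregates composites.
* **Realizability guard.** Configurations whose tiers plant no bridge
  paths must set `direct_edge_prob = 1`; otherwise a membership could
  exist in the ground truth with no path in the graph. Tier path counts
  must be strictly decreasing (or all zero, the forced-direct degenerate
  case).

What the generator does **not** emulate: the long-tailed degree
distribution of a literature-scale graph, its 133 semantic types and 54
relations (type counts are configuration, defaulting to three bridge
types), negation and relation semantics, per-sentence predication counts,
and citation structure (supporting-article identifiers are synthetic
counters). Passing parameter-recovery tests therefore shows the pipeline
is *correct* on graphs with known structure — not that rankings on the
real literature graph would be biologically valid, which is exactly why
the study used human full-text review as ground truth.

## Problem sizes and numerical tolerances

The test and acceptance suites run at sizes chosen to exercise every code
path while staying desk-sized: random graphs of 5–12 nodes (200 of them)
for the dual-route HeteSim check at 1e-9; synthetic graphs of 40–200 AAPP
nodes for module tests; 500 AAPP nodes for parameter recovery (exact
region and label recovery, perfect evidence metrics at the degenerate
direct-edge rates, and a positive high-versus-low mean-rank gap within
the all-three region for each disease). Exact-arithmetic claims
(inclusion–exclusion, F-measure from precision/recall, composite means)
are asserted to printed precision; floating-point recomputations to 1e-9
or tighter.

## Limitations

The lexicon mapper is a transparent stand-in for ontology/LLM mapping and
inherits keyword brittleness (a node named without any category keyword
maps to nothing, and is reported). The per-signature mean is one of
several defensible pooling rules and materially affects how extra weak
connectivity shifts ranks. Metapath enumeration beyond length 3 is out of
scope, as are sampled HeteSim variants, learned embeddings, overlap
significance testing, and any interactive visualization.
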