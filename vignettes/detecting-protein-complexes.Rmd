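---
title: "Detecting small and large protein complexes by functional grouping and Markov clustering"
author: "funComplexDetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting small and large protein complexes by functional grouping and Markov clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funComplexDetect)
```

## The problem and the model

Most graph-clustering approaches to protein-complex prediction search a
protein-protein interaction (PPI) network for densely connected subgraphs.
That works for complexes of four or more members, but roughly half of the
catalogued yeast complexes have only two or three members — in a network a
dimer is a single edge, and no density criterion can single out one edge
among thousands. funComplexDetect implements a from-function-to-interaction
strategy that handles both size regimes in one framework:

1. **Group proteins by function.** Every protein carries FunCat terms —
   dot-separated chains such as `01.01.03.01.01`, deeper fields being more
   specific. Truncating each term to its first $N$ fields cuts the
   annotation hierarchy at level $N$; proteins whose truncated terms are
   string-identical form one group. A multifunctional protein joins one
   group per distinct truncated term, so groups overlap.
2. **Cluster inside each group.** The PPI subnetwork induced by a group is
   clustered with Markov clustering (MCL). Because a group is small and
   functionally coherent, even a two-protein complex survives as its own
   MCL cluster — the interaction is the only edge its group offers.
   Singleton clusters are discarded; the rest are pooled over all groups.
3. **Merge redundant clusters.** Overlapping groups produce near-duplicate
   clusters. Clusters become nodes of an *overlap graph*, linked whenever
   their overlap rate
   $\mathrm{olr}(C_1, C_2) = |C_1 \cap C_2|^2 / (|C_1|\,|C_2|)$
   exceeds 0.8. Each maximal clique of that graph collapses to the union
   of its clusters' proteins; everything else passes through unchanged.

The central assumption is that co-complex proteins share specific
functional annotations *and* interact densely. Proteins without
annotations are invisible to the method by construction; their count is
reported, never silently ignored.

```{r pipeline}
sim <- simulateComplexData(nComplexes = 20, seed = 42)
pred <- predictComplexes(sim$network, sim$annotations, level = 6)
evaluateComplexes(pred, sim$catalogue)
```

## Evaluation

Predictions are benchmarked against a complex catalogue (MIPS or CYC2008
conventions: one complex per line, whitespace-separated members, size
$\ge 2$). A prediction and a benchmark complex match when their overlap
degree $w$ reaches 0.2 (inclusive). With $M_{bc}$ benchmark complexes
matched at least once and $M_{pc}$ predictions matched at least once,

$$\mathrm{recall} = M_{bc}/|BC|, \qquad
  \mathrm{precision} = M_{pc}/|PC|, \qquad
  F = \frac{2\,rp}{r + p},$$

with $F = 0$ when both are 0. Reports are stratified into small (2–3
members) and large ($\ge 4$) complexes alongside the total.

## Parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `level` | 6 | Annotation truncation level. 6 is the deepest FunCat level, i.e. the most specific grouping; coarser levels merge functionally related groups. |
| `overlapThreshold` | 0.8 | olr above which two clusters count as redundant. High on purpose: only near-duplicates merge. Strict inequality. |
| `wThreshold` | 0.2 | Match threshold on the overlap degree; the conventional value for the neighborhood-affinity score. Inclusive inequality. |
| `minScore` | unset | Optional strict (`>`) confidence filter on input edges, for scored interactomes (e.g. socio-affinity above 5). Pre-filtered networks need no value. |
| `MCLParams()` | expansion 2, inflation 2.0 | Canonical MCL defaults; inflation controls granularity (larger splits finer). |
| `pruneThreshold` | 1e-5 | Entries below it are zeroed after inflation — numerical hygiene that keeps matrices sparse without affecting the attractor structure. |
| `convergenceTol` | 1e-6 | Iteration stops when the largest elementwise change between successive post-inflation matrices falls below this. |
| `maxIterations` | 100 | Cap; hitting it warns and extracts from the last matrix rather than failing. |

## Numerical and design choices

Several points are deliberate choices where more than one reading was
defensible; they are all exposed as arguments so users can pick the other
branch.

* **Binary adjacency inside MCL.** The transition matrix encodes whether
  two proteins are linked, not how confidently; confidence belongs to the
  input filter (`minScore`), not the walk. Running MCL on score-weighted
  adjacency is a plausible alternative that this package does not take.
* **Self-loops before normalization.** Unit diagonal entries damp the
  odd/even oscillations of bipartite-ish walks — standard MCL practice —
  and guarantee positive column sums.
* **Cluster extraction.** Attractors are rows with positive diagonal mass
  in the converged matrix; attractors supporting each other form attractor
  systems, and a node joins every system that gives it positive mass, so
  clusters may overlap in symmetric graphs. Ties are kept, not broken.
* **The form of $w$.** The match score is taken as the same
  squared-intersection form as the overlap rate (the neighborhood-affinity
  score that the 0.2 threshold conventionally accompanies); plain Jaccard
  is available via `method = "jaccard"` and results should always be
  labelled with the choice.
* **Maximal cliques, consumed once.** "Cliques" of the overlap graph are
  interpreted as maximal cliques (Bron–Kerbosch enumeration via igraph).
  A cluster lying in several maximal cliques is merged exactly once, by
  the largest clique, ties broken lexicographically on the sorted member
  identities — this keeps protein conservation exact and output
  deterministic. Connected components of the overlap graph would be the
  coarser alternative reading. Merging is a single pass; merged complexes
  are not re-tested against each other.
* **Stratified metrics restrict both sides.** In the small column both
  predictions and benchmarks are restricted to sizes 2–3 (symmetric
  reading), so a large prediction cannot claim a small benchmark complex.
  The total row uses unrestricted sets. An empty stratum reports `NA`
  with `defined = FALSE`, never a silent zero.
* **Exact string terms.** `01` and `1` are different terms, and a term
  that exists only above the cut level forms its own group rather than
  joining deeper siblings that share its prefix.
* **Determinism.** All set-valued outputs are sorted in C-locale
  (radix) order, so repeated runs and reordered inputs give identical
  files.

## What the synthetic generator emulates — and what it does not

`simulateComplexData()` plants `nComplexes` disjoint complexes with sizes
drawn from 2–10. The default size weights imitate the small/large
composition of the CYC2008 catalogue (156 size-2, 66 size-3, 127 larger,
about 64% small). Each complex receives a unique depth-6 term; members are
annotated with it (minus `annotationDropout`), sometimes plus one random
extra term (`multiAnnotationRate`, default 0.1 — proteins are
multifunctional). Within-complex edges appear with probability `pIn`
(default 0.9) and a random spanning tree is overlaid, because a
disconnected planted complex is unrecoverable by *any* graph-clustering
method and would only make recovery tests flaky. Background noise edges
(default twice the number of planted proteins) connect uniformly chosen
pairs that share no complex, and 20% extra bystander proteins carry random
annotations. `sharedPrefixDepth` makes all complex terms agree on their
first $k$ fields, so grouping only resolves complexes at levels deeper
than $k$ — the device used to study the effect of the annotation level.

The generator does **not** emulate TAP-MS spoke/matrix artefacts,
correlated false positives around sticky baits, overlapping true
complexes, or the incompleteness structure of real annotation databases.
Passing recovery tests on these inputs therefore demonstrates that the
algorithmic machinery is correct under the model's own assumptions, not
that real-interactome performance will match.

## Problem sizes in the test suite

The suite verifies the MCL engine against an independently written dense
reference implementation on 50 random connected graphs of up to 20 nodes,
checks component confinement and node coverage on 200 random graphs,
overlap arithmetic on 1000 random set pairs, the merge contract on 100
random cluster collections, and end-to-end recovery on benchmarks of 50
planted complexes (roughly 250 proteins and 600 edges). These sizes give
stable properties at interactive runtimes; the pipeline itself handles
interactome-scale inputs since per-group subnetworks stay small.

## Known limitations

* Unannotated proteins can never be predicted — the grouping step defines
  the method's universe.
* Two complexes with identical membership in the benchmark count once
  (sets, not multisets).
* Overlap-graph construction is all-pairs ($O(n^2)$ in the number of
  preliminary clusters) and clique enumeration is worst-case exponential;
  both are fine for the sparse, tiny overlap graphs this method produces
  (a warning fires above 5000 clusters).
* Merged complexes are not iteratively re-merged; a chain of borderline
  overlaps can leave two similar output complexes.
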