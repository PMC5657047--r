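# funComplexDetect

Protein complex detection from protein-protein interaction (PPI)
networks, for computational biologists benchmarking complex-prediction
pipelines on yeast-style interactomes.

Classical graph clustering finds complexes of four or more members by
looking for dense subgraphs, but about half of the catalogued yeast
complexes have only two or three members — a dimer is a single edge, and
no density criterion can pick one edge out of an interactome.
funComplexDetect detects small and large complexes under one framework by
working *from function to interaction*:

1. **Group** proteins whose hierarchical FunCat annotations (dot-separated
   terms such as `01.01.03.01.01`) are identical after truncation to the
   first *N* levels ("cutting the annotation hierarchy"; default *N* = 6,
   the most specific level). Multifunctional proteins join several groups.
2. **Cluster** each group's induced PPI subnetwork with Markov clustering
   (MCL: alternating matrix expansion and Hadamard inflation on the
   column-stochastic transition matrix until convergence), discard
   singleton clusters, and pool the rest.
3. **Merge** redundant clusters: clusters are linked in an overlap graph
   when olr(C₁, C₂) = |C₁ ∩ C₂|² / (|C₁| · |C₂|) > 0.8, and every maximal
   clique collapses to the union of its clusters' proteins.

Predictions are benchmarked against complex catalogues (MIPS / CYC2008
file conventions) with size-stratified recall = M_bc/|BC|,
precision = M_pc/|PC| and F-measure = 2rp/(r+p), where a prediction and a
benchmark complex match when their overlap degree w reaches 0.2.
A seeded synthetic-data generator plants dense, annotated complexes in
noisy networks so every stage is testable without external downloads.

## Worked example

```r
library(funComplexDetect)

sim  <- simulateComplexData(nComplexes = 20, seed = 42)
sim$network
#> PPINetwork with 118 proteins and 432 interactions
sim$catalogue
#> ComplexSet 'planted': 20 complexes (9 small [2-3], 11 large [>=4])

pred <- predictComplexes(sim$network, sim$annotations, level = 6)
pred
#> ComplexSet 'predicted': 20 complexes (9 small [2-3], 11 large [>=4])

evaluateComplexes(pred, sim$catalogue)
#>  stratum defined nPredicted nBenchmark mPC mBC recall precision fMeasure
#>    small    TRUE          9          9   9   9      1         1        1
#>    large    TRUE         11         11  11  11      1         1        1
#>    total    TRUE         20         20  20  20      1         1        1
```

The report reads: all 9 planted small complexes and all 11 large ones
were recovered (recall 1 in both strata), and every predicted complex
matched a planted one (precision 1) — on this low-noise simulation the
pipeline reconstructs the ground truth exactly. On real interactomes use
`readEdgeList()` (optionally with `minScore` for confidence-scored edge
lists), `readAnnotations()` and `readComplexes()` in place of the
simulator.

A command-line wrapper with `predict`, `eval` and `synth` subcommands is
installed at `inst/scripts/complex-detect.R`:

```sh
Rscript inst/scripts/complex-detect.R predict \
    --ppi ppi.tsv --annotations annotations.tsv \
    --annotation-level 6 --overlap-threshold 0.8 --out predicted.tsv
Rscript inst/scripts/complex-detect.R eval \
    --predicted predicted.tsv --benchmark cyc2008.tsv --w-threshold 0.2
```

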