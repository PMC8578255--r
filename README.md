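# mxprop — informed multiplex network propagation for rare disease genes

`mxprop` is an R toolkit for prioritizing disease genes and patient candidate
variants on a *multiplex network*: a stack of gene–gene network layers
(co-expression, physical interaction, pathway co-membership, ontology-based
semantic similarity, phenotype similarity) sharing one gene universe. It is
aimed at computational geneticists who have per-layer edge lists — or the
primary data to build them — and a set of disease-associated genes or a
patient's phenotype terms, and want a ranking of candidate genes that uses
only the layers that actually carry signal for that disease.

## The method

**1. Layer relevance.** For disease genes *D* and layer *m*, the disease
module statistic is the largest connected component (LCC) of the subgraph
induced by *D*. Against a null of uniformly sampled node sets of the same
size this gives a z-score *z<sub>dm</sub>* and an empirical p-value
(Benjamini–Hochberg corrected across the disease × layer table). Layers with
*z<sub>dm</sub>* ≥ 1.645 (95% normal quantile) are *informative* and receive
relevance weights

&nbsp;&nbsp;&nbsp;&nbsp;π<sub>m</sub> = z<sub>dm</sub> / Σ<sub>m</sub> z<sub>dm</sub>.

**2. Informed walk.** A random walk with restart runs over (gene, layer)
states. Layer switches follow a Metropolis kernel
p(m|n) = (1/L)·min(1, π<sub>m</sub>/π<sub>n</sub>), which satisfies detailed
balance π<sub>n</sub> p(m|n) = π<sub>m</sub> p(n|m), so the walker visits
layers in proportion to their relevance. Within a layer, moves follow a
degree-normalized step; the iteration is
p<sub>t+1</sub> = (1 − r) S̃ p<sub>t</sub> + r p<sub>0</sub> with restart
r = 0.7. Genes are scored by their mean visiting probability across layers;
seeds are omitted from rankings.

**3. Layer construction.** Supporting builders cover the standard pipeline:
Spearman co-expression with an |ρ| > 0.75 cutoff, disparity-filter backbone
extraction (p<sub>ij</sub> = (1 − w<sub>ij</sub>)<sup>k−1</sup>, both-sided
rule), Resnik/Lin term similarity with best-match-average gene similarity,
pathway co-membership, core/tissue-specific splitting, edge-overlap layer
similarity S<sub>AB</sub> = |E<sub>A</sub> ∩ E<sub>B</sub>| / min(|E<sub>A</sub>|, |E<sub>B</sub>|)
with permutation significance, and per-layer structural statistics including
a node-level (local) assortativity decomposition.

See `vignettes/informed-multiplex-propagation.Rmd` for the model details,
parameter defaults and design decisions.

## Worked example

Simulate a 300-gene multiplex (6 layers, a 20-gene disease module planted in
layers L01–L03), score layer relevance, and retrieve held-out module genes:

```r
library(mxprop)

fx  <- make_multiplex(seed = 42)
tab <- relevance_table(fx$multiplex, list(fx$group), n_rand = 1000, seed = 42)
tab[, c("group", "layer", "lcc", "z", "p_adjusted", "stars")]
#>     group layer lcc       z p_adjusted stars
#> 1 planted   L01  20 11.5740      0.002    **
#> 2 planted   L02  20 13.3693      0.002    **
#> 3 planted   L03  20 12.8382      0.002    **
#> 4 planted   L04   3  0.0428      0.869
#> 5 planted   L05   2 -0.8953      0.986
#> 6 planted   L06   2 -0.7729      0.986
```

The module's LCC fills all 20 genes in the three planted layers (z ≈ 12,
adjusted p = 0.002, the resolution of 1000 null draws) and is
indistinguishable from random gene sets elsewhere. Normalizing the z-scores
of the informative layers gives the relevance profile:

```r
rel <- relevance_scores(setNames(tab$z, tab$layer))
round(rel$pi, 3)
#>   L01   L02   L03   L04   L05   L06
#> 0.306 0.354 0.340 0.000 0.000 0.000
```

Seed the informed walk with 15 of the 20 module genes and rank the rest of
the universe:

```r
ker <- layer_transition_kernel(rel)
res <- informed_rwr(fx$multiplex, ker, seeds = fx$group$genes[1:15])
head(aggregate_and_rank(res), 5)
#>    gene   score rank
#> 1 g0292 0.00138    1
#> 2 g0283 0.00128    2
#> 3 g0300 0.00127    3
#> 4 g0259 0.00125    4
#> 5 g0291 0.00104    5
```

The five held-out module genes occupy exactly ranks 1–5 of the 285
non-seed genes. The cross-validated view of the same contrast:

```r
kfold_retrieval(fx$multiplex, fx$group, relevance = rel,
                regime = "relevant_layers", seed = 42)$median_auroc
#> [1] 1
kfold_retrieval(fx$multiplex, fx$group, regime = "ppi_only",
                reference_layer = "L06", seed = 42)$median_auroc
#> [1] 0.4375
```

Retrieval through the relevant layers is essentially perfect, while a single
non-relevant layer performs at chance — the central claim of the
relevance-informed design, here on ground-truth synthetic data.

For patient-level use, `make_patient_case()` simulates a solved case
(phenotype terms, 50 candidates, known causal gene) and
`prioritize_patient()` seeds the walk from phenotype-annotated genes and
ranks the candidate list; `baseline_rank()` provides the pathway-count,
expression, literature-count and phenotype-similarity baselines.

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mxprop.R", package = "mxprop"))')
Rscript "$CLI" simulate --out demo --seed 1
Rscript "$CLI" modules --multiplex demo/manifest.json --groups demo/groups.gmt --out demo_rel
```

Subcommands: `simulate`, `build-coexpr`, `build-onto`, `build-pathway`,
`filter`, `overlap`, `stats`, `modules`, `propagate`, `crossval`,
`prioritize`. Every run writes a JSON manifest with its options and seed;
identical command and seed give byte-identical outputs.

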