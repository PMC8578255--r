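---
title: "Informed multiplex propagation: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Informed multiplex propagation: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxprop)
```

## The problem

Rare-disease gene discovery suffers from a mismatch between where disease
biology lives and where our data are densest. Physical interaction maps are
biased toward well-studied genes; co-expression captures regulatory
relationships invisible to proteomics; phenotype ontologies encode clinical
knowledge that never appears in an interactome. `mxprop` treats these sources
as layers of one *multiplex network* — every layer has the same gene
identities, different edges — and asks two questions for a given disease:

1. **Which layers are informative?** A disease whose genes cluster into a
   connected module on a layer can be *discovered* on that layer; a disease
   whose genes are scattered there cannot.
2. **How should a network walker exploit that knowledge?** By visiting
   informative layers in proportion to how informative they are.

## Disease-module significance

For disease genes $D$ and layer $m$, the module statistic is the size of the
largest connected component (LCC) of the subgraph induced by $D$ in $m$. Its
null distribution is obtained by drawing `n_rand` uniform node sets of size
$|D \cap V_m|$ from the layer's own node set, without replacement. We report

$$z_{dm} = \frac{LCC_{obs} - \mu_{null}}{s_{null}}, \qquad
p = \frac{\#\{null \ge obs\} + 1}{n_{rand} + 1},$$

with Benjamini–Hochberg correction across the whole disease × layer table.
Choices worth knowing:

* **Null node pool.** Random sets are drawn from the layer's node set, not
  the multiplex universe, so layers with poor gene coverage are not penalized
  twice.
* **Sample sd (ddof 1)** in the z-score; the add-one correction keeps
  empirical p-values strictly positive (resolution $1/(n_{rand}+1)$; the
  default `n_rand = 1000` matches the star thresholds used in the relevance
  heatmap down to $10^{-3}$).
* **Degenerate nulls** (e.g. complete graphs) give a sentinel `NA` z; the
  p-value from counts is still valid.
* Above the percolation threshold the null LCC is approximately normal,
  which is what makes the z-score a meaningful relevance measure; far below
  it, rely on the empirical p-value instead.

## Relevance scores and the layer kernel

Layers with $z_{dm} \ge 1.645$ (the one-sided 95% normal quantile) are
*informative*; their relevance is $\pi_m = z_m / \sum z_m$, zero elsewhere.
If no layer passes, the profile falls back to uniform weights over all layers
— the walk then degrades gracefully to the uninformed baseline rather than
failing.

Layer switching follows a Metropolis construction over the $L$ informative
layers:

$$p(m\,|\,n) = \tfrac{1}{L}\min\!\big(1, \pi_m/\pi_n\big), \qquad
p(n\,|\,n) = 1 - \sum_{m \ne n} p(m\,|\,n).$$

Because $\pi_n\,p(m|n) = \tfrac1L \min(\pi_n, \pi_m)$ is symmetric, detailed
balance holds exactly and $\pi$ is the stationary distribution: over a long
walk, the fraction of time spent in layer $m$ is $\pi_m$. This is the design
reason for the Metropolis form; the test suite asserts row-stochasticity,
balance and stationarity to $10^{-12}$ on random profiles. Layers with
$\pi = 0$ are removed from the state space entirely (equivalent to never
visiting them, and cheaper).

## The informed walk

States are (gene, informative layer) pairs. From $(g, n)$ the walker moves
intra-layer with probability $p(n|n)$ along a uniformly chosen layer-$n$ edge
of $g$ — neighbors equally likely; post-backbone layers are unweighted so
degree normalization is the natural choice — and jumps to $(g, m)$ with
probability $p(m|n)$. The iteration is the classic restart form

$$p_{t+1} = (1 - r)\,\tilde S\,p_t + r\,p_0, \qquad r = 0.7,$$

with $p_0$ spreading each seed gene's weight equally over the informative
layers. Numerical choices:

* **Convergence** is declared when the L1 change drops below `tol = 1e-8`
  (exact equality of successive iterates is unattainable in floating point);
  the cap is 10,000 iterations and non-convergence is flagged, never silent.
  With $r = 0.7$ the iteration contracts by $0.3$ per step, so convergence
  takes a few dozen iterations.
* **Dangling states.** A gene with no edges in its current layer has nowhere
  to move intra-layer; that probability mass is redirected to the restart
  vector, keeping the operator stochastic (a `"stay"` alternative is
  available). Total visiting probability is conserved to $10^{-9}$.
* A gene's final score is the arithmetic mean of its visiting probability
  across informative layers; seeds are omitted from rankings (they trivially
  dominate), with deterministic lexicographic tie-breaks.

The implementation is validated two independent ways: against a direct dense
linear solve of $p = (1-r)\tilde S p + r p_0$ (max abs error $< 10^{-8}$ on
multiplexes with up to 60 states), and — with uniform $\pi$ — against a
separately written dense uninformed multiplex walk ($< 10^{-10}$).

## Building layers

**Co-expression.** All-pairs Spearman correlation (average ranks for ties);
zero-variance genes are excluded before pairing since their rank correlation
is undefined. Pairs with $|\rho| \le 0.75$ are discarded and $|\rho|$ becomes
the edge weight — the sign is already consumed by the cutoff, and the
backbone filter needs a magnitude. No TPM pre-filter is applied; the
disparity filter is the sole backbone criterion.

**Disparity filter.** For node $i$ of degree $k$ with incident weights
normalized to sum 1, edge significance from $i$'s side is
$p_{ij} = (1 - w_{ij})^{k-1}$. An edge survives only when **both** endpoint
p-values are below $\alpha$ (default 0.05). Note two deliberate conventions:
the AND rule is stricter than the OR rule of the original disparity-filter
literature (an `or_rule` flag restores it), and a degree-1 node has
$p = (1-1)^0 := 1$, so pendant edges never pass from their pendant side —
under the AND rule they are always removed.

**Ontology similarity.** Information content is topology-based:
$IC(t) = -\ln(n_t/N)$ with $n_t$ the descendant count *including $t$
itself*, so $IC(root) = 0$, $p(t) \in (0,1]$, and ancestors are never more
informative than descendants. Natural log is a documented constant: any other
base rescales Resnik uniformly and leaves Lin invariant. Gene similarity is
the best-match average over the genes' *direct* annotations; ancestor closure
enters only the frequency method ($|T_{g_1} \cap T_{g_2}|$ with closures).
Pairs whose only common ancestor is the root carry no shared information and
are removed before the disparity backbone is extracted.

**Pathways.** Two genes are connected when at least `min_shared = 5` gene
sets contain both.

**Core vs tissue-specific.** Edges occurring in at least `min_count = 5` of
the tissue layers form the core layer; each tissue layer minus the core is
its specific counterpart. Every input edge lands in exactly one of the two.

## Structural statistics

`layer_summary()` computes density, transitivity (3 × triangles / connected
triples — *global* clustering, not the average of local coefficients) and
degree assortativity (Pearson correlation of excess degrees over directed
edge ends) from first principles; the test suite cross-checks all three
against igraph on random graphs. Undefined statistics (zero degree variance,
no triples) are sentinels (`NA`), never silent zeros.

`local_assortativity()` decomposes the global assortativity into node
contributions $\rho_v = j_v(j_v+1)(\bar k_v - \mu_q) / (2M\sigma_q^2)$. Here
$\bar k_v$ is the mean excess degree *of $v$'s neighbours* — with a global
mean in its place the expression is identically zero — and $\sigma_q^2$ is
the population variance of the excess-degree distribution over edge ends.
These two readings are pinned down by the defining property, asserted to
$10^{-9}$: the node values sum to the global assortativity.

## Cross-validation and patient scoring

`kfold_retrieval()` shuffles a disease's genes into k folds (default 10);
each fold is retrieved by propagation seeded from the others, scored by
AUROC (Mann–Whitney with 1/2 for ties) against all universe genes not
associated with the disease. The four regimes — relevance-weighted,
all-layers uniform, best single layer, designated reference layer —
share folds and seeds, so their comparison is paired. The relevance profile
is computed once from the full gene set, mirroring the intended use where
layer relevance is an annotation-level property rather than a per-fold
estimate; the headline summary is the median over folds.

`prioritize_patient()` seeds the walk with the genes annotated to the
patient's phenotype terms, each weighted by how many of the patient's terms
annotate it, and ranks the candidate list. Candidates that are themselves
seeds stay in the ranking (the causal gene of a solved case is often
phenotype-annotated) — a deliberate, toggleable exception to the global
"seeds omitted" rule.

## What the synthetic fixtures emulate — and what they do not

The generators in `make_multiplex()`, `make_expression()`,
`make_toy_ontology()` and `make_patient_case()` reproduce the statistical
structure the method relies on, at desk scale:

* **Planted modules** (default: 300 genes, 6 layers, module of 20 planted in
  3 layers at edge probability 0.3 over an Erdős–Rényi background of 0.02,
  with a spanning-tree connectivity guarantee). The 20-gene module matches
  the smallest disease-group size the method is intended for; 300 genes and
  6 layers keep a 10-fold CV × 20-seed experiment in seconds while the
  background density keeps the null LCC well below the module size. A
  heterogeneous-degree background (`degree_background = TRUE`) is available
  to check robustness of the LCC null to degree variance.
* **Block co-expression**: `latent_corr` is defined as the target *pairwise*
  within-block correlation (gene loading $\sqrt{c}$ on a shared latent
  profile); defining it as the gene–latent loading instead would square the
  pairwise correlation and make the generator's own contract (within-block
  pairs pass the 0.75 cutoff at $c = 0.9$) unsatisfiable. Values are
  exponentiated to a TPM-like scale — irrelevant to Spearman, convenient for
  realistic file fixtures.
* **Patient cases**: module genes share phenotype leaves from a 3-leaf
  disease pool; the patient's term set is one of the causal gene's two
  leaves plus two noise leaves. Phenotype information is thus deliberately
  imperfect — decoys can match the noise terms — which reproduces the
  qualitative benchmark ordering the method targets: phenotype similarity is
  the strongest gene-level baseline, and informed propagation beats it.

What passing tests on these fixtures does **not** show: behaviour under
scale-free degree distributions fitted to real interactomes, under the
literature bias of curated databases, under correlated layers (fixture layers
are independent given the module), or at genome scale where layer coverage
differs by thousands of genes. Results on real data additionally depend on
identifier mapping and curation quality, both out of scope here (gene
identifiers are opaque case-sensitive strings).

## Known limitations

* Edge weights are not used inside the walk; layers are expected to be
  post-backbone and unweighted. A strength-weighted intra-layer step would be
  a straightforward extension.
* The permutation overlap test's empirical p-value is conservative on sparse
  layers where the null overlap distribution is heavily tied.
* `relevance_table()` cells with fewer than two mappable genes are reported
  as not testable rather than extrapolated.
* The CLI is a thin wrapper; programmatic use through the package functions
  is the primary interface.

## Reproducibility

Every stochastic entry point takes an integer `seed` and restores the
caller's RNG state; identical inputs and seed give bitwise-identical results,
including CLI outputs (scores serialized at 10 significant digits). Problem
sizes used by the bundled experiments: 20 fixture seeds, `n_rand` = 1000
(relevance) / 500 (patient runs), 10-fold CV, 50-candidate patient cases.
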