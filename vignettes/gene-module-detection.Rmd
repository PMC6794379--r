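---
title: "Detecting annotated gene modules in single-cell coexpression networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting annotated gene modules in single-cell coexpression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmodules)
```

## The problem

Single-cell RNA-seq resolves a tissue into cell clusters (types or
states), and each cluster is deep enough to support its own gene-gene
coexpression network. Interpreting such a network means grouping its
genes into *functional modules* — subnetworks that are both densely
interconnected and coherently annotated (a GO term, a Reactome pathway).
This is a different task from cell clustering (which happens upstream,
e.g. in Seurat) and from plain enrichment (which returns terms for a
gene list but no module structure or module-module relations).

`scmodules` covers the post-clustering stretch of the analysis:

1. **Coexpression** — a symmetric gene × gene similarity matrix per
   cluster;
2. **Thinning** — reducing the fully connected weighted network to its
   informative edges;
3. **Assessment** — benchmarking competing extraction settings against a
   ground-truth network;
4. **Module detection** — partitioning the extracted network by jointly
   optimizing topology and annotation agreement;
5. **Collapse** — summarizing the result as a module-module network with
   self-loops.

## Coexpression metrics

`coexpression()` offers Pearson, Spearman and Kendall (tau-b)
correlation plus the two proportionality measures from the
compositional-data literature, computed on `log(x + pseudocount)`:

\[
\rho(x, y) = 1 - \frac{\operatorname{var}(\log x - \log y)}
                      {\operatorname{var}(\log x) + \operatorname{var}(\log y)},
\qquad
\phi(x, y) = \frac{\operatorname{var}(\log x - \log y)}
                  {\operatorname{var}(\log x)}.
\]

Proportionality is attractive for sparse, dropout-ridden single-cell
counts because it is invariant to per-gene scaling; rank-based Spearman
and Kendall are robust to outliers and monotone distortions. There is no
universally best choice, which is why the assessment step exists.

Numerical choices worth knowing:

* **Pseudocount** (default 1): \(\rho\) and \(\phi\) need strictly
  positive values; the pseudocount is configurable and a value of 0 with
  zeros present is an error, not a silent `log(0)`.
* **phi symmetry**: \(\phi\) is asymmetric in its arguments. The matrix
  entry averages \(\phi(x,y)\) and \(\phi(y,x)\) so the coexpression
  matrix is exactly symmetric; the vector-level `phi_prop()` keeps the
  classic asymmetric definition. Note \(\phi\) is a *dissimilarity*
  (0 = perfectly proportional) — rank-transform or invert it before
  magnitude-based thinning.
* **Zero-variance genes** yield `NA` entries (flagged undefined), never
  silent zeros; thinning treats `NA` as "no edge".

## Thinning

The coexpression matrix is a fully connected network whose weight
distribution is typically highly skewed: most pairs carry noise-level
weights. Three strategies extract the informative subnetwork, all
operating on \(|c_{ik}|\) with an inclusive boundary (so percentile 100
and threshold 0 are exact identities):

* `thin_abs_threshold(C, t)` — keep \(|c| \ge t\);
* `thin_percentile(C, q)` — keep the top \(q\%\) of defined pairs,
  retaining all boundary ties;
* `thin_scale_free(C, grid, gamma_target)` — grid search over cutoffs,
  scoring each candidate subnetwork by how scale-free it is.

Biological networks typically show power-law degree distributions with
exponent \(\gamma \in [2, 3]\). For each cutoff we fit a discrete power
law by maximum likelihood with \(x_{\min} = 1\) and score the candidate
by

\[ \text{score} = \mathrm{KS} + |\hat\gamma - \gamma_{\text{target}}|, \]

the Kolmogorov–Smirnov distance of the fit plus the distance of the
exponent from the target, with equal weight. "Best fit" and "target
exponent" are the two ingredients a scale-free criterion supplies; the
full per-cutoff log is returned so users can re-rank under their own
weighting. \(x_{\min}\) is fixed at 1 rather than estimated: degree-1
nodes carry most of the mass in thinned coexpression networks, and
estimating \(x_{\min}\) would silently discard them. Isolated genes are
dropped from extracted networks (modularity is undefined for degree-0
nodes).

## Assessing extracted networks

With five metrics and three thinning families there is no one-size-fits-all
extraction; different cell types genuinely prefer different settings.
Given a user-supplied ground-truth network (GTN; any undirected gene-pair
edge list, e.g. compiled from complex or interaction databases), each
candidate network \(N\) is scored by the affinity score

\[ AS(N, GTN) = \frac{h(N, GTN)^2}{|E_N| \cdot |E_{GTN}|} \in [0, 1], \]

where \(h\) counts edges present in both networks. Because \(AS\)
depends on both networks' sizes, it is calibrated per network: we rewire
\(N\) by degree-preserving double-edge swaps (default 10 swaps per
edge), recompute \(AS\) for each of `n_perm` replicates, and report the
add-one permutation p-value

\[ p = \frac{1 + \#\{AS_{\text{rewired}} \ge AS_{\text{obs}}\}}{1 + n_{\text{perm}}}, \]

which is never exactly 0 and counts ties conservatively toward the null.
`rank_methods()` assembles the per-cell-type \(-\log p\) matrix,
min-max rescaled within each row (so each row uses the full color range
of a heatmap), and flags the best method(s) per cell type.
`clustering_coherence()` compares two finished partitions by the
fraction of shared genes carrying the same term label — the only module
identity comparable across independently extracted networks.

## Module detection

A partition of the network is scored by two quantities. Newman
modularity,

\[ Q = \sum_h \left[ \frac{e_h}{|E|} - \left( \frac{d_h}{2|E|} \right)^2 \right] \in [-1, 1], \]

measures within-module edge excess over a degree-matched random graph
(`modularity_q()` is cross-checked in the test suite against both
exhaustive enumeration and igraph's implementation). Annotation
agreement,

\[ Q_{GO} = \sum_h \frac{|\delta(t_h) \cap C_h|}{N_{\mathrm{AnnSo}}} \in [0, 1], \]

counts, per module, the members contained in the module's selected term
\(t_h\), normalized by the number of network nodes carrying at least one
dictionary annotation. Term selection (`select_module_term()`)
maximizes overlap with the module, breaking ties toward the smaller
(more specific) gene set and then lexicographically — deterministic by
construction.

`detect_modules()` optimizes the blended objective
\(w \cdot Q + (1 - w) \cdot Q_{GO}\) (default \(w = 0.5\)):

1. modules are seeded from the dictionary terms present in the network
   (each annotated gene joins its preferred term's module; unannotated
   genes attach to their strongest term-seeded neighbor or start as
   singletons — with no dictionary the start is all singletons);
2. each iteration fixes module terms, then sweeps the nodes in
   seed-shuffled order, moving each to the adjacent module (or a fresh
   singleton) with the largest positive blended gain — the \(Q_{GO}\)
   part of the gain is exactly the attraction of a gene toward modules
   whose term contains it;
3. emptied modules dissolve, terms are reselected, and \((Q, Q_{GO})\)
   is recorded;
4. the run stops when both scores change by less than \(T = 10^{-4}\)
   between consecutive iterations (or at `max_iter`, flagged
   unconverged).

Local moves with per-iteration term reselection realize the two design
principles — topology and annotations co-driving module reshaping at
every step — while staying simple enough to audit: the recorded
trajectory is recomputed from scratch on the returned partition and must
agree to 1e-10 (a standing test). Tie-breaking on equal gain is "stay
put", which makes runs reproducible given the seed.

Two knobs matter in practice:

* `topology_weight` (default 0.5) trades modularity against annotation
  agreement; 1 is pure topology (dictionary ignored), 0 trusts the
  dictionary entirely.
* `density_mode = TRUE` returns the iterate with the highest mean
  within-module edge density (singletons count 0) instead of the final
  iterate — useful when the annotation source is suspected of biasing
  module shapes, since density depends only on the network.

## The module-module network

`collapse_modules()` aggregates \(|w|\) over gene edges: cross-module
edges sum into module-module edges, within-module edges into self-loops,
so total aggregated weight conserves the total gene-edge weight exactly
(a standing test; a `mean` mode is available for size-independent edge
thickness, at the cost of conservation). Module color indices are
assigned by descending member count for stable visual output.
`export_network()` writes GraphML, a plain JSON dialect, or edge TSV,
self-loops included.

## Synthetic data: what it emulates, what it does not

All tests run on seed-deterministic generators, so nothing is downloaded:

* `gen_planted_network()` — stochastic block model (within-block edge
  probability `p_in`, cross-block `p_out`); the planted module-recovery
  benchmark uses 4 blocks × 30 genes, `p_in = 0.4`, `p_out = 0.02`.
* `gen_planted_expression()` — a per-block latent cell factor enters
  every member gene's log expression (`sqrt(base_corr) * z`), plus
  `noise_sd` Gaussian noise, exponentiation, integer rounding and
  quantile-based dropout (default rate 0.3). This emulates the block
  correlation structure and zero inflation of normalized scRNA-seq
  counts; the within-block log-scale correlation is
  `base_corr / (base_corr + noise_sd^2)`.
* `gen_annotation_dict()` — one term per block with tunable coverage and
  contamination, plus optional decoy terms.
* `gen_power_law_network()` — inverse-CDF degree sample from
  \(P(k) \propto k^{-\gamma}\) wired by the configuration model and
  simplified.

These fixtures deliberately omit library-size variation, batch effects
and doublets. Passing tests therefore demonstrate algorithmic
correctness (score definitions, conservation laws, null calibration,
recovery of planted structure at realistic noise), not robustness to
every artifact of real droplet data — on real data the assessment
module, not the simulator, is the arbiter of extraction quality.

## Default parameters at a glance

| Parameter | Default | Unit / range | Why |
|---|---|---|---|
| `pseudocount` | 1 | counts | standard log-transform offset for zeros |
| `percentile` | 20 | % of defined pairs | keeps the strong tail of a skewed weight distribution |
| `gamma_target` | 2.5 | exponent | midpoint of the biological range \([2, 3]\) |
| `n_swap_multiplier` | 10 | swaps per edge | ample mixing for degree-preserving rewiring |
| `n_perm` | 100 | replicates | p-value resolution 1/101 |
| `T` | 1e-4 | score units | convergence tolerance on both Q and QGO |
| `topology_weight` | 0.5 | \([0,1]\) | equal footing for topology and annotation |
| QC `min_genes` | 500 | genes/cell | droplet QC convention |
| QC `max_umi` | 10,000 | UMIs/cell | doublet guard (inclusive bound) |
| QC `max_mito_fraction` | 0.1 | fraction | stressed/dying-cell guard |
| `min_cluster_size` | 50 | cells | below this, per-cluster correlations are unstable (strict `<` removal) |
| dropout rate (simulator) | 0.3 | fraction | typical zero inflation of normalized counts |

The QC defaults are conventions for mouse droplet atlases, not claims of
generality — adjust them per data set. Mitochondrial genes are detected
by configurable id prefix (`MT-` after normalization).

## Degenerate inputs and edge cases

* Fewer than 3 cells in a cluster: coexpression errors (correlation is
  meaningless).
* Networks with a single edge cannot be rewired; the input is returned
  with a warning.
* A triangle rewires to itself (no degree-preserving alternative
  exists) — the permutation p-value is then 1 by construction.
* Empty dictionary: detection degenerates to pure-topology optimization;
  modules carry the `"unlabeled"` sentinel.
* Degree multisets with fewer than 3 distinct values cannot support a
  power-law fit and are flagged undefined; a grid whose every cutoff is
  undefined errors with advice to densify the grid.

## Known limitations

* The node-move schedule is a local optimizer; on adversarial graphs it
  can stop at a local optimum (the test suite bounds this on small
  graphs by exhaustive enumeration: the returned objective beats at
  least 95% of all partitions).
* Kendall coexpression is \(O(g^2 m \log m)\) and becomes slow beyond a
  few thousand genes; Spearman is the pragmatic default.
* Thinning compares \(|c|\), which is the right scale for correlations
  but inverted for \(\phi\); convert \(\phi\) to a similarity first.
* Problem sizes in the test suite (networks of 100–5,000 nodes,
  200-replicate calibrations) were chosen so the whole suite runs in a
  few minutes on a laptop while keeping binomial error bars tight enough
  to be meaningful.

## A worked run

```{r, eval = FALSE}
sim <- gen_planted_expression(c(30, 30, 30, 30), n_cells = 200, seed = 1)
dict <- gen_annotation_dict(sim$truth, coverage = 0.9, contamination = 0.1,
                            seed = 1)
C <- coexpression(sim$expression, "spearman")
net <- thin_percentile(C, 10)
part <- detect_modules(net, dict, seed = 1)
part
collapse_modules(net, part)
```

The same flow, file-to-file, is available through `run_pipeline()` with
a `run_config()`, or from the shell via the thin CLI in
`inst/cli/scmodules` (subcommands `coexpr`, `thin`, `assess`, `detect`,
`collapse`, `fixtures`, `run`).
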