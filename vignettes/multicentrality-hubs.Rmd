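---
title: "Multi-centrality hub detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-centrality hub detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multicent)
```

## The problem

Protein-protein interaction (PPI) networks built around a curated seed list
— here, proteins functionally tied to vitamins — are sparse, fragmented at
the periphery, and held together by a small set of proteins that are
prominent at every topological scale. A single centrality index cannot
certify such proteins: degree sees only the immediate neighborhood,
betweenness only brokerage, closeness only average reach. `multicent`
identifies *multi-centrality hubs*: proteins that score highly on six
indices spanning the local, meso and global scale simultaneously, extracted
by model-based clustering rather than by an arbitrary score cutoff.

## The six indices

For a simple undirected graph with degrees $D_i$:

* **Degree** $D_i$ and **eigenvector score** $EC_i$ (dominant adjacency
  eigenvector, rescaled to maximum 1) describe the local neighborhood.
* **Betweenness** $B_i$ (raw pair counts, endpoints excluded, geodesic
  fractions for ties) and **closeness** $C_i = (n-1)/\sum_j d(i,j)$
  describe global position. These conventions — and no others — reproduce
  the hand-computable values on the bundled 9-node toy tree ($B = 19$,
  $C = 0.615$ for its barycentric hub), which the test suite checks jointly.
* **Topological importance** bridges the scales. Define the one-step
  effect of $j$ on $i$ as $r_{1,ij} = a_{ij}/D_i$: each protein splits a
  unit of received influence equally among its partners, making the effect
  matrix $E$ row-stochastic. Effects compose multiplicatively along walks
  and add across walks, so the $q$-step effect of $i$ on $j$ is
  $(E^q)_{ji}$, and

  $$TI^m_i = \frac{1}{m}\sum_{q=1}^{m}\phi_{q,i}, \qquad
    \phi_{q,i} = \sum_{j \ne i} (E^q)_{ji}.$$

  The package computes $TI^1$ (a reweighted degree: the sum of reciprocal
  neighbor degrees) and $TI^4$ (meso-scale influence; four steps is
  roughly the barycentric radius of networks whose diameter is near ten).

Two conventions inside TI deserve note. Walks may revisit nodes: the
multiplicative/additive composition has no exclusion rule, and the one-step
case then matches the toy example exactly. Self-effects are removed only
through the diagonal of each individual power $E^q$; on sparse graphs an
alternative that zeroes intermediate diagonals differs in the third decimal
at $m = 4$, and we document rather than expose that variant. Row-stochasticity
gives a free invariant, $\sum_i TI^1_i = n$, asserted to machine precision in
the tests, and $B$, $C$ and $TI^{m\le3}$ are checked against brute-force
geodesic/walk enumeration oracles on every connected graph with at most 7
nodes (one representative per isomorphism class, via the graph atlas;
the walk oracle, whose cost grows exponentially with $m$ and degree, is run
exhaustively through 6 nodes and on a fixed subsample of the 7-node classes).

Because the indices have different natural ranges, each column is divided by
its own maximum ("max-normalization"), putting all six on $[0, 1]$ before
clustering. An all-zero column (possible in degenerate subtables) is left
unscaled with a warning rather than dividing by zero.

## Hub extraction: two rounds of model-based clustering

Normalized 6-dimensional profiles are clustered with finite Gaussian
mixtures (the mclust family system: spherical, diagonal and ellipsoidal
covariance structures, shared or per-component). For every candidate family
and every $K$ in `k_min:k_max` the EM fit is scored by
$BIC = 2\log L - k\log n$, and the best model wins. The component whose mean
vector, averaged over the six indices, is largest is the *central cluster*
(ties — effectively impossible with continuous profiles — would fall to the
larger mean betweenness, then the smaller component). Clustering is repeated
on the central cluster alone, and the second round's central component is
the hub set.

Design notes:

* **Why two rounds.** The first round separates the broad centrality
  continuum from the periphery; the second resolves the fine structure at
  the top that the first round's likelihood cannot afford to model.
* **Initialization.** mclust's EM starts from deterministic model-based
  agglomerative clustering, so fits are reproducible by construction; a
  `n_init` restart knob exists for interface compatibility but has no
  effect. Rows are internally sorted by protein identifier, making results
  invariant to input row order.
* **Degeneracies.** Candidates whose EM collapses are skipped; if all
  collapse, fitting is retried with a light conjugate prior, and
  zero-variance inputs (identical rows) fall back to an exact regularized
  one-component fit.
* **Defaults.** `k_min = 1`, `k_max = 20`: empirical selections on
  networks of this kind land well below 10, and the replicate benchmarks
  in the test suite use `k_max = 9` to keep twenty full two-round fits
  affordable; the selected $K$ never touched that ceiling in any run.
* **Degenerate input contract.** If round 1 isolates fewer than
  `min_central_cluster` (default 10) proteins, round 2 is skipped with a
  warning and the round-1 selection returned — re-clustering a handful of
  points would only fit noise.
* **BIC magnitudes are convention-bound** (they shift with additive
  likelihood constants and parameter counting), so the package reports its
  convention in the fit metadata and no analysis compares BIC values across
  software.

## Redundancy of the indices

Whether four indices could replace six is answered in rank space:
for every index pair, Goodman-Kruskal's $\gamma = (C - D)/(C + D)$ over all
unordered protein pairs, with pairs tied in either ranking excluded
(classical $\gamma$; no average-rank pre-processing). $\gamma$ is invariant
under strictly monotone transforms, so raw and normalized columns give
identical matrices. The six indices are then clustered: the dissimilarity
between two indices is the Euclidean distance between their association
profiles with the *other* indices (self/cross entries removed pairwise),
so indices merge when they relate to the rest of the system alike — the
criterion that groups degree with betweenness on assortative networks even
though one is local and the other global. Average linkage is the default;
the tree exports to Newick with merge heights as branch lengths.

Reduced 4-index subsets are evaluated by rerunning the full two-round
procedure on the restricted columns and counting how many reference hubs
land in the top one and top two round-2 components.

## Null models

Three matched references contextualize the redundancy structure: uniform
$G(n,m)$; degree-preserving double-edge-swap rewiring (10 attempted swaps
per edge by default); and a Watts-Strogatz small-world surrogate built at a
deliberately smaller node count so its density exceeds the reference's
while keeping the same edge count — its ring lattice is rewired edge by
edge with rejection of loops and duplicates, so the edge count is conserved
exactly at any rewiring probability (default $p = 0.05$). Each replicate's
giant component is profiled and the association matrices are averaged
entrywise.

## The synthetic benchmark

The generator emulates the statistical structure the analysis assumes,
with ground truth for parameter recovery:

1. a backbone of `n_hubs = 20` planted hubs, pairwise connected with
   `backbone_p = 0.4` (an assortative core);
2. the remaining `n_seed - n_hubs = 180` seed proteins attach to one or
   two existing seed/hub nodes, forming short branches;
3. `n_total - n_seed = 1400` periphery nodes attach with
   $1 + \mathrm{Poisson}(0.6)$ edges (mean `periphery_attach = 1.6`) to
   degree-proportionally chosen targets.

With these defaults the giant component lands at density $\approx 0.002$,
diameter $\approx 11$ and average path length $\approx 5$ — the sparse,
fragmented-but-short-pathed regime the pipeline is designed for — and its
degree-betweenness association exceeds 0.9. Annotations give each hub the
"D" label with probability 0.85 (otherwise a background draw), mark hubs as
transcription factors with probability 0.8 against 0.15 in the background,
draw non-hub seed labels uniformly from the 13 vitamin classes, and model
publication counts as log-normal (meanlog 3, sdlog 1 — a median of ~20
papers with a heavy tail). Uniform background labels are the neutral
choice: enrichment contrasts then measure exactly the planted hub signal.

What the generator does *not* emulate: true interactome degree
distributions (no power-law fitting), literature-driven annotation bias,
multi-label vitamin associations (exercised in unit tests instead), or
false-positive/false-negative interaction noise. Passing recovery
benchmarks therefore certifies the statistical machinery — that a planted
multi-centrality backbone of realistic size and density is found with
median recall $\ge 0.9$ and precision $\ge 0.8$ over twenty generator
seeds — not performance on any particular curated interactome.

## Numerical choices

* Eigenvector scores come from a Lanczos solver on the adjacency
  structure; the eigen-relation residual is verified against `tol`
  (default $10^{-8}$), and the start vector is pinned so scores are
  bit-reproducible. Disconnected input is an error directing the user to
  `giant_component()` — on fragments the dominant eigenvector is not
  comparable across components.
* $TI$ uses sparse matrix powers; exact rational arithmetic is
  unnecessary since row-stochasticity bounds all entries in $[0,1]$.
* Giant-component ties (possible on tiny or synthetic graphs) break to
  the component containing the lexicographically smallest protein
  identifier, in C-locale order, for platform independence.
* Floating-point test comparisons use absolute tolerance $10^{-9}$ unless
  a printed value's own rounding dictates otherwise (the toy example's
  $TI^1 = 1.58$ is compared at $\pm 0.01$ because the printed sum rounds
  $1/3$ to $0.33$).
* Master seeds fan out to stages through a fixed affine rule
  (`stage_seed()`), so every stage can be rerun in isolation with an
  identical stream.

## Known limitations

* The hub contract assumes a unimodal "most central" component; centrality
  structures with two disjoint elite groups would be split across
  components and only one returned.
* Goodman-Kruskal $\gamma$ is computed by exact $O(n^2)$ pair counting —
  fine to a few thousand proteins, quadratic beyond.
* The annotation statistics take the curated seed list as the background
  population; they do not model selection effects in how that list was
  assembled.
* On networks whose central cluster is very large, the second clustering
  round dominates runtime; `k_max` is the lever that trades resolution
  for time.
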