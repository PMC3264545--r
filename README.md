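# multicent

Multi-centrality hub detection in protein-protein interaction (PPI)
networks.

Interaction networks assembled around a curated seed list — for example,
proteins functionally associated with vitamins — are sparse and fragmented,
yet typically centralized around a small group of proteins that are
prominent at every topological scale. `multicent` identifies these
**multi-centrality hubs** and quantifies how much information the
individual centrality indices actually add, for systems-biology users who
want a score-cutoff-free, model-based definition of "hub".

The package implements, end to end:

* **Six-index centrality profiling** of every protein: degree *D*,
  eigenvector score *EC* (max-rescaled), **topological importance**
  *TI¹*/*TI⁴*, betweenness *B* (raw, endpoints excluded) and closeness
  *C* = (n−1)/Σⱼ d(i,j). Topological importance propagates influence
  through the row-stochastic effect matrix E (E·ᵢⱼ = aᵢⱼ/Dᵢ):

      TIᵐᵢ = (1/m) Σ_{q=1..m} Σ_{j≠i} (E^q)ⱼᵢ

  bridging local and global scales (at m = 1 it is the sum of reciprocal
  neighbor degrees).
* **Two-round Gaussian-mixture clustering** (mclust families, BIC model
  selection) of the max-normalized profiles; the most central component of
  the second round is the hub set.
* **Centrality redundancy**: Goodman-Kruskal rank concordance (γ) for all
  index pairs, an index-similarity dendrogram (Newick export), and
  evaluation of reduced 4-index subsets against the reference hub set.
* **Null models**: uniform G(n,m), degree-preserving rewiring, and an
  edge-count-conserving small-world surrogate, each rerun through the
  redundancy analysis.
* **Annotation statistics**: fat- vs water-soluble and transcription-factor
  chi-squared tests (corrected and uncorrected always both reported),
  per-vitamin enrichment profiles in 13- and 6-class schemes, and
  two-sample Kolmogorov-Smirnov comparisons.
* A **synthetic-network generator** with a planted assortative hub
  backbone and hub-enriched vitamin-D labels, used for parameter-recovery
  benchmarking throughout the test suite.

## Worked example

The toy network used throughout the documentation is a 9-node tree: a hub
`b` adjacent to three branch nodes carrying 0, 3 and 2 leaves
(`inst/extdata/fig1_toy_edgelist.tsv`).

```r
library(multicent)

net <- read_edgelist(system.file("extdata", "fig1_toy_edgelist.tsv",
                                 package = "multicent"))
degree_centrality(net)[["b"]]                  # 3
topological_importance(net, 1)[["b"]]          # 1.583333  (1 + 1/4 + 1/3)
betweenness_centrality(net)[["b"]]             # 19
closeness_centrality(net)[["b"]]               # 0.6153846 (= 8/13)
eigenvector_centrality(net)[["b"]]             # 0.9250127
```

`b` tops betweenness and closeness (it is the barycenter: 19 of the 28
node pairs communicate through it), while the three-leaf branch node tops
degree and eigenvector score — exactly the disagreement between scales
that motivates using all six indices at once.

A full synthetic analysis (generation → statistics → hub detection →
redundancy → null models → enrichment) is laid out as numbered drivers
under `analysis/`; run them in order from the repository root:

```sh
Rscript analysis/01_simulate_network.R
Rscript analysis/02_network_stats.R
Rscript analysis/03_centrality_hubs.R
Rscript analysis/04_redundancy.R
Rscript analysis/05_null_models.R
Rscript analysis/06_annotation_stats.R
```

With the default generator settings (1,600 proteins, 200 seeds, 20 planted
hubs, seed 1) this prints, among other things:

```
  nodes: 1600   edges: 2561
  density: 0.002002   clustering (transitivity): 0.0171
  diameter: 11   average path length: 4.9588

Round 1: VEV, K = 9 -> central cluster of 43 proteins
Round 2: VEV, K = 2 -> 20 multi-centrality hubs
recovery vs planted hubs: precision 1.00, recall 1.00, F1 1.00

gnm        D-B association: 0.943 (empirical 0.939)
rewired    D-B association: 0.908 (empirical 0.939)
smallworld D-B association: 0.608 (empirical 0.939)

13-class: hub D-proportion 0.90 vs background 0.17; KS D = 0.846, p = 0.000181
```

i.e. the sparse short-path regime, a two-round extraction that recovers
the planted backbone exactly, a degree-betweenness redundancy preserved
only by the degree-preserving null, and a strong vitamin-D enrichment of
the detected hubs.

All computation lives in the package (`R/`); the analysis scripts are thin
drivers, and `run_pipeline()` executes the same sequence programmatically
with a config object, per-stage seeds and a TSV/JSON/Newick report bundle.

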