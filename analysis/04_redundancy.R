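#!/usr/bin/env Rscript
# Redundancy among the six centrality indices: Goodman-Kruskal rank
# concordance for every index pair, the index-similarity dendrogram, and
# the performance of 4-index subsets at recovering the reference hub set.

suppressMessages(library(multicent))

tab <- read_centrality_table("results/centrality_table.tsv")
hubs <- unlist(jsonlite::read_json("results/hub_result.json")$hubs)

mat <- association_matrix(tab)
print(round(unclass(mat), 3))
write_association_matrix(mat, "results/association_matrix.tsv")

dend <- index_dendrogram(mat)
write_dendrogram_newick(dend, "results/index_dendrogram.nwk")
first <- sort(dend$labels[-dend$merge[1, ]])
message("first merge in the index dendrogram: ", paste(first, collapse = " + "))

cfg <- hub_config(k_max = 9, seed = 1)
for (sub in list(c("D", "EC", "TI1", "TI4"), c("TI1", "TI4", "B", "C"),
                 c("EC", "TI1", "TI4", "B"), c("D", "TI1", "TI4", "C"))) {
  ev <- suppressWarnings(evaluate_subset(tab, sub, hubs, cfg))
  print(ev)
}
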