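#!/usr/bin/env Rscript
# Generate the synthetic vitamin-network benchmark: a sparse interaction
# network with a planted assortative hub backbone, plus seed-protein
# annotations in which the hubs are enriched for the vitamin-D label.
# Writes the edgelist, annotation table and ground truth under
# results/synthetic/.

suppressMessages(library(multicent))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(seed = 1)   # defaults: 1600 nodes, 200 seeds, 20 hubs
gen <- generate_network(spec)
annot <- generate_annotations(gen$truth, spec)

write_edgelist(gen$network, file.path(out, "edgelist.tsv"))
write_annotations(annot, file.path(out, "annotations.tsv"))
jsonlite::write_json(gen$truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

st <- global_stats(gen$network)
print(st)
message(sprintf("planted hubs: %d of %d seed proteins; D-labelled hubs: %d",
                length(gen$truth$hub_ids), length(gen$truth$seed_ids),
                sum(annot$vitamins[annot$accession %in% gen$truth$hub_ids] == "D")))
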