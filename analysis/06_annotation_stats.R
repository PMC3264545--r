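#!/usr/bin/env Rscript
# Annotation statistics for the detected hubs against the seed-protein
# background: fat- vs water-soluble chi-squared, transcription-factor
# chi-squared, per-vitamin enrichment profiles (13- and 6-class), and the
# KS comparisons.

suppressMessages(library(multicent))

annot <- read_annotations("results/synthetic/annotations.tsv")
hubs <- unlist(jsonlite::read_json("results/hub_result.json")$hubs)
hubs <- intersect(hubs, annot$accession)
background <- setdiff(annot$accession, hubs)

sol <- rbind(hubs = solubility_split(annot, hubs),
             background = solubility_split(annot, background))
print(sol)
chi <- chi2_test(sol)
message(sprintf("solubility chi2 = %.3f (uncorrected %.3f), df = %d, p = %.3g",
                chi$statistic_corrected, chi$statistic_uncorrected, chi$df, chi$p))

tf <- rbind(hubs = c(tf = sum(annot$is_tf[annot$accession %in% hubs]),
                     non_tf = sum(!annot$is_tf[annot$accession %in% hubs])),
            background = c(sum(annot$is_tf[annot$accession %in% background]),
                           sum(!annot$is_tf[annot$accession %in% background])))
chi_tf <- chi2_test(tf)
message(sprintf("transcription-factor chi2 = %.3f (uncorrected %.3f), p = %.3g",
                chi_tf$statistic_corrected, chi_tf$statistic_uncorrected, chi_tf$p))

for (scheme in c("13-class", "6-class")) {
  prof <- enrichment_profile(annot, hubs, scheme)
  utils::write.table(prof, sprintf("results/enrichment_%s.tsv", scheme),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ks <- ks_two_sample(prof$subset_prop, prof$background_prop)
  message(sprintf("%s: hub D-proportion %.2f vs background %.2f; KS D = %.3f, p = %.3g",
                  scheme, prof$subset_prop[prof$class == "D"],
                  prof$background_prop[prof$class == "D"], ks$statistic, ks$p))
}
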