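#!/usr/bin/env Rscript
# Partition the genome into feature classes and census adjacent gene pairs.
suppressPackageStartupMessages(library(lifecyclechromatin))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

ds <- simulate_dataset(seed = seed, tracks = FALSE)
map <- build_feature_partition(ds$annotation)
comp <- class_composition(map)
write.table(comp, "results/feature_composition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("feature-class composition (fractions):\n")
print(comp[, c("class", "fraction")], digits = 3)

pairs <- classify_adjacent_pairs(ds$annotation)
write.table(pairs, "results/pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cen <- divergent_flanking_fraction(pairs)
st <- pair_length_stats(pairs)
cat(sprintf("\n%d TSS-adjacent intergenics; %.1f%% of flanking genes are in divergent pairs\n",
            cen$n_tss_adjacent, 100 * cen$divergent_flanking_fraction))
cat(sprintf("median intergenic length: divergent %d bp, tandem %d bp (Wilcoxon p = %.3g)\n",
            st$medians[["divergent"]], st$medians[["tandem"]],
            st$test$p_value))
write.table(data.frame(orientation = names(st$medians),
                       median_bp = as.numeric(st$medians),
                       n = as.integer(st$n[names(st$medians)])),
            "results/pair_stats.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
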