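#!/usr/bin/env Rscript
# Call peaks for every mark, associate them with TSSs and feature classes,
# and quantify mark co-localisation and TE association.
suppressPackageStartupMessages(library(lifecyclechromatin))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

ds <- simulate_dataset(seed = seed)
ann <- ds$annotation
map <- build_feature_partition(ann)

tss_marks <- c("H3K4me2", "H3K4me3", "H3K9ac", "H3K14ac", "H3K27ac")
presence <- list(); tracks_sp <- list()
for (mk in tss_marks) {
  tr <- pool_tracks(ds$tracks$chip[[mk]]$sporophyte)
  tracks_sp[[mk]] <- tr
  pk <- call_peaks(tr, ds$tracks$input$sporophyte, mode = "narrow")
  write_intervals(pk, sprintf("results/peaks_%s_sporophyte.bed", mk))
  pres <- tss_presence(pk, ann)
  presence[[mk]] <- pres$marked
  cat(sprintf("%s: %d peaks; %.1f%% of genes have a peak within 500 bp of the TSS\n",
              mk, nrow(pk), 100 * pres$fraction))
}
pm <- do.call(cbind, presence)
write.table(data.frame(gene_id = rownames(pm), pm),
            "results/tss_presence_sporophyte.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# TE-associated mark: class distribution and TE association
tr20 <- pool_tracks(ds$tracks$chip$H4K20me3$sporophyte)
pk20 <- call_peaks(tr20, ds$tracks$input$sporophyte, mode = "narrow")
dist20 <- peak_class_distribution(pk20, map)
write.table(dist20, "results/h4k20me3_class_distribution.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
iv <- map_to_intervals(map)
intr_te <- iv[iv$class %in% c("intron_te", "first_intron_te"), ]
intr_no <- iv[iv$class %in% c("intron_no_te", "first_intron_no_te"), ]
ta <- te_association_test(pk20, intr_te, intr_no, tes = ann$tes)
cat(sprintf("\nH4K20me3 vs TE-containing introns: chi2 = %.1f, p = %.3g; %.1f%% of peaks co-localise with a TE\n",
            ta$test$statistic, ta$test$p_value,
            100 * ta$colocalized_fraction))

cm <- colocalization_matrix(tracks = tracks_sp)
write.table(round(cm$pearson, 3), "results/coloc_pearson.tsv", sep = "\t",
            quote = FALSE)
cat(sprintf("TSS-mark co-localisation: Pearson r range %.2f-%.2f off-diagonal\n",
            min(cm$pearson[upper.tri(cm$pearson)]),
            max(cm$pearson[upper.tri(cm$pearson)])))
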