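#!/usr/bin/env Rscript
# Divergent vs tandem pair chromatin: TSS signal, shared NDRs from MNase,
# expression correlation, and lncRNA-coding GBG co-regulation.
suppressPackageStartupMessages(library(lifecyclechromatin))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L
dir.create("results", showWarnings = FALSE)

ds <- simulate_dataset(seed = seed)
ann <- ds$annotation
pairs <- classify_adjacent_pairs(ann)

tracks <- list(H3K4me3 = pool_tracks(ds$tracks$chip$H3K4me3$sporophyte),
               H3K9ac = pool_tracks(ds$tracks$chip$H3K9ac$sporophyte))
ps <- pair_tss_signal(tracks, pairs, ann)
write.table(ps$records, "results/pair_signal.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (mk in names(tracks))
  cat(sprintf("%s at gene-2 TSS: divergent vs tandem Wilcoxon p = %.3g\n",
              mk, ps$tests[[mk]]$p_value))

ndr <- shared_ndr_rate(pairs, ann, ds$tracks$mnase$sporophyte)
cat(sprintf("shared NDR: %.1f%% of divergent pairs <= 600 bp (n = %d) vs %.1f%% above (n = %d)\n",
            100 * ndr$rate_short, ndr$n_short,
            100 * ndr$rate_long, ndr$n_long))

tpm <- rowMeans(ds$expression$tpm)
for (sub in c("all", "divergent", "divergent_lt")) {
  r <- pair_expression_correlation(tpm, pairs, sub)
  cat(sprintf("within-pair expression correlation (%s): r = %.3f\n",
              sub, r$estimate))
}

de <- simple_de_test(ds$expression$tpm, c("sp_rep1", "sp_rep2"),
                     c("ga_rep1", "ga_rep2"))
gb <- call_gbgs(list(de))
co <- adjacent_gbg_coregulation(gb$gbgs, pairs, ann)
cat(sprintf("lncRNA GBGs adjacent to coding GBGs: %d; co-directional fraction: %s\n",
            co$n_lncrna_gbg_adjacent_coding_gbg,
            format(co$fraction_codirectional)))
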