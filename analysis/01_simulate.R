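#!/usr/bin/env Rscript
# Generate the default synthetic study dataset and write it to disk:
# a 2 x 1 Mb genome with 1,000 genes, eight ChIP marks x two generations x
# two replicates, input and MNase tracks, expression, and ground truth.
suppressPackageStartupMessages(library(lifecyclechromatin))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

ds <- simulate_dataset(seed = seed)
outdir <- "results/dataset"
emit_dataset(ds, outdir)
print(ds$annotation)
cat("generation-biased genes planted:", nrow(ds$truth$gbgs), "\n")
cat("dataset written to", outdir, "\n")
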