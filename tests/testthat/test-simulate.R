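test_that("the generator is deterministic per seed and varies across seeds", {
  d1 <- simulate_dataset(seed = 5, tracks = FALSE)
  d2 <- simulate_dataset(seed = 5, tracks = FALSE)
  expect_identical(d1$annotation$genes, d2$annotation$genes)
  expect_identical(d1$expression$tpm, d2$expression$tpm)
  d3 <- simulate_dataset(seed = 6, tracks = FALSE)
  expect_false(identical(d1$annotation$genes$start,
                         d3$annotation$genes$start))
})

test_that("emitted datasets are byte-identical per seed and parse back", {
  cfg <- synthetic_config(n_genes = 60, scaffold_length = 2e5,
                          n_scaffolds = 1)
  out1 <- file.path(tempdir(), "emit1"); out2 <- file.path(tempdir(), "emit2")
  emit_dataset(simulate_dataset(cfg, seed = 9), out1)
  emit_dataset(simulate_dataset(cfg, seed = 9), out2)
  for (f in list.files(out1, recursive = TRUE)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  ann <- read_annotation(file.path(out1, "genes.gff3"))
  expect_equal(nrow(ann$genes), 60)
  expect_silent(tr <- read_track(file.path(out1, "tracks",
                                           "H3K4me3_sporophyte_rep1.bedGraph"),
                                 50, ann))
  expect_gt(tr$library_size, 0)
  truth <- jsonlite::read_json(file.path(out1, "truth.json"),
                               simplifyVector = TRUE)
  expect_named(truth, c("gbgs", "presence", "domains", "te_marked"))
  # different seed changes the tracks
  out3 <- file.path(tempdir(), "emit3")
  emit_dataset(simulate_dataset(cfg, seed = 10), out3)
  expect_false(identical(
    readLines(file.path(out1, "tracks", "input_sporophyte.bedGraph")),
    readLines(file.path(out3, "tracks", "input_sporophyte.bedGraph"))))
})

test_that("realized divergent fraction and gap medians match the configured models", {
  ds <- default_dataset()
  pairs <- classify_adjacent_pairs(ds$annotation)
  dff <- divergent_flanking_fraction(pairs)
  expect_gt(dff$divergent_flanking_fraction, 0.617 - 0.05)
  expect_lt(dff$divergent_flanking_fraction, 0.617 + 0.05)
  dv <- pairs$length[pairs$orientation == "divergent"]
  expect_gt(length(dv), 200)
  expect_lt(abs(median(dv) - 409) / 409, 0.1)
  # configured ordering of medians is preserved in the sample
  td <- pairs$length[pairs$orientation == "tandem"]
  expect_lt(median(dv), median(td))
})

test_that("degenerate generator configs behave as documented", {
  empty <- generate_annotation(synthetic_config(n_genes = 0))
  expect_equal(nrow(empty$genes), 0)
  expect_error(generate_annotation(synthetic_config(
    n_genes = 5000, scaffold_length = 1e5, n_scaffolds = 1)), "too small")
  cfg0 <- synthetic_config(
    expression_model = modifyList(synthetic_config()$expression_model,
                                  list(gbg_fraction = 0)))
  ds0 <- simulate_dataset(cfg0, seed = 2, tracks = FALSE)
  expect_equal(nrow(ds0$truth$gbgs), 0)
  expect_error(simulate_expression(
    ds0$annotation,
    synthetic_config(expression_model = modifyList(
      synthetic_config()$expression_model, list(replicates = 1)))),
    "2 replicates")
})

test_that("planted GBG count follows its binomial and noiseless folds are exact", {
  ds <- default_dataset()
  n <- nrow(ds$annotation$genes)
  k <- nrow(ds$truth$gbgs)
  expect_lt(abs(k - 0.04 * n), 3 * sqrt(n * 0.04 * 0.96) + 1)
  # GBG truth count equals the flagged genes (conservation)
  expect_equal(k, length(unique(ds$truth$gbgs$gene_id)))
  # noiseless mode with a fixed planted log2fc of 2: measured fold exactly 4
  cfg <- synthetic_config(expression_model = modifyList(
    synthetic_config()$expression_model,
    list(replicate_sd = 0, log2fc_range = c(2, 2), pair_correlation = 0)))
  dsn <- simulate_dataset(cfg, seed = 8, tracks = FALSE)
  tpm <- scale_samples(dsn$expression$tpm)
  tg <- dsn$truth$gbgs
  up <- ifelse(tg$bias == "sporophyte", "sp_rep1", "ga_rep1")
  dn <- ifelse(tg$bias == "sporophyte", "ga_rep1", "sp_rep1")
  fold <- tpm[cbind(tg$gene_id, up)] / tpm[cbind(tg$gene_id, dn)]
  expect_equal(fold, rep(4, nrow(tg)), tolerance = 1e-6)
})

test_that("expression-coupled marks correlate with TPM at the TSS", {
  ds <- default_dataset()
  ann <- ds$annotation
  tr <- pool_tracks(ds$tracks$chip$H3K4me3$sporophyte)
  nb <- normalized_bins(tr)
  marked <- ds$truth$presence$sporophyte[, "H3K4me3"]
  g <- ann$genes[marked[ann$genes$gene_id], ]
  sig <- vapply(seq_len(nrow(g)), function(i)
    window_mean_for_test(nb[[g$scaffold[i]]], tr$bin_size, g$tss[i] - 100,
                         g$tss[i] + 100, tr$scaffold_lengths[[g$scaffold[i]]]),
    0)
  tpm <- ds$expression$gen_tpm[g$gene_id, "sporophyte"]
  expect_gt(cor(sig, tpm, method = "spearman"), 0.3)
})

test_that("noiseless tracks realize their construction exactly", {
  cfg <- synthetic_config(n_genes = 100, scaffold_length = 4e5,
                          n_scaffolds = 1)
  ds <- simulate_dataset(cfg, seed = 3, noiseless = TRUE)
  # double-peak mark: two local maxima around each marked TSS
  tr <- ds$tracks$chip$H3K4me2$sporophyte[[1]]
  g <- ds$annotation$genes
  marked <- ds$truth$presence$sporophyte[, "H3K4me2"]
  mm <- cfg$mark_models$H3K4me2
  hits <- 0; total <- 0
  v <- tr$bins$scaffold_01
  for (i in which(marked[g$gene_id])) {
    lo <- floor((g$tss[i] - mm$offset - mm$width) / 50)
    hi <- ceiling((g$tss[i] + mm$offset + mm$width) / 50)
    if (lo < 3 || hi > length(v) - 2) next
    win <- v[lo:hi]
    is_max <- which(diff(sign(diff(win))) == -2)
    total <- total + 1
    if (length(is_max) >= 2) hits <- hits + 1
  }
  expect_gt(total, 20)
  expect_gte(hits / total, 0.8)   # neighbouring-gene bumps can merge a few
  # broad mark with zero jitter: elevated bins coincide with truth domains
  cfg2 <- synthetic_config(n_genes = 100, scaffold_length = 4e5,
                           n_scaffolds = 1,
                           domain_model = modifyList(
                             synthetic_config()$domain_model,
                             list(border_jitter_sd = 0, n_domains = 15,
                                  unique_fraction = 0)))
  ds2 <- simulate_dataset(cfg2, seed = 4, noiseless = TRUE)
  v2 <- ds2$tracks$chip$H3K79me2$sporophyte[[1]]$bins$scaffold_01
  bg <- cfg2$noise$reads_per_bin_mean
  elevated <- which(v2 > bg)
  truth_bins <- integer(0)
  dd <- ds2$truth$domains$sporophyte
  for (i in seq_len(nrow(dd)))
    truth_bins <- c(truth_bins,
                    (floor(dd$start[i] / 50) + 1):ceiling(dd$end[i] / 50))
  expect_setequal(elevated, unique(truth_bins))
  # all amplitudes zero: ChIP means equal the input background everywhere
  mm0 <- synthetic_config()$mark_models
  for (nm in names(mm0)) mm0[[nm]]$amplitude <- 0
  ds3 <- simulate_dataset(synthetic_config(n_genes = 50,
                                           scaffold_length = 2e5,
                                           n_scaffolds = 1,
                                           mark_models = mm0),
                          seed = 5, noiseless = TRUE)
  expect_equal(ds3$tracks$chip$H3K9ac$sporophyte[[1]]$bins,
               ds3$tracks$input$sporophyte$bins)
})
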