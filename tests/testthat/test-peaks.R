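test_that("flat track equal to control yields no peaks", {
  tr <- flat_track()
  ctl <- flat_track()
  expect_equal(nrow(call_peaks(tr, ctl)), 0)
  # all-zero track and control: empty set, not an error
  z <- flat_track(background = 0)
  expect_equal(nrow(call_peaks(z, z)), 0)
})

test_that("a planted bump yields exactly one peak containing its maximum", {
  tr <- flat_track(starts = 40000, ends = 40300, heights = 50)
  ctl <- flat_track()
  pk <- call_peaks(tr, ctl, mode = "narrow")
  expect_equal(nrow(pk), 1)
  expect_lte(pk$start, 40000)
  expect_gte(pk$end, 40300)
  expect_true(pk$summit > 40000 - 50 && pk$summit < 40300 + 50)
  expect_error(call_peaks(tr, flat_track(bin = 100)), "bin")
})

test_that("TSS presence uses a strict bidirectional distance window", {
  ann <- three_gene_annotation()          # TSSs at 1000, 5000, 12000
  pk <- peak_df("s1", 900, 1100)          # overlaps first TSS
  pres <- tss_presence(pk, ann)
  expect_true(pres$marked[["a"]])
  expect_equal(pres$distance[["a"]], 0)
  # peak edge exactly 501 bp from the TSS: unmarked at window 500
  pk2 <- peak_df("s1", 5000 + 501, 5000 + 700)
  pres2 <- tss_presence(pk2, ann)
  expect_false(pres2$marked[["b"]])
  expect_true(tss_presence(pk2, ann, window = 501)$marked[["b"]])
  # empty set -> fraction 0; monotone in window
  empty <- peak_df(character(0), numeric(0), numeric(0), numeric(0))
  expect_equal(tss_presence(empty, ann)$fraction, 0)
  m250 <- tss_presence(pk2, ann, window = 250)$marked
  m800 <- tss_presence(pk2, ann, window = 800)$marked
  expect_true(all(!m250 | m800))
})

test_that("peak bp distribute over feature classes by exact intersection", {
  ann <- tiny_annotation()               # exon1 [1000,1300), intron [1300,1700)
  m <- build_feature_partition(ann)
  inside <- peak_df("s1", 1050, 1250)    # fully in first exon
  d <- peak_class_distribution(inside, m)
  expect_equal(d$proportion[d$class == "first_exon"], 1)
  half <- peak_df("s1", 1200, 1400)      # 100 bp exon, 100 bp intron
  d2 <- peak_class_distribution(half, m)
  expect_equal(d2$proportion[d2$class == "first_exon"], 0.5)
  expect_equal(d2$proportion[d2$class == "first_intron_no_te"], 0.5)
  expect_equal(sum(d2$proportion), 1, tolerance = 1e-9)
})

test_that("co-localisation matrices have unit diagonal and sane off-diagonals", {
  set.seed(42)
  a <- flat_track(); a$bins$s1 <- as.numeric(rpois(length(a$bins$s1), 5))
  b <- flat_track(); b$bins$s1 <- as.numeric(rpois(length(b$bins$s1), 5))
  cm <- colocalization_matrix(tracks = list(A = a, B = b))
  expect_equal(diag(cm$pearson), c(A = 1, B = 1))
  expect_lt(abs(cm$pearson["A", "B"]), 0.1)  # independent backgrounds
  expect_equal(cm$pearson, t(cm$pearson))
  # constant track: flagged NA, not zero
  const <- flat_track()
  cmc <- colocalization_matrix(tracks = list(A = a, C = const))
  expect_true(is.na(cmc$pearson["A", "C"]))
  # peak mode: identical sets give 1, disjoint give 0
  p1 <- peak_df("s1", c(100, 500), c(200, 700))
  p2 <- peak_df("s1", c(1000, 2000), c(1100, 2100))
  cj <- colocalization_matrix(peaksets = list(X = p1, Y = p1, Z = p2))
  expect_equal(cj$jaccard["X", "Y"], 1)
  expect_equal(cj$jaccard["X", "Z"], 0)
})

test_that("TE association detects planted co-occurrence and is null when equal", {
  with_te <- data.frame(scaffold = "s1", start = seq(0, 39000, 1000),
                        end = seq(500, 39500, 1000))
  without <- data.frame(scaffold = "s1", start = seq(500, 39500, 1000),
                        end = seq(1000, 40000, 1000))
  # peaks only inside TE-containing regions
  pk <- peak_df("s1", with_te$start[1:30] + 100, with_te$start[1:30] + 200)
  res <- te_association_test(pk, with_te, without)
  expect_lt(res$test$p_value, 1e-6)
  expect_equal(res$colocalized_fraction, NA_real_)
  # identical occupancy -> near-zero statistic
  pk2 <- peak_df("s1", c(with_te$start[1:5] + 100, without$start[1:5] + 100),
                 c(with_te$start[1:5] + 200, without$start[1:5] + 200))
  res2 <- te_association_test(pk2, with_te, without,
                              tes = with_te)
  expect_lt(res2$test$statistic, 0.5)
  expect_equal(res2$colocalized_fraction, 0.5)
})

test_that("metaprofile has the right geometry and is flat on constant signal", {
  ann <- three_gene_annotation()
  tr <- flat_track(length = 20000, background = 3)
  mp <- metaprofile(tr, ann, flank_bp = 2000, n_body_bins = 100)
  expect_equal(ncol(mp$matrix), 2 * (2000 / 50) + 100)
  expect_equal(unname(mp$profile), rep(3 / tr$library_size * 1e6,
                                       length(mp$profile)))
})

test_that("metaprofile peaks at the TSS column for a TSS-bumped track", {
  ann <- three_gene_annotation(c("+", "-", "+"))
  tss <- ann$genes$tss
  tr <- flat_track(length = 20000, starts = tss - 100, ends = tss + 100,
                   heights = 60)
  mp <- metaprofile(tr, ann, flank_bp = 1000, n_body_bins = 50)
  nf <- mp$n_flank_bins
  # argmax within one column of the flank/body boundary (the TSS)
  expect_lte(abs(which.max(mp$profile) - (nf + 1)), 2)
})

test_that("decile profiles need 10 genes and split evenly", {
  ds <- default_dataset()
  ann <- ds$annotation
  tpm <- rowMeans(ds$expression$tpm)
  tr <- ds$tracks$chip$H3K4me3$sporophyte[[1]]
  small <- genome_annotation(ann$scaffolds, ann$genes[1:5, ])
  expect_error(decile_profiles(tr, small, tpm), ">= 10")
  sub <- genome_annotation(ann$scaffolds, ann$genes[1:100, ],
                           ann$exons[ann$exons$gene_id %in%
                                       ann$genes$gene_id[1:100], ])
  dp <- decile_profiles(tr, sub, tpm, flank_bp = 500, n_body_bins = 20)
  expect_equal(as.integer(table(dp$decile)), rep(10L, 10))
})
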