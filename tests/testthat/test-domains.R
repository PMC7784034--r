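test_that("broad peaks merge across gaps up to merge_gap", {
  p <- peak_df("s1", c(1000, 2000), c(1500, 2600), score = c(2, 4))
  one <- segment_domains(p, merge_gap = 1000)   # 500 bp gap -> merged
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start, one$end), c(1000, 2600))
  # score is the length-weighted mean: (500*2 + 600*4) / 1100
  expect_equal(one$score, (500 * 2 + 600 * 4) / 1100)
  p2 <- peak_df("s1", c(1000, 3100), c(1500, 3600))
  expect_equal(nrow(segment_domains(p2, merge_gap = 1000)), 2)  # 1600 bp gap
  expect_equal(nrow(segment_domains(peak_df(character(0), numeric(0),
                                            numeric(0)))), 0)
})

test_that("domain summary reports coverage and genes per long domain", {
  ann <- genome_annotation(
    data.frame(name = c("s1", "s2"), length = c(1e6, 1e6)),
    data.frame(gene_id = c("g1", "g2"), scaffold = "s1",
               start = c(10000, 20000), end = c(14000, 24000),
               strand = "+", biotype = "protein_coding"))
  d <- peak_df("s1", 0, 1e6)
  class(d) <- c("domain_set", "data.frame")
  s <- domain_summary(d, ann)
  expect_equal(s$genome_fraction, 0.5)
  expect_equal(s$fraction_long, 1)
  expect_equal(s$mean_genes_per_long, 2)
  # no long domains: fraction 0, mean genes absent
  d2 <- peak_df("s1", 1000, 3000); class(d2) <- c("domain_set", "data.frame")
  s2 <- domain_summary(d2, ann)
  expect_equal(s2$fraction_long, 0)
  expect_true(is.na(s2$mean_genes_per_long))
  # bp totals equal the sum of domain lengths exactly
  expect_equal(s$total_bp, 1e6)
})

test_that("gene-in-domain rule is strictly more than half the body", {
  ann <- genome_annotation(
    data.frame(name = "s1", length = 100000),
    data.frame(gene_id = c("exact", "over", "inside"), scaffold = "s1",
               start = c(1000, 11000, 21000), end = c(2000, 12000, 22000),
               strand = "+", biotype = "protein_coding"))
  dom <- peak_df("s1", c(1000, 11000, 20000), c(1500, 11510, 23000))
  class(dom) <- c("domain_set", "data.frame")
  cl <- classify_genes_by_domain(ann, dom)
  expect_false(cl$in_domain[cl$gene_id == "exact"])   # exactly 50%
  expect_true(cl$in_domain[cl$gene_id == "over"])     # 51%
  expect_true(cl$in_domain[cl$gene_id == "inside"])
  expect_equal(cl$joint, c("neither", "k79_only", "k79_only"))
  # with H4K20me3 peaks the joint class combines
  k20 <- peak_df("s1", 1100, 1200)
  cl2 <- classify_genes_by_domain(ann, dom, k20)
  expect_equal(cl2$joint[cl2$gene_id == "exact"], "k20_only")
})

test_that("generation overlap applies the 1 bp uniqueness rule symmetrically", {
  mk <- function(s, e) {
    d <- peak_df("s1", s, e); class(d) <- c("domain_set", "data.frame"); d
  }
  a <- mk(0, 10000); b <- mk(9000, 20000)
  ov <- generation_overlap(a, b)
  expect_equal(ov$fraction_unique_sp, 0)
  expect_equal(ov$fraction_unique_ga, 0)
  ident <- generation_overlap(a, a)
  expect_equal(ident$fraction_unique_sp, 0)
  disj <- generation_overlap(mk(0, 6000), mk(50000, 60000))
  expect_equal(disj$fraction_unique_sp, 1)
  expect_equal(disj$fraction_unique_ga, 1)
  # symmetry
  sw <- generation_overlap(b, a)
  expect_equal(sw$fraction_unique_sp, ov$fraction_unique_ga)
})

test_that("borders planted on gene ends give zero distances and a rejection", {
  set.seed(7)
  ds <- default_dataset()
  ann <- ds$annotation
  g <- ann$genes[ann$genes$scaffold == "scaffold_01", ]
  # domains spanning genes 10..14, 30..34, ... borders exactly at TSS/TES
  idx <- seq(10, 90, 20)
  dom <- data.frame(scaffold = "scaffold_01", start = g$start[idx],
                    end = g$end[idx + 4], score = 1)
  class(dom) <- c("domain_set", "data.frame")
  bt <- border_proximity_test(dom, ann, min_len = 5000,
                              n_anchor_draws = 200)
  expect_true(all(bt$observed == 0))
  expect_equal(bt$fraction_within_1kb, 1)
  expect_lt(bt$test$p_value, 0.01)
  expect_gt(median(bt$null), 0)
  expect_error(border_proximity_test(dom, ann, min_len = 1e7), "no domain")
})

test_that("border test is invariant under coordinate translation", {
  set.seed(11)
  ann <- genome_annotation(
    data.frame(name = "s1", length = 200000),
    data.frame(gene_id = paste0("g", 1:20), scaffold = "s1",
               start = seq(5000, 195000, 10000),
               end = seq(5000, 195000, 10000) + 3000,
               strand = "+", biotype = "protein_coding"))
  dom <- peak_df("s1", c(20000, 80000), c(33000, 96000))
  class(dom) <- c("domain_set", "data.frame")
  shift <- 1000
  ann2 <- genome_annotation(
    ann$scaffolds,
    transform(ann$genes, start = start + shift, end = end + shift))
  dom2 <- dom; dom2$start <- dom2$start + shift; dom2$end <- dom2$end + shift
  set.seed(99); b1 <- border_proximity_test(dom, ann, n_anchor_draws = 50)
  set.seed(99); b2 <- border_proximity_test(dom2, ann2, n_anchor_draws = 50)
  expect_equal(b1$observed, b2$observed)
  expect_equal(b1$fraction_within_1kb, b2$fraction_within_1kb)
})

test_that("group comparison reports medians, adjusted tests and additivity", {
  classes <- data.frame(
    gene_id = paste0("g", 1:80),
    in_domain = rep(c(TRUE, FALSE), 40),
    has_h4k20me3_peak = rep(c(TRUE, TRUE, FALSE, FALSE), 20))
  classes$joint <- ifelse(classes$in_domain & classes$has_h4k20me3_peak,
                          "both", ifelse(classes$in_domain, "k79_only",
                          ifelse(classes$has_h4k20me3_peak, "k20_only",
                                 "neither")))
  # identical values: every adjusted p = 1
  v <- setNames(rep(5, 80), classes$gene_id)
  gc <- group_comparison(classes, v, "in_out")
  expect_true(all(vapply(gc$tests, `[[`, 0, "p_adjusted") == 1))
  # planted repression: both < single < neither
  base <- c(both = 1, k79_only = 10, k20_only = 8, neither = 100)
  set.seed(3)
  v2 <- setNames(base[classes$joint] * exp(rnorm(80, 0, 0.1)),
                 classes$gene_id)
  gc2 <- group_comparison(classes, v2, "joint4")
  expect_true(gc2$additive)
  expect_true(all(vapply(gc2$tests, `[[`, 0, "p_adjusted") < 0.05))
  # an empty group only narrows the family
  cl3 <- classes[classes$joint != "both", ]
  expect_warning(gc3 <- group_comparison(cl3, v2[cl3$gene_id], "joint4"),
                 "both")
  expect_equal(length(gc3$tests), 3)
  expect_error(group_comparison(classes, setNames(rep(NA_real_, 80),
                                                  classes$gene_id), "in_out"),
               "absent")
})
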