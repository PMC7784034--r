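test_that("TPM normalizes each sample to one million with the stated formula", {
  counts <- matrix(c(10, 10, 7, 13), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  tpm <- compute_tpm(counts, c(g1 = 1000, g2 = 2000))
  # equal counts, lengths 1 and 2 kb -> 2:1 split of a million
  expect_equal(tpm[, "s1"], c(g1 = 2e6 / 3, g2 = 1e6 / 3), tolerance = 1e-9)
  expect_equal(colSums(tpm), c(s1 = 1e6, s2 = 1e6), tolerance = 1e-3)
  single <- compute_tpm(matrix(5, 1, 1, dimnames = list("g", "s")),
                        c(g = 500))
  expect_equal(unname(single[1, 1]), 1e6)
  expect_error(compute_tpm(matrix(0, 1, 1, dimnames = list("g", "s")),
                           c(g = 500)), "all-zero")
})

test_that("DE stand-in is exact on noiseless planted fold changes", {
  # planted 4-fold change, zero replicate noise, groups internally identical
  tpm <- rbind(g1 = c(400, 400, 100, 100), g2 = c(50, 50, 50, 50))
  colnames(tpm) <- c("sp1", "sp2", "ga1", "ga2")
  de <- simple_de_test(tpm, c("sp1", "sp2"), c("ga1", "ga2"),
                       rescale = FALSE)
  expect_equal(de$log2fc[de$gene_id == "g1"],
               log2((400 + 0.5) / (100 + 0.5)), tolerance = 1e-12)
  expect_equal(de$pvalue[de$gene_id == "g2"], 1)   # identical groups
  expect_equal(de$pvalue[de$gene_id == "g1"], 0)   # zero variance, real shift
  expect_error(simple_de_test(tpm, "sp1", c("ga1", "ga2")), "2 replicates")
  # BH column equals an independent recomputation
  ds <- default_dataset()
  de2 <- simple_de_test(ds$expression$tpm, c("sp_rep1", "sp_rep2"),
                        c("ga_rep1", "ga_rep2"))
  p <- de2$pvalue; n <- length(p)
  o <- order(p, decreasing = TRUE)
  bh <- pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
  expect_equal(de2$padj, bh, tolerance = 1e-12)
})

test_that("GBG calling applies every threshold and the intersection rule", {
  mk <- function(padj, l2fc, tpm_sp = 10, tpm_ga = 10)
    data.frame(gene_id = "g", log2fc = l2fc, pvalue = padj / 2, padj = padj,
               mean_tpm_sp = tpm_sp, mean_tpm_ga = tpm_ga)
  pass <- call_gbgs(list(mk(0.04, log2(3)), mk(0.04, log2(3))))
  expect_equal(nrow(pass$gbgs), 1)
  expect_equal(pass$gbgs$bias, "sporophyte")
  # padj 0.06 in one experiment breaks the intersection
  expect_equal(nrow(call_gbgs(list(mk(0.04, log2(3)),
                                   mk(0.06, log2(3))))$gbgs), 0)
  # fold change 1.9 fails the strict > 2 rule
  expect_equal(nrow(call_gbgs(list(mk(0.01, log2(1.9))))$gbgs), 0)
  # TPM <= 1 in the biased generation fails
  expect_equal(nrow(call_gbgs(list(mk(0.01, 2, tpm_sp = 0.9)))$gbgs), 0)
  # conflicting directions across experiments are excluded and counted
  confl <- call_gbgs(list(mk(0.01, 2), mk(0.01, -2)))
  expect_equal(nrow(confl$gbgs), 0)
  expect_equal(confl$n_direction_conflict, 1)
})

test_that("GBG calling is monotone in its thresholds", {
  ds <- default_dataset()
  de <- simple_de_test(ds$expression$tpm, c("sp_rep1", "sp_rep2"),
                       c("ga_rep1", "ga_rep2"))
  loose <- call_gbgs(list(de), padj_max = 0.1, min_fold = 1.5,
                     min_tpm = 0.5)$gbgs$gene_id
  for (args in list(list(padj_max = 0.01), list(min_fold = 4),
                    list(min_tpm = 10))) {
    tight <- do.call(call_gbgs, c(list(list(de)), args))$gbgs$gene_id
    expect_true(all(tight %in% loose))
  }
})

test_that("the 16 chromatin states are a bijection with declared anchors", {
  combos <- expand.grid(H3K4me2 = c(TRUE, FALSE), H3K4me3 = c(TRUE, FALSE),
                        H3K9ac = c(TRUE, FALSE), H3K27ac = c(TRUE, FALSE))
  m <- as.matrix(combos)
  rownames(m) <- paste0("g", seq_len(16))
  ids <- call_states(m)
  expect_setequal(ids, 1:16)                       # bijective over 2^4
  expect_equal(unname(ids[rowSums(m) == 4]), 1)    # all four -> state 1
  expect_equal(unname(ids[rowSums(m) == 0]), 16)   # none -> state 16
  # round trip through the mark-set view
  for (s in 1:16) {
    v <- matrix(STATE_MARKS_PRESENT <- colnames(m) %in% state_marks(s),
                1, 4, dimnames = list("g", colnames(m)))
    expect_equal(unname(call_states(v)), s)
  }
  expect_error(call_states(m[, 1:3]), "missing state mark")
})

test_that("stability summary counts identical presence calls per mark", {
  m <- matrix(TRUE, 10, 4, dimnames = list(paste0("g", 1:10), STATE_MARKS))
  expect_equal(unname(stability_summary(m, m)), rep(1, 4))
  m2 <- m; m2[1, "H3K9ac"] <- FALSE
  expect_equal(stability_summary(m, m2)[["H3K9ac"]], 0.9)
})

test_that("transition analysis recovers the planted gain rule and asymmetry", {
  cfg <- synthetic_config(n_genes = 5000, scaffold_length = 5e6)
  ds <- simulate_dataset(cfg, seed = 2, tracks = FALSE)
  pr <- ds$truth$presence
  ta <- transition_analysis(call_states(pr$sporophyte),
                            call_states(pr$gametophyte),
                            pr$sporophyte, pr$gametophyte, ds$truth$gbgs)
  expect_equal(sum(ta$counts), nrow(ds$truth$gbgs))
  expect_gte(ta$gain_concordance, 0.9)
  expect_gt(ta$fraction_to_state1[["sporophyte"]],
            ta$fraction_to_state1[["gametophyte"]])
  expect_gt(ta$z_test$statistic, 0)
  expect_lt(ta$z_test$p_value, 0.05)
  expect_gt(ta$fraction_unchanged, 0.5)
  expect_gt(ta$fraction_unchanged_state1, 0.6)
})

test_that("degenerate transition inputs are handled", {
  pres <- matrix(TRUE, 3, 4, dimnames = list(c("a", "b", "c"), STATE_MARKS))
  st <- call_states(pres)
  gb <- data.frame(gene_id = c("a", "b"), bias = "sporophyte", log2fc = 2)
  expect_warning(ta <- transition_analysis(st, st, pres, pres, gb),
                 "no state-changing")
  expect_equal(ta$fraction_unchanged, 1)
  expect_null(ta$z_test)
})

test_that("lncRNA enrichment flags a planted excess and fails on zero margins", {
  ds <- default_dataset()
  ann <- ds$annotation
  enr <- lncrna_enrichment(ds$truth$gbgs, ann)
  expect_equal(sum(enr$table), nrow(ann$genes))
  # background equal to genome composition: tiny statistic
  set.seed(5)
  fake <- data.frame(gene_id = sample(ann$genes$gene_id, 300))
  enr0 <- lncrna_enrichment(fake, ann)
  expect_gt(enr0$test$p_value, 0.01)
  no_lnc <- genome_annotation(ann$scaffolds,
                              transform(ann$genes,
                                        biotype = "protein_coding"))
  expect_error(lncrna_enrichment(fake, no_lnc), "margin")
})
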