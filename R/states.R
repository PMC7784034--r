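STATE_MARKS <- c("H3K4me2", "H3K4me3", "H3K9ac", "H3K27ac")

#' TPM from counts
#'
#' TPM_i = 1e6 (c_i / L_i) / sum_j (c_j / L_j), per sample; every sample
#' column sums to one million.
#'
#' @param counts gene x sample non-negative matrix with rownames.
#' @param effective_lengths named per-gene lengths in bp (> 0).
#' @return TPM matrix of the same shape.
#' @export
compute_tpm <- function(counts, effective_lengths) {
  counts <- as.matrix(counts)
  L <- effective_lengths[rownames(counts)]
  stopifnot(all(L > 0), all(counts >= 0))
  rate <- counts / L
  tot <- colSums(rate)
  if (any(tot == 0)) stop("all-zero sample column: ",
                          colnames(counts)[which(tot == 0)[1]])
  sweep(rate, 2, tot, "/") * 1e6
}

#' Median-of-ratios sample scaling
#'
#' Rescales each sample by the median ratio of its values to the per-gene
#' geometric mean across samples (computed over genes positive everywhere).
#' TPM is a within-sample normalization only: when a subset of genes moves
#' strongly in one condition, the shared denominator shifts every other
#' gene's ratio (compositional bias). Size-factor scaling removes that
#' shift, the same way count-model DE tools do.
#'
#' @param tpm gene x sample non-negative matrix.
#' @return the rescaled matrix.
#' @export
scale_samples <- function(tpm) {
  pos <- rowSums(tpm <= 0) == 0
  if (sum(pos) < 2) return(tpm)
  ref <- exp(rowMeans(log(tpm[pos, , drop = FALSE])))
  sf <- apply(tpm[pos, , drop = FALSE], 2, function(v) stats::median(v / ref))
  sweep(tpm, 2, sf, "/")
}

#' Simple between-generation differential-expression test
#'
#' A stand-in usable when no external DE table is supplied: samples are
#' first put on a common scale by \code{\link{scale_samples}}, then each
#' gene gets a two-sided pooled-variance t-test on log2(TPM + 1) between
#' the two generations' replicate columns (replicate designs this small
#' make per-group variance estimates too unstable for Welch's
#' degrees-of-freedom approximation), with log2fc = log2((mean SP TPM + 0.5) /
#' (mean GA TPM + 0.5)) and Benjamini-Hochberg adjustment over all genes.
#' An externally computed DE table (e.g. from a count-model tool) takes
#' precedence when available.
#'
#' @param tpm gene x sample TPM matrix.
#' @param sp_cols,ga_cols column names or indices of the sporophyte and
#'   gametophyte replicates (>= 2 each).
#' @param rescale apply median-of-ratios scaling first (default TRUE).
#' @return data.frame \code{gene_id}, \code{log2fc}, \code{pvalue},
#'   \code{padj}, \code{mean_tpm_sp}, \code{mean_tpm_ga}.
#' @export
simple_de_test <- function(tpm, sp_cols, ga_cols, rescale = TRUE) {
  if (length(sp_cols) < 2 || length(ga_cols) < 2)
    stop("need >= 2 replicates per generation")
  if (rescale) tpm <- scale_samples(tpm)
  a <- log2(tpm[, sp_cols, drop = FALSE] + 1)
  b <- log2(tpm[, ga_cols, drop = FALSE] + 1)
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se2 <- sp2 * (1 / n1 + 1 / n2)
  df <- n1 + n2 - 2
  t <- ifelse(se2 == 0, ifelse(m1 == m2, 0, Inf * sign(m1 - m2)),
              (m1 - m2) / sqrt(se2))
  p <- ifelse(is.infinite(t), 0,
              ifelse(t == 0 & se2 == 0, 1, 2 * stats::pt(-abs(t), df)))
  msp <- rowMeans(tpm[, sp_cols, drop = FALSE])
  mga <- rowMeans(tpm[, ga_cols, drop = FALSE])
  data.frame(gene_id = rownames(tpm),
             log2fc = log2((msp + 0.5) / (mga + 0.5)),
             pvalue = p, padj = stats::p.adjust(p, "BH"),
             mean_tpm_sp = msp, mean_tpm_ga = mga)
}

#' Call generation-biased genes (GBGs)
#'
#' A gene is a GBG when it passes padj < 0.05, fold change > 2 and
#' TPM > 1 (mean, in the biased generation), with a consistent bias
#' direction, in every supplied experiment. Genes significant in all
#' experiments but with conflicting directions are excluded and counted.
#'
#' @param de_tables list of DE data.frames as returned by
#'   \code{\link{simple_de_test}} (columns \code{gene_id}, \code{log2fc},
#'   \code{padj}, \code{mean_tpm_sp}, \code{mean_tpm_ga}), sharing a gene
#'   universe.
#' @param padj_max,min_fold,min_tpm calling thresholds (defaults 0.05, 2, 1).
#' @return list with \code{gbgs} (data.frame \code{gene_id}, \code{bias} in
#'   \{sporophyte, gametophyte\}, \code{log2fc} from the first experiment)
#'   and \code{n_direction_conflict}.
#' @export
call_gbgs <- function(de_tables, padj_max = 0.05, min_fold = 2, min_tpm = 1) {
  stopifnot(length(de_tables) >= 1)
  ids <- de_tables[[1]]$gene_id
  for (d in de_tables) stopifnot(setequal(d$gene_id, ids))
  pass <- matrix(FALSE, length(ids), length(de_tables))
  dir <- matrix(NA_integer_, length(ids), length(de_tables))
  for (k in seq_along(de_tables)) {
    d <- de_tables[[k]][match(ids, de_tables[[k]]$gene_id), ]
    up_tpm <- ifelse(d$log2fc > 0, d$mean_tpm_sp, d$mean_tpm_ga)
    ok <- !is.na(d$padj) & d$padj < padj_max &
      abs(d$log2fc) > log2(min_fold) & up_tpm > min_tpm
    pass[, k] <- ok
    dir[, k] <- sign(d$log2fc)
  }
  all_pass <- rowSums(pass) == length(de_tables)
  consistent <- apply(dir, 1, function(r) length(unique(r)) == 1)
  sel <- all_pass & consistent
  conflict <- sum(all_pass & !consistent)
  d1 <- de_tables[[1]][match(ids, de_tables[[1]]$gene_id), ]
  gbgs <- data.frame(
    gene_id = ids[sel],
    bias = ifelse(d1$log2fc[sel] > 0, "sporophyte", "gametophyte"),
    log2fc = d1$log2fc[sel])
  rownames(gbgs) <- NULL
  list(gbgs = gbgs, n_direction_conflict = conflict)
}

# canonical ordering of the 16 mark subsets: descending mark count, ties
# broken so that subsets containing earlier-listed marks rank earlier
state_table <- function() {
  m <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), 4)))[, 4:1]
  colnames(m) <- STATE_MARKS
  ord <- order(-rowSums(m), -m[, 1], -m[, 2], -m[, 3], -m[, 4])
  m <- m[ord, , drop = FALSE]
  rownames(m) <- as.character(seq_len(16))
  m
}

#' Combinatorial chromatin states from four TSS marks
#'
#' Maps each gene's presence/absence combination of H3K4me2, H3K4me3,
#' H3K9ac and H3K27ac to one of 16 states. State 1 is all four marks
#' present and state 16 none; within the fixed ordering, states with more
#' marks come first, ties broken by the mark order above.
#'
#' @param presence gene x mark logical matrix (columns must include the four
#'   state marks; rownames are gene ids).
#' @return named integer vector of state ids (1-16) per gene.
#' @export
call_states <- function(presence) {
  missing <- setdiff(STATE_MARKS, colnames(presence))
  if (length(missing) > 0)
    stop("missing state mark column(s): ", paste(missing, collapse = ", "))
  st <- state_table()
  key <- apply(st, 1, paste, collapse = "")
  obs <- apply(presence[, STATE_MARKS, drop = FALSE], 1, paste, collapse = "")
  ids <- match(obs, key)
  stats::setNames(ids, rownames(presence))
}

#' Mark set of a state id
#' @param state_id integer 1-16.
#' @return character vector of marks present in that state.
#' @export
state_marks <- function(state_id) {
  st <- state_table()
  STATE_MARKS[st[state_id, ]]
}

#' Per-mark cross-generation stability
#'
#' Fraction of genes whose presence call is identical in the two
#' generations (stably present or stably absent), per mark.
#'
#' @param presence_sp,presence_ga gene x mark logical matrices over the same
#'   genes and marks.
#' @return named numeric vector of stable fractions per mark.
#' @export
stability_summary <- function(presence_sp, presence_ga) {
  stopifnot(identical(dim(presence_sp), dim(presence_ga)),
            identical(colnames(presence_sp), colnames(presence_ga)))
  colMeans(presence_sp == presence_ga[rownames(presence_sp), , drop = FALSE])
}

#' Chromatin-state transitions at generation-biased genes
#'
#' Restricted to the GBG set, cross-tabulates (sporophyte state,
#' gametophyte state) and summarises: the fraction of GBGs that do not
#' change state (and, of those, the fraction sitting in state 1); for
#' state-changing GBGs, gain-concordance (the biased generation shows a net
#' gain of marks: gained minus lost > 0, computed in the up-regulated
#' generation); the per-bias fraction of transitions whose destination (the
#' biased-generation state) is state 1, compared by a two-proportion z test
#' (sporophyte minus gametophyte); and a two-sided Wilcoxon comparing
#' |log2fc| of transitions landing in state 1 vs other destinations.
#'
#' @param states_sp,states_ga named per-gene state ids (from
#'   \code{\link{call_states}}).
#' @param presence_sp,presence_ga the underlying presence matrices (for mark
#'   gain/loss counting).
#' @param gbgs GBG data.frame (\code{gene_id}, \code{bias}, \code{log2fc}).
#' @return list with \code{counts} (16 x 16), \code{fraction_unchanged},
#'   \code{fraction_unchanged_state1}, \code{gain_concordance},
#'   \code{fraction_to_state1} (per bias), \code{z_test},
#'   \code{state1_foldchange_test}, \code{n_changers}.
#' @export
transition_analysis <- function(states_sp, states_ga, presence_sp,
                                presence_ga, gbgs) {
  stopifnot(nrow(gbgs) > 0)
  ids <- gbgs$gene_id
  stopifnot(all(ids %in% names(states_sp)), all(ids %in% names(states_ga)))
  s_sp <- states_sp[ids]; s_ga <- states_ga[ids]
  counts <- table(factor(s_sp, 1:16), factor(s_ga, 1:16))
  unchanged <- s_sp == s_ga
  frac_unchanged <- mean(unchanged)
  frac_unch_s1 <- if (any(unchanged)) mean(s_sp[unchanged] == 1) else NA_real_

  ch <- which(!unchanged)
  res <- list(counts = counts, fraction_unchanged = frac_unchanged,
              fraction_unchanged_state1 = frac_unch_s1,
              n_changers = length(ch))
  if (length(ch) == 0) {
    warning("no state-changing GBGs; transition tests unavailable")
    res$gain_concordance <- NA_real_
    res$fraction_to_state1 <- c(sporophyte = NA_real_, gametophyte = NA_real_)
    res$z_test <- NULL
    res$state1_foldchange_test <- NULL
    return(res)
  }

  cid <- ids[ch]
  bias <- gbgs$bias[ch]
  up_m <- ifelse(bias == "sporophyte", 1, 2)  # which matrix is up-generation
  net_gain <- vapply(seq_along(cid), function(k) {
    up <- if (up_m[k] == 1) presence_sp[cid[k], STATE_MARKS]
          else presence_ga[cid[k], STATE_MARKS]
    dn <- if (up_m[k] == 1) presence_ga[cid[k], STATE_MARKS]
          else presence_sp[cid[k], STATE_MARKS]
    sum(up & !dn) - sum(dn & !up)
  }, 0)
  res$gain_concordance <- mean(net_gain > 0)

  dest <- ifelse(bias == "sporophyte", s_sp[ch], s_ga[ch])
  to1 <- dest == 1
  n_sp <- sum(bias == "sporophyte"); n_ga <- sum(bias == "gametophyte")
  res$fraction_to_state1 <- c(
    sporophyte = if (n_sp > 0) mean(to1[bias == "sporophyte"]) else NA_real_,
    gametophyte = if (n_ga > 0) mean(to1[bias == "gametophyte"]) else NA_real_)
  res$z_test <- if (n_sp > 0 && n_ga > 0)
    stat_test("two_proportion_z",
              x = c(sum(to1[bias == "sporophyte"]),
                    sum(to1[bias == "gametophyte"])),
              n = c(n_sp, n_ga)) else NULL
  fc <- abs(gbgs$log2fc[ch])
  res$state1_foldchange_test <- if (any(to1) && any(!to1))
    stat_test("wilcoxon", fc[to1], fc[!to1]) else NULL
  res
}

#' lncRNA enrichment among GBGs
#'
#' Yates-corrected chi-squared on the 2x2 table biotype (lncRNA vs
#' protein-coding) x GBG membership over all annotated genes.
#'
#' @param gbgs GBG data.frame.
#' @param annotation a \code{genome_annotation}.
#' @return list with \code{test}, \code{table} and \code{n_lncrna_gbgs}.
#' @export
lncrna_enrichment <- function(gbgs, annotation) {
  g <- annotation$genes
  is_lnc <- g$biotype == "lncRNA"
  is_gbg <- g$gene_id %in% gbgs$gene_id
  tb <- rbind(lncRNA = c(gbg = sum(is_lnc & is_gbg),
                         other = sum(is_lnc & !is_gbg)),
              coding = c(gbg = sum(!is_lnc & is_gbg),
                         other = sum(!is_lnc & !is_gbg)))
  list(test = stat_test("chi2_yates", table = tb), table = tb,
       n_lncrna_gbgs = sum(is_lnc & is_gbg))
}
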