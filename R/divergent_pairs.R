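#' Mark signal at the second TSS of adjacent gene pairs
#'
#' For every pair, "gene 2" is the right-hand gene in scaffold coordinates;
#' the signal is the mean normalized coverage in a window of \code{window}
#' bp either side of its TSS. Per mark, divergent and tandem pairs are
#' compared by a two-sided Wilcoxon rank-sum test, and signal medians are
#' reported for intergenic-length strata (the < 1 kbp stratum first).
#'
#' @param tracks named list of \code{signal_track}s (one per mark).
#' @param pairs output of \code{\link{classify_adjacent_pairs}}.
#' @param annotation a \code{genome_annotation}.
#' @param window half-window in bp (default 500; 0 = single-bin lookup).
#' @param strata intergenic-length breakpoints in bp.
#' @return list with \code{records} (pair x mark signal data.frame),
#'   \code{tests} (per-mark \code{test_result}), \code{strata_medians}.
#' @export
pair_tss_signal <- function(tracks, pairs, annotation, window = 500,
                            strata = c(0, 1000, 2000, 5000, Inf)) {
  if (nrow(pairs) == 0) stop("empty pair set")
  g <- annotation$genes
  tss2 <- g$tss[match(pairs$right_gene, g$gene_id)]
  rec <- pairs[, c("scaffold", "left_gene", "right_gene", "orientation",
                   "length")]
  for (mk in names(tracks)) {
    tr <- tracks[[mk]]
    nb <- normalized_bins(tr)
    rec[[mk]] <- vapply(seq_len(nrow(pairs)), function(i) {
      sn <- pairs$scaffold[i]
      w <- if (window == 0) c(floor(tss2[i] / tr$bin_size) * tr$bin_size,
                              floor(tss2[i] / tr$bin_size) * tr$bin_size +
                                tr$bin_size)
           else c(tss2[i] - window, tss2[i] + window)
      window_mean(nb[[sn]], tr$bin_size, w[1], w[2],
                  tr$scaffold_lengths[[sn]])
    }, 0)
  }
  tests <- list()
  for (mk in names(tracks)) {
    d <- rec[[mk]][rec$orientation == "divergent"]
    t <- rec[[mk]][rec$orientation == "tandem"]
    tests[[mk]] <- if (length(d) > 0 && length(t) > 0)
      stat_test("wilcoxon", d, t) else NULL
  }
  stratum <- cut(rec$length, strata, right = FALSE, include.lowest = TRUE)
  sm <- lapply(stats::setNames(names(tracks), names(tracks)), function(mk)
    tapply(rec[[mk]], list(rec$orientation, stratum), stats::median))
  list(records = rec, tests = tests, strata_medians = sm)
}

#' Detect nucleosome-depleted regions in an MNase track
#'
#' An NDR is a maximal run of bins whose smoothed value (three-bin running
#' mean, which keeps sampling noise from splitting a depleted run) falls
#' below \code{depth_threshold} times the local background, the median raw
#' MNase signal in a window of \code{background_window} bp centred on the
#' queried region. Calls are scale-invariant: multiplying the track by a
#' positive constant changes nothing.
#'
#' @param track MNase \code{signal_track}.
#' @param scaffold,start,end queried region (e.g. an intergenic interval);
#'   scanning extends one bin either side.
#' @param tss_points optional bp positions (e.g. the two divergent TSSs);
#'   each NDR reports whether it contains all of them within one bin.
#' @param depth_threshold fraction of background below which a bin is
#'   depleted (default 0.5).
#' @param background_window background estimation window, bp (default 5000).
#' @param min_width minimum NDR width in bp (default one bin).
#' @return data.frame \code{scaffold}, \code{start}, \code{end},
#'   \code{depth} (fractional dip below background),
#'   \code{spans_both_tss}.
#' @export
detect_ndr <- function(track, scaffold, start, end, tss_points = NULL,
                       depth_threshold = 0.5, background_window = 5000,
                       min_width = NULL) {
  bs <- track$bin_size
  if (is.null(min_width)) min_width <- bs
  L <- track$scaffold_lengths[[scaffold]]
  if (end - start < 1) stop("region shorter than 1 bp")
  v <- track$bins[[scaffold]]
  mid <- (start + end) / 2
  bg_i0 <- max(1, floor((mid - background_window / 2) / bs) + 1)
  bg_i1 <- min(length(v), ceiling((mid + background_window / 2) / bs))
  bg <- stats::median(v[bg_i0:bg_i1])
  empty <- data.frame(scaffold = character(), start = numeric(),
                      end = numeric(), depth = numeric(),
                      spans_both_tss = logical())
  if (bg <= 0) return(empty)
  vs <- running_mean(v, 1)                 # 3-bin smoothing
  i0 <- max(1, floor(start / bs))          # one bin of flank
  i1 <- min(length(v), ceiling(end / bs) + 1)
  idx <- i0:i1
  low <- vs[idx] < depth_threshold * bg
  if (!any(low)) return(empty)
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- c(1, ends[-length(ends)] + 1)
  out <- list()
  for (k in which(r$values)) {
    bi <- idx[starts[k]:ends[k]]
    s <- (bi[1] - 1) * bs; e <- min(bi[length(bi)] * bs, L)
    if (e - s < min_width) next
    depth <- 1 - mean(v[bi]) / bg
    spans <- if (is.null(tss_points) || length(tss_points) == 0) NA
             else all(tss_points >= s - bs & tss_points <= e + bs)
    out[[length(out) + 1]] <- data.frame(
      scaffold = scaffold, start = s, end = e, depth = depth,
      spans_both_tss = spans)
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Shared-NDR rate of divergent pairs by intergenic length
#'
#' For each divergent pair the intergenic region is scanned for NDRs; the
#' pair shares an NDR when a single call contains both partners' TSSs. The
#' shared fraction is reported separately for pairs at or below and above
#' the length threshold.
#'
#' @param pairs output of \code{\link{classify_adjacent_pairs}}.
#' @param annotation a \code{genome_annotation}.
#' @param mnase_track MNase \code{signal_track}.
#' @param length_threshold stratification length, bp (default 600).
#' @param ... passed to \code{\link{detect_ndr}}.
#' @return list with \code{rate_short}, \code{rate_long} (NA when a stratum
#'   is empty), \code{n_short}, \code{n_long}, and per-pair \code{shared}.
#' @export
shared_ndr_rate <- function(pairs, annotation, mnase_track,
                            length_threshold = 600, ...) {
  dv <- pairs[pairs$orientation == "divergent" & !pairs$overlapping, ,
              drop = FALSE]
  if (nrow(dv) == 0) stop("no divergent pairs")
  g <- annotation$genes
  shared <- logical(nrow(dv))
  for (i in seq_len(nrow(dv))) {
    tssL <- g$tss[match(dv$left_gene[i], g$gene_id)]
    tssR <- g$tss[match(dv$right_gene[i], g$gene_id)]
    ndr <- detect_ndr(mnase_track, dv$scaffold[i], dv$start[i], dv$end[i],
                      tss_points = c(tssL, tssR), ...)
    shared[i] <- nrow(ndr) > 0 && any(ndr$spans_both_tss)
  }
  short <- dv$length <= length_threshold
  list(rate_short = if (any(short)) mean(shared[short]) else NA_real_,
       rate_long = if (any(!short)) mean(shared[!short]) else NA_real_,
       n_short = sum(short), n_long = sum(!short),
       shared = data.frame(dv[, c("left_gene", "right_gene", "length")],
                           shared = shared))
}

#' Within-pair expression correlation
#'
#' Pearson correlation of log2(TPM + 1) between the two members of each
#' pair, optionally restricted to divergent pairs or to divergent pairs
#' with short intergenics.
#'
#' @param tpm named per-gene TPM vector (or one-column summary).
#' @param pairs output of \code{\link{classify_adjacent_pairs}}.
#' @param subset \code{"all"}, \code{"divergent"} or \code{"divergent_lt"}.
#' @param max_length length cutoff for \code{"divergent_lt"} (default 600).
#' @return a \code{test_result} (Pearson), with \code{estimate} = r.
#' @export
pair_expression_correlation <- function(tpm, pairs,
                                        subset = c("all", "divergent",
                                                   "divergent_lt"),
                                        max_length = 600) {
  subset <- match.arg(subset)
  sel <- switch(subset,
    all = rep(TRUE, nrow(pairs)),
    divergent = pairs$orientation == "divergent",
    divergent_lt = pairs$orientation == "divergent" &
      pairs$length < max_length)
  p <- pairs[sel, , drop = FALSE]
  if (nrow(p) < 3) stop("fewer than 3 pairs in subset '", subset, "'")
  x <- log2(tpm[p$left_gene] + 1)
  y <- log2(tpm[p$right_gene] + 1)
  stat_test("pearson", unname(x), unname(y))
}

#' lncRNA-coding co-regulation among adjacent GBGs
#'
#' Counts lncRNA GBGs whose adjacent pair partner is a protein-coding GBG
#' and the fraction of such couples biased toward the same generation.
#'
#' @param gbgs GBG data.frame (\code{gene_id}, \code{bias}).
#' @param pairs output of \code{\link{classify_adjacent_pairs}}.
#' @param annotation a \code{genome_annotation}.
#' @return list with \code{n_lncrna_gbg_adjacent_coding_gbg} and
#'   \code{fraction_codirectional} (NA when no such couple exists).
#' @export
adjacent_gbg_coregulation <- function(gbgs, pairs, annotation) {
  g <- annotation$genes
  bio <- stats::setNames(g$biotype, g$gene_id)
  bias <- stats::setNames(gbgs$bias, gbgs$gene_id)
  is_gbg <- g$gene_id %in% gbgs$gene_id
  names(is_gbg) <- g$gene_id
  hits <- 0; codir <- 0
  seen <- character(0)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$left_gene[i]; b <- pairs$right_gene[i]
    for (ord in list(c(a, b), c(b, a))) {
      lnc <- ord[1]; cod <- ord[2]
      if (bio[lnc] == "lncRNA" && bio[cod] == "protein_coding" &&
          is_gbg[lnc] && is_gbg[cod]) {
        key <- paste(lnc, cod)
        if (key %in% seen) next
        seen <- c(seen, key)
        hits <- hits + 1
        if (bias[lnc] == bias[cod]) codir <- codir + 1
      }
    }
  }
  list(n_lncrna_gbg_adjacent_coding_gbg = hits,
       fraction_codirectional = if (hits > 0) codir / hits else NA_real_)
}
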