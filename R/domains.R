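#' Segment broad domains from broad-mode peaks
#'
#' Merges broad peaks separated by at most \code{merge_gap} bp into
#' continuous domains; the domain score is the length-weighted mean of the
#' merged peak scores.
#'
#' @param peaks a broad-mode \code{peak_set}.
#' @param merge_gap maximum gap bridged, bp (default 1000).
#' @return a \code{domain_set}: data.frame \code{scaffold}, \code{start},
#'   \code{end}, \code{score}, sorted and non-overlapping.
#' @export
segment_domains <- function(peaks, merge_gap = 1000) {
  out <- list()
  for (sn in unique(peaks$scaffold)) {
    p <- peaks[peaks$scaffold == sn, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    grp <- cumsum(c(0, ifelse(p$start[-1] - p$end[-nrow(p)] > merge_gap, 1, 0)))
    for (gi in unique(grp)) {
      q <- p[grp == gi, , drop = FALSE]
      w <- q$end - q$start
      out[[length(out) + 1]] <- data.frame(
        scaffold = sn, start = min(q$start), end = max(q$end),
        score = sum(q$score * w) / sum(w))
    }
  }
  d <- if (length(out) == 0)
    data.frame(scaffold = character(), start = numeric(), end = numeric(),
               score = numeric())
  else do.call(rbind, out)
  d <- d[order(d$scaffold, d$start), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "mark") <- attr(peaks, "mark")
  attr(d, "generation") <- attr(peaks, "generation")
  class(d) <- c("domain_set", "data.frame")
  d
}

# bp overlap of gene bodies with a set of intervals; returns per-gene bp
gene_domain_overlap_bp <- function(annotation, domains) {
  g <- annotation$genes
  ov <- stats::setNames(numeric(nrow(g)), g$gene_id)
  for (sn in unique(g$scaffold)) {
    d <- IRanges::reduce(iranges_of(domains, sn))
    gi <- which(g$scaffold == sn)
    if (length(d) == 0 || length(gi) == 0) next
    gr <- IRanges::IRanges(g$start[gi] + 1, g$end[gi])
    hits <- IRanges::findOverlaps(gr, d)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(gr[qi], d[si]))
    agg <- tapply(w, qi, sum)
    ov[g$gene_id[gi[as.integer(names(agg))]]] <- as.numeric(agg)
  }
  ov
}

#' Summary statistics for a domain set
#'
#' Total covered bp, genome fraction, fraction of domains longer than 5 kbp,
#' and the mean number of genes per > 5 kbp domain. A gene counts toward a
#' domain when more than half its body (TSS-TES span) lies inside it — the
#' same rule as \code{\link{classify_genes_by_domain}}.
#'
#' @param domains a \code{domain_set}.
#' @param annotation a \code{genome_annotation}.
#' @param long_threshold length defining a long domain, bp (default 5000).
#' @return list with \code{total_bp}, \code{genome_fraction},
#'   \code{n_domains}, \code{fraction_long}, \code{mean_genes_per_long}
#'   (NA when no long domain exists).
#' @export
domain_summary <- function(domains, annotation, long_threshold = 5000) {
  len <- domains$end - domains$start
  total <- sum(len)
  long <- domains[len > long_threshold, , drop = FALSE]
  mean_genes <- NA_real_
  if (nrow(long) > 0) {
    g <- annotation$genes
    counts <- numeric(nrow(long))
    for (i in seq_len(nrow(long))) {
      gi <- which(g$scaffold == long$scaffold[i])
      if (length(gi) == 0) next
      ov <- pmax(0, pmin(g$end[gi], long$end[i]) -
                    pmax(g$start[gi], long$start[i]))
      counts[i] <- sum(ov / (g$end[gi] - g$start[gi]) > 0.5)
    }
    mean_genes <- mean(counts)
  }
  list(total_bp = total, genome_fraction = total / genome_length(annotation),
       n_domains = nrow(domains),
       fraction_long = if (nrow(domains) > 0) nrow(long) / nrow(domains)
                       else NA_real_,
       mean_genes_per_long = mean_genes)
}

# distance from each position to the nearest TSS-or-TES point (pooled over
# strands and genes); binary search per scaffold
nearest_point_distance <- function(positions, scaffold, points_by_scaffold) {
  out <- rep(Inf, length(positions))
  for (sn in unique(scaffold)) {
    pts <- sort(points_by_scaffold[[sn]])
    sel <- which(scaffold == sn)
    if (length(pts) == 0) next
    pos <- positions[sel]
    i <- findInterval(pos, pts)
    d_lo <- ifelse(i >= 1, pos - pts[pmax(i, 1)], Inf)
    d_hi <- ifelse(i < length(pts), pts[pmin(i + 1, length(pts))] - pos, Inf)
    out[sel] <- pmin(d_lo, d_hi)
  }
  out
}

#' Test domain-border proximity to gene starts and ends
#'
#' For every border (two per domain of at least \code{min_len} bp) the
#' distance to the nearest TSS or TES over all genes is computed. The null is
#' built by drawing \code{n_anchor_draws} sets of random anchor points,
#' uniform over the scaffolds, each set the same size as the border set, and
#' computing the same distances. Observed vs pooled null distances are
#' compared by a two-sided Wilcoxon rank-sum test.
#'
#' @param domains a \code{domain_set}.
#' @param annotation a \code{genome_annotation}.
#' @param min_len only domains at least this long contribute borders.
#' @param n_anchor_draws number of random anchor sets.
#' @param within_bp distance band reported as a fraction (default 1000).
#' @return list with \code{observed} (bp distances), \code{null} (pooled),
#'   \code{fraction_within_1kb}, \code{n_borders} and \code{test}.
#' @export
border_proximity_test <- function(domains, annotation, min_len = 5000,
                                  n_anchor_draws = 1000, within_bp = 1000) {
  len <- domains$end - domains$start
  qual <- domains[len >= min_len, , drop = FALSE]
  if (nrow(qual) == 0)
    stop("no domain of length >= ", min_len, " (", nrow(domains),
         " domains total)")
  if (nrow(annotation$genes) == 0) stop("annotation has no genes")
  pts <- with(annotation$genes,
              split(c(tss, tes), rep(scaffold, 2)))
  borders <- data.frame(
    scaffold = rep(qual$scaffold, 2),
    pos = c(qual$start, qual$end))
  obs <- nearest_point_distance(borders$pos, borders$scaffold, pts)

  slen <- scaffold_lengths(annotation)
  cum <- cumsum(as.numeric(slen))
  total <- cum[length(cum)]
  nb <- nrow(borders)
  null <- numeric(0)
  for (k in seq_len(n_anchor_draws)) {
    u <- stats::runif(nb, 0, total)
    si <- findInterval(u, c(0, cum), rightmost.closed = TRUE)
    pos <- u - c(0, cum)[si]
    null <- c(null, nearest_point_distance(pos, names(slen)[si], pts))
  }
  test <- stat_test("wilcoxon", obs, null)
  list(observed = obs, null = null,
       fraction_within_1kb = mean(obs <= within_bp),
       n_borders = nb, test = test)
}

#' Cross-generation domain stability
#'
#' Fraction of long domains detected uniquely in each generation: a domain
#' of at least \code{min_len} bp is unique when it overlaps no domain of the
#' other generation (of any length) by at least one bp.
#'
#' @param domains_sp,domains_ga \code{domain_set}s for the two generations.
#' @param min_len qualifying length, bp (default 5000).
#' @return list with \code{fraction_unique_sp}, \code{fraction_unique_ga}
#'   and the qualifying counts.
#' @export
generation_overlap <- function(domains_sp, domains_ga, min_len = 5000) {
  frac_unique <- function(a, b) {
    qual <- a[a$end - a$start >= min_len, , drop = FALSE]
    if (nrow(qual) == 0) return(list(frac = NA_real_, n = 0L))
    hit <- overlaps_any(qual, b)
    list(frac = mean(!hit), n = nrow(qual))
  }
  sp <- frac_unique(domains_sp, domains_ga)
  ga <- frac_unique(domains_ga, domains_sp)
  list(fraction_unique_sp = sp$frac, fraction_unique_ga = ga$frac,
       n_long_sp = sp$n, n_long_ga = ga$n)
}

#' Classify genes by broad-domain and H4K20me3 status
#'
#' A gene is "in" a domain when strictly more than \code{threshold} of its
#' body (TSS-TES span) lies inside domain intervals; it carries an H4K20me3
#' peak when its body overlaps at least one such peak by one bp. The joint
#' class combines both calls.
#'
#' @param annotation a \code{genome_annotation}.
#' @param domains a \code{domain_set} (broad mark).
#' @param h4k20me3_peaks a \code{peak_set}, or NULL (all genes called FALSE).
#' @param threshold body-overlap fraction (default 0.5; strict inequality).
#' @return data.frame \code{gene_id}, \code{in_domain},
#'   \code{has_h4k20me3_peak}, \code{joint} in
#'   \{neither, k79_only, k20_only, both\}.
#' @export
classify_genes_by_domain <- function(annotation, domains,
                                     h4k20me3_peaks = NULL, threshold = 0.5) {
  g <- annotation$genes
  ov <- gene_domain_overlap_bp(annotation, domains)
  in_domain <- ov / (g$end - g$start) > threshold
  has_k20 <- if (is.null(h4k20me3_peaks) || nrow(h4k20me3_peaks) == 0)
    rep(FALSE, nrow(g))
  else overlaps_any(g[, c("scaffold", "start", "end")], h4k20me3_peaks)
  joint <- ifelse(in_domain & has_k20, "both",
           ifelse(in_domain, "k79_only",
           ifelse(has_k20, "k20_only", "neither")))
  data.frame(gene_id = g$gene_id, in_domain = unname(in_domain),
             has_h4k20me3_peak = has_k20, joint = joint)
}

#' Compare a per-gene metric across domain classes
#'
#' Pairwise two-sided Wilcoxon rank-sum tests between groups, Bonferroni
#' adjusted across the family, with per-group medians. For the four-way
#' joint grouping an additivity flag reports whether the doubly marked group
#' has the lowest median (below both singly marked groups).
#'
#' @param classes output of \code{\link{classify_genes_by_domain}}.
#' @param values named per-gene numeric vector (TPM, exon count, length,
#'   TSS signal, ...).
#' @param grouping \code{"in_out"} (in_domain TRUE/FALSE) or \code{"joint4"}.
#' @return list with \code{medians}, \code{n}, \code{tests} (named list of
#'   adjusted \code{test_result}s) and \code{additive} (joint4 only).
#' @export
group_comparison <- function(classes, values, grouping = c("in_out", "joint4")) {
  grouping <- match.arg(grouping)
  v <- values[classes$gene_id]
  if (mean(is.na(v)) > 0.5) stop("metric absent for more than half the genes")
  grp <- if (grouping == "in_out")
    ifelse(classes$in_domain, "in", "out") else classes$joint
  keep <- !is.na(v)
  v <- v[keep]; grp <- grp[keep]
  groups <- split(v, grp)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need >= 2 non-empty groups")
  expected <- if (grouping == "in_out") c("in", "out") else
    c("neither", "k79_only", "k20_only", "both")
  missing <- setdiff(expected, names(groups))
  if (length(missing) > 0)
    warning("empty group(s): ", paste(missing, collapse = ", "))
  medians <- vapply(groups, stats::median, 0)
  cmb <- utils::combn(names(groups), 2)
  tests <- lapply(seq_len(ncol(cmb)), function(k)
    stat_test("wilcoxon", groups[[cmb[1, k]]], groups[[cmb[2, k]]]))
  names(tests) <- apply(cmb, 2, paste, collapse = "_vs_")
  tests <- adjust_family(tests, "bonferroni")
  additive <- NA
  if (grouping == "joint4" &&
      all(c("both", "k79_only", "k20_only") %in% names(medians)))
    additive <- medians[["both"]] <
      min(medians[["k79_only"]], medians[["k20_only"]])
  list(medians = medians, n = lengths(groups), tests = tests,
       additive = additive)
}
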