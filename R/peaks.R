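#' Call enriched intervals from a binned track
#'
#' A deliberately simple Poisson bin caller: per-bin counts are tested
#' against a Poisson background whose rate is the larger of the global
#' control mean and a local (10 kb window) control mean, scaled for library
#' size; p-values are Benjamini-Hochberg adjusted across all genome bins and
#' bins at q below the threshold are merged into peaks. Without a control
#' the track's own median bin value serves as the global background. The
#' contribution of this pipeline is downstream of peak calling; no
#' equivalence with read-level callers is claimed.
#'
#' @param track treatment \code{signal_track} (counts; pool replicates with
#'   \code{\link{pool_tracks}} first).
#' @param control input-chromatin \code{signal_track} on the same bin grid,
#'   or NULL.
#' @param mode \code{"narrow"} (merge gap one bin, min length 2 bins) or
#'   \code{"broad"} (merge gap 1 kb, min length 10 bins).
#' @param q_threshold FDR threshold (default 0.01).
#' @param min_len,max_gap overrides in bp for the mode defaults.
#' @param local_window window for the local background estimate, bp.
#' @return A \code{peak_set}: data.frame \code{scaffold}, \code{start},
#'   \code{end}, \code{score} (-log10 q at the peak's best bin),
#'   \code{summit} (midpoint of the highest bin), with \code{mark} /
#'   \code{generation} attributes.
#' @export
call_peaks <- function(track, control = NULL, mode = c("narrow", "broad"),
                       q_threshold = 0.01, min_len = NULL, max_gap = NULL,
                       local_window = 10000) {
  mode <- match.arg(mode)
  bs <- track$bin_size
  if (is.null(max_gap)) max_gap <- if (mode == "narrow") bs else 1000
  if (is.null(min_len)) min_len <- if (mode == "narrow") 2 * bs else 10 * bs
  if (!is.null(control)) {
    stopifnot(control$bin_size == bs)
    ratio <- if (control$library_size > 0)
      track$library_size / control$library_size else 1
  }

  hw <- max(1L, round(local_window / 2 / bs))
  pvals <- list(); xs <- list()
  for (sn in names(track$bins)) {
    x <- track$bins[[sn]]
    if (!is.null(control)) {
      cb <- control$bins[[sn]]
      lam_global <- mean(unlist(control$bins))
      lam <- pmax(lam_global, running_mean(cb, hw)) * ratio
    } else {
      lam <- rep(max(stats::median(unlist(track$bins)), 1e-6), length(x))
    }
    lam <- pmax(lam, 1e-6)
    pvals[[sn]] <- stats::ppois(ceiling(x) - 1, lam, lower.tail = FALSE)
    xs[[sn]] <- x
  }
  q <- stats::p.adjust(unlist(pvals), method = "BH")
  qs <- split(q, rep(names(pvals), lengths(pvals)))[names(pvals)]

  res <- list()
  for (sn in names(track$bins)) {
    sig <- which(qs[[sn]] <= q_threshold & xs[[sn]] > 0)
    if (length(sig) == 0) next
    gap_bins <- floor(max_gap / bs)
    brk <- c(0, which(diff(sig) - 1 > gap_bins), length(sig))
    L <- track$scaffold_lengths[[sn]]
    for (k in seq_len(length(brk) - 1)) {
      idx <- sig[(brk[k] + 1):brk[k + 1]]
      s <- (idx[1] - 1) * bs
      e <- min(idx[length(idx)] * bs, L)
      if (e - s < min_len) next
      span <- idx[1]:idx[length(idx)]
      best <- span[which.max(xs[[sn]][span])]
      res[[length(res) + 1]] <- data.frame(
        scaffold = sn, start = s, end = e,
        score = min(-log10(max(min(qs[[sn]][idx]), 1e-300)), 300),
        summit = min((best - 0.5) * bs, L))
    }
  }
  peaks <- if (length(res) == 0)
    data.frame(scaffold = character(), start = numeric(), end = numeric(),
               score = numeric(), summit = numeric())
  else do.call(rbind, res)
  peaks <- peaks[order(peaks$scaffold, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  attr(peaks, "mark") <- track$mark
  attr(peaks, "generation") <- track$generation
  class(peaks) <- c("peak_set", "data.frame")
  peaks
}

# distance from point p to interval [s, e): 0 when inside or touching
point_interval_distance <- function(p, s, e) pmax(0, s - p, p - e)

#' Per-gene TSS mark presence
#'
#' A gene carries a mark when some peak lies within \code{window} bp of its
#' TSS point on either side (distance 0 when the TSS is inside a peak).
#'
#' @param peaks a \code{peak_set}.
#' @param annotation a \code{genome_annotation}.
#' @param window maximum TSS-to-peak distance in bp (default 500).
#' @return list with \code{marked} (named logical per gene),
#'   \code{distance} (bp to nearest peak, Inf if none on the scaffold) and
#'   \code{fraction} marked.
#' @export
tss_presence <- function(peaks, annotation, window = 500) {
  g <- annotation$genes
  marked <- stats::setNames(rep(FALSE, nrow(g)), g$gene_id)
  dist <- stats::setNames(rep(Inf, nrow(g)), g$gene_id)
  for (sn in unique(g$scaffold)) {
    p <- peaks[peaks$scaffold == sn, , drop = FALSE]
    gi <- which(g$scaffold == sn)
    if (nrow(p) == 0) next
    for (i in gi) {
      d <- min(point_interval_distance(g$tss[i], p$start, p$end))
      dist[g$gene_id[i]] <- d
      marked[g$gene_id[i]] <- d <= window
    }
  }
  list(marked = marked, distance = dist,
       fraction = if (nrow(g) == 0) NA_real_ else mean(marked))
}

#' Distribution of peak base pairs over feature classes
#'
#' Peak bp are apportioned to the classes of \code{\link{build_feature_partition}}
#' by exact base-pair intersection; the three non-genic classes are split
#' into te / no_te sectors.
#'
#' @param peaks a \code{peak_set}.
#' @param map a \code{feature_class_map}.
#' @return data.frame \code{class}, \code{bp}, \code{proportion}
#'   (proportions sum to 1 when at least one peak exists).
#' @export
peak_class_distribution <- function(peaks, map) {
  labels <- split_class_labels(map$classes)
  bp <- stats::setNames(numeric(length(labels)), labels)
  for (i in seq_len(nrow(peaks))) {
    sn <- peaks$scaffold[i]
    idx <- (peaks$start[i] + 1):min(peaks$end[i], length(map$codes[[sn]]))
    lab <- map$classes[map$codes[[sn]][idx]]
    el <- lab %in% TE_ELIGIBLE
    lab[el] <- paste0(lab[el], ifelse(map$te[[sn]][idx][el], "_te", "_no_te"))
    tb <- table(lab)
    bp[names(tb)] <- bp[names(tb)] + as.numeric(tb)
  }
  tot <- sum(bp)
  data.frame(class = names(bp), bp = as.numeric(bp),
             proportion = if (tot > 0) as.numeric(bp) / tot else
               rep(NA_real_, length(bp)))
}

iranges_of <- function(df, sn) {
  d <- df[df$scaffold == sn, , drop = FALSE]
  IRanges::IRanges(start = d$start + 1, end = d$end)
}

# total bp of pairwise intersection / union across scaffolds
jaccard_bp <- function(a, b) {
  sns <- union(unique(a$scaffold), unique(b$scaffold))
  inter <- 0; uni <- 0
  for (sn in sns) {
    ia <- IRanges::reduce(iranges_of(a, sn))
    ib <- IRanges::reduce(iranges_of(b, sn))
    inter <- inter + sum(IRanges::width(IRanges::intersect(ia, ib)))
    uni <- uni + sum(IRanges::width(IRanges::union(ia, ib)))
  }
  if (uni == 0) NA_real_ else inter / uni
}

#' Mark co-localisation matrices
#'
#' Track mode: Pearson correlation of per-bin normalized values for every
#' mark pair (constant tracks give NA, flagged rather than zero). Peak mode:
#' base-pair Jaccard overlap of peak sets.
#'
#' @param tracks named list of \code{signal_track}s sharing a bin grid, or
#'   NULL.
#' @param peaksets named list of \code{peak_set}s, or NULL.
#' @return list with matrices \code{pearson} and/or \code{jaccard}
#'   (symmetric, unit diagonal).
#' @export
colocalization_matrix <- function(tracks = NULL, peaksets = NULL) {
  out <- list()
  if (!is.null(tracks)) {
    stopifnot(length(tracks) >= 2)
    vals <- lapply(tracks, function(t) unlist(normalized_bins(t)))
    m <- matrix(NA_real_, length(vals), length(vals),
                dimnames = list(names(tracks), names(tracks)))
    for (i in seq_along(vals)) for (j in seq_along(vals)) {
      if (stats::sd(vals[[i]]) == 0 || stats::sd(vals[[j]]) == 0) {
        m[i, j] <- if (i == j) 1 else NA_real_
      } else m[i, j] <- stats::cor(vals[[i]], vals[[j]])
    }
    out$pearson <- m
  }
  if (!is.null(peaksets)) {
    stopifnot(length(peaksets) >= 2)
    m <- matrix(NA_real_, length(peaksets), length(peaksets),
                dimnames = list(names(peaksets), names(peaksets)))
    for (i in seq_along(peaksets)) for (j in seq_along(peaksets))
      m[i, j] <- if (i == j) 1 else jaccard_bp(peaksets[[i]], peaksets[[j]])
    out$jaccard <- m
  }
  out
}

overlaps_any <- function(query, subject) {
  hit <- rep(FALSE, nrow(query))
  for (sn in unique(query$scaffold)) {
    qi <- which(query$scaffold == sn)
    s <- iranges_of(subject, sn)
    if (length(s) == 0) next
    q <- IRanges::IRanges(query$start[qi] + 1, query$end[qi])
    hit[qi] <- IRanges::countOverlaps(q, s) > 0
  }
  hit
}

#' Test peak association with transposon-containing regions
#'
#' Builds the 2x2 table (region contains >= 1 peak) x (region contains a TE)
#' over the union of the two region sets and applies the Yates-corrected
#' chi-squared test. Optionally reports the fraction of peaks co-localising
#' (>= 1 bp) with a TE/repeat interval.
#'
#' @param peaks a \code{peak_set}.
#' @param regions_with_te,regions_without_te disjoint interval data.frames
#'   (e.g. introns or intergenics split by TE content).
#' @param tes optional TE/repeat intervals for the co-localised fraction.
#' @return list with \code{test} (a \code{test_result}), \code{table}, and
#'   \code{colocalized_fraction} (NA when \code{tes} is NULL).
#' @export
te_association_test <- function(peaks, regions_with_te, regions_without_te,
                                tes = NULL) {
  stopifnot(nrow(regions_with_te) > 0, nrow(regions_without_te) > 0)
  occ_te <- overlaps_any(regions_with_te, peaks)
  occ_no <- overlaps_any(regions_without_te, peaks)
  tb <- rbind(te = c(peak = sum(occ_te), no_peak = sum(!occ_te)),
              no_te = c(peak = sum(occ_no), no_peak = sum(!occ_no)))
  coloc <- NA_real_
  if (!is.null(tes) && nrow(peaks) > 0)
    coloc <- mean(overlaps_any(as.data.frame(peaks), tes))
  list(test = stat_test("chi2_yates", table = tb), table = tb,
       colocalized_fraction = coloc)
}

#' Metagene profile matrix
#'
#' Per-gene signal with fixed-bp flanks at native resolution and the gene
#' body rescaled to a fixed number of fractional-length bins (length-weighted
#' means), strand-flipped so 5' is always on the left. Flank columns falling
#' off a scaffold are NA.
#'
#' @param track a \code{signal_track}.
#' @param annotation a \code{genome_annotation}.
#' @param flank_bp flank extent in bp (default 2000).
#' @param n_body_bins number of scaled gene-body columns (default 100).
#' @return list with \code{matrix} (genes x columns), \code{profile}
#'   (column means over genes) and \code{columns} (labels). Column count is
#'   2 * flank_bp / bin_size + n_body_bins.
#' @export
metaprofile <- function(track, annotation, flank_bp = 2000,
                        n_body_bins = 100) {
  g <- annotation$genes
  stopifnot(nrow(g) > 0)
  bs <- track$bin_size
  nf <- floor(flank_bp / bs)
  nb <- normalized_bins(track)
  ncol_total <- 2 * nf + n_body_bins
  m <- matrix(NA_real_, nrow(g), ncol_total)
  rownames(m) <- g$gene_id
  for (i in seq_len(nrow(g))) {
    sn <- g$scaffold[i]; L <- track$scaffold_lengths[[sn]]
    v <- nb[[sn]]
    body_edges <- seq(g$start[i], g$end[i], length.out = n_body_bins + 1)
    body <- vapply(seq_len(n_body_bins), function(k)
      window_mean(v, bs, body_edges[k], body_edges[k + 1], L), 0)
    up <- vapply(seq_len(nf), function(k)
      window_mean(v, bs, g$start[i] - (nf - k + 1) * bs,
                  g$start[i] - (nf - k) * bs, L), 0)
    dn <- vapply(seq_len(nf), function(k)
      window_mean(v, bs, g$end[i] + (k - 1) * bs, g$end[i] + k * bs, L), 0)
    row <- c(up, body, dn)
    if (g$strand[i] == "-") row <- rev(row)
    m[i, ] <- row
  }
  cols <- c(sprintf("up_%d", seq_len(nf)), sprintf("body_%d", seq_len(n_body_bins)),
            sprintf("down_%d", seq_len(nf)))
  list(matrix = m, profile = colMeans(m, na.rm = TRUE), columns = cols,
       n_flank_bins = nf, n_body_bins = n_body_bins)
}

#' Metagene profiles by expression decile
#'
#' Genes are ranked by TPM (ties broken by gene id) and split into 10
#' equal-size groups; one mean profile is returned per decile (decile 1 =
#' lowest expression).
#'
#' @param track a \code{signal_track}.
#' @param annotation a \code{genome_annotation}.
#' @param tpm named per-gene TPM vector covering all genes.
#' @param ... passed to \code{\link{metaprofile}}.
#' @return list with \code{profiles} (10 x columns matrix), \code{decile}
#'   (named per-gene assignment) and the metaprofile metadata.
#' @export
decile_profiles <- function(track, annotation, tpm, ...) {
  g <- annotation$genes
  if (nrow(g) < 10) stop("need >= 10 genes for decile profiles")
  stopifnot(all(g$gene_id %in% names(tpm)))
  mp <- metaprofile(track, annotation, ...)
  ord <- order(tpm[g$gene_id], g$gene_id)
  dec <- integer(nrow(g))
  dec[ord] <- ceiling(seq_along(ord) / (length(ord) / 10))
  dec <- pmin(dec, 10L)
  names(dec) <- g$gene_id
  profs <- t(vapply(1:10, function(d)
    colMeans(mp$matrix[dec[rownames(mp$matrix)] == d, , drop = FALSE],
             na.rm = TRUE), numeric(ncol(mp$matrix))))
  rownames(profs) <- paste0("decile_", 1:10)
  list(profiles = profs, decile = dec, columns = mp$columns,
       n_flank_bins = mp$n_flank_bins, n_body_bins = mp$n_body_bins)
}
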