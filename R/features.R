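FEATURE_CLASSES <- c("intergenic", "intron", "first_intron", "exon",
                     "first_exon", "upstream_tss_500")
TE_ELIGIBLE <- c("intergenic", "intron", "first_intron")

#' Partition the genome into feature classes
#'
#' Every base pair of every scaffold receives exactly one of six classes:
#' \code{upstream_tss_500} (the window 5' of a TSS, default 500 bp),
#' \code{first_exon}, \code{exon} (all other exon sequence),
#' \code{first_intron}, \code{intron} (all other intron sequence) and
#' \code{intergenic}. Where overlapping or nested genes make classes collide
#' the priority is upstream > first_exon > exon > first_intron > intron >
#' intergenic; the upstream window never extends into a neighbouring gene
#' body (it is truncated there, and at scaffold edges). For the three
#' non-genic classes a transposon overlay subdivides each class into
#' \code{te} / \code{no_te} sectors by base-pair intersection with the
#' annotation's TE intervals.
#'
#' @param annotation a \code{\link{genome_annotation}}.
#' @param tss_window upstream window size in bp (default 500).
#' @return A \code{feature_class_map}: per-scaffold per-bp class codes plus a
#'   TE mask. Use \code{\link{class_composition}} for bp totals and
#'   \code{\link{map_to_intervals}} for an interval view.
#' @export
build_feature_partition <- function(annotation, tss_window = 500) {
  slen <- scaffold_lengths(annotation)
  codes <- lapply(slen, function(L) rep.int(1L, L))  # 1 = intergenic
  temask <- lapply(slen, function(L) rep.int(FALSE, L))
  g <- annotation$genes

  paint <- function(codes, sn, start, end, code) {
    start <- max(0, start); end <- min(end, length(codes[[sn]]))
    if (end > start) codes[[sn]][(start + 1):end] <- code
    codes
  }

  if (nrow(g) > 0) {
    ex_by_gene <- split(annotation$exons, annotation$exons$gene_id)
    # collect per-class interval lists, then paint in priority order
    layers <- list(intron = list(), first_intron = list(), exon = list(),
                   first_exon = list())
    for (i in seq_len(nrow(g))) {
      gid <- g$gene_id[i]; sn <- g$scaffold[i]
      ex <- ex_by_gene[[gid]]
      ex <- ex[order(ex$start), , drop = FALSE]
      k <- nrow(ex)
      fe_idx <- if (g$strand[i] == "+") 1L else k  # 5'-most exon
      for (j in seq_len(k)) {
        cls <- if (j == fe_idx) "first_exon" else "exon"
        layers[[cls]][[length(layers[[cls]]) + 1]] <-
          c(sn = sn, s = ex$start[j], e = ex$end[j])
      }
      if (k > 1) {
        fi_idx <- if (g$strand[i] == "+") 1L else (k - 1L)  # 5'-most intron
        for (j in seq_len(k - 1)) {
          cls <- if (j == fi_idx) "first_intron" else "intron"
          layers[[cls]][[length(layers[[cls]]) + 1]] <-
            c(sn = sn, s = ex$end[j], e = ex$start[j + 1])
        }
      }
    }
    code_of <- stats::setNames(seq_along(FEATURE_CLASSES), FEATURE_CLASSES)
    for (cls in c("intron", "first_intron", "exon", "first_exon")) {
      for (iv in layers[[cls]])
        codes <- paint(codes, iv[["sn"]], as.numeric(iv[["s"]]),
                       as.numeric(iv[["e"]]), code_of[[cls]])
    }
    # upstream windows last, but only over bp outside every gene body
    in_gene <- lapply(slen, function(L) rep.int(FALSE, L))
    for (i in seq_len(nrow(g))) {
      sn <- g$scaffold[i]
      in_gene[[sn]][(g$start[i] + 1):g$end[i]] <- TRUE
    }
    for (i in seq_len(nrow(g))) {
      sn <- g$scaffold[i]
      win <- if (g$strand[i] == "+") c(g$tss[i] - tss_window, g$tss[i])
             else c(g$tss[i], g$tss[i] + tss_window)
      s <- max(0, win[1]); e <- min(win[2], slen[[sn]])
      if (e > s) {
        idx <- (s + 1):e
        idx <- idx[!in_gene[[sn]][idx]]
        codes[[sn]][idx] <- code_of[["upstream_tss_500"]]
      }
    }
  }

  te <- annotation$tes
  if (nrow(te) > 0) {
    for (i in seq_len(nrow(te))) {
      sn <- te$scaffold[i]
      s <- max(0, te$start[i]); e <- min(te$end[i], slen[[sn]])
      if (e > s) temask[[sn]][(s + 1):e] <- TRUE
    }
  }

  structure(list(codes = codes, te = temask, classes = FEATURE_CLASSES,
                 tss_window = tss_window),
            class = "feature_class_map")
}

#' Base-pair composition of a feature-class map
#'
#' @param map a \code{feature_class_map}.
#' @return data.frame with columns \code{class} (TE-eligible classes appear
#'   as \code{<class>_te} / \code{<class>_no_te}), \code{bp} and
#'   \code{fraction}; fractions sum to 1.
#' @export
class_composition <- function(map) {
  labels <- split_class_labels(map$classes)
  bp <- stats::setNames(numeric(length(labels)), labels)
  for (sn in names(map$codes)) {
    code <- map$codes[[sn]]
    te <- map$te[[sn]]
    for (ci in seq_along(map$classes)) {
      cls <- map$classes[ci]
      sel <- code == ci
      if (cls %in% TE_ELIGIBLE) {
        bp[paste0(cls, "_te")] <- bp[paste0(cls, "_te")] + sum(sel & te)
        bp[paste0(cls, "_no_te")] <- bp[paste0(cls, "_no_te")] + sum(sel & !te)
      } else {
        bp[cls] <- bp[cls] + sum(sel)
      }
    }
  }
  data.frame(class = names(bp), bp = as.numeric(bp),
             fraction = as.numeric(bp) / sum(bp))
}

split_class_labels <- function(classes) {
  unlist(lapply(classes, function(cls)
    if (cls %in% TE_ELIGIBLE) paste0(cls, c("_te", "_no_te")) else cls))
}

#' Interval view of a feature-class map
#'
#' @param map a \code{feature_class_map}.
#' @param split_te subdivide TE-eligible classes by the TE mask.
#' @return data.frame \code{scaffold}, \code{start}, \code{end}, \code{class}.
#' @export
map_to_intervals <- function(map, split_te = TRUE) {
  out <- list()
  for (sn in names(map$codes)) {
    lab <- map$classes[map$codes[[sn]]]
    if (split_te) {
      el <- lab %in% TE_ELIGIBLE
      lab[el] <- paste0(lab[el], ifelse(map$te[[sn]][el], "_te", "_no_te"))
    }
    r <- rle(lab)
    e <- cumsum(r$lengths)
    out[[sn]] <- data.frame(scaffold = sn, start = c(0, e[-length(e)]),
                            end = e, class = r$values)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify adjacent gene pairs by orientation
#'
#' For every couple of genes adjacent on a scaffold (sorted by start, no gene
#' between them) the pair is \code{divergent} when the left gene is on
#' \code{-} and the right on \code{+} (transcription pointing away from the
#' shared intergenic), \code{tandem} when both share a strand, and
#' \code{convergent} when left is \code{+} and right \code{-}. The intergenic
#' interval is the gap between gene bodies; pairs whose bodies overlap get
#' length 0 and \code{overlapping = TRUE}.
#'
#' @param annotation a \code{genome_annotation}.
#' @return data.frame with one row per adjacent pair: \code{scaffold},
#'   \code{left_gene}, \code{right_gene}, \code{orientation}, \code{start},
#'   \code{end}, \code{length}, \code{overlapping}.
#' @export
classify_adjacent_pairs <- function(annotation) {
  g <- annotation$genes
  out <- list()
  for (sn in unique(g$scaffold)) {
    gs <- g[g$scaffold == sn, , drop = FALSE]
    if (nrow(gs) < 2) next
    i <- seq_len(nrow(gs) - 1)
    ls <- gs$strand[i]; rs <- gs$strand[i + 1]
    orientation <- ifelse(ls == rs, "tandem",
                          ifelse(ls == "-", "divergent", "convergent"))
    s <- gs$end[i]; e <- gs$start[i + 1]
    out[[sn]] <- data.frame(
      scaffold = sn, left_gene = gs$gene_id[i], right_gene = gs$gene_id[i + 1],
      orientation = orientation, start = pmin(s, e), end = pmax(s, e),
      length = pmax(0, e - s), overlapping = e < s)
  }
  if (length(out) == 0)
    return(data.frame(scaffold = character(), left_gene = character(),
                      right_gene = character(), orientation = character(),
                      start = numeric(), end = numeric(), length = numeric(),
                      overlapping = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intergenic length statistics by pair orientation
#'
#' Reports the median intergenic length per orientation class and a two-sided
#' Wilcoxon rank-sum test of divergent vs tandem lengths.
#'
#' @param pairs output of \code{\link{classify_adjacent_pairs}}.
#' @return list with \code{medians} (named vector), \code{n} (named counts)
#'   and \code{test} (a \code{test_result}, or NULL with a warning when a
#'   class is empty).
#' @export
pair_length_stats <- function(pairs) {
  lens <- split(pairs$length, pairs$orientation)
  medians <- vapply(lens, stats::median, 0)
  n <- lengths(lens)
  d <- pairs$length[pairs$orientation == "divergent"]
  t <- pairs$length[pairs$orientation == "tandem"]
  test <- NULL
  if (length(d) >= 1 && length(t) >= 1) {
    test <- stat_test("wilcoxon", d, t)
  } else {
    warning("empty orientation class; divergent-vs-tandem test skipped")
  }
  list(medians = medians, n = n, test = test)
}

#' Fraction of TSS-adjacent-flanking genes in divergent pairs
#'
#' TSS-adjacent intergenic regions are those of divergent and tandem pairs
#' (a convergent gap touches two TESs and no TSS). Among the genes flanking
#' such regions, this returns the fraction that belong to at least one
#' divergent pair.
#'
#' @param pairs output of \code{\link{classify_adjacent_pairs}}.
#' @return list with \code{n_tss_adjacent} (count of divergent + tandem
#'   intergenics) and \code{divergent_flanking_fraction}.
#' @export
divergent_flanking_fraction <- function(pairs) {
  ta <- pairs[pairs$orientation %in% c("divergent", "tandem"), , drop = FALSE]
  flanking <- unique(c(ta$left_gene, ta$right_gene))
  dv <- pairs[pairs$orientation == "divergent", , drop = FALSE]
  in_div <- unique(c(dv$left_gene, dv$right_gene))
  list(n_tss_adjacent = nrow(ta),
       divergent_flanking_fraction =
         if (length(flanking) == 0) NA_real_
         else mean(flanking %in% in_div))
}
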