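#' Genome annotation container
#'
#' Bundles scaffolds, genes (with exon structure and strand-aware TSS/TES
#' points), and transposable-element (TE) intervals into a single validated
#' object. All coordinates are internal convention: 0-based, half-open
#' \code{[start, end)}. TSS and TES are strand-aware points: for a gene on
#' \code{+}, TSS = \code{start} and TES = \code{end}; on \code{-}, TSS =
#' \code{end} and TES = \code{start}.
#'
#' @param scaffolds data.frame with columns \code{name}, \code{length}.
#' @param genes data.frame with columns \code{gene_id}, \code{scaffold},
#'   \code{start}, \code{end}, \code{strand} (\code{"+"} or \code{"-"}) and
#'   \code{biotype} (\code{"protein_coding"} or \code{"lncRNA"}).
#' @param exons data.frame with columns \code{gene_id}, \code{scaffold},
#'   \code{start}, \code{end}; one row per exon.
#' @param tes data.frame of TE intervals with columns \code{scaffold},
#'   \code{start}, \code{end}; may be empty.
#' @return An object of class \code{genome_annotation}: a list with elements
#'   \code{scaffolds}, \code{genes} (gains \code{tss}/\code{tes} point
#'   columns, sorted by scaffold then start), \code{exons}, \code{tes}.
#' @export
genome_annotation <- function(scaffolds, genes, exons = NULL, tes = NULL) {
  scaffolds <- as.data.frame(scaffolds)
  stopifnot(all(c("name", "length") %in% names(scaffolds)))
  if (anyDuplicated(scaffolds$name)) stop("duplicate scaffold names")
  if (any(scaffolds$length <= 0)) stop("scaffold lengths must be positive")

  genes <- as.data.frame(genes)
  if (nrow(genes) > 0) {
    need <- c("gene_id", "scaffold", "start", "end", "strand")
    stopifnot(all(need %in% names(genes)))
    if (!"biotype" %in% names(genes)) genes$biotype <- "protein_coding"
    bad <- setdiff(unique(genes$scaffold), scaffolds$name)
    if (length(bad) > 0)
      stop("gene scaffold not declared: ", paste(bad, collapse = ", "))
    if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
    if (any(genes$start < 0) || any(genes$start >= genes$end))
      stop("invalid gene interval (need 0 <= start < end)")
    slen <- stats::setNames(scaffolds$length, scaffolds$name)
    if (any(genes$end > slen[genes$scaffold]))
      stop("gene extends beyond scaffold end: ",
           genes$gene_id[which(genes$end > slen[genes$scaffold])[1]])
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
    genes <- genes[order(genes$scaffold, genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(gene_id = character(), scaffold = character(),
                        start = integer(), end = integer(),
                        strand = character(), biotype = character(),
                        tss = integer(), tes = integer())
  }

  if (is.null(exons) || nrow(as.data.frame(exons)) == 0) {
    # default: single-exon genes spanning the full body
    exons <- genes[, c("gene_id", "scaffold", "start", "end")]
  } else {
    exons <- as.data.frame(exons)
    stopifnot(all(c("gene_id", "scaffold", "start", "end") %in% names(exons)))
    gs <- stats::setNames(genes$start, genes$gene_id)
    ge <- stats::setNames(genes$end, genes$gene_id)
    unk <- setdiff(unique(exons$gene_id), genes$gene_id)
    if (length(unk) > 0) stop("exon references unknown gene: ", unk[1])
    out <- exons$start < gs[exons$gene_id] | exons$end > ge[exons$gene_id]
    if (any(out))
      stop("exon outside gene span for gene ", exons$gene_id[which(out)[1]])
    exons <- exons[order(exons$scaffold, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
  }

  if (is.null(tes)) {
    tes <- data.frame(scaffold = character(), start = integer(), end = integer())
  } else {
    tes <- as.data.frame(tes)
    if (nrow(tes) > 0) {
      stopifnot(all(c("scaffold", "start", "end") %in% names(tes)))
      tes <- tes[order(tes$scaffold, tes$start), , drop = FALSE]
      rownames(tes) <- NULL
    }
  }

  structure(list(scaffolds = scaffolds, genes = genes,
                 exons = exons, tes = tes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %d scaffold(s), %.3g Mb, %d gene(s) (%d lncRNA), %d TE interval(s)\n",
    nrow(x$scaffolds), sum(x$scaffolds$length) / 1e6, nrow(x$genes),
    sum(x$genes$biotype == "lncRNA"), nrow(x$tes)))
  invisible(x)
}

#' Total genome length of an annotation
#' @param annotation a \code{genome_annotation}.
#' @return total length in bp.
#' @export
genome_length <- function(annotation) sum(annotation$scaffolds$length)

#' Named vector of scaffold lengths
#' @param annotation a \code{genome_annotation}.
#' @return named integer vector, names are scaffold names.
#' @export
scaffold_lengths <- function(annotation)
  stats::setNames(annotation$scaffolds$length, annotation$scaffolds$name)

# exons of one gene ordered 5'->3' (i.e. reversed for minus-strand genes)
gene_exons_5p3p <- function(annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(g) == 1 && g$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}
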