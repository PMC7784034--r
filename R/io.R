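#' Read a genome annotation from GFF3
#'
#' Parses gene / mRNA / exon features. GFF3 1-based closed coordinates are
#' converted to the internal 0-based half-open convention at this boundary.
#' Scaffold lengths are taken from \code{##sequence-region} pragmas, which are
#' required: a feature on an undeclared scaffold is an error.
#'
#' @param path GFF3 file.
#' @return A \code{\link{genome_annotation}} (without TE intervals; see
#'   \code{\link{read_bed}} for those).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path)
  sr <- grep("^##sequence-region", lines, value = TRUE)
  scaffolds <- data.frame(name = character(), length = numeric())
  if (length(sr) > 0) {
    parts <- strsplit(trimws(sr), "[ \t]+")
    scaffolds <- data.frame(
      name = vapply(parts, `[`, "", 2),
      length = as.numeric(vapply(parts, `[`, "", 4)))
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0)
    return(genome_annotation(scaffolds, genes = data.frame()))
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 9)) stop("malformed GFF3 record (expected 9 columns)")
  f <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  names(f) <- c("scaffold", "source", "type", "start", "end",
                "score", "strand", "phase", "attr")
  f$start <- as.numeric(f$start) - 1  # to 0-based half-open
  f$end <- as.numeric(f$end)

  bad <- setdiff(unique(f$scaffold), scaffolds$name)
  if (length(bad) > 0)
    stop("feature on undeclared scaffold: ", paste(bad, collapse = ", "))

  attr_get <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }

  gf <- f[f$type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene_id = attr_get(gf$attr, "ID"), scaffold = gf$scaffold,
    start = gf$start, end = gf$end, strand = gf$strand,
    biotype = attr_get(gf$attr, "biotype"))
  genes$biotype[is.na(genes$biotype)] <- "protein_coding"

  # exon Parent may point at an mRNA; resolve through the mRNA -> gene map
  mf <- f[f$type == "mRNA", , drop = FALSE]
  m2g <- stats::setNames(attr_get(mf$attr, "Parent"), attr_get(mf$attr, "ID"))
  ef <- f[f$type == "exon", , drop = FALSE]
  if (nrow(ef) > 0) {
    par <- attr_get(ef$attr, "Parent")
    via <- par %in% names(m2g)
    par[via] <- m2g[par[via]]
    exons <- data.frame(gene_id = par, scaffold = ef$scaffold,
                        start = ef$start, end = ef$end)
  } else exons <- NULL

  genome_annotation(scaffolds, genes, exons)
}

#' Write a genome annotation as GFF3
#'
#' Inverse of \code{\link{read_annotation}}: internal 0-based half-open
#' coordinates go back to 1-based closed. Output ordering is deterministic
#' (scaffold, start), so identical annotations give byte-identical files.
#'
#' @param annotation a \code{genome_annotation}.
#' @param path output file.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  sc <- annotation$scaffolds
  writeLines(sprintf("##sequence-region %s 1 %d", sc$name,
                     as.integer(sc$length)), con)
  g <- annotation$genes
  if (nrow(g) == 0) return(invisible(path))
  ex <- annotation$exons
  out <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    out <- c(out, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                          g$scaffold[i], as.integer(g$start[i]) + 1L,
                          as.integer(g$end[i]), g$strand[i], gid, g$biotype[i]),
             sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                     g$scaffold[i], as.integer(g$start[i]) + 1L,
                     as.integer(g$end[i]), g$strand[i], gid, gid))
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 0)
      out <- c(out, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s.t1",
                            e$scaffold, as.integer(e$start) + 1L,
                            as.integer(e$end), g$strand[i], gid))
  }
  writeLines(out, con)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' Columns beyond the first three (name, score, strand) are kept when present.
#'
#' @param path BED file.
#' @return data.frame with columns \code{scaffold}, \code{start}, \code{end}
#'   and optionally \code{name}, \code{score}, \code{strand}.
#' @export
read_bed <- function(path) {
  empty <- data.frame(scaffold = character(), start = integer(),
                      end = integer())
  if (file.size(path) == 0) return(empty)
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(x) == 0) return(empty)
  cn <- c("scaffold", "start", "end", "name", "score", "strand")
  names(x) <- cn[seq_len(min(ncol(x), 6))]
  x
}

#' Write scored intervals as BED or ENCODE broadPeak
#'
#' Scores are rescaled to the 0--1000 integer range of the BED score column.
#' Rows are emitted in deterministic (scaffold, start, end) order.
#'
#' @param items data.frame with \code{scaffold}, \code{start}, \code{end} and
#'   optional \code{name}, \code{score} columns (peak/domain sets qualify).
#' @param path output file.
#' @param dialect \code{"bed"} or \code{"broadPeak"}.
#' @export
write_intervals <- function(items, path, dialect = c("bed", "broadPeak")) {
  dialect <- match.arg(dialect)
  items <- as.data.frame(items)
  if (nrow(items) == 0) {
    file.create(path)
    return(invisible(path))
  }
  items <- items[order(items$scaffold, items$start, items$end), , drop = FALSE]
  nm <- if ("name" %in% names(items)) items$name else
    sprintf("region_%d", seq_len(nrow(items)))
  sc <- if ("score" %in% names(items)) items$score else 0
  smax <- max(sc, 1e-9)
  bed_score <- as.integer(round(1000 * sc / smax))
  lines <- if (dialect == "bed") {
    sprintf("%s\t%d\t%d\t%s\t%d", items$scaffold, as.integer(items$start),
            as.integer(items$end), nm, bed_score)
  } else {
    sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.4f\t-1\t%.4f", items$scaffold,
            as.integer(items$start), as.integer(items$end), nm, bed_score,
            sc, sc)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a binned signal track
#'
#' Values are rebinned to \code{bin_size} by length-weighted mean; base pairs
#' not covered by any record count as zero. Records must be sorted and
#' non-overlapping. Mass (value x covered length) is conserved.
#'
#' @param path bedGraph file (4 columns, no track line).
#' @param bin_size bin width in bp.
#' @param scaffolds named vector of scaffold lengths, or a
#'   \code{genome_annotation}.
#' @param mark,generation,replicate track labels stored on the object.
#' @return a \code{\link{signal_track}}.
#' @export
read_track <- function(path, bin_size, scaffolds, mark = NA_character_,
                       generation = NA_character_, replicate = 1L) {
  if (inherits(scaffolds, "genome_annotation"))
    scaffolds <- scaffold_lengths(scaffolds)
  recs <- if (file.size(path) == 0) {
    data.frame(scaffold = character(), start = numeric(),
               end = numeric(), value = numeric())
  } else {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("scaffold", "start", "end", "value"))
    x
  }
  bad <- setdiff(unique(recs$scaffold), names(scaffolds))
  if (length(bad) > 0)
    stop("bedGraph record on unknown scaffold: ", paste(bad, collapse = ", "))
  bins <- lapply(names(scaffolds), function(sn) {
    L <- scaffolds[[sn]]
    n <- ceiling(L / bin_size)
    mass <- numeric(n)
    r <- recs[recs$scaffold == sn, , drop = FALSE]
    if (nrow(r) > 0) {
      r <- r[order(r$start), , drop = FALSE]
      if (any(r$start[-1] < r$end[-nrow(r)]))
        stop("overlapping bedGraph records on ", sn)
      if (any(r$end > L)) stop("record beyond scaffold end on ", sn)
      for (i in seq_len(nrow(r))) {
        s <- r$start[i]; e <- r$end[i]; v <- r$value[i]
        i0 <- floor(s / bin_size) + 1
        i1 <- ceiling(e / bin_size)
        if (i0 == i1) {
          mass[i0] <- mass[i0] + v * (e - s)
        } else {
          ov <- rep(bin_size, i1 - i0 + 1)
          ov[1] <- i0 * bin_size - s
          ov[length(ov)] <- e - (i1 - 1) * bin_size
          mass[i0:i1] <- mass[i0:i1] + v * ov
        }
      }
    }
    w <- rep(bin_size, n)
    w[n] <- L - (n - 1) * bin_size
    mass / w
  })
  names(bins) <- names(scaffolds)
  signal_track(bins, bin_size, scaffolds, mark = mark,
               generation = generation, replicate = replicate)
}

#' Write a signal track as bedGraph
#'
#' Adjacent bins with equal value are merged into one record; zero-valued
#' runs are written too, so a read/write cycle is lossless. Values are
#' formatted with up to six significant digits.
#'
#' @param track a \code{signal_track}.
#' @param path output file.
#' @export
write_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sn in names(track$bins)) {
    v <- track$bins[[sn]]
    if (length(v) == 0) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts <- c(0, ends_bin[-length(ends_bin)]) * track$bin_size
    ends <- pmin(ends_bin * track$bin_size, track$scaffold_lengths[[sn]])
    writeLines(sprintf("%s\t%d\t%d\t%s", sn, as.integer(starts),
                       as.integer(ends), formatC(r$values, format = "g",
                                                 digits = 6)), con)
  }
  invisible(path)
}

#' Load expression and differential-expression tables
#'
#' Joins a per-sample expression matrix (TPM) and an optional DE table on
#' gene id, keeping only genes present in the annotation. Genes in the tables
#' but absent from the annotation are dropped with a counted warning.
#'
#' @param expression_path TSV with column \code{gene_id} plus one numeric
#'   column per sample.
#' @param annotation a \code{genome_annotation}.
#' @param de_path optional TSV with columns \code{gene_id}, \code{log2fc},
#'   \code{pvalue}, \code{padj}.
#' @return An \code{expression_table}: list with \code{tpm} (gene x sample
#'   matrix), \code{de} (data.frame or NULL), \code{dropped} (count).
#' @export
load_tables <- function(expression_path, annotation, de_path = NULL) {
  ex <- utils::read.table(expression_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = ".")
  if (!"gene_id" %in% names(ex)) stop("expression table needs gene_id column")
  if (anyDuplicated(ex$gene_id)) stop("duplicate gene ids in expression table")
  num <- ex[setdiff(names(ex), "gene_id")]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]))
    if (length(bad) > 0)
      stop("non-numeric expression value at row ", bad[1])
    num[[j]] <- v
  }
  keep <- ex$gene_id %in% annotation$genes$gene_id
  dropped <- sum(!keep)
  if (dropped > 0)
    warning(dropped, " gene id(s) in expression table absent from annotation")
  tpm <- as.matrix(num[keep, , drop = FALSE])
  rownames(tpm) <- ex$gene_id[keep]

  de <- NULL
  if (!is.null(de_path)) {
    de <- utils::read.table(de_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, na.strings = ".")
    if (nrow(de) > 0) {
      stopifnot(all(c("gene_id", "log2fc", "pvalue", "padj") %in% names(de)))
      if (anyDuplicated(de$gene_id)) stop("duplicate gene ids in DE table")
      de <- de[de$gene_id %in% annotation$genes$gene_id, , drop = FALSE]
    } else de <- NULL
  }
  structure(list(tpm = tpm, de = de, dropped = dropped),
            class = "expression_table")
}

#' Write an expression matrix as TSV
#' @param tpm gene x sample numeric matrix with rownames.
#' @param path output file.
#' @export
write_expression <- function(tpm, path) {
  df <- data.frame(gene_id = rownames(tpm), as.data.frame(tpm),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
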