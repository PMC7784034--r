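#' Binned coverage track
#'
#' Fixed-bin coverage for one mark x generation x replicate. Bin values are
#' raw (library-scale) counts or count means; \code{\link{normalized_bins}}
#' converts to counts-per-million for cross-track comparison. The final bin
#' of a scaffold may be narrower than \code{bin_size}.
#'
#' @param bins named list (one numeric vector per scaffold) of per-bin values.
#' @param bin_size bin width in bp.
#' @param scaffolds named vector of scaffold lengths.
#' @param mark,generation,replicate labels.
#' @return object of class \code{signal_track}.
#' @export
signal_track <- function(bins, bin_size, scaffolds, mark = NA_character_,
                         generation = NA_character_, replicate = 1L) {
  stopifnot(is.list(bins), !is.null(names(bins)))
  stopifnot(setequal(names(bins), names(scaffolds)))
  for (sn in names(bins)) {
    n_exp <- ceiling(scaffolds[[sn]] / bin_size)
    if (length(bins[[sn]]) != n_exp)
      stop("bin vector length mismatch on ", sn, ": got ",
           length(bins[[sn]]), ", expected ", n_exp)
    if (any(bins[[sn]] < 0)) stop("negative bin value on ", sn)
  }
  structure(list(bins = bins[names(scaffolds)], bin_size = bin_size,
                 scaffold_lengths = scaffolds, mark = mark,
                 generation = generation, replicate = replicate,
                 library_size = sum(vapply(bins, sum, 0))),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %s %s rep%s | %d scaffold(s), %d bp bins, library %.4g\n",
              x$mark, x$generation, paste(x$replicate, collapse = "+"),
              length(x$bins), x$bin_size, x$library_size))
  invisible(x)
}

#' Per-million normalized bin values
#'
#' @param track a \code{signal_track}.
#' @return named list of per-scaffold numeric vectors, scaled so the genome
#'   total is 1e6.
#' @export
normalized_bins <- function(track) {
  ls <- track$library_size
  if (ls == 0) return(track$bins)
  lapply(track$bins, function(v) v / ls * 1e6)
}

#' Pool replicate tracks
#'
#' Sums bin counts (and hence library sizes) across replicates of the same
#' mark and generation; pooling before peak calling is equivalent to merging
#' the underlying read sets.
#'
#' @param tracks list of \code{signal_track}s on a shared bin grid.
#' @return a pooled \code{signal_track}.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  t1 <- tracks[[1]]
  if (length(tracks) == 1) return(t1)
  bins <- t1$bins
  for (tr in tracks[-1]) {
    stopifnot(tr$bin_size == t1$bin_size)
    for (sn in names(bins)) bins[[sn]] <- bins[[sn]] + tr$bins[[sn]]
  }
  signal_track(bins, t1$bin_size, t1$scaffold_lengths, mark = t1$mark,
               generation = t1$generation,
               replicate = unlist(lapply(tracks, `[[`, "replicate")))
}

# mean of normalized signal over [start, end) on one scaffold,
# length-weighted across partially covered bins
window_mean <- function(values, bin_size, start, end, scaffold_length) {
  start <- max(0, start); end <- min(end, scaffold_length)
  if (end <= start) return(NA_real_)
  i0 <- floor(start / bin_size) + 1
  i1 <- ceiling(end / bin_size)
  idx <- i0:i1
  lo <- pmax((idx - 1) * bin_size, start)
  hi <- pmin(idx * bin_size, end)
  sum(values[idx] * (hi - lo)) / (end - start)
}

# centred running mean with shrinking windows at the edges
running_mean <- function(x, half_width) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half_width, 1)
  hi <- pmin(seq_len(n) + half_width, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
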