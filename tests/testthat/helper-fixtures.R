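# shared fixtures: tiny hand-built annotations plus one cached default
# synthetic dataset (simulated once per test run)

.fixture_env <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- simulate_dataset(seed = 1)
  .fixture_env$ds
}

# one scaffold of 10 kb with a single 2-exon plus-strand gene
# gene [1000, 2000), exons [1000,1300) and [1700,2000), intron [1300,1700)
tiny_annotation <- function(te = NULL) {
  genome_annotation(
    scaffolds = data.frame(name = "s1", length = 10000),
    genes = data.frame(gene_id = "g1", scaffold = "s1", start = 1000,
                       end = 2000, strand = "+", biotype = "protein_coding"),
    exons = data.frame(gene_id = c("g1", "g1"), scaffold = "s1",
                       start = c(1000, 1700), end = c(1300, 2000)),
    tes = te)
}

# three genes on one scaffold with configurable strands
three_gene_annotation <- function(strands = c("+", "+", "+")) {
  genome_annotation(
    scaffolds = data.frame(name = "s1", length = 20000),
    genes = data.frame(gene_id = c("a", "b", "c"), scaffold = "s1",
                       start = c(1000, 5000, 12000),
                       end = c(2000, 7000, 15000),
                       strand = strands,
                       biotype = "protein_coding"))
}

# flat track with optional planted bumps: value `background` everywhere,
# plus `heights[i]` over [starts[i], ends[i])
flat_track <- function(length = 100000, bin = 50, background = 5,
                       starts = numeric(0), ends = numeric(0),
                       heights = numeric(0), mark = "m", gen = "sporophyte") {
  n <- ceiling(length / bin)
  v <- rep(background, n)
  heights <- rep(heights, length.out = length(starts))
  for (i in seq_along(starts)) {
    i0 <- floor(starts[i] / bin) + 1
    i1 <- ceiling(ends[i] / bin)
    v[i0:i1] <- v[i0:i1] + heights[i]
  }
  signal_track(list(s1 = v), bin, c(s1 = length), mark = mark,
               generation = gen)
}

peak_df <- function(scaffold, start, end, score = 1) {
  p <- data.frame(scaffold = scaffold, start = start, end = end,
                  score = rep(score, length.out = length(start)),
                  summit = (start + end) / 2)
  class(p) <- c("peak_set", "data.frame")
  p
}

# exact two-sided rank-sum p by exhaustive enumeration of group assignments
exact_wilcoxon_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  r <- rank(all_v)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  stats_all <- apply(combs, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}
window_mean_for_test <- function(...) lifecyclechromatin:::window_mean(...)
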