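#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a desk-scale toy genome (2 scaffolds x 1 Mb, 1,000
#' genes, 50 bp bins) whose statistical structure mirrors the organism
#' studied: a strong excess of divergently transcribed neighbours
#' (target 0.617 of pair-flanking genes), log-normal intergenic lengths
#' with divergent medians far below tandem medians (409 vs 2293 bp),
#' transposons (>= 400 bp) placed in introns and intergenics, five
#' TSS-peaked marks (one double-peaked) whose amplitude couples
#' log-linearly to expression, a gene-body mark, a TE-associated mark, a
#' broad multi-gene domain mark with borders at gene starts/ends, MNase
#' dips at marked TSSs (one shared dip for divergent pairs closer than 600
#' bp), and ~4% generation-biased genes whose biased generation gains
#' TSS marks.
#'
#' @param ... named overrides of any default; nested lists are replaced
#'   wholesale.
#' @return a \code{synthetic_config} list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_scaffolds = 2,
    scaffold_length = 1e6,
    n_genes = 1000,
    bin_size = 50,
    divergent_fraction_target = 0.617,
    intergenic_length_model = list(
      divergent = c(median = 409, sigma = 0.5),
      tandem = c(median = 2293, sigma = 0.5),
      convergent = c(median = 800, sigma = 0.5)),
    exon_count_p = 0.5,                       # exons per gene = 1 + Geom(p)
    exon_length = c(median = 120, sigma = 0.4),
    intron_length = c(median = 150, sigma = 0.9),
    lncrna_fraction = 0.05,
    te_density_per_100kb = 5,
    te_weights = c(intergenic = 0.56, intron = 0.44),
    te_length = c(median = 800, sigma = 0.4),
    te_min_length = 400,
    mark_models = list(
      H3K4me2 = list(shape = "tss_double_peak", amplitude = 6, width = 150,
                     offset = 250, coupling = 0.3, presence_prob = 0.8),
      H3K4me3 = list(shape = "tss_peak", amplitude = 8, width = 200,
                     offset = 0, coupling = 0.3, presence_prob = 0.8),
      H3K9ac = list(shape = "tss_peak", amplitude = 8, width = 200,
                    offset = 0, coupling = 0.3, presence_prob = 0.8),
      H3K14ac = list(shape = "tss_peak", amplitude = 8, width = 200,
                     offset = 0, coupling = 0.3, presence_prob = 0.8),
      H3K27ac = list(shape = "tss_peak", amplitude = 8, width = 200,
                     offset = 0, coupling = 0.3, presence_prob = 0.8),
      H3K36me3 = list(shape = "gene_body", amplitude = 4, coupling = 0.3,
                      presence_prob = 0.8),
      H4K20me3 = list(shape = "te_peak", amplitude = 10,
                      presence_prob = 0.9),
      H3K79me2 = list(shape = "broad_domain", amplitude = 8)),
    domain_model = list(n_domains = 150, genes_per_domain_p = 0.4,
                        border_jitter_sd = 200,
                        fraction_borders_at_tss_tes = 1,
                        min_separation = 2000,
                        unique_fraction = 0.01),
    expression_model = list(abundance_meanlog = 3, abundance_sdlog = 1.2,
                            gbg_fraction = 0.04, sp_bias_fraction = 0.65,
                            log2fc_range = c(1.2, 4.2),
                            replicate_sd = 0.02,   # log2 scale
                            replicates = 2,
                            pair_correlation = 0.042,
                            gbg_lncrna_enrichment = 3),
    gbg_state_model = list(change_prob = 0.389,
                           state1_dest_prob = c(sporophyte = 0.748,
                                                gametophyte = 0.264),
                           unchanged_state1_prob = 0.814,
                           tss_mark_prob = 0.8),
    ndr_model = list(depth = 0.75, width = 150, shared_below = 600),
    mnase_level = 40,
    noise = list(reads_per_bin_mean = 5))
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "synthetic_config")
}

rlnorm_med <- function(n, model) {
  stats::rlnorm(n, meanlog = log(model[["median"]]), sdlog = model[["sigma"]])
}

#' Generate a synthetic genome annotation with TE intervals
#'
#' Gene strands follow a two-state chain whose flip probability equals the
#' divergent-fraction target, so the expected fraction of pair-member genes
#' in divergent pairs matches the target. Intergenic gaps are drawn from
#' the per-orientation log-normal models (rescaled proportionally in the
#' rare case a scaffold overflows); exon/intron structure from the
#' configured models; TEs are placed inside introns and intergenics, never
#' in exons.
#'
#' Randomness comes from the session RNG; seed via
#' \code{\link{simulate_dataset}} or \code{set.seed}.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return a \code{\link{genome_annotation}}.
#' @export
generate_annotation <- function(config) {
  n_sc <- config$n_scaffolds
  per <- rep(floor(config$n_genes / n_sc), n_sc)
  if (config$n_genes %% n_sc > 0)
    per[seq_len(config$n_genes %% n_sc)] <- per[seq_len(config$n_genes %% n_sc)] + 1
  scaffolds <- data.frame(name = sprintf("scaffold_%02d", seq_len(n_sc)),
                          length = rep(config$scaffold_length, n_sc))
  genes <- list(); exons <- list(); gidx <- 0
  intron_ivs <- list(); gap_ivs <- list()

  for (si in seq_len(n_sc)) {
    ng <- per[si]
    if (ng == 0) next
    sn <- scaffolds$name[si]
    # strand chain: flip with probability = divergent target
    strand <- character(ng)
    strand[1] <- sample(c("+", "-"), 1)
    if (ng > 1) {
      flips <- stats::runif(ng - 1) < config$divergent_fraction_target
      for (i in 2:ng)
        strand[i] <- if (flips[i - 1]) setdiff(c("+", "-"), strand[i - 1])
                     else strand[i - 1]
    }
    # gene structures
    k <- 1 + stats::rgeom(ng, config$exon_count_p)
    ex_lens <- lapply(k, function(kk)
      pmax(30, round(rlnorm_med(kk, config$exon_length))))
    in_lens <- lapply(k, function(kk)
      if (kk > 1) pmax(30, round(rlnorm_med(kk - 1, config$intron_length)))
      else numeric(0))
    glen <- vapply(seq_len(ng), function(i)
      sum(ex_lens[[i]]) + sum(in_lens[[i]]), 0)
    # gaps by orientation of the preceding pair
    orient <- function(l, r)
      if (l == r) "tandem" else if (l == "-") "divergent" else "convergent"
    gaps <- numeric(ng)
    gaps[1] <- round(stats::runif(1, 200, 1000))
    if (ng > 1) for (i in 2:ng) {
      m <- config$intergenic_length_model[[orient(strand[i - 1], strand[i])]]
      gaps[i] <- pmax(60, pmin(round(rlnorm_med(1, as.list(m))),
                               8 * m[["median"]]))
    }
    need <- sum(glen) + sum(gaps)
    L <- config$scaffold_length
    if (need > L - 500) {
      avail <- L - 500 - sum(glen)
      if (avail < 0.5 * sum(gaps))
        stop("genome too small for ", ng, " genes on ", sn,
             "; need about ", need + 500, " bp")
      gaps <- pmax(60, floor(gaps * avail / sum(gaps)))
    }
    pos <- 0
    for (i in seq_len(ng)) {
      pos <- pos + gaps[i]
      gidx <- gidx + 1
      gid <- sprintf("gene_%04d", gidx)
      s <- pos; e <- pos + glen[i]
      genes[[gidx]] <- data.frame(
        gene_id = gid, scaffold = sn, start = s, end = e, strand = strand[i],
        biotype = if (stats::runif(1) < config$lncrna_fraction) "lncRNA"
                  else "protein_coding")
      es <- s + c(0, cumsum(ex_lens[[i]][-length(ex_lens[[i]])] +
                              in_lens[[i]]))
      exons[[gidx]] <- data.frame(gene_id = gid, scaffold = sn,
                                  start = es, end = es + ex_lens[[i]])
      if (k[i] > 1) {
        is_ <- es[-length(es)] + ex_lens[[i]][-k[i]]
        intron_ivs[[length(intron_ivs) + 1]] <-
          data.frame(scaffold = sn, start = is_, end = is_ + in_lens[[i]])
      }
      if (i > 1)
        gap_ivs[[length(gap_ivs) + 1]] <-
          data.frame(scaffold = sn, start = pos - gaps[i], end = pos)
      pos <- e
    }
  }
  genes <- if (gidx > 0) do.call(rbind, genes) else data.frame()
  exons <- if (gidx > 0) do.call(rbind, exons) else NULL

  # transposons: one per chosen candidate interval, never touching exons
  tes <- data.frame(scaffold = character(), start = numeric(),
                    end = numeric())
  n_te <- round(config$te_density_per_100kb * sum(scaffolds$length) / 1e5)
  if (n_te > 0 && gidx > 0) {
    cands <- rbind(
      if (length(intron_ivs) > 0)
        cbind(do.call(rbind, intron_ivs), kind = "intron") else NULL,
      if (length(gap_ivs) > 0)
        cbind(do.call(rbind, gap_ivs), kind = "intergenic") else NULL)
    min_fit <- config$te_min_length
    cands <- cands[cands$end - cands$start >= min_fit, , drop = FALSE]
    if (nrow(cands) > 0) {
      # compartment first (so the configured intron/intergenic split is
      # realized), then a length-weighted candidate within it
      kinds <- sample(names(config$te_weights), min(n_te, nrow(cands)),
                      replace = TRUE, prob = config$te_weights)
      avail <- seq_len(nrow(cands))
      take <- integer(0)
      for (kd in kinds) {
        pool <- avail[cands$kind[avail] == kd]
        if (length(pool) == 0) pool <- avail
        ci <- if (length(pool) == 1) pool else
          sample(pool, 1, prob = cands$end[pool] - cands$start[pool])
        take <- c(take, ci)
        avail <- setdiff(avail, ci)
        if (length(avail) == 0) break
      }
      rows <- list()
      for (ci in take) {
        cl <- cands$end[ci] - cands$start[ci]
        tl <- min(cl, max(config$te_min_length,
                          round(rlnorm_med(1, config$te_length))))
        off <- if (cl > tl) floor(stats::runif(1, 0, cl - tl)) else 0
        rows[[length(rows) + 1]] <- data.frame(
          scaffold = cands$scaffold[ci], start = cands$start[ci] + off,
          end = cands$start[ci] + off + tl)
      }
      tes <- do.call(rbind, rows)
    }
  }
  genome_annotation(scaffolds, genes, exons, tes)
}

#' Simulate a generation-resolved expression matrix
#'
#' Baseline abundances are log-normal; log-abundances of divergent-pair
#' members are correlated at the configured level. A configured fraction of
#' genes (lncRNAs over-sampled by the enrichment factor) receives a
#' generation-specific fold change with |log2fc| above 1; replicate columns
#' add log-normal noise; columns are TPM-normalized (sum 1e6).
#'
#' @param annotation a \code{genome_annotation}.
#' @param config a \code{synthetic_config}.
#' @return list with \code{tpm} (gene x sample matrix, columns
#'   \code{sp_rep*}, \code{ga_rep*}), \code{gen_tpm} (noiseless per-gene
#'   TPM per generation), \code{gbgs} (truth data.frame \code{gene_id},
#'   \code{bias}, \code{log2fc}).
#' @export
simulate_expression <- function(annotation, config) {
  em <- config$expression_model
  if (em$replicates < 2) stop("need >= 2 replicates per generation")
  g <- annotation$genes
  n <- nrow(g)
  if (n == 0) stop("annotation has no genes")
  z <- stats::rnorm(n)
  names(z) <- g$gene_id
  rho <- em$pair_correlation
  if (!is.null(rho) && rho != 0) {
    pairs <- classify_adjacent_pairs(annotation)
    dv <- pairs[pairs$orientation == "divergent", , drop = FALSE]
    z[dv$right_gene] <- rho * z[dv$left_gene] +
      sqrt(1 - rho^2) * z[dv$right_gene]
  }
  base <- exp(em$abundance_meanlog + em$abundance_sdlog * z)

  n_gbg <- round(em$gbg_fraction * n)
  wt <- ifelse(g$biotype == "lncRNA", em$gbg_lncrna_enrichment, 1)
  gbg_idx <- if (n_gbg > 0) sample(n, n_gbg, prob = wt) else integer(0)
  bias <- sample(c("sporophyte", "gametophyte"), length(gbg_idx),
                 replace = TRUE,
                 prob = c(em$sp_bias_fraction, 1 - em$sp_bias_fraction))
  mag <- stats::runif(length(gbg_idx), em$log2fc_range[1], em$log2fc_range[2])

  ab_sp <- base; ab_ga <- base
  up_sp <- gbg_idx[bias == "sporophyte"]; up_ga <- gbg_idx[bias == "gametophyte"]
  ab_sp[up_sp] <- ab_sp[up_sp] * 2^(mag[bias == "sporophyte"])
  ab_ga[up_ga] <- ab_ga[up_ga] * 2^(mag[bias == "gametophyte"])

  to_tpm <- function(v) v / sum(v) * 1e6
  r <- em$replicates
  cols <- list()
  for (k in seq_len(r))
    cols[[paste0("sp_rep", k)]] <-
      to_tpm(ab_sp * 2^(stats::rnorm(n, 0, em$replicate_sd)))
  for (k in seq_len(r))
    cols[[paste0("ga_rep", k)]] <-
      to_tpm(ab_ga * 2^(stats::rnorm(n, 0, em$replicate_sd)))
  tpm <- do.call(cbind, cols)
  rownames(tpm) <- g$gene_id

  gbgs <- data.frame(
    gene_id = g$gene_id[gbg_idx], bias = bias,
    log2fc = ifelse(bias == "sporophyte", mag, -mag))
  list(tpm = tpm,
       gen_tpm = cbind(sporophyte = to_tpm(ab_sp), gametophyte = to_tpm(ab_ga)),
       gbgs = gbgs)
}

# draw a presence vector over the four state marks, conditioned != all-four
draw_not_all4 <- function(p) {
  repeat {
    v <- stats::runif(4) < p
    if (!all(v)) return(v)
  }
}

#' Simulate true per-gene mark presence for both generations
#'
#' Non-biased genes keep identical presence in both generations (per-mark
#' Bernoulli at the configured probability). Generation-biased genes either
#' keep their state (mostly parked in the all-four state) or change it: the
#' down-regulated generation gets a sparse mark set and the up-regulated
#' generation gains marks — all four with the per-bias destination
#' probability, otherwise a strict net gain that stops short of the full
#' set.
#'
#' @param annotation a \code{genome_annotation}.
#' @param gbgs truth GBG data.frame from \code{\link{simulate_expression}}.
#' @param config a \code{synthetic_config}.
#' @return list of two gene x mark logical matrices, \code{sporophyte} and
#'   \code{gametophyte} (state marks plus H3K14ac and H3K36me3).
#' @export
simulate_mark_presence <- function(annotation, gbgs, config) {
  sm <- config$gbg_state_model
  g <- annotation$genes
  n <- nrow(g)
  marks <- c(STATE_MARKS, "H3K14ac", "H3K36me3")
  p_of <- vapply(marks, function(m)
    config$mark_models[[m]]$presence_prob %||% sm$tss_mark_prob, 0)
  base <- matrix(stats::runif(n * length(marks)) < rep(p_of, each = n),
                 n, length(marks), dimnames = list(g$gene_id, marks))
  sp <- base; ga <- base
  bias_of <- stats::setNames(gbgs$bias, gbgs$gene_id)
  for (gid in gbgs$gene_id) {
    if (stats::runif(1) >= sm$change_prob) {
      # unchanged: mostly parked in the all-four state
      v <- if (stats::runif(1) < sm$unchanged_state1_prob) rep(TRUE, 4)
           else draw_not_all4(sm$tss_mark_prob)
      sp[gid, STATE_MARKS] <- v; ga[gid, STATE_MARKS] <- v
    } else {
      # sparse down-state (<= 2 marks) so a non-full destination exists
      repeat {
        down <- stats::runif(4) < 0.5
        if (sum(down) <= 2) break
      }
      up <- if (stats::runif(1) < sm$state1_dest_prob[[bias_of[gid]]]) {
        rep(TRUE, 4)
      } else {
        u <- down
        absent <- which(!down)
        gain <- absent[stats::runif(length(absent)) < 0.5]
        if (length(gain) == 0) gain <- sample(absent, 1)
        if (length(gain) == length(absent) && length(absent) >= 2)
          gain <- gain[-sample(length(gain), 1)]  # stop short of all four
        u[gain] <- TRUE
        u
      }
      if (bias_of[gid] == "sporophyte") {
        sp[gid, STATE_MARKS] <- up; ga[gid, STATE_MARKS] <- down
      } else {
        sp[gid, STATE_MARKS] <- down; ga[gid, STATE_MARKS] <- up
      }
    }
  }
  list(sporophyte = sp, gametophyte = ga)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate true broad-domain intervals
#'
#' Domains cover runs of consecutive genes; each border sits at the outer
#' TSS/TES of the run's flanking gene (with the configured probability,
#' otherwise uniform in the adjacent intergenic) plus Gaussian jitter.
#' Domains keep at least \code{min_separation} bp of depleted sequence
#' between them, so marked regions stay discrete. A small fraction of
#' domains is made generation-unique.
#'
#' @param annotation a \code{genome_annotation}.
#' @param config a \code{synthetic_config}.
#' @return list of data.frames \code{sporophyte}, \code{gametophyte}
#'   (\code{scaffold}, \code{start}, \code{end}, \code{first_gene},
#'   \code{last_gene}).
#' @export
simulate_domains <- function(annotation, config) {
  dm <- config$domain_model
  g <- annotation$genes
  slen <- scaffold_lengths(annotation)
  rows <- list()
  min_sep <- dm$min_separation %||% 2000
  for (sn in unique(g$scaffold)) {
    gi <- which(g$scaffold == sn)
    used <- rep(FALSE, length(gi))
    placed <- matrix(numeric(0), ncol = 2)
    target <- round(dm$n_domains * length(gi) / nrow(g))
    got <- 0; tries <- 0
    while (got < target && tries < 50 * target) {
      tries <- tries + 1
      k <- 1 + stats::rgeom(1, dm$genes_per_domain_p)
      s0 <- sample(length(gi), 1)
      if (s0 + k - 1 > length(gi)) next
      span <- s0:(s0 + k - 1)
      guard <- max(1, s0 - 1):min(length(gi), s0 + k)
      if (any(used[guard])) next
      cand <- c(g$start[gi[s0]], g$end[gi[s0 + k - 1]])
      if (nrow(placed) > 0 &&
          any(cand[1] - min_sep < placed[, 2] &
              cand[2] + min_sep > placed[, 1])) next
      used[guard] <- TRUE
      placed <- rbind(placed, cand)
      first <- gi[s0]; last <- gi[s0 + k - 1]
      b1 <- g$start[first]; b2 <- g$end[last]
      if (stats::runif(1) >= dm$fraction_borders_at_tss_tes) {
        prev_end <- if (s0 > 1) g$end[gi[s0 - 1]] else 0
        b1 <- stats::runif(1, prev_end, g$start[first])
      }
      if (stats::runif(1) >= dm$fraction_borders_at_tss_tes) {
        next_start <- if (s0 + k <= length(gi)) g$start[gi[s0 + k]]
                      else slen[[sn]]
        b2 <- stats::runif(1, g$end[last], next_start)
      }
      b1 <- b1 + stats::rnorm(1, 0, dm$border_jitter_sd)
      b2 <- b2 + stats::rnorm(1, 0, dm$border_jitter_sd)
      b1 <- max(0, min(b1, slen[[sn]] - 1))
      b2 <- max(b1 + config$bin_size, min(b2, slen[[sn]]))
      rows[[length(rows) + 1]] <- data.frame(
        scaffold = sn, start = round(b1), end = round(b2),
        first_gene = g$gene_id[first], last_gene = g$gene_id[last])
      got <- got + 1
    }
  }
  all <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(scaffold = character(), start = numeric(), end = numeric(),
               first_gene = character(), last_gene = character())
  all <- all[order(all$scaffold, all$start), , drop = FALSE]
  rownames(all) <- NULL
  uniq <- stats::runif(nrow(all)) < dm$unique_fraction
  which_gen <- sample(c("sporophyte", "gametophyte"), nrow(all),
                      replace = TRUE)
  list(sporophyte = all[!(uniq & which_gen == "gametophyte"), , drop = FALSE],
       gametophyte = all[!(uniq & which_gen == "sporophyte"), , drop = FALSE])
}

add_bump <- function(v, bs, L, center, height, sigma) {
  i0 <- max(1, floor((center - 3 * sigma) / bs) + 1)
  i1 <- min(length(v), ceiling((center + 3 * sigma) / bs))
  if (i1 < i0) return(v)
  mid <- ((i0:i1) - 0.5) * bs
  v[i0:i1] <- v[i0:i1] + height * exp(-(mid - center)^2 / (2 * sigma^2))
  v
}

add_plateau <- function(v, bs, L, start, end, height) {
  i0 <- max(1, floor(start / bs) + 1)
  i1 <- min(length(v), ceiling(end / bs))
  if (i1 >= i0) v[i0:i1] <- v[i0:i1] + height
  v
}

#' Simulate coverage tracks for all marks, generations and replicates
#'
#' Per mark x generation, a per-bin mean is built from the configured shape
#' (TSS bump, double bump at TSS +/- offset, gene-body plateau, TE plateau,
#' or broad-domain plateau) on top of a flat background; TSS/body
#' amplitudes scale as amplitude x (1 + coupling x log1p(TPM)) with the
#' generation's expression. Each replicate is an independent Poisson sample
#' of the mean (unless \code{noiseless}). Input tracks are background only;
#' MNase is a plateau with dips at marked TSSs, one shared dip per divergent
#' pair closer than the configured threshold.
#'
#' @param annotation a \code{genome_annotation}.
#' @param expr output of \code{\link{simulate_expression}}.
#' @param presence output of \code{\link{simulate_mark_presence}}.
#' @param domains output of \code{\link{simulate_domains}}.
#' @param config a \code{synthetic_config}.
#' @param noiseless return the Poisson means instead of sampling.
#' @return list with \code{chip} (nested list mark -> generation -> list of
#'   replicate \code{signal_track}s), \code{input}, \code{mnase} (per
#'   generation), \code{te_marked} (logical per TE interval row).
#' @export
simulate_tracks <- function(annotation, expr, presence, domains, config,
                            noiseless = FALSE) {
  bs <- config$bin_size
  slen <- scaffold_lengths(annotation)
  g <- annotation$genes
  gens <- c("sporophyte", "gametophyte")
  bg <- config$noise$reads_per_bin_mean
  blank <- lapply(slen, function(L) rep(bg, ceiling(L / bs)))

  te_marked <- if (nrow(annotation$tes) > 0)
    stats::runif(nrow(annotation$tes)) <
      (config$mark_models$H4K20me3$presence_prob %||% 0.9)
  else logical(0)

  sample_track <- function(means, mark, gen, rep_i) {
    bins <- if (noiseless) means else
      lapply(means, function(v) as.numeric(stats::rpois(length(v), v)))
    signal_track(bins, bs, slen, mark = mark, generation = gen,
                 replicate = rep_i)
  }
  n_rep <- config$expression_model$replicates

  chip <- list()
  for (mk in names(config$mark_models)) {
    mm <- config$mark_models[[mk]]
    chip[[mk]] <- list()
    for (gen in gens) {
      means <- blank
      if (mm$shape %in% c("tss_peak", "tss_double_peak", "gene_body")) {
        pres <- presence[[gen]]
        has_col <- mk %in% colnames(pres)
        tpm <- expr$gen_tpm[, gen]
        for (i in seq_len(nrow(g))) {
          if (has_col && !pres[g$gene_id[i], mk]) next
          h <- mm$amplitude * (1 + (mm$coupling %||% 0) * log1p(tpm[i]))
          sn <- g$scaffold[i]
          if (mm$shape == "gene_body") {
            means[[sn]] <- add_plateau(means[[sn]], bs, slen[[sn]],
                                       g$start[i], g$end[i], h)
          } else if (mm$shape == "tss_peak") {
            means[[sn]] <- add_bump(means[[sn]], bs, slen[[sn]], g$tss[i],
                                    h, mm$width)
          } else {
            for (d in c(-1, 1))
              means[[sn]] <- add_bump(means[[sn]], bs, slen[[sn]],
                                      g$tss[i] + d * mm$offset, h, mm$width)
          }
        }
      } else if (mm$shape == "te_peak") {
        te <- annotation$tes
        for (i in seq_len(nrow(te))) {
          if (!te_marked[i]) next
          means[[te$scaffold[i]]] <- add_plateau(
            means[[te$scaffold[i]]], bs, slen[[te$scaffold[i]]],
            te$start[i], te$end[i], mm$amplitude)
        }
      } else if (mm$shape == "broad_domain") {
        dd <- domains[[gen]]
        for (i in seq_len(nrow(dd)))
          means[[dd$scaffold[i]]] <- add_plateau(
            means[[dd$scaffold[i]]], bs, slen[[dd$scaffold[i]]],
            dd$start[i], dd$end[i], mm$amplitude)
      } else stop("unknown mark shape: ", mm$shape)
      chip[[mk]][[gen]] <- lapply(seq_len(n_rep), function(k)
        sample_track(means, mk, gen, k))
    }
  }

  input <- lapply(stats::setNames(gens, gens), function(gen)
    sample_track(blank, "input", gen, 1L))

  nm <- config$ndr_model
  pairs <- classify_adjacent_pairs(annotation)
  dv_short <- pairs[pairs$orientation == "divergent" &
                    pairs$length <= nm$shared_below &
                    !pairs$overlapping, , drop = FALSE]
  mnase <- list()
  for (gen in gens) {
    means <- lapply(slen, function(L) rep(config$mnase_level,
                                          ceiling(L / bs)))
    pres <- presence[[gen]]
    any_tss_mark <- rowSums(pres[, c(STATE_MARKS, "H3K14ac"),
                                 drop = FALSE]) > 0
    in_shared <- g$gene_id %in% c(dv_short$left_gene, dv_short$right_gene)
    dip <- function(means, sn, s, e) {
      i0 <- max(1, floor(s / bs) + 1)
      i1 <- min(length(means[[sn]]), ceiling(e / bs))
      if (i1 >= i0) means[[sn]][i0:i1] <-
        means[[sn]][i0:i1] * (1 - nm$depth)
      means
    }
    for (i in seq_len(nrow(g))) {
      if (!any_tss_mark[g$gene_id[i]] || in_shared[i]) next
      means <- dip(means, g$scaffold[i], g$tss[i] - nm$width / 2,
                   g$tss[i] + nm$width / 2)
    }
    for (i in seq_len(nrow(dv_short))) {
      means <- dip(means, dv_short$scaffold[i],
                   dv_short$start[i] - nm$width,
                   dv_short$end[i] + nm$width)
    }
    mnase[[gen]] <- sample_track(means, "mnase", gen, 1L)
  }
  list(chip = chip, input = input, mnase = mnase, te_marked = te_marked)
}

#' Generate a complete seeded synthetic dataset
#'
#' Runs annotation, expression, mark-presence, domain and track simulation
#' under one seed and bundles the results with their ground truth. Identical
#' (config, seed) give identical datasets.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer RNG seed.
#' @param tracks also simulate coverage tracks (the expensive part).
#' @param noiseless Poisson sampling off (tracks carry their means).
#' @return a \code{synthetic_dataset}: list with \code{annotation},
#'   \code{expression}, \code{truth} (list: \code{gbgs}, \code{presence},
#'   \code{domains}, \code{te_marked}), \code{tracks} (or NULL),
#'   \code{config}, \code{seed}.
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1,
                             tracks = TRUE, noiseless = FALSE) {
  set.seed(seed)
  annotation <- generate_annotation(config)
  expr <- simulate_expression(annotation, config)
  presence <- simulate_mark_presence(annotation, expr$gbgs, config)
  domains <- simulate_domains(annotation, config)
  trk <- NULL
  te_marked <- logical(0)
  if (tracks) {
    trk <- simulate_tracks(annotation, expr, presence, domains, config,
                           noiseless = noiseless)
    te_marked <- trk$te_marked
  }
  structure(list(annotation = annotation, expression = expr,
                 truth = list(gbgs = expr$gbgs, presence = presence,
                              domains = domains, te_marked = te_marked),
                 tracks = trk, config = config, seed = seed),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the complete input set for the downstream pipeline: annotation
#' GFF3, TE BED, expression TSV, per-track bedGraphs (raw counts), the
#' ground truth as \code{truth.json} and a config echo as
#' \code{config.yaml}. Output is deterministic: the same dataset writes
#' byte-identical files.
#'
#' The truth schema: \code{gbgs} (gene_id/bias/log2fc records),
#' \code{presence} (per generation, per mark: marked gene ids),
#' \code{domains} (per generation interval records), \code{te_marked}
#' (per TE row of the BED, whether the TE mark covers it).
#'
#' @param dataset a \code{synthetic_dataset} (with tracks).
#' @param outdir output directory, created if needed.
#' @return \code{outdir}, invisibly.
#' @export
emit_dataset <- function(dataset, outdir) {
  missing <- c(annotation = is.null(dataset$annotation),
               expression = is.null(dataset$expression),
               tracks = is.null(dataset$tracks))
  if (any(missing))
    stop("incomplete dataset; missing: ",
         paste(names(missing)[missing], collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "tracks"), showWarnings = FALSE)
  write_annotation(dataset$annotation, file.path(outdir, "genes.gff3"))
  write_intervals(dataset$annotation$tes, file.path(outdir, "te.bed"))
  write_expression(dataset$expression$tpm, file.path(outdir, "expression.tsv"))
  tr <- dataset$tracks
  for (mk in names(tr$chip)) for (gen in names(tr$chip[[mk]]))
    for (k in seq_along(tr$chip[[mk]][[gen]]))
      write_track(tr$chip[[mk]][[gen]][[k]],
                  file.path(outdir, "tracks",
                            sprintf("%s_%s_rep%d.bedGraph", mk, gen, k)))
  for (gen in names(tr$input))
    write_track(tr$input[[gen]],
                file.path(outdir, "tracks", sprintf("input_%s.bedGraph", gen)))
  for (gen in names(tr$mnase))
    write_track(tr$mnase[[gen]],
                file.path(outdir, "tracks", sprintf("mnase_%s.bedGraph", gen)))
  pres <- lapply(dataset$truth$presence, function(m)
    lapply(as.data.frame(m), function(col) rownames(m)[col]))
  truth <- list(
    gbgs = dataset$truth$gbgs,
    presence = pres,
    domains = dataset$truth$domains,
    te_marked = dataset$truth$te_marked)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg <- dataset$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(outdir, "config.yaml"))
  invisible(outdir)
}
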