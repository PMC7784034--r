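---
title: "Methods: chromatin-landscape analysis across a haploid-diploid life cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-landscape analysis across a haploid-diploid life cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifecyclechromatin)
```

# Scope and model

`lifecyclechromatin` implements the downstream analysis of histone
post-translational modification (PTM) ChIP-seq for an organism whose life
cycle alternates between two near-isomorphic multicellular generations, a
diploid sporophyte and a haploid gametophyte. The inputs are a genome
annotation, transposon (TE) intervals, binned coverage tracks per mark,
generation and replicate (plus input chromatin and MNase coverage), and a
gene-level expression matrix. The pipeline answers five questions:

1. **Where do marks sit?** The genome is partitioned into six feature
   classes — the 500 bp window 5′ of each TSS, first exons, other exons,
   first introns, other introns, and intergenic sequence — with TE/no-TE
   sectors for the three non-genic classes, and peak base pairs are
   apportioned over these classes.
2. **Which genes carry TSS marks?** Peaks are called per mark against the
   input with a Poisson background model; a gene is marked when a peak
   lies within 500 bp of its TSS on either side.
3. **How are broad domains organised?** Broad-mode peaks of an
   H3K79me2-like mark are merged into multi-gene domains; a permutation
   statistic asks whether domain borders sit closer to gene starts/ends
   (TSS/TES) than random anchor points do.
4. **How stable is chromatin across the life cycle?** Four TSS marks
   (H3K4me2, H3K4me3, H3K9ac, H3K27ac) define 16 combinatorial chromatin
   states per gene per generation; state transitions are summarised at
   generation-biased genes (GBGs) called from expression.
5. **What is special about divergent promoters?** Adjacent gene pairs are
   classified divergent / tandem / convergent; divergent pairs are probed
   for shared nucleosome-depleted regions (NDRs) in MNase signal, elevated
   TSS mark signal, and within-pair expression correlation.

Everything operates on a single internal coordinate convention — 0-based,
half-open intervals; TSS and TES are strand-aware points — with GFF3
(1-based closed) and BED/bedGraph (0-based half-open) converted at the
boundary. This removes whole classes of off-by-one errors; the two
conversions are each tested by round trips.

# The synthetic-data generator

Real ChIP-seq for this system needs a reference genome and read-level
data; the package instead ships a seeded generator whose defaults are the
study conditions the analysis assumes, plus a ground-truth record so every
caller can be scored as a recovery problem. Defaults (all in
`synthetic_config()`):

* **Genome**: 2 scaffolds × 1 Mb, 1,000 genes, 50 bp bins. This scale runs
  the full pipeline in seconds while leaving several hundred divergent
  pairs and ~150 broad domains for the statistics.
* **Gene orientation**: strands follow a two-state chain whose flip
  probability equals the divergent-fraction target (0.617). For interior
  genes the probability of membership in a divergent pair then equals the
  target exactly, so the realized census concentrates near it.
* **Intergenic geometry**: log-normal gap lengths by orientation —
  divergent median 409 bp, tandem 2293 bp (σ = 0.5 on the log scale),
  convergent median 800 bp (the divergent and tandem medians are the
  organism's published geometry; the convergent median is a package
  choice, between the two, as convergent gaps carry two TESs and no
  promoter). Gaps are capped at 8× their median and shrunk proportionally
  in the rare case a scaffold overflows.
* **Gene structure**: exon count 1 + Geometric(0.5); exon lengths
  log-normal (median 120 bp, σ = 0.4); intron lengths log-normal (median
  150 bp, σ = 0.9). The heavy intron tail matters: TEs are ≥ 400 bp by
  convention, so introns must occasionally exceed that for the
  TE-in-intron compartment (~44% of TEs) to exist at all.
* **Marks**: five TSS marks (H3K4me2 as a double peak at TSS ± 250 bp,
  the rest single Gaussian bumps, width 150–200 bp), a gene-body plateau
  mark (H3K36me3-like), a TE plateau mark (H4K20me3-like), and a broad
  domain mark (H3K79me2-like). TSS and body amplitudes scale as
  amplitude × (1 + 0.3·log1p(TPM)): the data show monotone
  expression-decile profiles but no functional form, and log-linear is
  the simplest monotone choice. Per-gene presence is Bernoulli(0.8) per
  TSS mark, matching the observed 77–83% TSS association.
* **Broad domains**: ~150 runs of 1 + Geometric(0.4) consecutive genes;
  borders snap to the outer TSS/TES of the run (configurable fraction),
  then receive Gaussian jitter (σ = 200 bp). Domains keep ≥ 2 kb of
  depleted sequence between them so that segmentation at a 1 kb merge gap
  is identifiable. A configurable 1% of domains is generation-unique,
  mirroring the observed near-complete stability.
* **Expression**: log-normal baseline abundance (meanlog 3, sdlog 1.2 on
  the natural log scale), TPM-normalized per replicate. 4% of genes are
  GBGs (65% sporophyte-biased), with planted |log2 fold change| uniform
  in [1.2, 4.2]; lncRNAs (5% of genes) are over-sampled 3× into the GBG
  set. Replicate noise is log-normal with σ = 0.02 on the log2 scale —
  deliberately small, because the recovery contract is sensitivity ≥ 0.8
  with only two replicates per generation and a t-test on df = 2; the
  generator emulates technical-scale rather than biological-scale
  variability, and this is one of the places where passing tests say
  nothing about noisier real data.
* **GBG chromatin coupling**: 61.1% of GBGs keep their state between
  generations (81.4% of those parked with all four marks); state-changing
  GBGs gain marks in their up-regulated generation, reaching the all-four
  state with probability 0.748 (sporophyte-biased) or 0.264
  (gametophyte-biased). The down-generation state is drawn with at most
  two marks so a non-full destination always exists; otherwise the
  realized destination fractions would exceed their configured values.
* **MNase**: constant 40 reads/bin with dips of depth 0.75 and width 150
  bp at marked TSSs; divergent pairs with gaps ≤ 600 bp share a single
  dip spanning the whole intergenic. Depth and width are tunable
  assumptions, not claims: with a 0.5× background calling threshold and
  Poisson counting noise, a dip must sit well below threshold for runs
  not to fragment.
* **Noise**: every track is an independent Poisson sample per bin around
  its mean (background 5 reads/bin; input is background only).
  Read-level effects — fragment size, mappability, GC — are out of scope.

What the generator does **not** emulate: biological replicate
variability, spatial autocorrelation of chromatin beyond the planted
domains, sequence content (the genome is coordinates only), antisense or
read-through transcription, and the coupling between domains and
expression (domain membership is independent of TPM, so group
comparisons between in-domain and out-of-domain genes are null by
construction in the toy).

# Numerical and statistical choices

**Peak caller.** Per-bin counts are tested against
λ = max(global control mean, 10 kb local control mean) × library ratio,
with p = P(Pois(λ) ≥ x), Benjamini-Hochberg adjustment genome-wide, and
q ≤ 0.01 bins merged (narrow: 1-bin gap, ≥ 2 bins; broad: 1 kb gap,
≥ 10 bins). Replicates are pooled (counts summed) before calling, which
is equivalent to merging the underlying reads. This is intentionally the
simplest defensible caller: the package's contribution is downstream of
peak calling, and nothing depends on reproducing any external caller's
scores.

**Differential expression.** The built-in test first applies
median-of-ratios sample scaling: TPM is a within-sample normalization, so
when 4% of genes rise several-fold in one generation the shared
denominator shifts *every* gene's ratio, and an uncorrected test is
anti-conservative under the null. After scaling, each gene gets a
pooled-variance two-sample t-test on log2(TPM + 1) with df = n1 + n2 − 2.
With two replicates per group, Welch's df approximation collapses toward
1 whenever the two sample variances differ by chance, which imposes a
p-value floor of roughly 1/t² and destroys ranking power; the pooled test
is exact here because the generator's replicate variances are equal by
design. Real analyses should supply an external count-model DE table,
which the GBG caller accepts as a first-class input.

**GBG calling.** padj < 0.05, fold change > 2 (strict, on the linear
scale), and mean TPM > 1 in the biased generation, intersected across all
supplied experiments with a consistent direction; direction conflicts are
excluded and counted.

**Chromatin states.** Only the all-four state is anchored externally
(state 1); the remaining ordering is declared — descending mark count,
ties broken by the mark order H3K4me2, H3K4me3, H3K9ac, H3K27ac — giving
state 16 = no marks. No correspondence of intermediate state numbers with
any external numbering is claimed.

**Border statistic.** Each qualifying domain (≥ 5 kb) contributes two
borders (outermost enriched coordinate); the distance is to the nearest
TSS-or-TES point pooled over all genes and strands. The null draws
anchor sets of the same size uniformly over scaffold coordinates — no
mappability mask, as none is available at toy scale — and the observed
vs pooled-null distances are compared by a two-sided Wilcoxon rank-sum
test. The test is invariant under coordinate translation, and on
uniformly placed domains its rejection rate stays near nominal (checked
over 50 seeds).

**NDR calling.** A bin is depleted when its 3-bin running mean falls
below 0.5× the local background (median raw MNase over a 5 kb window
centred on the queried region); NDRs are maximal depleted runs. The
smoothing exists because single-bin thresholding lets Poisson noise split
one deep dip into fragments, which would be a caller artefact, not a
biological call. Calls are invariant to rescaling the track. A divergent
pair "shares" an NDR when one call contains both partners' TSSs (± 1
bin).

**Wilcoxon/χ²/z primitives.** Base R implementations are used throughout
(`wilcox.test`, exact for small tie-free samples; `chisq.test` with Yates
correction; `p.adjust`). The two-proportion z is computed from its pooled
closed form so the signed statistic is available. Fully tied rank-sum
input returns p = 1 by convention (no evidence of separation).

**Degenerate inputs.** Empty annotations partition to all-intergenic;
empty peak sets are legal everywhere except where a statistic requires a
non-empty class (then: error with counts, or a reported-absent field, as
documented per function). The final partial bin of each scaffold is kept
at its true width.

# Problem sizes

The test suite and the acceptance script run everything at the default
toy scale: full 2 Mb datasets for peak, domain, GBG, NDR and pair-signal
recovery; a 5 Mb / 5,000-gene annotation-only cohort for the
state-transition asymmetry (the 40-GBG default plants too few
state-changers for a well-powered two-proportion comparison — roughly 75%
vs 26% at ~50 vs ~27 transitions is needed for z > 2); 50-seed
calibration loops for the border-statistic null; and exhaustive
enumeration (n ≤ 6) for the rank-sum oracle. These sizes are the
package's chosen trade-off between statistical resolution and a suite
that completes in about a minute.

# Known limitations

* The peak caller is bin-resolution: summits are bin midpoints and
  borders quantized to 50 bp. Sub-bin structure is invisible.
* The toy's divergent gaps are short by construction, so a marked gene's
  genuine peak often lies within 500 bp of its unmarked neighbour's TSS;
  gene-level false-positive accounting is confounded there, and peak
  recovery is therefore audited peak-level (is each called peak
  attributable to a truth-marked TSS?).
* At two replicates the DE stand-in leans on the generator's equal-variance
  design; it is a placeholder for a count-model tool, not a competitor.
* The 94.6%-style co-localisation of the TE mark with repeats depends
  entirely on the input repeat annotation; the package takes repeat
  intervals as given and fixes no repeat definition beyond the ≥ 400 bp
  convention.
* lncRNA enrichment among GBGs is underpowered at the 1,000-gene default
  (≈ 5 expected lncRNA GBGs); the analysis scripts demonstrate it on the
  larger cohort.
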