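# lifecyclechromatin

Downstream analysis of histone post-translational modification (PTM)
ChIP-seq across the two generations — diploid sporophyte and haploid
gametophyte — of a haploid-diploid life cycle, as found in brown algae.
The package is aimed at epigenomics analysts who have per-mark binned
coverage, a genome annotation with transposon intervals, and gene-level
expression, and who want the standard battery of chromatin-landscape
questions answered reproducibly:

* **Feature partitioning** — every base pair assigned to one of six
  classes (upstream TSS 500 bp, first exon, exon, first intron, intron,
  intergenic) with a transposon overlay, and peak base pairs apportioned
  over them.
* **Peak calling and TSS association** — a Poisson/Benjamini-Hochberg bin
  caller against input chromatin (per-bin `p = P(Pois(λ) ≥ x)` with
  `λ = max(global, local 10 kb control mean)`, q ≤ 0.01); a gene carries a
  mark when a peak lies within 500 bp of its TSS.
* **Broad-domain segmentation** — merged broad peaks form multi-gene
  domains; borders are tested for proximity to the nearest TSS/TES
  against uniformly drawn random anchors (two-sided Wilcoxon of observed
  vs pooled null distances).
* **Combinatorial chromatin states** — the 2⁴ = 16 presence/absence
  combinations of H3K4me2, H3K4me3, H3K9ac and H3K27ac per gene per
  generation (state 1 = all four present), with transition summaries at
  generation-biased genes: fraction unchanged, mark-gain concordance, and
  a two-proportion z comparing per-bias transitions into state 1.
* **Generation-biased genes (GBGs)** — called at padj < 0.05, fold
  change > 2, TPM > 1 in the biased generation, intersected across
  experiments; a built-in size-factor-scaled t-test on log2(TPM+1) stands
  in when no external DE table is supplied.
* **Divergent gene pairs** — adjacent pairs classified divergent / tandem
  / convergent; MNase-based nucleosome-depleted-region (NDR) calls, with
  the shared-NDR rate of divergent pairs stratified at 600 bp; TSS signal
  and within-pair expression correlation by orientation.

Because the analyses are statistical contracts, the package ships a
seeded synthetic-data generator (`simulate_dataset()`) that produces a
toy genome (2 × 1 Mb, 1,000 genes), expression, and Poisson-sampled
coverage tracks with ground truth, so every caller is tested as a
parameter-recovery problem. See the methods vignette
(`vignettes/chromatin-landscape-methods.Rmd`) for the model, defaults and
their rationale.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on the
default synthetic dataset (`Rscript analysis/02_features_pairs.R 1` etc.;
the argument is the seed). Highlights of a seed-1 run, with tables
written under `results/`:

```
$ Rscript analysis/02_features_pairs.R 1
689 TSS-adjacent intergenics; 62.1% of flanking genes are in divergent pairs
median intergenic length: divergent 430 bp, tandem 2257 bp (Wilcoxon p = 7.23e-109)
```

The pair census recovers the generator's planted orientation structure: a
strong excess of divergent neighbours whose shared intergenics are about
five times shorter than tandem ones.

```
$ Rscript analysis/03_peaks_tss.R 1
H3K4me3: 631 peaks; 88.3% of genes have a peak within 500 bp of the TSS
H4K20me3 vs TE-containing introns: chi2 = 636.9, p = 1.56e-140; 100.0% of peaks co-localise with a TE
TSS-mark co-localisation: Pearson r range 0.58-0.74 off-diagonal

$ Rscript analysis/04_domains.R 1
sporophyte domains: 106 covering 21.1% of the genome; 26.4% > 5 kbp with 3.96 genes each on average
domain borders: 100.0% within 1 kb of a TSS/TES (median 115 bp); vs random anchors Wilcoxon p = 3.96e-14
long domains unique to one generation: 0.0% (SP), 0.0% (GA)
```

TSS marks land at most genes' promoters and co-localise with each other;
the TE mark sits almost exclusively on transposon-containing introns and
intergenics; broad domains span several genes, their borders hug gene
starts/ends far more tightly than random anchors, and they are stable
across the life cycle.

```
$ Rscript analysis/05_states_gbgs.R 1
called 40 GBGs (25 sporophyte-, 15 gametophyte-biased); truth has 40
GBG chromatin states: 65.0% unchanged between generations (of those, 88.5% in state 1)
state-changing GBGs: 100.0% gain marks in the biased generation; to-state-1 87.5% (SP) vs 16.7% (GA), z = 2.65, p = 0.00804
larger cohort (200 GBGs): to-state-1 75.0% (SP) vs 20.0% (GA), z = 4.64, p = 3.52e-06

$ Rscript analysis/06_divergent_pairs.R 1
shared NDR: 99.6% of divergent pairs <= 600 bp (n = 242) vs 0.0% above (n = 68)
within-pair expression correlation (divergent): r = 0.014
```

All 40 planted GBGs are recovered with zero false calls; most keep their
chromatin state between generations while state-changers gain marks in
their up-regulated generation, sporophyte-biased genes preferentially
reaching the all-four state. Divergent promoters closer than 600 bp share
one NDR, yet pair members' expression stays uncorrelated — promoter
sharing without co-regulation.

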