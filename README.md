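# crossoccupy

Comparative analysis of pioneer-factor occupancy and chromatin accessibility
across cell types, from ChIP-seq peak sets and ATAC-seq fragment data.

Pioneer transcription factors such as *Drosophila* Zelda (Zld) can engage
nucleosome-occluded DNA, and in the early embryo their binding is driven
largely by sequence. In differentiated tissues (e.g. larval type II
neuroblasts) the same factor binds a largely different set of loci, and the
question becomes: how much of occupancy is explained by motif content versus
cell-type-specific chromatin accessibility? `crossoccupy` implements the
genomic side of that comparison as a reusable, tested R pipeline:

- **Peak post-processing** — summit extension to fixed-width regions
  (`[summit − 100, summit + 100)`), replicate-reproducibility filtering
  (a peak survives iff ≥ 50% of its length overlaps a peak of the other
  replicate; survivors are union-merged), and cross-cell-type classification
  (shared iff the best single-partner overlap is ≥ 10 bp).
- **Coverage z-score tracks** — fragment-overlap counts in 10-bp bins,
  standardized genome-wide: `z = (c − mean(c)) / sd(c)` pooled over all bins
  of all chromosomes; summit-centered profile matrices (±600 bp → 120
  columns) and average profiles.
- **IUPAC motif scanning** — native degenerate-alphabet matching on both
  strands (e.g. Zld `CAGGTAG`/`CAGGTARV`, CLAMP `ACMGRG`, Dref/Beaf-32
  `HATCGATA`, M1BP `GGTCACA`, Erm `AAAWGVVCMNH`), per-region presence
  tallies, summit-proximal flags (motif start within ±200 bp of the summit),
  and rank-binned motif-fraction tables (peaks sorted by z score, bins of
  100).
- **Feature annotation** — summit-based classification with promoter
  defined as −500 to +150 bp of the TSS in gene orientation, priority
  promoter > 5'UTR > 3'UTR > exon > intron > downstream > distal; nearest
  gene by TSS distance; randomized-placement background and Fisher
  enrichment.
- **Accessibility dynamics** — nucleosome-free fragment filtering
  (length < 100 bp, MAPQ > 30), median-of-ratios size factors, a
  negative-binomial likelihood-ratio test of per-timepoint means vs a common
  mean (statistic `2(ℓ_full − ℓ_reduced)` vs χ² with T − 1 df,
  Benjamini-Hochberg adjusted), k-means clustering of z-scored trajectories
  (`nstart = 25`, `iter.max = 1000`), cluster-level binding enrichment, and
  motif-stratified accessibility-decay comparisons (two-sided Wilcoxon
  rank-sum per timepoint).
- **Synthetic data** — a generator that emits a small genome, gene models,
  peak sets with an exactly planted shared fraction and motif flags,
  fragment sets with a controlled nucleosome-free length mixture and
  enrichment ratio, and five-timepoint NB count matrices built from six
  trajectory archetypes — every claim the generator makes is literally true
  of the emitted data, so each pipeline stage can be tested against ground
  truth.

## Worked example

```r
library(crossoccupy)

# a ground-truth-labelled world: 2 x 500 kb genome, 500 peaks per condition,
# 40% of them planted as shared (>= 10 bp mutual overlap)
w  <- make_world(n_peaks = 500, shared_frac = 0.4, seed = 17)
cl <- classify_cross_condition(w$peaks_a, w$peaks_b, overlap_min = 10)
summary(cl)
#>    category count
#> 1  shared_A   200
#> 2  shared_B   200
#> 3  unique_A   300
#> 4  unique_B   300

# ATAC-style fragments enriched 5x at peaks; z-score coverage track
fr <- make_fragments(w$chrom_sizes, w$peaks_a, depth = 1e5, rho = 5, seed = 1)
z  <- zscore_normalize(bin_coverage(filter_fragments(fr), 10, w$chrom_sizes))
pk <- peak_zscores(z, w$peaks_a)

# motif fraction by z-score rank bin
tb <- rank_binned_fraction(pk, list(w$motif), w$genome, bin_size = 100)

# five-timepoint differential accessibility and trajectory clustering
tc  <- make_timecourse(n_regions = 2000, pi = 0.3, mu = 50, alpha = 0.1, seed = 2)
res <- nb_lrt(tc$counts)
sum(res$padj < 0.05)
#> [1] 468
clu <- cluster_trajectories(tc$counts, k = 6, nstart = 25, seed = 3)
```

The classification recovers the planted 200/300/300 partition exactly; the
LRT calls ~470 of the 600 truly changing regions at an empirical false
discovery rate below 5%.

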