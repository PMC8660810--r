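---
title: "Methods: comparative occupancy and accessibility analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative occupancy and accessibility analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossoccupy)
```

`crossoccupy` compares where a pioneer transcription factor binds in two
cell types, and how chromatin accessibility at those sites changes over a
differentiation time course. This vignette documents the models and
procedures, the parameters that matter, the numerical choices, and what the
synthetic-data tests do and do not establish about real data.

## Coordinate conventions

All internal coordinates are 0-based, half-open (`[start, end)`), the BED
convention. Conversion happens only at I/O boundaries: GTF input (1-based,
closed) is converted on read, and written back on GTF export. Chromosome
names are matched as exact strings — no `chr` aliasing — so mismatched genome
builds fail loudly rather than silently mis-joining.

## Peak processing and cross-condition classification

Peaks enter as narrowPeak records; the summit is the peak start plus the
column-10 offset, with a midpoint fallback for records called without
summits (offset −1), which keeps the summit-inside-interval invariant
satisfiable for any input.

- **Summit extension** (`extend_summits`): each peak becomes
  `[summit − flank, summit + flank)`, clipped at the chromosome; the default
  flank of 100 bp yields the standard 200-bp summit-centered regions.
- **Reproducibility filter** (`reproducible_peaks`): a peak from either
  replicate is retained iff at least `min_frac` (default 0.5) of its own
  length overlaps some single peak of the other replicate (best-partner,
  BEDtools `-f` semantics — overlaps are not summed across partners).
  Retained peaks from both replicates are union-merged (overlapping or
  bookended survivors become one region). The merge is symmetric and
  order-independent; because the anchoring convention is genuinely open, a
  `mode = "rep1"` flag exposes the replicate-1-anchored alternative.
- **Cross-condition classification** (`classify_cross_condition`): a peak is
  *shared* iff its maximum single-partner overlap with the other condition's
  set is at least `overlap_min` bp. The default of 10 bp is read as ≥ 10,
  forced by the complementary definition of *unique* as "less than 10 bp".
  Bookended intervals (overlap 0) are never shared. The partition is
  exhaustive and disjoint per set, and symmetric in the two conditions.

Overlap arithmetic is delegated to `IRanges` (interval trees); the test
suite holds it to an all-pairs brute-force oracle on hundreds of random
instances.

## Coverage tracks and profiles

Fragment coverage is binned at `bin_width = 10` bp; a bin's value is the
number of fragments overlapping it by ≥ 1 bp (a count, not a per-base mean —
at 10-bp bins the difference is immaterial and the count definition is
exactly testable against a double-loop oracle). Z-score normalization
subtracts the genome-wide mean bin count and divides by the genome-wide
standard deviation, pooling **all** bins of all assembled chromosomes,
zeros included. The *population* SD is used: at genome scale it is
indistinguishable from the sample SD, and it makes small worked examples
exact (bins `(2, 4, 6)` map to `(−1.2247, 0, 1.2247)`). A constant track is
an error (zero variance), and z-scoring is idempotent because it is an
affine map.

A per-peak z score is the mean z over the bins overlapping the peak
interval. The summit-bin value is exposed as an option
(`peak_zscores(stat = "summit")`) because the region-mean choice, while
natural, is not the only defensible reading of "peak z score".

Profile matrices (`profile_matrix`) take the bins covering
`[summit − flank, summit + flank)` per peak — 120 columns at the 600-bp /
10-bp defaults — zero-filling and flagging out-of-chromosome bins, with rows
ordered by a declared ranking (descending mean z by default, ties broken by
coordinate).

## IUPAC motif scanning

Motif matching is implemented natively over the IUPAC degenerate alphabet: a
position matches iff every sequence base is a member of the corresponding
pattern character's class. Three deliberate choices:

- `N` in the *genome* matches nothing, not even pattern `N` — assembly gaps
  must not create motifs.
- Both strands are scanned by default (the reverse complement of the pattern
  is scanned on the forward sequence and reported in forward coordinates);
  a `both_strands = FALSE` mode preserves the forward-only alternative since
  tally conventions vary.
- All overlapping occurrences are reported.

Region tallies (`count_regions_with_motif`) require a match fully inside the
region. Summit-proximal flags (`motif_near_summit`) use a *closed* window on
the match start, `[summit − 200, summit + 200]`, the simplest reading of
"within 200 bp of the summit"; the boundary behavior (start at +200 is
positive, +201 is not) is pinned by tests. Rank-binned motif fractions sort
peaks by z score (descending, coordinate tie-break), cut them into
consecutive bins of 100, and report the fraction of peaks per bin containing
each motif; a final partial bin is kept and its fraction uses its actual
size. The scanner is validated against two independent engines: a PCRE
lookahead-regex oracle and `Biostrings` pattern matching.

## Feature annotation

Peaks are classified by **summit position** with fixed priority
promoter > 5'UTR > 3'UTR > exon > intron > downstream > distal intergenic,
which guarantees exactly one class per peak (pie-chart arithmetic). The
promoter window is −500 to +150 bp around the TSS *in gene orientation*.
Summit-based single-class assignment is a design choice: annotation tools
that use any-overlap precedence can produce different percentages, so exact
replication of any particular tool's distribution is out of scope — the
direction of enrichment is the supported claim. "Downstream" is capped at
1 kb past the gene's 3' end (a number must be picked; it is configurable).
UTR calls require CDS features in the gene models and fall back to "exon"
without them.

Enrichment against background uses `randomized_background` (each region
re-placed uniformly on its own chromosome, lengths preserved,
seed-reproducible) and a two-sided Fisher exact test on
in-category/out-of-category counts, with a Haldane 0.5 correction on the
sample odds ratio when a cell is zero.

## Time-course differential accessibility

Fragments are filtered to nucleosome-free, high-confidence records with
*strict* inequalities — length < 100 bp and MAPQ > 30 — matching the stated
filters. Counting is overlap-based (≥ 1 bp); a fragment spanning two regions
counts toward both by default, with an exclusive-assignment policy flag.

Size factors are median-of-ratios: for sample *j*,
`sf_j = median_r (y_rj / g_r)` over regions `r` with all-positive counts,
where `g_r` is the geometric mean across samples. No all-positive region is
an error (a pseudo-reference fallback is suggested in the message rather
than silently applied).

The differential test is a per-region negative-binomial likelihood-ratio
test: the full model fits one normalized mean per timepoint
(`mu_tj = q_t * sf_j`), the reduced model one common mean, and
`Λ = 2(ℓ_full − ℓ_reduced)` is referred to χ² with `T − 1` degrees of
freedom, BH-adjusted across regions. The dispersion `α` (variance
`μ + αμ²`) is estimated once per region by the Pearson moment equation under
the full model's fitted means, floored at 1e−8, and then **moderated by
pooling**: the working value is `max(α_r, mean_r(α_r))`. The moderation is
load-bearing. With two replicates per timepoint the per-region moment
estimate has only `N − T` residual degrees of freedom; regions whose
dispersion it underestimates would inflate Λ and the test would reject far
too often under the null. Taking the max borrows strength across regions
(the same motivation as dispersion sharing in the established differential
packages) while remaining conservative for genuinely high-dispersion
regions. The acceptance suite verifies the resulting null calibration
(rejection rate within 3–7% at p < 0.05 on 2,000 null regions) and the
Poisson limit (at the dispersion floor, Λ equals the closed-form Poisson
LRT). Mean fits at fixed α are exact 1-D score-equation roots
(`uniroot` at tolerance 1e−10), so Λ ≥ 0 up to numerical tolerance;
all-zero regions are flagged with p = 1. No dispersion shrinkage toward a
trend, no Wald contrasts: the LRT is the supported inference, and exact
replication of any published region count is explicitly not claimed.

Power depends strongly on the design. At the null-simulation conditions
(mean 50, dispersion 0.1, two replicates) a clean two-fold step is detected
for only a minority of regions; the recovery property test therefore uses a
well-replicated design (three replicates, dispersion 0.05, mean 100), where
the suite verifies FDR ≤ 0.08 with sensitivity ≥ 0.8 at a two-fold effect.

## Trajectory clustering and downstream comparisons

Clustering input is the z-scored (mean 0, SD 1 across timepoints),
replicate-averaged, size-factor-normalized trajectory of each region called
differentially accessible — z-scoring makes clusters reflect temporal shape
rather than accessibility level; a `scale = "none"` flag preserves the
raw-normalized alternative since the input scale is genuinely open.
Clustering is R's `stats::kmeans` with `nstart = 25` restarts and
`iter.max = 1000` — the same call the analysis convention uses — and is
deterministic given a seed. The `k = n` corner case (every point its own
cluster, within-SS 0) is handled directly. The six default clusters
correspond to the archetypal patterns early/late/transient increase and
early/late/transient loss.

Clusters are grouped into *decreasing* vs *increasing* accessibility by the
sign of (mean of the last two centroid timepoints − mean of the first two);
note a transient-increase shape ends below its start and lands in the
decreasing group under this operational rule. Binding enrichment between
the groups is a two-sided Fisher exact test. Motif-stratified decay
comparisons run a two-sided Wilcoxon rank-sum test per timepoint between
motif-containing and motif-lacking regions, with box-plot summaries
(median, quartiles, 1.5×IQR whiskers).

## Exact tests

`fisher_exact_two_sided` sums hypergeometric point probabilities not
exceeding the observed table's (with a 1 + 1e−7 relative guard against
floating-point ties, the convention of the standard R implementation). The
suite checks it against full enumeration for *all* tables with margins ≤ 12.
`wilcoxon_rank_sum` enumerates all rank assignments when the pooled size is
≤ 20 without ties (the two-sided p is the null probability of a rank-sum
deviation at least as extreme; for tie-free data this equals the usual
doubled tail) and otherwise uses the tie-corrected normal approximation with
continuity correction. Enumerating larger strata exactly is combinatorially
infeasible (C(50, 25) ≈ 1.3e14), so the ≤ 20 threshold applies uniformly,
including inside the decay comparison. `replicate_pearson` correlates
`log2(count + 1)` between replicates; the pseudocount (configurable, 0
allowed for all-positive counts) handles zeros that a bare log would drop.

## The synthetic world: what it does and does not emulate

`make_world` plants every truth it reports:

- **Shared fraction**: shared pairs are emitted with 10–190 bp of mutual
  overlap (keeping the two summits ≥ 10 bp apart so discordant motif flags
  stay plantable); unique peaks sit ≥ 1 kb from any other entity, so the
  classifier must recover the planted fraction *exactly*, not
  approximately.
- **Motif flags**: motif-positive peaks receive a sampled concrete instance
  of the IUPAC pattern within ±200 bp of the summit; motif-negative
  neighborhoods are rejection-sampled until no occurrence remains on either
  strand (rejection keeps base composition realistic, unlike masking).
  Overlapping shared-pair windows are planted jointly with verification and
  retry, so the flags of both partners are simultaneously true.
- **Fragments**: lengths follow the mixture
  `f·N(60, 15) + (1 − f)·N(200, 25)` truncated to [20, 500] bp
  (nucleosome-free + mono-nucleosome modes); placement is uniform background
  plus an enrichment component giving rate ratio `rho` inside peaks,
  optionally weighted per peak; MAPQ is low (≤ 30) with a stated fraction.
- **Time courses**: archetype mean shapes (e.g. early loss
  `1, 0.4, 0.3, 0.3, 0.3` over 0/6/12/18/24 h), scaled to mean 1 so baseline
  level is comparable across archetypes, with NB counts at dispersion `α`
  and planted size factors. The changing fraction π and the archetype
  allocation are exact by construction.

Defaults (two 500-kb chromosomes at GC 0.43, 60 genes, 500 peaks per
condition, 200-bp peaks, baseline mean 50, dispersion 0.1, two replicates,
five timepoints) are fixed study conditions, chosen once to be small enough
to regenerate in seconds yet large enough for the statistical checks.

What the generator does **not** emulate: read-level sequences and
sequencing error, duplicate fragments, GC- or mappability-dependent
coverage bias, correlated peak shapes, overdispersion trends that vary with
mean, and annotation complexity (one transcript per gene, fixed exon/CDS
layout). Passing tests therefore establish the *correctness of the
computations* against their definitions and planted truths — they do not
establish that real libraries satisfy the generative assumptions, and on
real data the usual caveats (peak-caller artifacts, batch effects,
mean-dispersion trends) still apply.

## Numerical choices, degenerate inputs, reproducibility

- Population SD in z-scoring; zero-SD tracks error.
- Pearson moment equation solved by `uniroot` on a bracketed monotone
  function; dispersion floor 1e−8; NB mean fits by bracketed score roots.
- Ties in every ranking are broken by (chromosome, start) so orderings are
  deterministic; nearest-gene ties break to the lexicographically smaller
  gene id.
- Empty inputs: empty BED reads to an empty frame; an empty replicate in
  the reproducibility filter warns and returns empty; empty strata,
  empty query sets and constant vectors are errors, not NaNs.
- All generators are deterministic given `seed`; identical seeds reproduce
  byte-identical emitted files.

## Known limitations

- The NB-LRT uses plug-in moderated dispersions, not an empirical-Bayes
  trend; its calibration is verified at the simulated conditions, and
  designs far from them (very low counts, single replicates) deserve a
  fresh look at the null rejection rate via `make_timecourse(pi = 0, ...)`.
- Summit-based annotation intentionally differs from any-overlap annotation
  tools; percentages are not comparable across conventions.
- bigWig is not written natively; bedGraph is the canonical track output.
- BAM is not parsed; fragments are expected as BED-like tables with a MAPQ
  column produced upstream.
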