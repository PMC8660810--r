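# Hand-built toy genome: three genes on one chromosome, classes derived by
# hand before coding.
#   gA: + strand, span [10000, 16000), TSS 10000, exons [10000,11000) and
#       [14000,16000), CDS [10500, 15500)
#   gB: - strand, span [30000, 36000), TSS 35999, single exon = span,
#       CDS [30500, 35500)
#   gC: + strand, span [50000, 51000), TSS 50000, exon = span, no CDS
toy_genes <- toy_gene_models(
  genes = data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr3", strand = c("+", "-", "+"),
    start = c(10000L, 30000L, 50000L), end = c(16000L, 36000L, 51000L),
    tss = c(10000L, 35999L, 50000L),
    cds_start = c(10500L, 30500L, NA), cds_end = c(15500L, 35500L, NA)),
  exons = data.frame(
    gene_id = c("gA", "gA", "gB", "gC"),
    chrom = "chr3",
    start = c(10000L, 14000L, 30000L, 50000L),
    end = c(11000L, 16000L, 36000L, 51000L)))

toy_peak <- function(summits) {
  data.frame(chrom = "chr3", start = summits - 50L, end = summits + 50L,
             summit = summits)
}

test_that("feature assignment matches the hand-derived toy truth", {
  summits <- c(
    9600L,   # 400 bp upstream of gA TSS -> promoter
    10200L,  # inside gA exon1, before CDS start, + strand -> 5'UTR
    15700L,  # inside gA exon2, past CDS end, + strand -> 3'UTR
    10700L,  # inside gA exon1 and CDS -> exon
    12000L,  # inside gA, between exons -> intron
    16500L,  # 500 bp past gA end, + strand -> downstream
    36200L,  # 201 bp upstream of gB TSS (- strand window) -> promoter
    30200L,  # gB exon before CDS on - strand -> 3'UTR
    40000L)  # nowhere near a gene -> distal intergenic
  fa <- assign_features(toy_peak(summits), toy_genes)
  expect_equal(as.character(fa$feature),
               c("promoter", "five_prime_utr", "three_prime_utr", "exon",
                 "intron", "downstream", "promoter", "three_prime_utr",
                 "distal_intergenic"))
  # class counts always partition the peak set
  expect_equal(sum(table(fa$feature)), length(summits))
})

test_that("promoter window is strand-aware and its boundary is closed", {
  # + strand TSS 10000: -500 -> 9500 in, 9499 out; +150 -> 10150 in, 10151 not promoter
  fa <- assign_features(toy_peak(c(9500L, 9499L, 10150L, 10151L)), toy_genes)
  expect_equal(as.character(fa$feature)[1:3],
               c("promoter", "distal_intergenic", "promoter"))
  expect_false(fa$feature[4] == "promoter")

  # degenerate (0, 0)-width window leaves the promoter class empty
  fa0 <- assign_features(toy_peak(c(9600L, 10000L)), toy_genes,
                         promoter_window = c(0, 0))
  expect_equal(sum(fa0$feature == "promoter"), 0L)
})

test_that("nearest gene minimizes TSS distance with lexicographic ties", {
  # equidistant between gA TSS (10000) and gB TSS (35999): midpoint 22999.5;
  # use 23000 -> dA = 13000, dB = 12999 -> gB; 22999 -> dA = 12999 -> tie? no.
  ng <- nearest_gene(toy_peak(c(10000L, 23000L)), toy_genes)
  expect_equal(ng$gene_id, c("gA", "gB"))
  expect_equal(ng$distance[1], 0)

  # construct an exact tie: TSSs at 10000 and 35999 have no integer midpoint;
  # add a toy pair with even separation instead
  tie_genes <- toy_gene_models(genes = data.frame(
    gene_id = c("gZ", "gY"), chrom = "chr3", strand = "+",
    start = c(1000L, 3000L), end = c(2000L, 4000L),
    tss = c(1000L, 3000L), cds_start = NA, cds_end = NA))
  ng2 <- nearest_gene(toy_peak(2000L), tie_genes)
  expect_equal(ng2$gene_id, "gY")   # lexicographically smaller of gY/gZ

  # signed distance is in gene orientation (negative upstream)
  ng3 <- nearest_gene(toy_peak(36500L), toy_genes)   # 501 bp upstream of gB
  expect_equal(ng3$distance, -501)

  # brute-force oracle on random placements
  set.seed(23)
  w <- make_world(n_peaks = 40, shared_frac = 0,
                  chrom_sizes = c(chrA = 150000L, chrB = 150000L), seed = 24)
  ng4 <- nearest_gene(w$peaks_a, w$genes)
  g <- w$genes$genes
  for (i in seq_len(nrow(w$peaks_a))) {
    gc <- g[g$chrom == w$peaks_a$chrom[i], ]
    d <- abs(w$peaks_a$summit[i] - gc$tss)
    expect_equal(abs(ng4$distance[i]), min(d))
  }
})

test_that("randomized background conserves lengths and is seed-reproducible", {
  set.seed(25)
  cs <- c(chrA = 100000L, chrB = 60000L)
  p <- random_peak_set(200, cs)
  b1 <- randomized_background(p, cs, seed = 5)
  b2 <- randomized_background(p, cs, seed = 5)
  expect_identical(b1, b2)
  expect_equal(sort(b1$end - b1$start), sort(p$end - p$start))
  expect_equal(table(b1$chrom), table(p$chrom))
  expect_true(all(b1$start >= 0 & b1$end <= cs[as.character(b1$chrom)]))

  long <- data.frame(chrom = "chrB", start = 0L, end = 70000L)
  expect_error(randomized_background(long, cs), "longer than")
})

test_that("background promoter fraction matches the toy genome geometry", {
  # one chromosome, promoters cover a known bp fraction; randomized summits
  # are uniform, so the promoter fraction has a closed-form expectation
  cs <- c(chr3 = 60000L)
  set.seed(26)
  p <- data.frame(chrom = "chr3", start = sample(0:59800, 2000, replace = TRUE))
  p$end <- p$start + 1L   # point summits make geometry exact
  p$summit <- p$start
  bg <- randomized_background(p, cs, seed = 7)
  fa <- assign_features(bg, toy_genes)
  # promoter windows: gA [9500,10150], gB [35849,36499], gC [49500,50150]
  prom_bp <- 3 * 651
  expected <- prom_bp / 60000
  phat <- mean(fa$feature == "promoter")
  se <- sqrt(expected * (1 - expected) / 2000)
  expect_lt(abs(phat - expected), 4 * se)
})

test_that("peaks planted at TSSs are all classified as promoters", {
  g <- toy_genes$genes
  fa <- assign_features(toy_peak(g$tss), toy_genes)
  expect_true(all(fa$feature == "promoter"))
})

test_that("category enrichment reproduces exact Fisher results", {
  flat <- category_enrichment(10, 10, 10, 10)
  expect_equal(flat$odds.ratio, 1.0)
  expect_equal(flat$p.value, 1.0)

  sep <- category_enrichment(5, 0, 0, 5)
  expect_equal(sep$p.value, 2 / 252, tolerance = 1e-12)
  expect_gt(sep$odds.ratio, 1)   # Haldane-corrected, finite

  expect_error(category_enrichment(-1, 2, 3, 4), "negative")
})
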