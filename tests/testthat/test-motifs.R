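test_that("motif_pattern validates the IUPAC alphabet", {
  expect_s3_class(motif_pattern("Zld", "CAGGTARV"), "motif_pattern")
  expect_error(motif_pattern("bad", "CAGGTAX"), "invalid IUPAC")
  expect_error(motif_pattern("empty", ""), "empty")
})

test_that("find_matches handles literal, reverse-strand and degenerate matches", {
  zld <- motif_pattern("Zld", "CAGGTAG")
  m <- find_matches(zld, "ACAGGTAGT")
  expect_equal(m$start, 1L)
  expect_equal(m$strand, "+")

  # CTACCTG = revcomp(CAGGTAG) embedded at position 1
  m2 <- find_matches(zld, "ACTACCTGT")
  expect_equal(m2$start, 1L)
  expect_equal(m2$strand, "-")
  expect_equal(nrow(find_matches(zld, "ACTACCTGT", both_strands = FALSE)), 0L)

  deg <- motif_pattern("Zld_deg", "CAGGTARV")
  expect_equal(find_matches(deg, "CAGGTAGA", both_strands = FALSE)$start, 0L)
  expect_equal(nrow(find_matches(deg, "CAGGTATA", both_strands = FALSE)), 0L)

  # N in the sequence matches nothing, not even pattern N
  nn <- motif_pattern("anyN", "CANG")
  expect_equal(nrow(find_matches(nn, "CANG", both_strands = FALSE)), 0L)
  expect_equal(find_matches(nn, "CATG", both_strands = FALSE)$start, 0L)

  # overlapping matches are all reported
  aa <- motif_pattern("run", "AA")
  expect_equal(find_matches(aa, "AAAA", both_strands = FALSE)$start, 0:2)
})

test_that("scanner equals regex and positional brute-force oracles", {
  set.seed(13)
  motifs <- default_motifs()
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    for (mo in motifs) {
      got <- find_matches(mo, s)
      expect_equal(got, oracle_find_matches(mo$iupac, s),
                   ignore_attr = TRUE)
      expect_equal(got$start[got$strand == "+"],
                   oracle_scan_positions(mo$iupac, s))
    }
  }
})

test_that("reverse-complement symmetry of matching", {
  set.seed(14)
  rc_seq <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
    mo <- motif_pattern("Zld_deg", "CAGGTARV")
    m <- nchar(mo$iupac)
    fwd <- find_matches(mo, s)
    rc <- motif_pattern("rc", reverse_complement(mo$iupac))
    flip <- find_matches(rc, rc_seq(s))
    # a + match of P at p on S reads as a + match of revcomp(P) at
    # n - p - m on revcomp(S); - matches map to - matches likewise
    expect_setequal(nchar(s) - fwd$start[fwd$strand == "+"] - m,
                    flip$start[flip$strand == "+"])
    expect_setequal(nchar(s) - fwd$start[fwd$strand == "-"] - m,
                    flip$start[flip$strand == "-"])
  }
})

test_that("region tallies require full containment and recover planted truth", {
  mo <- motif_pattern("Zld", "CAGGTAG")
  genome <- c(chrM = paste0(strrep("T", 50), "CAGGTAG", strrep("T", 43)))
  expect_equal(count_regions_with_motif(
    mo, data.frame(chrom = character(), start = integer(), end = integer()),
    genome)$count, 0L)
  # fully inside vs straddling the region edge
  r_in <- data.frame(chrom = "chrM", start = 45L, end = 60L)
  r_straddle <- data.frame(chrom = "chrM", start = 40L, end = 55L)
  expect_equal(count_regions_with_motif(mo, r_in, genome)$count, 1L)
  expect_equal(count_regions_with_motif(mo, r_straddle, genome)$count, 0L)

  # monotone under region extension
  set.seed(15)
  w <- make_world(n_peaks = 120, shared_frac = 0.4, motif_rate = 0.5,
                  chrom_sizes = c(chrA = 250000L, chrB = 250000L), seed = 16)
  base <- count_regions_with_motif(w$motif, w$peaks_a, w$genome)$positive
  ext <- w$peaks_a
  ext$start <- pmax(ext$start - 150L, 0L); ext$end <- ext$end + 150L
  extp <- count_regions_with_motif(w$motif, ext, w$genome)$positive
  expect_true(all(extp >= base))

  # planted ground truth recovered exactly over summit windows
  mlen <- nchar(w$motif$iupac)
  win <- data.frame(chrom = w$peaks_a$chrom,
                    start = pmax(w$peaks_a$summit - 200L, 0L),
                    end = w$peaks_a$summit + 200L + mlen)
  cr <- count_regions_with_motif(w$motif, win, w$genome)
  expect_identical(cr$positive, w$peaks_a$motif)
  expect_equal(cr$count, sum(w$peaks_a$motif))
})

test_that("motif_near_summit applies a closed +/- window on match starts", {
  mo <- motif_pattern("Zld", "CAGGTA")
  mk_genome <- function(at, n = 2000L) {
    s <- strrep("T", n)
    substr(s, at + 1L, at + 6L) <- "CAGGTA"
    c(chrW = s)
  }
  pk <- peak_row("chrW", 900L, 1100L, summit = 1000L)
  expect_true(motif_near_summit(mo, pk, mk_genome(1200L)))    # start = +200
  expect_false(motif_near_summit(mo, pk, mk_genome(1201L)))   # start = +201
  expect_true(motif_near_summit(mo, pk, mk_genome(800L)))     # start = -200
  expect_false(motif_near_summit(mo, pk, mk_genome(799L)))

  w <- make_world(n_peaks = 100, shared_frac = 0.3, motif_rate = 0.5,
                  chrom_sizes = c(chrA = 250000L, chrB = 250000L), seed = 17)
  expect_identical(unname(motif_near_summit(w$motif, w$peaks_a, w$genome)),
                   w$peaks_a$motif)
  expect_identical(unname(motif_near_summit(w$motif, w$peaks_b, w$genome)),
                   w$peaks_b$motif)
})

test_that("rank-binned fractions partition correctly and track planted gradients", {
  set.seed(18)
  # partition arithmetic: 250 peaks -> bins of 100, 100, 50
  genome <- c(chrQ = paste(sample(c("A", "C", "G", "T"), 60000, replace = TRUE),
                           collapse = ""))
  s <- seq(300, 59000, length.out = 250)
  p <- data.frame(chrom = "chrQ", start = as.integer(s) - 50L,
                  end = as.integer(s) + 50L, summit = as.integer(s),
                  zscore = rnorm(250))
  tb <- rank_binned_fraction(p, list(motif_pattern("Zld", "CAGGTAG")), genome)
  expect_equal(tb$n_peaks, c(100L, 100L, 50L))
  expect_equal(sum(tb$n_peaks), 250L)
  expect_true(all(tb$Zld >= 0 & tb$Zld <= 1))

  # every peak contains the motif -> all fractions 1
  genome_all <- c(chrQ = paste(rep("CAGGTAG", 9000), collapse = ""))
  tb1 <- rank_binned_fraction(p, list(motif_pattern("Zld", "CAGGTAG")),
                              genome_all)
  expect_true(all(tb1$Zld == 1))

  # planted rank-dependent gradient decays monotonically (Spearman)
  w <- make_world(n_peaks = 1000, shared_frac = 0, motif_rate = c(0.9, 0.05),
                  chrom_sizes = c(chrA = 1200000L, chrB = 1200000L), seed = 19)
  pk <- extend_summits(w$peaks_a, 200L + nchar(w$motif$iupac), w$chrom_sizes)
  tb2 <- rank_binned_fraction(pk, list(w$motif), w$genome, bin_size = 100L)
  rho <- cor(tb2$bin, tb2$Zld_core, method = "spearman")
  expect_lt(rho, -0.8)
})
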