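FEATURE_CLASSES <- c("promoter", "five_prime_utr", "three_prime_utr",
                     "exon", "intron", "downstream", "distal_intergenic")

# strand-aware promoter window [tss + win[1], tss + win[2]] in gene
# orientation, as closed genomic coordinates
promoter_span <- function(tss, strand, win) {
  if (strand == "-") c(tss - win[2], tss - win[1]) else c(tss + win[1], tss + win[2])
}

#' Assign peaks to genomic feature classes
#'
#' Classifies each peak by its summit position with the fixed priority
#' promoter > 5'UTR > 3'UTR > exon > intron > downstream > distal intergenic,
#' so every peak lands in exactly one class. The promoter test is
#' strand-aware: the summit must fall in `[TSS - 500, TSS + 150]` in gene
#' orientation at the defaults. UTR classes require CDS annotation in the
#' gene models; "downstream" means within `downstream_max` bp past the gene's
#' 3' end.
#'
#' @param peaks peak data frame with `summit`.
#' @param genes a `gene_models` object from [read_gtf_genes()] (or the
#'   synthetic generator).
#' @param promoter_window numeric(2), bp relative to the TSS in gene
#'   orientation (default `c(-500, 150)`).
#' @param downstream_max bp past the gene 3' end still called "downstream"
#'   (default 1000).
#' @return data frame, one row per peak: `feature` (factor over the seven
#'   classes), `gene_id` and `distance` of the nearest gene (signed, in gene
#'   orientation, negative upstream of the TSS).
#' @export
assign_features <- function(peaks, genes, promoter_window = c(-500, 150),
                            downstream_max = 1000L) {
  validate_peaks(peaks)
  g <- genes$genes
  if (!nrow(g)) stop("gene models are empty", call. = FALSE)
  ex <- genes$exons
  feature <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    s <- peaks$summit[i]
    ch <- as.character(peaks$chrom[i])
    gc <- g[g$chrom == ch, , drop = FALSE]
    if (!nrow(gc)) { feature[i] <- "distal_intergenic"; next }
    # promoter
    spans <- vapply(seq_len(nrow(gc)), function(j)
      promoter_span(gc$tss[j], gc$strand[j], promoter_window), numeric(2))
    in_prom <- s >= spans[1, ] & s <= spans[2, ] &
      promoter_window[2] > promoter_window[1]
    if (any(in_prom)) { feature[i] <- "promoter"; next }
    in_gene <- s >= gc$start & s < gc$end
    exc <- ex[ex$chrom == ch & ex$gene_id %in% gc$gene_id[in_gene], , drop = FALSE]
    in_exon <- nrow(exc) && any(s >= exc$start & s < exc$end)
    if (in_exon) {
      # UTR classes: inside an exon but outside the CDS span, 5' vs 3' by
      # gene orientation
      utr5 <- utr3 <- FALSE
      for (j in which(in_gene)) {
        if (is.na(gc$cds_start[j])) next
        exj <- exc[exc$gene_id == gc$gene_id[j], , drop = FALSE]
        if (!nrow(exj) || !any(s >= exj$start & s < exj$end)) next
        if (s < gc$cds_start[j]) {
          if (gc$strand[j] == "-") utr3 <- TRUE else utr5 <- TRUE
        } else if (s >= gc$cds_end[j]) {
          if (gc$strand[j] == "-") utr5 <- TRUE else utr3 <- TRUE
        }
      }
      feature[i] <- if (utr5) "five_prime_utr" else if (utr3) "three_prime_utr" else "exon"
      next
    }
    if (any(in_gene)) { feature[i] <- "intron"; next }
    # downstream: within downstream_max past the 3' end, strand-aware
    down <- ifelse(gc$strand == "-",
                   s < gc$start & s >= gc$start - downstream_max,
                   s >= gc$end & s < gc$end + downstream_max)
    feature[i] <- if (any(down)) "downstream" else "distal_intergenic"
  }
  ng <- nearest_gene(peaks, genes)
  data.frame(feature = factor(feature, levels = FEATURE_CLASSES),
             gene_id = ng$gene_id, distance = ng$distance)
}

#' Nearest-gene assignment by TSS distance
#'
#' Assigns each peak the gene whose TSS is closest to the peak summit
#' (`|summit - TSS|` minimized; ties broken by the lexicographically smaller
#' `gene_id`). The reported distance is signed in gene orientation: negative
#' when the summit is upstream of the TSS.
#'
#' @param peaks peak data frame with `summit`.
#' @param genes a `gene_models` object.
#' @return data frame with `gene_id` (`NA` on chromosomes without genes) and
#'   signed `distance`.
#' @export
nearest_gene <- function(peaks, genes) {
  validate_peaks(peaks)
  g <- genes$genes
  gene_id <- rep(NA_character_, nrow(peaks))
  distance <- rep(NA_real_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    gc <- g[g$chrom == as.character(peaks$chrom[i]), , drop = FALSE]
    if (!nrow(gc)) next
    d <- abs(peaks$summit[i] - gc$tss)
    cand <- which(d == min(d))
    j <- cand[order(gc$gene_id[cand])][1]
    gene_id[i] <- gc$gene_id[j]
    raw <- peaks$summit[i] - gc$tss[j]
    distance[i] <- if (gc$strand[j] == "-") -raw else raw
  }
  data.frame(gene_id = gene_id, distance = distance)
}

#' Randomize peak placement for background comparison
#'
#' Places each region uniformly at random on its original chromosome,
#' preserving the number and lengths of the input regions, to provide the
#' randomized-genome background for feature-class enrichment.
#'
#' @param peaks interval data frame.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param seed integer seed for reproducibility (optional).
#' @return interval data frame of the randomized regions, with summits set to
#'   the region midpoint.
#' @export
randomized_background <- function(peaks, chrom_sizes, seed = NULL) {
  validate_intervals(peaks)
  unknown <- setdiff(unique(as.character(peaks$chrom)), names(chrom_sizes))
  if (length(unknown)) {
    stop("peaks on unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  len <- peaks$end - peaks$start
  maxstart <- chrom_sizes[as.character(peaks$chrom)] - len
  if (any(maxstart < 0)) {
    stop("a region is longer than its chromosome", call. = FALSE)
  }
  start <- floor(runif(nrow(peaks), 0, maxstart + 1))
  start <- pmin(as.integer(start), as.integer(maxstart))
  out <- data.frame(chrom = peaks$chrom, start = start, end = start + len)
  out$summit <- out$start + len %/% 2L
  out
}

#' Enrichment of a feature category against a background
#'
#' Tests whether a category (e.g. promoters) is enriched among observed peaks
#' relative to a background set, via a 2x2 Fisher's exact test on
#' in-category/out-of-category counts.
#'
#' @param observed_in,observed_out counts of observed peaks inside/outside
#'   the category.
#' @param background_in,background_out same for the background regions.
#' @return list with `odds.ratio` (sample OR, Haldane-corrected when a cell
#'   is 0), `p.value` (two-sided exact), and the underlying `table`.
#' @export
category_enrichment <- function(observed_in, observed_out,
                                background_in, background_out) {
  counts <- c(observed_in, observed_out, background_in, background_out)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  tab <- rbind(c(observed_in, observed_out),
               c(background_in, background_out))
  ft <- fisher_exact_two_sided(tab)
  list(odds.ratio = ft$odds.ratio, p.value = ft$p.value, table = tab)
}
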