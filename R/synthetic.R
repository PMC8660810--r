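#' Trajectory archetype mean shapes
#'
#' The six canonical accessibility time-course shapes over the five
#' timepoints (0, 6, 12, 18, 24 h): early/late/transient increase and
#' early/late/transient loss. Values are relative accessibility levels
#' (low = 0.3, high = 1.0); the early-loss shape, for example, is
#' (1, 0.4, 0.3, 0.3, 0.3).
#'
#' @return 6 x 5 numeric matrix, one archetype per row, columns named by
#'   timepoint.
#' @export
trajectory_archetypes <- function() {
  m <- rbind(
    early_increase     = c(0.3, 0.9, 1.0, 1.0, 1.0),
    late_increase      = c(0.3, 0.3, 0.3, 0.4, 1.0),
    transient_increase = c(0.3, 0.9, 1.0, 0.4, 0.3),
    early_loss         = c(1.0, 0.4, 0.3, 0.3, 0.3),
    late_loss          = c(1.0, 1.0, 1.0, 0.9, 0.3),
    transient_loss     = c(1.0, 0.4, 0.3, 0.9, 1.0))
  colnames(m) <- c(0, 6, 12, 18, 24)
  m
}

# draw one concrete instance of an IUPAC pattern
sample_motif_instance <- function(iupac) {
  chars <- strsplit(iupac, "")[[1]]
  paste(vapply(chars, function(ch) {
    cls <- IUPAC_CLASSES[[ch]]
    cls[sample.int(length(cls), 1)]
  }, ""), collapse = "")
}

random_dna <- function(n, gc = 0.43) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a ground-truth-labelled synthetic world
#'
#' Builds a small genome with gene models and two condition-specific peak
#' sets whose shared fraction, per-peak motif status and peak ranking are
#' known exactly, so every downstream analysis can be checked against the
#' generator's truth. Shared peaks are emitted as pairs with at least 10 bp
#' of mutual overlap; unique peaks have zero overlap with the other set.
#' Motif-positive peaks carry at least one planted occurrence of the motif
#' within 200 bp of the summit; motif-negative peak neighborhoods are
#' rejection-sampled until they contain no occurrence on either strand (so
#' base composition stays realistic).
#'
#' @param n_peaks peaks per condition (default 500).
#' @param shared_frac fraction of each set planted as shared, in `[0, 1]`
#'   (default 0.4).
#' @param chrom_sizes named integer vector (default two 500-kb chromosomes).
#' @param gc genome GC content (default 0.43).
#' @param n_genes number of genes (default 60).
#' @param peak_width width of emitted peak regions in bp (default 200).
#' @param motif [motif_pattern()] planted in motif-positive peaks (default
#'   the canonical core motif, CAGGTA).
#' @param motif_rate either a single probability, or `c(hi, lo)` for a
#'   rank-dependent gradient: the motif probability decays linearly from `hi`
#'   at the highest-ranked peak to `lo` at the lowest (per condition).
#' @param min_spacing minimum distance between planted peak entities in bp
#'   (default 1000).
#' @param seed integer seed; the world is deterministic given the seed.
#' @return object of class `synthetic_world`: list with `genome` (named
#'   character), `chrom_sizes`, `genes` (a `gene_models`), `peaks_a`,
#'   `peaks_b` (peak data frames with truth columns `shared` and `motif` and
#'   a planted descending `zscore`), `motif`, and `params`.
#' @export
make_world <- function(n_peaks = 500L, shared_frac = 0.4,
                       chrom_sizes = c(chr2L = 500000L, chr2R = 500000L),
                       gc = 0.43, n_genes = 60L, peak_width = 200L,
                       motif = motif_pattern("Zld_core", "CAGGTA"),
                       motif_rate = 0.4, min_spacing = 1000L, seed = 1L) {
  stopifnot(shared_frac >= 0, shared_frac <= 1, n_peaks >= 1)
  set.seed(seed)
  n_shared <- round(shared_frac * n_peaks)
  n_unique <- n_peaks - n_shared
  n_slots <- n_shared + 2L * n_unique
  margin <- 2000L
  slot_cap <- sum(pmax(0L, (chrom_sizes - 2L * margin) %/% min_spacing))
  if (n_slots > slot_cap) {
    stop("genome too small for ", n_slots, " peak entities at ",
         min_spacing, " bp spacing (capacity ", slot_cap, ")", call. = FALSE)
  }
  # lay out entity anchor positions, evenly spread then jittered
  anchors <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n_ch <- (chrom_sizes[[ch]] - 2L * margin) %/% min_spacing
    data.frame(chrom = ch,
               pos = margin + (seq_len(n_ch) - 1L) * min_spacing +
                 sample.int(min_spacing %/% 4L, n_ch, replace = TRUE))
  }))
  anchors <- anchors[sort(sample.int(nrow(anchors), n_slots)), , drop = FALSE]
  kind <- sample(rep(c("shared", "unique_a", "unique_b"),
                     c(n_shared, n_unique, n_unique)))

  build_peak <- function(chrom, start, shared, pair) {
    data.frame(chrom = chrom, start = start, end = start + peak_width,
               summit = start + peak_width %/% 2L, shared = shared,
               pair_id = pair)
  }
  pa <- list(); pb <- list()
  for (i in seq_len(n_slots)) {
    ch <- anchors$chrom[i]; p <- anchors$pos[i]
    if (kind[i] == "shared") {
      # overlap in [10, width - 10] keeps the two summits >= 10 bp apart so
      # discordant motif flags remain plantable
      ov <- sample(10:(peak_width - 10L), 1)
      pa[[length(pa) + 1L]] <- build_peak(ch, p, TRUE, i)
      pb[[length(pb) + 1L]] <- build_peak(ch, p + peak_width - ov, TRUE, i)
    } else if (kind[i] == "unique_a") {
      pa[[length(pa) + 1L]] <- build_peak(ch, p, FALSE, NA_integer_)
    } else {
      pb[[length(pb) + 1L]] <- build_peak(ch, p, FALSE, NA_integer_)
    }
  }
  finish_set <- function(lst, label) {
    d <- do.call(rbind, lst)
    d <- d[order(d$chrom, d$start), , drop = FALSE]
    # planted ranking signal: strictly decreasing z score over a random order
    rank_order <- sample.int(nrow(d))
    d$zscore <- NA_real_
    d$zscore[rank_order] <- sort(rexp(nrow(d), rate = 0.5) + 0.1,
                                 decreasing = TRUE)
    d$score <- d$zscore * 10
    d$name <- sprintf("%s_peak_%04d", label, seq_len(nrow(d)))
    rownames(d) <- NULL
    d
  }
  peaks_a <- finish_set(pa, "A")
  peaks_b <- finish_set(pb, "B")

  # motif truth: probability per peak, constant or decaying with z-score rank
  motif_prob <- function(d) {
    r <- rank(-d$zscore, ties.method = "first")
    if (length(motif_rate) == 2L) {
      motif_rate[1] + (motif_rate[2] - motif_rate[1]) * (r - 1) / max(nrow(d) - 1, 1)
    } else {
      rep(motif_rate, nrow(d))
    }
  }
  peaks_a$motif <- runif(nrow(peaks_a)) < motif_prob(peaks_a)
  peaks_b$motif <- runif(nrow(peaks_b)) < motif_prob(peaks_b)

  genome <- setNames(
    vapply(names(chrom_sizes), function(ch) random_dna(chrom_sizes[[ch]], gc),
           ""),
    names(chrom_sizes))

  # plant / scrub motif occurrences around each summit (window +/- 200 bp).
  # A shared pair's windows overlap, so each entity (unique peak or pair) is
  # handled jointly: scrub the combined neighborhood of all occurrences,
  # plant required instances at positions admissible for exactly the desired
  # windows, then verify every flag and retry on any chance interference.
  window <- 200L
  mlen <- nchar(motif$iupac)
  plant_entity <- function(genome, ch, summits, flags, span) {
    lo <- pmax(summits - window, 0L)
    hi <- pmin(summits + window, nchar(genome[[ch]]) - mlen)
    rlo <- min(lo, span[1])
    rhi <- max(hi + mlen, span[2])
    for (attempt in 1:200) {
      s <- substr(genome[[ch]], rlo + 1L, rhi)
      hits <- rlo + find_matches(motif, s)$start
      if (!length(hits)) {
        for (w in which(flags)) {
          admissible <- lo[w]:hi[w]
          for (o in which(!flags)) {
            admissible <- setdiff(admissible, lo[o]:hi[o])
          }
          at <- admissible[sample.int(length(admissible), 1)]
          substr(genome[[ch]], at + 1L, at + mlen) <-
            sample_motif_instance(motif$iupac)
        }
        s <- substr(genome[[ch]], rlo + 1L, rhi)
        hits <- rlo + find_matches(motif, s)$start
        now <- vapply(seq_along(summits), function(w) {
          any(hits >= lo[w] & hits <= summits[w] + window)
        }, logical(1))
        if (identical(now, flags)) return(genome)
      }
      substr(genome[[ch]], rlo + 1L, rhi) <- random_dna(rhi - rlo, gc)
    }
    stop("motif planting did not converge", call. = FALSE)
  }
  for (i in which(!peaks_a$shared)) {
    genome <- plant_entity(genome, as.character(peaks_a$chrom[i]),
                           peaks_a$summit[i], peaks_a$motif[i],
                           c(peaks_a$start[i], peaks_a$end[i]))
  }
  for (i in which(!peaks_b$shared)) {
    genome <- plant_entity(genome, as.character(peaks_b$chrom[i]),
                           peaks_b$summit[i], peaks_b$motif[i],
                           c(peaks_b$start[i], peaks_b$end[i]))
  }
  for (pid in peaks_a$pair_id[peaks_a$shared]) {
    ia <- which(peaks_a$pair_id %in% pid)
    ib <- which(peaks_b$pair_id %in% pid)
    genome <- plant_entity(
      genome, as.character(peaks_a$chrom[ia]),
      c(peaks_a$summit[ia], peaks_b$summit[ib]),
      c(peaks_a$motif[ia], peaks_b$motif[ib]),
      c(min(peaks_a$start[ia], peaks_b$start[ib]),
        max(peaks_a$end[ia], peaks_b$end[ib])))
  }
  peaks_a$pair_id <- NULL
  peaks_b$pair_id <- NULL

  genes <- make_gene_models(n_genes, chrom_sizes)

  structure(list(genome = genome, chrom_sizes = chrom_sizes, genes = genes,
                 peaks_a = peaks_a, peaks_b = peaks_b, motif = motif,
                 params = list(n_peaks = n_peaks, shared_frac = shared_frac,
                               gc = gc, n_genes = n_genes,
                               peak_width = peak_width,
                               motif_rate = motif_rate,
                               min_spacing = min_spacing, seed = seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", sum(nchar(x$genome)), "bp genome,",
      nrow(x$genes$genes), "genes,",
      nrow(x$peaks_a), "+", nrow(x$peaks_b), "peaks (shared fraction",
      x$params$shared_frac, ")\n")
  invisible(x)
}

# simple gene models: fixed structure, two exons with an internal CDS span
make_gene_models <- function(n_genes, chrom_sizes) {
  glen <- 3000L
  per_chrom <- diff(round(seq(0, n_genes, length.out = length(chrom_sizes) + 1)))
  genes <- list(); exons <- list()
  gi <- 0L
  for (ci in seq_along(chrom_sizes)) {
    ch <- names(chrom_sizes)[ci]
    n_ch <- per_chrom[ci]
    if (!n_ch) next
    starts <- sort(sample.int(chrom_sizes[[ci]] - glen - 1L, n_ch))
    for (s in starts) {
      gi <- gi + 1L
      id <- sprintf("gene%03d", gi)
      strand <- sample(c("+", "-"), 1)
      genes[[gi]] <- data.frame(
        gene_id = id, chrom = ch, strand = strand, start = s, end = s + glen,
        tss = if (strand == "-") s + glen - 1L else s,
        cds_start = s + 400L, cds_end = s + 2600L)
      exons[[length(exons) + 1L]] <- data.frame(
        gene_id = id, chrom = ch,
        start = c(s, s + 2200L), end = c(s + 800L, s + glen))
    }
  }
  structure(list(genes = do.call(rbind, genes), exons = do.call(rbind, exons)),
            class = "gene_models")
}

#' Generate synthetic ATAC-style fragments
#'
#' Draws fragment lengths from a two-component normal mixture
#' (`f * N(60, 15) + (1 - f) * N(200, 25)`, truncated to `[20, 500]` bp),
#' places fragments with Poisson background across the genome and a planted
#' enrichment rate ratio `rho` inside the given peaks, and assigns mapping
#' qualities with a stated low-quality fraction.
#'
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param peaks interval data frame of enriched regions (may be empty when
#'   `rho = 1`).
#' @param depth number of fragments to draw.
#' @param nfr_frac mixture weight `f` of the nucleosome-free (short)
#'   component (default 0.6).
#' @param rho enrichment rate ratio inside peaks vs background (default 5).
#' @param mapq_low_frac fraction of fragments drawn with MAPQ <= 30
#'   (default 0.1).
#' @param peak_weights optional positive per-peak relative enrichment
#'   strengths (default equal); weights shape how the enrichment component is
#'   shared among peaks, giving peaks heterogeneous signal as in real data.
#' @param seed integer seed (optional).
#' @return fragment data frame: `chrom`, `start`, `end`, `mapq`, plus truth
#'   columns `nfr` (drawn from the short component) and `in_peak` (placed by
#'   the enrichment component).
#' @export
make_fragments <- function(chrom_sizes, peaks = NULL, depth = 10000L,
                           nfr_frac = 0.6, rho = 5, mapq_low_frac = 0.1,
                           peak_weights = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (depth == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      mapq = integer(), nfr = logical(), in_peak = logical()))
  }
  # truncated-normal lengths by rejection
  nfr <- runif(depth) < nfr_frac
  draw_len <- function(n, mu, sdv) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, mu, sdv)
      out <- c(out, x[x >= 20 & x <= 500])
    }
    round(out[seq_len(n)])
  }
  len <- integer(depth)
  len[nfr] <- draw_len(sum(nfr), 60, 15)
  len[!nfr] <- draw_len(sum(!nfr), 200, 25)

  genome_bp <- sum(as.numeric(chrom_sizes))
  peak_bp <- if (is.null(peaks) || !nrow(peaks)) 0 else sum(peaks$end - peaks$start)
  w_enrich <- if (peak_bp > 0) {
    (rho - 1) * peak_bp / ((rho - 1) * peak_bp + genome_bp)
  } else 0
  in_peak <- runif(depth) < w_enrich
  mid <- numeric(depth)
  chrom <- character(depth)
  n_bg <- sum(!in_peak)
  if (n_bg) {
    pos <- floor(runif(n_bg, 0, genome_bp))
    brk <- cumsum(as.numeric(chrom_sizes))
    offs <- c(0, head(brk, -1))
    ci <- findInterval(pos, offs)                 # chromosome index
    chrom[!in_peak] <- names(chrom_sizes)[ci]
    mid[!in_peak] <- pos - offs[ci]
  }
  if (any(in_peak)) {
    widths <- peaks$end - peaks$start
    wts <- peak_weights %||% rep(1, nrow(peaks))
    pk <- sample.int(nrow(peaks), sum(in_peak), replace = TRUE,
                     prob = widths * wts)
    chrom[in_peak] <- as.character(peaks$chrom[pk])
    mid[in_peak] <- peaks$start[pk] + floor(runif(sum(in_peak), 0, widths[pk]))
  }
  start <- pmax(0, pmin(round(mid - len / 2),
                        chrom_sizes[chrom] - len))
  low <- runif(depth) < mapq_low_frac
  mapq <- integer(depth)
  mapq[low] <- sample(0:30, sum(low), replace = TRUE)
  mapq[!low] <- sample(31:60, sum(!low), replace = TRUE)
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + len), mapq = mapq,
             nfr = nfr, in_peak = in_peak, row.names = NULL)
}

#' Generate a synthetic accessibility time course
#'
#' Emits a region-by-sample negative-binomial count matrix over the five
#' timepoints (0, 6, 12, 18, 24 h) in which a fraction `pi` of regions follow
#' one of the six trajectory archetypes (scaled to mean 1 so the baseline
#' level is comparable across archetypes) and the rest are flat, together
#' with the per-region truth labels.
#'
#' @param n_regions number of regions (default 2000).
#' @param pi fraction of truly changing regions in `[0, 1]` (default 0.3).
#' @param mu baseline mean count per replicate (default 50).
#' @param alpha negative-binomial dispersion (variance `mu + alpha * mu^2`);
#'   `alpha = 0` gives Poisson counts (default 0.1).
#' @param reps replicates per timepoint (default 2).
#' @param sf per-sample size factors (default all 1).
#' @param archetype_mix relative weights of the six archetypes among changing
#'   regions (default equal).
#' @param seed integer seed (optional).
#' @return list with `counts` (a `count_matrix`) and `truth` (data frame:
#'   `region`, `archetype` — `"null"` for flat regions — and `changing`).
#' @export
make_timecourse <- function(n_regions = 2000L, pi = 0.3, mu = 50, alpha = 0.1,
                            reps = 2L, sf = NULL, archetype_mix = NULL,
                            seed = NULL) {
  stopifnot(pi >= 0, pi <= 1)
  if (!is.null(seed)) set.seed(seed)
  arch <- trajectory_archetypes()
  arch <- arch / rowMeans(arch)          # scale shapes to mean 1
  tps <- as.numeric(colnames(arch))
  n_samp <- length(tps) * reps
  sample_tp <- rep(tps, each = reps)
  if (is.null(sf)) sf <- rep(1, n_samp)
  mix <- archetype_mix %||% rep(1, nrow(arch))
  n_change <- round(pi * n_regions)
  # deterministic split of the changing regions across archetypes by weight
  alloc <- diff(round(cumsum(c(0, mix)) / sum(mix) * n_change))
  labels <- if (n_change) sample(rep(rownames(arch), alloc)) else character(0)
  labels <- c(labels, rep("null", n_regions - n_change))
  labels <- sample(labels)
  rel <- matrix(1, n_regions, length(tps))
  changing <- labels != "null"
  rel[changing, ] <- arch[labels[changing], , drop = FALSE]
  mu_mat <- mu * rel[, rep(seq_along(tps), each = reps)] *
    matrix(sf, n_regions, n_samp, byrow = TRUE)
  y <- if (alpha > 0) {
    rnbinom(length(mu_mat), size = 1 / alpha, mu = mu_mat)
  } else {
    rpois(length(mu_mat), mu_mat)
  }
  counts <- matrix(y, n_regions, n_samp,
                   dimnames = list(sprintf("region%05d", seq_len(n_regions)),
                                   sprintf("t%02g_rep%d", sample_tp,
                                           rep(seq_len(reps), length(tps)))))
  list(counts = new_count_matrix(counts, sample_tp,
                                 rep(seq_len(reps), length(tps))),
       truth = data.frame(region = rownames(counts), archetype = labels,
                          changing = changing))
}

#' Generate noisy trajectories drawn from the six archetypes
#'
#' Produces z-scored archetype trajectories with additive Gaussian noise —
#' the direct substrate for clustering-recovery checks.
#'
#' @param n_per regions per archetype (default 100).
#' @param noise_sd SD of the additive Gaussian noise on the z-scored
#'   trajectories (default 0.3).
#' @param seed integer seed (optional).
#' @return list with `trajectories` (matrix, `6 * n_per` x 5) and `labels`
#'   (archetype per row).
#' @export
make_trajectories <- function(n_per = 100L, noise_sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arch <- trajectory_archetypes()
  zarch <- t(apply(arch, 1, function(v) (v - mean(v)) / sd(v)))
  labels <- rep(rownames(arch), each = n_per)
  mat <- zarch[labels, , drop = FALSE] +
    matrix(rnorm(length(labels) * ncol(arch), 0, noise_sd),
           ncol = ncol(arch))
  rownames(mat) <- sprintf("traj%04d", seq_along(labels))
  list(trajectories = mat, labels = labels)
}

#' Generate a query/reference pair with an exact planted overlap rate
#'
#' Builds `n` query peaks of which exactly `round(rate * n)` overlap a
#' reference interval (by at least 1 bp) and the rest are disjoint from all
#' reference intervals.
#'
#' @param n number of query peaks.
#' @param rate fraction of query peaks overlapping the reference.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param width peak width in bp (default 200).
#' @param seed integer seed (optional).
#' @return list with `query` (peak data frame with truth column `overlaps`)
#'   and `reference` (interval data frame).
#' @export
make_overlap_sets <- function(n, rate, chrom_sizes, width = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacing <- 3L * width + 200L
  cap <- sum((chrom_sizes - 2L * width) %/% spacing)
  if (n > cap) stop("genome too small for ", n, " spaced peaks", call. = FALSE)
  anchors <- do.call(rbind, lapply(names(chrom_sizes), function(ch) {
    n_ch <- (chrom_sizes[[ch]] - 2L * width) %/% spacing
    data.frame(chrom = ch, pos = width + (seq_len(n_ch) - 1L) * spacing)
  }))
  anchors <- anchors[sort(sample.int(nrow(anchors), n)), , drop = FALSE]
  overlaps <- sample(rep(c(TRUE, FALSE), c(round(rate * n), n - round(rate * n))))
  query <- data.frame(chrom = anchors$chrom, start = anchors$pos,
                      end = anchors$pos + width,
                      summit = anchors$pos + width %/% 2L,
                      overlaps = overlaps)
  ref <- data.frame(chrom = anchors$chrom[overlaps],
                    start = anchors$pos[overlaps] + width %/% 2L,
                    end = anchors$pos[overlaps] + width + width %/% 2L)
  list(query = query, reference = ref)
}

#' Write a synthetic world to standard-format files
#'
#' Emits the genome (FASTA), gene models (GTF), both peak sets (narrowPeak)
#' and the truth table (TSV) into a directory, for exercising the file
#' readers on realistic inputs.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gtf"),
             peaks_a = file.path(dir, "peaks_a.narrowPeak"),
             peaks_b = file.path(dir, "peaks_b.narrowPeak"),
             truth = file.path(dir, "truth.tsv"),
             chrom_sizes = file.path(dir, "genome.chrom.sizes"))
  write_fasta(world$genome, paths["genome"])
  write_gtf(world$genes, paths["genes"])
  write_narrowpeak(world$peaks_a, paths["peaks_a"])
  write_narrowpeak(world$peaks_b, paths["peaks_b"])
  truth <- rbind(cbind(set = "A", world$peaks_a[, c("name", "shared", "motif")]),
                 cbind(set = "B", world$peaks_b[, c("name", "shared", "motif")]))
  write.table(truth, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(names(world$chrom_sizes), world$chrom_sizes),
              paths["chrom_sizes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  paths
}

#' Write peaks in narrowPeak format
#'
#' @param peaks peak data frame with `summit` and `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peaks(peaks)
  d <- data.frame(peaks$chrom, peaks$start, peaks$end,
                  peaks$name %||% paste0("peak", seq_len(nrow(peaks))),
                  0L, ".", peaks$score %||% 0, -1, -1,
                  peaks$summit - peaks$start)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write gene models in GTF format
#'
#' Internal 0-based half-open coordinates are converted back to GTF's 1-based
#' closed convention.
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  g <- genes$genes
  rows <- character(0)
  fmt <- function(chrom, feat, start0, end0, strand, id) {
    sprintf("%s\tsynthetic\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            chrom, feat, start0 + 1L, end0, strand, id)
  }
  for (i in seq_len(nrow(g))) {
    rows <- c(rows, fmt(g$chrom[i], "gene", g$start[i], g$end[i],
                        g$strand[i], g$gene_id[i]))
    ex <- genes$exons[genes$exons$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      rows <- c(rows, fmt(ex$chrom[j], "exon", ex$start[j], ex$end[j],
                          g$strand[i], g$gene_id[i]))
    }
    if (!is.na(g$cds_start[i])) {
      rows <- c(rows, fmt(g$chrom[i], "CDS", g$cds_start[i], g$cds_end[i],
                          g$strand[i], g$gene_id[i]))
    }
  }
  writeLines(rows, path)
  invisible(path)
}
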