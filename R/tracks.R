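#' Construct a binned coverage track
#'
#' A binned track stores one value per fixed-width genomic bin, per
#' chromosome. Bin `i` (0-based) covers `[i*bin_width, (i+1)*bin_width)`;
#' the final bin of each chromosome is implicitly clipped at the chromosome
#' length.
#'
#' @param values named list of numeric vectors, one per chromosome, each of
#'   length `ceiling(chrom_size / bin_width)`.
#' @param bin_width bin width in bp.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return object of class `binned_track`.
#' @export
binned_track <- function(values, bin_width, chrom_sizes) {
  stopifnot(is.list(values), !is.null(names(values)), bin_width >= 1)
  if (!setequal(names(values), names(chrom_sizes))) {
    stop("track chromosomes must match names(chrom_sizes)", call. = FALSE)
  }
  for (ch in names(values)) {
    expect_n <- as.integer(ceiling(chrom_sizes[[ch]] / bin_width))
    if (length(values[[ch]]) != expect_n) {
      stop("chromosome ", ch, ": expected ", expect_n, " bins, got ",
           length(values[[ch]]), call. = FALSE)
    }
    if (any(!is.finite(values[[ch]]))) {
      stop("chromosome ", ch, ": non-finite bin values", call. = FALSE)
    }
  }
  structure(list(values = values[names(chrom_sizes)],
                 bin_width = as.integer(bin_width),
                 chrom_sizes = chrom_sizes),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat("binned_track: bin_width", x$bin_width, "bp,",
      length(x$values), "chromosome(s),",
      sum(lengths(x$values)), "bins\n")
  invisible(x)
}

#' Bin fragment coverage across the genome
#'
#' Counts, for every fixed-width bin, the number of fragments overlapping the
#' bin by at least 1 bp. This is the count-based coverage the z-score
#' normalization operates on; at 10-bp bins it is indistinguishable in
#' practice from per-base averaging and has an exactly testable definition.
#'
#' @param fragments interval data frame (`chrom`, `start`, `end`).
#' @param bin_width bin width in bp (default 10).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return a [binned_track()] of integer-valued fragment-overlap counts.
#' @export
bin_coverage <- function(fragments, bin_width = 10L, chrom_sizes) {
  validate_intervals(fragments, "fragments")
  check_chroms(fragments, chrom_sizes, "fragments")
  vals <- lapply(names(chrom_sizes), function(ch) {
    n <- as.integer(ceiling(chrom_sizes[[ch]] / bin_width))
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (!nrow(f)) return(numeric(n))
    first <- f$start %/% bin_width                      # first bin overlapped
    last <- (f$end - 1L) %/% bin_width                  # last bin overlapped
    # difference-array accumulation: +1 at first bin, -1 past last bin
    delta <- numeric(n + 1L)
    inc <- tabulate(first + 1L, nbins = n + 1L)
    dec <- tabulate(last + 2L, nbins = n + 1L)
    head(cumsum(inc - dec), n)
  })
  binned_track(setNames(vals, names(chrom_sizes)), bin_width, chrom_sizes)
}

#' Z-score-normalize a coverage track genome-wide
#'
#' Standardizes bin values by subtracting the genome-wide mean bin coverage
#' and dividing by the genome-wide standard deviation, pooling all
#' chromosomes (zero bins included). The population standard deviation is
#' used; at genome scale it is indistinguishable from the sample SD and it
#' makes small worked examples exact. The result has mean 0 and SD 1 over all
#' bins and is an affine map of the input, so normalization is idempotent.
#'
#' @param track a [binned_track()].
#' @return a `binned_track` of z scores.
#' @export
zscore_normalize <- function(track) {
  stopifnot(inherits(track, "binned_track"))
  all_vals <- unlist(track$values, use.names = FALSE)
  if (length(all_vals) < 2L) stop("track must have >= 2 bins", call. = FALSE)
  mu <- mean(all_vals)
  sigma <- sqrt(mean((all_vals - mu)^2))
  if (sigma == 0) {
    stop("constant track: zero standard deviation, cannot z-normalize",
         call. = FALSE)
  }
  binned_track(lapply(track$values, function(v) (v - mu) / sigma),
               track$bin_width, track$chrom_sizes)
}

# mean track value over the bins overlapping [start, end); positions outside
# the chromosome contribute nothing
region_bin_mean <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  bw <- track$bin_width
  b0 <- max(start %/% bw, 0L)
  b1 <- min((end - 1L) %/% bw, length(v) - 1L)
  if (b1 < b0) return(NA_real_)
  mean(v[(b0 + 1L):(b1 + 1L)])
}

#' Annotate peaks with their mean z score
#'
#' The per-peak z score used for ranking is the mean of z-normalized bin
#' values over the bins overlapping the peak interval. Passing
#' `stat = "summit"` instead uses the single bin containing the summit.
#'
#' @param track a z-score-normalized [binned_track()].
#' @param peaks peak data frame (`chrom`, `start`, `end`, `summit`).
#' @param stat `"mean"` (region mean, default) or `"summit"` (summit bin).
#' @return `peaks` with a `zscore` column appended (or replaced).
#' @export
peak_zscores <- function(track, peaks, stat = c("mean", "summit")) {
  stopifnot(inherits(track, "binned_track"))
  validate_peaks(peaks)
  check_chroms(peaks, track$chrom_sizes, "peaks")
  stat <- match.arg(stat)
  z <- vapply(seq_len(nrow(peaks)), function(i) {
    ch <- as.character(peaks$chrom[i])
    if (stat == "summit") {
      b <- peaks$summit[i] %/% track$bin_width
      track$values[[ch]][b + 1L]
    } else {
      region_bin_mean(track, ch, peaks$start[i], peaks$end[i])
    }
  }, numeric(1))
  peaks$zscore <- z
  peaks
}

#' Build a summit-centered profile matrix
#'
#' Extracts, for each peak, the track bins covering
#' `[summit - flank, summit + flank)` and stacks them into a matrix of
#' `2 * flank / bin_width` columns (120 at the 600-bp / 10-bp defaults). Bins
#' falling outside the chromosome are filled with 0 and recorded in the
#' `clipped` attribute. Rows are ordered by the declared ranking.
#'
#' @param track a [binned_track()] (typically z-score normalized).
#' @param peaks peak data frame with `summit`; must carry the ranking column.
#' @param flank half-window around the summit in bp; must be a multiple of
#'   the track bin width.
#' @param order_by column of `peaks` used to rank rows in decreasing order
#'   (ties broken by `chrom`, `start`), or `NULL` to keep input order.
#' @return numeric matrix (peaks x bins) with attributes `offsets` (bp offset
#'   of each column's left edge from the summit), `peak_names`, and `clipped`
#'   (logical per row: any out-of-chromosome bin zero-filled).
#' @export
profile_matrix <- function(track, peaks, flank = 600L, order_by = "zscore") {
  stopifnot(inherits(track, "binned_track"))
  validate_peaks(peaks)
  bw <- track$bin_width
  if (flank %% bw != 0L) {
    stop("flank must be a multiple of the track bin width", call. = FALSE)
  }
  if (!is.null(order_by)) {
    if (!order_by %in% names(peaks)) {
      stop("ranking column '", order_by, "' not found in peaks", call. = FALSE)
    }
    o <- order(-peaks[[order_by]], as.character(peaks$chrom), peaks$start)
    peaks <- peaks[o, , drop = FALSE]
  }
  ncol_out <- as.integer(2L * flank / bw)
  mat <- matrix(0, nrow = nrow(peaks), ncol = ncol_out)
  clipped <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ch <- as.character(peaks$chrom[i])
    v <- track$values[[ch]]
    b0 <- (peaks$summit[i] - flank) %/% bw        # bin holding summit - flank
    idx <- b0 + seq_len(ncol_out) - 1L            # 0-based bin indices
    ok <- idx >= 0L & idx < length(v)
    clipped[i] <- any(!ok)
    mat[i, ok] <- v[idx[ok] + 1L]
  }
  structure(mat,
            offsets = (seq_len(ncol_out) - 1L) * bw - flank,
            peak_names = if ("name" %in% names(peaks)) peaks$name else NULL,
            clipped = clipped)
}

#' Column-wise average profile of a profile matrix
#'
#' @param mat a matrix from [profile_matrix()].
#' @return numeric vector of per-column (per-bin) means.
#' @export
average_profile <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 1L) {
    stop("profile matrix must have at least one row", call. = FALSE)
  }
  colMeans(mat)
}
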