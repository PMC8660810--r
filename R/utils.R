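#' @keywords internal
#' @importFrom stats median optimize pchisq p.adjust rbinom rnbinom rnorm
#'   rpois runif sd setNames cor dnbinom kmeans qnorm pnorm dhyper
#' @importFrom utils head read.delim write.table
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Validate a set of genomic intervals
#'
#' Checks the data frame contract used for all interval-shaped inputs:
#' columns `chrom`, `start`, `end` with `0 <= start < end` (0-based,
#' half-open) and non-empty chromosome names.
#'
#' @param x data frame with at least `chrom`, `start`, `end` columns.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @keywords internal
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) stop(what, " must be a data frame", call. = FALSE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, " lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(x)) {
    if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
      stop(what, ": empty chromosome name", call. = FALSE)
    }
    bad <- which(!(x$start >= 0 & x$start < x$end))
    if (length(bad)) {
      stop(what, ": invalid interval (need 0 <= start < end) at row ",
           bad[1], call. = FALSE)
    }
  }
  invisible(x)
}

validate_peaks <- function(x, what = "peaks") {
  validate_intervals(x, what)
  if (!"summit" %in% names(x)) {
    stop(what, " lacks a 'summit' column", call. = FALSE)
  }
  if (nrow(x)) {
    bad <- which(!(x$summit >= x$start & x$summit < x$end))
    if (length(bad)) {
      stop(what, ": summit outside its interval at row ", bad[1], call. = FALSE)
    }
  }
  invisible(x)
}

check_chroms <- function(x, chrom_sizes, what = "intervals") {
  unknown <- setdiff(unique(as.character(x$chrom)), names(chrom_sizes))
  if (length(unknown)) {
    stop(what, " on unknown chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  over <- which(x$end > chrom_sizes[as.character(x$chrom)])
  if (length(over)) {
    stop(what, " extend past chromosome end at row ", over[1], call. = FALSE)
  }
  invisible(x)
}

# per-chromosome IRanges overlap hits between two interval frames;
# returns data.frame(qi, si, overlap_bp) with row indices into x and y
interval_overlaps <- function(x, y, min_bp = 1L) {
  out <- list()
  for (ch in intersect(unique(as.character(x$chrom)), unique(as.character(y$chrom)))) {
    qi <- which(x$chrom == ch)
    si <- which(y$chrom == ch)
    qr <- IRanges::IRanges(start = x$start[qi] + 1L, end = x$end[qi])
    sr <- IRanges::IRanges(start = y$start[si] + 1L, end = y$end[si])
    h <- IRanges::findOverlaps(qr, sr, minoverlap = min_bp)
    if (length(h)) {
      ov <- IRanges::width(IRanges::pintersect(
        qr[S4Vectors::queryHits(h)], sr[S4Vectors::subjectHits(h)]))
      out[[ch]] <- data.frame(
        qi = qi[S4Vectors::queryHits(h)],
        si = si[S4Vectors::subjectHits(h)],
        overlap_bp = ov)
    }
  }
  if (!length(out)) {
    return(data.frame(qi = integer(), si = integer(), overlap_bp = integer()))
  }
  do.call(rbind, unname(out))
}

#' Union-merge overlapping or bookended intervals
#'
#' Collapses a set of intervals into maximal disjoint regions per chromosome;
#' overlapping and bookended (zero-gap) intervals become one region.
#'
#' @param x interval data frame (`chrom`, `start`, `end`).
#' @return data frame of merged intervals sorted by chromosome and start.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (!nrow(x)) return(x[, c("chrom", "start", "end")])
  pieces <- lapply(split(x, as.character(x$chrom)), function(d) {
    # default min.gapwidth = 1 merges bookended as well as overlapping runs
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1],
               start = IRanges::start(r) - 1L,
               end = IRanges::end(r))
  })
  out <- do.call(rbind, unname(pieces))
  out[order(out$chrom, out$start), , drop = FALSE]
}
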