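#' Extend peak summits into fixed-width regions
#'
#' Replaces each peak interval by `[summit - flank, summit + flank)`, clipped
#' to the chromosome, giving the standard 200-bp summit-centered regions at
#' the default 100-bp flank.
#'
#' @param peaks peak data frame (`chrom`, `start`, `end`, `summit`, ...).
#' @param flank bp added on either side of the summit (default 100).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return peaks with `start`/`end` replaced by the summit-centered window;
#'   all other columns preserved.
#' @export
extend_summits <- function(peaks, flank = 100L, chrom_sizes) {
  validate_peaks(peaks)
  unknown <- setdiff(unique(as.character(peaks$chrom)), names(chrom_sizes))
  if (length(unknown)) {
    stop("peaks on unknown chromosome(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sizes <- chrom_sizes[as.character(peaks$chrom)]
  if (nrow(peaks) && any(peaks$summit < 0 | peaks$summit >= sizes)) {
    stop("summit outside chromosome bounds", call. = FALSE)
  }
  peaks$start <- pmax(peaks$summit - flank, 0L)
  peaks$end <- pmin(peaks$summit + flank, as.integer(sizes))
  validate_peaks(peaks)
  peaks
}

#' Filter peaks for reproducibility across two replicates
#'
#' A peak from either replicate is retained iff at least `min_frac` of its
#' own length overlaps some peak of the other replicate (best single partner,
#' BEDtools `-f` semantics). Retained peaks from both replicates are then
#' union-merged (overlapping or bookended survivors become one region) into
#' the high-confidence set. With `mode = "rep1"` the merged regions are the
#' retained replicate-1 peaks only, anchoring the final regions on the first
#' replicate instead of the symmetric union.
#'
#' @param rep1,rep2 peak data frames, typically summit-extended to equal
#'   width via [extend_summits()].
#' @param min_frac minimum fraction of a peak's own length that must overlap
#'   a peak of the other replicate (default 0.5).
#' @param mode `"union"` (default) or `"rep1"`.
#' @return data frame of merged high-confidence regions (`chrom`, `start`,
#'   `end`).
#' @export
reproducible_peaks <- function(rep1, rep2, min_frac = 0.5, mode = c("union", "rep1")) {
  mode <- match.arg(mode)
  validate_intervals(rep1, "rep1"); validate_intervals(rep2, "rep2")
  if (!nrow(rep1) || !nrow(rep2)) {
    warning("a replicate is empty; no reproducible peaks")
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  keep_frac <- function(q, s) {
    h <- interval_overlaps(q, s)
    need <- ceiling(min_frac * (q$end - q$start))
    ok <- rep(FALSE, nrow(q))
    if (nrow(h)) {
      best <- tapply(h$overlap_bp, h$qi, max)
      qi <- as.integer(names(best))
      ok[qi] <- best >= need[qi]
    }
    q[ok, , drop = FALSE]
  }
  k1 <- keep_frac(rep1, rep2)
  k2 <- keep_frac(rep2, rep1)
  survivors <- if (mode == "rep1") k1 else {
    cols <- c("chrom", "start", "end")
    rbind(k1[, cols, drop = FALSE], k2[, cols, drop = FALSE])
  }
  merge_intervals(survivors)
}

#' Classify peaks across two conditions into shared and specific sets
#'
#' A peak is shared iff its maximum single-partner overlap with the other
#' condition's peak set is at least `overlap_min` bp (default 10); otherwise
#' it is condition-specific. The partition is exhaustive and disjoint, and
#' classifying a set against itself yields 100% shared.
#'
#' @param set_a,set_b peak data frames for the two conditions.
#' @param overlap_min minimum overlap in bp for "shared" (default 10).
#' @param labels character(2) condition names used in the summary.
#' @return object of class `classified_peaks`: list with `shared_a`,
#'   `shared_b` (the shared peaks of each set), `pairs` (row indices and
#'   overlap bp of every qualifying pair), `unique_a`, `unique_b`, `labels`.
#' @export
classify_cross_condition <- function(set_a, set_b, overlap_min = 10L,
                                     labels = c("A", "B")) {
  validate_intervals(set_a, "set_a"); validate_intervals(set_b, "set_b")
  h <- interval_overlaps(set_a, set_b, min_bp = 1L)
  h <- h[h$overlap_bp >= overlap_min, , drop = FALSE]
  shared_a_idx <- sort(unique(h$qi))
  shared_b_idx <- sort(unique(h$si))
  structure(list(
    shared_a = set_a[shared_a_idx, , drop = FALSE],
    shared_b = set_b[shared_b_idx, , drop = FALSE],
    pairs = h,
    unique_a = set_a[setdiff(seq_len(nrow(set_a)), shared_a_idx), , drop = FALSE],
    unique_b = set_b[setdiff(seq_len(nrow(set_b)), shared_b_idx), , drop = FALSE],
    labels = labels), class = "classified_peaks")
}

#' @export
print.classified_peaks <- function(x, ...) {
  cat(sprintf("classified_peaks [%s vs %s]: %d/%d shared in %s, %d/%d shared in %s\n",
              x$labels[1], x$labels[2],
              nrow(x$shared_a), nrow(x$shared_a) + nrow(x$unique_a), x$labels[1],
              nrow(x$shared_b), nrow(x$shared_b) + nrow(x$unique_b), x$labels[2]))
  invisible(x)
}

#' Summary counts of a cross-condition classification
#'
#' @param object a `classified_peaks` object.
#' @param ... unused.
#' @return data frame of category and count.
#' @export
summary.classified_peaks <- function(object, ...) {
  data.frame(
    category = c(paste0("shared_", object$labels[1]),
                 paste0("shared_", object$labels[2]),
                 paste0("unique_", object$labels[1]),
                 paste0("unique_", object$labels[2])),
    count = c(nrow(object$shared_a), nrow(object$shared_b),
              nrow(object$unique_a), nrow(object$unique_b)))
}

#' Fraction of query peaks overlapping a reference set
#'
#' Computes the fraction of query peaks with at least 1 bp overlap with any
#' reference interval — e.g. the fraction of binding sites falling in
#' accessible chromatin.
#'
#' @param query non-empty peak/interval data frame.
#' @param reference interval data frame.
#' @return fraction in `[0, 1]`.
#' @export
overlap_fraction_with_set <- function(query, reference) {
  validate_intervals(query, "query"); validate_intervals(reference, "reference")
  if (!nrow(query)) stop("query peak set is empty", call. = FALSE)
  h <- interval_overlaps(query, reference, min_bp = 1L)
  length(unique(h$qi)) / nrow(query)
}
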