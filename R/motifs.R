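# IUPAC degenerate nucleotide classes. A base in the genome matches a pattern
# character iff it is a member of that character's class; N in the *sequence*
# is deliberately absent from every class so assembly gaps never create
# motif matches (not even against pattern N).
IUPAC_CLASSES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

#' Construct an IUPAC motif pattern
#'
#' @param name motif label (e.g. the factor it is bound by).
#' @param iupac motif string over the IUPAC nucleotide alphabet
#'   (`ACGTRYSWKMBDHVN`).
#' @return object of class `motif_pattern`.
#' @examples
#' motif_pattern("Zld", "CAGGTARV")
#' @export
motif_pattern <- function(name, iupac) {
  iupac <- toupper(iupac)
  chars <- strsplit(iupac, "")[[1]]
  if (!length(chars)) stop("empty motif pattern", call. = FALSE)
  bad <- setdiff(chars, names(IUPAC_CLASSES))
  if (length(bad)) {
    stop("invalid IUPAC character(s) in motif '", name, "': ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, iupac = iupac), class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("motif_pattern:", x$name, "=", x$iupac, "\n")
  invisible(x)
}

#' Reverse-complement a DNA or IUPAC string
#'
#' @param s character string over the IUPAC alphabet.
#' @return the reverse complement, degenerate codes complemented class-wise.
#' @export
reverse_complement <- function(s) {
  chars <- rev(strsplit(toupper(s), "")[[1]])
  out <- IUPAC_COMPLEMENT[chars]
  if (any(is.na(out))) stop("cannot complement character(s): ",
                            paste(unique(chars[is.na(out)]), collapse = ", "),
                            call. = FALSE)
  paste(out, collapse = "")
}

#' The motif dictionary used throughout the analyses
#'
#' Canonical and degenerate pioneer-factor (Zelda) motifs plus the
#' promoter/insulator-factor motifs tallied alongside them: CAGGTAG and
#' CAGGTA (canonical Zld), CAGGTARV (degenerate Zld), ACMGRG (CLAMP/GAF),
#' HATCGATA (Dref/Beaf-32), GGTCACA (M1BP), AAAWGVVCMNH (Erm).
#'
#' @return named list of [motif_pattern()] objects.
#' @export
default_motifs <- function() {
  defs <- c(Zld_canonical = "CAGGTAG", Zld_core = "CAGGTA",
            Zld_degenerate = "CAGGTARV", CLAMP = "ACMGRG",
            Dref_Beaf32 = "HATCGATA", M1BP = "GGTCACA", Erm = "AAAWGVVCMNH")
  out <- lapply(names(defs), function(n) motif_pattern(n, defs[[n]]))
  setNames(out, names(defs))
}

# scan one strand: 0-based start positions where every pattern character's
# IUPAC class contains the sequence base
scan_one_strand <- function(pattern_chars, seq_chars) {
  m <- length(pattern_chars)
  n <- length(seq_chars)
  if (n < m) return(integer())
  ok <- rep(TRUE, n - m + 1L)
  for (i in seq_len(m)) {
    allowed <- IUPAC_CLASSES[[pattern_chars[i]]]
    ok <- ok & (seq_chars[i:(n - m + i)] %in% allowed)
  }
  which(ok) - 1L
}

#' Find all IUPAC motif matches in a sequence
#'
#' Position `p` (0-based) matches on the forward strand iff every sequence
#' base is in the IUPAC class of the corresponding pattern character; `N` in
#' the sequence matches nothing. With `both_strands = TRUE` the reverse
#' complement of the pattern is also scanned and reported in forward-strand
#' coordinates with strand `-`. Overlapping matches are all reported.
#'
#' @param pattern a [motif_pattern()].
#' @param sequence character string over `A/C/G/T/N`.
#' @param both_strands scan the reverse strand too (default `TRUE`).
#' @return data frame with `start` (0-based forward-strand position of the
#'   match's leftmost base) and `strand`, sorted by `start`.
#' @export
find_matches <- function(pattern, sequence, both_strands = TRUE) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  pat_chars <- strsplit(pattern$iupac, "")[[1]]
  fwd <- scan_one_strand(pat_chars, seq_chars)
  out <- data.frame(start = fwd,
                    strand = rep("+", length(fwd)))
  if (both_strands) {
    rc_chars <- strsplit(reverse_complement(pattern$iupac), "")[[1]]
    rev_hits <- scan_one_strand(rc_chars, seq_chars)
    out <- rbind(out, data.frame(start = rev_hits,
                                 strand = rep("-", length(rev_hits))))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Tally regions containing at least one motif occurrence
#'
#' A region is positive iff at least one match lies fully inside it; a match
#' straddling the region edge does not count.
#'
#' @param pattern a [motif_pattern()].
#' @param regions interval data frame.
#' @param genome named character vector of chromosome sequences.
#' @param both_strands scan both strands (default `TRUE`).
#' @return list with `count` (number of positive regions) and `positive`
#'   (logical per region).
#' @export
count_regions_with_motif <- function(pattern, regions, genome,
                                     both_strands = TRUE) {
  validate_intervals(regions, "regions")
  sizes <- setNames(nchar(genome), names(genome))
  check_chroms(regions, sizes, "regions")
  positive <- vapply(seq_len(nrow(regions)), function(i) {
    ch <- as.character(regions$chrom[i])
    s <- substr(genome[[ch]], regions$start[i] + 1L, regions$end[i])
    nrow(find_matches(pattern, s, both_strands)) > 0L
  }, logical(1))
  list(count = sum(positive), positive = positive)
}

#' Flag peaks with a motif near the summit
#'
#' A peak is positive iff at least one match starts within the closed window
#' `[summit - window, summit + window]`, clipped at the chromosome bounds.
#'
#' @param pattern a [motif_pattern()]; the canonical core motif by default.
#' @param peaks peak data frame with `summit`.
#' @param genome named character vector of chromosome sequences.
#' @param window half-width of the summit window in bp (default 200).
#' @param both_strands scan both strands (default `TRUE`).
#' @return logical vector, one flag per peak.
#' @export
motif_near_summit <- function(pattern = motif_pattern("Zld_core", "CAGGTA"),
                              peaks, genome, window = 200L,
                              both_strands = TRUE) {
  validate_peaks(peaks)
  m <- nchar(pattern$iupac)
  vapply(seq_len(nrow(peaks)), function(i) {
    ch <- as.character(peaks$chrom[i])
    len <- nchar(genome[[ch]])
    lo <- max(peaks$summit[i] - window, 0L)
    # last admissible start is summit + window; the match may extend past it
    hi <- min(peaks$summit[i] + window + m - 1L, len - 1L)
    if (hi < lo) return(FALSE)
    s <- substr(genome[[ch]], lo + 1L, hi + 1L)
    hits <- find_matches(pattern, s, both_strands)
    any(lo + hits$start <= peaks$summit[i] + window)
  }, logical(1))
}

#' Rank-binned motif-fraction table
#'
#' Sorts peaks by z score from highest to lowest (ties broken by `chrom`,
#' `start`), partitions them into consecutive bins of `bin_size` peaks (final
#' partial bin kept), and reports per bin and per motif the fraction of peaks
#' containing at least one occurrence of the motif anywhere in the peak
#' interval.
#'
#' @param peaks peak data frame carrying a `zscore` column.
#' @param motifs list of [motif_pattern()] objects (default [default_motifs()]).
#' @param genome named character vector of chromosome sequences.
#' @param bin_size peaks per bin (default 100).
#' @param both_strands scan both strands (default `TRUE`).
#' @return data frame with `bin` (1-based index, 1 = highest z scores),
#'   `n_peaks`, and one fraction column per motif.
#' @export
rank_binned_fraction <- function(peaks, motifs = default_motifs(), genome,
                                 bin_size = 100L, both_strands = TRUE) {
  validate_peaks(peaks)
  if (!"zscore" %in% names(peaks)) {
    stop("peaks must carry a 'zscore' column; see peak_zscores()", call. = FALSE)
  }
  o <- order(-peaks$zscore, as.character(peaks$chrom), peaks$start)
  peaks <- peaks[o, , drop = FALSE]
  n <- nrow(peaks)
  bin <- (seq_len(n) - 1L) %/% bin_size + 1L
  if (is.null(names(motifs))) {
    names(motifs) <- vapply(motifs, `[[`, "", "name")
  }
  flags <- lapply(motifs, function(p) {
    count_regions_with_motif(p, peaks, genome, both_strands)$positive
  })
  out <- data.frame(bin = sort(unique(bin)),
                    n_peaks = as.integer(table(bin)))
  for (nm in names(flags)) {
    out[[nm]] <- as.numeric(tapply(flags[[nm]], bin, mean))
  }
  out
}
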