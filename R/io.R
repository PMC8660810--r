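#' Read a BED file of genomic intervals
#'
#' Reads BED3/BED6 records into the package's interval data frame. BED
#' coordinates are already 0-based half-open and are adopted verbatim; all
#' internal coordinates follow the same convention, so conversion only ever
#' happens at I/O boundaries (GTF input, below).
#'
#' @param path path to a tab-separated BED file (>= 3 columns).
#' @return data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, one row per record in file order. Missing optional columns are
#'   filled with `"."`/`NA`/`"."` respectively.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr2L\t100\t300\tp1\t0\t+", tf)
#' read_bed(tf)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 columns",
         call. = FALSE)
  }
  grab <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default,
           NA_character_)
  }
  start <- suppressWarnings(as.integer(grab(2L, NA_character_)))
  end <- suppressWarnings(as.integer(grab(3L, NA_character_)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1], ": non-numeric coordinates",
         call. = FALSE)
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop("invalid interval at BED line ", bad[1],
         ": need 0 <= start < end", call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(grab(5L, NA_character_)))
  data.frame(chrom = grab(1L, NA), start = start, end = end,
             name = grab(4L, "."), score = score,
             strand = ifelse(grab(6L, ".") %in% c("+", "-"), grab(6L, "."), "."))
}

#' Read an ENCODE narrowPeak file
#'
#' Parses the 10-column narrowPeak format produced by MACS2. The summit is
#' the peak start plus the column-10 offset; records called without a summit
#' (offset `-1`) fall back to the interval midpoint (floored) so every peak
#' carries a usable summit.
#'
#' @param path path to a 10-column narrowPeak file.
#' @return data frame of peaks with columns `chrom`, `start`, `end`, `name`,
#'   `score` (the signalValue, column 7) and `summit` (absolute bp).
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), summit = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 10L)) {
    stop("narrowPeak line ", which(nf != 10L)[1], " has ", nf[nf != 10L][1],
         " columns; expected 10", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  bad <- which(is.na(start) | is.na(end) | start >= end | start < 0L)
  if (length(bad)) {
    stop("invalid interval at narrowPeak line ", bad[1], call. = FALSE)
  }
  offset <- as.integer(m[, 10])
  summit <- ifelse(offset >= 0L, start + offset,
                   start + (end - start) %/% 2L)
  out <- data.frame(chrom = m[, 1], start = start, end = end, name = m[, 4],
                    score = as.numeric(m[, 7]), summit = as.integer(summit))
  validate_peaks(out, "narrowPeak records")
  out
}

#' Read gene models from a GTF file
#'
#' Collects, per `gene_id`, the gene span, exon set and (when CDS features
#' are present) the CDS span. GTF's 1-based closed coordinates are converted
#' to the internal 0-based half-open convention at this boundary. The TSS is
#' the leftmost coordinate of the gene span for `+` strand genes and the
#' rightmost base (`end - 1`) for `-` strand genes.
#'
#' @param path path to a GTF file with `gene_id` attributes.
#' @return object of class `gene_models`: a list with data frames `genes`
#'   (`gene_id`, `chrom`, `strand`, `start`, `end`, `tss`, `cds_start`,
#'   `cds_end`; CDS columns `NA` when absent) and `exons`
#'   (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("GTF contains no feature records", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L)) {
    stop("malformed GTF line ", which(lengths(fields) < 9L)[1], call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", m[, 9])
  no_id <- which(!grepl("gene_id", m[, 9], fixed = TRUE))
  if (length(no_id)) {
    stop("GTF line ", no_id[1], " lacks a gene_id attribute", call. = FALSE)
  }
  start1 <- as.integer(m[, 4]); end1 <- as.integer(m[, 5])
  bad <- which(is.na(start1) | is.na(end1) | end1 < start1)
  if (length(bad)) stop("invalid coordinates at GTF line ", bad[1], call. = FALSE)
  # 1-based closed -> 0-based half-open
  d <- data.frame(gene_id = gid, chrom = m[, 1], feature = m[, 3],
                  start = start1 - 1L, end = end1, strand = m[, 7])
  per_gene <- split(d, d$gene_id)
  genes <- do.call(rbind, lapply(per_gene, function(g) {
    strand <- g$strand[1]
    gstart <- min(g$start); gend <- max(g$end)
    cds <- g[g$feature == "CDS", , drop = FALSE]
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = strand,
               start = gstart, end = gend,
               tss = if (strand == "-") gend - 1L else gstart,
               cds_start = if (nrow(cds)) min(cds$start) else NA_integer_,
               cds_end = if (nrow(cds)) max(cds$end) else NA_integer_)
  }))
  rownames(genes) <- NULL
  exons <- d[d$feature == "exon", c("gene_id", "chrom", "start", "end")]
  if (!nrow(exons)) {  # gene-only GTF: treat each gene span as one exon
    exons <- genes[, c("gene_id", "chrom", "start", "end")]
  }
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Write a binned coverage track as bedGraph
#'
#' Serializes a [binned_track()] with one record per maximal run of
#' equal-valued adjacent bins. Coordinates are half-open multiples of the bin
#' width, with the last bin clipped at the chromosome length, so a round trip
#' through [read_bedgraph()] reproduces the bin values exactly.
#'
#' @param track a `binned_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "binned_track"))
  con <- file(path, "w")
  on.exit(close(con))
  bw <- track$bin_width
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts <- c(0L, head(ends_bin, -1L)) * bw
    ends <- pmin(ends_bin * bw, track$chrom_sizes[[ch]])
    writeLines(sprintf("%s\t%d\t%d\t%.10g", ch, starts, ends, r$values), con)
  }
  invisible(path)
}

#' Read a bedGraph file back into a binned track
#'
#' Inverse of [write_bedgraph()] for tracks whose record boundaries sit on
#' multiples of `bin_width` (the last record per chromosome may be clipped at
#' the chromosome end). Bins not covered by any record are 0.
#'
#' @param path bedGraph path.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param bin_width bin width in bp.
#' @return a `binned_track`.
#' @export
read_bedgraph <- function(path, chrom_sizes, bin_width = 10L) {
  d <- read.delim(path, header = FALSE,
                  col.names = c("chrom", "start", "end", "value"))
  vals <- lapply(names(chrom_sizes), function(ch) {
    n <- as.integer(ceiling(chrom_sizes[[ch]] / bin_width))
    v <- numeric(n)
    dd <- d[d$chrom == ch, , drop = FALSE]
    if (nrow(dd)) {
      b0 <- dd$start %/% bin_width
      b1 <- pmin(as.integer(ceiling(dd$end / bin_width)), n) - 1L
      for (i in seq_len(nrow(dd))) v[(b0[i] + 1L):(b1[i] + 1L)] <- dd$value[i]
    }
    v
  })
  binned_track(setNames(vals, names(chrom_sizes)), bin_width, chrom_sizes)
}

#' Write intervals or peaks as BED
#'
#' @param x interval data frame (`chrom`, `start`, `end`, optionally `name`,
#'   `score`, `strand`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  d <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                  name = x$name %||% ".",
                  score = ifelse(is.na(x$score %||% NA), 0, x$score %||% 0),
                  strand = x$strand %||% ".")
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA into named character sequences
#'
#' @param path FASTA path.
#' @return named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path tab-separated file of chromosome name and length.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- read.delim(path, header = FALSE, col.names = c("chrom", "size"))
  setNames(as.integer(d$size), as.character(d$chrom))
}
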