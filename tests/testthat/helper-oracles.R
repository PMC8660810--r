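# Independent oracles used across the suite. Each deliberately takes a
# different computational route than the package implementation.

# all-pairs O(n^2) overlap classification: shared flags for both sets
oracle_classify <- function(a, b, min_bp = 10L) {
  ov <- function(x1, x2, y1, y2) max(0L, min(x2, y2) - max(x1, y1))
  shared_a <- vapply(seq_len(nrow(a)), function(i) {
    any(vapply(seq_len(nrow(b)), function(j) {
      a$chrom[i] == b$chrom[j] &&
        ov(a$start[i], a$end[i], b$start[j], b$end[j]) >= min_bp
    }, logical(1)))
  }, logical(1))
  shared_b <- vapply(seq_len(nrow(b)), function(j) {
    any(vapply(seq_len(nrow(a)), function(i) {
      a$chrom[i] == b$chrom[j] &&
        ov(a$start[i], a$end[i], b$start[j], b$end[j]) >= min_bp
    }, logical(1)))
  }, logical(1))
  list(shared_a = shared_a, shared_b = shared_b)
}

# naive per-bin overlap counting: double loop over fragments and bins
oracle_bin_counts <- function(fragments, bin_width, chrom_sizes) {
  lapply(setNames(nm = names(chrom_sizes)), function(ch) {
    n <- as.integer(ceiling(chrom_sizes[[ch]] / bin_width))
    v <- numeric(n)
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      for (b in seq_len(n)) {
        b0 <- (b - 1L) * bin_width; b1 <- b * bin_width
        if (f$start[i] < b1 && f$end[i] > b0) v[b] <- v[b] + 1
      }
    }
    v
  })
}

# IUPAC scan through a different engine: PCRE lookahead regex (overlapping
# matches), both strands reported in forward coordinates
iupac_to_regex <- function(iupac) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
               D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(classes[strsplit(iupac, "")[[1]]], collapse = "")
}

oracle_find_matches <- function(iupac, sequence, both_strands = TRUE) {
  scan <- function(pat) {
    m <- gregexpr(paste0("(?=", iupac_to_regex(pat), ")"), sequence,
                  perl = TRUE)[[1]]
    if (m[1] == -1) integer() else as.integer(m) - 1L
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  rc <- paste(rev(comp[strsplit(iupac, "")[[1]]]), collapse = "")
  fw <- scan(iupac)
  out <- data.frame(start = fw, strand = rep("+", length(fw)))
  if (both_strands) {
    rv <- scan(rc)
    out <- rbind(out, data.frame(start = rv, strand = rep("-", length(rv))))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# character-by-character positional brute force (third route, pure loop)
oracle_scan_positions <- function(iupac, sequence) {
  classes <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                  Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                  D = c("A", "G", "T"), H = c("A", "C", "T"),
                  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  pat <- strsplit(iupac, "")[[1]]
  sq <- strsplit(sequence, "")[[1]]
  hits <- integer()
  for (p in seq_len(max(0, length(sq) - length(pat) + 1L))) {
    ok <- TRUE
    for (k in seq_along(pat)) {
      if (!(sq[p + k - 1L] %in% classes[[pat[k]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p - 1L)
  }
  hits
}

# exact Fisher two-sided p by full enumeration of tables with fixed margins,
# probabilities from the closed multinomial form via lchoose
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  logp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  p_obs <- exp(lchoose(m, a) + lchoose(n, c_) - lchoose(m + n, k))
  sum(exp(logp)[exp(logp) <= p_obs * (1 + 1e-7)])
}

# permutation oracle for the two-sided rank-sum p
oracle_perm_wilcoxon <- function(x, y, B = 1e5, seed = 1) {
  set.seed(seed)
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  mu <- nx * mean(r)
  obs <- abs(sum(r[seq_len(nx)]) - mu)
  dev <- vapply(seq_len(B), function(i) {
    abs(sum(r[sample.int(length(r), nx)]) - mu)
  }, numeric(1))
  mean(dev >= obs - 1e-9)
}

# tiny hand-checkable gene models: builds a gene_models object directly
toy_gene_models <- function(genes, exons = NULL) {
  if (is.null(exons)) {
    exons <- genes[, c("gene_id", "chrom", "start", "end")]
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

peak_row <- function(chrom, start, end, summit = NULL, ...) {
  data.frame(chrom = chrom, start = start, end = end,
             summit = summit %||% (start + (end - start) %/% 2L), ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_peak_set <- function(n, chrom_sizes, width_range = c(50L, 300L)) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  w <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(chrom_sizes[[chrom[i]]] - w[i], 1) - 1L
  }, integer(1))
  data.frame(chrom = chrom, start = start, end = start + w,
             summit = start + w %/% 2L)
}
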