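#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed (up to a small relative tolerance) that of the
#' observed table.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`.
#' @return list with `p.value` and `odds.ratio` (sample odds ratio `ad/bc`,
#'   with a Haldane 0.5 correction added to every cell when any cell is 0).
#' @examples
#' fisher_exact_two_sided(rbind(c(5, 0), c(0, 5)))$p.value  # 2/252
#' @export
fisher_exact_two_sided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row-1 margin
  n <- cc + d         # row-2 margin
  k <- a + cc         # column-1 margin
  if (m + n == 0 || k == 0 || (b + d) == 0 || m == 0 || n == 0) {
    stop("all table margins must be positive", call. = FALSE)
  }
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(a, m, n, k)
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  list(p.value = p, odds.ratio = or)
}

# exact two-sided rank-sum p by enumeration of all C(nx+ny, nx) assignments
# of the pooled ranks to group x; valid with or without ties (ties enter
# through midranks)
rank_sum_exact_p <- function(rx_sum, ranks, nx) {
  combos <- utils::combn(length(ranks), nx)
  sums <- colSums(matrix(ranks[combos], nrow = nx))
  n_total <- ncol(combos)
  mu <- nx * mean(ranks) # expected rank sum under the null
  obs_dev <- abs(rx_sum - mu)
  sum(abs(sums - mu) >= obs_dev - 1e-9) / n_total
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p-value by full enumeration of rank assignments when the pooled
#' sample size is at most 20 and there are no ties; otherwise a tie-corrected
#' normal approximation with continuity correction. The two-sided exact p is
#' the probability of a rank-sum deviation from its null expectation at least
#' as large as observed.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return list with `U` (Mann-Whitney statistic for `x`), `p.value`, and
#'   `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  rx <- sum(ranks[seq_len(nx)])
  U <- rx - nx * (nx + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = (nx + ny) <= 20L && !has_ties)
  if (use_exact) {
    p <- rank_sum_exact_p(rx, ranks, nx)
    return(list(U = U, p.value = min(1, p), method = "exact"))
  }
  mu <- nx * ny / 2
  n <- nx + ny
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(U = U, p.value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p.value = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Pearson correlation of log2 counts between replicates
#'
#' The replicate-reproducibility statistic: per-peak read counts from two
#' replicates are log2-transformed after adding a pseudocount and their
#' Pearson correlation returned.
#'
#' @param counts_rep1,counts_rep2 equal-length non-negative count vectors
#'   (length >= 3).
#' @param pseudocount value added before the log2 transform (default 1; use 0
#'   only when all counts are positive).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
replicate_pearson <- function(counts_rep1, counts_rep2, pseudocount = 1) {
  if (length(counts_rep1) != length(counts_rep2)) {
    stop("replicate count vectors must have equal length", call. = FALSE)
  }
  if (length(counts_rep1) < 3L) stop("need at least 3 peaks", call. = FALSE)
  l1 <- log2(counts_rep1 + pseudocount)
  l2 <- log2(counts_rep2 + pseudocount)
  if (sd(l1) == 0 || sd(l2) == 0) {
    stop("zero variance in a replicate's log counts", call. = FALSE)
  }
  cor(l1, l2)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a clustering and a reference labeling;
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
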