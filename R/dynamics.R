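#' Filter ATAC fragments to high-quality nucleosome-free fragments
#'
#' Keeps fragments strictly shorter than `max_len` bp (sub-nucleosomal,
#' likely originating between nucleosomes) with mapping quality strictly
#' greater than `min_mapq`. Both inequalities are strict; input order is
#' preserved.
#'
#' @param fragments data frame with `chrom`, `start`, `end` and `mapq`.
#' @param max_len exclusive fragment-length cutoff in bp (default 100).
#' @param min_mapq exclusive mapping-quality cutoff (default 30).
#' @return the retained rows of `fragments`.
#' @export
filter_fragments <- function(fragments, max_len = 100L, min_mapq = 30L) {
  validate_intervals(fragments, "fragments")
  if (!"mapq" %in% names(fragments)) {
    stop("fragments lack a 'mapq' column", call. = FALSE)
  }
  len <- fragments$end - fragments$start
  fragments[len < max_len & fragments$mapq > min_mapq, , drop = FALSE]
}

#' Build a region-by-sample fragment count matrix
#'
#' Counts, per region and sample, the fragments overlapping the region by at
#' least 1 bp. Under the default policy a fragment spanning two regions
#' counts toward both; `policy = "exclusive"` assigns each fragment only to
#' the first region (by coordinate order) it overlaps.
#'
#' @param fragments_by_sample named list of fragment data frames, one per
#'   sample.
#' @param regions interval data frame; region ids are taken from `name` when
#'   present (must be unique), else `chrom:start-end`.
#' @param timepoints numeric vector, one timepoint per sample (hours).
#' @param replicates optional replicate labels per sample.
#' @param policy `"all"` (default) or `"exclusive"`.
#' @return object of class `count_matrix`: list with integer `counts`
#'   (regions x samples), `regions`, and `samples`
#'   (`sample`, `timepoint`, `replicate`).
#' @export
count_matrix <- function(fragments_by_sample, regions, timepoints,
                         replicates = NULL, policy = c("all", "exclusive")) {
  policy <- match.arg(policy)
  validate_intervals(regions, "regions")
  stopifnot(is.list(fragments_by_sample), length(fragments_by_sample) >= 1L)
  if (length(timepoints) != length(fragments_by_sample)) {
    stop("need one timepoint per sample", call. = FALSE)
  }
  ids <- if ("name" %in% names(regions) && !anyNA(regions$name)) {
    as.character(regions$name)
  } else {
    paste0(regions$chrom, ":", regions$start, "-", regions$end)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate region ids: ", ids[anyDuplicated(ids)], call. = FALSE)
  }
  samples <- names(fragments_by_sample) %||% paste0("sample", seq_along(fragments_by_sample))
  counts <- vapply(fragments_by_sample, function(f) {
    validate_intervals(f, "fragments")
    h <- interval_overlaps(regions, f, min_bp = 1L)
    if (policy == "exclusive" && nrow(h)) {
      # keep each fragment's first region in coordinate order
      o <- order(regions$chrom[h$qi], regions$start[h$qi])
      h <- h[o, , drop = FALSE]
      h <- h[!duplicated(h$si), , drop = FALSE]
    }
    tabulate(h$qi, nbins = nrow(regions))
  }, integer(nrow(regions)))
  counts <- matrix(as.integer(counts), nrow = nrow(regions),
                   dimnames = list(ids, samples))
  new_count_matrix(counts, timepoints,
                   replicates %||% ave(seq_along(samples), timepoints, FUN = seq_along),
                   regions)
}

#' Assemble a count matrix from an existing matrix of counts
#'
#' @param counts non-negative integer matrix, regions x samples.
#' @param timepoints numeric vector, one per sample.
#' @param replicates optional replicate labels per sample.
#' @param regions optional interval data frame matching the rows.
#' @return a `count_matrix` object.
#' @export
new_count_matrix <- function(counts, timepoints, replicates = NULL,
                             regions = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be complete and non-negative", call. = FALSE)
  }
  if (length(timepoints) != ncol(counts)) {
    stop("need one timepoint per sample (column)", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("region", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  structure(list(
    counts = counts,
    samples = data.frame(
      sample = colnames(counts), timepoint = timepoints,
      replicate = replicates %||% ave(seq_len(ncol(counts)), timepoints,
                                      FUN = seq_along)),
    regions = regions), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "regions x", ncol(x$counts),
      "samples;", length(unique(x$samples$timepoint)), "timepoint(s)\n")
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median over regions
#' (restricted to regions with all-positive counts) of the ratio of the
#' sample's count to the region's geometric mean across samples.
#'
#' @param counts a `count_matrix` or a plain count matrix (regions x samples).
#' @return named numeric vector of positive size factors.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("no region has all-positive counts; cannot form the geometric-mean ",
         "reference (consider a pseudo-reference fallback)", call. = FALSE)
  }
  lm_ <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lm_)
  sf <- apply(exp(lm_ - geo), 2, median)
  setNames(sf, colnames(m))
}

# NB log-likelihood of one group of counts at common normalized mean q,
# size factors s, dispersion alpha; q = 0 only if all counts are 0
nb_group_loglik <- function(y, s, q, alpha) {
  if (q <= 0) return(if (all(y == 0)) 0 else -Inf)
  sum(dnbinom(y, size = 1 / alpha, mu = q * s, log = TRUE))
}

# MLE of the common normalized mean q for counts y with size factors s at
# fixed dispersion alpha; score is monotone with root in (0, max(y/s)]
nb_fit_mean <- function(y, s, alpha) {
  if (all(y == 0)) return(0)
  qhat <- sum(y) / sum(s)              # Poisson/equal-s MLE, exact if s equal
  score <- function(q) sum((y - q * s) / (1 + alpha * q * s))
  if (abs(score(qhat)) < 1e-10) return(qhat)
  hi <- max(y / s)
  if (score(hi) > 0) return(hi)
  stats::uniroot(score, lower = min(qhat, hi) * 1e-6, upper = hi,
                 tol = 1e-10)$root
}

#' Negative-binomial likelihood-ratio test across timepoints
#'
#' Per-region test of a full model with one normalized mean per timepoint
#' against a reduced model with a single common mean, both negative binomial
#' with a shared per-region dispersion. The dispersion is estimated once per
#' region by method of moments under the full model (Pearson moment equation
#' on the full-model fitted means, floored at 1e-8), then moderated by
#' pooling: the working dispersion is the larger of the region's own estimate
#' and the mean estimate across all regions. Per-region moment estimates at
#' these replicate numbers are noisy, and regions whose dispersion is
#' underestimated would otherwise inflate the statistic; taking the max
#' borrows strength across regions while staying conservative for
#' high-dispersion regions. The dispersion is then held fixed while both
#' models are maximized, so `2 * (logLik_full - logLik_reduced)` is
#' non-negative and is referred to a chi-squared distribution with `T - 1`
#' degrees of freedom. P-values are Benjamini-Hochberg adjusted across
#' regions. All-zero regions get p = 1 and are flagged.
#'
#' @param counts a `count_matrix`, or a plain matrix with `timepoints` given.
#' @param timepoints per-sample timepoints (ignored for a `count_matrix`).
#' @param sf per-sample size factors; computed by [size_factors()] when
#'   `NULL`.
#' @return data frame, one row per region: `stat`, `df`, `pvalue`, `padj`,
#'   `dispersion` (the moderated working value), `all_zero`.
#' @export
nb_lrt <- function(counts, timepoints = NULL, sf = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  tp <- if (inherits(counts, "count_matrix")) counts$samples$timepoint else timepoints
  if (is.null(tp)) stop("timepoints are required", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("region", seq_len(nrow(m)))
  tps <- sort(unique(tp))
  if (length(tps) < 2L) stop("need >= 2 timepoints", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(m)
  groups <- lapply(tps, function(t) which(tp == t))
  n <- ncol(m)
  df_resid <- n - length(tps)
  all_zero <- rowSums(m) == 0
  # pass 1: full-model moment fits and per-region Pearson moment dispersion
  mu_hat <- m * 0
  for (g in groups) {
    q_t <- rowSums(m[, g, drop = FALSE]) / sum(sf[g])
    mu_hat[, g] <- outer(q_t, sf[g])
  }
  alpha_r <- vapply(seq_len(nrow(m)), function(r) {
    if (all_zero[r] || df_resid <= 0) return(1e-8)
    y <- m[r, ]; mu <- mu_hat[r, ]
    ok <- mu > 0
    pearson <- function(a) sum((y[ok] - mu[ok])^2 / (mu[ok] * (1 + a * mu[ok])))
    if (pearson(0) <= df_resid) return(1e-8)
    hi <- 10
    while (pearson(hi) > df_resid && hi < 1e6) hi <- hi * 10
    max(1e-8, stats::uniroot(function(a) pearson(a) - df_resid,
                             lower = 0, upper = hi, tol = 1e-10)$root)
  }, numeric(1))
  alpha_pooled <- if (any(!all_zero)) mean(alpha_r[!all_zero]) else 1e-8
  alpha_work <- pmax(alpha_r, alpha_pooled)
  # pass 2: profile both models at the fixed working dispersion
  res <- vapply(seq_len(nrow(m)), function(r) {
    if (all_zero[r]) return(c(0, 1))
    y <- m[r, ]; a <- alpha_work[r]
    ll_full <- sum(vapply(groups, function(g) {
      nb_group_loglik(y[g], sf[g], nb_fit_mean(y[g], sf[g], a), a)
    }, numeric(1)))
    ll_red <- nb_group_loglik(y, sf, nb_fit_mean(y, sf, a), a)
    stat <- max(0, 2 * (ll_full - ll_red))
    c(stat, pchisq(stat, df = length(tps) - 1L, lower.tail = FALSE))
  }, numeric(2))
  out <- data.frame(region = rownames(m),
                    stat = res[1, ], df = length(tps) - 1L,
                    pvalue = res[2, ], padj = p.adjust(res[2, ], "BH"),
                    dispersion = alpha_work, all_zero = all_zero)
  rownames(out) <- NULL
  out
}

#' Replicate-averaged normalized trajectory matrix
#'
#' Normalizes counts by size factors, averages replicates within each
#' timepoint, and returns a regions x timepoints matrix — the substrate of
#' trajectory clustering and the decay comparisons.
#'
#' @param counts a `count_matrix`.
#' @param sf size factors (computed when `NULL`).
#' @return numeric matrix, regions x timepoints, columns ordered and named by
#'   timepoint.
#' @export
trajectory_matrix <- function(counts, sf = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts$counts, 2, sf, "/")
  tps <- sort(unique(counts$samples$timepoint))
  out <- vapply(tps, function(t) {
    rowMeans(norm[, counts$samples$timepoint == t, drop = FALSE])
  }, numeric(nrow(norm)))
  colnames(out) <- tps
  out
}

# z-score rows to mean 0, SD 1 (sample SD across timepoints); constant rows
# become all-zero with a warning
zscore_rows <- function(mat) {
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  flat <- s == 0
  if (any(flat)) {
    warning(sum(flat), " constant trajectories set to zero before clustering")
    s[flat] <- 1
  }
  (mat - mu) / s
}

#' K-means clustering of accessibility trajectories
#'
#' Clusters per-region accessibility time courses by k-means (best of
#' `nstart` random initializations, at most `max_iter` iterations),
#' reproducing the standard R k-means call the analysis is built on. Input
#' trajectories are z-scored per region (mean 0, SD 1 across timepoints) by
#' default, so cluster shapes reflect the temporal pattern rather than the
#' accessibility level. The input should be restricted to regions called
#' differentially accessible (e.g. `padj < 0.05` from [nb_lrt()]).
#'
#' @param x a `count_matrix` (normalized and replicate-averaged internally)
#'   or a plain regions x timepoints matrix.
#' @param k number of clusters (default 6).
#' @param nstart random restarts (default 25).
#' @param max_iter maximum iterations (default 1000).
#' @param seed integer seed; the clustering is deterministic given the seed.
#' @param scale `"zscore"` (default) or `"none"` (cluster the normalized
#'   trajectories directly).
#' @return object of class `trajectory_clustering`: list with `labels`
#'   (named integer vector in 1..k), `centroids` (k x T), `tot_withinss`,
#'   `k`, `nstart`, `seed`, and the clustered `trajectories`.
#' @export
cluster_trajectories <- function(x, k = 6L, nstart = 25L, max_iter = 1000L,
                                 seed = NULL, scale = c("zscore", "none")) {
  scale <- match.arg(scale)
  mat <- if (inherits(x, "count_matrix")) trajectory_matrix(x) else as.matrix(x)
  if (scale == "zscore") mat <- zscore_rows(mat)
  if (k > nrow(unique(mat))) {
    stop("k exceeds the number of distinct trajectories", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (k == nrow(mat)) {
    # every point is its own cluster; stats::kmeans requires k < n
    km <- list(cluster = seq_len(nrow(mat)), centers = mat,
               tot.withinss = 0)
  } else {
    km <- kmeans(mat, centers = k, nstart = nstart, iter.max = max_iter)
  }
  structure(list(labels = setNames(km$cluster, rownames(mat)),
                 centroids = km$centers,
                 tot_withinss = km$tot.withinss,
                 k = k, nstart = nstart, seed = seed,
                 trajectories = mat),
            class = "trajectory_clustering")
}

#' @export
print.trajectory_clustering <- function(x, ...) {
  cat("trajectory_clustering: k =", x$k, "on", length(x$labels),
      "regions; total within-SS =", signif(x$tot_withinss, 6), "\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Binding enrichment in decreasing- vs increasing-accessibility clusters
#'
#' Partitions clusters by the sign of (mean of the last two centroid
#' timepoints minus mean of the first two): negative = decreasing
#' accessibility, non-negative = increasing. Tests whether bound regions are
#' enriched in the decreasing group with a two-sided Fisher's exact test.
#'
#' @param clustering a `trajectory_clustering`.
#' @param bound logical vector (or named, matched by region), one flag per
#'   clustered region: is the region bound by the factor?
#' @return list with `fraction_decreasing`, `fraction_increasing` (bound
#'   fractions per group), `odds.ratio`, `p.value`, `group_of_cluster`, and
#'   the 2x2 `table`.
#' @export
cluster_binding_enrichment <- function(clustering, bound) {
  stopifnot(inherits(clustering, "trajectory_clustering"))
  if (!is.null(names(bound))) bound <- bound[names(clustering$labels)]
  if (length(bound) != length(clustering$labels) || anyNA(bound)) {
    stop("need one non-missing bound flag per clustered region", call. = FALSE)
  }
  cen <- clustering$centroids
  nt <- ncol(cen)
  delta <- rowMeans(cen[, c(nt - 1L, nt), drop = FALSE]) -
    rowMeans(cen[, 1:2, drop = FALSE])
  group_of_cluster <- ifelse(delta < 0, "decreasing", "increasing")
  grp <- group_of_cluster[clustering$labels]
  if (length(unique(grp)) < 2L) {
    stop("all clusters fall in one direction; cannot form the two groups",
         call. = FALSE)
  }
  dec <- grp == "decreasing"
  tab <- rbind(c(sum(bound & dec), sum(!bound & dec)),
               c(sum(bound & !dec), sum(!bound & !dec)))
  ft <- fisher_exact_two_sided(tab)
  list(fraction_decreasing = mean(bound[dec]),
       fraction_increasing = mean(bound[!dec]),
       odds.ratio = ft$odds.ratio, p.value = ft$p.value,
       group_of_cluster = group_of_cluster, table = tab)
}

#' Motif-stratified accessibility-decay comparison
#'
#' At each timepoint, compares accessibility z scores between motif-containing
#' and motif-lacking regions with a two-sided Wilcoxon rank-sum test, and
#' reports the box-plot summary (median, quartiles, 1.5 x IQR whiskers) per
#' stratum.
#'
#' @param traj regions x timepoints matrix of accessibility z scores (e.g.
#'   the `trajectories` component of a [cluster_trajectories()] result).
#' @param motif logical vector, one flag per region; both strata must be
#'   non-empty.
#' @return list with `tests` (per timepoint: `timepoint`, `U`, `p.value`) and
#'   `summaries` (per timepoint and stratum: median, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`).
#' @export
motif_stratified_decay <- function(traj, motif) {
  traj <- as.matrix(traj)
  if (length(motif) != nrow(traj)) {
    stop("need one motif flag per region", call. = FALSE)
  }
  if (!any(motif) || all(motif)) {
    stop("both motif strata must be non-empty", call. = FALSE)
  }
  tps <- colnames(traj) %||% as.character(seq_len(ncol(traj)))
  box <- function(v) {
    q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75)))
    iqr <- q[3] - q[1]
    c(median = q[2], q1 = q[1], q3 = q[3],
      whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
      whisker_hi = max(v[v <= q[3] + 1.5 * iqr]))
  }
  tests <- data.frame(timepoint = tps, U = NA_real_, p.value = NA_real_)
  summaries <- list()
  for (j in seq_len(ncol(traj))) {
    w <- wilcoxon_rank_sum(traj[motif, j], traj[!motif, j])
    tests$U[j] <- w$U; tests$p.value[j] <- w$p.value
    summaries[[j]] <- cbind(
      data.frame(timepoint = tps[j], stratum = c("motif", "no_motif")),
      rbind(box(traj[motif, j]), box(traj[!motif, j])))
  }
  list(tests = tests, summaries = do.call(rbind, summaries))
}
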