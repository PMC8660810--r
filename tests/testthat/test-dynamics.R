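test_that("fragment filter applies strict length and MAPQ cutoffs", {
  fr <- data.frame(chrom = "c", start = c(0L, 0L, 0L, 10L),
                   end = c(99L, 100L, 50L, 60L),
                   mapq = c(31L, 60L, 30L, 42L))
  kept <- filter_fragments(fr)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$end, c(99L, 60L))    # len 100 dropped, mapq 30 dropped
  expect_equal(rownames(kept), c("1", "4"))  # order preserved
  expect_error(filter_fragments(fr[, 1:3]), "mapq")
})

test_that("count matrix counts overlaps under both assignment policies", {
  regions <- data.frame(chrom = "c", start = c(0L, 100L), end = c(100L, 200L),
                        name = c("r1", "r2"))
  fr <- data.frame(chrom = "c", start = c(10L, 95L, 300L), end = c(20L, 105L, 350L))
  cm <- count_matrix(list(s1 = fr), regions, timepoints = 0)
  expect_equal(unname(cm$counts[, 1]), c(2L, 1L))   # spanning fragment counts twice
  cme <- count_matrix(list(s1 = fr), regions, timepoints = 0,
                      policy = "exclusive")
  expect_equal(unname(cme$counts[, 1]), c(2L, 0L))
  expect_equal(sum(cme$counts), 2L)

  dup <- regions; dup$name <- c("r", "r")
  expect_error(count_matrix(list(s1 = fr), dup, timepoints = 0), "duplicate")
})

test_that("count matrix equals a brute-force double loop on random fixtures", {
  set.seed(41)
  cs <- c(cA = 5000L)
  regions <- data.frame(chrom = "cA", start = seq(0L, 4500L, by = 500L))
  regions$end <- regions$start + sample(100:400, nrow(regions), replace = TRUE)
  for (rep in 1:3) {
    st <- sample(0:4900, 200, replace = TRUE)
    fr <- data.frame(chrom = "cA", start = st,
                     end = st + sample(20:250, 200, replace = TRUE))
    fr$end <- pmin(fr$end, 5000L)
    cm <- count_matrix(list(s = fr), regions, timepoints = 0)
    brute <- vapply(seq_len(nrow(regions)), function(i) {
      sum(vapply(seq_len(nrow(fr)), function(j) {
        fr$start[j] < regions$end[i] && fr$end[j] > regions$start[i]
      }, logical(1)))
    }, integer(1))
    expect_equal(unname(cm$counts[, 1]), brute)
  }
})

test_that("size factors follow the median-of-ratios definition", {
  set.seed(42)
  base <- rpois(200, 40) + 1
  m <- cbind(s1 = base, s2 = 2L * base)
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)

  m_id <- cbind(base, base, base)
  expect_equal(unname(size_factors(m_id)), c(1, 1, 1))

  # scaling one sample by c multiplies its factor by c^(1 - 1/n) and the
  # others by c^(-1/n) (geometric-mean reference shifts by c^(1/n))
  m3 <- cbind(base, rpois(200, 40) + 1, rpois(200, 40) + 1)
  sf3 <- size_factors(m3)
  m3c <- m3; m3c[, 1] <- m3[, 1] * 8L
  sf3c <- size_factors(m3c)
  expect_equal(unname(sf3c[1] / sf3[1]), 8 * 8^(-1 / 3), tolerance = 1e-10)
  expect_equal(unname(sf3c[2] / sf3[2]), 8^(-1 / 3), tolerance = 1e-10)

  zero <- cbind(c(0L, 5L), c(3L, 0L))
  expect_error(size_factors(zero), "all-positive")
})

test_that("NB LRT handles degenerate regions and matches the Poisson limit", {
  # identical counts at every timepoint: nested models coincide
  y <- matrix(rep(c(5L, 9L), 5), 1)   # same two replicate values per timepoint
  r <- nb_lrt(y, timepoints = rep(c(0, 6, 12, 18, 24), each = 2),
              sf = rep(1, 10))
  expect_lt(r$stat, 1e-6)
  expect_gt(r$pvalue, 0.999)

  # all-zero region flagged with p = 1
  m <- rbind(rep(0L, 10), rpois(10, 20))
  r0 <- nb_lrt(m, timepoints = rep(c(0, 6, 12, 18, 24), each = 2),
               sf = rep(1, 10))
  expect_true(r0$all_zero[1])
  expect_equal(r0$pvalue[1], 1)

  # alpha -> 0 limit equals the closed-form Poisson LRT on a toy table
  y2 <- matrix(c(5L, 7L, 20L, 16L), 1)
  r2 <- nb_lrt(y2, timepoints = c(0, 0, 6, 6), sf = rep(1, 4))
  lam <- 2 * sum(c(5, 7, 20, 16) * log(c(6, 6, 18, 18) / 12))
  expect_equal(r2$stat, lam, tolerance = 1e-6)
  expect_equal(r2$df[1], 1L)
})

test_that("NB LRT is invariant to replicate relabeling and global rescaling", {
  set.seed(43)
  tc <- make_timecourse(50, 0.5, 50, 0.1, reps = 2, seed = 44)
  m <- tc$counts$counts
  tp <- tc$counts$samples$timepoint
  r1 <- nb_lrt(m, timepoints = tp, sf = rep(1, 10))
  # swap the two replicates of every timepoint
  perm <- as.vector(matrix(seq_len(10), 2)[2:1, ])
  r2 <- nb_lrt(m[, perm], timepoints = tp[perm], sf = rep(1, 10))
  expect_equal(r2$stat, r1$stat, tolerance = 1e-8)

  # doubling one sample's counts is absorbed by its size factor: the LRT
  # decision is preserved (a rescaled NB variable is not exactly NB, so the
  # statistics agree approximately, not identically)
  m3 <- m; m3[, 4] <- 2L * m[, 4]
  sf3 <- rep(1, 10); sf3[4] <- 2
  r3 <- nb_lrt(m3, timepoints = tp, sf = sf3)
  expect_gt(cor(r3$stat, r1$stat), 0.99)
  expect_gte(mean((r3$pvalue < 0.05) == (r1$pvalue < 0.05)), 0.96)
})

test_that("BH adjustment is monotone and bounded below by raw p", {
  set.seed(45)
  tc <- make_timecourse(300, 0.2, 50, 0.1, seed = 46)
  r <- nb_lrt(tc$counts)
  expect_true(all(r$padj >= r$pvalue - 1e-12))
  o <- order(r$pvalue)
  expect_true(all(diff(r$padj[o]) >= -1e-12))
})

test_that("differential regions are recovered with controlled FDR", {
  # well-replicated design: 3 replicates, alpha = 0.05, mean 100, 2x effect
  set.seed(47)
  n <- 1200; chg <- sample(n, 360)
  mu <- matrix(100, n, 15); mu[chg, 10:15] <- 200
  y <- matrix(rnbinom(n * 15, size = 20, mu = mu), n, 15)
  r <- nb_lrt(y, timepoints = rep(c(0, 6, 12, 18, 24), each = 3),
              sf = rep(1, 15))
  sig <- which(r$padj < 0.05)
  fdr <- length(setdiff(sig, chg)) / max(1, length(sig))
  expect_lte(fdr, 0.08)
  expect_gte(length(intersect(sig, chg)) / length(chg), 0.8)
})

test_that("trajectory k-means is deterministic and self-consistent", {
  tj <- make_trajectories(40, 0.3, seed = 48)
  cl <- cluster_trajectories(tj$trajectories, k = 6, seed = 17)
  cl2 <- cluster_trajectories(tj$trajectories, k = 6, seed = 17)
  expect_identical(cl$labels, cl2$labels)
  expect_identical(cl$tot_withinss, cl2$tot_withinss)

  # assigning each point to its nearest centroid reproduces the labels
  d <- as.matrix(dist(rbind(cl$centroids, cl$trajectories)))[-(1:6), 1:6]
  expect_equal(unname(apply(d, 1, which.min)), unname(cl$labels))

  # k = number of distinct points -> zero within-cluster SS
  pts <- matrix(c(0, 0, 1, 1, 5, 5, 9, 9), 4, byrow = TRUE) +
    matrix(rep(c(0, 1), each = 4), 4)
  clp <- cluster_trajectories(pts, k = 4, nstart = 5, seed = 1, scale = "none")
  expect_equal(clp$tot_withinss, 0)
  expect_error(cluster_trajectories(pts, k = 5, seed = 1, scale = "none"),
               "distinct")
})

test_that("count-matrix clustering input is z-scored replicate-averaged", {
  tc <- make_timecourse(300, 1, 50, 0.02, seed = 49)
  cl <- cluster_trajectories(tc$counts, k = 6, seed = 17)
  expect_equal(unname(rowMeans(cl$trajectories)), rep(0, 300), tolerance = 1e-12)
  expect_equal(unname(apply(cl$trajectories, 1, sd)), rep(1, 300),
               tolerance = 1e-12)
  expect_equal(ncol(cl$trajectories), 5L)
})

test_that("binding enrichment recovers planted bound fractions", {
  set.seed(50)
  tj <- make_trajectories(500, 0.3, seed = 51)
  cl <- cluster_trajectories(tj$trajectories, k = 6, seed = 17)
  # archetypes whose centroid ends below its start under the endpoint rule
  losing <- tj$labels %in% c("early_loss", "late_loss", "transient_increase")
  bound <- ifelse(losing, runif(3000) < 0.30, runif(3000) < 0.15)
  enr <- cluster_binding_enrichment(cl, bound)
  expect_lt(abs(enr$fraction_decreasing - 0.30), 0.02)
  expect_lt(abs(enr$fraction_increasing - 0.15), 0.02)
  expect_lt(enr$p.value, 1e-6)
  expect_gt(enr$odds.ratio, 1)

  # equal fractions: no association signal
  bound_eq <- runif(3000) < 0.2
  expect_gt(cluster_binding_enrichment(cl, bound_eq)$p.value, 0.01)
})

test_that("motif-stratified decay tests each timepoint with rank-sum", {
  # identical strata: p = 1 at every timepoint
  traj <- matrix(rep(c(1, 2, 3, 4, 5), each = 6), 6)
  msd <- motif_stratified_decay(traj, rep(c(TRUE, FALSE), 3))
  expect_true(all(msd$tests$p.value == 1))

  # hand-enumerated exact case: {1,2,3} vs {4,5,6} -> p = 0.1
  t2 <- matrix(c(1, 2, 3, 4, 5, 6), 6)
  msd2 <- motif_stratified_decay(t2, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(msd2$tests$p.value, 0.1)

  # box-plot summary numbers
  s <- msd2$summaries
  expect_equal(s$median, c(2, 5))
  expect_equal(s$q1, c(1.5, 4.5))
  expect_equal(s$whisker_hi, c(3, 6))

  # exact enumeration equals the permutation oracle on small strata
  set.seed(52)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(6)
    p_exact <- wilcoxon_rank_sum(x, y, mode = "exact")$p.value
    p_perm <- oracle_perm_wilcoxon(x, y, B = 2e4, seed = i)
    expect_lt(abs(p_exact - p_perm), 0.015)
  }

  expect_error(motif_stratified_decay(t2, rep(TRUE, 6)), "non-empty")
})
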