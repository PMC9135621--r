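test_that("one-sample t-map matches the textbook formula", {
  d <- c(2L, 1L, 1L)
  m1 <- array(c(-1, 1), d); m2 <- array(c(1, 2), d); m3 <- array(c(1, 3), d)
  tm <- one_sample_t_map(list(m1, m2, m3))
  expect_equal(tm$df, 2L)
  # voxel 2 holds {1, 2, 3}: t = 2 / (1 / sqrt(3)) = 3.4641
  expect_equal(tm$data[2, 1, 1], 3.4641, tolerance = 1e-4)
  # voxel values {-1, 1, 1} -> t = 1/3 / (sd/sqrt(3)); check against oracle
  set.seed(4)
  maps <- lapply(1:7, function(i) array(rnorm(24), c(4, 3, 2)))
  tm2 <- one_sample_t_map(maps)
  flat <- sapply(maps, as.vector)
  oracle <- apply(flat, 1,
                  function(v) mean(v) / (sd(v) / sqrt(length(v))))
  expect_lt(max(abs(as.vector(tm2$data) - oracle)), 1e-10)
  expect_error(one_sample_t_map(maps[1]), "at least 2")
  # equal and opposite values give t = 0
  tm3 <- one_sample_t_map(list(m1, -m1))
  expect_equal(as.vector(tm3$data), c(0, 0))
})

test_that("t-to-z conversion is exact, monotone, odd and tail-stable", {
  expect_equal(t_to_z(0, 5), 0)
  expect_equal(t_to_z(3.29, 1e7), 3.29, tolerance = 1e-3)
  # independent quantile-composition oracle at t = 2, df = 17
  oracle <- qnorm(pt(2.0, 17))
  expect_equal(t_to_z(2.0, 17), oracle, tolerance = 1e-8)
  tt <- seq(-6, 6, by = 0.25)
  for (df in c(1, 5, 17, 100)) {
    z <- t_to_z(tt, df)
    expect_true(all(diff(z) > 0))
    expect_equal(z, -t_to_z(-tt, df), tolerance = 1e-12)
  }
  # far tails stay finite where naive pt/qnorm composition underflows
  expect_true(is.finite(t_to_z(60, 30)))
  expect_true(is.na(t_to_z(NA, 10)))
})

test_that("the cluster-defining threshold matches the two-tailed quantile", {
  expect_equal(cluster_defining_z(0.001), qnorm(0.9995))
  expect_equal(round(cluster_defining_z(0.001), 2), 3.29)
})

test_that("cluster labelling follows the chosen connectivity", {
  d <- c(6L, 6L, 6L)
  z <- array(0, d)
  # an all-zero z map yields no candidate clusters
  expect_equal(length(label_clusters(z, cdt = 3.29)$sizes), 0L)
  # one isolated suprathreshold voxel -> one candidate cluster of size 1
  z[3, 3, 3] <- 4
  lab <- label_clusters(z, cdt = 3.29)
  expect_equal(lab$sizes, 1L)
  # a planted 10-voxel bar at z = 5 -> exactly one cluster of size 10
  z2 <- array(0, c(12L, 4L, 4L)); z2[1:10, 2, 2] <- 5
  lab2 <- label_clusters(z2, cdt = 3.29)
  expect_equal(lab2$sizes, 10L)
  expect_equal(lab2$signs, 1L)
  # diagonal voxels merge under 26- but not 6-connectivity
  z3 <- array(0, c(4L, 4L, 4L)); z3[1, 1, 1] <- 5; z3[2, 2, 2] <- 5
  expect_equal(length(label_clusters(z3, connectivity = 6L)$sizes), 2L)
  expect_equal(length(label_clusters(z3, connectivity = 26L)$sizes), 1L)
  # opposite-sign neighbours never share a cluster
  z4 <- array(0, c(4L, 4L, 4L)); z4[1, 1, 1] <- 5; z4[2, 1, 1] <- -5
  l4 <- label_clusters(z4)
  expect_equal(sort(l4$signs), c(-1L, 1L))
})

test_that("permutation cluster inference finds a strong planted effect", {
  d <- c(12L, 12L, 12L)
  maps <- smooth_noise_maps(12, d, sd = 0.3, seed = 9L)
  block <- array(FALSE, d); block[5:7, 5:7, 5:7] <- TRUE
  maps <- maps + 2 * rep(as.vector(block), each = nrow(maps))
  res <- cluster_threshold(maps, n_perm = 200, perm_seed = 3L, dims = d)
  expect_gte(nrow(res$table), 1)
  big <- res$table[which.max(res$table$size), ]
  expect_lt(big$p_fwe, 0.05)
  expect_true(block[big$peak_i, big$peak_j, big$peak_k])
  # inference is invariant to participant order
  res2 <- cluster_threshold(maps[rev(seq_len(nrow(maps))), ],
                            n_perm = 200, perm_seed = 3L, dims = d)
  expect_equal(res$table, res2$table)
})

test_that("ROI means equal the loop-based oracle", {
  d <- c(5L, 5L, 2L)
  labels <- array(0L, d); labels[1:3, 1, 1] <- 1L; labels[5, 5, 2] <- 2L
  cmap <- array(7, d)
  expect_equal(unname(extract_roi_means(cmap, labels)), c(7, 7))
  set.seed(6)
  m <- array(rnorm(prod(d)), d)
  expect_equal(unname(extract_roi_means(m, labels)),
               c(mean(m[1:3, 1, 1]), m[5, 5, 2]), tolerance = 1e-12)
  expect_equal(length(extract_roi_means(m, array(0L, d))), 0L)
})

test_that("repeated-measures ANOVA matches sums-of-squares oracle", {
  set.seed(7)
  x <- matrix(rnorm(30), 10, 3,
              dimnames = list(NULL, c("placebo", "drug", "both")))
  res <- repeated_measures_anova(x)
  # brute-force within-subject decomposition
  gm <- mean(x)
  ss_cond <- nrow(x) * sum((colMeans(x) - gm)^2)
  ss_subj <- ncol(x) * sum((rowMeans(x) - gm)^2)
  ss_tot <- sum((x - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- ncol(x) - 1; df2 <- (nrow(x) - 1) * (ncol(x) - 1)
  F_oracle <- (ss_cond / df1) / (ss_err / df2)
  expect_equal(res$F, F_oracle, tolerance = 1e-8)
  expect_equal(res$p, pf(F_oracle, df1, df2, lower.tail = FALSE),
               tolerance = 1e-8)
  expect_equal(res$df1, df1); expect_equal(res$df2, df2)
  # two conditions: F equals the squared paired t
  res2 <- repeated_measures_anova(x[, 1:2])
  tt <- t.test(x[, 1], x[, 2], paired = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-8)
  # identical columns: no effect, no error variance
  res3 <- repeated_measures_anova(x[, c(1, 1, 1)])
  expect_equal(res3$F, 0); expect_equal(res3$p, 1)
  expect_error(repeated_measures_anova(cbind(x[, 1], NA)), "complete")
})

test_that("BH FDR matches the exhaustive step-up reference", {
  expect_equal(fdr_bh(0.03)$p_adjusted, 0.03)
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r$reject))
  expect_false(any(fdr_bh(c(0.5, 0.9))$reject))
  expect_equal(length(fdr_bh(numeric(0))$reject), 0L)
  # all subsets (sizes 1..6) of a fixed p-value grid against brute force
  grid <- c(0.001, 0.008, 0.039, 0.041, 0.2, 0.74)
  for (k in 1:6) {
    sets <- utils::combn(6, k)
    for (j in seq_len(ncol(sets))) {
      p <- grid[sets[, j]]
      got <- fdr_bh(p, q = 0.05)
      expect_equal(got$reject, bh_oracle_reject(p, 0.05))
      expect_true(all(got$p_adjusted >= p - 1e-15))
      expect_true(all(got$p_adjusted <= 1))
    }
  }
})
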