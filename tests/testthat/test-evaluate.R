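test_that("k-means separates well-separated clouds and handles k = 1", {
  set.seed(1)
  pts <- rbind(matrix(rnorm(60, 0), ncol = 2),
               matrix(rnorm(60, 8), ncol = 2))
  truth <- rep(0:1, each = 30)
  lab <- kmeans_cluster(pts, 2, seed = 5)
  expect_equal(adjusted_rand_index(lab, truth), 1)
  expect_identical(kmeans_cluster(pts, 1), rep(0L, 60))
  expect_error(kmeans_cluster(pts[1:3, ], 5), "exceeds")
  # duplicating every point preserves the partition structure
  lab2 <- kmeans_cluster(rbind(pts, pts), 2, seed = 5)
  expect_equal(adjusted_rand_index(lab2[1:60], lab2[61:120]), 1)
  expect_equal(adjusted_rand_index(lab2[1:60], truth), 1)
})

test_that("ARI matches hand-computed and degenerate cases", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 1, 1)), 0)
  expect_equal(adjusted_rand_index(rep(0, 5), 0:4), 0)
  expect_error(adjusted_rand_index(c(0, 1), c(0, 1, 2)), "length")
})

test_that("ARI agrees with a pair-counting oracle on all partitions of 6", {
  parts <- all_partitions(6)
  expect_length(parts, 203)                      # Bell number B6
  refs <- list(c(0, 0, 0, 1, 1, 1), c(0, 1, 2, 0, 1, 2),
               rep(0L, 6), 0:5, c(0, 0, 1, 1, 2, 2))
  for (ref in refs) {
    for (p in parts) {
      expect_equal(adjusted_rand_index(ref, p), ari_pair_oracle(ref, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("ARI agrees with an independent reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(3)
  for (i in 1:20) {
    a <- sample(0:3, 40, replace = TRUE)
    b <- sample(0:2, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("ARI of independent labelings concentrates near zero", {
  set.seed(11)
  vals <- replicate(100, {
    a <- sample(0:1, 1000, replace = TRUE)
    b <- sample(0:1, 1000, replace = TRUE)
    adjusted_rand_index(a, b)
  })
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("ARI is symmetric and invariant to label permutation", {
  set.seed(7)
  a <- sample(0:2, 50, replace = TRUE)
  b <- sample(0:3, 50, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_equal(adjusted_rand_index(a, b),
               adjusted_rand_index(2 - a, b))
})

test_that("the PCA baseline reflects snapshot variance structure", {
  n <- 5
  A <- complete_graph(n)
  g_const <- tevograph(rep(list(A), 6))
  emb <- pca_baseline(g_const, 2)
  expect_equal(max(abs(emb)), 0, tolerance = 1e-10)  # zero variance

  B <- path_graph(n)
  g_alt <- tevograph(rep(list(A, B), 5))
  e1 <- pca_baseline(g_alt, 1)
  lab <- kmeans_cluster(e1, 2, seed = 1)
  expect_equal(adjusted_rand_index(lab, rep(0:1, 5)), 1)

  # reconstruction error is non-increasing in d
  g <- rand_tevograph(n = 6, T_ = 15, seed = 9)
  X <- t(vapply(g$snapshots, as.numeric, numeric(36)))
  Xc <- scale(X, scale = FALSE)
  errs <- vapply(1:4, function(d) {
    s <- svd(Xc, nu = d, nv = d)
    sum((Xc - s$u %*% diag(s$d[1:d], d) %*% t(s$v))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(pca_baseline(g, 100), "exceeds")

  # embedding is invariant (up to sign) to snapshot order
  ord <- sample(1:15)
  e_perm <- pca_baseline(tevograph(g$snapshots[ord]), 2)
  e_orig <- pca_baseline(g, 2)[ord, ]
  for (j in 1:2)
    expect_true(isTRUE(all.equal(e_perm[, j], e_orig[, j], tolerance = 1e-6)) ||
                isTRUE(all.equal(e_perm[, j], -e_orig[, j], tolerance = 1e-6)))
})

test_that("metastability diagnostics recover transition structure", {
  d_const <- metastability_diagnostics(rep(2L, 10), s = 3)
  expect_equal(d_const$transition_matrix[3, 3], 1)
  expect_equal(d_const$stay_probability, 1)

  d_alt <- metastability_diagnostics(rep(c(0L, 1L), 10))
  expect_equal(diag(d_alt$transition_matrix), c(0, 0))
  expect_equal(d_alt$stay_probability, 0)

  # seeded two-state chain with known flip rate
  eps <- 0.05
  set.seed(13)
  T_ <- 4000
  st <- integer(T_)
  for (t in 2:T_) st[t] <- if (runif(1) < eps) 1L - st[t - 1] else st[t - 1]
  dg <- metastability_diagnostics(st)
  se <- sqrt(eps * (1 - eps) / (T_ / 2))
  expect_lt(abs(dg$transition_matrix[1, 1] - (1 - eps)), 3 * se)
  expect_lt(abs(dg$transition_matrix[2, 2] - (1 - eps)), 3 * se)
  expect_error(metastability_diagnostics(1L), "2 time points")
})

test_that("temporal splits are contiguous and cover the sequence", {
  sp <- temporal_split(100)
  expect_identical(sp$train, 1:80)
  expect_identical(sp$test, 81:100)
  expect_identical(sort(c(sp$train, sp$test)), 1:100)
  sp2 <- temporal_split(5, train_frac = 0.5)
  expect_identical(sp2$train, 1:2)
})

test_that("evaluate_embedding clusters the full sequence, scores the test", {
  set.seed(5)
  states <- rep(rep(c(0L, 1L), each = 10), 5)
  emb <- matrix(rnorm(200, mean = rep(states * 6, 2)), ncol = 2)
  ev <- evaluate_embedding(emb, states, seed = 2)
  expect_length(ev$labels, 100)
  expect_equal(ev$ari, 1)
  expect_identical(ev$indices, 81:100)
  expect_gte(ev$stay_probability, 0.9)
})
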