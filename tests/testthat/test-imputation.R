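test_that("every method passes observed entries through and completes the matrix", {
  md <- tiny_masked(alpha = 0.2, beta = 0.5, seed = 3)
  for (m in all_methods) {
    imp <- impute(md, m)
    expect_false(anyNA(imp$values))
    expect_identical(imp$values[!md$mask], md$observed[!md$mask])
  }
})

test_that("imputation with no missing entries returns the input for every method", {
  md <- tiny_masked(alpha = 0, beta = 0.5)
  for (m in all_methods) {
    imp <- impute(md, m)
    expect_identical(imp$values, md$observed)
  }
})

test_that("imputation is deterministic for a fixed seed", {
  md <- tiny_masked(alpha = 0.2, beta = 0.5, seed = 11)
  for (m in all_methods) {
    a <- impute(md, imputation_config(m, seed = 42))
    b <- impute(md, imputation_config(m, seed = 42))
    expect_identical(a$values, b$values)
  }
  # stochastic methods differ across seeds
  for (m in c("ND", "RF")) {
    a <- impute(md, imputation_config(m, seed = 1))
    b <- impute(md, imputation_config(m, seed = 2))
    expect_false(identical(a$values, b$values))
  }
})

test_that("LOD substitutes the global observed minimum", {
  truth <- matrix(c(5, 7, 9, 6, 8, 10), 3, 2)
  mask <- matrix(c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE), 3, 2)
  imp <- impute_lod(masked_from(truth, mask))
  expect_equal(unique(imp$values[mask]), 5)

  # property: the matrix minimum never changes
  set.seed(21)
  for (s in 1:5) {
    m <- matrix(rnorm(200, 20, 2), 20, 10)
    mk <- matrix(runif(200) < 0.3, 20, 10)
    mk[1, ] <- FALSE                      # keep every row partly observed
    imp <- impute_lod(masked_from(m, mk))
    expect_equal(min(imp$values), min(m[!mk]))
  }
})

test_that("ND draws from the downshifted narrowed normal", {
  set.seed(31)
  truth <- matrix(rnorm(300 * 40, 20, 1), 300, 40)
  mask <- matrix(runif(300 * 40) < 1 / 12, 300, 40)
  md <- masked_from(truth, mask)
  mu_m <- mean(md$observed[!mask])
  sd_m <- sd(md$observed[!mask])
  imp <- impute_nd(md, imputation_config("ND", seed = 5))
  vals <- imp$values[mask]
  n <- length(vals)
  expect_gt(n, 800)
  expect_equal(mean(vals), mu_m - 2.2 * sd_m,
               tolerance = 4 * 0.3 * sd_m / sqrt(n) / abs(mu_m - 2.2 * sd_m))
  expect_equal(sd(vals), 0.3 * sd_m, tolerance = 0.05)
  # the imputed distribution sits in the left tail
  expect_lt(quantile(vals, 0.99), mu_m)

  # degenerate width: all draws collapse onto the downshifted mean
  imp0 <- impute_nd(md, imputation_config("ND", nd_width = 1e-9, seed = 5))
  expect_equal(unique(round(imp0$values[mask] - (mu_m - 2.2 * sd_m), 6)), 0)

  # per-sample variant uses column statistics
  imp_ps <- impute_nd(md, imputation_config("ND", nd_per_sample = TRUE,
                                            seed = 5))
  j <- which(colSums(mask) > 5)[1]
  mu_j <- mean(md$observed[!mask[, j], j])
  expect_lt(mean(imp_ps$values[mask[, j], j]), mu_j)
})

test_that("kNN averages the k nearest protein neighbours", {
  # a twin row at distance zero dominates with k = 1
  truth <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(9, 9, 9, 9))
  mask <- matrix(FALSE, 3, 4); mask[1, 4] <- TRUE
  imp <- impute_knn(masked_from(truth, mask),
                    imputation_config("KNN", k_neighbors = 1))
  expect_equal(imp$values[1, 4], 4)

  # brute-force oracle on a 5x3 matrix with k = 2
  truth <- matrix(c(1.0, 2.0, 3.0,
                    1.1, 2.1, 3.2,
                    5.0, 5.5, 6.0,
                    0.9, 1.8, 2.9,
                    4.0, 1.0, 0.5), 5, 3, byrow = TRUE)
  mask <- matrix(FALSE, 5, 3); mask[1, 3] <- TRUE
  obs <- truth; obs[mask] <- NA
  # independent enumeration: scaled Euclidean distance over co-observed cols
  cand <- 2:5
  d <- sapply(cand, function(q) {
    shared <- 1:2                       # target observed in cols 1:2 only
    sqrt(3 / length(shared) * sum((obs[1, shared] - obs[q, shared])^2))
  })
  near <- cand[order(d)[1:2]]
  expected <- mean(obs[near, 3])
  imp <- impute_knn(masked_from(truth, mask),
                    imputation_config("KNN", k_neighbors = 2))
  expect_equal(imp$values[1, 3], expected)

  # constant matrix stays constant
  truth <- matrix(7, 6, 4)
  mask <- matrix(FALSE, 6, 4); mask[2, 2] <- TRUE
  imp <- impute_knn(masked_from(truth, mask),
                    imputation_config("KNN", k_neighbors = 3))
  expect_equal(imp$values[2, 2], 7)
})

test_that("LLS recovers exact linear structure and matches a pseudoinverse oracle", {
  # target is an exact linear function of two complete neighbours
  set.seed(7)
  n1 <- rnorm(8); n2 <- rnorm(8)
  target <- 2 * n1 - 0.5 * n2
  truth <- rbind(target, n1, n2, rnorm(8), rnorm(8))
  mask <- matrix(FALSE, 5, 8); mask[1, c(3, 7)] <- TRUE
  imp <- impute_lls(masked_from(truth, mask),
                    imputation_config("LLS", k_similar = 4))
  expect_equal(imp$values[1, c(3, 7)], target[c(3, 7)], tolerance = 1e-8,
               ignore_attr = TRUE)

  # minimum-norm least-squares oracle on a 6x4 matrix, k = 3
  set.seed(8)
  truth <- matrix(rnorm(24, 10, 2), 6, 4)
  mask <- matrix(FALSE, 6, 4); mask[1, 4] <- TRUE
  obs <- truth; obs[mask] <- NA
  y <- obs[1, 1:3]
  r <- abs(apply(obs[2:6, 1:3], 1, function(z) cor(z, y)))
  nbrs <- (2:6)[order(-r)[1:3]]
  A <- t(obs[nbrs, 1:3])                 # 3 equations, 3 unknowns
  w <- MASS::ginv(A) %*% y
  expected <- drop(t(obs[nbrs, 4]) %*% w)
  imp <- impute_lls(masked_from(truth, mask),
                    imputation_config("LLS", k_similar = 3))
  expect_equal(imp$values[1, 4], expected, tolerance = 1e-8)

  # identical rows share their value
  truth <- matrix(rep(c(3, 1, 4, 1, 5), each = 4), 4, 5)
  mask <- matrix(FALSE, 4, 5); mask[2, 5] <- TRUE
  imp <- impute_lls(masked_from(truth, mask), imputation_config("LLS"))
  expect_equal(imp$values[2, 5], 5, tolerance = 1e-8)
})

test_that("RF imputation learns cross-sample structure", {
  set.seed(3)
  x1 <- rnorm(500)
  truth <- cbind(a = x1, b = 2 * x1 + 1)
  mask <- matrix(FALSE, 500, 2)
  mask[sample(500, 25), 2] <- TRUE
  md <- masked_from(truth, mask)
  imp <- impute_rf(md, imputation_config("RF", seed = 1))
  rmse_rf <- sqrt(mean((imp$values[mask] - truth[mask])^2))
  rmse_mean <- sqrt(mean((mean(truth[!mask[, 2], 2]) - truth[, 2][mask[, 2]])^2))
  expect_lt(rmse_rf, 0.25 * rmse_mean)

  # forest predictions are averages of observed targets: range containment
  expect_true(all(imp$values[mask] >= min(truth[!mask[, 2], 2])))
  expect_true(all(imp$values[mask] <= max(truth[!mask[, 2], 2])))

  expect_error(impute_rf(masked_from(matrix(1:5, 5, 1),
                                     matrix(FALSE, 5, 1))), "2 columns")
})

test_that("SVD imputation completes low-rank structure and terminates", {
  # exact rank-1 matrix: one masked entry is recovered
  u <- c(1, 2, 3, 4, 5); v <- c(2, 4, 6, 8)
  truth <- outer(u, v)
  mask <- matrix(FALSE, 5, 4); mask[2, 3] <- TRUE
  imp <- impute_svd(masked_from(truth, mask),
                    imputation_config("SVD", npcs = 1, tol = 1e-9))
  expect_equal(imp$values[2, 3], truth[2, 3], tolerance = 1e-6 * truth[2, 3])

  # convergence trace is non-increasing after the first sweep
  for (s in 1:10) {
    set.seed(s)
    M <- matrix(rnorm(100 * 2), 100, 2) %*% matrix(rnorm(2 * 10), 2, 10) +
      matrix(rnorm(1000, 0, 0.05), 100, 10)
    mk <- matrix(runif(1000) < 0.1, 100, 10)
    imp <- suppressWarnings(
      impute_svd(masked_from(M, mk),
                 imputation_config("SVD", npcs = 2, tol = 1e-9,
                                   max_iter = 50)))
    tr <- imp$diagnostics$trace
    expect_true(all(diff(tr[-1]) <= 1e-12))
  }

  # near-full-rank request still terminates via the iteration guard
  set.seed(30)
  M <- matrix(rnorm(80), 10, 8)
  mk <- matrix(runif(80) < 0.15, 10, 8)
  expect_warning(
    imp <- impute_svd(masked_from(M, mk),
                      imputation_config("SVD", npcs = 7, tol = 1e-12,
                                        max_iter = 5)),
    "converge")
  expect_false(imp$diagnostics$converged)
  expect_false(anyNA(imp$values))
})

test_that("BPCA completes noisy low-rank data and prunes surplus components", {
  set.seed(11)
  u <- rnorm(200); v <- rnorm(12)
  truth <- outer(u, v) + matrix(rnorm(2400, 0, 0.01), 200, 12)
  mk <- matrix(runif(2400) < 0.1, 200, 12)
  imp <- impute_bpca(masked_from(truth, mk), imputation_config("BPCA"))
  expect_lt(nrmse_abundance(imp, truth, mk), 0.2)

  # ARD: with npcs = 5 on rank-2 data, at least 3 loading columns vanish
  set.seed(12)
  M <- matrix(rnorm(100 * 2), 100, 2) %*% matrix(rnorm(2 * 10), 2, 10) +
    matrix(rnorm(1000, 0, 0.05), 100, 10)
  mk2 <- matrix(runif(1000) < 0.1, 100, 10)
  imp2 <- impute_bpca(masked_from(M, mk2),
                      imputation_config("BPCA", npcs = 5, max_iter = 200))
  ln <- sort(imp2$diagnostics$loading_norms, decreasing = TRUE)
  expect_gte(sum(ln < 0.1 * ln[2]), 3)
})

test_that("left-censored imputers sit below the observed distribution", {
  md <- tiny_masked(alpha = 0.25, beta = 0.5, seed = 9)
  lod <- impute_lod(md)
  nd <- impute_nd(md, imputation_config("ND", seed = 2))
  expect_lte(mean(lod$values[md$mask]), mean(nd$values[md$mask]))
  expect_lt(mean(nd$values[md$mask]), mean(md$observed[!md$mask]))
})

test_that("configuration invariants are enforced", {
  expect_error(imputation_config("NOPE"), "unknown method")
  expect_error(imputation_config("KNN", k_neighbors = 0), "k_neighbors")
  expect_error(imputation_config("ND", nd_width = 0), "nd_width")
  md <- tiny_masked()
  expect_error(impute_svd(md, imputation_config("SVD", npcs = 40)), "npcs")
})
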