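planted_two_clusters <- function(n = 40, p = 6, sep = 4, seed = 51) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X[seq_len(n / 2), 1L] <- X[seq_len(n / 2), 1L] + sep
  list(X = X, truth = rep(1:2, each = n / 2))
}

test_that("weights concentrate on the separating feature as s -> 1", {
  d <- planted_two_clusters(sep = 6)
  fit <- sparse_kmeans(d$X, k = 2, s = 1.1, seed = 3)
  expect_gt(fit$weights[1L], 0.99)
  expect_gte(adjusted_rand_index(fit$labels, d$truth), 0.9)
})

test_that("the unpenalized limit reduces to plain k-means", {
  # exchangeable features (equal per-feature BCSS): weights collapse to
  # the uniform vector and labels coincide with unweighted k-means
  set.seed(52)
  n <- 30; p <- 4
  base <- c(rnorm(n / 2) + 4, rnorm(n / 2))
  X <- matrix(rep(base, p), n, p)
  fit <- sparse_kmeans(X, k = 2, s = sqrt(p), seed = 5)
  expect_equal(unname(fit$weights), rep(1 / sqrt(p), p), tolerance = 1e-8)
  km <- kmeans(X, 2, nstart = 20)
  expect_equal(adjusted_rand_index(fit$labels, km$cluster), 1)
})

test_that("tiny instances match the exhaustive weighted-BCSS search", {
  for (seed in c(61, 62, 63)) {
    set.seed(seed)
    X <- matrix(rnorm(12), 6, 2)
    s <- 1.3
    fit <- sparse_kmeans(X, k = 2, s = s, n_restarts = 30, seed = seed)
    oracle <- oracle_sparse_2means(X, s)
    expect_equal(fit$objective, oracle$objective, tolerance = 1e-8)
    expect_equal(adjusted_rand_index(fit$labels, oracle$labels), 1)
  }
})

test_that("weight constraints hold and the objective never decreases", {
  d <- planted_two_clusters(n = 30, p = 5, sep = 2)
  for (s in c(1.2, 1.8, sqrt(5))) {
    fit <- sparse_kmeans(d$X, k = 2, s = s, seed = 9)
    expect_true(all(fit$weights >= 0))
    expect_equal(sum(fit$weights^2), 1, tolerance = 1e-8)
    expect_lte(sum(fit$weights), s + 1e-8)
    expect_true(all(diff(fit$objective_trace) >= -1e-8))
  }
})

test_that("sparse k-means is deterministic given its seed", {
  d <- planted_two_clusters(seed = 55)
  f1 <- sparse_kmeans(d$X, k = 2, s = 2, seed = 10)
  f2 <- sparse_kmeans(d$X, k = 2, s = 2, seed = 10)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$weights, f2$weights)
})

test_that("degenerate inputs are rejected", {
  expect_error(sparse_kmeans(matrix(rnorm(4), 1, 4), k = 2, s = 1.5),
               "fewer samples")
  expect_error(sparse_kmeans(matrix(1, 10, 3), k = 2, s = 1.5),
               "zero-variance")
  expect_error(sparse_kmeans(matrix(rnorm(20), 10, 2), k = 2, s = 0.5),
               "s must lie")
  expect_error(sparse_kmeans(matrix(rnorm(20), 10, 2), k = 2, s = 5),
               "s must lie")
})

test_that("the permutation gap statistic picks a sensible bound", {
  d <- planted_two_clusters(n = 40, p = 8, sep = 5, seed = 57)
  sel <- choose_sparsity(d$X, k = 2, n_perms = 8, seed = 4)
  expect_true(sel$s > 1 && sel$s <= sqrt(8) + 1e-8)
  expect_length(sel$gaps, length(sel$s_grid))
  # signal only in feature 1: the selected bound should stay well below
  # the unpenalized limit
  expect_lt(sel$s, sqrt(8))
})
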