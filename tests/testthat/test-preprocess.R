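test_that("magnitude normalization scales samples to the common median", {
  m <- tiny_expr(cbind(c(5, 10, 15), c(10, 20, 30)), scale_flag = "raw")
  out <- magnitude_normalize(m)
  # sample medians 10 and 20, target median(10, 20) = 15
  expect_equal(unname(attr(out, "norm_factors")), c(1.5, 0.75))
  expect_equal(apply(out$values, 2L, median), c(s01 = 15, s02 = 15))

  same <- tiny_expr(cbind(c(1, 2, 3), c(3, 2, 1)), scale_flag = "raw")
  expect_equal(magnitude_normalize(same)$values, same$values)

  single <- tiny_expr(matrix(c(1, 2, 3), 3), scale_flag = "raw")
  expect_equal(magnitude_normalize(single)$values, single$values)

  expect_error(magnitude_normalize(tiny_expr(matrix(c(-1, 2), 2),
                                             scale_flag = "raw")),
               "positive")
  expect_error(magnitude_normalize(tiny_expr(matrix(1:4, 2))), "raw")
})

test_that("log2 transform matches the exponential identity", {
  m <- tiny_expr(matrix(c(8, 1, 2, 0.5), 2), scale_flag = "raw")
  out <- log2_transform(m)
  expect_equal(out$values[1L, 1L], 3)
  expect_equal(out$values[2L, 1L], 0)
  expect_identical(out$scale_flag, "log2")

  rnd <- random_raw_expr(p = 12, n = 5, seed = 4)
  expect_equal(2^log2_transform(rnd)$values, rnd$values, tolerance = 1e-12)

  bad <- tiny_expr(matrix(c(1, 0), 2), scale_flag = "raw")
  expect_error(log2_transform(bad), "probe 'g02', sample 's01'")
})

test_that("batch removal recenters batches on the grand mean", {
  # one gene, batch means 5 and 7, grand mean 6 -> +1 and -1
  m <- tiny_expr(matrix(c(4, 6, 6, 8), 1), scale_flag = "log2",
                 batch = c("a", "a", "b", "b"))
  out <- remove_batch_effect(m)
  expect_equal(unname(out$values[1L, ]), c(5, 7, 5, 7))

  single <- tiny_expr(matrix(1:4, 1), scale_flag = "log2",
                      batch = rep("a", 4))
  expect_message(out2 <- remove_batch_effect(single), "single batch")
  expect_equal(out2$values, single$values)

  set.seed(8)
  big <- tiny_expr(matrix(rnorm(60), 5), scale_flag = "log2",
                   batch = rep(c("a", "b", "c"), each = 4))
  adj <- remove_batch_effect(big)
  for (b in c("a", "b", "c")) {
    bm <- rowMeans(adj$values[, adj$batch == b])
    expect_equal(bm, rowMeans(adj$values), tolerance = 1e-9)
  }

  lone <- tiny_expr(matrix(rnorm(15), 5), scale_flag = "log2",
                    batch = c("a", "a", "b"))
  expect_warning(out3 <- remove_batch_effect(lone), "single sample")
  expect_equal(out3$values[, 3L], lone$values[, 3L])
})

test_that("mean centering is exact and idempotent", {
  m <- tiny_expr(rbind(c(2, 2, 2), c(1, 2, 3)), scale_flag = "log2")
  out <- mean_center(m)
  expect_equal(unname(out$values[1L, ]), c(0, 0, 0))
  expect_equal(unname(out$values[2L, ]), c(-1, 0, 1))
  expect_equal(mean_center(out)$values, out$values)
  set.seed(2)
  rnd <- tiny_expr(matrix(rnorm(40), 8), scale_flag = "log2")
  expect_true(all(abs(rowMeans(mean_center(rnd)$values)) < 1e-9))
})

test_that("probe collapsing keeps the most variable probe per gene", {
  vals <- rbind(c(0, 2, 4),    # var 4
                c(1, 1.5, 2),  # var 0.25
                c(5, 5, 6))
  m <- expression_matrix(vals, probe_ids = c("pA", "pB", "pC"),
                         gene_ids = c("G1", "G1", "G2"),
                         sample_ids = c("s1", "s2", "s3"),
                         scale_flag = "log2")
  out <- collapse_probes(m)
  expect_identical(out$probe_ids, c("pA", "pC"))
  expect_identical(out$gene_ids, c("G1", "G2"))

  # exact variance tie -> lexicographically smaller probe id retained
  tie <- expression_matrix(rbind(c(0, 1), c(1, 0)),
                           probe_ids = c("p2", "p1"),
                           gene_ids = c("G", "G"),
                           sample_ids = c("s1", "s2"),
                           scale_flag = "log2")
  expect_identical(collapse_probes(tie)$probe_ids, "p1")
})

test_that("variance filtering selects top-k and commutes with permutation", {
  set.seed(5)
  vals <- matrix(rnorm(50), 5) * c(3, 0.1, 2, 0.5, 1)
  m <- tiny_expr(vals, scale_flag = "log2")
  out <- select_most_variable(m, 2L)
  v <- apply(vals, 1L, var)
  expect_setequal(out$gene_ids,
                  m$gene_ids[order(-v)][1:2])

  expect_warning(all_kept <- select_most_variable(m, 10L), "keeping all")
  expect_equal(nrow(all_kept$values), 5L)

  perm <- sample(ncol(vals))
  mp <- tiny_expr(vals[, perm], samples = m$sample_ids[perm],
                  scale_flag = "log2")
  expect_setequal(select_most_variable(mp, 2L)$gene_ids, out$gene_ids)
})

test_that("the preprocessing chain runs in the fixed stage order", {
  sim <- generate_expression(cohort_spec(n_per_subtype =
    c("LAR" = 10, "basal" = 10, "CLDN-low" = 5, "CLDN-high" = 5),
    n_noise_genes = 10L, seed = 2L))
  out <- preprocess_expression(sim$expression, top_k = 100L)
  steps <- names(attr(out, "steps"))
  expect_identical(steps, c("magnitude_normalize", "log2", "remove_batch",
                            "mean_center", "collapse_probes",
                            "select_most_variable"))
  expect_identical(out$scale_flag, "centered")
  expect_equal(nrow(out$values), 100L)
  expect_true(all(abs(rowMeans(out$values)) < 1e-9))
})
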