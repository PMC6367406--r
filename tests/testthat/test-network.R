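test_that("Gaussian mutual information follows the closed form", {
  expect_equal(gaussian_mi(0), 0)
  expect_equal(gaussian_mi(0.8), -0.5 * log(1 - 0.64))
  expect_equal(gaussian_mi(0.8), 0.5108, tolerance = 1e-4)
  expect_equal(gaussian_mi(-0.8), gaussian_mi(0.8))
  expect_warning(capped <- gaussian_mi(1), "capped")
  expect_true(is.finite(capped))
})

test_that("association graph equals the pairwise correlation oracle", {
  set.seed(13)
  m <- tiny_expr(matrix(rnorm(4 * 10), 4), scale_flag = "centered")
  g <- build_association_graph(m)
  expect_equal(nrow(g$edges), choose(4, 2))
  for (k in seq_len(nrow(g$edges))) {
    a <- m$values[g$edges$gene_a[k], ]
    b <- m$values[g$edges$gene_b[k], ]
    expect_equal(g$edges$weight[k], -0.5 * log(1 - cor(a, b)^2))
  }
  expect_true(all(g$edges$gene_a < g$edges$gene_b))

  flat <- tiny_expr(rbind(rnorm(5), rep(1, 5)), scale_flag = "centered")
  expect_error(build_association_graph(flat), "g02")

  dup <- tiny_expr(rbind(1:5, 1:5), scale_flag = "centered")
  expect_warning(gd <- build_association_graph(dup), "capped")
  expect_equal(gd$edges$weight, -0.5 * log(1e-12), tolerance = 1e-5)
})

test_that("spanning forest matches exhaustive maximization", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 4L + (seed %% 3L)
    m <- tiny_expr(matrix(rnorm(n * 12), n), scale_flag = "centered")
    g <- build_association_graph(m)
    forest <- max_spanning_forest(g, min_edge_weight = 0)
    W <- matrix(0, n, n, dimnames = list(m$gene_ids, m$gene_ids))
    for (k in seq_len(nrow(g$edges)))
      W[g$edges$gene_a[k], g$edges$gene_b[k]] <-
        W[g$edges$gene_b[k], g$edges$gene_a[k]] <- g$edges$weight[k]
    expect_equal(sum(forest$edges$weight),
                 oracle_max_forest_weight(W, 0))
    expect_equal(nrow(forest$edges), n - 1L)  # connected: spanning tree
  }
})

test_that("spanning forest agrees with igraph on larger instances", {
  set.seed(99)
  m <- tiny_expr(matrix(rnorm(15 * 30), 15), scale_flag = "centered")
  g <- build_association_graph(m)
  forest <- max_spanning_forest(g, min_edge_weight = 0)
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE)
  mst <- igraph::mst(ig, weights = -igraph::E(ig)$weight)
  expect_equal(sum(forest$edges$weight),
               sum(igraph::E(mst)$weight * -1) * -1)
})

test_that("edge threshold and ties behave deterministically", {
  set.seed(3)
  m <- tiny_expr(matrix(rnorm(5 * 8), 5), scale_flag = "centered")
  g <- build_association_graph(m)
  expect_equal(nrow(max_spanning_forest(g, Inf)$edges), 0L)

  # all weights equal: run-twice identity through the lexicographic order
  g2 <- g
  g2$edges$weight <- 1
  f1 <- max_spanning_forest(g2, 0)
  f2 <- max_spanning_forest(g2, 0)
  expect_identical(f1$edges, f2$edges)
  expect_equal(nrow(f1$edges), 4L)
})

test_that("branch splitting follows the lightest-edge cut order", {
  forest <- structure(list(
    genes = c("a", "b", "c", "d"),
    edges = data.frame(gene_a = c("a", "b", "c"),
                       gene_b = c("b", "c", "d"),
                       weight = c(3, 1, 2)),
    structure = "forest"), class = "assoc_graph")
  br <- split_branches(forest, max_branch_size = 2L, min_branch_size = 2L)
  expect_equal(lapply(br, `[[`, "genes"),
               list(c("a", "b"), c("c", "d")))

  # already small enough: one branch per component
  br2 <- split_branches(forest, max_branch_size = 4L, min_branch_size = 2L)
  expect_length(br2, 1L)
  expect_identical(br2[[1L]]$genes, c("a", "b", "c", "d"))

  # conservation at min_branch_size = 1
  br3 <- split_branches(forest, max_branch_size = 1L, min_branch_size = 1L)
  expect_setequal(unlist(lapply(br3, `[[`, "genes")), forest$genes)

  expect_error(split_branches(forest, 1L, 5L), "max_branch_size")
})

test_that("planted modules are recovered as branches", {
  mods <- lapply(1:4, function(i)
    module_spec(sprintf("m%d", i), "other",
                sprintf("M%dG%02d", i, 1:15), rho = 0.8))
  spec <- cohort_spec(n_per_subtype = c("LAR" = 75, "basal" = 75,
                                        "CLDN-low" = 0, "CLDN-high" = 0),
                      modules = mods, n_noise_genes = 30L,
                      batch_count = 1L, batch_shift = 0, seed = 17L)
  sim <- generate_expression(spec, emit = "log2")
  m <- mean_center(sim$expression)
  forest <- max_spanning_forest(build_association_graph(m))
  br <- suppressMessages(split_branches(forest, 150L, 10L))
  membership <- rep(NA_character_, length(m$gene_ids))
  names(membership) <- m$gene_ids
  for (b in br) membership[b$genes] <- b$branch_id
  truth_mod <- sub("G.*", "", grep("^M", m$gene_ids, value = TRUE))
  got <- membership[grep("^M", m$gene_ids, value = TRUE)]
  # every module concentrated in one branch
  for (mod in unique(truth_mod)) {
    tab <- table(got[truth_mod == mod], useNA = "always")
    expect_gte(max(tab) / 15, 0.9)
  }
  keep <- !is.na(got)
  expect_gte(adjusted_rand_index(truth_mod[keep], got[keep]), 0.8)
})
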