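# Shared fixture builders; everything is generated in code at test time.

# Small deterministic expression matrix (collapsed, centered unless stated).
tiny_expr <- function(values, genes = NULL, samples = NULL,
                      scale_flag = "centered", batch = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  expression_matrix(values, probe_ids = genes, gene_ids = genes,
                    sample_ids = samples, batch = batch,
                    scale_flag = scale_flag)
}

# Random seeded positive matrix on the raw scale.
random_raw_expr <- function(p = 10, n = 6, seed = 1) {
  set.seed(seed)
  tiny_expr(matrix(stats::rexp(p * n, rate = 0.1) + 1, p, n),
            scale_flag = "raw")
}

# Minimal functional-node object.
fake_node <- function(id, genes)
  structure(list(node_id = id, genes = genes, label_term = id,
                 term_id = id, enrichment_p = 0.001, enrichment_q = 0.001),
            class = "functional_node")

# Sparse k-means result wrapper for orientation tests.
fake_skm <- function(labels) {
  structure(list(labels = labels, weights = 1, s = 1.5, objective = 1),
            class = "sparse_kmeans")
}

# Reduced-size cohort settings for fast pipeline tests: default module
# layout, 200 samples at the default subtype mix.
small_cohort_args <- function(seed = 7L)
  list(n_per_subtype = c("LAR" = 36, "basal" = 126, "CLDN-low" = 22,
                         "CLDN-high" = 16),
       n_noise_genes = 60L, seed = seed)

fast_control <- function(seed = 7L)
  tnbc_control(n_restarts = 8L, n_perms = 5L, seed = seed)

# Exhaustive maximum-weight spanning forest oracle: enumerates all labeled
# spanning trees via Pruefer sequences (n <= 7), drops edges below the
# threshold from each tree, and returns the best achievable total weight.
# With all pairwise weights above the threshold this is the maximum
# spanning tree weight.
oracle_max_forest_weight <- function(w, min_edge_weight = -Inf) {
  n <- nrow(w)
  stopifnot(n >= 3, n <= 7)
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- -Inf
  for (k in seq_len(nrow(seqs))) {
    prufer <- seqs[k, ]
    degree <- rep(1L, n)
    for (v in prufer) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1, 2)
    deg <- degree
    avail <- prufer
    for (i in seq_along(avail)) {
      leaf <- min(which(deg == 1L))
      edges[i, ] <- c(leaf, avail[i])
      deg[leaf] <- 0L
      deg[avail[i]] <- deg[avail[i]] - 1L
    }
    last <- which(deg == 1L)
    edges[n - 1, ] <- last
    ww <- w[edges]
    tw <- sum(ww[ww >= min_edge_weight])
    if (tw > best) best <- tw
  }
  best
}

# Exhaustive sparse 2-means oracle on tiny instances: maximizes the
# weighted BCSS over every 2-partition, with the optimal weights for each
# partition given by the soft-threshold update.
oracle_sparse_2means <- function(X, s) {
  n <- nrow(X)
  best <- list(objective = -Inf)
  for (code in 1:(2^(n - 1) - 1)) {
    labels <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(labels)) < 2L) next
    a <- tnbctype:::feature_bcss(X, labels)
    w <- tnbctype:::update_weights(a, s)
    obj <- sum(w * a)
    if (obj > best$objective)
      best <- list(objective = obj, labels = labels, weights = w)
  }
  best
}
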