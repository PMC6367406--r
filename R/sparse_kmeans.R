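# Sparse k-means (Witten & Tibshirani): k-means with nonnegative feature
# weights w, ||w||_2 = 1 and ||w||_1 <= s, maximizing the weighted
# between-cluster sum of squares  sum_j w_j * BCSS_j.

# Per-feature between-cluster sum of squares for a given partition,
# computed on the unweighted data.
feature_bcss <- function(X, labels) {
  tss <- colSums(sweep(X, 2L, colMeans(X))^2)
  wss <- rep(0, ncol(X))
  for (cl in unique(labels)) {
    idx <- labels == cl
    sub <- X[idx, , drop = FALSE]
    wss <- wss + colSums(sweep(sub, 2L, colMeans(sub))^2)
  }
  tss - wss
}

# Weight update: w = S(a, delta)_+ / ||S(a, delta)_+||_2 with the soft
# threshold delta found by bisection so that ||w||_1 = s (delta = 0 when
# the unthresholded weights already satisfy the L1 bound).
update_weights <- function(a, s) {
  soft <- function(delta) pmax(a - delta, 0)
  norm_w <- function(delta) {
    v <- soft(delta)
    n2 <- sqrt(sum(v^2))
    if (n2 == 0) rep(0, length(v)) else v / n2
  }
  w <- norm_w(0)
  if (sum(w) <= s + 1e-10) return(w)
  lo <- 0
  hi <- max(a)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(norm_w(mid)) > s) lo <- mid else hi <- mid
  }
  norm_w((lo + hi) / 2)
}

#' Sparse k-means clustering
#'
#' Alternating optimization of the weighted between-cluster sum of squares:
#' (a) given weights `w`, k-means on the feature-rescaled data
#' `X diag(sqrt(w))` (warm-started from the previous centers, so the
#' objective never decreases); (b) given labels, per-feature BCSS `a_j` is
#' soft-thresholded and renormalized into new weights under the constraints
#' `w >= 0`, `||w||_2 = 1`, `||w||_1 <= s`. Best of `n_restarts` random
#' initializations; deterministic given `seed`.
#'
#' @param X Numeric matrix, samples x features.
#' @param k Number of clusters (default 2, the high/low split).
#' @param s L1 sparsity bound in `(1, sqrt(p)]`; `NULL` (default) selects it
#'   by the permutation gap statistic ([choose_sparsity()]).
#' @param n_restarts Random restarts (default 20).
#' @param max_iter Maximum alternations per restart (default 20).
#' @param seed Integer seed; mandatory for reproducible runs.
#' @param n_perms,s_grid_length Passed to [choose_sparsity()] when `s` is
#'   `NULL`.
#' @return An object of class `sparse_kmeans`: `labels` (integer per
#'   sample), `weights` (per feature, named), `s`, `objective`, `bcss`
#'   (per-feature, at the final labels), `iterations`, `n_restarts`, `seed`.
#' @export
sparse_kmeans <- function(X, k = 2L, s = NULL, n_restarts = 20L,
                          max_iter = 20L, seed = 1L, n_perms = 25L,
                          s_grid_length = 10L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < k) stop("fewer samples than clusters")
  if (all(apply(X, 2L, stats::sd) == 0))
    stop("zero-variance feature set")
  if (is.null(s))
    s <- choose_sparsity(X, k = k, seed = seed, n_perms = n_perms,
                         s_grid_length = s_grid_length)$s
  if (s <= 1 || s > sqrt(p) + 1e-8)
    stop("s must lie in (1, sqrt(p)]")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- .skm_single(X, k, s, max_iter)
      if (is.null(best) || fit$objective > best$objective) best <- fit
    }
    best
  }) -> best
  best$n_restarts <- n_restarts
  best$s <- s
  best$seed <- seed
  names(best$weights) <- colnames(X)
  names(best$labels) <- rownames(X)
  class(best) <- "sparse_kmeans"
  best
}

.skm_single <- function(X, k, s, max_iter) {
  p <- ncol(X)
  w <- rep(1 / sqrt(p), p)
  centers <- NULL
  labels <- NULL
  objective <- -Inf
  trace <- numeric(0)
  safe_kmeans <- function(Xw, centers_or_k) {
    tryCatch(
      suppressWarnings(stats::kmeans(Xw, centers = centers_or_k,
                                     nstart = 1L, iter.max = 50L)),
      error = function(e)  # empty cluster from a degenerate start
        suppressWarnings(stats::kmeans(Xw, centers = k, nstart = 1L,
                                       iter.max = 50L)))
  }
  for (it in seq_len(max_iter)) {
    Xw <- sweep(X, 2L, sqrt(w), `*`)
    warm <- FALSE
    if (is.null(centers)) {
      km <- safe_kmeans(Xw, k)
    } else {
      cw <- sweep(centers, 2L, sqrt(w), `*`)
      warm <- nrow(unique(cw)) == k
      km <- safe_kmeans(Xw, if (warm) cw else k)
    }
    new_labels <- km$cluster
    a <- feature_bcss(X, new_labels)
    w_new <- update_weights(a, s)
    new_obj <- sum(w_new * a)
    if (new_obj < objective - 1e-8) {
      # warm-started alternation cannot decrease the objective; a decrease
      # can only come from a fallback random restart, which we discard
      if (warm) stop("internal error: sparse k-means objective decreased")
      break
    }
    trace <- c(trace, new_obj)
    centers <- do.call(rbind, lapply(sort(unique(new_labels)), function(cl)
      colMeans(X[new_labels == cl, , drop = FALSE])))
    converged <- !is.null(labels) && all(new_labels == labels) &&
      abs(new_obj - objective) < 1e-10
    labels <- new_labels
    w <- w_new
    objective <- new_obj
    if (converged) break
  }
  list(labels = labels, weights = w, objective = objective,
       bcss = feature_bcss(X, labels), iterations = it,
       objective_trace = trace)
}

#' @export
print.sparse_kmeans <- function(x, ...) {
  cat(sprintf(paste0("sparse_kmeans: %d samples, %d features, k = %d\n",
                     "  s = %.3f, %d/%d features with non-zero weight,",
                     " objective = %.4g\n"),
              length(x$labels), length(x$weights),
              length(unique(x$labels)), x$s, sum(x$weights > 0),
              length(x$weights), x$objective))
  invisible(x)
}

#' Select the sparse k-means L1 bound by the permutation gap statistic
#'
#' For each candidate `s`, the gap is `log(O(s))` on the observed data minus
#' the mean of `log(O*(s))` over datasets whose columns are independently
#' permuted (destroying cluster structure but keeping marginals); the `s`
#' with the largest gap is selected.
#'
#' @param X Samples x features matrix.
#' @param k Number of clusters.
#' @param s_grid Candidate values; default an even grid in `(1, sqrt(p)]`.
#' @param n_perms Number of permuted datasets (default 25).
#' @param n_restarts Restarts per sparse k-means run during selection.
#' @param seed Integer seed.
#' @param s_grid_length Grid size when `s_grid` is `NULL`.
#' @return List with `s` (the selected bound), `gaps`, `s_grid`.
#' @export
choose_sparsity <- function(X, k = 2L, s_grid = NULL, n_perms = 25L,
                            n_restarts = 5L, seed = 1L,
                            s_grid_length = 10L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 features")
  if (is.null(s_grid))
    s_grid <- seq(1.2, sqrt(p), length.out = max(2L, s_grid_length))
  s_grid <- s_grid[s_grid > 1 & s_grid <= sqrt(p) + 1e-8]
  obj_at <- function(M, s, sd) {
    with_seed(sd, {
      best <- -Inf
      for (r in seq_len(n_restarts)) {
        fit <- .skm_single(M, k, s, max_iter = 15L)
        if (fit$objective > best) best <- fit$objective
      }
      best
    })
  }
  obs <- vapply(seq_along(s_grid),
                function(i) obj_at(X, s_grid[i], seed + i), 0)
  perm_log <- matrix(NA_real_, n_perms, length(s_grid))
  for (b in seq_len(n_perms)) {
    Xp <- with_seed(seed + 1000L + b,
                    apply(X, 2L, function(col) col[sample.int(nrow(X))]))
    perm_log[b, ] <- vapply(seq_along(s_grid), function(i)
      log(obj_at(Xp, s_grid[i], seed + 2000L + b * 100L + i)), 0)
  }
  gaps <- log(obs) - colMeans(perm_log)
  list(s = s_grid[which.max(gaps)], gaps = gaps, s_grid = s_grid)
}
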