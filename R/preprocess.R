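#' Magnitude-normalize raw intensities
#'
#' Equalizes array scale before the log transform: each sample's values are
#' multiplied by a single factor chosen so that its median equals the global
#' target (the median of per-sample medians). A `"mean"` variant scales
#' per-sample means instead.
#'
#' @param m An `expr_matrix` with `scale_flag = "raw"` and strictly positive
#'   values.
#' @param statistic `"median"` (default) or `"mean"`.
#' @return Normalized `expr_matrix`, still on the raw scale.
#' @export
magnitude_normalize <- function(m, statistic = c("median", "mean")) {
  stopifnot(inherits(m, "expr_matrix"))
  statistic <- match.arg(statistic)
  if (m$scale_flag != "raw")
    stop("magnitude_normalize expects raw-scale values")
  if (any(m$values <= 0, na.rm = TRUE))
    stop("magnitude_normalize requires strictly positive values")
  fn <- if (statistic == "median") function(x) stats::median(x, na.rm = TRUE)
        else function(x) mean(x, na.rm = TRUE)
  per_sample <- apply(m$values, 2L, fn)
  target <- stats::median(per_sample)
  factors <- target / per_sample
  m$values <- sweep(m$values, 2L, factors, `*`)
  attr(m, "norm_factors") <- stats::setNames(factors, m$sample_ids)
  m
}

#' Log2-transform an expression matrix
#'
#' @param m An `expr_matrix` with strictly positive values.
#' @return The elementwise log2 matrix with `scale_flag = "log2"`.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value at probe '%s', sample '%s'",
                 m$probe_ids[bad[1L, 1L]], m$sample_ids[bad[1L, 2L]]))
  m$values <- log2(m$values)
  m$scale_flag <- "log2"
  m
}

#' Remove an additive batch effect
#'
#' One-way fixed-effect adjustment: for every gene, each batch's mean is
#' subtracted and the gene's grand mean added back, so that after adjustment
#' all per-gene per-batch means coincide. Applied on the log2 scale, before
#' any sample labels exist, so no covariates are modelled. Batches holding a
#' single sample cannot be adjusted this way (their mean is the observation
#' itself); they are left unchanged with a warning.
#'
#' @param m An `expr_matrix` with `scale_flag = "log2"`.
#' @param batch Per-sample batch labels; defaults to `m$batch`.
#' @return Batch-adjusted `expr_matrix`.
#' @export
remove_batch_effect <- function(m, batch = m$batch) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale_flag != "log2")
    stop("remove_batch_effect expects log2-scale values")
  if (is.null(batch)) stop("no batch labels available")
  batch <- as.character(batch)
  if (length(batch) != ncol(m$values))
    stop("batch must have one label per sample")
  sizes <- table(batch)
  if (length(sizes) < 2L) {
    message("single batch: matrix returned unchanged")
    return(m)
  }
  singletons <- names(sizes)[sizes == 1L]
  if (length(singletons))
    warning("batch(es) with a single sample left unadjusted: ",
            paste(singletons, collapse = ", "))
  grand <- rowMeans(m$values)
  for (b in setdiff(names(sizes), singletons)) {
    idx <- which(batch == b)
    bm <- rowMeans(m$values[, idx, drop = FALSE])
    m$values[, idx] <- m$values[, idx] - bm + grand
  }
  m$batch <- batch
  m
}

#' Mean-center every gene
#'
#' Subtracts each row's mean so that per-gene means are 0; idempotent.
#'
#' @param m An `expr_matrix`.
#' @return Centered `expr_matrix` with `scale_flag = "centered"`.
#' @export
mean_center <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  m$values <- m$values - rowMeans(m$values)
  m$scale_flag <- "centered"
  m
}

#' Collapse probes to genes by maximal variance
#'
#' For each gene, keeps the probe with the largest (unbiased, n-1
#' denominator) variance across all samples; exact variance ties are broken
#' toward the lexicographically smallest probe id.
#'
#' @param m An `expr_matrix` with a probe-to-gene map.
#' @return An `expr_matrix` with one row per gene.
#' @export
collapse_probes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  v <- row_variances(m$values)
  ord <- order(m$gene_ids, -v, m$probe_ids)
  keep <- ord[!duplicated(m$gene_ids[ord])]
  keep <- sort(keep)  # preserve original row order
  expression_matrix(m$values[keep, , drop = FALSE], m$probe_ids[keep],
                    m$gene_ids[keep], m$sample_ids, m$batch, m$scale_flag)
}

#' Keep the k most variable genes
#'
#' Ranks genes by unbiased sample variance (ties broken by gene id) and
#' keeps the top `k`; `k = 2000` by default, the working set for network
#' inference.
#'
#' @param m A collapsed `expr_matrix` (one row per gene).
#' @param k Number of genes to keep.
#' @return An `expr_matrix` restricted to the `k` most variable genes, in
#'   their original row order.
#' @export
select_most_variable <- function(m, k = 2000L) {
  stopifnot(inherits(m, "expr_matrix"), k >= 1L)
  if (anyDuplicated(m$gene_ids))
    stop("select_most_variable requires a collapsed matrix")
  n <- nrow(m$values)
  if (k >= n) {
    warning("k (", k, ") >= gene count (", n, "): keeping all genes")
    return(m)
  }
  v <- row_variances(m$values)
  keep <- sort(order(-v, m$gene_ids)[seq_len(k)])
  expression_matrix(m$values[keep, , drop = FALSE], m$probe_ids[keep],
                    m$gene_ids[keep], m$sample_ids, m$batch, m$scale_flag)
}

# Unbiased per-row variances without a matrixStats dependency.
row_variances <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(0, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: magnitude normalization (raw input only), log2,
#' additive batch removal (when batch labels are present), per-gene mean
#' centering, probe collapsing, variance filtering. Input and output
#' dimensions of every applied step are recorded in the `"steps"` attribute
#' for the run manifest.
#'
#' @param m An `expr_matrix` (raw or log2 scale).
#' @param top_k Number of most-variable genes to keep (default 2000).
#' @param normalize_stat Statistic for [magnitude_normalize()].
#' @return A centered, collapsed, variance-filtered `expr_matrix`.
#' @export
preprocess_expression <- function(m, top_k = 2000L,
                                  normalize_stat = "median") {
  stopifnot(inherits(m, "expr_matrix"))
  steps <- list()
  log_step <- function(name, before, after)
    steps[[name]] <<- list(dim_in = dim(before$values),
                           dim_out = dim(after$values))
  if (any(is.na(m$values))) {
    m2 <- drop_incomplete_genes(m); log_step("drop_missing", m, m2); m <- m2
  }
  if (m$scale_flag == "raw") {
    m2 <- magnitude_normalize(m, normalize_stat)
    log_step("magnitude_normalize", m, m2); m <- m2
    m2 <- log2_transform(m); log_step("log2", m, m2); m <- m2
  }
  if (!is.null(m$batch) && length(unique(m$batch)) > 1L) {
    m2 <- remove_batch_effect(m); log_step("remove_batch", m, m2); m <- m2
  }
  m2 <- mean_center(m); log_step("mean_center", m, m2); m <- m2
  m2 <- collapse_probes(m); log_step("collapse_probes", m, m2); m <- m2
  if (top_k < nrow(m2$values)) {
    m3 <- select_most_variable(m2, top_k)
    log_step("select_most_variable", m2, m3); m2 <- m3
  }
  attr(m2, "steps") <- steps
  m2
}
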