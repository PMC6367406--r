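#' Build per-subgroup centroids
#'
#' A centroid is the per-gene arithmetic mean of the (centered log2)
#' expression over the samples carrying a label, restricted to a stated
#' gene universe; the cellular centroids use the luminal + basal + claudin
#' genes and the immune centroids the immune-metanode genes.
#'
#' @param m A collapsed `expr_matrix`.
#' @param labels Named character vector (sample id -> label) covering a
#'   subset of the matrix samples; every label needs at least 2 samples.
#' @param gene_universe Genes the centroids are built on (subset of the
#'   matrix genes).
#' @return A `centroid_set`: genes x labels numeric matrix with the gene
#'   universe as row names.
#' @export
build_centroids <- function(m, labels, gene_universe) {
  stopifnot(inherits(m, "expr_matrix"))
  sub <- subset_genes(m, gene_universe)
  idx <- match(names(labels), sub$sample_ids)
  if (anyNA(idx))
    stop("labeled sample(s) absent from matrix: ",
         paste(names(labels)[is.na(idx)], collapse = ", "))
  counts <- table(labels)
  small <- names(counts)[counts < 2L]
  if (length(small))
    stop("label(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  out <- vapply(sort(names(counts)), function(lb) {
    rowMeans(sub$values[, idx[labels == lb], drop = FALSE])
  }, numeric(length(gene_universe)))
  rownames(out) <- gene_universe
  structure(out, class = c("centroid_set", class(out)))
}

#' Assign samples to the nearest centroid
#'
#' Each sample profile (restricted to the centroid gene universe) is
#' assigned the label of the centroid it correlates with most; genes absent
#' from the new cohort are dropped pairwise, with a warning when more than
#' 20% of the universe is missing. Correlation ties go to the
#' lexicographically first label, with a warning.
#'
#' @param profiles Genes x samples numeric matrix with gene row names (a
#'   single named vector is also accepted), or an `expr_matrix`.
#' @param centroids A `centroid_set` from [build_centroids()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A data.frame with `sample_id`, `label`, `n_genes_used` and one
#'   correlation column `r_<label>` per centroid.
#' @export
assign_by_centroid <- function(profiles, centroids,
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(centroids, "centroid_set"))
  if (inherits(profiles, "expr_matrix")) {
    mat <- profiles$values
    rownames(mat) <- profiles$gene_ids
    profiles <- mat
  }
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, ncol = 1L,
                       dimnames = list(names(profiles), "sample"))
  universe <- rownames(centroids)
  common <- intersect(universe, rownames(profiles))
  if (length(common) < 3L)
    stop("fewer than 3 centroid genes present in the profiles")
  missing_frac <- 1 - length(common) / length(universe)
  if (missing_frac > 0.2)
    warning(sprintf("%.0f%% of the centroid gene universe missing from %s",
                    100 * missing_frac, "the new cohort"))
  P <- profiles[common, , drop = FALSE]
  C <- centroids[common, , drop = FALSE]
  if (any(apply(P, 2L, stats::sd) == 0))
    stop("constant sample profile(s): ",
         paste(colnames(P)[apply(P, 2L, stats::sd) == 0], collapse = ", "))
  r <- stats::cor(P, C, method = method)  # samples x labels
  labs <- colnames(centroids)
  pick <- apply(r, 1L, function(row) {
    top <- which(row == max(row))
    if (length(top) > 1L)
      warning("correlation tie broken lexicographically")
    sort(labs[top])[1L]
  })
  out <- data.frame(sample_id = colnames(P), label = unname(pick),
                    n_genes_used = length(common),
                    stringsAsFactors = FALSE)
  colnames(r) <- paste0("r_", labs)
  cbind(out, as.data.frame(r, row.names = NULL))
}
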