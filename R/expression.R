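#' Construct an expression matrix object
#'
#' The container used throughout the package: a probes-by-samples numeric
#' matrix carrying a probe-to-gene map, optional per-sample batch labels and
#' a scale flag recording where the values sit in the preprocessing chain
#' (`"raw"` intensities, `"log2"` values, or per-gene `"centered"` log2
#' values).
#'
#' @param values Numeric matrix, probes in rows, samples in columns.
#' @param probe_ids Character vector of probe identifiers, one per row.
#' @param gene_ids Character vector of gene symbols, one per row; several
#'   probes may map to the same gene until [collapse_probes()] is applied.
#' @param sample_ids Character vector of sample identifiers, one per column.
#' @param batch Optional per-sample batch labels (character or factor).
#' @param scale_flag One of `"raw"`, `"log2"`, `"centered"`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, probe_ids, gene_ids, sample_ids,
                              batch = NULL,
                              scale_flag = c("raw", "log2", "centered")) {
  scale_flag <- match.arg(scale_flag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  probe_ids <- as.character(probe_ids)
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids) || nrow(values) != length(gene_ids))
    stop("row count must equal length of probe_ids and gene_ids")
  if (ncol(values) != length(sample_ids))
    stop("column count must equal length of sample_ids")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("empty expression matrix")
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ids")
  if (any(is.nan(values) | is.infinite(values)))
    stop("expression values must be finite or NA")
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != length(sample_ids))
      stop("batch must have one label per sample")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(
    list(values = values, probe_ids = probe_ids, gene_ids = gene_ids,
         sample_ids = sample_ids, batch = batch, scale_flag = scale_flag),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes (%d genes) x %d samples [%s]\n",
              nrow(x$values), length(unique(x$gene_ids)),
              ncol(x$values), x$scale_flag))
  if (!is.null(x$batch))
    cat("  batches:", paste(names(table(x$batch)), table(x$batch),
                            sep = "=", collapse = ", "), "\n")
  if (any(is.na(x$values)))
    cat("  missing entries:", sum(is.na(x$values)), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene symbols
#'
#' Requires a collapsed (one row per gene) matrix; rows are returned in the
#' order of `genes`.
#'
#' @param m An `expr_matrix`.
#' @param genes Character vector of gene symbols, all present in `m`.
#' @return An `expr_matrix` restricted to `genes`.
#' @export
subset_genes <- function(m, genes) {
  stopifnot(inherits(m, "expr_matrix"))
  if (anyDuplicated(m$gene_ids))
    stop("subset_genes requires a collapsed matrix (one row per gene)")
  idx <- match(genes, m$gene_ids)
  if (anyNA(idx))
    stop("genes absent from matrix: ",
         paste(genes[is.na(idx)], collapse = ", "))
  expression_matrix(m$values[idx, , drop = FALSE], m$probe_ids[idx],
                    m$gene_ids[idx], m$sample_ids, m$batch, m$scale_flag)
}

#' Drop genes containing missing values
#'
#' Downstream algebra (correlations, k-means) assumes complete data, so rows
#' with any `NA` are removed and reported.
#'
#' @param m An `expr_matrix`.
#' @return An `expr_matrix` with complete rows only; the ids of dropped
#'   probes are attached as attribute `"dropped"`.
#' @export
drop_incomplete_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  bad <- rowSums(is.na(m$values)) > 0L
  if (!any(bad)) return(m)
  if (all(bad)) stop("every probe has missing values")
  message(sum(bad), " probe(s) with missing values dropped")
  out <- expression_matrix(m$values[!bad, , drop = FALSE],
                           m$probe_ids[!bad], m$gene_ids[!bad],
                           m$sample_ids, m$batch, m$scale_flag)
  attr(out, "dropped") <- m$probe_ids[bad]
  out
}
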