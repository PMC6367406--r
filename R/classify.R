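#' Orient sparse k-means clusters as high/low activity
#'
#' The two clusters returned by [sparse_kmeans()] are anonymous; the one
#' whose mean metanode activity is larger is called `"high"`. An exact tie
#' is broken toward `"low"` for every sample, with a warning.
#'
#' @param result A `sparse_kmeans` fit with k = 2.
#' @param activity Per-sample metanode activity, aligned with the samples
#'   clustered in `result`.
#' @return Named character vector (sample id -> `"high"`/`"low"`).
#' @export
orient_high_low <- function(result, activity) {
  stopifnot(inherits(result, "sparse_kmeans"))
  labels <- result$labels
  if (length(activity) != length(labels))
    stop("activity must align with clustered samples")
  cl <- sort(unique(labels))
  if (length(cl) != 2L) stop("expected exactly 2 clusters")
  means <- vapply(cl, function(c) mean(activity[labels == c]), 0)
  if (means[1L] == means[2L]) {
    warning("equal cluster mean activities: all samples called 'low'")
    calls <- rep("low", length(labels))
  } else {
    high <- cl[which.max(means)]
    calls <- ifelse(labels == high, "high", "low")
  }
  stats::setNames(calls, names(labels))
}

#' High/low call on one metanode
#'
#' Runs sparse k-means (k = 2) on the samples-by-genes block of a metanode
#' and orients the clusters by mean activity.
#'
#' @param m A collapsed, centered `expr_matrix`.
#' @param genes Gene set of the metanode (or claudin node).
#' @param s,n_restarts,seed,n_perms Passed to [sparse_kmeans()].
#' @return List with `call` (sample -> high/low) and `fit` (the
#'   `sparse_kmeans` object).
#' @export
classify_metanode <- function(m, genes, s = NULL, n_restarts = 20L,
                              seed = 1L, n_perms = 25L) {
  X <- t(subset_genes(m, genes)$values)  # samples x genes
  fit <- sparse_kmeans(X, k = 2L, s = s, n_restarts = n_restarts,
                       seed = seed, n_perms = n_perms)
  act <- metanode_activity(m, genes)
  list(call = orient_high_low(fit, act), fit = fit)
}

#' Cellular decision workflow
#'
#' Turns the three high/low calls into the four-way cellular label, walking
#' the differentiation axis of the cancer stem cell hypothesis from most
#' (LAR) to least (CLDN-low) differentiated: high luminal activity -> LAR;
#' luminal-low and basal-high -> basal; luminal-low, basal-low and
#' claudin-high -> CLDN-high; all three low -> CLDN-low. Samples that are
#' both luminal-high and basal-high are assigned LAR (the workflow tests
#' luminal first) and flagged ambiguous.
#'
#' @param luminal,basal,claudin Named high/low call vectors over identical
#'   sample sets.
#' @return A data.frame with columns `sample_id`, `luminal`, `basal`,
#'   `claudin`, `cellular` (LAR / basal / CLDN-low / CLDN-high) and
#'   `ambiguous` (logical).
#' @export
cellular_workflow <- function(luminal, basal, claudin) {
  samples <- names(luminal)
  if (is.null(samples)) stop("calls must be named by sample id")
  for (v in list(luminal, basal, claudin)) {
    if (!setequal(names(v), samples))
      stop("luminal, basal and claudin calls must cover the same samples")
    if (anyNA(v) || !all(v %in% c("high", "low")))
      stop("calls must be 'high' or 'low' for every sample")
  }
  basal <- basal[samples]
  claudin <- claudin[samples]
  cellular <- ifelse(luminal == "high", "LAR",
              ifelse(basal == "high", "basal",
              ifelse(claudin == "high", "CLDN-high", "CLDN-low")))
  data.frame(sample_id = samples,
             luminal = unname(luminal), basal = unname(basal),
             claudin = unname(claudin), cellular = unname(cellular),
             ambiguous = unname(luminal == "high" & basal == "high"),
             stringsAsFactors = FALSE)
}

#' Immune layer call
#'
#' The sparse k-means split on immune-metanode genes, with the high-activity
#' cluster labeled IM+ and the other IM-.
#'
#' @param im_result A `sparse_kmeans` fit on immune-metanode genes.
#' @param im_activity Per-sample immune-metanode activity.
#' @return Named character vector (sample id -> `"IM+"`/`"IM-"`).
#' @export
immune_call <- function(im_result, im_activity) {
  hl <- orient_high_low(im_result, im_activity)
  stats::setNames(ifelse(hl == "high", "IM+", "IM-"), names(hl))
}
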