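#' Fit the two-layer TNBC classification
#'
#' Runs the full analysis on one cohort: preprocessing (magnitude
#' normalization, log2, batch removal, centering, probe collapsing,
#' variance filtering), Chow-Liu association forest over Gaussian mutual
#' information, branch decomposition, over-representation labeling of
#' branches into functional nodes, metanode formation by average-linkage
#' clustering of node activities, marker-based role assignment, sparse
#' k-means high/low calls on the luminal metanode, basal metanode and the
#' claudin functional node feeding the cellular decision workflow
#' (LAR / basal / CLDN-low / CLDN-high), an independent sparse k-means
#' split on immune-metanode genes (IM+/IM-), and centroid construction for
#' transfer to new cohorts via [predict.tnbc_fit()].
#'
#' @param expr An [expression_matrix()] (raw intensities or log2 values).
#' @param gene_sets A `gene_set_collection` used to label branches; `NULL`
#'   skips enrichment and keeps every branch as an unlabeled node.
#' @param markers A [marker_config()] (default [default_markers()]).
#' @param control A [tnbc_control()] list of tuning parameters.
#' @return An object of class `tnbc_fit`; see Details.
#' @details The returned object carries `calls` (data.frame with
#'   `sample_id`, the three high/low calls, `cellular`, `ambiguous`,
#'   `immune`), `nodes`, `metanodes` (role table, claudin node id),
#'   `activity`, `clustering`, `forest`, `centroids` (cellular and immune
#'   `centroid_set`s), `sparse_fits`, the preprocessed matrix `expr`, and
#'   `manifest` (parameters and stage dimensions).
#' @seealso [predict.tnbc_fit()], [summary.tnbc_fit()], [run_pipeline()]
#' @export
tnbc_fit <- function(expr, gene_sets = NULL, markers = default_markers(),
                     control = tnbc_control()) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(markers, "marker_config"))
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  m <- stage("preprocess",
             preprocess_expression(expr, top_k = control$top_k))
  graph <- stage("network", build_association_graph(m))
  forest <- stage("network",
                  max_spanning_forest(graph, control$min_edge_weight))
  branches <- stage("network",
                    split_branches(forest, control$max_branch_size,
                                   control$min_branch_size))
  if (!length(branches)) stop("stage 'network': no branches found")
  nodes <- if (!is.null(gene_sets)) {
    stage("functional_nodes", {
      enr <- lapply(branches, enrich_branch, genesets = gene_sets,
                    background = m$gene_ids)
      label_nodes(branches, enr, alpha = control$alpha)
    })
  } else {
    lapply(seq_along(branches), function(i)
      structure(list(node_id = sprintf("node_%02d", i),
                     genes = branches[[i]]$genes,
                     label_term = NA_character_, term_id = NA_character_,
                     enrichment_p = NA_real_, enrichment_q = NA_real_),
                class = "functional_node"))
  }
  if (length(nodes) < 2L)
    stop("stage 'functional_nodes': fewer than 2 nodes retained")
  act <- stage("activity", node_activity(m, nodes))
  clustering <- stage("activity",
                      cluster_metanodes(act, control$cut_height))
  roles <- stage("activity",
                 assign_roles(clustering, nodes, markers, m$gene_ids,
                              alpha = control$alpha))
  need <- c("luminal", "basal")
  have <- lengths(roles$metanode_genes[need]) > 0L
  if (!all(have))
    stop("stage 'classify': no metanode assigned role(s): ",
         paste(need[!have], collapse = ", "))
  if (is.na(roles$claudin_node))
    stop("stage 'classify': no claudin functional node identified")
  if (!length(roles$metanode_genes$immune))
    stop("stage 'classify': no immune metanode identified")
  node_ids <- vapply(nodes, `[[`, "", "node_id")
  claudin_genes <- nodes[[match(roles$claudin_node, node_ids)]]$genes
  layers <- list(luminal = roles$metanode_genes$luminal,
                 basal = roles$metanode_genes$basal,
                 claudin = claudin_genes)
  sk_seed <- control$seed
  fits <- list()
  calls <- list()
  for (i in seq_along(layers)) {
    cm <- stage("classify",
                classify_metanode(m, layers[[i]], s = control$s,
                                  n_restarts = control$n_restarts,
                                  seed = sk_seed + i,
                                  n_perms = control$n_perms))
    fits[[names(layers)[i]]] <- cm$fit
    calls[[names(layers)[i]]] <- cm$call
  }
  im <- stage("classify",
              classify_metanode(m, roles$metanode_genes$immune,
                                s = control$s,
                                n_restarts = control$n_restarts,
                                seed = sk_seed + 10L,
                                n_perms = control$n_perms))
  fits$immune <- im$fit
  immune <- stats::setNames(ifelse(im$call == "high", "IM+", "IM-"),
                            names(im$call))
  cellular <- stage("classify",
                    cellular_workflow(calls$luminal, calls$basal,
                                      calls$claudin))
  cellular$immune <- unname(immune[cellular$sample_id])
  cellular_universe <- sort(unique(c(layers$luminal, layers$basal,
                                     layers$claudin)))
  centroids <- stage("transfer", list(
    cellular = build_centroids(
      m, stats::setNames(cellular$cellular, cellular$sample_id),
      cellular_universe),
    immune = build_centroids(
      m, stats::setNames(cellular$immune, cellular$sample_id),
      roles$metanode_genes$immune)))
  structure(list(
    calls = cellular, nodes = nodes, metanodes = roles,
    activity = act, clustering = clustering, forest = forest,
    branches = branches, centroids = centroids, sparse_fits = fits,
    expr = m, markers = markers, control = control,
    manifest = list(
      parameters = unclass(control),
      n_samples = ncol(m$values), n_genes = nrow(m$values),
      n_branches = length(branches), n_nodes = length(nodes),
      roles = roles$roles, claudin_node = roles$claudin_node,
      preprocess_steps = attr(m, "steps"),
      sparsity = vapply(fits, `[[`, 0, "s"),
      package_version = as.character(utils::packageVersion("tnbctype")))),
    class = "tnbc_fit")
}

#' Control parameters for [tnbc_fit()]
#'
#' @param top_k Most-variable genes kept (default 2000).
#' @param min_edge_weight Forest edge threshold (default MI at |r| = 0.3).
#' @param max_branch_size,min_branch_size Branch size window (150 / 10).
#' @param alpha Significance level for enrichment and role assignment.
#' @param cut_height Metanode dendrogram cut (default 0.7).
#' @param s Sparse k-means L1 bound; `NULL` selects it per metanode by the
#'   permutation gap statistic.
#' @param n_restarts,n_perms Sparse k-means restarts (20) and selection
#'   permutations (25).
#' @param seed Integer seed for every stochastic step.
#' @return A classed list of parameters.
#' @export
tnbc_control <- function(top_k = 2000L,
                         min_edge_weight = default_min_edge_weight(),
                         max_branch_size = 150L, min_branch_size = 10L,
                         alpha = 0.05, cut_height = 0.7, s = NULL,
                         n_restarts = 20L, n_perms = 25L, seed = 1L) {
  structure(list(top_k = top_k, min_edge_weight = min_edge_weight,
                 max_branch_size = max_branch_size,
                 min_branch_size = min_branch_size, alpha = alpha,
                 cut_height = cut_height, s = s, n_restarts = n_restarts,
                 n_perms = n_perms, seed = seed),
            class = "tnbc_control")
}

#' @export
print.tnbc_fit <- function(x, ...) {
  cat("Two-layer TNBC classification fit\n")
  cat(sprintf("  %d samples, %d genes, %d functional nodes\n",
              nrow(x$calls), x$manifest$n_genes, x$manifest$n_nodes))
  cat("  cellular:",
      paste(names(table(x$calls$cellular)), table(x$calls$cellular),
            sep = "=", collapse = ", "), "\n")
  cat("  immune:  ",
      paste(names(table(x$calls$immune)), table(x$calls$immune),
            sep = "=", collapse = ", "), "\n")
  if (any(x$calls$ambiguous))
    cat("  ", sum(x$calls$ambiguous),
        "luminal+/basal+ double-positive sample(s) flagged\n")
  invisible(x)
}

#' Summarize a TNBC classification fit
#'
#' @param object A `tnbc_fit`.
#' @param ... Unused.
#' @return A list with `cellular`, `immune` and `cross` count/percentage
#'   tables (percentages by [percent_report()]), printed on request.
#' @export
summary.tnbc_fit <- function(object, ...) {
  n <- nrow(object$calls)
  mk_tab <- function(v) {
    tb <- table(v)
    data.frame(group = names(tb), n = as.integer(tb),
               percent = percent_report(as.integer(tb), n))
  }
  out <- list(n = n,
              cellular = mk_tab(object$calls$cellular),
              immune = mk_tab(object$calls$immune),
              cross = table(object$calls$cellular, object$calls$immune),
              n_ambiguous = sum(object$calls$ambiguous))
  class(out) <- "summary.tnbc_fit"
  out
}

#' @export
print.summary.tnbc_fit <- function(x, ...) {
  cat("Cellular classification (n =", x$n, "):\n")
  for (i in seq_len(nrow(x$cellular)))
    cat(sprintf("  %-10s %4d (%d%%)\n", x$cellular$group[i],
                x$cellular$n[i], x$cellular$percent[i]))
  cat("Immune layer:\n")
  for (i in seq_len(nrow(x$immune)))
    cat(sprintf("  %-10s %4d (%d%%)\n", x$immune$group[i],
                x$immune$n[i], x$immune$percent[i]))
  if (x$n_ambiguous)
    cat("Ambiguous luminal+/basal+ samples:", x$n_ambiguous, "\n")
  invisible(x)
}

#' Transfer the classification to a new cohort
#'
#' Nearest-centroid assignment: the new cohort is preprocessed with the
#' same chain (its own magnitude scaling and centering — no batch removal
#' unless it carries batch labels), then every sample is assigned the
#' cellular and immune label of the centroid it correlates with most.
#'
#' @param object A `tnbc_fit`.
#' @param newdata An `expr_matrix` (raw or log2).
#' @param layer `"both"` (default), `"cellular"` or `"immune"`.
#' @param method Correlation flavour for [assign_by_centroid()].
#' @param ... Unused.
#' @return A data.frame with `sample_id`, `cellular` and/or `immune`, and
#'   per-centroid correlation columns.
#' @export
predict.tnbc_fit <- function(object, newdata,
                             layer = c("both", "cellular", "immune"),
                             method = "pearson", ...) {
  layer <- match.arg(layer)
  stopifnot(inherits(newdata, "expr_matrix"))
  m <- preprocess_expression(newdata, top_k = nrow(newdata$values))
  out <- data.frame(sample_id = m$sample_ids, stringsAsFactors = FALSE)
  if (layer %in% c("both", "cellular")) {
    a <- assign_by_centroid(m, object$centroids$cellular, method = method)
    out$cellular <- a$label
    out <- cbind(out, a[grep("^r_", colnames(a))])
  }
  if (layer %in% c("both", "immune")) {
    a <- assign_by_centroid(m, object$centroids$immune, method = method)
    out$immune <- a$label
    out <- cbind(out, a[grep("^r_", colnames(a))])
  }
  out
}

#' Plot a TNBC classification fit
#'
#' Two base-graphics panels: the metanode dendrogram (cut height marked)
#' and per-sample luminal/basal metanode activities colored by cellular
#' call.
#'
#' @param x A `tnbc_fit`.
#' @param which `1` (dendrogram), `2` (activity scatter) or both.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tnbc_fit <- function(x, which = c(1L, 2L), ...) {
  if (1L %in% which) {
    graphics::plot(x$clustering$dendrogram,
                   main = "Metanode clustering of functional nodes",
                   xlab = "", sub = "", ...)
    graphics::abline(h = x$clustering$cut_height, lty = 2, col = "grey40")
  }
  if (2L %in% which) {
    lum <- metanode_activity(x$expr, x$metanodes$metanode_genes$luminal)
    bas <- metanode_activity(x$expr, x$metanodes$metanode_genes$basal)
    cls <- factor(x$calls$cellular)
    graphics::plot(lum, bas, col = as.integer(cls), pch = 19, cex = 0.6,
                   xlab = "luminal metanode activity (log2)",
                   ylab = "basal metanode activity (log2)", ...)
    graphics::legend("topright", legend = levels(cls), pch = 19,
                     col = seq_len(nlevels(cls)), bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Survival characterization of fitted subgroups
#'
#' Joins the fit's calls to a clinical table and compares RFS between the
#' requested grouping's levels (Kaplan-Meier, log-rank, and the Cox hazard
#' ratio for two-level groupings). Samples with missing time or event are
#' excluded and the n actually used is reported.
#'
#' @param fit A `tnbc_fit` (or any data.frame of calls with `sample_id`,
#'   `cellular`, `immune`).
#' @param clinical A `clinical_table`.
#' @param by `"immune"` (default), `"cellular"`, or `"immune_within"` with
#'   `subgroup` naming a cellular subgroup.
#' @param subgroup Cellular subgroup for `by = "immune_within"`.
#' @return A `survival_result`.
#' @export
tnbc_survival <- function(fit, clinical,
                          by = c("immune", "cellular", "immune_within"),
                          subgroup = NULL) {
  by <- match.arg(by)
  calls <- if (inherits(fit, "tnbc_fit")) fit$calls else fit
  idx <- match(calls$sample_id, clinical$sample_id)
  if (all(is.na(idx))) stop("no overlap between calls and clinical table")
  dat <- data.frame(calls, rfs_time = clinical$rfs_time[idx],
                    event = clinical$event[idx])
  if (by == "immune_within") {
    if (is.null(subgroup)) stop("subgroup required for immune_within")
    dat <- dat[dat$cellular == subgroup, , drop = FALSE]
  }
  grp <- if (by == "cellular") dat$cellular else dat$immune
  compare_survival(dat$rfs_time, dat$event, grp)
}
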