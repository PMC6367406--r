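#' Functional-node activity scores
#'
#' A node's activity in a sample is the unweighted arithmetic mean of the
#' (log2, centered) expression of its member genes.
#'
#' @param m A collapsed `expr_matrix` containing every node gene.
#' @param nodes List of `functional_node` objects (or any list of objects
#'   with `node_id` and `genes` fields).
#' @return Numeric matrix, nodes x samples, with node ids as row names.
#' @export
node_activity <- function(m, nodes) {
  stopifnot(inherits(m, "expr_matrix"), length(nodes) >= 1L)
  if (anyDuplicated(m$gene_ids))
    stop("node_activity requires a collapsed matrix")
  act <- matrix(NA_real_, length(nodes), ncol(m$values),
                dimnames = list(vapply(nodes, `[[`, "", "node_id"),
                                m$sample_ids))
  for (i in seq_along(nodes)) {
    idx <- match(nodes[[i]]$genes, m$gene_ids)
    if (anyNA(idx))
      stop("gene(s) ", paste(nodes[[i]]$genes[is.na(idx)], collapse = ", "),
           " of node ", nodes[[i]]$node_id, " absent from matrix")
    act[i, ] <- colMeans(m$values[idx, , drop = FALSE])
  }
  act
}

#' Group functional nodes into metanodes
#'
#' Agglomerative average-linkage clustering of node-activity profiles under
#' correlation distance `d(u, v) = 1 - r(u, v)`; the partition is obtained
#' by cutting the dendrogram at `cut_height`.
#'
#' @param activity Nodes x samples activity matrix from [node_activity()].
#' @param cut_height Dendrogram cut (default 0.7, i.e. merge while average
#'   inter-node correlation exceeds 0.3).
#' @return A list with `dendrogram` (an `hclust`), `partition` (named
#'   integer vector node id -> metanode) and `cut_height`.
#' @export
cluster_metanodes <- function(activity, cut_height = 0.7) {
  stopifnot(is.matrix(activity), nrow(activity) >= 2L)
  sds <- apply(activity, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant activity row(s): ",
         paste(rownames(activity)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(t(activity))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  part <- stats::cutree(hc, h = cut_height)
  list(dendrogram = hc, partition = part, cut_height = cut_height)
}

#' Export a metanode dendrogram in Newick format
#'
#' @param clustering Result of [cluster_metanodes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  hc <- clustering$dendrogram
  rec <- function(i) {
    if (i < 0) return(hc$labels[-i])
    h <- hc$height[i]
    kids <- hc$merge[i, ]
    child_h <- vapply(kids, function(k) if (k < 0) 0 else hc$height[k], 0)
    paste0("(", rec(kids[1L]), ":", format(h - child_h[1L]), ",",
           rec(kids[2L]), ":", format(h - child_h[2L]), ")")
  }
  writeLines(paste0(rec(nrow(hc$merge)), ";"), path)
  invisible(path)
}

#' Assign biological roles to metanodes
#'
#' Each metanode's gene union is tested for enrichment of every marker list
#' (one-sided hypergeometric against the matrix gene universe, BH-adjusted
#' across roles within the metanode); the metanode takes the best role with
#' `q <= alpha`, otherwise `"other"`. The claudin role is attached to a
#' single functional node, not a metanode: the node containing all claudin
#' markers (or, failing that, the node with the strongest claudin
#' enrichment at `alpha`).
#'
#' @param clustering Result of [cluster_metanodes()].
#' @param nodes The functional-node list the clustering was built on.
#' @param markers A [marker_config()].
#' @param background Gene universe of the analyzed matrix.
#' @param alpha Significance level (default 0.05).
#' @return A list with `table` (data.frame node_id, metanode_id, role),
#'   `roles` (metanode id -> role), `claudin_node` (node id or NA) and
#'   `metanode_genes` (role -> gene union for luminal/basal/immune).
#' @export
assign_roles <- function(clustering, nodes, markers, background,
                         alpha = 0.05) {
  stopifnot(inherits(markers, "marker_config"))
  part <- clustering$partition
  node_ids <- vapply(nodes, `[[`, "", "node_id")
  stopifnot(setequal(names(part), node_ids))
  background <- unique(as.character(background))
  N <- length(background)
  roles <- character(0)
  for (mn in sort(unique(part))) {
    members <- node_ids[node_ids %in% names(part)[part == mn]]
    union_genes <- unique(unlist(lapply(nodes[match(members, node_ids)],
                                        `[[`, "genes")))
    p <- vapply(names(markers), function(role) {
      mk <- intersect(markers[[role]], background)
      x <- length(intersect(mk, union_genes))
      stats::phyper(x - 1L, length(mk), N - length(mk),
                    length(union_genes), lower.tail = FALSE)
    }, 0)
    q <- stats::p.adjust(p, method = "BH")
    best <- names(q)[order(q, names(q))][1L]
    roles[as.character(mn)] <- if (q[best] <= alpha) best else "other"
  }
  cellular_roles <- roles[roles %in% c("luminal", "basal", "immune")]
  dup <- names(table(cellular_roles))[table(cellular_roles) > 1L]
  if (length(dup)) {
    claimed <- vapply(dup, function(r)
      paste(names(roles)[roles == r], collapse = ", "), "")
    stop("role(s) claimed by several metanodes: ",
         paste(sprintf("%s (metanodes %s)", dup, claimed), collapse = "; "),
         " - refine markers or cut height")
  }
  # claudin: a single functional node carrying the claudin markers
  cl_mark <- intersect(markers$claudin, background)
  has_all <- vapply(nodes, function(n) all(cl_mark %in% n$genes), NA)
  claudin_node <- NA_character_
  if (sum(has_all) == 1L) {
    claudin_node <- node_ids[has_all]
  } else if (sum(has_all) > 1L) {
    stop("several nodes contain all claudin markers: ",
         paste(node_ids[has_all], collapse = ", "))
  } else {
    p <- vapply(nodes, function(n) {
      x <- length(intersect(cl_mark, n$genes))
      stats::phyper(x - 1L, length(cl_mark), N - length(cl_mark),
                    length(n$genes), lower.tail = FALSE)
    }, 0)
    if (min(p) <= alpha)
      claudin_node <- node_ids[order(p, node_ids)][1L]
  }
  tab <- data.frame(node_id = node_ids,
                    metanode_id = unname(part[node_ids]),
                    role = unname(roles[as.character(part[node_ids])]),
                    stringsAsFactors = FALSE)
  metanode_genes <- lapply(c(luminal = "luminal", basal = "basal",
                             immune = "immune"), function(r) {
    ids <- tab$node_id[tab$role == r]
    sort(unique(unlist(lapply(nodes[match(ids, node_ids)], `[[`, "genes"))))
  })
  list(table = tab, roles = roles, claudin_node = claudin_node,
       metanode_genes = metanode_genes)
}

#' Metanode activity as mean over the gene union
#'
#' Identical to the gene-count-weighted mean of member node activities.
#'
#' @param m A collapsed `expr_matrix`.
#' @param genes Gene union of the metanode.
#' @return Numeric vector of per-sample activity.
#' @export
metanode_activity <- function(m, genes) {
  idx <- match(genes, m$gene_ids)
  if (anyNA(idx))
    stop("gene(s) absent from matrix: ",
         paste(genes[is.na(idx)], collapse = ", "))
  colMeans(m$values[idx, , drop = FALSE])
}
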