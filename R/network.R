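#' Gaussian mutual information from a correlation
#'
#' For a bivariate Gaussian, the mutual information between two variables
#' with Pearson correlation r is `-0.5 * log(1 - r^2)` nats. Correlations
#' with `r^2 >= 1 - 1e-12` are capped there (with a warning) so the weight
#' stays finite.
#'
#' @param r Numeric vector of correlations in `[-1, 1]`.
#' @return Mutual information in nats, same length as `r`.
#' @export
gaussian_mi <- function(r) {
  r2 <- r^2
  cap <- 1 - 1e-12
  if (any(r2 >= cap)) {
    warning("correlation(s) with |r| ~ 1 capped")
    r2 <- pmin(r2, cap)
  }
  -0.5 * log(1 - r2)
}

# Edge weight for the minimum MI kept in the forest: by default the MI of
# |r| = 0.3, below which an association is treated as spurious.
#' Default minimum edge weight (MI at |r| = 0.3)
#' @return A scalar MI threshold in nats.
#' @export
default_min_edge_weight <- function() gaussian_mi(0.3)

#' Build the all-pairs gene association graph
#'
#' Computes the complete weighted graph over genes with Gaussian mutual
#' information of pairwise Pearson correlations as edge weights — the input
#' of the Chow-Liu forest construction.
#'
#' @param m A centered, collapsed `expr_matrix` with at least 3 samples.
#' @return An `assoc_graph`: list with `genes`, `edges` (data.frame
#'   `gene_a`, `gene_b`, `weight` over the upper triangle, with
#'   `gene_a < gene_b`) and `structure = "complete"`.
#' @export
build_association_graph <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 3L) stop("need at least 3 samples")
  if (anyDuplicated(m$gene_ids))
    stop("association graph requires a collapsed matrix")
  v <- row_variances(m$values)
  if (any(v == 0))
    stop("zero-variance gene(s): ",
         paste(m$gene_ids[v == 0], collapse = ", "))
  cors <- suppressWarnings(stats::cor(t(m$values)))
  p <- nrow(cors)
  ut <- which(upper.tri(cors), arr.ind = TRUE)
  edges <- data.frame(gene_a = m$gene_ids[ut[, 1L]],
                      gene_b = m$gene_ids[ut[, 2L]],
                      weight = gaussian_mi(cors[ut]),
                      stringsAsFactors = FALSE)
  swap <- edges$gene_a > edges$gene_b
  if (any(swap)) {
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
  }
  structure(list(genes = m$gene_ids, edges = edges, structure = "complete"),
            class = "assoc_graph")
}

#' @export
print.assoc_graph <- function(x, ...) {
  cat(sprintf("assoc_graph (%s): %d genes, %d edges\n",
              x$structure, length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Maximum-weight spanning forest (Chow-Liu construction)
#'
#' Kruskal's algorithm on edges sorted by decreasing weight (ties broken by
#' the lexicographic `(gene_a, gene_b)` pair, so the result is
#' deterministic); edges lighter than `min_edge_weight` are discarded first,
#' which is what turns the spanning tree into a forest. Every vertex of the
#' input graph is retained.
#'
#' @param g An `assoc_graph`.
#' @param min_edge_weight Minimum MI for an edge to be considered;
#'   default [default_min_edge_weight()].
#' @return An `assoc_graph` with `structure = "forest"`.
#' @export
max_spanning_forest <- function(g, min_edge_weight = default_min_edge_weight()) {
  stopifnot(inherits(g, "assoc_graph"))
  e <- g$edges[g$edges$weight >= min_edge_weight, , drop = FALSE]
  e <- e[order(-e$weight, e$gene_a, e$gene_b), , drop = FALSE]
  n <- length(g$genes)
  id <- stats::setNames(seq_len(n), g$genes)
  parent <- seq_len(n)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {  # path compression
      nxt <- parent[i]; parent[i] <<- root; i <- nxt
    }
    root
  }
  keep <- logical(nrow(e))
  ia <- id[e$gene_a]; ib <- id[e$gene_b]
  for (k in seq_len(nrow(e))) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) {
      parent[ra] <- rb
      keep[k] <- TRUE
    }
  }
  structure(list(genes = g$genes,
                 edges = e[keep, , drop = FALSE],
                 structure = "forest"),
            class = "assoc_graph")
}

# Connected components of a forest; returns an integer component id per
# gene (singletons included).
forest_components <- function(genes, edges) {
  id <- stats::setNames(seq_along(genes), genes)
  parent <- seq_along(genes)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]; parent[i] <<- root; i <- nxt
    }
    root
  }
  if (nrow(edges)) {
    ia <- id[edges$gene_a]; ib <- id[edges$gene_b]
    for (k in seq_len(nrow(edges))) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(genes), find, 0L)
  match(roots, unique(roots))
}

#' Split a forest into branches
#'
#' Candidate functional nodes are produced by pruning: while any connected
#' component exceeds `max_branch_size` vertices, the lightest edge inside an
#' oversized component is deleted (ties broken by the lexicographic endpoint
#' pair). Components with at least `min_branch_size` vertices become
#' branches; smaller ones are reported as residue.
#'
#' @param forest An `assoc_graph` with `structure = "forest"`.
#' @param max_branch_size Largest allowed branch (default 150).
#' @param min_branch_size Smallest component kept as a branch (default 10).
#' @return A list of `branch` objects (fields `branch_id`, `genes`,
#'   `edges`), with the residue gene ids in attribute `"residue"`.
#' @export
split_branches <- function(forest, max_branch_size = 150L,
                           min_branch_size = 10L) {
  stopifnot(inherits(forest, "assoc_graph"),
            forest$structure == "forest")
  if (max_branch_size < min_branch_size)
    stop("max_branch_size must be >= min_branch_size")
  edges <- forest$edges
  repeat {
    comp <- forest_components(forest$genes, edges)
    sizes <- tabulate(comp)
    over <- which(sizes > max_branch_size)
    if (!length(over)) break
    ecomp <- comp[match(edges$gene_a, forest$genes)]
    cand <- which(ecomp %in% over)
    cut <- cand[order(edges$weight[cand], edges$gene_a[cand],
                      edges$gene_b[cand])][1L]
    edges <- edges[-cut, , drop = FALSE]
  }
  comp <- forest_components(forest$genes, edges)
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_branch_size)
  # stable, deterministic branch ids: by decreasing size, ties by first gene
  first_gene <- vapply(keep, function(k) min(forest$genes[comp == k]), "")
  keep <- keep[order(-sizes[keep], first_gene)]
  branches <- lapply(seq_along(keep), function(i) {
    k <- keep[i]
    genes <- forest$genes[comp == k]
    structure(list(branch_id = sprintf("branch_%02d", i),
                   genes = sort(genes),
                   edges = edges[edges$gene_a %in% genes &
                                   edges$gene_b %in% genes, , drop = FALSE]),
              class = "branch")
  })
  residue <- sort(forest$genes[comp %in% setdiff(seq_along(sizes), keep)])
  if (length(residue))
    message(length(residue), " gene(s) in components below min_branch_size")
  attr(branches, "residue") <- residue
  branches
}

#' Export a forest as a TSV edge list
#'
#' Columns: gene_a, gene_b, weight, branch_id (NA for edges outside any
#' branch).
#'
#' @param forest An `assoc_graph` forest.
#' @param branches Branch list from [split_branches()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forest <- function(forest, branches, path) {
  e <- forest$edges
  e$branch_id <- NA_character_
  for (b in branches)
    e$branch_id[e$gene_a %in% b$genes & e$gene_b %in% b$genes] <- b$branch_id
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
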