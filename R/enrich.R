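#' Over-representation of gene sets in a branch
#'
#' One-sided hypergeometric upper-tail test per term: with `N` background
#' genes, `K` of which belong to the term, and a branch of `n` genes of
#' which `x` are in the term, `p = P(X >= x)` for
#' `X ~ Hypergeom(N, K, n)`. P-values are Benjamini-Hochberg adjusted
#' across terms within the branch and the table is sorted by ascending p
#' (ties by term id).
#'
#' @param branch A `branch` object or a character vector of gene symbols.
#' @param genesets A `gene_set_collection`.
#' @param background Character vector of background genes; must contain
#'   every branch gene (the gene universe of the analyzed matrix).
#' @return A data.frame with columns `term_id`, `term_name`, `overlap`,
#'   `term_size`, `p`, `q`.
#' @export
enrich_branch <- function(branch, genesets, background) {
  genes <- if (inherits(branch, "branch")) branch$genes
           else as.character(branch)
  stopifnot(inherits(genesets, "gene_set_collection"))
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  out <- setdiff(genes, background)
  if (length(out))
    stop("branch gene(s) outside background: ",
         paste(utils::head(out, 5L), collapse = ", "))
  N <- length(background)
  n <- length(genes)
  K <- vapply(genesets$genes,
              function(g) length(intersect(g, background)), 0L)
  x <- vapply(genesets$genes,
              function(g) length(intersect(g, genes)), 0L)
  # P(X >= x); phyper is P(X <= q), so evaluate the upper tail at x - 1
  p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
  res <- data.frame(term_id = genesets$term_id,
                    term_name = genesets$term_name,
                    overlap = x, term_size = K, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  res[order(res$p, res$term_id), , drop = FALSE]
}

#' Label branches as functional nodes
#'
#' A branch becomes a functional node when its best BH-adjusted enrichment
#' reaches `alpha`; the node is labeled by that top term. Branches with no
#' enrichment at `alpha` are dropped from node-level analyses and reported.
#'
#' @param branches List of `branch` objects.
#' @param enrichments List of enrichment tables from [enrich_branch()],
#'   parallel to `branches`.
#' @param alpha Significance level on adjusted values (default 0.05).
#' @return A list of `functional_node` objects (fields `node_id`, `genes`,
#'   `label_term`, `term_id`, `enrichment_p`, `enrichment_q`, `enrichment`),
#'   with dropped branch ids in attribute `"dropped"`.
#' @export
label_nodes <- function(branches, enrichments, alpha = 0.05) {
  stopifnot(length(branches) == length(enrichments))
  nodes <- list()
  dropped <- character()
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    e <- enrichments[[i]]
    if (nrow(e) && e$q[1L] <= alpha) {
      nodes[[length(nodes) + 1L]] <- structure(
        list(node_id = sprintf("node_%02d", length(nodes) + 1L),
             genes = b$genes,
             label_term = e$term_name[1L],
             term_id = e$term_id[1L],
             enrichment_p = e$p[1L],
             enrichment_q = e$q[1L],
             enrichment = e),
        class = "functional_node")
    } else {
      dropped <- c(dropped, b$branch_id)
    }
  }
  if (length(dropped))
    message("branch(es) without enrichment at alpha = ", alpha,
            " dropped: ", paste(dropped, collapse = ", "))
  attr(nodes, "dropped") <- dropped
  nodes
}

#' @export
print.functional_node <- function(x, ...) {
  cat(sprintf("functional_node %s: %d genes, '%s' (q = %.3g)\n",
              x$node_id, length(x$genes), x$label_term, x$enrichment_q))
  invisible(x)
}

#' Write functional nodes as a table and a GMT
#'
#' @param nodes List of `functional_node` objects.
#' @param table_path Path for the summary TSV (node_id, label, n_genes, p, q).
#' @param gmt_path Optional path for a GMT of node gene sets.
#' @return `table_path`, invisibly.
#' @export
write_nodes <- function(nodes, table_path, gmt_path = NULL) {
  tab <- data.frame(
    node_id = vapply(nodes, `[[`, "", "node_id"),
    label = vapply(nodes, `[[`, "", "label_term"),
    n_genes = vapply(nodes, function(n) length(n$genes), 0L),
    p = vapply(nodes, `[[`, 0, "enrichment_p"),
    q = vapply(nodes, `[[`, 0, "enrichment_q"))
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(gmt_path) && length(nodes))
    write_gmt(gene_set_collection(tab$node_id, tab$label,
                                  lapply(nodes, `[[`, "genes"),
                                  source = "functional_nodes"),
              gmt_path)
  invisible(table_path)
}
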