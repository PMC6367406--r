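#' Run the end-to-end pipeline and write a result bundle
#'
#' Orchestrates simulate/ingest -> preprocess -> network -> nodes ->
#' activity -> classify -> transfer (optional) -> survival, writing every
#' stage output as TSV plus a JSON run manifest. Configuration is an R list
#' (or a YAML file path, read with the yaml package when installed) with
#' entries:
#' \describe{
#'   \item{expression / clinical / gene_sets}{paths of input TSV / GMT
#'     files, or in-memory objects; omit `expression` to simulate.}
#'   \item{simulate}{list of [cohort_spec()] arguments used when no
#'     expression input is given; `survival = TRUE` also simulates RFS.}
#'   \item{markers}{list with luminal/basal/claudin/immune marker vectors;
#'     default [default_markers()]. All four roles must be present.}
#'   \item{control}{list of [tnbc_control()] arguments.}
#'   \item{transfer}{path or `expr_matrix` of a second cohort to classify
#'     by centroid transfer.}
#' }
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed overriding `config$control$seed`.
#' @return Invisibly, a list with the fit, calls, optional transfer
#'   assignments and survival result, and the manifest.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  markers <- if (is.null(config$markers)) default_markers() else {
    mk <- config$markers
    need <- c("luminal", "basal", "claudin", "immune")
    miss <- setdiff(need, names(mk))
    if (length(miss))
      stop("config validation: marker role(s) missing: ",
           paste(miss, collapse = ", "))
    do.call(marker_config, mk[need])
  }
  control <- do.call(tnbc_control, if (is.null(config$control)) list()
                     else config$control)
  if (!is.null(seed)) control$seed <- as.integer(seed)

  truth <- NULL
  clinical <- NULL
  if (is.null(config$expression)) {
    spec_args <- if (is.null(config$simulate)) list() else config$simulate
    spec_args$survival <- NULL
    spec_args$seed <- control$seed
    spec <- do.call(cohort_spec, spec_args)
    sim <- generate_expression(spec)
    expr <- sim$expression
    truth <- sim$truth
    gene_sets <- generate_genesets(spec)
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (isTRUE(config$simulate$survival)) {
      clinical <- generate_survival(truth, default_hazard_map(truth),
                                    seed = control$seed + 1L)
      write_clinical(clinical, file.path(out_dir, "clinical.tsv"))
    }
    write_expression(expr, file.path(out_dir, "expression.tsv"))
  } else {
    expr <- if (inherits(config$expression, "expr_matrix"))
      config$expression else read_expression(config$expression)
    gene_sets <- if (is.null(config$gene_sets)) NULL
      else if (inherits(config$gene_sets, "gene_set_collection"))
        config$gene_sets else read_gmt(config$gene_sets)
    if (!is.null(config$clinical))
      clinical <- if (inherits(config$clinical, "clinical_table"))
        config$clinical else read_clinical(config$clinical)
  }

  fit <- tnbc_fit(expr, gene_sets = gene_sets, markers = markers,
                  control = control)

  utils::write.table(fit$calls, file.path(out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(node_id = rownames(fit$activity), fit$activity,
               check.names = FALSE),
    file.path(out_dir, "activity.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(fit$metanodes$table,
                     file.path(out_dir, "metanodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_nodes(fit$nodes, file.path(out_dir, "nodes.tsv"),
              file.path(out_dir, "nodes.gmt"))
  write_forest(fit$forest, fit$branches,
               file.path(out_dir, "forest_edges.tsv"))
  write_dendrogram_newick(fit$clustering,
                          file.path(out_dir, "metanode_dendrogram.nwk"))
  for (ly in names(fit$centroids))
    utils::write.table(
      data.frame(gene = rownames(fit$centroids[[ly]]),
                 unclass(fit$centroids[[ly]]), check.names = FALSE),
      file.path(out_dir, sprintf("centroids_%s.tsv", ly)), sep = "\t",
      quote = FALSE, row.names = FALSE)

  transfer <- NULL
  if (!is.null(config$transfer)) {
    new_expr <- if (inherits(config$transfer, "expr_matrix"))
      config$transfer else read_expression(config$transfer)
    transfer <- stats::predict(fit, new_expr)
    utils::write.table(transfer, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  surv <- NULL
  if (!is.null(clinical)) {
    surv <- tnbc_survival(fit, clinical, by = "immune")
    hr <- surv$hr
    utils::write.table(
      data.frame(comparison = "IM+ vs IM-",
                 n = sum(surv$n), logrank_chi2 = surv$logrank$chi2,
                 logrank_p = surv$logrank$p,
                 hr = if (is.null(hr)) NA else hr$hr,
                 ci_low = if (is.null(hr)) NA else hr$ci[1L],
                 ci_high = if (is.null(hr)) NA else hr$ci[2L]),
      file.path(out_dir, "survival.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    for (g in names(surv$km))
      utils::write.table(surv$km[[g]],
                         file.path(out_dir, sprintf("km_%s.tsv",
                                                    gsub("[^A-Za-z0-9]", "_", g))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- c(fit$manifest,
                list(seed = control$seed,
                     simulated = is.null(config$expression),
                     r_version = as.character(getRversion()),
                     outputs = list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(fit = fit, truth = truth, clinical = clinical,
                 transfer = transfer, survival = surv,
                 manifest = manifest))
}
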