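# Synthetic-cohort generator: planted co-expression modules with a
# single-latent-factor (equicorrelation) structure, four cellular subtypes,
# an independent binary immune layer, additive batch shifts and
# label-dependent exponential survival.

#' Specify one planted gene module
#'
#' A module emulates one functional node: a block of genes sharing a latent
#' factor (target within-module correlation `rho`) and a role-dependent
#' mean shift per (subtype x immune) combination.
#'
#' @param module_id Unique module identifier.
#' @param role One of `"luminal"`, `"basal"`, `"claudin"`, `"immune"`,
#'   `"other"`.
#' @param genes Character vector of gene symbols (disjoint across modules).
#' @param rho Target within-module correlation in `[0, 1)`.
#' @param shift Named numeric vector of log2 mean shifts; names are
#'   cellular subtypes (`LAR`, `basal`, `CLDN-low`, `CLDN-high`) for
#'   cellular roles, or `IM+`/`IM-` for immune modules. Missing labels
#'   shift by 0.
#' @param gene_loadings Per-gene response magnitudes multiplying the
#'   module shift (mean 1); the default spreads them evenly over
#'   `[0.5, 1.5]`, so genes of one module respond to the planted signal
#'   with individual strengths, as probes of a real functional node do.
#'   `NULL` keeps them at exactly 1.
#' @return A `module_spec`.
#' @export
module_spec <- function(module_id, role = c("other", "luminal", "basal",
                                            "claudin", "immune"),
                        genes, rho = 0.8, shift = numeric(0),
                        gene_loadings = NULL) {
  role <- match.arg(role)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  genes <- unique(as.character(genes))
  if (is.null(gene_loadings))
    gene_loadings <- if (length(genes) > 1L)
      seq(0.5, 1.5, length.out = length(genes)) else 1
  if (length(gene_loadings) != length(genes))
    stop("gene_loadings must have one value per gene")
  structure(list(module_id = module_id, role = role,
                 genes = genes, rho = rho,
                 shift = shift, gene_loadings = gene_loadings),
            class = "module_spec")
}

#' Specify a synthetic cohort
#'
#' Defaults reproduce the working conditions of the analysis the package
#' validates against: 400 tumors at the observed subtype mix (18% LAR, 63%
#' basal, 11% CLDN-low, 8% CLDN-high), an immune-positive fraction of 0.52
#' in every subtype (the two layers are independent), 26 planted modules at
#' rho = 0.8 with 1.0 log2-unit role shifts, 200 unstructured noise genes,
#' two batches shifted by 0.3 log2 units and a residual noise sd of 0.35
#' log2 units.
#'
#' @param n_per_subtype Named integer vector of sample counts for `LAR`,
#'   `basal`, `CLDN-low`, `CLDN-high`.
#' @param immune_positive_fraction Scalar or per-subtype named vector in
#'   `[0, 1]`.
#' @param modules List of [module_spec()] objects; `NULL` for the default
#'   26-module layout ([default_modules()]).
#' @param n_noise_genes Unstructured genes with no planted signal.
#' @param batch_count Number of batches (samples assigned round-robin).
#' @param batch_shift Additive log2 shift between consecutive batches.
#' @param noise_sd Residual log2 noise sd (> 0).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_per_subtype = c("LAR" = 72, "basal" = 252,
                                          "CLDN-low" = 44,
                                          "CLDN-high" = 32),
                        immune_positive_fraction = 0.52,
                        modules = NULL, n_noise_genes = 200L,
                        batch_count = 2L, batch_shift = 0.3,
                        noise_sd = 0.35, seed = 1L) {
  subtypes <- c("LAR", "basal", "CLDN-low", "CLDN-high")
  if (!setequal(names(n_per_subtype), subtypes))
    stop("n_per_subtype must name exactly: ",
         paste(subtypes, collapse = ", "))
  if (any(n_per_subtype < 0)) stop("subtype counts must be >= 0")
  if (length(immune_positive_fraction) == 1L)
    immune_positive_fraction <-
      stats::setNames(rep(immune_positive_fraction, 4L), subtypes)
  if (!setequal(names(immune_positive_fraction), subtypes))
    stop("immune_positive_fraction must be scalar or per-subtype")
  if (any(immune_positive_fraction < 0 | immune_positive_fraction > 1))
    stop("immune fractions must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (is.null(modules)) modules <- default_modules()
  all_genes <- unlist(lapply(modules, `[[`, "genes"))
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup))
    stop("gene(s) in several modules: ", paste(dup, collapse = ", "))
  structure(list(n_per_subtype = n_per_subtype[subtypes],
                 immune_positive_fraction =
                   immune_positive_fraction[subtypes],
                 modules = modules, n_noise_genes = n_noise_genes,
                 batch_count = batch_count, batch_shift = batch_shift,
                 noise_sd = noise_sd, seed = seed),
            class = "cohort_spec")
}

#' Default 26-module layout
#'
#' Mirrors the functional-node structure the classifier expects: 6 luminal
#' modules (carrying AR/FOXA1-type markers), 5 basal modules (basal
#' cytokeratins), 4 immune modules (lymphocyte and antigen-presentation
#' genes), one 34-gene claudin node containing CLDN3/CLDN4/CLDN7, and 10
#' unshifted `"other"` modules. Filler symbols are synthetic
#' (`M<module>G<i>`).
#'
#' Modules of one role respond with different effect magnitudes (as
#' functional nodes of a transcriptional programme do in real cohorts):
#' each module's shift is `shift_size` scaled by a fixed per-module
#' multiplier in `[0.7, 1.3]` averaging 1 within the role. This gradient
#' is also what gives the role centroids gene-to-gene structure, which
#' correlation-based centroid transfer relies on.
#'
#' @param shift_size Mean log2 magnitude of the role shifts (default 1.0).
#' @param rho Within-module correlation (default 0.8).
#' @param genes_per_module Genes per non-claudin module (default 20).
#' @return List of [module_spec()] objects.
#' @export
default_modules <- function(shift_size = 1.0, rho = 0.8,
                            genes_per_module = 20L) {
  mk <- default_markers()
  filler <- function(m, n) sprintf("M%02dG%02d", m, seq_len(n))
  pad <- function(seed_genes, m, n)
    c(seed_genes, filler(m, n - length(seed_genes)))
  mods <- list()
  mid <- 0L
  add <- function(role, genes, shift) {
    mid <<- mid + 1L
    mods[[mid]] <<- module_spec(sprintf("mod_%02d", mid), role, genes,
                                rho = rho, shift = shift)
  }
  lum_mult <- c(0.7, 0.85, 1.0, 1.0, 1.15, 1.3)
  bas_mult <- c(0.7, 0.85, 1.0, 1.15, 1.3)
  imm_mult <- c(0.7, 0.9, 1.1, 1.3)
  lum_seeds <- split(mk$luminal, rep(1:6, length.out = length(mk$luminal)))
  for (i in 1:6)
    add("luminal", pad(lum_seeds[[i]], i, genes_per_module),
        c("LAR" = shift_size * lum_mult[i]))
  bas_seeds <- split(mk$basal, rep(1:5, length.out = length(mk$basal)))
  for (i in 1:5)
    add("basal", pad(bas_seeds[[i]], 6L + i, genes_per_module),
        c("basal" = shift_size * bas_mult[i]))
  imm_seeds <- split(mk$immune, rep(1:4, length.out = length(mk$immune)))
  for (i in 1:4)
    add("immune", pad(imm_seeds[[i]], 11L + i, genes_per_module),
        c("IM+" = shift_size * imm_mult[i]))
  add("claudin", pad(mk$claudin, 16L, 34L),
      c("CLDN-high" = shift_size))
  for (i in 1:10)
    add("other", filler(16L + i, genes_per_module), numeric(0))
  mods
}

#' Generate a synthetic expression cohort
#'
#' Gene g of module m in sample i takes the value
#' `loading_g * shift(m, subtype_i, immune_i) + noise_sd * (sqrt(rho)
#' z_i^m + sqrt(1 - rho) e_gi) + batch_shift(batch_i)` on the log2 scale,
#' with
#' `z` (one latent factor per module and sample) and `e` independent
#' standard normals; noise genes have no shift and no latent factor. With
#' `emit = "raw"` (default) a baseline of `baseline_log2` is added and the
#' values are exponentiated to intensities, so the full preprocessing chain
#' applies; `emit = "log2"` returns the log2 values directly.
#'
#' @param spec A [cohort_spec()].
#' @param emit `"raw"` or `"log2"`.
#' @param baseline_log2 Baseline log2 intensity for raw output (default 7).
#' @return List with `expression` (an `expr_matrix`) and `truth` (a
#'   data.frame `sample_id`, `cellular`, `immune`, `batch`).
#' @export
generate_expression <- function(spec, emit = c("raw", "log2"),
                                baseline_log2 = 7) {
  stopifnot(inherits(spec, "cohort_spec"))
  emit <- match.arg(emit)
  with_seed(spec$seed, {
    subtypes <- rep(names(spec$n_per_subtype), spec$n_per_subtype)
    n <- length(subtypes)
    if (n == 0L) stop("empty cohort")
    immune <- unlist(lapply(names(spec$n_per_subtype), function(st) {
      ns <- spec$n_per_subtype[[st]]
      ifelse(stats::runif(ns) < spec$immune_positive_fraction[[st]],
             "IM+", "IM-")
    }))
    batch <- sprintf("b%d", 1L + (seq_len(n) - 1L) %% spec$batch_count)
    sample_ids <- sprintf("S%04d", seq_len(n))
    genes <- c(unlist(lapply(spec$modules, `[[`, "genes")),
               if (spec$n_noise_genes > 0L)
                 sprintf("NOISE%04d", seq_len(spec$n_noise_genes)))
    p <- length(genes)
    vals <- matrix(0, p, n, dimnames = list(genes, sample_ids))
    row0 <- 0L
    for (m in spec$modules) {
      g <- length(m$genes)
      z <- stats::rnorm(n)
      eps <- matrix(stats::rnorm(g * n), g, n)
      noise <- spec$noise_sd *
        (sqrt(m$rho) * matrix(z, g, n, byrow = TRUE) +
           sqrt(1 - m$rho) * eps)
      shift_of <- function(st, im) {
        s <- 0
        if (st %in% names(m$shift)) s <- s + m$shift[[st]]
        if (im %in% names(m$shift)) s <- s + m$shift[[im]]
        s
      }
      shifts <- mapply(shift_of, subtypes, immune)
      vals[row0 + seq_len(g), ] <-
        outer(m$gene_loadings, shifts) + noise
      row0 <- row0 + g
    }
    if (spec$n_noise_genes > 0L) {
      vals[row0 + seq_len(spec$n_noise_genes), ] <-
        spec$noise_sd * matrix(stats::rnorm(spec$n_noise_genes * n),
                               spec$n_noise_genes, n)
    }
    bshift <- (match(batch, sprintf("b%d", seq_len(spec$batch_count))) - 1L) *
      spec$batch_shift
    vals <- sweep(vals, 2L, bshift, `+`)
    if (emit == "raw") vals <- 2^(vals + baseline_log2)
    expr <- expression_matrix(vals, probe_ids = genes, gene_ids = genes,
                              sample_ids = sample_ids, batch = batch,
                              scale_flag = if (emit == "raw") "raw"
                                           else "log2")
    truth <- data.frame(sample_id = sample_ids, cellular = subtypes,
                        immune = immune, batch = batch,
                        stringsAsFactors = FALSE)
    list(expression = expr, truth = truth)
  })
}

#' Generate matching gene-set annotations
#'
#' One term per planted module (named by role) plus unannotated decoy
#' terms, so the over-representation stage can label branches in synthetic
#' runs.
#'
#' @param spec A [cohort_spec()].
#' @param n_decoys Number of decoy terms drawn from the noise genes.
#' @return A `gene_set_collection`.
#' @export
generate_genesets <- function(spec, n_decoys = 5L) {
  stopifnot(inherits(spec, "cohort_spec"))
  role_names <- c(luminal = "luminal differentiation programme",
                  basal = "basal epithelium programme",
                  claudin = "tight junction assembly",
                  immune = "immune response",
                  other = "housekeeping module")
  ids <- vapply(spec$modules, `[[`, "", "module_id")
  names <- sprintf("%s (%s)",
                   role_names[vapply(spec$modules, `[[`, "", "role")], ids)
  genes <- lapply(spec$modules, `[[`, "genes")
  if (n_decoys > 0L && spec$n_noise_genes >= 5L) {
    noise <- sprintf("NOISE%04d", seq_len(spec$n_noise_genes))
    dec <- with_seed(spec$seed + 77L, lapply(seq_len(n_decoys), function(i)
      sample(noise, min(15L, length(noise)))))
    ids <- c(ids, sprintf("decoy_%02d", seq_len(n_decoys)))
    names <- c(names, sprintf("decoy term %02d", seq_len(n_decoys)))
    genes <- c(genes, dec)
  }
  gene_set_collection(ids, names, genes, source = "synthetic")
}

#' Generate label-dependent exponential survival
#'
#' Event times are exponential with the per-label rate; censoring is the
#' minimum of an independent exponential (`censor_rate`) and administrative
#' censoring at `horizon_months`. `event = 1` iff the event time does not
#' exceed the censoring time.
#'
#' @param truth Truth table from [generate_expression()] (or any data.frame
#'   with `sample_id` plus the label column).
#' @param hazard_map Named vector: label -> events per month (> 0). Every
#'   label present in the truth must have a rate.
#' @param censor_rate Exponential censoring rate per month (0 disables
#'   random censoring).
#' @param horizon_months Administrative censoring horizon.
#' @param seed Integer seed.
#' @param label `"combined"` (cellular and immune pasted with `"|"`),
#'   `"cellular"` or `"immune"`.
#' @return A `clinical_table` with `rfs_time` and `event` filled in.
#' @export
generate_survival <- function(truth, hazard_map, censor_rate = 0.01,
                              horizon_months = 120, seed = 1L,
                              label = c("combined", "cellular", "immune")) {
  label <- match.arg(label)
  labels <- switch(label,
    combined = paste(truth$cellular, truth$immune, sep = "|"),
    cellular = truth$cellular,
    immune = truth$immune)
  miss <- setdiff(unique(labels), names(hazard_map))
  if (length(miss))
    stop("no hazard for label(s): ", paste(miss, collapse = ", "))
  if (any(hazard_map <= 0)) stop("hazard rates must be > 0")
  if (censor_rate < 0 || horizon_months < 0)
    stop("censor_rate and horizon_months must be >= 0")
  with_seed(seed, {
    n <- nrow(truth)
    t_event <- stats::rexp(n, rate = hazard_map[labels])
    t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate)
              else rep(Inf, n)
    t_cens <- pmin(t_cens, horizon_months)
    validate_clinical(data.frame(
      sample_id = truth$sample_id,
      rfs_time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE))
  })
}

#' Default hazard map for the synthetic cohort
#'
#' A base rate of 0.012 events/month in every cellular subtype (the
#' cellular layer carries no prognostic signal) multiplied by 0.73 for
#' immune-positive samples, on the combined `cellular|immune` labels.
#'
#' @param truth Truth table.
#' @param base_rate Events per month for immune-negative samples.
#' @param immune_hr Hazard ratio of IM+ vs IM-.
#' @return Named rate vector over the combined labels.
#' @export
default_hazard_map <- function(truth, base_rate = 0.012, immune_hr = 0.73) {
  labels <- unique(paste(truth$cellular, truth$immune, sep = "|"))
  stats::setNames(ifelse(grepl("IM\\+$", labels),
                         base_rate * immune_hr, base_rate), labels)
}
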