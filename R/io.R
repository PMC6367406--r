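#' Read an expression matrix from TSV
#'
#' Canonical dialect: UTF-8, tab-delimited, '.' decimal. The first column
#' holds probe ids and the second gene symbols (set `gene_column = NULL` if
#' probes are already gene symbols); remaining columns are samples with a
#' header row of sample ids. With `orientation = "samples_in_rows"` the file
#' is transposed (samples in rows, probes in the header) and no gene column
#' is expected.
#'
#' @param path Path to a TSV file.
#' @param orientation `"probes_in_rows"` (default) or `"samples_in_rows"`.
#' @param batch A named character vector (sample id -> batch) or `NULL`.
#' @param scale_flag Declared scale of the stored values.
#' @param gene_column Name or index of the gene-symbol column, or `NULL`.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, orientation = c("probes_in_rows",
                                                  "samples_in_rows"),
                            batch = NULL, scale_flag = "raw",
                            gene_column = 2L) {
  orientation <- match.arg(orientation)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  if (nrow(tab) == 0L) stop("empty matrix in ", path)
  if (orientation == "samples_in_rows") {
    sample_ids <- tab[[1L]]
    probe_ids <- colnames(tab)[-1L]
    num <- t(.parse_numeric_block(tab[-1L], path, row_offset = 1L))
    gene_ids <- probe_ids
  } else {
    probe_ids <- tab[[1L]]
    if (!is.null(gene_column)) {
      gene_ids <- tab[[gene_column]]
      drop <- c(1L, if (is.numeric(gene_column)) gene_column
                else match(gene_column, colnames(tab)))
    } else {
      gene_ids <- probe_ids
      drop <- 1L
    }
    sample_ids <- colnames(tab)[-drop]
    num <- .parse_numeric_block(tab[-drop], path, row_offset = 1L)
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample id(s) in header of ", path, ": ",
         paste(dup, collapse = ", "))
  if (!is.null(batch)) {
    if (is.null(names(batch))) {
      if (length(batch) != length(sample_ids))
        stop("unnamed batch vector must match sample count")
    } else {
      miss <- setdiff(sample_ids, names(batch))
      if (length(miss)) stop("batch labels missing for: ",
                             paste(miss, collapse = ", "))
      batch <- unname(batch[sample_ids])
    }
  }
  expression_matrix(num, probe_ids, gene_ids, sample_ids, batch, scale_flag)
}

# Coerce a character data.frame block to numeric, reporting the 1-based file
# line and column name of the first offending cell.
.parse_numeric_block <- function(block, path, row_offset) {
  num <- matrix(NA_real_, nrow(block), ncol(block))
  for (j in seq_along(block)) {
    v <- block[[j]]
    ok <- is.na(v) | grepl("^[+-]?([0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?)$", v)
    if (!all(ok)) {
      i <- which(!ok)[1L]
      stop(sprintf("non-numeric value '%s' at line %d, column '%s' of %s",
                   v[i], i + row_offset, colnames(block)[j], path))
    }
    num[, j] <- as.numeric(v)
  }
  num
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()] (probes-in-rows orientation); values are
#' written at full precision so that write-then-read round-trips exactly.
#'
#' @param m An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  tab <- data.frame(probe_id = m$probe_ids, gene_id = m$gene_ids,
                    check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.data.frame(m$values, check.names = FALSE)
  for (j in seq_along(vals)) vals[[j]] <- sprintf("%.17g", vals[[j]])
  tab <- cbind(tab, vals)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `term<TAB>description<TAB>gene...`.
#' Duplicate genes within a term are stored once.
#'
#' @param path Path to a GMT file.
#' @param source_tag Free-text provenance tag stored with the collection.
#' @return A `gene_set_collection`: list with `term_id`, `term_name`,
#'   `genes` (list of character vectors) and `source`.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("GMT line ", which(nf < 3L)[1L], " of ", path,
         " has fewer than 3 fields")
  genes <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  gene_set_collection(term_id = vapply(fields, `[[`, "", 1L),
                      term_name = vapply(fields, `[[`, "", 2L),
                      genes = genes, source = source_tag)
}

#' Construct a gene-set collection
#'
#' @param term_id,term_name Character vectors, one entry per set.
#' @param genes List of character vectors of gene symbols.
#' @param source Provenance tag.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(term_id, term_name = term_id, genes,
                                source = "user") {
  stopifnot(length(term_id) == length(term_name),
            length(term_id) == length(genes))
  if (any(lengths(genes) == 0L)) stop("every term must have at least 1 gene")
  genes <- lapply(genes, function(g) unique(as.character(g)))
  structure(list(term_id = as.character(term_id),
                 term_name = as.character(term_name),
                 genes = genes, source = source),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms (source: %s), %d-%d genes/term\n",
              length(x$term_id), x$source,
              min(lengths(x$genes)), max(lengths(x$genes))))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param gs A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path) {
  stopifnot(inherits(gs, "gene_set_collection"))
  lines <- vapply(seq_along(gs$term_id), function(i) {
    paste(c(gs$term_id[i], gs$term_name[i], gs$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

.clinical_levels <- list(
  size = c("T1", "gtT1"),
  grade = c("G1_2", "G3"),
  nodal = c("N0", "N1"),
  adjuvant_chemo = c("yes", "no"),
  path_response = c("pCR", "RD"))

# Token synonyms accepted on input, mapped onto the canonical dialect above.
.clinical_synonyms <- list(
  size = c(">T1" = "gtT1", "gt_T1" = "gtT1"),
  grade = c("G1&2" = "G1_2", "G1" = "G1_2", "G2" = "G1_2"),
  nodal = c(),
  adjuvant_chemo = c("Yes" = "yes", "No" = "no"),
  path_response = c())

#' Read a clinical table from TSV
#'
#' Expected columns: `sample_id`, `rfs_time` (months), `event` (0 censored /
#' 1 distant relapse), `size` (T1 vs >T1), `grade` (G1&2 vs G3), `nodal`
#' (N0/N1), `adjuvant_chemo` (yes/no), `path_response` (pCR/RD). Both `NA`
#' and the empty string are read as missing; unknown category tokens are
#' rejected by name. Missing columns are filled with `NA`.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           na.strings = c("NA", ""))
  if (!"sample_id" %in% colnames(tab))
    stop("clinical table must have a sample_id column")
  out <- data.frame(sample_id = tab$sample_id, stringsAsFactors = FALSE)
  out$rfs_time <- if ("rfs_time" %in% colnames(tab))
    suppressWarnings(as.numeric(tab$rfs_time)) else NA_real_
  bad_num <- !is.na(tab$rfs_time) & is.na(out$rfs_time)
  if ("rfs_time" %in% colnames(tab) && any(bad_num))
    stop("non-numeric rfs_time at line ", which(bad_num)[1L] + 1L)
  out$event <- if ("event" %in% colnames(tab))
    suppressWarnings(as.integer(tab$event)) else NA_integer_
  for (col in names(.clinical_levels)) {
    v <- if (col %in% colnames(tab)) tab[[col]] else NA_character_
    syn <- .clinical_synonyms[[col]]
    if (length(syn)) {
      hit <- v %in% names(syn)
      v[hit] <- syn[v[hit]]
    }
    bad <- !is.na(v) & !v %in% .clinical_levels[[col]]
    if (any(bad))
      stop("unknown ", col, " token '", v[which(bad)[1L]], "' at line ",
           which(bad)[1L] + 1L)
    out[[col]] <- v
  }
  validate_clinical(out)
}

#' Validate a clinical table
#'
#' Enforces the clinical dialect: non-negative RFS times, events coded 0/1
#' and defined only alongside a time, restricted category levels.
#'
#' @param tab A data.frame with (a subset of) the clinical columns.
#' @return `tab` with class `clinical_table`.
#' @export
validate_clinical <- function(tab) {
  stopifnot(is.data.frame(tab), "sample_id" %in% colnames(tab))
  for (col in c("rfs_time", "event", names(.clinical_levels)))
    if (!col %in% colnames(tab)) tab[[col]] <- NA
  if (any(!is.na(tab$rfs_time) & tab$rfs_time < 0))
    stop("negative rfs_time for sample ",
         tab$sample_id[which(tab$rfs_time < 0)[1L]])
  if (any(!is.na(tab$event) & !tab$event %in% c(0L, 1L)))
    stop("event must be 0 or 1")
  if (any(!is.na(tab$event) & is.na(tab$rfs_time)))
    stop("event defined without rfs_time")
  for (col in names(.clinical_levels)) {
    bad <- !is.na(tab[[col]]) & !tab[[col]] %in% .clinical_levels[[col]]
    if (any(bad))
      stop("unknown ", col, " token '", tab[[col]][which(bad)[1L]], "'")
  }
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' Write a clinical table to TSV
#'
#' @param tab A `clinical_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Marker configuration for metanode role assignment
#'
#' Maps each metanode role to its marker gene list. The claudin role must
#' include CLDN3, CLDN4 and CLDN7, the three claudin genes whose loss
#' defines the claudin-low phenotype.
#'
#' @param luminal,basal,claudin,immune Character vectors of marker symbols.
#' @return A named list of class `marker_config`.
#' @export
marker_config <- function(luminal, basal, claudin, immune) {
  cfg <- list(luminal = unique(as.character(luminal)),
              basal = unique(as.character(basal)),
              claudin = unique(as.character(claudin)),
              immune = unique(as.character(immune)))
  if (any(lengths(cfg) == 0L)) stop("every role needs at least one marker")
  if (!all(c("CLDN3", "CLDN4", "CLDN7") %in% cfg$claudin))
    stop("claudin markers must include CLDN3, CLDN4 and CLDN7")
  structure(cfg, class = "marker_config")
}

#' Default marker configuration
#'
#' Canonical TNBC subtype markers: androgen-receptor/luminal transcription
#' programme, basal cytokeratins, the three claudins, and lymphocyte /
#' antigen-presentation genes.
#'
#' @return A `marker_config`.
#' @export
default_markers <- function() {
  marker_config(
    luminal = c("AR", "FOXA1", "SPDEF", "XBP1", "TFF3", "KRT18"),
    basal = c("KRT5", "KRT14", "KRT17", "SFRP1", "FABP7"),
    claudin = c("CLDN3", "CLDN4", "CLDN7"),
    immune = c("CD3D", "CD4", "CD8A", "CD2", "HLA-DRA", "CXCL9"))
}
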