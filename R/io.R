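# Delimited-text readers and writers: abundance tables (first column sample
# ID, remaining columns cell types) and sample metadata.

guess_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a cell-type abundance table
#'
#' First column: sample IDs (must be unique); remaining columns: one per
#' cell type. Comma- or tab-separated (auto-detected from the header line).
#' Whether the table holds counts (all integers) or proportions is detected
#' and recorded in the `"type"` attribute.
#'
#' @param path File path.
#' @param sep Field separator; default auto-detect.
#' @return Numeric matrix with sample IDs as row names and attribute
#'   `type` in `c("counts", "proportions")`.
#' @export
read_abundance <- function(path, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("abundance table needs a sample-ID column and ",
                          "at least 2 component columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- colnames(df)[-1L][!vapply(df[-1L], is.numeric, logical(1))]
    stop("non-numeric abundance column(s): ", paste(bad, collapse = ", "))
  }
  rownames(M) <- ids
  attr(M, "type") <- if (is_whole(M) && max(M) > 1 + 1e-8) "counts"
                     else "proportions"
  M
}

#' Read a sample metadata table
#'
#' First column: sample IDs; remaining columns: predictor and covariates.
#'
#' @inheritParams read_abundance
#' @return A data frame with sample IDs as row names.
#' @export
read_metadata <- function(path, sep = NULL) {
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  df
}

#' Load and align an abundance table with its metadata
#'
#' Reads both files, aligns the metadata to the abundance rows by sample ID
#' (row order in either file is irrelevant), and extracts the predictor and
#' any covariate columns. Missing or unmatched samples are reported by name.
#'
#' @param table_path Abundance table (see [read_abundance()]).
#' @param metadata_path Metadata table (see [read_metadata()]).
#' @param predictor Name of the predictor column in the metadata.
#' @param covariates Optional character vector of covariate column names.
#' @return List with `abundance` (matrix, `type` attribute), `predictor`
#'   (vector), `covariates` (data frame or NULL) and `metadata` (aligned
#'   data frame).
#' @export
load_dataset <- function(table_path, metadata_path, predictor,
                         covariates = NULL) {
  M <- read_abundance(table_path)
  meta <- read_metadata(metadata_path)
  missing_meta <- setdiff(rownames(M), rownames(meta))
  if (length(missing_meta))
    stop("metadata missing for sample(s): ",
         paste(missing_meta, collapse = ", "))
  meta <- meta[rownames(M), , drop = FALSE]
  for (col in c(predictor, covariates)) {
    if (!col %in% colnames(meta))
      stop("column '", col, "' not found in metadata")
  }
  list(abundance = M,
       predictor = meta[[predictor]],
       covariates = if (length(covariates))
         meta[, covariates, drop = FALSE] else NULL,
       metadata = meta)
}

#' Write a matrix as a delimited table with sample IDs
#'
#' Companion writer to [read_abundance()]: first column `sample`, then one
#' column per component. Used to export abundance tables and, for audit,
#' distance or kernel matrices.
#'
#' @param M Matrix with row names (sample IDs).
#' @param path Output path; `.tsv` extension selects tab separation.
#' @param sep Field separator; default from extension.
#' @export
write_abundance <- function(M, path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- data.frame(sample = rownames(M) %||% seq_len(nrow(M)),
                   as.data.frame(unclass(M)), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Flat key-value record of a test result (one line per field) plus an
# optional JSON twin for machines.
write_test_result <- function(fit, out_prefix) {
  stopifnot(inherits(fit, "codak"))
  rec <- list(statistic = fit$statistic, dcor = fit$dcor,
              p_value = fit$p.value, n_perm = fit$n_perm,
              exact = fit$exact, kernel = fit$kernel,
              gamma = fit$gamma, predictor_kind = fit$predictor_kind,
              adjustment = fit$adjustment, n = fit$n, q = fit$q,
              seed = fit$seed %||% NA,
              version = as.character(utils::packageVersion("codak")))
  txt <- paste0(names(rec), "\t",
                vapply(rec, function(v) format(v, digits = 10), ""))
  writeLines(txt, paste0(out_prefix, ".txt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(rec, paste0(out_prefix, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(out_prefix)
}
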