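#' Read gene sets from a GMT file
#'
#' Parses the standard GMT layout: one set per line, tab-separated fields
#' `name`, `description`, then gene ids. Lines with fewer than 3 fields
#' raise an error naming the line number; duplicate genes within a set are
#' removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate gene(s) in set '", fields[[1]], "' deduplicated")
      genes <- unique(genes)
    }
    nms[[i]] <- fields[[1]]
    sets[[i]] <- genes
  }
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[[i]], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header of sample ids and a first column of gene ids.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric genes x samples matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  check_expression(m)
}

#' Write an expression matrix to TSV
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @param id_column Name of the gene-id column (default `"gene_id"`).
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path, id_column = "gene_id") {
  expr <- check_expression(expr)
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample tumor purity table from TSV
#'
#' Expects columns `sample_id` and `purity` (fractions in `[0, 1]`).
#'
#' @param path Path to a tab-separated file.
#' @return Named numeric vector of purities.
#' @export
read_purity_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "purity") %in% names(df)))
    stop("purity TSV needs columns 'sample_id' and 'purity'")
  p <- as.numeric(df$purity)
  names(p) <- as.character(df$sample_id)
  if (anyDuplicated(names(p))) stop("sample ids must be unique")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("purity must lie in [0, 1]")
  p
}

#' Read a clinical table from TSV
#'
#' Expects a `sample_id` column plus outcome/covariate columns (e.g.
#' `os_time`, `os_event`, `pfs_time`, `pfs_event`, `response`, `cd8_ihc`,
#' biomarker scores, baseline covariates).
#'
#' @param path Path to a tab-separated file.
#' @return data.frame with unique `sample_id`.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("clinical TSV needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  df
}
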