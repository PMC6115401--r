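#' Immune reference profile
#'
#' Bundles a genes x cell-type expression matrix with the subset of columns
#' regarded as T-cell subtypes/states, emulating signature matrices of the
#' LM22 kind (marker genes across 22 immune cell types and states).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   cell types in columns (colnames = cell-type ids). At least 2 columns.
#' @param t_cell_columns Character vector of column names treated as the
#'   T-cell lineage; defaults to the seven T-lineage columns of the LM22
#'   layout when present.
#' @return Object of class `"reference_profile"`.
#' @export
reference_profile <- function(values, t_cell_columns = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("reference profile needs gene rownames and cell-type colnames")
  if (ncol(values) < 2L) stop("at least 2 cell types are required")
  if (anyDuplicated(rownames(values))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(values))) stop("cell-type ids must be unique")
  if (any(!is.finite(values))) stop("reference profile values must be finite")
  if (is.null(t_cell_columns)) {
    t_cell_columns <- intersect(lm22_t_cell_columns(), colnames(values))
    if (length(t_cell_columns) == 0L)
      stop("no default T-cell columns found; supply t_cell_columns")
  }
  missing_cols <- setdiff(t_cell_columns, colnames(values))
  if (length(missing_cols))
    stop("t_cell_columns not present in profile: ",
         paste(missing_cols, collapse = ", "))
  structure(list(values = values, t_cell_columns = t_cell_columns),
            class = "reference_profile")
}

#' Default T-lineage column names (LM22 layout)
#'
#' The seven T-cell subtype/state columns of the canonical 22-type immune
#' reference layout.
#'
#' @return Character vector of seven column names.
#' @export
lm22_t_cell_columns <- function() {
  c("T.cells.CD8", "T.cells.CD4.naive", "T.cells.CD4.memory.resting",
    "T.cells.CD4.memory.activated", "T.cells.follicular.helper",
    "T.cells.regulatory.Tregs", "T.cells.gamma.delta")
}

#' Derive marker genes from a reference profile
#'
#' Standardizes each gene across all cell-type columns (gene-wise z-score,
#' mean and n-1 standard deviation over all columns) and returns the genes
#' whose z-score exceeds `z_threshold` in at least one target column.
#' This is the rule used to call T-cell markers from an immune reference
#' profile: genes overexpressed (z > 2) in at least one T-cell
#' subtype/state. Genes constant across cell types are skipped with a
#' warning (their z-score is undefined).
#'
#' @param ref A [reference_profile()].
#' @param z_threshold Z-score cutoff (default 2).
#' @param target_columns Columns in which the threshold must be exceeded;
#'   default: the profile's T-cell columns.
#' @return Character vector of marker gene ids, in profile row order.
#' @export
derive_markers <- function(ref, z_threshold = 2, target_columns = NULL) {
  stopifnot(inherits(ref, "reference_profile"))
  if (is.null(target_columns)) target_columns <- ref$t_cell_columns
  if (length(target_columns) == 0L) stop("target_columns must be non-empty")
  missing_cols <- setdiff(target_columns, colnames(ref$values))
  if (length(missing_cols))
    stop("target column not present in profile: ",
         paste(missing_cols, collapse = ", "))
  v <- ref$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  constant <- sdv == 0
  if (any(constant)) {
    warning(sum(constant),
            " gene(s) constant across cell types skipped (undefined z-score)")
    v <- v[!constant, , drop = FALSE]
    mu <- mu[!constant]
    sdv <- sdv[!constant]
  }
  z <- (v - mu) / sdv
  hit <- apply(z[, target_columns, drop = FALSE] > z_threshold, 1L, any)
  rownames(v)[hit]
}

#' Per-sample signature score
#'
#' Scores each sample by the arithmetic mean of the log2 expression of the
#' genes in a set -- the construction behind the infiltrating T-cell
#' abundance (ITA), hallmark-EMT, stromal/immune-average, and
#' EMT/Stroma_core scores. Set genes absent from the matrix are dropped
#' (with a message recording the count) or raise an error, depending on
#' `missing_policy`.
#'
#' @param expr Numeric genes x samples matrix of log2-scale expression with
#'   gene rownames and sample colnames.
#' @param genes Character vector of gene ids (a gene set).
#' @param missing_policy `"drop"` (default) or `"error"`.
#' @param name Optional signature name stored on the result.
#' @return Named numeric vector of per-sample scores with attributes
#'   `n_genes_used` and `signature`.
#' @export
score_signature <- function(expr, genes, missing_policy = c("drop", "error"),
                            name = NULL) {
  missing_policy <- match.arg(missing_policy)
  expr <- check_expression(expr)
  genes <- unique(as.character(genes))
  if (length(genes) == 0L) stop("gene set is empty")
  present <- intersect(genes, rownames(expr))
  n_missing <- length(genes) - length(present)
  if (length(present) == 0L)
    stop("no gene of the set is present in the expression matrix")
  if (n_missing > 0L) {
    if (missing_policy == "error")
      stop(n_missing, " set gene(s) missing from the expression matrix")
    message(n_missing, " of ", length(genes),
            " set gene(s) not in the matrix; scoring on ", length(present))
  }
  scores <- colMeans(expr[present, , drop = FALSE])
  attr(scores, "n_genes_used") <- length(present)
  attr(scores, "signature") <- name
  scores
}

#' Log2-transform a raw expression matrix
#'
#' Applies `log2(x + pseudocount)` to a matrix of non-negative raw values
#' (e.g. RSEM-normalized counts) and flags the result as log-transformed.
#'
#' @param raw Numeric matrix with non-negative values. Must not already
#'   carry a `log_transformed` flag.
#' @param pseudocount Value added before taking logs (default 1).
#' @return Matrix of `log2(raw + pseudocount)` with attribute
#'   `log_transformed = TRUE`.
#' @export
log_transform <- function(raw, pseudocount = 1) {
  raw <- as.matrix(raw)
  if (isTRUE(attr(raw, "log_transformed")))
    stop("matrix is already flagged as log-transformed")
  if (any(raw < 0, na.rm = TRUE)) stop("raw expression values must be >= 0")
  out <- log2(raw + pseudocount)
  attr(out, "log_transformed") <- TRUE
  out
}

check_expression <- function(expr) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(expr))) stop("sample ids must be unique")
  expr
}
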