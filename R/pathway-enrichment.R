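#' Per-gene correlation with a score
#'
#' Pearson correlation of every gene's expression with a per-sample score,
#' over their shared samples. Genes constant across the shared samples have
#' an undefined coefficient and are excluded with a message.
#'
#' @param expr Numeric genes x samples matrix (log2 scale) with dimnames.
#' @param score Named numeric vector of per-sample scores.
#' @param method Correlation method; only `"pearson"` is offered, matching
#'   the per-gene correlation underlying the pathway ranking.
#' @return Named numeric vector of per-gene correlation coefficients.
#' @export
per_gene_correlation <- function(expr, score, method = "pearson") {
  method <- match.arg(method, "pearson")
  expr <- check_expression(expr)
  if (is.null(names(score))) stop("score must be named by sample id")
  shared <- intersect(colnames(expr), names(score))
  if (length(shared) < 3L)
    stop("at least 3 shared samples are required")
  m <- expr[, shared, drop = FALSE]
  s <- as.numeric(score[shared])
  constant <- apply(m, 1L, function(r) stats::sd(r) == 0)
  if (any(constant))
    message(sum(constant), " constant gene(s) excluded (undefined correlation)")
  m <- m[!constant, , drop = FALSE]
  cc <- as.numeric(stats::cor(t(m), s, method = method))
  names(cc) <- rownames(m)
  cc
}

#' Rank pathways by the concordance of member-gene correlations
#'
#' For each pathway, compares the correlation coefficients (CCs) of its
#' member genes against the CCs of all other genes with a two-sided
#' Wilcoxon rank-sum test. Direction is the sign of the difference between
#' the member and complement median CC, and the reported `signed_score` is
#' `-log10(p)` for positively associated pathways and `+log10(p)` for
#' negatively associated ones, so that a ranking by `signed_score`
#' descending puts the most strongly positively associated pathways on top.
#'
#' @param cc Named numeric vector of per-gene correlation coefficients
#'   (e.g. from [per_gene_correlation()]).
#' @param collection Named list of character vectors (gene sets).
#' @param min_genes Minimum number of member genes with CCs required to
#'   test a pathway (default 10).
#' @return data.frame with columns `pathway`, `n_genes_in_matrix`,
#'   `direction` (+1/-1), `p_value`, `signed_score`, sorted by
#'   `signed_score` descending. Pathways failing `min_genes` or covering
#'   every gene are skipped with a warning.
#' @export
rank_pathways <- function(cc, collection, min_genes = 10L) {
  if (is.null(names(cc))) stop("cc must be named by gene id")
  if (is.null(names(collection))) stop("collection must be a named list")
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(names(cc), collection[[nm]])
    if (length(members) < min_genes) {
      warning("pathway '", nm, "' skipped: fewer than ", min_genes,
              " member genes with correlations")
      return(NULL)
    }
    complement <- setdiff(names(cc), members)
    if (length(complement) == 0L) {
      warning("pathway '", nm, "' skipped: covers all genes (empty complement)")
      return(NULL)
    }
    rt <- wilcoxon_rank_sum(cc[members], cc[complement])
    direction <- if (stats::median(cc[members]) >=
                     stats::median(cc[complement])) 1 else -1
    data.frame(pathway = nm,
               n_genes_in_matrix = length(members),
               direction = direction,
               p_value = rt$p_value,
               signed_score = direction * -log10(rt$p_value),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pathway could be tested")
  out <- out[order(out$signed_score, decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
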