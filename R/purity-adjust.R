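#' Residualize a signature score on tumor purity
#'
#' Removes the tumor-purity component of a per-sample score by ordinary
#' least squares on the model `score ~ 1 + log(1 - purity)` and returns the
#' residuals -- the purity-adjusted score. Purity is clipped to
#' `1 - clip_epsilon` before the log so fully pure samples stay finite.
#' Samples without a purity value are dropped with a message.
#'
#' @param score Named numeric vector of per-sample scores.
#' @param purity Named numeric vector of purities in `[0, 1]` (names =
#'   sample ids), or a data.frame with columns `sample_id` and `purity`.
#' @param clip_epsilon Upper clip for purity (default 1e-3, i.e. purity is
#'   capped at 0.999).
#' @return Named numeric vector of residuals over the shared samples, with
#'   attribute `n_dropped` (samples lacking purity).
#' @export
adjust_for_purity <- function(score, purity, clip_epsilon = 1e-3) {
  purity <- as_purity(purity)
  if (is.null(names(score))) stop("score must be named by sample id")
  shared <- intersect(names(score), names(purity))
  n_dropped <- length(score) - length(shared)
  if (length(shared) < 3L)
    stop("at least 3 samples with both score and purity are required")
  if (n_dropped > 0L)
    message(n_dropped, " sample(s) without purity dropped")
  s <- as.numeric(score[shared])
  p <- pmin(purity[shared], 1 - clip_epsilon)
  x <- log(1 - p)
  if (stats::sd(x) == 0) stop("purity is constant; adjustment is undefined")
  fit <- stats::lm(s ~ x)
  res <- stats::residuals(fit)
  names(res) <- shared
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Score-score association before and after purity adjustment
#'
#' Correlates two per-sample scores on their shared samples, then
#' residualizes each on `log(1 - purity)` and correlates the residuals.
#' The drop from `raw` to `adjusted` measures how much of the association
#' is carried by shared tumor-purity variation.
#'
#' @param score_a,score_b Named numeric score vectors.
#' @param purity Purity table as in [adjust_for_purity()].
#' @param method Correlation flavor, `"spearman"` (default, matching the
#'   usual reporting for purity relationships) or `"pearson"`.
#' @param clip_epsilon Passed to [adjust_for_purity()].
#' @return List with `raw`, `adjusted`, `method`, `n` (shared samples).
#' @export
adjusted_association <- function(score_a, score_b, purity,
                                 method = c("spearman", "pearson"),
                                 clip_epsilon = 1e-3) {
  method <- match.arg(method)
  purity <- as_purity(purity)
  shared <- Reduce(intersect,
                   list(names(score_a), names(score_b), names(purity)))
  if (length(shared) < 3L) stop("at least 3 shared samples are required")
  a <- score_a[shared]
  b <- score_b[shared]
  raw <- cor_coef(a, b, method)
  ra <- adjust_for_purity(a, purity[shared], clip_epsilon)
  rb <- adjust_for_purity(b, purity[shared], clip_epsilon)
  adjusted <- cor_coef(ra[shared], rb[shared], method)
  list(raw = raw, adjusted = adjusted, method = method, n = length(shared))
}

as_purity <- function(purity) {
  if (is.data.frame(purity)) {
    if (!all(c("sample_id", "purity") %in% names(purity)))
      stop("purity data.frame needs columns 'sample_id' and 'purity'")
    p <- as.numeric(purity$purity)
    names(p) <- as.character(purity$sample_id)
    purity <- p
  }
  if (is.null(names(purity))) stop("purity must be named by sample id")
  if (anyDuplicated(names(purity))) stop("purity sample ids must be unique")
  if (any(purity < 0 | purity > 1, na.rm = TRUE))
    stop("purity must lie in [0, 1]")
  purity[!is.na(purity)]
}
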