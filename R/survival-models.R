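#' Fit a Cox proportional-hazards model on a clinical table
#'
#' Maximizes the Cox partial likelihood (Efron handling of tied event
#' times) for overall or progression-free survival as a function of the
#' given formula terms (columns of `clinical`, `a:b` interactions
#' allowed). Rows with missing values in any used column are dropped with
#' a message.
#'
#' @param clinical data.frame with `sample_id`, `<endpoint>_time`,
#'   `<endpoint>_event` and covariate columns.
#' @param endpoint `"os"` or `"pfs"`.
#' @param terms Character vector of model terms, e.g.
#'   `c("cd8_ihc", "emt_stroma", "cd8_ihc:emt_stroma")`.
#' @return Object of class `"cox_fit"`: list with `model` (the underlying
#'   `coxph` fit), `terms`, `coef`, `vcov`, `log_likelihood`,
#'   `null_log_likelihood`, `n`, `n_events`, `endpoint`, `data`.
#' @export
fit_cox <- function(clinical, endpoint = c("os", "pfs"), terms) {
  endpoint <- match.arg(endpoint)
  if (length(terms) == 0L) stop("at least one model term is required")
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  dat <- endpoint_data(clinical, c(tcol, ecol), terms)
  if (sum(dat[[ecol]]) < 2L) stop("at least 2 events are required")
  check_nonconstant(dat, terms)
  fml <- stats::as.formula(paste0(
    "survival::Surv(", tcol, ", ", ecol, ") ~ ", paste(terms, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron", x = TRUE),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w)))
        stop("Cox fit failed (possible separation/non-convergence): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  structure(
    list(model = fit, terms = terms, coef = stats::coef(fit),
         vcov = stats::vcov(fit),
         log_likelihood = fit$loglik[2], null_log_likelihood = fit$loglik[1],
         n = fit$n, n_events = fit$nevent, endpoint = endpoint, data = dat),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s): n = %d, events = %d, loglik = %.3f\n",
              toupper(x$endpoint), x$n, x$n_events, x$log_likelihood))
  print(summary_table(x))
  invisible(x)
}

#' Interquartile-scaled hazard or odds ratios
#'
#' Re-expresses each fitted coefficient as the ratio comparing the 75th to
#' the 25th percentile of the corresponding biomarker: `exp(beta * (q75 -
#' q25))`, with a Wald confidence interval scaled identically. Because the
#' model is linear in the biomarker, the ratio depends only on the
#' interquartile distance. Quantiles use linear interpolation between order
#' statistics (R type 7). For interaction terms `a:b` the quantiles of the
#' elementwise product are used unless explicit values are supplied.
#'
#' @param fit A `"cox_fit"` or `"logistic_fit"`.
#' @param terms Terms to scale (default: all fitted terms).
#' @param values Optional named list mapping a term to the numeric vector
#'   whose quartiles define the scaling.
#' @param confidence Confidence level for the Wald interval (default 0.95).
#' @return data.frame with `term`, `beta`, `iqr`, `ratio`, `lower`,
#'   `upper`, `wald_p`. `ratio` is a hazard ratio for Cox fits and an odds
#'   ratio for logistic fits.
#' @export
scaled_effect <- function(fit, terms = NULL, values = NULL,
                          confidence = 0.95) {
  stopifnot(inherits(fit, c("cox_fit", "logistic_fit")))
  if (is.null(terms)) terms <- names(fit$coef)
  terms <- setdiff(terms, "(Intercept)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  rows <- lapply(terms, function(tm) {
    if (!tm %in% names(fit$coef)) stop("term absent from fit: ", tm)
    v <- if (!is.null(values) && tm %in% names(values)) values[[tm]]
         else term_values(fit$data, tm)
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    d <- q[2] - q[1]
    beta <- fit$coef[[tm]]
    se <- sqrt(fit$vcov[tm, tm])
    data.frame(term = tm, beta = beta, iqr = d,
               ratio = exp(beta * d),
               lower = exp((beta - z * se) * d),
               upper = exp((beta + z * se) * d),
               wald_p = 2 * stats::pnorm(-abs(beta / se)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test between nested fits
#'
#' Twice the log-likelihood difference between a full and a nested model,
#' referred to a chi-square distribution with degrees of freedom equal to
#' the difference in coefficient count. The models must be of the same
#' family, fitted on the same samples, and the nested model's terms must be
#' a subset of the full model's.
#'
#' @param nested,full Fits of class `"cox_fit"` or `"logistic_fit"`.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, c("cox_fit", "logistic_fit")),
            inherits(full, c("cox_fit", "logistic_fit")))
  if (class(nested)[1] != class(full)[1])
    stop("nested and full fits must be of the same model family")
  if (!is.null(nested$endpoint) && !identical(nested$endpoint, full$endpoint))
    stop("nested and full fits must use the same endpoint")
  if (nested$n != full$n)
    stop("nested and full fits must be fitted on the same samples")
  if (!all(nested$terms %in% full$terms))
    stop("models are not nested: nested terms must be a subset of full terms")
  df <- length(full$coef) - length(nested$coef)
  statistic <- max(0, 2 * (full$log_likelihood - nested$log_likelihood))
  p <- if (df == 0L) 1 else stats::pchisq(statistic, df, lower.tail = FALSE)
  list(statistic = statistic, df = df, p_value = p)
}

#' Per-gene survival screen conditioned on a signature score
#'
#' For each candidate gene fits the bivariate Cox model
#' `lambda(t) = lambda0(t) * exp(beta1 * score + beta2 * gene)` and ranks
#' genes by the Wald p-value of the gene coefficient. Genes with
#' coefficient above zero (harmful direction) are reported with
#' `signed_log10_p = log10(p)` and protective genes with `-log10(p)`, so
#' a plot of the signed value separates directions. Benjamini-Hochberg
#' adjusted p-values are included, and the genes passing `p_cutoff` on the
#' raw Wald p form the selected set (the EMT/Stroma_core construction uses
#' cutoff 1e-6).
#'
#' @param expr Numeric genes x samples log2 expression matrix.
#' @param conditioning_score Named numeric per-sample score (e.g. ITA).
#' @param clinical Clinical table with `sample_id` and endpoint columns.
#' @param candidate_genes Character vector of gene ids to screen.
#' @param p_cutoff Raw Wald p-value selection cutoff (default 1e-6).
#' @param endpoint `"os"` (default) or `"pfs"`.
#' @return List with `results` (data.frame: `gene`, `beta`, `wald_p`,
#'   `bh_adjusted_p`, `signed_log10_p`, `rank`, ordered by p) and
#'   `selected` (character vector of genes with `wald_p < p_cutoff`).
#' @export
screen_genes <- function(expr, conditioning_score, clinical, candidate_genes,
                         p_cutoff = 1e-6, endpoint = "os") {
  expr <- check_expression(expr)
  endpoint <- match.arg(endpoint, c("os", "pfs"))
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  if (is.null(names(conditioning_score)))
    stop("conditioning_score must be named by sample id")
  shared <- Reduce(intersect, list(colnames(expr), names(conditioning_score),
                                   as.character(clinical$sample_id)))
  if (length(shared) < 10L) stop("too few shared samples for the screen")
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  base <- data.frame(time = cl[[tcol]], event = cl[[ecol]],
                     score = as.numeric(conditioning_score[shared]))
  keep <- stats::complete.cases(base)
  base <- base[keep, , drop = FALSE]
  shared <- shared[keep]
  candidates <- intersect(candidate_genes, rownames(expr))
  if (length(candidates) == 0L)
    stop("no candidate gene present in the expression matrix")
  n_skipped <- 0L
  rows <- lapply(candidates, function(g) {
    gv <- as.numeric(expr[g, shared])
    if (stats::sd(gv) == 0) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    dat <- base
    dat$gene <- gv
    fit <- tryCatch(
      suppressWarnings(survival::coxph(
        survival::Surv(time, event) ~ score + gene, data = dat,
        ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)[["gene"]])) return(NULL)
    beta <- stats::coef(fit)[["gene"]]
    se <- sqrt(stats::vcov(fit)["gene", "gene"])
    p <- 2 * stats::pnorm(-abs(beta / se))
    data.frame(gene = g, beta = beta, wald_p = p, stringsAsFactors = FALSE)
  })
  if (n_skipped > 0L)
    warning(n_skipped, " constant gene(s) skipped in the survival screen")
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no gene could be screened")
  res$bh_adjusted_p <- bh_adjust(res$wald_p)
  res$signed_log10_p <- ifelse(res$beta > 0, log10(res$wald_p),
                               -log10(res$wald_p))
  res <- res[order(res$wald_p), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  list(results = res, selected = res$gene[res$wald_p < p_cutoff])
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit survival estimate within each group label.
#'
#' @param clinical Clinical table with endpoint columns.
#' @param endpoint `"os"` or `"pfs"`.
#' @param groups Factor or character vector of group labels, one per row of
#'   `clinical`; missing labels raise an error.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `survival`; attribute `n_per_group` holds group sizes.
#' @export
km_estimate <- function(clinical, endpoint = c("os", "pfs"), groups) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  if (length(groups) != nrow(clinical))
    stop("groups must have one label per clinical row")
  if (anyNA(groups)) stop("unknown (missing) group label")
  groups <- factor(groups)
  dat <- data.frame(time = clinical[[tcol]], event = clinical[[ecol]],
                    group = groups)
  if (anyNA(dat$time) || anyNA(dat$event))
    stop("missing endpoint values; drop them before KM estimation")
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  if (is.null(sf$strata)) {
    grp <- rep(levels(groups)[1], length(sf$time))
  } else {
    grp <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  }
  out <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, survival = sf$surv,
                    stringsAsFactors = FALSE)
  attr(out, "n_per_group") <- table(groups)
  out
}

#' Median-split group labels from one or two scores
#'
#' Dichotomizes each score at its median, labelling a sample `high` when
#' its score is greater than or equal to the median (ties go high). With
#' two scores the 2 x 2 cross yields four labels such as
#' `"ita_high.emt_low"`.
#'
#' @param scores Named list of one or two named numeric score vectors; the
#'   list names become the label prefixes.
#' @return Named factor of group labels over the samples shared by all
#'   scores.
#' @export
median_split_groups <- function(scores) {
  if (!is.list(scores)) scores <- list(score = scores)
  if (length(scores) < 1L || length(scores) > 2L)
    stop("one or two scores are required")
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    names(scores) <- paste0("score", seq_along(scores))
  if (any(vapply(scores, length, 1L) == 0L)) stop("empty score")
  if (any(vapply(scores, function(s) is.null(names(s)), TRUE)))
    stop("scores must be named by sample id")
  shared <- Reduce(intersect, lapply(scores, names))
  if (length(shared) == 0L) stop("no shared samples between scores")
  labs <- lapply(names(scores), function(nm) {
    s <- scores[[nm]][shared]
    paste0(nm, "_", ifelse(s >= stats::median(s), "high", "low"))
  })
  out <- factor(do.call(paste, c(labs, sep = ".")))
  names(out) <- shared
  out
}

#' Ratio (or log-scale difference) of two scores
#'
#' Elementwise ratio of two aligned per-sample scores, e.g. the ITA-to-EMT
#' balance. Because mean-log2 scores live on a log scale, the difference
#' `numerator - denominator` (a log fold change) is available behind
#' `log_difference = TRUE`.
#'
#' @param numerator,denominator Named numeric score vectors.
#' @param log_difference If `TRUE` return `numerator - denominator`
#'   instead of the literal ratio.
#' @return Named numeric vector over the shared samples.
#' @export
ratio_score <- function(numerator, denominator, log_difference = FALSE) {
  if (is.null(names(numerator)) || is.null(names(denominator)))
    stop("scores must be named by sample id")
  shared <- intersect(names(numerator), names(denominator))
  if (length(shared) == 0L) stop("no shared samples")
  num <- as.numeric(numerator[shared])
  den <- as.numeric(denominator[shared])
  out <- if (log_difference) {
    num - den
  } else {
    if (any(den == 0)) stop("zero denominator score; ratio undefined")
    num / den
  }
  names(out) <- shared
  out
}

#' Proportional-hazards diagnostics from scaled Schoenfeld residuals
#'
#' Computes, per model term, the Pearson correlation between the scaled
#' Schoenfeld residuals and (Kaplan-Meier transformed) event time, plus
#' the score-test p-value for a time trend (via [survival::cox.zph()]).
#' A small p flags a violation of proportional hazards for that term.
#'
#' @param fit A `"cox_fit"`.
#' @param transform Time transform passed to [survival::cox.zph()]
#'   (default `"km"`).
#' @return data.frame with `term`, `cor_with_time`, `chisq`, `df`, `p`;
#'   attribute `n_residuals` gives the residual row count (one per event).
#' @export
ph_diagnostics <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 2L) stop("at least 2 events are required")
  zph <- survival::cox.zph(fit$model, transform = transform)
  y <- as.matrix(zph$y)
  terms <- colnames(y)
  ct <- vapply(seq_along(terms),
               function(j) stats::cor(zph$x, y[, j]), numeric(1))
  tab <- zph$table
  out <- data.frame(term = terms, cor_with_time = ct,
                    chisq = tab[terms, "chisq"], df = tab[terms, "df"],
                    p = tab[terms, "p"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_residuals") <- nrow(y)
  out
}

# shared helpers ------------------------------------------------------------

endpoint_data <- function(clinical, outcome_cols, terms) {
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  needed <- c(outcome_cols, vars)
  missing_cols <- setdiff(needed, names(clinical))
  if (length(missing_cols))
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "))
  keep <- stats::complete.cases(clinical[, needed, drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " sample(s) with missing values dropped")
  clinical[keep, , drop = FALSE]
}

check_nonconstant <- function(dat, terms) {
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in vars) {
    if (length(unique(dat[[v]])) < 2L)
      stop("constant covariate: ", v)
  }
}

term_values <- function(data, term) {
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  if (!all(vars %in% names(data)))
    stop("no data column(s) for term '", term,
         "'; supply values= explicitly")
  Reduce(`*`, lapply(vars, function(v) as.numeric(data[[v]])))
}

summary_table <- function(fit) {
  se <- sqrt(diag(fit$vcov))
  data.frame(term = names(fit$coef), beta = unname(fit$coef), se = unname(se),
             wald_p = unname(2 * stats::pnorm(-abs(fit$coef / se))),
             stringsAsFactors = FALSE)
}
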