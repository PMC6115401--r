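#' Fit a logistic regression model of objective response
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' convergence tolerance 1e-8, at most 100 iterations) of a binary
#' response on the given terms. Complete separation raises an error with a
#' diagnostic rather than returning a degenerate fit.
#'
#' @param clinical data.frame with the response column and covariates.
#' @param terms Character vector of model terms (`a:b` interactions
#'   allowed).
#' @param response_col Name of the 0/1 response column (default
#'   `"response"`).
#' @return Object of class `"logistic_fit"`: list with `model` (the `glm`
#'   fit), `terms`, `coef`, `vcov`, `log_likelihood`, `n`, `data`.
#' @export
fit_logistic <- function(clinical, terms, response_col = "response") {
  if (length(terms) == 0L) stop("at least one model term is required")
  dat <- endpoint_data(clinical, response_col, terms)
  y <- dat[[response_col]]
  if (!all(y %in% c(0, 1))) stop("response must be coded 0/1")
  if (length(unique(y)) < 2L) stop("both response classes must be present")
  check_nonconstant(dat, terms)
  fml <- stats::as.formula(paste0(response_col, " ~ ",
                                  paste(terms, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged || any(abs(stats::coef(fit)[-1]) > 15))
    stop("logistic fit failed: complete or quasi-complete separation ",
         "(fitted probabilities numerically 0 or 1)")
  structure(
    list(model = fit, terms = terms, coef = stats::coef(fit),
         vcov = stats::vcov(fit),
         log_likelihood = as.numeric(stats::logLik(fit)),
         n = nrow(dat), endpoint = "response", data = dat),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (objective response): n = %d, loglik = %.3f\n",
              x$n, x$log_likelihood))
  print(summary_table(x))
  invisible(x)
}

#' Default nested-model ladder for CD8 x EMT/Stroma interaction analyses
#'
#' The ten likelihood-ratio tests probing how CD8 infiltration,
#' EMT/Stroma_core gene expression, their interaction, and baseline
#' covariates (hemoglobin, liver metastases, PD-L1) relate to outcome.
#' Each row compares a model II against its nested model I.
#'
#' @param cd8,stroma Column names of the CD8 and EMT/Stroma_core scores.
#' @param baseline Character vector of baseline covariate column names.
#' @return List of rows, each `list(label, model_1, model_2)`.
#' @export
default_ladder <- function(cd8 = "cd8_ihc", stroma = "emt_stroma",
                           baseline = c("hbn", "livermet", "pdl1")) {
  int <- paste0(cd8, ":", stroma)
  list(
    list(label = "Effect of CD8 alone",
         model_1 = character(0), model_2 = cd8),
    list(label = "Overall effect of adding EMT/Stroma_core",
         model_1 = cd8, model_2 = c(cd8, stroma, int)),
    list(label = "CD8:EMT/Stroma_core interaction",
         model_1 = c(cd8, stroma), model_2 = c(cd8, stroma, int)),
    list(label = "Effect of adding CD8 to baseline variables",
         model_1 = baseline, model_2 = c(baseline, cd8)),
    list(label = "Overall effect of adding EMT/Stroma_core to baseline and CD8",
         model_1 = c(baseline, cd8), model_2 = c(baseline, cd8, stroma, int)),
    list(label = "CD8:EMT/Stroma_core interaction with baseline variables",
         model_1 = c(baseline, cd8, stroma),
         model_2 = c(baseline, cd8, stroma, int)),
    list(label = "Effect of EMT/Stroma_core alone",
         model_1 = character(0), model_2 = stroma),
    list(label = "Overall effect of adding CD8",
         model_1 = stroma, model_2 = c(stroma, cd8, int)),
    list(label = "Effect of adding EMT/Stroma_core to baseline variables",
         model_1 = baseline, model_2 = c(baseline, stroma)),
    list(label = "Overall effect of adding CD8 to baseline and EMT/Stroma_core",
         model_1 = c(baseline, stroma), model_2 = c(baseline, stroma, cd8, int))
  )
}

#' Nested-model likelihood-ratio ladder across endpoints
#'
#' Runs each (model I, model II) pair of a ladder as a likelihood-ratio
#' test for every requested endpoint: Cox proportional-hazards models for
#' `pfs` and `os`, logistic regression for `response`. All fits within a
#' row/endpoint use the complete cases over the union of model II
#' variables, so nested and full models see the same samples. No
#' multiplicity correction is applied across the ladder.
#'
#' @param clinical Clinical table with endpoint and covariate columns.
#' @param ladder Ladder specification as produced by [default_ladder()].
#' @param endpoints Subset of `c("pfs", "os", "response")`.
#' @return data.frame with one row per test: `test`, `model_I`,
#'   `model_II`, and one `p_<endpoint>` column per endpoint.
#' @export
model_ladder <- function(clinical, ladder = default_ladder(),
                         endpoints = c("pfs", "os", "response")) {
  endpoints <- match.arg(endpoints, several.ok = TRUE)
  rows <- lapply(ladder, function(row) {
    m1 <- row$model_1
    m2 <- row$model_2
    if (!all(m1 %in% m2) || length(m2) <= length(m1))
      stop("ladder row not properly nested: ", row$label)
    out <- data.frame(test = row$label,
                      model_I = ladder_model_label(m1),
                      model_II = ladder_model_label(m2),
                      stringsAsFactors = FALSE)
    for (ep in endpoints) {
      out[[paste0("p_", ep)]] <- ladder_test_p(clinical, m1, m2, ep)
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("model_ladder", class(out))
  out
}

ladder_model_label <- function(terms) {
  if (length(terms) == 0L) "Intercept"
  else paste(c("Intercept", terms), collapse = " + ")
}

ladder_test_p <- function(clinical, m1, m2, endpoint) {
  vars <- unique(unlist(strsplit(m2, ":", fixed = TRUE)))
  if (endpoint == "response") {
    needed <- c("response", vars)
    dat <- clinical[stats::complete.cases(clinical[, needed, drop = FALSE]), ,
                    drop = FALSE]
    full <- fit_logistic(dat, m2)
    nested_ll <- if (length(m1) == 0L) {
      null_fit <- stats::glm(response ~ 1, data = dat,
                             family = stats::binomial())
      as.numeric(stats::logLik(null_fit))
    } else {
      fit_logistic(dat, m1)$log_likelihood
    }
    df <- length(m2) - length(m1)
  } else {
    tcol <- paste0(endpoint, "_time")
    ecol <- paste0(endpoint, "_event")
    needed <- c(tcol, ecol, vars)
    dat <- clinical[stats::complete.cases(clinical[, needed, drop = FALSE]), ,
                    drop = FALSE]
    full <- fit_cox(dat, endpoint, m2)
    nested_ll <- if (length(m1) == 0L) full$null_log_likelihood
                 else fit_cox(dat, endpoint, m1)$log_likelihood
    df <- length(m2) - length(m1)
  }
  statistic <- max(0, 2 * (full$log_likelihood - nested_ll))
  stats::pchisq(statistic, df, lower.tail = FALSE)
}

#' Objective response rate by subgroup with exact confidence intervals
#'
#' Tabulates responders and response rate per subgroup, with a two-sided
#' Clopper-Pearson exact confidence interval for each rate. Empty
#' subgroups are reported with `n = 0` and an undefined-CI flag rather
#' than dropped.
#'
#' @param clinical Clinical table with a 0/1 `response` column.
#' @param groups Factor of subgroup labels (e.g. from
#'   [median_split_groups()]), one per clinical row.
#' @param confidence Confidence level (default 0.95).
#' @return data.frame with `group`, `responders`, `n`, `rate`, `lower`,
#'   `upper`, `defined` (FALSE for empty subgroups).
#' @export
subgroup_response <- function(clinical, groups, confidence = 0.95) {
  if (length(groups) != nrow(clinical))
    stop("groups must have one label per clinical row")
  if (!is.factor(groups)) groups <- factor(groups)  # keep declared levels
  y <- clinical$response
  keep <- !is.na(y)
  y <- y[keep]
  g <- droplevels_keep(groups[keep], levels(groups))
  rows <- lapply(levels(groups), function(lv) {
    idx <- g == lv
    n <- sum(idx)
    if (n == 0L) {
      return(data.frame(group = lv, responders = 0L, n = 0L, rate = NA_real_,
                        lower = NA_real_, upper = NA_real_, defined = FALSE,
                        stringsAsFactors = FALSE))
    }
    x <- sum(y[idx])
    ci <- clopper_pearson(x, n, confidence)
    data.frame(group = lv, responders = x, n = n, rate = ci$point,
               lower = ci$lower, upper = ci$upper, defined = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

droplevels_keep <- function(f, lev) factor(as.character(f), levels = lev)

#' Compare CD8 spatial densities between stroma-score groups
#'
#' Splits specimens at the median stroma score (ties high) and compares
#' intratumoral CD8 density, peritumoral CD8 density, and the
#' peritumoral-to-intratumoral ratio between the high and low groups with
#' two-sided Wilcoxon rank-sum tests (high group first, so the reported
#' statistic is the rank sum of the high-stroma specimens). When the
#' intratumoral density is zero the ratio is undefined; a continuity
#' offset (default 0.5 cells/mm^2) is added to both numerator and
#' denominator for those records, and the affected count is messaged.
#'
#' @param records data.frame with columns `sample_id`,
#'   `intratumoral_density`, `peritumoral_density`, `stroma_score`
#'   (densities in cells/mm^2, non-negative).
#' @param ratio_offset Continuity offset for zero intratumoral densities.
#' @return List with `intratumoral`, `peritumoral`, `ratio` (each a
#'   `"rank_test"`), `groups` (factor), and `ratios` (the per-sample
#'   ratios used).
#' @export
cd8_spatial_compare <- function(records, ratio_offset = 0.5) {
  needed <- c("sample_id", "intratumoral_density", "peritumoral_density",
              "stroma_score")
  if (!all(needed %in% names(records)))
    stop("records need columns: ", paste(needed, collapse = ", "))
  it <- records$intratumoral_density
  pt <- records$peritumoral_density
  if (any(it < 0 | pt < 0)) stop("densities must be non-negative")
  grp <- factor(ifelse(records$stroma_score >=
                         stats::median(records$stroma_score),
                       "high", "low"), levels = c("high", "low"))
  if (any(table(grp) < 2L))
    stop("at least 2 records are required on each side of the median split")
  ratio <- pt / it
  undef <- it == 0
  if (any(undef)) {
    message(sum(undef), " record(s) with zero intratumoral density; ",
            "continuity offset ", ratio_offset, " applied")
    ratio[undef] <- (pt[undef] + ratio_offset) / (it[undef] + ratio_offset)
  }
  hi <- grp == "high"
  list(intratumoral = wilcoxon_rank_sum(it[hi], it[!hi]),
       peritumoral = wilcoxon_rank_sum(pt[hi], pt[!hi]),
       ratio = wilcoxon_rank_sum(ratio[hi], ratio[!hi]),
       groups = grp, ratios = stats::setNames(ratio, records$sample_id))
}
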