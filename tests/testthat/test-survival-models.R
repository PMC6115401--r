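test_that("Cox fit maximizes the partial likelihood (oracle check)", {
  # 6-subject tie-free toy against a golden-section maximizer of the
  # explicitly coded partial likelihood
  d <- data.frame(sample_id = 1:6,
                  os_time = c(1.1, 2.3, 3.1, 4.7, 5.2, 6.9),
                  os_event = c(1, 1, 0, 1, 1, 1),
                  x = c(0.3, -1.2, 0.8, 1.5, -0.4, 0.1))
  fit <- fit_cox(d, "os", "x")
  expect_equal(unname(fit$coef), cox_oracle_beta(d$os_time, d$os_event, d$x),
               tolerance = 1e-6)
  # reported log-likelihood equals the coded one at the fitted beta
  expect_equal(fit$log_likelihood,
               cox_partial_loglik(fit$coef, d$os_time, d$os_event, d$x),
               tolerance = 1e-8)

  expect_error(fit_cox(transform(d, os_event = 0), "os", "x"), "2 events")
  expect_error(fit_cox(transform(d, x = 1), "os", "x"), "constant")
})

test_that("partial-likelihood maximizer matches the oracle on random toys", {
  for (s in 1:30) {
    d <- random_survival_toy(sample(4:8, 1), seed = 400 + s)
    d$sample_id <- seq_len(nrow(d))
    names(d)[1:2] <- c("os_time", "os_event")
    fit <- tryCatch(fit_cox(d, "os", "x"), error = function(e) NULL)
    if (is.null(fit)) next  # monotone-likelihood instances are rejected
    expect_lt(abs(unname(fit$coef) -
                    cox_oracle_beta(d$os_time, d$os_event, d$x)), 1e-6)
  }
})

test_that("scaled hazard ratios follow the interquartile closed form", {
  d <- toy_clinical(300, seed = 12)
  fit <- fit_cox(d, "os", "x")

  # null covariate: scaled HR interval contains 1
  null_d <- toy_clinical(500, seed = 13)
  null_fit <- fit_cox(null_d, "os", "z")
  se_null <- scaled_effect(null_fit)
  expect_true(se_null$lower <= 1 && 1 <= se_null$upper)

  # closed form with supplied values
  fit2 <- fit_cox(d, "os", "x")
  fit2$coef[["x"]] <- log(2)
  expect_equal(scaled_effect(fit2, values = list(x = c(0, 0, 1, 1)))$ratio, 2)
  expect_equal(scaled_effect(fit2, values = list(x = c(0, 0, 2, 2)))$ratio, 4)

  # rescaling the covariate halves beta but leaves the scaled HR unchanged
  d2 <- d
  d2$x <- 2 * d2$x
  refit <- fit_cox(d2, "os", "x")
  expect_equal(unname(refit$coef), unname(fit$coef) / 2, tolerance = 1e-6)
  expect_equal(scaled_effect(refit)$ratio, scaled_effect(fit)$ratio,
               tolerance = 1e-6)

  expect_error(scaled_effect(fit, terms = "absent"), "absent")
})

test_that("likelihood-ratio test equals twice the loglik gap", {
  d <- toy_clinical(80, seed = 14)
  nested <- fit_cox(d, "os", "x")
  full <- fit_cox(d, "os", c("x", "z"))
  lrt <- likelihood_ratio_test(nested, full)
  expect_equal(lrt$df, 1)

  # independent evaluation of both log-likelihoods at the fitted betas
  X1 <- matrix(d$x)
  X2 <- cbind(d$x, d$z)
  ll_n <- cox_partial_loglik_multi(nested$coef, d$os_time, d$os_event, X1)
  ll_f <- cox_partial_loglik_multi(full$coef, d$os_time, d$os_event, X2)
  expect_equal(lrt$statistic, 2 * (ll_f - ll_n), tolerance = 1e-6)
  expect_equal(lrt$p_value, pchisq(lrt$statistic, 1, lower.tail = FALSE))

  # identical models: statistic 0, p 1
  same <- likelihood_ratio_test(nested, fit_cox(d, "os", "x"))
  expect_equal(same$statistic, 0, tolerance = 1e-8)
  expect_equal(same$p_value, 1)

  expect_error(likelihood_ratio_test(full, nested), "not nested")
  expect_error(likelihood_ratio_test(fit_cox(d, "pfs", "x"), full), "endpoint")
})

test_that("the per-gene survival screen finds planted genes and ranks by Wald p", {
  sim <- simulate_bulk_cohort(cohort_config(
    seed = 21, n_samples = 200, n_genes = 800, n_screen_candidates = 40,
    screen_planted = 2, beta_screen = 1.5,
    n_random_pathways = 0))
  ita <- score_signature(sim$expr, sim$gene_sets$t_cell_markers)
  sc <- screen_genes(sim$expr, ita, sim$clinical,
                     sim$gene_sets$screen_candidates, p_cutoff = 1e-4)
  expect_true(all(sim$truth$planted_genes %in% sc$selected))
  expect_equal(sc$results$rank, seq_len(nrow(sc$results)))
  expect_true(all(diff(sc$results$wald_p) >= 0))
  expect_equal(sc$results$bh_adjusted_p, bh_adjust(sc$results$wald_p)[
    order(order(sc$results$wald_p))], tolerance = 1e-12)
  # signed reporting separates harmful from protective directions
  expect_true(all((sc$results$beta > 0) == (sc$results$signed_log10_p < 0)))

  # constant genes are skipped, not fatal
  expr2 <- sim$expr
  expr2[sim$gene_sets$screen_candidates[10], ] <- 3
  expect_warning(
    sc2 <- screen_genes(expr2, ita, sim$clinical,
                        sim$gene_sets$screen_candidates, p_cutoff = 1e-4),
    "constant")
  expect_false(sim$gene_sets$screen_candidates[10] %in% sc2$results$gene)
})

test_that("Kaplan-Meier estimate matches the hand product-limit table", {
  d <- data.frame(sample_id = 1:5,
                  os_time = c(1, 2, 3, 4, 5),
                  os_event = c(1, 1, 0, 1, 0))
  km <- km_estimate(d, "os", rep("all", 5))
  # S(1) = 4/5; S(2) = 4/5 * 3/4 = 3/5; S(4) = 3/5 * 1/2 = 3/10
  expect_equal(km$survival[km$time == 1], 0.8)
  expect_equal(km$survival[km$time == 2], 0.6)
  expect_equal(km$survival[km$time == 4], 0.3)
  expect_true(all(diff(km$survival) <= 0))

  # no events: survival stays at 1
  km0 <- km_estimate(transform(d, os_event = 0), "os", rep("all", 5))
  expect_true(all(km0$survival == 1))

  # no censoring in a single group: equals the empirical survival function
  d2 <- data.frame(sample_id = 1:8, os_time = c(2, 4, 1, 7, 3, 6, 5, 8),
                   os_event = 1)
  km2 <- km_estimate(d2, "os", rep("g", 8))
  expect_equal(km2$survival, 1 - ecdf(d2$os_time)(sort(d2$os_time)))

  # group sizes conserved
  grp <- rep(c("a", "b"), c(3, 2))
  km3 <- km_estimate(d, "os", grp)
  expect_equal(sum(attr(km3, "n_per_group")), 5)
  expect_error(km_estimate(d, "os", c(grp[-5], NA)), "group label")
})

test_that("median splits follow the >= convention and cross to four groups", {
  s <- setNames(c(1, 2, 3, 4), paste0("p", 1:4))
  g <- median_split_groups(list(score = s))
  expect_equal(as.character(g), c("score_low", "score_low",
                                  "score_high", "score_high"))

  # value equal to the median goes high
  s_odd <- setNames(c(1, 2, 3), paste0("p", 1:3))
  expect_equal(as.character(median_split_groups(list(v = s_odd))[2]), "v_high")

  # 2x2 cross against explicit enumeration
  ita <- setNames(c(5, 1, 6, 2), paste0("p", 1:4))
  emt <- setNames(c(1, 5, 6, 2), paste0("p", 1:4))
  g4 <- median_split_groups(list(ita = ita, emt = emt))
  manual <- paste0("ita_", ifelse(ita >= median(ita), "high", "low"), ".",
                   "emt_", ifelse(emt >= median(emt), "high", "low"))
  expect_equal(as.character(g4), manual)
  expect_error(median_split_groups(list(a = numeric(0))), "empty")
})

test_that("ratio_score divides aligned scores (difference behind a flag)", {
  num <- setNames(c(4, 6), c("a", "b"))
  den <- setNames(c(2, 3), c("a", "b"))
  expect_equal(unname(ratio_score(num, den)), c(2, 2))
  expect_equal(unname(ratio_score(num, num)), c(1, 1))
  expect_equal(unname(ratio_score(num, den, log_difference = TRUE)), c(2, 3))
  expect_error(ratio_score(num, setNames(c(0, 1), c("a", "b"))), "zero")
})

test_that("Schoenfeld diagnostics calibrate under PH and detect violations", {
  ph_p <- tv_p <- numeric(100)
  for (r in 1:100) {
    withr::with_seed(3000 + r, {
      n <- 120
      x <- rnorm(n)
      # proportional hazards world
      d_ph <- data.frame(sample_id = 1:n, os_time = rexp(n, exp(0.7 * x)),
                         os_event = 1, x = x)
      # effect reverses sign midway: strong PH violation
      t1 <- rexp(n, exp(1.5 * x))
      tv_time <- ifelse(t1 < 0.5, t1, 0.5 + rexp(n, exp(-1.5 * x)))
      d_tv <- data.frame(sample_id = 1:n, os_time = tv_time,
                         os_event = 1, x = x)
    })
    ph_p[r] <- ph_diagnostics(fit_cox(d_ph, "os", "x"))$p
    tv_p[r] <- ph_diagnostics(fit_cox(d_tv, "os", "x"))$p
  }
  expect_gte(mean(ph_p > 0.05), 0.9)
  expect_gte(mean(tv_p < 0.05), 0.8)

  # one scaled residual per event
  d <- toy_clinical(60, seed = 31)
  diag <- ph_diagnostics(fit_cox(d, "os", "x"))
  expect_equal(attr(diag, "n_residuals"), sum(d$os_event))
  expect_true(is.finite(diag$cor_with_time))
})
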