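test_that("logistic fit matches closed forms and an independent optimizer", {
  # 2x2 table: 20/30 responders vs 10/40 -> OR = (20*40)/(30*10)
  d <- data.frame(sample_id = 1:100,
                  response = c(rep(1, 20), rep(0, 30), rep(1, 10), rep(0, 40)),
                  arm = rep(c(1, 0), c(50, 50)))
  fit <- fit_logistic(d, "arm")
  expect_equal(exp(unname(fit$coef["arm"])), (20 * 40) / (30 * 10),
               tolerance = 1e-6)

  # ML solution equals a gradient-free maximizer of the coded likelihood
  for (s in 1:5) {
    withr::with_seed(500 + s, {
      n <- 30
      toy <- data.frame(sample_id = 1:n, x = rnorm(n), z = rnorm(n))
      toy$response <- rbinom(n, 1, plogis(0.3 * toy$x - 0.5 * toy$z))
    })
    if (length(unique(toy$response)) < 2) next
    ft <- tryCatch(fit_logistic(toy, c("x", "z")), error = function(e) NULL)
    if (is.null(ft)) next
    oracle <- logistic_oracle_beta(toy$response, cbind(1, toy$x, toy$z))
    expect_equal(unname(ft$coef), oracle, tolerance = 1e-5)
  }

  # complete separation is an error with a diagnostic, not a silent fit
  sep <- data.frame(sample_id = 1:20, response = rep(c(0, 1), each = 10),
                    x = c(rnorm(10, -5), rnorm(10, 5)))
  expect_error(fit_logistic(sep, "x"), "separation")
  expect_error(fit_logistic(transform(sep, response = 1), "x"), "classes")
})

test_that("scaled odds ratios share the HR scaling invariance", {
  withr::with_seed(40, {
    n <- 500
    d <- data.frame(sample_id = 1:n, x = rnorm(n), z = rnorm(n))
    d$response <- rbinom(n, 1, plogis(-1 + 0.8 * d$x))
  })
  fit <- fit_logistic(d, c("x", "z"))
  se <- scaled_effect(fit)

  # null term: CI contains 1
  zrow <- se[se$term == "z", ]
  expect_true(zrow$lower <= 1 && 1 <= zrow$upper)

  # covariate rescaling leaves the scaled OR unchanged
  d2 <- d
  d2$x <- d2$x / 4
  refit <- fit_logistic(d2, c("x", "z"))
  expect_equal(scaled_effect(refit)[1, "ratio"], se[1, "ratio"],
               tolerance = 1e-6)
})

test_that("the model ladder emits the full nested-test grid", {
  sim <- simulate_bulk_cohort(checkmate_config(seed = 2))
  lad <- model_ladder(sim$clinical)
  expect_equal(nrow(lad), 10)
  expect_true(all(c("p_pfs", "p_os", "p_response") %in% names(lad)))
  expect_true(all(lad$p_pfs > 0 & lad$p_pfs <= 1))
  expect_true(all(lad$p_os > 0 & lad$p_os <= 1))
  expect_true(all(lad$p_response > 0 & lad$p_response <= 1))

  # the interaction rows agree with a direct nested LRT
  cl <- sim$clinical
  full <- fit_logistic(cl, c("cd8_ihc", "emt_stroma", "cd8_ihc:emt_stroma"))
  nested <- fit_logistic(cl, c("cd8_ihc", "emt_stroma"))
  direct <- likelihood_ratio_test(nested, full)
  expect_equal(lad$p_response[lad$test == "CD8:EMT/Stroma_core interaction"],
               direct$p_value, tolerance = 1e-10)

  # a non-nested row is refused by name
  bad <- list(list(label = "bad row", model_1 = "cd8_ihc",
                   model_2 = "emt_stroma"))
  expect_error(model_ladder(sim$clinical, bad), "bad row")
})

test_that("subgroup response rates carry exact intervals and conserve counts", {
  sim <- simulate_bulk_cohort(checkmate_config(seed = 3))
  cl <- sim$clinical
  cd8 <- setNames(cl$cd8_ihc, cl$sample_id)
  core <- setNames(cl$emt_stroma, cl$sample_id)
  grp <- median_split_groups(list(cd8 = cd8, stroma = core))
  tab <- subgroup_response(cl, grp[cl$sample_id])
  expect_equal(sum(tab$n), sum(!is.na(cl$response)))
  expect_equal(sum(tab$responders), sum(cl$response, na.rm = TRUE))

  # interval equals a direct Clopper-Pearson call
  i <- which(tab$n > 0)[1]
  direct <- clopper_pearson(tab$responders[i], tab$n[i])
  expect_equal(tab$lower[i], direct$lower)
  expect_equal(tab$upper[i], direct$upper)

  # zero responders: rate 0 with lower bound 0
  d0 <- data.frame(sample_id = 1:12, response = 0)
  t0 <- subgroup_response(d0, factor(rep("g", 12)))
  expect_equal(t0$rate, 0)
  expect_equal(t0$lower, 0)

  # empty subgroups are reported, flagged undefined
  g2 <- factor(rep("a", 12), levels = c("a", "b"))
  t2 <- subgroup_response(d0, g2)
  expect_equal(t2$n[t2$group == "b"], 0)
  expect_false(t2$defined[t2$group == "b"])
})

test_that("CD8 spatial comparison tests densities and ratios by stroma group", {
  # clean separation in intratumoral density: 4 vs 4, minimal exact p
  rec <- data.frame(sample_id = 1:8,
                    intratumoral_density = c(1, 2, 3, 4, 10, 11, 12, 13),
                    peritumoral_density = c(5, 6, 7, 8, 5, 6, 7, 8),
                    stroma_score = c(9, 9, 9, 9, 1, 1, 1, 1))
  res <- cd8_spatial_compare(rec)
  expect_equal(res$intratumoral$p_value, enum_wilcox_p(c(1, 2, 3, 4),
                                                       c(10, 11, 12, 13)))
  expect_equal(res$intratumoral$p_value, 2 / choose(8, 4))
  expect_equal(levels(res$groups), c("high", "low"))

  # near-identical distributions: no signal
  rec2 <- rec
  rec2$intratumoral_density <- rep(c(1, 2, 3, 4), 2)
  rec2$peritumoral_density <- rep(c(4, 3, 2, 1), 2)
  res2 <- cd8_spatial_compare(rec2)
  expect_gte(res2$intratumoral$p_value, 0.9)
  expect_gte(res2$peritumoral$p_value, 0.9)

  # zero intratumoral density handled by the continuity offset
  rec3 <- rec
  rec3$intratumoral_density[1] <- 0
  expect_message(res3 <- cd8_spatial_compare(rec3), "offset")
  expect_true(all(is.finite(res3$ratios)))
  expect_equal(unname(res3$ratios[1]), (5 + 0.5) / 0.5)

  expect_error(cd8_spatial_compare(rec[rec$stroma_score == 9, ]),
               "each side")
})
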