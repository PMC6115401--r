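make_counts <- function(h, m) {
  dn <- list(sprintf("g%d", seq_len(nrow(h))),
             sprintf("s%d", seq_len(ncol(h))))
  dimnames(h) <- dn
  dimnames(m) <- dn
  species_counts(h, m)
}

test_that("species_counts validates shape and integer non-negativity", {
  h <- matrix(1:4, 2, 2)
  m <- matrix(0:3, 2, 2)
  sc <- make_counts(h, m)
  expect_equal(unname(sc$lib_human), c(3, 7))
  h3 <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_error(species_counts(sc$human, h3), "shape")
  expect_error(make_counts(h, m - 2), "non-negative")
  expect_error(make_counts(h + 0.5, m), "integers")
})

test_that("low-count filter keeps genes reaching the threshold in either species", {
  h <- rbind(c(0, 0), c(4, 4), c(5, 0), c(0, 0), c(2, 3), c(1, 6))
  m <- rbind(c(0, 0), c(4, 3), c(0, 0), c(9, 0), c(4, 4), c(0, 0))
  sc <- make_counts(h, m)
  filt <- filter_low_counts(sc, min_count = 5)
  # hand enumeration: g1 all zero (drop), g2 max 4 (drop), g3 human 5 (keep),
  # g4 mouse 9 (keep), g5 max 4 (drop), g6 human 6 (keep)
  expect_setequal(rownames(filt$human), c("g3", "g4", "g6"))
  # pre-filter library sizes preserved
  expect_equal(filt$lib_human, sc$lib_human)
  expect_equal(filt$lib_mouse, sc$lib_mouse)
})

test_that("mouse fraction per gene under both aggregations", {
  h <- rbind(c(30, 10), c(20, 0), c(0, 0))
  m <- rbind(c(10, 10), c(0, 0), c(0, 5))
  sc <- make_counts(h, m)

  med <- mouse_fraction(sc, "per_sample_median")
  # g1: median(10/40, 10/20) = median(0.25, 0.5); g2: all human -> 0;
  # g3: sample 1 undefined, sample 2 = 1
  expect_equal(unname(med), c(median(c(0.25, 0.5)), 0, 1))

  pooled <- mouse_fraction(sc, "pooled")
  expect_equal(unname(pooled), c(20 / 60, 0, 5 / 5))

  # zero-total gene is undefined, not zero
  h2 <- rbind(c(5, 5), c(0, 0))
  m2 <- rbind(c(5, 5), c(0, 0))
  sc2 <- make_counts(h2, m2)
  expect_true(is.na(mouse_fraction(sc2)[2]))
  # complement identity where defined
  expect_equal(unname(mouse_fraction(sc2)[1]), 0.5)
})

test_that("species RPM scales by species library and is depth-invariant", {
  h <- rbind(c(10L), c(30L), c(60L))
  m <- rbind(c(100L), c(0L), c(0L))
  sc <- make_counts(h, m)
  rpm <- species_rpm(sc)
  expect_equal(unname(rpm$human_rpm[, 1]), c(10, 30, 60) / 100 * 1e6)
  # one gene carrying the whole mouse library
  expect_equal(unname(rpm$mouse_rpm[1, 1]), 1e6)

  sc10 <- make_counts(h * 10L, m * 10L)
  expect_equal(species_rpm(sc10)$human_rpm, species_rpm(sc)$human_rpm)

  expect_error(species_rpm(make_counts(h, m * 0L)), "zero species library")
})

test_that("RPM log2 fold change follows the pseudo-read formula", {
  # equal within-species composition: FC 0 regardless of library imbalance
  # (counts large enough that the pseudo reads are negligible)
  h <- rbind(c(100000L), c(300000L))
  m <- rbind(c(10000L), c(30000L))
  expect_equal(as.numeric(rpm_log2fc(make_counts(h, m))), c(0, 0),
               tolerance = 1e-3)

  # fourfold mouse RPM with large counts: log2 FC near 2
  h2 <- rbind(c(1000L), c(1000L))
  m2 <- rbind(c(4000L), c(1000L))
  fc <- rpm_log2fc(make_counts(h2, m2))
  # direct evaluation of the documented formula
  lib_h <- 2000; lib_m <- 5000
  f <- function(cm, ch) log2((cm / lib_m * 1e6 + 0.5 / lib_m * 1e6) /
                               (ch / lib_h * 1e6 + 0.5 / lib_h * 1e6))
  expect_equal(as.numeric(fc), c(f(4000, 1000), f(1000, 1000)))

  # zero human count stays finite and matches the formula
  h3 <- rbind(c(0L), c(500L))
  m3 <- rbind(c(50L), c(450L))
  fc3 <- rpm_log2fc(make_counts(h3, m3))
  expect_true(all(is.finite(fc3)))
  lib_h3 <- 500; lib_m3 <- 500
  expect_equal(unname(fc3[1]),
               log2((50 / lib_m3 * 1e6 + 0.5 / lib_m3 * 1e6) /
                      (0 + 0.5 / lib_h3 * 1e6)))

  # invariance to a common per-sample depth factor
  h4 <- matrix(as.integer(c(40, 80, 120, 20, 40, 60)), 3, 2)
  m4 <- matrix(as.integer(c(8, 16, 24, 4, 8, 12)), 3, 2)
  sc4 <- make_counts(h4, m4)
  sc4s <- make_counts(sweep(h4, 2, c(3L, 7L), "*"),
                      sweep(m4, 2, c(3L, 7L), "*"))
  expect_equal(attr(rpm_log2fc(sc4), "per_sample")[, 1],
               attr(rpm_log2fc(sc4s), "per_sample")[, 1],
               tolerance = 0.05)
})

test_that("read-based purity is the human read share", {
  h <- matrix(c(940000L, 0L), 2, 1)
  m <- matrix(c(0L, 60000L), 2, 1)
  expect_equal(unname(purity_from_reads(make_counts(h, m))), 0.94)
  expect_equal(unname(purity_from_reads(make_counts(h, h * 0L))), 1)
  expect_error(purity_from_reads(make_counts(h * 0L, m * 0L)), "zero total")
})

test_that("gene-set contrasts compose with the rank-sum test", {
  vals <- setNames(c(10, 11, 12, 13, 1, 2, 3, 4, 7), paste0("g", 1:9))
  a <- paste0("g", 1:4)
  b <- paste0("g", 5:8)
  res <- compare_gene_sets(vals, a, b)
  expect_equal(res$p_value, wilcoxon_rank_sum(vals[a], vals[b])$p_value)
  expect_equal(res$p_value, 2 / choose(8, 4))  # extreme separation
  expect_equal(res$median_a, median(vals[a]))

  # overlap removal changes the contrast exactly as direct calls do
  a2 <- c(a, "g9")
  b2 <- c(b, "g9")
  with_ov <- compare_gene_sets(vals, a2, b2, remove_overlap = FALSE)
  no_ov <- compare_gene_sets(vals, a2, b2, remove_overlap = TRUE)
  expect_equal(with_ov$p_value,
               wilcoxon_rank_sum(vals[a2], vals[b2])$p_value)
  expect_equal(no_ov$p_value, wilcoxon_rank_sum(vals[a], vals[b])$p_value)

  # identical distributions: p near 1
  vv <- setNames(rep(c(1, 2, 3), 2), paste0("h", 1:6))
  same <- compare_gene_sets(vv, paste0("h", 1:3), paste0("h", 4:6))
  expect_gte(same$p_value, 0.9)

  expect_error(compare_gene_sets(vals, "g9", "g9"), "no values")
})
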