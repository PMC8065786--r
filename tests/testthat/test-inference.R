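test_that("permutation test matches exhaustive enumeration at 3+3", {
  set.seed(21)
  z_a <- matrix(rnorm(3 * 4), 3)
  z_b <- matrix(rnorm(3 * 4, mean = c(1.5, 0, 0, 0)[col(matrix(0, 3, 4))]), 3)
  res <- permutation_edge_test(z_a, z_b, seed = 1)
  expect_identical(attr(res, "method"), "exhaustive")
  for (e in 1:4) {
    expect_equal(res$p[e], oracle_exhaustive_p(z_a[, e], z_b[, e]))
    expect_equal(res$t[e], oracle_pooled_t(z_a[, e], z_b[, e]),
                 tolerance = 1e-12)
  }
  expect_true(all(res$p > 0))
})

test_that("identical groups give t = 0 and p = 1 everywhere", {
  set.seed(2)
  x <- matrix(rnorm(12), 3)
  # duplicated rows: every permutation statistic ties the observed zero
  res <- permutation_edge_test(x, x, seed = 1)
  expect_equal(res$t, rep(0, 4), tolerance = 1e-12)
  expect_true(all(res$p == 1))

  # an edge constant in both groups is degenerate: warned, p = 1
  z_a <- cbind(rnorm(4), 5)
  z_b <- cbind(rnorm(4, 2), 5)
  expect_warning(res2 <- permutation_edge_test(z_a, z_b, seed = 1),
                 "zero variance")
  expect_identical(res2$p[2], 1)
  expect_identical(res2$t[2], 0)
})

test_that("Monte-Carlo and exhaustive modes agree and are seed-stable", {
  set.seed(5)
  z_a <- matrix(rnorm(5 * 3), 5)
  z_b <- matrix(rnorm(6 * 3, 1), 6)
  ex <- permutation_edge_test(z_a, z_b)
  B <- 4000L
  mc <- permutation_edge_test(z_a, z_b, replicates = B, seed = 9,
                              exhaustive_limit = 1)
  expect_identical(attr(mc, "method"), "monte_carlo")
  expect_lt(max(abs(mc$p - ex$p)), 2 / sqrt(B))
  mc2 <- permutation_edge_test(z_a, z_b, replicates = B, seed = 9,
                               exhaustive_limit = 1)
  expect_identical(mc$p, mc2$p)
})

test_that("null p-values are approximately uniform", {
  set.seed(31)
  z_a <- matrix(rnorm(8 * 400), 8)
  z_b <- matrix(rnorm(8 * 400), 8)
  res <- permutation_edge_test(z_a, z_b, replicates = 400, seed = 2,
                               exhaustive_limit = 1)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("significance filtering reproduces the direction-block layout", {
  tab2 <- read_table2_fixture()
  sig <- filter_significant(tab2, alpha = 0.01)
  expect_identical(nrow(sig), 46L)
  counts <- attr(sig, "direction_counts")
  expect_identical(unname(counts["Mathematicians > Non-mathematicians"]), 22L)
  expect_identical(unname(counts["Non-Mathematicians > Mathematicians"]), 24L)
  # ascending p within each block
  for (d in unique(sig$direction)) {
    expect_false(is.unsorted(sig$p[sig$direction == d]))
  }
  expect_identical(nrow(filter_significant(tab2, alpha = 0)), 0L)
  expect_identical(nrow(filter_significant(tab2, alpha = 1)), 46L)
  g <- glance(sig)
  expect_identical(g$n_edges, 46L)
})

test_that("edge-score correlation matches the closed-form oracle", {
  z <- c(0.1, 0.4, -0.2, 0.3, 0.8, -0.5, 0.05, 0.6)
  set.seed(8)
  s <- 3 * z + rnorm(8, 0, 0.5)
  res <- edge_score_correlation(z, s)
  ora <- oracle_pearson(z, s)
  expect_equal(res$r, ora$r, tolerance = 1e-10)
  expect_equal(res$p, ora$p, tolerance = 1e-10)
  expect_identical(res$n, 8L)

  lin <- edge_score_correlation(z, 2 + 5 * z)
  expect_equal(lin$r, 1)
  expect_lt(lin$p, 1e-12)
  expect_equal(edge_score_correlation(z, -z)$r, -1)
  expect_error(edge_score_correlation(z, rep(1, 8)), "zero variance")
  expect_error(edge_score_correlation(z[1:2], s[1:2]), "3 participants")
})

test_that("summary t-tests reproduce the cohort comparison table", {
  same <- summary_two_sample_t(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # mathematics test: overwhelming group difference
  math <- summary_two_sample_t(70.95, 7.13, 21, 40.71, 7.69, 23)
  expect_lt(math$p, 0.001)

  # age: computed from the printed summaries
  age <- summary_two_sample_t(33.42, 5.62, 21, 27.23, 8.21, 23)
  expect_equal(age$t, 2.89, tolerance = 0.01)
  expect_equal(age$p, 0.006, tolerance = 0.15)

  # welch variant has smaller df than pooled
  w <- summary_two_sample_t(33.42, 5.62, 21, 27.23, 8.21, 23, variant = "welch")
  expect_lt(w$df, age$df)

  tab1 <- cohort_table(read_table1_fixture())
  expect_identical(nrow(tab1), 8L)
  gender_p <- tab1$p[grepl("Gender", tab1$measure)]
  expect_equal(round(gender_p, 3), 0.276)
})

test_that("2x2 chi-square matches the hand-computed statistic", {
  res <- chi_square_2x2(16, 5, 14, 9)
  ora <- oracle_chisq_2x2(16, 5, 14, 9)
  expect_equal(res$statistic, ora$statistic, tolerance = 1e-10)
  expect_equal(res$p, ora$p, tolerance = 1e-10)
  expect_equal(round(res$p, 3), 0.276)
  expect_equal(res$statistic, 1.186, tolerance = 0.005)

  prop <- chi_square_2x2(10, 10, 20, 20)
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)

  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
})
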