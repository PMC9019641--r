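test_that("contingency_table validates its invariants", {
  expect_error(contingency_table(matrix(1:3, 1)), "at least 2 rows")
  expect_error(contingency_table(rbind(c(1, -1), c(2, 3))), "non-negative")
  expect_error(contingency_table(rbind(c(0.5, 1), c(2, 3))), "non-negative")
  expect_error(contingency_table(matrix(0L, 2, 2)), "grand total")
  tab <- contingency_table(rbind(c(1, 2), c(3, 4)),
                           row_labels = c("a", "b"), col_labels = c("x", "y"))
  expect_identical(rownames(tab), c("a", "b"))
})

test_that("chi_square reproduces the printed baseline statistics", {
  # frozen from the study's baseline table; all verified against
  # stats::chisq.test during development
  cases <- list(
    list(m = rbind(c(86, 95), c(47, 22)), yates = TRUE,  stat = 7.709, df = 1),
    list(m = rbind(c(114, 92), c(19, 25)), yates = TRUE, stat = 1.692, df = 1),
    list(m = rbind(c(118, 102), c(15, 15)), yates = TRUE, stat = 0.032, df = 1),
    list(m = rbind(c(70, 51), c(63, 66)), yates = TRUE,  stat = 1.692, df = 1),
    list(m = rbind(c(48, 56), c(34, 25), c(20, 16), c(31, 20)),
         yates = FALSE, stat = 3.797, df = 3),
    list(m = rbind(c(18, 16), c(70, 58), c(45, 43)),
         yates = FALSE, stat = 0.265, df = 2),
    list(m = rbind(c(126, 112), c(7, 5)), yates = TRUE, stat = 0.005, df = 1)
  )
  for (cs in cases) {
    res <- chi_square(cs$m, yates = cs$yates)
    expect_equal(round(res$statistic, 3), cs$stat)
    expect_identical(res$df, as.integer(cs$df))
  }
  res <- chi_square(rbind(c(10, 10), c(10, 10)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("chi_square agrees with the closed form and base R on random tables", {
  set.seed(101)
  for (i in 1:25) {
    m <- random_table(2, 2)
    expect_equal(chi_square(m)$statistic, chisq_2x2_closed_form(m),
                 tolerance = 1e-12)
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    m2 <- random_table(r, c)
    ours <- chi_square(m2)
    ref <- suppressWarnings(chisq.test(m2, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_identical(ours$df, as.integer((r - 1) * (c - 1)))
  }
})

test_that("chi_square rejects misuse", {
  expect_error(chi_square(random_table(2, 3), yates = TRUE), "2x2")
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "grand total|expected")
})

test_that("fisher_exact matches frozen exact values", {
  expect_equal(round(fisher_exact(rbind(c(77, 52, 4), c(90, 22, 5)))$p_value, 3),
               0.002)
  expect_equal(fisher_exact(rbind(c(5, 5), c(5, 5)))$p_value, 1)
  # hand enumeration: 2 * (P(a=0) + P(a=1)) with margins 10/10
  expect_equal(fisher_exact(rbind(c(1, 9), c(9, 1)))$p_value, 0.001093334,
               tolerance = 1e-6)
})

test_that("fisher_exact matches the hypergeometric oracle on 2x2 tables", {
  set.seed(202)
  for (i in 1:30) {
    m <- random_table(2, 2, lambda = sample(c(2, 6, 15), 1))
    expect_equal(fisher_exact(m)$p_value, fisher_2x2_hypergeom(m),
                 tolerance = 1e-10)
  }
})

test_that("fisher_exact matches base R's network algorithm on r x c tables", {
  set.seed(303)
  for (i in 1:10) {
    m <- random_table(sample(2:3, 1), sample(2:3, 1), lambda = 4)
    expect_equal(fisher_exact(m)$p_value, fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("fisher_exact p is invariant under row and column permutation", {
  set.seed(404)
  for (i in 1:8) {
    m <- random_table(3, 3, lambda = 3)
    p0 <- fisher_exact(m)$p_value
    expect_equal(fisher_exact(m[sample(3), sample(3)])$p_value, p0,
                 tolerance = 1e-12)
    expect_equal(fisher_exact(t(m))$p_value, p0, tolerance = 1e-12)
  }
})

test_that("fisher_exact guards its enumeration bound", {
  big <- matrix(200L, 6, 6)
  expect_error(fisher_exact(big, max_tables = 1e4), "chi_square")
})

test_that("welch_t reproduces the printed age comparison", {
  res <- welch_t(summary_stats(32.37, 5.62, 133),
                 summary_stats(28.41, 7.07, 117))
  # closed form: 3.96 / sqrt(5.62^2/133 + 7.07^2/117) = 4.8572
  expect_equal(res$statistic, 4.857166, tolerance = 1e-6)
  expect_lt(res$p_value, 0.001)
  # Welch-Satterthwaite df, not the pooled 248
  expect_equal(res$df, 220.838, tolerance = 1e-3)
})

test_that("welch_t closed forms and antisymmetry", {
  expect_equal(welch_t(summary_stats(1, 1, 100),
                       summary_stats(0, 1, 100))$statistic,
               1 / sqrt(2 / 100), tolerance = 1e-12)
  a <- summary_stats(3.2, 1.1, 40); b <- summary_stats(2.7, 2.3, 55)
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
  same <- welch_t(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(welch_t(summary_stats(1, 0, 10), summary_stats(2, 0, 10)),
               "zero")
  expect_error(summary_stats(1, 1, 1), "at least 2")
})

test_that("median_iqr honours both quantile conventions", {
  expect_equal(median_iqr(c(1, 2, 3, 4)),
               c(median = 2.5, q1 = 1.75, q3 = 3.25))
  expect_equal(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  expect_equal(median_iqr(c(1, 2, 3, 4), type = "nearest"),
               c(median = 2, q1 = 1, q3 = 3))
  # majority value is the median under either convention
  v <- c(rep(0.961, 130), runif(120, -0.2, 0.9))
  expect_equal(unname(median_iqr(v)["median"]), 0.961)
  expect_equal(unname(median_iqr(v, type = "nearest")["median"]), 0.961)
  expect_error(median_iqr(numeric(0)), "empty")
  expect_error(median_iqr(c(1, NA)), "NA")
})
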