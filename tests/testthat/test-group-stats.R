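test_that("exact Mann-Whitney p-values match full enumeration", {
  # oracle: the exact null CDF of U (base R's pwilcox)
  withr::local_seed(17)
  for (n1 in 1:5) {
    for (n2 in 1:5) {
      x <- rnorm(n1)
      y <- rnorm(n2)
      res <- exact_mann_whitney(x, y)
      u <- sum(outer(x, y, ">"))
      p_ref <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                              1 - stats::pwilcox(u - 1, n1, n2)))
      expect_equal(res$u, u)
      expect_equal(res$p_value, p_ref)
      # and against wilcox.test's exact two-sided p (same convention)
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE))
      expect_equal(res$p_value, wt$p.value)
    }
  }
})

test_that("complete separation attains the minimum exact two-tailed p", {
  # the three group-size configurations of the cohort sensitivity analysis
  expect_equal(exact_mann_whitney(1:5, 6:8)$p_value, 2 / 56)
  expect_equal(exact_mann_whitney(1:4, 5:7)$p_value, 2 / 35)
  expect_equal(exact_mann_whitney(1:3, 4:6)$p_value, 2 / 20)
  # printed two-decimal forms
  expect_equal(round(exact_mann_whitney(1:5, 6:8)$p_value, 3), 0.036)
  expect_equal(round(exact_mann_whitney(1:4, 5:7)$p_value, 3), 0.057)
  expect_equal(exact_mann_whitney(1:3, 4:6)$p_value, 0.1)
})

test_that("the test is rank-based and symmetric", {
  x <- c(0.3, 1.2, 5.4, 2.2)
  y <- c(0.9, 7.7, 3.1)
  p0 <- exact_mann_whitney(x, y)$p_value
  # invariant under any strictly monotone transform of the pooled data
  expect_equal(exact_mann_whitney(exp(x), exp(y))$p_value, p0)
  expect_equal(exact_mann_whitney(rank(c(x, y))[1:4],
                                  rank(c(x, y))[5:7])$p_value, p0)
  # invariant under swapping the groups
  expect_equal(exact_mann_whitney(y, x)$p_value, p0)
  expect_error(exact_mann_whitney(c(1, 2), c(2, 3)), "ties")
})

test_that("Spearman rho matches direct rank correlation and hits the poles", {
  expect_equal(spearman_rank(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  expect_equal(spearman_rank(1:6, -(1:6))$rho, -1)
  withr::local_seed(8)
  x <- rnorm(11)
  y <- rnorm(11)
  brute <- 1 - 6 * sum((rank(x) - rank(y))^2) / (11 * (11^2 - 1))
  expect_equal(spearman_rank(x, y)$rho, brute, tolerance = 1e-12)
  expect_error(spearman_rank(1:4, 1:5), "equal length")
})

test_that("Spearman p-values: exact permutation for small n, t otherwise", {
  withr::local_seed(31)
  # exact route against cor.test's exact computation
  for (n in c(5, 6, 7)) {
    x <- rnorm(n)
    y <- rnorm(n)
    res <- spearman_rank(x, y)
    expect_equal(res$method, "exact permutation")
    ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
  # perfectly monotone: the doubled single-permutation tail
  expect_equal(spearman_rank(1:5, c(10, 20, 21, 34, 35))$p_value,
               2 / factorial(5))
  # large n: t approximation
  x <- rnorm(20)
  y <- x + rnorm(20, 0, 2)
  res <- spearman_rank(x, y)
  expect_equal(res$method, "t approximation")
  rho <- res$rho
  tref <- rho * sqrt(18 / (1 - rho^2))
  expect_equal(res$p_value, 2 * stats::pt(-abs(tref), 18))
  expect_warning(spearman_rank(c(1, 1, 2, 3), 1:4), "ties")
})

test_that("cohort comparison mirrors the leave-one-out sensitivity analysis", {
  # headline configuration: 5 cases above 3 controls in every metric
  cohort <- tibble::tibble(
    subject_id = sprintf("S%02d", 1:8),
    group = rep(c("case", "control"), c(5, 3)),
    ki = c(9.1, 5.2, 4.8, 4.4, 4.1, 3.0, 2.6, 2.2) # S01 is the extreme subject
  )
  res <- cohort_compare(cohort, "ki")
  expect_equal(res$p_value, 2 / 56)
  expect_true(res$significant)
  # (i) drop the extreme subject: 4-vs-3 complete separation, p rises to 0.057
  res_drop <- cohort_compare(cohort[-1, ], "ki")
  expect_equal(res_drop$p_value, 2 / 35)
  expect_equal(round(res_drop$p_value, 3), 0.057)
  expect_false(res_drop$significant)
  # (ii) replace it with the within-group minimum (jittered to stay
  # tie-free): separation intact, p unchanged at 0.036
  cohort2 <- cohort
  cohort2$ki[1] <- min(cohort$ki[1:5]) - 0.01
  res_sub <- cohort_compare(cohort2, "ki")
  expect_equal(res_sub$p_value, 2 / 56)
  # interleaved groups sit deep in the null
  cohort3 <- tibble::tibble(
    group = rep(c("a", "b"), 4),
    m = c(1, 2, 3, 4, 5, 6, 7, 8)
  )
  expect_gt(cohort_compare(cohort3, "m")$p_value, 0.5)
  # Bonferroni column is computed but does not drive the flag
  multi <- dplyr::mutate(cohort, tbr = ki + 0.001)
  res_m <- cohort_compare(multi, c("ki", "tbr"))
  expect_equal(res_m$p_bonferroni, pmin(1, res_m$p_value * 2))
  expect_true(all(res_m$significant == (res_m$p_value < 0.05)))
  expect_error(cohort_compare(cohort, "absent"), "not found")
})
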