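test_that("Welch's t-test matches hand-computed formulas", {
  res <- welch_t_test(1:5, c(2, 4, 6, 8, 10))
  # mean diff -3, se = sqrt(2.5/5 + 10/5), df by Welch-Satterthwaite
  expect_equal(res$statistic, -3 / sqrt(0.5 + 2), tolerance = 1e-12)
  expect_equal(res$statistic, -1.8974, tolerance = 1e-4)
  expect_equal(res$df, 6.25 / (0.25 / 4 + 4 / 4), tolerance = 1e-12)
  expect_equal(res$df, 5.882, tolerance = 1e-3)

  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  expect_error(welch_t_test(c(1, 1), c(1, 1)), "zero variance")
  expect_error(welch_t_test(1, 1:3), "at least 2")
})

test_that("Welch df collapses to the pooled df for equal groups", {
  x <- c(1, 4, 2, 8); y <- x + 100   # equal n, exactly equal variance
  res <- welch_t_test(x, y)
  expect_equal(res$df, length(x) + length(y) - 2, tolerance = 1e-9)
})

test_that("Welch's t-test equals the reference implementation", {
  set.seed(101)
  for (i in 1:200) {
    x <- rnorm(sample(3:15, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:15, 1), mean = runif(1, -1, 1))
    res <- welch_t_test(x, y)
    ref <- t.test(x, y)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(res$df, unname(ref$parameter), tolerance = 1e-6)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("Levene's test behaves on symmetric and degenerate groups", {
  g <- list(c(1, 2, 3, 4), c(11, 12, 13, 14))   # identical spread patterns
  res <- levene_test(g)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_warning(res0 <- levene_test(list(c(1, 1), c(2, 2))), "undefined")
  expect_true(is.na(res0$p_value))
  expect_error(levene_test(list(1:3)), "at least 2 groups")
})

test_that("Levene's test (both centers) equals the reference implementation", {
  skip_if_not_installed("car")
  set.seed(102)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(4:12, 1), sd = runif(1, 0.5, 4)))
    y <- unlist(groups)
    f <- factor(rep(seq_len(k), lengths(groups)))
    for (ctr in c("mean", "median")) {
      res <- levene_test(groups, center = ctr)
      ref <- car::leveneTest(y, f, center = if (ctr == "mean") mean else median)
      expect_equal(res$statistic, ref$`F value`[1], tolerance = 1e-6)
      expect_equal(res$p_value, ref$`Pr(>F)`[1], tolerance = 1e-6)
    }
  }
})

test_that("Mann-Whitney exact p matches the derived enumeration example", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(as.numeric(res$statistic), 0)
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)   # 2/20 arrangements
  expect_identical(res$flags, "exact")
  # identical multisets are maximally non-significant
  resid <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gte(resid$p_value, 0.99)
  # the 6-vs-5 early/late design takes the exact path (30 <= 400, no ties)
  res65 <- mann_whitney(rnorm(6), rnorm(5))
  expect_identical(res65$flags, "exact")
})

test_that("Mann-Whitney agrees with the reference implementation", {
  set.seed(103)
  for (i in 1:200) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    res <- mann_whitney(x, y)
    ref <- suppressWarnings(wilcox.test(x, y))
    expect_equal(as.numeric(res$statistic), unname(ref$statistic),
                 tolerance = 1e-9)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
  }
  # tied data forces the corrected normal approximation, as in the reference
  for (i in 1:50) {
    x <- sample(1:6, 10, replace = TRUE); y <- sample(1:6, 9, replace = TRUE)
    res <- mann_whitney(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
    expect_identical(res$flags, "normal_approx")
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
  }
  expect_error(mann_whitney(c(1, 1, 2), c(1, 3), exact = TRUE), "ties")
})

test_that("linear regression recovers exact and textbook fits", {
  x <- 1:6
  res <- linear_regression(x, 2 * x)
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_equal(res$r_squared, 1)
  expect_lt(res$p_value, 1e-12)

  # brute-force normal equations on the textbook triple
  xs <- c(1, 2, 3); ys <- c(1, 3, 2)
  res3 <- linear_regression(xs, ys)
  X <- cbind(1, xs)
  beta <- solve(t(X) %*% X, t(X) %*% ys)
  expect_equal(res3$intercept, beta[1], tolerance = 1e-12)
  expect_equal(res3$slope, beta[2], tolerance = 1e-12)
  expect_error(linear_regression(c(1, 1, 1), 1:3), "constant")
  expect_error(linear_regression(1:2, 1:2), "at least 3")
})

test_that("linear regression equals lm and R2 survives affine x-rescaling", {
  set.seed(104)
  for (i in 1:100) {
    x <- rnorm(sample(4:20, 1)); y <- 0.5 * x + rnorm(length(x))
    res <- linear_regression(x, y)
    ref <- summary(lm(y ~ x))
    expect_equal(res$slope, ref$coefficients[2, 1], tolerance = 1e-6)
    expect_equal(res$r_squared, ref$r.squared, tolerance = 1e-6)
    expect_equal(res$p_value, ref$coefficients[2, 4], tolerance = 1e-6)
    scaled <- linear_regression(3 * x - 7, y)
    expect_equal(scaled$r_squared, res$r_squared, tolerance = 1e-9)
  }
})

test_that("Pearson correlation matrix matches the covariance formula", {
  set.seed(105)
  df <- data.frame(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  R <- pearson_correlation_matrix(df)
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_equal(R, t(R))
  expect_equal(R["a", "b"], cor(df$a, df$b), tolerance = 1e-9)
  expect_equal(pearson_correlation_matrix(data.frame(x = 1:5, y = -(1:5)))["x", "y"],
               -1, tolerance = 1e-12)
  expect_warning(Rc <- pearson_correlation_matrix(
    data.frame(x = 1:5, z = rep(2, 5))), "constant")
  expect_true(is.na(Rc["x", "z"]))
})

test_that("regression grid recovers planted effects and rejects misalignment", {
  env <- simulate_environment(11, 6, seed = 106)
  set.seed(107)
  planted <- data.frame(gene = "g1", metric = "abundance",
                        t_index = env$t_index,
                        value = 0.05 * env$cl_mgL + rnorm(11, 0, 0.02))
  grid <- env_regression_grid(planted, env)
  cell <- grid[grid$covariate == "cl_mgL", ]
  expect_true(cell$significant_05)
  expect_identical(nrow(grid), 4L)
  expect_true(all(c("p_adj", "marginal_10") %in% names(grid)))

  empty <- env_regression_grid(planted[0, ], env)
  expect_identical(nrow(empty), 0L)
  bad <- planted; bad$t_index[1] <- 99
  expect_error(env_regression_grid(bad, env), "misaligned")
})

test_that("family variability comparison flags volatile vs stable families", {
  A_stable <- simulate_abundance_series(regime_params("resistant", 20, 11, 0.05, seed = 108))
  A_volatile <- simulate_abundance_series(regime_params("resilient", 20, 11, 1.5, seed = 109))
  res <- family_variability_test(list(a = A_stable, b = A_volatile))
  expect_lt(res$p_value, 0.05)
})
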