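test_that("richness counts positive entries", {
  expect_identical(richness(c(0.2, 0, 0.8)), 2L)
  expect_identical(richness(c(0, 0, 0)), 0L)
  expect_identical(richness(rep(1 / 7, 7)), 7L)
  expect_error(richness(c(-1, 1)), ">= 0")
})

test_that("inverse Simpson matches closed forms", {
  expect_equal(inverse_simpson(rep(0.25, 4)), 4)
  expect_equal(inverse_simpson(1), 1)
  expect_equal(inverse_simpson(c(0.5, 0.3, 0.2)), 1 / 0.38, tolerance = 1e-9)
  empty <- inverse_simpson(c(0, 0))
  expect_identical(as.numeric(empty), 0)
  expect_true(attr(empty, "empty"))
  expect_error(inverse_simpson(c(0.5, 0.3)), "sums to")
})

test_that("inverse Simpson agrees with vegan and respects richness bound", {
  skip_if_not_installed("vegan")
  set.seed(91)
  for (i in 1:20) {
    p <- rgamma(sample(2:12, 1), 1); p <- p / sum(p)
    expect_equal(inverse_simpson(p),
                 unname(vegan::diversity(p, index = "invsimpson")),
                 tolerance = 1e-9)
    expect_gte(inverse_simpson(p), 1)
    expect_lte(inverse_simpson(p), richness(p) + 1e-12)
  }
})

test_that("cumulative profiles pool RPKM and are monotone in richness", {
  mat <- matrix(0, 3, 4, dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
  mat[1, ] <- c(5, 5, 5, 5)
  mat[2, ] <- c(1, 0, 0, 0)
  mat[3, ] <- c(0, 0, 2, 0)   # phylotype appearing at t = 3
  cp <- cumulative_profiles(mat)
  expect_identical(cp$profile$cum_richness, c(2L, 2L, 3L, 3L))
  expect_true(all(diff(cp$profile$cum_richness) >= 0))
  expect_identical(cp$profile$delta_richness[1], 0L)
  expect_identical(cp$profile$delta_inv_simpson[1], 0)
  expect_equal(unname(colSums(cp$cumulative_rel)), rep(1, 4))

  # identical columns: all cumulative deltas stay zero
  same <- matrix(c(3, 1), 2, 5, dimnames = list(c("P1", "P2"), paste0("S", 1:5)))
  cps <- cumulative_profiles(same)
  expect_equal(cps$profile$delta_richness, rep(0L, 5))
  expect_equal(cps$profile$delta_inv_simpson, rep(0, 5), tolerance = 1e-12)

  # a rare phylotype adds richness but barely moves inverse Simpson
  rare <- matrix(c(1, 0, 1, 1e-4), 2, 2,
                 dimnames = list(c("P1", "P2"), c("S1", "S2")))
  cpr <- cumulative_profiles(rare)
  expect_identical(cpr$profile$cum_richness, c(1L, 2L))
  expect_lt(abs(cpr$profile$cum_inv_simpson[2] - cpr$profile$cum_inv_simpson[1]),
            0.01)
})

test_that("mean abundance variance matches hand computations", {
  const <- matrix(0.5, 2, 6)
  expect_identical(mean_abundance_variance(const), 0)
  swap <- matrix(c(1, 0, 0, 1), 2, 2)   # two phylotypes swapping over 2 times
  expect_equal(mean_abundance_variance(swap), 0.5)
  expect_error(mean_abundance_variance(matrix(1, 2, 1)), "2 timepoints")
  # appending an all-zero phylotype row lowers the mean (documented convention)
  expect_lt(mean_abundance_variance(rbind(swap, 0)),
            mean_abundance_variance(swap))
  # row order is irrelevant
  set.seed(92)
  m <- matrix(rgamma(40, 1), 8, 5)
  expect_equal(mean_abundance_variance(m), mean_abundance_variance(m[8:1, ]))
})

test_that("Bray-Curtis matches closed forms and vegan", {
  expect_identical(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(1, 0, 3), c(0, 2, 1)), 5 / 7, tolerance = 1e-9)
  expect_warning(res <- bray_curtis(c(0, 0), c(0, 0)), "undefined")
  expect_true(is.na(res))
  skip_if_not_installed("vegan")
  set.seed(93)
  for (i in 1:20) {
    u <- rgamma(6, 1); v <- rgamma(6, 1)
    expect_equal(bray_curtis(u, v),
                 as.numeric(vegan::vegdist(rbind(u, v), method = "bray")),
                 tolerance = 1e-9)
    expect_identical(bray_curtis(u, v), bray_curtis(v, u))
  }
})

test_that("distance decay enumerates all pairs and fits a slope", {
  same <- matrix(c(1, 2), 2, 5)
  dd <- distance_decay(same)
  expect_identical(nrow(dd$pairs), 10L)           # n(n-1)/2
  expect_true(all(dd$pairs$dissimilarity == 0))
  expect_identical(dd$fit$slope, 0)

  # drifting community: dissimilarity grows with lag
  A <- simulate_abundance_series(regime_params("resilient", 10, 11, 0.8, seed = 94))
  dd2 <- distance_decay(A)
  expect_identical(nrow(dd2$pairs), 55L)
  expect_gt(dd2$fit$slope, 0)

  # calendar dates change the lag units
  dts <- as.Date("2014-04-30") + 21 * (0:10)
  dd3 <- distance_decay(A, dates = dts)
  expect_equal(max(dd3$pairs$lag), 210)
})

test_that("turnover summary has one row per family with planted ordering", {
  A_stable <- simulate_abundance_series(regime_params("resistant", 6, 11, 0.05, seed = 95))
  A_volatile <- simulate_abundance_series(regime_params("resilient", 6, 11, 1.2, seed = 95))
  ts <- turnover_summary(list(stable = A_stable, volatile = A_volatile))
  expect_identical(ts$gene_family, c("stable", "volatile"))
  expect_identical(ts$phylotype_richness, c(6L, 6L))
  expect_lt(ts$mean_abundance_variance[1], ts$mean_abundance_variance[2])
})
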