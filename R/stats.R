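new_test_result <- function(statistic, df, p_value, method, n, flags = NULL) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method, n = n, flags = flags),
            class = "gd_test")
}

#' @export
print.gd_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.6g (n = %s)\n",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value, paste(x$n, collapse = ", ")))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test: `t = (mean(x) - mean(y)) / sqrt(sx2/n1 + sy2/n2)`
#' with Welch-Satterthwaite degrees of freedom and a two-sided p-value from
#' the t distribution.
#'
#' @param x,y numeric vectors with at least 2 values each.
#' @return a `gd_test` result (`statistic`, fractional `df`, `p_value`).
#' @export
welch_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop_param("each group needs at least 2 values")
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) stop_param("degenerate input: both groups have zero variance")
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  new_test_result(tstat, df, p, "Welch's t-test", c(n1, n2))
}

#' Levene's test for homogeneity of variance
#'
#' One-way F-test on absolute deviations from the group center: classic
#' Levene uses the group mean (the default); `center = "median"` gives the
#' Brown-Forsythe variant.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @param center `"mean"` (default) or `"median"`.
#' @return a `gd_test` result with `df = c(k - 1, N - k)`. When every
#'   deviation is zero in every group the statistic is undefined: `NA` values
#'   with flag `"degenerate"`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.list(groups) || length(groups) < 2L)
    stop_param("`groups` must be a list of at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop_param("each group needs at least 2 values")
  cf <- if (center == "mean") mean else median
  z <- lapply(groups, function(g) abs(g - cf(g)))
  k <- length(z); ni <- vapply(z, length, 0L); N <- sum(ni)
  zi <- vapply(z, mean, 0); zbar <- sum(ni * zi) / N
  ss_between <- sum(ni * (zi - zbar)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zi[i])^2), 0))
  if (ss_within == 0 && ss_between == 0) {
    warning("all deviations are zero: Levene statistic undefined")
    return(new_test_result(NA_real_, c(k - 1, N - k), NA_real_,
                           "Levene's test", ni, flags = "degenerate"))
  }
  W <- (ss_between / (k - 1)) / (ss_within / (N - k))
  p <- pf(W, k - 1, N - k, lower.tail = FALSE)
  new_test_result(W, c(k - 1, N - k), p,
                  sprintf("Levene's test (center = %s)", center), ni)
}

# Frequency table of the null Mann-Whitney U distribution for group sizes
# m, n (no ties): f[u + 1] = number of the choose(m + n, m) arrangements with
# exactly u (x > y) pairs, i.e. the coefficients of the Gaussian binomial
# [m + n choose m]_q, built by exact integer polynomial arithmetic from
# prod_i (1 - q^(n+i)) / (1 - q^i).
mw_u_counts <- function(m, n) {
  umax <- m * n
  f <- c(1, rep(0, umax))
  for (i in seq_len(m)) {
    g <- f
    if (n + i <= umax)
      g[(n + i + 1):(umax + 1)] <- g[(n + i + 1):(umax + 1)] -
        f[1:(umax - n - i + 1)]
    h <- g
    if (i <= umax)
      for (u in i:umax) h[u + 1] <- g[u + 1] + h[u - i + 1]
    f <- h
  }
  f
}

#' Mann-Whitney-Wilcoxon rank-sum test
#'
#' `U` counts pairs where `x > y` (ties add 1/2). The exact two-sided p-value
#' is computed from the full null distribution of U (counting recurrence over
#' all arrangements) when `n1 * n2 <= 400` and there are no ties; otherwise
#' the normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y nonempty numeric vectors.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path; default
#'   `NULL` chooses automatically.
#' @return a `gd_test` result; `flags` records `"exact"` or `"normal_approx"`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop_param("both groups must be nonempty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # pairs with x > y (+ ties/2)
  ties <- any(duplicated(c(x, y)))
  use_exact <- if (is.null(exact)) (n1 * n2 <= 400 && !ties) else isTRUE(exact)
  if (use_exact && ties)
    stop_param("exact p-value is not defined with ties")
  if (use_exact) {
    f <- mw_u_counts(n1, n2)
    tot <- sum(f)
    lo <- sum(f[seq_len(U + 1)]) / tot          # P(U <= u)
    hi <- sum(f[(U + 1):(n1 * n2 + 1)]) / tot   # P(U >= u)
    p <- min(1, 2 * min(lo, hi))
    flag <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie_tab <- table(c(x, y))
    sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
    cc <- sign(U - mu) * 0.5
    z <- (U - mu - cc) / sqrt(sig2)
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    flag <- "normal_approx"
  }
  new_test_result(U, NA_real_, p, "Mann-Whitney-Wilcoxon test", c(n1, n2),
                  flags = flag)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x`; `R^2 = 1 - SSE/SST`, F-statistic on
#' (1, n - 2) degrees of freedom, two-sided p-value.
#'
#' @param x nonconstant covariate values (n >= 3).
#' @param y response values.
#' @return object of class `gd_regression`: `slope`, `intercept`,
#'   `r_squared`, `f_statistic`, `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop_param("need at least 3 observations")
  if (length(y) != n) stop_param("x and y must have equal length")
  if (sd(x) == 0) stop_param("constant covariate: regression undefined")
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  sse <- sum((y - intercept - slope * x)^2)
  sst <- sum((y - my)^2)
  r2 <- if (sst == 0) 1 else 1 - sse / sst
  fstat <- if (sse == 0) Inf else (n - 2) * r2 / (1 - r2)
  p <- pf(fstat, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 f_statistic = fstat, p_value = p, n = n),
            class = "gd_regression")
}

#' @export
print.gd_regression <- function(x, ...) {
  cat(sprintf("OLS: slope = %.6g, intercept = %.6g, R2 = %.4f, p = %.6g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Pearson r for every pair of numeric columns, computed from the covariance
#' formula. Constant columns yield `NA` entries with a warning; the diagonal
#' is 1.
#'
#' @param env data.frame or matrix with >= 3 rows; non-numeric columns are
#'   dropped.
#' @return symmetric correlation matrix.
#' @export
pearson_correlation_matrix <- function(env) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, TRUE)
  env <- env[num]
  if (nrow(env) < 3L) stop_param("need at least 3 observations")
  k <- ncol(env)
  R <- diag(1, k)
  dimnames(R) <- list(names(env), names(env))
  const <- vapply(env, function(v) sd(v) == 0, TRUE)
  if (any(const))
    warning(sprintf("constant column(s) %s: correlations undefined",
                    paste(names(env)[const], collapse = ", ")))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (const[i] || const[j]) { R[i, j] <- NA_real_; next }
    xi <- env[[i]] - mean(env[[i]]); xj <- env[[j]] - mean(env[[j]])
    R[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
  }
  R
}

#' Regression grid of gene metrics against environmental covariates
#'
#' One simple linear regression per (gene, metric) x covariate cell, as used
#' to ask which environmental parameters are associated with changes in
#' diversity, richness or abundance. Cells are annotated significant at
#' p < 0.05 and marginal at p < 0.10; raw p-values are reported, with a
#' Benjamini-Hochberg adjusted column alongside for transparency.
#'
#' @param metrics long-format data.frame with columns `gene`, `metric`,
#'   `t_index`, `value`.
#' @param env data.frame with `t_index` plus covariate columns.
#' @param covariates covariate column names (default the four standard water
#'   chemistry covariates).
#' @return data.frame `gene`, `metric`, `covariate`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `p_adj`, `significant_05`, `marginal_10`.
#' @export
env_regression_grid <- function(metrics, env,
                                covariates = c("temp_c", "do_mgL", "cl_mgL",
                                               "npoc_mgL")) {
  need <- c("gene", "metric", "t_index", "value")
  if (!all(need %in% names(metrics)))
    stop_param("`metrics` must have columns %s", paste(need, collapse = ", "))
  if (!all(c("t_index", covariates) %in% names(env)))
    stop_param("`env` is missing column(s): %s",
               paste(setdiff(c("t_index", covariates), names(env)), collapse = ", "))
  if (nrow(metrics) == 0L)
    return(data.frame(gene = character(0), metric = character(0),
                      covariate = character(0), slope = numeric(0),
                      intercept = numeric(0), r_squared = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      significant_05 = logical(0), marginal_10 = logical(0)))
  if (!all(metrics$t_index %in% env$t_index))
    stop_param("metrics reference t_index values absent from env (misaligned series)")
  combos <- unique(metrics[c("gene", "metric")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- metrics[metrics$gene == combos$gene[i] &
                     metrics$metric == combos$metric[i], ]
    ev <- env[match(sub$t_index, env$t_index), ]
    for (cv in covariates) {
      fit <- linear_regression(ev[[cv]], sub$value)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = combos$gene[i], metric = combos$metric[i], covariate = cv,
        slope = fit$slope, intercept = fit$intercept,
        r_squared = fit$r_squared, p_value = fit$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out$significant_05 <- out$p_value < 0.05
  out$marginal_10 <- out$p_value < 0.10
  out
}

#' Levene comparison of phylotype profile variability between gene families
#'
#' Interprets "phylotype profile variability" as the set of per-phylotype
#' temporal variances of relative abundance: each family contributes one
#' group holding the variance of every phylotype's trajectory, and the groups
#' are compared with [levene_test()]. This grouping is one reasonable reading
#' of a family-level variability contrast and is flagged as an
#' interpretation.
#'
#' @param rel_mats named list of phylotype x timepoint relative-abundance
#'   matrices (>= 2 families, each with >= 2 phylotypes).
#' @param center passed to [levene_test()].
#' @return a `gd_test` result.
#' @export
family_variability_test <- function(rel_mats, center = c("mean", "median")) {
  stopifnot(is.list(rel_mats), length(rel_mats) >= 2L)
  groups <- lapply(rel_mats, function(m) apply(m, 1, var))
  levene_test(groups, center = match.arg(center))
}
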