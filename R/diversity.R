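#' Phylotype richness
#'
#' Number of distinct phylotypes observed, i.e. entries with abundance > 0.
#'
#' @param profile non-negative abundance vector.
#' @return integer count.
#' @export
richness <- function(profile) {
  if (any(profile < 0)) stop_param("abundances must be >= 0")
  sum(profile > 0)
}

#' Inverse Simpson diversity
#'
#' `1 / sum(p_i^2)` on a relative-abundance profile. Profiles are
#' renormalized internally when their sum is within 1e-6 of 1; other sums are
#' an error. The all-zero profile is defined as 0 and carries the attribute
#' `empty = TRUE` so rectangular time series with missing samples survive.
#'
#' @param profile relative abundances.
#' @return diversity value (>= 1 for non-empty profiles, never exceeding the
#'   richness).
#' @examples
#' inverse_simpson(rep(0.25, 4))  # 4
#' @export
inverse_simpson <- function(profile) {
  if (any(profile < 0)) stop_param("abundances must be >= 0")
  s <- sum(profile)
  if (s == 0) return(structure(0, empty = TRUE))
  if (abs(s - 1) > 1e-6)
    stop_param("profile sums to %.8f; expected 1 within 1e-6", s)
  p <- profile / s
  1 / sum(p^2)
}

#' Per-sample and cumulative diversity profiles
#'
#' Computes the diversity surface of a phylotype x sample abundance matrix
#' ordered by time: per-sample richness and inverse Simpson, the cumulative
#' versions obtained by pooling each time point with all previous time points
#' (column-wise RPKM sums, renormalized — so cumulative richness is exactly
#' the union of observed phylotypes and is non-decreasing), and delta series
#' expressing the cumulative values as the difference from the initial state
#' (first time point; deltas start at 0).
#'
#' @param mat phylotype x sample matrix of non-negative abundances (RPKM or
#'   relative), columns in time order.
#' @return list with `cumulative_rel` (phylotype x sample cumulative relative
#'   abundances) and `profile`, a data.frame with columns `sample_id`,
#'   `richness`, `inv_simpson`, `cum_richness`, `cum_inv_simpson`,
#'   `delta_richness`, `delta_inv_simpson`.
#' @export
cumulative_profiles <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1)
  if (any(mat < 0)) stop_param("abundances must be >= 0")
  tt <- ncol(mat)
  cum <- mat
  for (t in seq_len(tt)[-1L]) cum[, t] <- cum[, t - 1L] + mat[, t]
  tot <- colSums(cum)
  cum_rel <- sweep(cum, 2, ifelse(tot > 0, tot, 1), "/")
  per_tot <- colSums(mat)
  per_rel <- sweep(mat, 2, ifelse(per_tot > 0, per_tot, 1), "/")
  rich <- apply(per_rel, 2, richness)
  invs <- apply(per_rel, 2, function(p) as.numeric(inverse_simpson(p)))
  cum_rich <- apply(cum_rel, 2, richness)
  cum_invs <- apply(cum_rel, 2, function(p) as.numeric(inverse_simpson(p)))
  profile <- data.frame(
    sample_id = if (!is.null(colnames(mat))) colnames(mat) else
      sprintf("S%02d", seq_len(tt)),
    richness = rich, inv_simpson = invs,
    cum_richness = cum_rich, cum_inv_simpson = cum_invs,
    delta_richness = cum_rich - cum_rich[1L],
    delta_inv_simpson = cum_invs - cum_invs[1L],
    stringsAsFactors = FALSE, row.names = NULL)
  list(cumulative_rel = cum_rel, profile = profile)
}

#' Temporal turnover: mean abundance variance
#'
#' For each phylotype, the unbiased (n - 1) variance of its relative
#' abundance across all time points — time points where the phylotype was not
#' observed enter as 0 — then the mean over phylotypes. High values indicate
#' phylotype replacement through time; a constant profile gives exactly 0.
#' Note the convention implies that appending an all-zero phylotype row
#' lowers the mean.
#'
#' @param rel_mat phylotype x timepoint matrix of relative abundances.
#' @return non-negative scalar.
#' @export
mean_abundance_variance <- function(rel_mat) {
  stopifnot(is.matrix(rel_mat))
  if (ncol(rel_mat) < 2L)
    stop_param("need at least 2 timepoints to measure turnover")
  mean(apply(rel_mat, 1, var))
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|u - v|) / sum(u + v)` for non-negative abundance vectors; 0 for
#' identical profiles, 1 for disjoint supports. Two all-zero vectors are
#' undefined and return `NA` with a warning.
#'
#' @param u,v equal-length non-negative abundance vectors.
#' @return dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis(c(1, 0, 3), c(0, 2, 1))  # 5/7
#' @export
bray_curtis <- function(u, v) {
  if (length(u) != length(v)) stop_param("vectors must have equal length")
  if (any(u < 0) || any(v < 0)) stop_param("abundances must be >= 0")
  denom <- sum(u + v)
  if (denom == 0) {
    warning("both profiles are all-zero: Bray-Curtis undefined")
    return(NA_real_)
  }
  sum(abs(u - v)) / denom
}

#' Distance-decay of community dissimilarity over time
#'
#' All unordered sample pairs with their time lag and Bray-Curtis
#' dissimilarity, summarized by the least-squares slope of dissimilarity
#' against lag. Lag is measured in sample-index units by default, or in
#' calendar days when `dates` are supplied.
#'
#' @param mat phylotype x sample abundance matrix (>= 2 samples), columns in
#'   time order.
#' @param time numeric time coordinates per sample (default 1, 2, ...).
#' @param dates optional `Date` vector per sample; overrides `time` with
#'   calendar-day lags.
#' @return list with `pairs` (data.frame `sample_i`, `sample_j`, `lag`,
#'   `dissimilarity`) and `fit` (a [linear_regression()] result; slope 0 when
#'   all dissimilarities are equal).
#' @export
distance_decay <- function(mat, time = seq_len(ncol(mat)), dates = NULL) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  if (!is.null(dates)) time <- as.numeric(as.Date(dates))
  stopifnot(length(time) == ncol(mat))
  ij <- combn(ncol(mat), 2L)
  lag <- abs(time[ij[2L, ]] - time[ij[1L, ]])
  dis <- vapply(seq_len(ncol(ij)), function(q)
    bray_curtis(mat[, ij[1L, q]], mat[, ij[2L, q]]), 0)
  ids <- if (!is.null(colnames(mat))) colnames(mat) else
    sprintf("S%02d", seq_len(ncol(mat)))
  pairs <- data.frame(sample_i = ids[ij[1L, ]], sample_j = ids[ij[2L, ]],
                      lag = lag, dissimilarity = dis,
                      stringsAsFactors = FALSE)
  fit <- if (sd(dis) == 0)
    structure(list(slope = 0, intercept = dis[1L], r_squared = NA_real_,
                   f_statistic = NA_real_, p_value = NA_real_,
                   n = length(dis)), class = "gd_regression")
  else linear_regression(lag, dis)
  list(pairs = pairs, fit = fit)
}

#' Table-1-style turnover summary for one or more gene families
#'
#' @param rel_mats named list of phylotype x timepoint relative-abundance
#'   matrices, one per gene family.
#' @return data.frame `gene_family`, `phylotype_richness`,
#'   `mean_abundance_variance`.
#' @export
turnover_summary <- function(rel_mats) {
  stopifnot(is.list(rel_mats), !is.null(names(rel_mats)))
  data.frame(
    gene_family = names(rel_mats),
    phylotype_richness = vapply(rel_mats, function(m) richness(rowSums(m)), 0L),
    mean_abundance_variance = vapply(rel_mats, mean_abundance_variance, 0),
    stringsAsFactors = FALSE, row.names = NULL)
}
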