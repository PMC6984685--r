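test_that("degenerate pool: one phylotype, one variant", {
  pool <- generate_phylotype_pool(1, 1, 60, seed = 1, family = "g")
  expect_length(pool$protein, 1L)
  expect_identical(pool$labels$phylotype_id, "g_p01")
  expect_identical(nchar(pool$nucleotide[[1]]), 180L)
})

test_that("planted identity bounds verify with the aligner", {
  pool <- generate_phylotype_pool(2, 3, 60, between_identity_max = 0.60,
                                  within_identity_min = 0.95, seed = 5,
                                  family = "g")
  ids <- pool$labels$sequence_id
  pt <- setNames(pool$labels$phylotype_id, ids)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    idn <- global_align_identity(pool$protein[[ids[i]]], pool$protein[[ids[j]]])
    if (pt[ids[i]] == pt[ids[j]]) expect_gte(idn, 0.95) else expect_lte(idn, 0.60)
  }
})

test_that("pool generation is byte-deterministic under a fixed seed", {
  p1 <- generate_phylotype_pool(3, 2, 60, seed = 9, family = "g")
  p2 <- generate_phylotype_pool(3, 2, 60, seed = 9, family = "g")
  expect_identical(p1$protein, p2$protein)
  expect_identical(p1$nucleotide, p2$nucleotide)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(p1$protein, f1); write_fasta(p2$protein, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("infeasible identity bounds and mutation budgets are rejected", {
  expect_error(generate_phylotype_pool(2, 2, 60, between_identity_max = 0.97,
                                       within_identity_min = 0.95),
               "infeasible|margins")
  expect_error(generate_phylotype_pool(2, 2, 60, within_identity_min = 0.85,
                                       between_identity_max = 0.60),
               "margins")
  # a budget of zero substitutions cannot hold with within < 1
  expect_error(generate_phylotype_pool(2, 2, 50, within_identity_min = 0.995,
                                       between_identity_max = 0.60),
               "mutation budget")
})

test_that("protein and nucleotide sequences are consistent", {
  pool <- generate_phylotype_pool(2, 2, 60, seed = 13, family = "g")
  for (id in names(pool$protein)) {
    tr <- as.character(Biostrings::translate(
      Biostrings::DNAString(pool$nucleotide[[id]])))
    expect_identical(tr, pool$protein[[id]])
  }
})

test_that("abundance series columns are simplex points", {
  A <- simulate_abundance_series(regime_params("resilient", 8, 11, 0.8, seed = 3))
  expect_equal(unname(colSums(A)), rep(1, 11), tolerance = 1e-9)
  expect_true(all(A >= 0))
})

test_that("zero walk sigma freezes the profile; one phylotype is constant 1", {
  A <- simulate_abundance_series(regime_params("resistant", 5, 6, 0, seed = 4))
  expect_equal(A, A[, c(1, 1, 1, 1, 1, 1)], ignore_attr = TRUE)
  expect_identical(mean_abundance_variance(A), 0)
  A1 <- simulate_abundance_series(regime_params("resistant", 1, 4, 0.5, seed = 5))
  expect_equal(unname(A1[1, ]), rep(1, 4))
})

test_that("environment series has the right period split and shift contrasts", {
  env <- simulate_environment(11, 6, seed = 2)
  expect_identical(sum(env$period == "early"), 6L)
  expect_identical(sum(env$period == "late"), 5L)
  # noiseless construction: chloride steps up, organic carbon steps down
  env0 <- simulate_environment(11, 6, noise_scale = 0)
  expect_gt(mean(env0$cl_mgL[env0$period == "late"]),
            mean(env0$cl_mgL[env0$period == "early"]))
  expect_lt(mean(env0$npoc_mgL[env0$period == "late"]),
            mean(env0$npoc_mgL[env0$period == "early"]))
  # temperature arc rises then falls
  expect_gt(max(env0$temp_c), env0$temp_c[1])
  expect_gt(max(env0$temp_c), env0$temp_c[11])
  expect_identical(simulate_environment(11, 6, seed = 2), env)
  expect_error(simulate_environment(11, 11), "shift_index")
})

test_that("reads come from the right sources in the right proportions", {
  poolA <- generate_phylotype_pool(2, 1, 60, seed = 61, family = "g")
  mk <- generate_phylotype_pool(1, 1, 60, seed = 62, family = "m")
  A <- matrix(c(0.8, 0.2), 2, 1, dimnames = list(poolA$phylotype_ids, "S01"))

  # error-free reads are exact substrings of their source gene
  sim <- emit_reads(poolA, A, mk, reads_per_sample = 200, read_len_nt = 80,
                    error_rate = 0, seed = 63)
  rd <- sim$reads$S01
  src <- sim$truth$source_seq_id
  all_seq <- c(poolA$nucleotide, mk$nucleotide)
  hits <- vapply(seq_along(rd), function(i)
    grepl(rd[[i]], all_seq[[src[i]]], fixed = TRUE), TRUE)
  expect_true(all(hits))

  # 0.8 vs 0.2 abundance at equal length: 4x reads within binomial 99% bounds
  sim2 <- emit_reads(poolA, A, mk, reads_per_sample = 10000, read_len_nt = 80,
                     error_rate = 0, carriage = 1, seed = 64)
  gene_reads <- sim2$truth[sim2$truth$family == "g", ]
  nA <- sum(gene_reads$phylotype_id == "g_p01")
  n <- nrow(gene_reads)
  ci <- qbinom(c(0.005, 0.995), n, 0.8)
  expect_gte(nA, ci[1]); expect_lte(nA, ci[2])

  # single phylotype at abundance 1: all gene reads from it
  A1 <- matrix(1, 1, 1, dimnames = list("h_p01", "S01"))
  pool1 <- generate_phylotype_pool(1, 1, 60, seed = 65, family = "h")
  sim3 <- emit_reads(pool1, A1, mk, reads_per_sample = 100, read_len_nt = 80,
                     error_rate = 0, seed = 66)
  gr <- sim3$truth[sim3$truth$family == "h", ]
  expect_true(all(gr$phylotype_id == "h_p01"))
})

test_that("empty samples warn and read emission is deterministic", {
  pool <- generate_phylotype_pool(1, 1, 60, seed = 71, family = "g")
  mk <- generate_phylotype_pool(1, 1, 60, seed = 72, family = "m")
  A <- matrix(1, 1, 2, dimnames = list(pool$phylotype_ids, c("S01", "S02")))
  A1 <- A[, 1, drop = FALSE]
  expect_warning(emit_reads(pool, A1, mk, reads_per_sample = 0, seed = 1),
                 "empty sample")
  s1 <- emit_reads(pool, A, mk, reads_per_sample = 500, read_len_nt = 90,
                   seed = 73)
  s2 <- emit_reads(pool, A, mk, reads_per_sample = 500, read_len_nt = 90,
                   seed = 73)
  expect_identical(s1$reads, s2$reads)
  expect_error(emit_reads(pool, A, mk, reads_per_sample = 10,
                          read_len_nt = 500), "shortest coding sequence")
})
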