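# Shared fixtures and independent oracles used across the suite.

# canonical partition representation: list of sorted member vectors, ordered
# by their smallest member
canonical_partition <- function(members_by_cluster) {
  p <- unname(lapply(members_by_cluster, function(m) sort(as.character(m))))
  p[order(vapply(p, `[`, "", 1L))]
}

partition_of <- function(phylotype_set) {
  canonical_partition(split(phylotype_set$membership$sequence_id,
                            phylotype_set$membership$phylotype_id))
}

# Naive all-pairs reference implementation of the same greedy rule:
# precompute the full identity matrix, then walk the ordered sequences and
# attach each to the first (founding-order) representative at >= threshold.
naive_greedy_partition <- function(seqs, params = clustering_params()) {
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  n <- length(seqs)
  M <- diag(1, n)
  if (n > 1) for (i in seq_len(n - 1)) {
    idn <- genediv:::align_identity_many(seqs[[i]], seqs[(i + 1):n], params)
    M[i, (i + 1):n] <- M[(i + 1):n, i] <- idn
  }
  reps <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- reps[which(M[reps, i, drop = TRUE] >= params$threshold)[1L]]
    if (length(hit) == 0L || is.na(hit)) { reps <- c(reps, i); hit <- i }
    assign[i] <- hit
  }
  canonical_partition(split(names(seqs), assign))
}

# random clustering instance with identities straddling the threshold:
# founders plus variants mutated at 0..40% of positions
random_cluster_instance <- function(seed, max_seqs = 15L, L = 50L) {
  set.seed(seed)
  aa <- genediv:::AA_ALPHABET_STRICT
  n_base <- sample(2:5, 1)
  seqs <- character(0)
  k <- 0L
  for (b in seq_len(n_base)) {
    base <- sample(aa, L, replace = TRUE)
    for (v in seq_len(sample(1:4, 1))) {
      if (k >= max_seqs) break
      s <- base
      nmut <- sample(0:(0.4 * L), 1)
      if (nmut > 0) {
        pos <- sample(L, nmut)
        for (q in pos) s[q] <- sample(setdiff(aa, s[q]), 1)
      }
      k <- k + 1L
      seqs[sprintf("s%02d", k)] <- paste(s, collapse = "")
    }
  }
  seqs
}

# exact two-sided Mann-Whitney p by explicit enumeration of all
# choose(m+n, m) rank arrangements (distinct values assumed)
mw_enum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ranks <- seq_len(m + n)
  sets <- utils::combn(m + n, m)
  us <- colSums(matrix(ranks[sets], nrow = m)) - m * (m + 1) / 2
  lo <- mean(us <= u_obs); hi <- mean(us >= u_obs)
  min(1, 2 * min(lo, hi))
}

# small end-to-end pipeline configuration (3 families + marker)
demo_config <- function(reads_per_sample = 1500) {
  pre <- regime_presets(11)
  fam <- list(
    narG_like = modifyList(pre$narG_like,
                           list(regime = regime_params("resistant", 10, 11, 0.10))),
    nirKS_like = modifyList(pre$nirKS_like,
                            list(regime = regime_params("resilient", 6, 11, 0.80))),
    amoA_like = pre$amoA_like)
  mk <- modifyList(pre$rplB_like,
                   list(regime = regime_params("resistant", 8, 11, 0.10)))
  default_config(reads_per_sample = reads_per_sample, families = fam,
                 marker = mk)
}
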