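#' Dynamical regime parameters for a simulated gene family
#'
#' A phylotype abundance time series is modelled as the softmax of independent
#' Gaussian random walks on log-abundance. `walk_sigma` is the per-step
#' standard deviation of the walk and maps monotonically onto the temporal
#' turnover statistic (mean abundance variance): resistant regimes (stable
#' phylotype profiles) use small sigma, resilient regimes (phylotype
#' replacement) use large sigma. `dominance_alpha` is the symmetric Dirichlet
#' concentration of the initial profile; small values plant one dominant
#' phylotype.
#'
#' @param name regime class: `"resistant"`, `"resilient"` or `"low_richness"`.
#' @param n_phylotypes number of phylotypes (>= 1).
#' @param n_timepoints number of samples in the series (>= 2; default 11).
#' @param walk_sigma step size (sd) of the log-abundance random walk (>= 0).
#' @param dominance_alpha Dirichlet concentration of the initial draw (> 0).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return an object of class `regime_params`.
#' @export
regime_params <- function(name = c("resistant", "resilient", "low_richness"),
                          n_phylotypes, n_timepoints = 11L, walk_sigma,
                          dominance_alpha = 1, seed = NULL) {
  name <- match.arg(name)
  n_phylotypes <- check_count(n_phylotypes, "n_phylotypes", 1L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", 2L)
  if (!is.numeric(walk_sigma) || walk_sigma < 0)
    stop_param("`walk_sigma` must be >= 0")
  if (!is.numeric(dominance_alpha) || dominance_alpha <= 0)
    stop_param("`dominance_alpha` must be > 0")
  structure(list(name = name, n_phylotypes = n_phylotypes,
                 n_timepoints = n_timepoints, walk_sigma = walk_sigma,
                 dominance_alpha = dominance_alpha, seed = seed),
            class = "regime_params")
}

#' Preset gene-family regimes emulating an N-cycling hyporheic community
#'
#' Seven synthetic families spanning the observed diversity/turnover space of
#' nitrogen-cycling genes in a seasonal hyporheic community: high-richness /
#' low-turnover (narG-like, nosZ-like), lower-richness / high-turnover
#' (nirKS-like, norB-like), low-richness nitrification-like families (2
#' phylotypes amoA-like; 7 phylotypes with one dominant, nxrA-like), and a
#' universal single-copy marker (rplB-like, carried by every individual).
#' `carriage` is the fraction of individuals carrying the gene, set from
#' typical per-capita abundances of these families.
#'
#' @param n_timepoints series length (default 11).
#' @return named list; each element has `family`, `regime` (a
#'   [regime_params()] object), `carriage`, and `variants_per_phylotype`.
#' @export
regime_presets <- function(n_timepoints = 11L) {
  p <- function(nm, n, sig, alpha, carr, cls)
    list(family = nm,
         regime = regime_params(cls, n_phylotypes = n,
                                n_timepoints = n_timepoints,
                                walk_sigma = sig, dominance_alpha = alpha),
         carriage = carr, variants_per_phylotype = 2L)
  list(
    narG_like  = p("narG_like", 52L, 0.10, 1.00, 0.28, "resistant"),
    nosZ_like  = p("nosZ_like", 51L, 0.25, 1.00, 0.25, "resistant"),
    norB_like  = p("norB_like", 31L, 0.80, 1.00, 0.16, "resilient"),
    nirKS_like = p("nirKS_like", 23L, 0.80, 1.00, 0.40, "resilient"),
    nxrA_like  = p("nxrA_like", 7L, 0.10, 0.15, 0.10, "low_richness"),
    amoA_like  = p("amoA_like", 2L, 0.80, 0.50, 0.15, "low_richness"),
    rplB_like  = p("rplB_like", 124L, 0.10, 1.00, 1.00, "resistant"))
}

aa_to_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA_ALPHABET_STRICT]
}

#' Generate a pool of phylotype sequences with planted identity structure
#'
#' Draws one random founder protein per phylotype, then derives
#' `variants_per_phylotype` members by point substitutions, so that every
#' within-phylotype pair has global-alignment identity at least
#' `within_identity_min` and every between-phylotype pair at most
#' `between_identity_max`. Bounds are enforced by rejection sampling and
#' verified post hoc with the clustering aligner: founder pairs are checked
#' against `between_identity_max - 2 * (1 - within_identity_min)` (which
#' bounds all variant pairs by `between_identity_max`), and within-phylotype
#' pairs are checked directly. Generation fails loudly rather than emitting a
#' pool that violates the bounds. Each protein gets a consistent coding
#' nucleotide sequence (random synonymous codons, shared within a phylotype
#' except at mutated sites).
#'
#' @param n_phylotypes,variants_per_phylotype pool dimensions.
#' @param seq_len_aa protein length in residues (>= 50; default 60).
#' @param between_identity_max,within_identity_min identity bounds; the
#'   margins `between < threshold - 0.03 < within - 0.06` must hold so the
#'   clustering threshold separates the planted clusters.
#' @param cluster_threshold identity threshold the pool is built to be
#'   separable at (default 0.90).
#' @param family label used in sequence and phylotype ids.
#' @param seed integer seed or `NULL`.
#' @param params [clustering_params()] used for verification alignments.
#' @param max_tries rejection-sampling cap per founder.
#' @return an object of class `phylotype_pool`: list with `protein` and
#'   `nucleotide` (named character vectors, same ids), `labels` (data.frame
#'   `sequence_id`, `phylotype_id`), `phylotype_ids`, `family`, `seq_len_aa`.
#' @export
generate_phylotype_pool <- function(n_phylotypes, variants_per_phylotype = 2L,
                                    seq_len_aa = 60L,
                                    between_identity_max = 0.60,
                                    within_identity_min = 0.95,
                                    cluster_threshold = 0.90,
                                    family = "gene", seed = NULL,
                                    params = clustering_params(threshold = cluster_threshold),
                                    max_tries = 50L) {
  n_phylotypes <- check_count(n_phylotypes, "n_phylotypes", 1L)
  variants_per_phylotype <- check_count(variants_per_phylotype,
                                        "variants_per_phylotype", 1L)
  seq_len_aa <- check_count(seq_len_aa, "seq_len_aa", 50L)
  between_identity_max <- check_fraction(between_identity_max, "between_identity_max")
  within_identity_min <- check_fraction(within_identity_min, "within_identity_min")
  if (within_identity_min <= between_identity_max)
    stop_param("infeasible identity bounds: within_identity_min (%.2f) must exceed between_identity_max (%.2f)",
               within_identity_min, between_identity_max)
  if (!(between_identity_max < cluster_threshold - 0.03) ||
      !(cluster_threshold - 0.03 < within_identity_min - 0.06))
    stop_param("identity margins too tight: need between_identity_max < threshold - 0.03 < within_identity_min - 0.06")
  m_budget <- floor(seq_len_aa * (1 - within_identity_min) / 2)
  if (variants_per_phylotype > 1L && within_identity_min < 1 && m_budget < 1L)
    stop_param("mutation budget unsatisfiable at seq_len_aa = %d: no substitutions fit within within_identity_min = %.3f",
               seq_len_aa, within_identity_min)
  founder_bound <- between_identity_max - 2 * (1 - within_identity_min)
  if (founder_bound <= 0)
    stop_param("infeasible identity bounds: between_identity_max too small for the within margin")
  codons <- aa_to_codons()

  with_seed(seed, {
    founders <- character(n_phylotypes)
    for (p in seq_len(n_phylotypes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- paste(sample(AA_ALPHABET_STRICT, seq_len_aa, replace = TRUE),
                      collapse = "")
        if (p == 1L ||
            all(align_identity_many(cand, founders[seq_len(p - 1L)], params) <=
                founder_bound)) { ok <- TRUE; break }
      }
      if (!ok)
        stop_param("could not place founder %d within identity bounds after %d tries",
                   p, max_tries)
      founders[p] <- cand
    }

    pt_ids <- sprintf("%s_p%02d", family, seq_len(n_phylotypes))
    prot <- nt <- character(0); seq_pt <- character(0)
    for (p in seq_len(n_phylotypes)) {
      base_aa <- strsplit(founders[p], "")[[1]]
      base_nt <- vapply(base_aa, function(a) sample(codons[[a]], 1L), "")
      for (v in seq_len(variants_per_phylotype)) {
        aa <- base_aa; cn <- base_nt
        if (v > 1L && m_budget >= 1L) {
          pos <- sample.int(seq_len_aa, m_budget)
          for (q in pos) {
            aa[q] <- sample(setdiff(AA_ALPHABET_STRICT, aa[q]), 1L)
            cn[q] <- sample(codons[[aa[q]]], 1L)
          }
        }
        id <- sprintf("%s_v%d", pt_ids[p], v)
        prot[id] <- paste(aa, collapse = "")
        nt[id] <- paste(cn, collapse = "")
        seq_pt[id] <- pt_ids[p]
      }
      # verify the planted within-phylotype identity floor
      vids <- names(seq_pt)[seq_pt == pt_ids[p]]
      if (length(vids) > 1L) {
        for (i in seq_len(length(vids) - 1L)) {
          idn <- align_identity_many(prot[[vids[i]]],
                                     prot[vids[(i + 1L):length(vids)]], params)
          if (any(idn < within_identity_min))
            stop_param("within-phylotype identity bound violated in phylotype %s",
                       pt_ids[p])
        }
      }
    }
    structure(list(protein = prot, nucleotide = nt,
                   labels = data.frame(sequence_id = names(seq_pt),
                                       phylotype_id = unname(seq_pt),
                                       stringsAsFactors = FALSE),
                   phylotype_ids = pt_ids, family = family,
                   seq_len_aa = seq_len_aa),
              class = "phylotype_pool")
  })
}

#' Simulate a phylotype relative-abundance time series
#'
#' Softmax of Gaussian random walks on log-abundance: the initial profile is a
#' symmetric Dirichlet(`dominance_alpha`) draw; each phylotype's log-abundance
#' then takes independent N(0, `walk_sigma`^2) steps, and each timepoint is
#' renormalized. `walk_sigma = 0` yields identical columns (zero turnover).
#'
#' @param params a [regime_params()] object.
#' @param phylotype_ids optional row names (default `p01`, `p02`, ...).
#' @return matrix (phylotype x timepoint) of relative abundances; every
#'   column sums to 1.
#' @export
simulate_abundance_series <- function(params, phylotype_ids = NULL) {
  stopifnot(inherits(params, "regime_params"))
  n <- params$n_phylotypes; tt <- params$n_timepoints
  if (is.null(phylotype_ids)) phylotype_ids <- sprintf("p%02d", seq_len(n))
  stopifnot(length(phylotype_ids) == n)
  with_seed(params$seed, {
    g <- rgamma(n, shape = params$dominance_alpha, rate = 1)
    g <- pmax(g, 1e-12)
    x <- log(g / sum(g))
    A <- matrix(0, n, tt, dimnames = list(phylotype_ids,
                                          sprintf("S%02d", seq_len(tt))))
    for (t in seq_len(tt)) {
      if (t > 1L) x <- x + rnorm(n, 0, params$walk_sigma)
      p <- exp(x - max(x))
      A[, t] <- p / sum(p)
    }
    A
  })
}

#' Simulate environmental covariates across a mid-series hydrologic shift
#'
#' Emulates a seasonal surface-water-to-groundwater transition: water
#' temperature follows a rise-then-fall arc (about 9-20 degC), chloride (the
#' groundwater proxy) steps up and dissolved organic carbon (NPOC) steps down
#' after `shift_index`, and dissolved oxygen stays roughly constant (the
#' groundwater is oxic). Gaussian noise is added to each covariate;
#' `noise_scale = 0` gives the deterministic expectation. Samples up to
#' `shift_index` are labelled `early`, the rest `late`. Date labels run from
#' late April at three-week intervals, matching the sampling design the
#' defaults emulate (11 timepoints: 6 early, 5 late).
#'
#' @param n_timepoints number of samples (default 11).
#' @param shift_index last early sample; must satisfy
#'   `0 < shift_index < n_timepoints` (default 6).
#' @param noise_scale multiplier on the per-covariate noise sd
#'   (temp 0.8 degC, DO 0.5, Cl 0.8, NPOC 0.06 mg/L).
#' @param seed integer seed or `NULL`.
#' @return data.frame with columns `sample_id`, `t_index`, `date_label`,
#'   `temp_c`, `do_mgL`, `cl_mgL`, `npoc_mgL`, `total_reads` (NA until reads
#'   are simulated), `period`.
#' @export
simulate_environment <- function(n_timepoints = 11L, shift_index = 6L,
                                 noise_scale = 1, seed = NULL) {
  n_timepoints <- check_count(n_timepoints, "n_timepoints", 2L)
  shift_index <- check_count(shift_index, "shift_index", 1L)
  if (shift_index >= n_timepoints)
    stop_param("`shift_index` must satisfy 0 < shift_index < n_timepoints")
  if (noise_scale < 0) stop_param("`noise_scale` must be >= 0")
  t <- seq_len(n_timepoints)
  late <- t > shift_index
  with_seed(seed, {
    temp <- 7 + 13 * sin(pi * (t - 0.5) / n_timepoints) +
      rnorm(n_timepoints, 0, 0.8 * noise_scale)
    do <- 9 + rnorm(n_timepoints, 0, 0.5 * noise_scale)
    cl <- ifelse(late, 13, 5.5) + rnorm(n_timepoints, 0, 0.8 * noise_scale)
    npoc <- ifelse(late, 0.35, 0.90) + rnorm(n_timepoints, 0, 0.06 * noise_scale)
    data.frame(
      sample_id = sprintf("S%02d", t),
      t_index = t,
      date_label = format(as.Date("2014-04-30") + 21 * (t - 1L), "%Y-%m-%d"),
      temp_c = temp, do_mgL = do, cl_mgL = cl, npoc_mgL = pmax(npoc, 0.05),
      total_reads = NA_integer_,
      period = ifelse(late, "late", "early"),
      stringsAsFactors = FALSE)
  })
}

# Normalize the family inputs of emit_reads to a list of
# list(pool, abundance, carriage) and validate dimensions.
normalize_families <- function(sequences, abundance_series, carriage) {
  if (inherits(sequences, "phylotype_pool")) {
    sequences <- list(sequences); abundance_series <- list(abundance_series)
    names(sequences) <- names(abundance_series) <- sequences[[1L]]$family
  }
  stopifnot(is.list(sequences), is.list(abundance_series),
            length(sequences) == length(abundance_series))
  if (length(carriage) == 1L) carriage <- rep(carriage, length(sequences))
  fams <- vector("list", length(sequences))
  for (i in seq_along(sequences)) {
    pool <- sequences[[i]]; A <- abundance_series[[i]]
    stopifnot(inherits(pool, "phylotype_pool"), is.matrix(A))
    if (!setequal(rownames(A), pool$phylotype_ids))
      stop_param("abundance rows do not match pool phylotypes for family '%s'",
                 pool$family)
    A <- A[pool$phylotype_ids, , drop = FALSE]
    if (any(abs(colSums(A) - 1) > 1e-6))
      stop_param("abundance columns must be normalized (family '%s')", pool$family)
    fams[[i]] <- list(pool = pool, abundance = A, carriage = carriage[[i]])
  }
  fams
}

#' Simulate per-sample reads from gene pools plus a single-copy marker
#'
#' Draws single-end reads from coding sequences with sampling probability
#' proportional to abundance x carriage x gene length; the marker family is
#' sampled as if present at one copy per individual (carriage 1), so summed
#' marker abundance tracks total community size and gene RPKM / marker RPKM
#' recovers the planted carriage fraction. A phylotype's abundance is split
#' equally across its variant sequences. Substitution errors are applied per
#' base at `error_rate`; reads carry no indels.
#'
#' @param sequences a `phylotype_pool` or named list of pools (one per gene
#'   family).
#' @param abundance_series matrix or list of matrices (phylotype x sample,
#'   relative; columns sum to 1) matching `sequences`.
#' @param marker_sequences a `phylotype_pool` for the marker family.
#' @param marker_abundance optional marker abundance matrix; default is a
#'   uniform, time-constant profile.
#' @param reads_per_sample reads drawn per sample (0 gives an empty sample
#'   with a warning).
#' @param read_len_nt read length; must not exceed the shortest coding
#'   sequence.
#' @param error_rate per-base substitution probability.
#' @param carriage fraction of individuals carrying each gene family (scalar
#'   or vector along `sequences`).
#' @param seed integer seed or `NULL`.
#' @param out_dir if non-NULL, write one FASTQ per sample (Phred+33, constant
#'   Q30) plus ground-truth TSVs.
#' @return object of class `read_sim`: list with `reads` (per-sample named
#'   character vectors), `truth` (data.frame `sample_id`, `read_id`,
#'   `source_seq_id`, `phylotype_id`, `family`, `start`), `samples`,
#'   `total_reads`, `read_len_nt`, and `files` when written.
#' @export
emit_reads <- function(sequences, abundance_series, marker_sequences,
                       marker_abundance = NULL, reads_per_sample = 1e5,
                       read_len_nt = 100L, error_rate = 0.005, carriage = 1,
                       seed = NULL, out_dir = NULL) {
  reads_per_sample <- check_count(reads_per_sample, "reads_per_sample", 0L)
  read_len_nt <- check_count(read_len_nt, "read_len_nt", 1L)
  error_rate <- check_fraction(error_rate, "error_rate")
  stopifnot(inherits(marker_sequences, "phylotype_pool"))
  fams <- normalize_families(sequences, abundance_series, carriage)
  n_samples <- ncol(fams[[1L]]$abundance)
  if (is.null(marker_abundance)) {
    k <- length(marker_sequences$phylotype_ids)
    marker_abundance <- matrix(1 / k, k, n_samples,
                               dimnames = list(marker_sequences$phylotype_ids,
                                               colnames(fams[[1L]]$abundance)))
  }
  fams <- c(fams, normalize_families(marker_sequences, marker_abundance, 1))
  if (!all(vapply(fams, function(f) ncol(f$abundance), 0L) == n_samples))
    stop_param("all abundance series must have the same number of samples")

  # per-sequence static info and per-sample weights
  seq_tab <- do.call(rbind, lapply(fams, function(f) {
    lab <- f$pool$labels
    nvar <- table(lab$phylotype_id)
    data.frame(seq_id = lab$sequence_id, phylotype_id = lab$phylotype_id,
               family = f$pool$family,
               seq = unname(f$pool$nucleotide[lab$sequence_id]),
               len = nchar(f$pool$nucleotide[lab$sequence_id]),
               share = f$carriage / as.numeric(nvar[lab$phylotype_id]),
               stringsAsFactors = FALSE)
  }))
  if (read_len_nt > min(seq_tab$len))
    stop_param("read_len_nt (%d) exceeds the shortest coding sequence (%d nt)",
               read_len_nt, min(seq_tab$len))
  W <- do.call(rbind, lapply(fams, function(f) {
    lab <- f$pool$labels
    nvar <- table(lab$phylotype_id)
    f$abundance[lab$phylotype_id, , drop = FALSE] *
      (f$carriage / as.numeric(nvar[lab$phylotype_id])) *
      nchar(f$pool$nucleotide[lab$sequence_id])
  }))
  rownames(W) <- seq_tab$seq_id
  sample_ids <- colnames(fams[[1L]]$abundance)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%02d", seq_len(n_samples))

  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    reads_by_sample <- vector("list", n_samples)
    truth_list <- vector("list", n_samples)
    for (s in seq_len(n_samples)) {
      if (reads_per_sample == 0L) {
        warning(sprintf("sample %s: reads_per_sample = 0, emitting empty sample",
                        sample_ids[s]))
        reads_by_sample[[s]] <- character(0)
        truth_list[[s]] <- NULL
        next
      }
      cnt <- as.integer(rmultinom(1L, reads_per_sample, W[, s]))
      src <- rep.int(seq_len(nrow(seq_tab)), cnt)
      starts <- integer(length(src)); rds <- character(length(src))
      off <- 0L
      for (k in which(cnt > 0L)) {
        c_k <- cnt[k]
        st <- sample.int(seq_tab$len[k] - read_len_nt + 1L, c_k, replace = TRUE)
        rds[off + seq_len(c_k)] <- substring(seq_tab$seq[k], st,
                                             st + read_len_nt - 1L)
        starts[off + seq_len(c_k)] <- st
        off <- off + c_k
      }
      if (error_rate > 0) {
        nerr <- rbinom(length(rds), read_len_nt, error_rate)
        for (j in which(nerr > 0L)) {
          pos <- sample.int(read_len_nt, nerr[j])
          ch <- strsplit(rds[j], "")[[1L]]
          for (q in pos) ch[q] <- sample(setdiff(bases, ch[q]), 1L)
          rds[j] <- paste(ch, collapse = "")
        }
      }
      ids <- sprintf("%s_r%06d", sample_ids[s], seq_along(rds))
      names(rds) <- ids
      reads_by_sample[[s]] <- rds
      truth_list[[s]] <- data.frame(
        sample_id = sample_ids[s], read_id = ids,
        source_seq_id = seq_tab$seq_id[src],
        phylotype_id = seq_tab$phylotype_id[src],
        family = seq_tab$family[src], start = starts,
        stringsAsFactors = FALSE)
    }
    names(reads_by_sample) <- sample_ids
    sim <- structure(list(
      reads = reads_by_sample,
      truth = do.call(rbind, truth_list),
      samples = sample_ids,
      total_reads = vapply(reads_by_sample, length, 0L),
      read_len_nt = read_len_nt), class = "read_sim")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- file.path(out_dir, paste0(sample_ids, ".fastq"))
      for (s in seq_len(n_samples))
        write_fastq(reads_by_sample[[s]], files[s])
      write_tsv(sim$truth, file.path(out_dir, "read_truth.tsv"))
      sim$files <- files
    }
    sim
  })
}
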