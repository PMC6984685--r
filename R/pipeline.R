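#' Default pipeline configuration
#'
#' Simulation-backed run over the preset gene-family regimes (six
#' N-cycling-like families plus the rplB-like single-copy marker), 11
#' timepoints with the hydrologic shift after the 6th, and default read
#' simulation settings. Any field can be overridden; a family entry may
#' instead supply real inputs (`counts_tsv` + `membership_tsv`), in which
#' case simulation fields must be absent for that family.
#'
#' @param reads_per_sample reads drawn per sample (default 1e5).
#' @param n_timepoints,shift_index sampling design (default 11 / 6).
#' @param families named list of family entries; default [regime_presets()]
#'   without the marker.
#' @param marker marker family entry; default the rplB-like preset.
#' @return config list for [run_all()].
#' @export
default_config <- function(reads_per_sample = 1e5, n_timepoints = 11L,
                           shift_index = 6L, families = NULL, marker = NULL) {
  pre <- regime_presets(n_timepoints)
  if (is.null(families)) families <- pre[setdiff(names(pre), "rplB_like")]
  if (is.null(marker)) marker <- pre$rplB_like
  list(families = families, marker = marker,
       n_timepoints = n_timepoints, shift_index = shift_index,
       reads_per_sample = reads_per_sample, read_len_nt = 100L,
       error_rate = 0.005, seq_len_aa = 60L,
       between_identity_max = 0.60, within_identity_min = 0.95,
       clustering = clustering_params(),
       recruitment = recruitment_params(),
       env_tsv = NULL)
}

load_config <- function(config) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    base <- default_config()
    fams <- raw$families
    if (!is.null(fams))
      fams <- lapply(seq_along(fams), function(i) {
        f <- fams[[i]]
        if (!is.null(f$counts_tsv)) return(f)
        list(family = names(fams)[i],
             regime = regime_params(f$name %||% "resistant",
                                    n_phylotypes = f$n_phylotypes,
                                    n_timepoints = raw$n_timepoints %||% base$n_timepoints,
                                    walk_sigma = f$walk_sigma,
                                    dominance_alpha = f$dominance_alpha %||% 1),
             carriage = f$carriage %||% 1,
             variants_per_phylotype = f$variants_per_phylotype %||% 2L)
      })
    if (!is.null(fams)) names(fams) <- names(raw$families)
    cfg <- utils::modifyList(base, raw[setdiff(names(raw), "families")])
    if (!is.null(fams)) cfg$families <- fams
    cfg
  } else config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(cfg) {
  for (nm in names(cfg$families)) {
    f <- cfg$families[[nm]]
    real <- !is.null(f$counts_tsv) || !is.null(f$membership_tsv)
    sim <- !is.null(f$regime)
    if (real && sim)
      stop_param("family '%s': supply either real inputs or simulation params, not both", nm)
    if (!real && !sim)
      stop_param("family '%s': no inputs configured", nm)
    if (real && (is.null(f$counts_tsv) || is.null(f$membership_tsv)))
      stop_param("family '%s': real inputs need both counts_tsv and membership_tsv", nm)
  }
  if (any(vapply(cfg$families, function(f) !is.null(f$counts_tsv), TRUE)) &&
      is.null(cfg$env_tsv))
    stop_param("real-input families require `env_tsv` metadata")
  invisible(cfg)
}

#' Run the full pipeline: simulate, cluster, profile, diversity, stats
#'
#' Executes every stage in dependency order and writes the standard output
#' tree: per-family FASTA pools and ground truth, per-sample FASTQ reads,
#' phylotype membership tables and guide trees, count/RPKM/relative-abundance
#' matrices (heatmap-ready, rows in guide-tree leaf order), per-capita
#' abundance series, per-family diversity profiles (per-sample and
#' cumulative, with delta-from-initial series), a turnover summary table
#' (richness and mean abundance variance per family), Bray-Curtis pairwise
#' dissimilarities with distance-decay fits, the environmental regression
#' grid, and between-family tests. A JSON manifest records the configuration,
#' seed, per-stage wall time and md5 checksum of every output, so a re-run
#' with the same config and seed is byte-identical.
#'
#' @param config config list from [default_config()], or path to a YAML file.
#' @param seed integer seed for the whole run.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) an object of class `genediv_run`: list with the main
#'   in-memory results (`env`, `turnover`, `per_capita`, `diversity`,
#'   `relabund`, `grid`, `family_tests`, `decay`), `manifest` and `out_dir`.
#' @export
run_all <- function(config = default_config(), seed = 1L, out_dir) {
  cfg <- validate_config(load_config(config))
  t_all <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message(sprintf("[genediv] %s", sprintf(...)))
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(nm, t0) timings[[nm]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  set.seed(as.integer(seed))

  sim_fams <- names(cfg$families)[vapply(cfg$families, function(f) !is.null(f$regime), TRUE)]
  real_fams <- setdiff(names(cfg$families), sim_fams)

  ## stage: simulate ---------------------------------------------------------
  t0 <- tic(); log_stage("simulate: %d families + marker, %d timepoints",
                         length(sim_fams), cfg$n_timepoints)
  env <- simulate_environment(cfg$n_timepoints, cfg$shift_index)
  pools <- list(); abund <- list(); carriage <- c()
  for (nm in sim_fams) {
    f <- cfg$families[[nm]]
    pools[[nm]] <- generate_phylotype_pool(
      f$regime$n_phylotypes, f$variants_per_phylotype %||% 2L,
      cfg$seq_len_aa, cfg$between_identity_max, cfg$within_identity_min,
      cluster_threshold = cfg$clustering$threshold, family = nm,
      params = cfg$clustering)
    abund[[nm]] <- simulate_abundance_series(f$regime, pools[[nm]]$phylotype_ids)
    carriage[nm] <- f$carriage %||% 1
  }
  mk <- cfg$marker
  marker_pool <- generate_phylotype_pool(
    mk$regime$n_phylotypes, mk$variants_per_phylotype %||% 2L,
    cfg$seq_len_aa, cfg$between_identity_max, cfg$within_identity_min,
    cluster_threshold = cfg$clustering$threshold, family = mk$family %||% "marker",
    params = cfg$clustering)
  marker_abund <- simulate_abundance_series(mk$regime, marker_pool$phylotype_ids)
  sim_dir <- file.path(out_dir, "simulate")
  dir.create(sim_dir, showWarnings = FALSE)
  for (nm in names(pools)) {
    write_fasta(pools[[nm]]$protein, file.path(sim_dir, paste0(nm, "_protein.fasta")), "AA")
    write_fasta(pools[[nm]]$nucleotide, file.path(sim_dir, paste0(nm, "_nucleotide.fasta")), "DNA")
    write_tsv(pools[[nm]]$labels, file.path(sim_dir, paste0(nm, "_truth_labels.tsv")))
    write_tsv(as.data.frame(abund[[nm]]), file.path(sim_dir, paste0(nm, "_truth_abundance.tsv")),
              rownames_as = "phylotype_id")
  }
  write_fasta(marker_pool$protein, file.path(sim_dir, "marker_protein.fasta"), "AA")
  write_fasta(marker_pool$nucleotide, file.path(sim_dir, "marker_nucleotide.fasta"), "DNA")
  write_tsv(marker_pool$labels, file.path(sim_dir, "marker_truth_labels.tsv"))
  toc("simulate", t0)

  ## stage: reads ------------------------------------------------------------
  t0 <- tic(); log_stage("reads: %d per sample, len %d, error %.3g",
                         cfg$reads_per_sample, cfg$read_len_nt, cfg$error_rate)
  sim <- emit_reads(pools, abund, marker_pool, marker_abund,
                    reads_per_sample = cfg$reads_per_sample,
                    read_len_nt = cfg$read_len_nt, error_rate = cfg$error_rate,
                    carriage = carriage[names(pools)],
                    out_dir = file.path(out_dir, "reads"))
  env$total_reads <- as.integer(sim$total_reads[env$sample_id])
  write_tsv(env, file.path(sim_dir, "metadata.tsv"))
  toc("reads", t0)

  ## stage: cluster ----------------------------------------------------------
  t0 <- tic(); log_stage("cluster: threshold %.2f", cfg$clustering$threshold)
  clu_dir <- file.path(out_dir, "cluster")
  dir.create(clu_dir, showWarnings = FALSE)
  clusterings <- list(); trees <- list()
  for (nm in c(names(pools), "marker")) {
    pool <- if (nm == "marker") marker_pool else pools[[nm]]
    cl <- greedy_cluster(pool$protein, cfg$clustering, family = nm)
    clusterings[[nm]] <- cl
    write_tsv(cl$membership, file.path(clu_dir, paste0(nm, "_membership.tsv")))
    write_fasta(cl$representatives, file.path(clu_dir, paste0(nm, "_representatives.fasta")), "AA")
    trees[[nm]] <- build_guide_tree(cl$representatives, cfg$clustering)
    write_newick(trees[[nm]], file.path(clu_dir, paste0(nm, ".nwk")))
  }
  toc("cluster", t0)

  ## stage: profile ----------------------------------------------------------
  t0 <- tic(); log_stage("profile: recruiting %d samples", length(sim$samples))
  prof_dir <- file.path(out_dir, "profile")
  dir.create(prof_dir, showWarnings = FALSE)
  all_pools <- c(pools, list(marker = marker_pool))
  refs <- unlist(unname(lapply(all_pools, function(p) p$nucleotide)))
  counts <- sapply(sim$samples, function(s)
    recruit_reads(sim$reads[[s]], refs, cfg$recruitment)$counts)
  total_reads <- setNames(env$total_reads, env$sample_id)[colnames(counts)]
  ref_len <- nchar(refs)[rownames(counts)]
  rpkm_mat <- rpkm(counts, ref_len, rep(total_reads, each = nrow(counts)))
  write_tsv(as.data.frame(counts), file.path(prof_dir, "counts.tsv"),
            rownames_as = "sequence_id")
  write_tsv(as.data.frame(rpkm_mat), file.path(prof_dir, "rpkm.tsv"),
            rownames_as = "sequence_id")

  # per-family phylotype matrices, ordered by the guide tree
  seq2fam <- rep(names(all_pools),
                 vapply(all_pools, function(p) length(p$protein), 0L))
  names(seq2fam) <- unlist(unname(lapply(all_pools, function(p) names(p$protein))))
  relabund <- list(); pt_rpkm <- list()
  for (nm in names(all_pools)) {
    rows <- rownames(rpkm_mat)[seq2fam[rownames(rpkm_mat)] == nm]
    sub <- rpkm_mat[rows, , drop = FALSE]
    memb <- clusterings[[nm]]$membership
    # map membership phylotype ids onto representative-seq leaf labels
    rel <- phylotype_relative_abundance(sub, memb)
    agg <- rowsum(sub, group = memb$phylotype_id[match(rownames(sub), memb$sequence_id)])
    rep_of <- memb$sequence_id[memb$representative_flag]
    pt_of_rep <- memb$phylotype_id[match(rep_of, memb$sequence_id)]
    leaf <- guide_tree_leaf_order(trees[[nm]])
    ord <- pt_of_rep[match(leaf, rep_of)]
    relabund[[nm]] <- rel[ord, , drop = FALSE]
    pt_rpkm[[nm]] <- agg[ord, , drop = FALSE]
    write_tsv(as.data.frame(relabund[[nm]]),
              file.path(prof_dir, paste0(nm, "_relabund.tsv")),
              rownames_as = "phylotype_id")
  }
  per_capita <- do.call(rbind, lapply(names(pools), function(nm)
    per_capita_abundance(pt_rpkm[[nm]], pt_rpkm[["marker"]])))
  dimnames(per_capita) <- list(names(pools), colnames(rpkm_mat))
  write_tsv(as.data.frame(per_capita), file.path(prof_dir, "per_capita.tsv"),
            rownames_as = "gene_family")

  # real-input families enter here from precomputed tables
  for (nm in real_fams) {
    f <- cfg$families[[nm]]
    ct <- read_tsv(f$counts_tsv, required = c("sequence_id", "gene_len_nt"))
    mb <- read_tsv(f$membership_tsv, required = c("sequence_id", "phylotype_id"))
    meta <- read_tsv(cfg$env_tsv, required = c("sample_id", "total_reads"))
    scols <- setdiff(names(ct), c("sequence_id", "gene_len_nt"))
    cm <- as.matrix(ct[scols]); rownames(cm) <- ct$sequence_id
    tr <- setNames(meta$total_reads, meta$sample_id)[scols]
    rk <- rpkm(cm, ct$gene_len_nt, rep(tr, each = nrow(cm)))
    relabund[[nm]] <- phylotype_relative_abundance(rk, mb)
    pt_rpkm[[nm]] <- rowsum(rk, mb$phylotype_id[match(rownames(rk), mb$sequence_id)])
    write_tsv(as.data.frame(relabund[[nm]]),
              file.path(prof_dir, paste0(nm, "_relabund.tsv")),
              rownames_as = "phylotype_id")
  }
  toc("profile", t0)

  ## stage: diversity --------------------------------------------------------
  t0 <- tic(); log_stage("diversity: %d families", length(relabund))
  div_dir <- file.path(out_dir, "diversity")
  dir.create(div_dir, showWarnings = FALSE)
  diversity <- list(); decay <- list()
  for (nm in names(relabund)) {
    cp <- cumulative_profiles(pt_rpkm[[nm]])
    diversity[[nm]] <- cp$profile
    write_tsv(cp$profile, file.path(div_dir, paste0(nm, "_diversity.tsv")))
    dd <- distance_decay(relabund[[nm]])
    decay[[nm]] <- dd
    write_tsv(dd$pairs, file.path(div_dir, paste0(nm, "_braycurtis_pairs.tsv")))
  }
  turnover <- turnover_summary(relabund)
  write_tsv(turnover, file.path(div_dir, "turnover_summary.tsv"))
  toc("diversity", t0)

  ## stage: stats ------------------------------------------------------------
  t0 <- tic(); log_stage("stats: regression grid + family tests")
  stat_dir <- file.path(out_dir, "stats")
  dir.create(stat_dir, showWarnings = FALSE)
  gene_fams <- setdiff(names(relabund), "marker")
  metrics <- do.call(rbind, lapply(gene_fams, function(nm) {
    prof <- diversity[[nm]]
    t_index <- env$t_index[match(prof$sample_id, env$sample_id)]
    out <- rbind(
      data.frame(gene = nm, metric = "richness", t_index = t_index,
                 value = prof$richness, stringsAsFactors = FALSE),
      data.frame(gene = nm, metric = "inv_simpson", t_index = t_index,
                 value = prof$inv_simpson, stringsAsFactors = FALSE))
    if (nm %in% rownames(per_capita))
      out <- rbind(out, data.frame(gene = nm, metric = "abundance",
                                   t_index = env$t_index[match(colnames(per_capita), env$sample_id)],
                                   value = per_capita[nm, ],
                                   stringsAsFactors = FALSE))
    out
  }))
  grid <- env_regression_grid(metrics, env)
  write_tsv(grid, file.path(stat_dir, "env_regression_grid.tsv"))
  write_tsv(as.data.frame(pearson_correlation_matrix(
    env[c("temp_c", "do_mgL", "cl_mgL", "npoc_mgL")])),
    file.path(stat_dir, "env_correlation.tsv"), rownames_as = "covariate")

  family_tests <- list()
  if (length(gene_fams) >= 2L) {
    prs <- combn(gene_fams, 2L)
    for (q in seq_len(ncol(prs))) {
      a <- prs[1L, q]; b <- prs[2L, q]
      wt <- tryCatch(welch_t_test(diversity[[a]]$richness, diversity[[b]]$richness),
                     error = function(e) NULL)
      lv <- tryCatch(family_variability_test(relabund[c(a, b)]),
                     error = function(e) NULL)
      mw <- if (a %in% rownames(per_capita) && b %in% rownames(per_capita))
        mann_whitney(per_capita[a, ], per_capita[b, ]) else NULL
      add <- function(test, res) if (!is.null(res))
        family_tests[[length(family_tests) + 1L]] <<- data.frame(
          test = test, family_a = a, family_b = b,
          statistic = as.numeric(res$statistic[1L]),
          p_value = res$p_value, stringsAsFactors = FALSE)
      add("welch_richness", wt); add("levene_variability", lv)
      add("mann_whitney_per_capita", mw)
    }
    # early vs late per-capita abundance, per family
    early <- env$sample_id[env$period == "early"]
    late <- env$sample_id[env$period == "late"]
    for (nm in intersect(gene_fams, rownames(per_capita))) {
      mw <- mann_whitney(per_capita[nm, early], per_capita[nm, late])
      family_tests[[length(family_tests) + 1L]] <- data.frame(
        test = "mann_whitney_early_late", family_a = nm, family_b = nm,
        statistic = as.numeric(mw$statistic), p_value = mw$p_value,
        stringsAsFactors = FALSE)
    }
  }
  family_tests <- if (length(family_tests)) do.call(rbind, family_tests) else
    data.frame(test = character(0), family_a = character(0),
               family_b = character(0), statistic = numeric(0),
               p_value = numeric(0))
  write_tsv(family_tests, file.path(stat_dir, "family_tests.tsv"))
  toc("stats", t0)

  ## manifest ----------------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  checksums <- tools::md5sum(files)
  names(checksums) <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out_dir), "/?"),
                          "", names(checksums))
  manifest <- list(
    package = "genediv",
    version = as.character(utils::packageVersion("genediv")),
    seed = as.integer(seed),
    config = config_snapshot(cfg),
    stage_seconds = as.list(timings),
    total_seconds = round(as.numeric(Sys.time() - t_all, units = "secs"), 3),
    checksums = as.list(checksums))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_stage("done in %.1f s; manifest at %s", manifest$total_seconds, manifest_path)
  invisible(structure(list(env = env, turnover = turnover,
                           per_capita = per_capita, diversity = diversity,
                           relabund = relabund, grid = grid,
                           family_tests = family_tests, decay = decay,
                           manifest = manifest, out_dir = out_dir),
                      class = "genediv_run"))
}

# Flatten the config into plain lists so every default (variance estimator,
# identity denominator, pooling rule) is auditable in the manifest.
config_snapshot <- function(cfg) {
  strip <- function(x) {
    if (inherits(x, c("clustering_params", "recruitment_params",
                      "regime_params"))) x <- unclass(x)
    if (is.list(x)) lapply(x, strip) else x
  }
  snap <- strip(cfg)
  snap$conventions <- list(
    variance_estimator = "unbiased (n-1), zeros included for unobserved timepoints",
    identity_denominator = cfg$clustering$identity_denominator,
    cumulative_pooling = "sum RPKM across samples, then renormalize",
    multimapping = "best hit, ties to lexicographically smallest reference id")
  snap
}

#' @export
print.genediv_run <- function(x, ...) {
  cat(sprintf("genediv_run: %d families, %d samples -> %s\n",
              nrow(x$turnover), nrow(x$env), x$out_dir))
  print(x$turnover)
  invisible(x)
}
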