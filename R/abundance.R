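#' Read-recruitment parameters
#'
#' @param min_nucleotide_identity minimum identity of the read against the
#'   reference window for an assignment (default 0.95).
#' @param min_alignment_len_nt minimum aligned length; default (`NULL`) is
#'   0.8 x read length. Recruitment compares the full read against an
#'   ungapped reference window, so reads shorter than this are discarded.
#' @param kmer_seed_len exact-match seed length used to locate candidate
#'   reference windows (default 16).
#' @return an object of class `recruitment_params`.
#' @export
recruitment_params <- function(min_nucleotide_identity = 0.95,
                               min_alignment_len_nt = NULL,
                               kmer_seed_len = 16L) {
  min_nucleotide_identity <- check_fraction(min_nucleotide_identity,
                                            "min_nucleotide_identity")
  if (min_nucleotide_identity <= 0)
    stop_param("`min_nucleotide_identity` must be in (0, 1]")
  kmer_seed_len <- check_count(kmer_seed_len, "kmer_seed_len", 4L)
  structure(list(min_nucleotide_identity = min_nucleotide_identity,
                 min_alignment_len_nt = min_alignment_len_nt,
                 kmer_seed_len = kmer_seed_len),
            class = "recruitment_params")
}

#' Recruit reads to reference gene sequences
#'
#' Best-hit assignment of each read to at most one reference: k-mer seeds
#' taken from the start, middle and end of the read locate candidate
#' reference offsets by exact match, the full read is then compared to the
#' implied ungapped reference window, and the best-identity candidate passing
#' the identity and length thresholds wins. Ties are broken by the
#' lexicographically smallest reference id. Reads matching nothing at the
#' threshold are counted as unassigned.
#'
#' @param reads named character vector or `DNAStringSet` of reads.
#' @param references named character vector or `DNAStringSet` of reference
#'   coding sequences (nonempty).
#' @param params a [recruitment_params()] object.
#' @return list with `counts` (named integer, one entry per reference,
#'   including zeros), `assignments` (data.frame `read_id`, `ref_id`,
#'   `identity`), and `n_unassigned`.
#' @export
recruit_reads <- function(reads, references, params = recruitment_params()) {
  refs <- as_named_seqs(references, "reference")
  if (!length(refs)) stop_param("`references` must be nonempty")
  counts <- setNames(integer(length(refs)), names(refs))
  rds <- if (length(reads)) as_named_seqs(reads, "read") else character(0)
  if (!length(rds)) {
    warning("empty read set: returning all-zero counts")
    return(list(counts = counts,
                assignments = data.frame(read_id = character(0),
                                         ref_id = character(0),
                                         identity = numeric(0)),
                n_unassigned = 0L))
  }
  L <- unique(nchar(rds))
  if (length(L) != 1L)
    stop_param("reads must have uniform length (got %d distinct lengths)",
               length(L))
  k <- params$kmer_seed_len
  if (k > L) stop_param("kmer_seed_len exceeds read length")
  min_len <- if (is.null(params$min_alignment_len_nt)) ceiling(0.8 * L) else
    params$min_alignment_len_nt
  if (L < min_len)
    stop_param("read length %d below min_alignment_len_nt %d", L, min_len)

  # reference k-mer index (every offset)
  ref_len <- nchar(refs)
  idx <- data.table::rbindlist(lapply(names(refs), function(r) {
    n <- ref_len[[r]] - k + 1L
    if (n < 1L) return(NULL)
    data.table::data.table(kmer = substring(refs[[r]], 1:n, k:(k + n - 1L)),
                           ref = r, rpos = 1:n)
  }))
  data.table::setkey(idx, kmer)

  seed_pos <- unique(c(1L, as.integer((L - k) %/% 2L) + 1L, L - k + 1L))
  seeds <- data.table::rbindlist(lapply(seed_pos, function(sp)
    data.table::data.table(read = seq_along(rds),
                           kmer = substring(rds, sp, sp + k - 1L),
                           spos = sp)))
  cand <- idx[seeds, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  ident <- NULL; offset <- NULL; read <- NULL; ref <- NULL  # NSE notes
  cand[, offset := rpos - spos + 1L]
  cand <- cand[offset >= 1L & offset + L - 1L <= ref_len[ref]]
  cand <- unique(cand, by = c("read", "ref", "offset"))

  if (nrow(cand)) {
    win <- substring(refs[cand$ref], cand$offset, cand$offset + L - 1L)
    rstr <- rds[cand$read]
    mm <- integer(nrow(cand))
    ne <- which(rstr != win)
    for (j in ne)
      mm[j] <- sum(charToRaw(rstr[j]) != charToRaw(win[j]))
    cand[, ident := 1 - mm / L]
    cand <- cand[ident >= params$min_nucleotide_identity]
  }
  if (nrow(cand)) {
    data.table::setorder(cand, read, -ident, ref)
    best <- cand[!duplicated(read)]
    tab <- table(best$ref)
    counts[names(tab)] <- as.integer(tab)
    assignments <- data.frame(read_id = names(rds)[best$read],
                              ref_id = best$ref, identity = best$ident,
                              stringsAsFactors = FALSE)
  } else {
    assignments <- data.frame(read_id = character(0), ref_id = character(0),
                              identity = numeric(0))
  }
  list(counts = counts, assignments = assignments,
       n_unassigned = length(rds) - nrow(assignments))
}

#' Reads per kilobase of gene length per million reads
#'
#' `RPKM = read_count / (gene_len_nt / 1000) / (total_reads / 1e6)`.
#' Vectorized over its arguments.
#'
#' @param read_count non-negative read counts.
#' @param gene_len_nt gene lengths in nucleotides (> 0).
#' @param total_reads per-sample library sizes (> 0).
#' @return RPKM values.
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(read_count, gene_len_nt, total_reads) {
  if (any(total_reads <= 0))
    stop_param("total_reads must be > 0 (empty sample)")
  if (any(gene_len_nt <= 0)) stop_param("gene_len_nt must be > 0")
  if (any(read_count < 0)) stop_param("read_count must be >= 0")
  read_count / (gene_len_nt / 1000) / (total_reads / 1e6)
}

#' Per-capita gene abundance relative to a single-copy marker
#'
#' Summed gene RPKM divided by summed marker RPKM (the marker sum pools all
#' marker forms, e.g. bacterial and archaeal). With a universal single-copy
#' marker this estimates the fraction of individuals carrying the gene.
#' Matrix inputs (member x sample) give one estimate per sample; samples with
#' zero marker signal yield `NA` with a warning.
#'
#' @param gene_rpkm numeric vector (members) or matrix (members x samples).
#' @param marker_rpkm marker RPKM values, same shape convention.
#' @return scalar or per-sample named vector of carriage fractions.
#' @examples
#' per_capita_abundance(30, 120)  # 0.25
#' @export
per_capita_abundance <- function(gene_rpkm, marker_rpkm) {
  gs <- if (is.matrix(gene_rpkm)) colSums(gene_rpkm) else sum(gene_rpkm)
  ms <- if (is.matrix(marker_rpkm)) colSums(marker_rpkm) else sum(marker_rpkm)
  if (length(gs) != length(ms))
    stop_param("gene and marker series must cover the same samples")
  bad <- ms <= 0
  if (any(bad)) {
    warning(sprintf("zero marker signal in %d sample(s); per-capita set to NA",
                    sum(bad)))
    ms[bad] <- NA_real_
  }
  gs / ms
}

#' Collapse member-sequence RPKM to phylotype relative abundance
#'
#' Member rows are summed into phylotype rows, then each sample column is
#' divided by its column sum. Columns with zero total stay all-zero and are
#' flagged in the `"not_observed"` attribute (grey columns in a heatmap).
#'
#' @param mat numeric matrix, rows = sequence (or phylotype) ids, columns =
#'   samples.
#' @param membership data.frame with `sequence_id` and `phylotype_id`
#'   covering every row of `mat`.
#' @return phylotype x sample matrix of relative abundances with attribute
#'   `not_observed` (logical per column).
#' @export
phylotype_relative_abundance <- function(mat, membership) {
  stopifnot(is.matrix(mat))
  if (!all(rownames(mat) %in% membership$sequence_id))
    stop_param("membership does not cover row id(s): %s",
               paste(setdiff(rownames(mat), membership$sequence_id), collapse = ", "))
  pt <- membership$phylotype_id[match(rownames(mat), membership$sequence_id)]
  agg <- rowsum(mat, group = pt)
  tot <- colSums(agg)
  rel <- sweep(agg, 2, ifelse(tot > 0, tot, 1), "/")
  attr(rel, "not_observed") <- tot == 0
  rel
}
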