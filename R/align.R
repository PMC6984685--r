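#' Clustering parameters
#'
#' Scoring and threshold settings used to define phylotypes by greedy centroid
#' clustering of protein sequences. Defaults follow common practice for
#' protein global alignment: BLOSUM62 scoring with affine gaps (open 11,
#' extend 1) and a 90% amino-acid identity threshold, the level of similarity
#' typical between organisms of the same genus.
#'
#' @param threshold identity fraction in (0, 1] at which a sequence joins an
#'   existing phylotype representative (default 0.90).
#' @param matrix name of the substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend non-negative gap penalties (positive numbers;
#'   they are applied as costs).
#' @param ordering rule that fixes the greedy pass order: `"length_desc"`
#'   (default) or `"abundance_desc"`; ties are always broken lexicographically
#'   by sequence id so clustering is deterministic.
#' @param identity_denominator `"alignment"` (default: identical pairs divided
#'   by all alignment columns, gaps included) or `"shorter"` (divided by the
#'   shorter sequence length).
#' @return an object of class `clustering_params`.
#' @export
clustering_params <- function(threshold = 0.90, matrix = "BLOSUM62",
                              gap_open = 11, gap_extend = 1,
                              ordering = c("length_desc", "abundance_desc"),
                              identity_denominator = c("alignment", "shorter")) {
  threshold <- check_fraction(threshold, "threshold")
  if (threshold <= 0) stop_param("`threshold` must be in (0, 1]")
  if (gap_open < 0 || gap_extend < 0)
    stop_param("gap penalties must be non-negative costs")
  structure(list(threshold = threshold, matrix = matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 ordering = match.arg(ordering),
                 identity_denominator = match.arg(identity_denominator)),
            class = "clustering_params")
}

AA_ALPHABET_STRICT <- c("A","R","N","D","C","Q","E","G","H","I",
                        "L","K","M","F","P","S","T","W","Y","V")

validate_protein <- function(seqs, ids = names(seqs)) {
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET_STRICT, collapse = "")),
                   seqs[[i]])
    if (bad > 0L)
      stop_param("invalid residue '%s' in sequence '%s' at position %d",
                 substr(seqs[[i]], bad, bad),
                 if (is.null(ids)) as.character(i) else ids[i], bad)
    if (!nzchar(seqs[[i]]))
      stop_param("sequence '%s' is empty",
                 if (is.null(ids)) as.character(i) else ids[i])
  }
  invisible(TRUE)
}

.sub_matrix_cache <- new.env(parent = emptyenv())

get_sub_matrix <- function(name) {
  if (!exists(name, envir = .sub_matrix_cache, inherits = FALSE)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .sub_matrix_cache)
  }
  get(name, envir = .sub_matrix_cache, inherits = FALSE)
}

# Vectorized identity of one query against many targets. Every pair is
# aligned in canonical (lexicographic) order so identity is exactly symmetric
# even when co-optimal alignments differ in column count.
align_identity_many <- function(query, targets, params = clustering_params()) {
  sm <- get_sub_matrix(params$matrix)
  ident <- numeric(length(targets))
  fwd <- targets <= query   # canonical order: pattern is the smaller string
  for (grp in list(which(fwd), which(!fwd))) {
    if (!length(grp)) next
    if (fwd[grp[1]]) {
      pat <- Biostrings::AAStringSet(targets[grp]); sub <- Biostrings::AAString(query)
    } else {
      pat <- Biostrings::AAStringSet(rep(query, length(grp)))
      sub <- Biostrings::AAStringSet(targets[grp])
    }
    al <- Biostrings::pairwiseAlignment(pat, sub, type = "global",
                                        substitutionMatrix = sm,
                                        gapOpening = params$gap_open,
                                        gapExtension = params$gap_extend)
    # alignment columns = aligned-region width (internal gaps included,
    # nchar(al)) plus terminal-gap columns outside the aligned region
    p <- Biostrings::pattern(al); s <- Biostrings::subject(al)
    len_p <- nchar(if (fwd[grp[1]]) targets[grp] else rep(query, length(grp)))
    len_s <- if (fwd[grp[1]]) nchar(query) else nchar(targets[grp])
    ncol_aln <- Biostrings::nchar(al) +
      (Biostrings::start(p) - 1L) + (len_p - Biostrings::end(p)) +
      (Biostrings::start(s) - 1L) + (len_s - Biostrings::end(s))
    denom <- switch(params$identity_denominator,
                    alignment = ncol_aln,
                    shorter = pmin(nchar(targets[grp]), nchar(query)))
    ident[grp] <- Biostrings::nmatch(al) / denom
  }
  ident
}

#' Global-alignment amino-acid identity
#'
#' Needleman-Wunsch global alignment of two protein sequences under the
#' scoring in `params`; identity is the number of identical aligned residue
#' pairs divided by the total number of alignment columns (gap columns count
#' in the denominator). The function is symmetric: `f(a, b) == f(b, a)`.
#'
#' @param seq_a,seq_b protein sequences (single strings); invalid residues
#'   raise an error naming the offending position.
#' @param params a [clustering_params()] object.
#' @return identity fraction in `[0, 1]`.
#' @examples
#' global_align_identity("AAAA", "AATA")  # 0.75
#' @export
global_align_identity <- function(seq_a, seq_b, params = clustering_params()) {
  stopifnot(is.character(seq_a) || inherits(seq_a, "AAString"),
            is.character(seq_b) || inherits(seq_b, "AAString"))
  a <- as.character(seq_a); b <- as.character(seq_b)
  nm <- c(if (!is.null(names(seq_a))) names(seq_a) else "seq_a",
          if (!is.null(names(seq_b))) names(seq_b) else "seq_b")
  validate_protein(c(a, b), nm)
  align_identity_many(a, b, params)
}
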