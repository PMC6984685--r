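#' Greedy centroid clustering of protein sequences into phylotypes
#'
#' CD-HIT-style greedy clustering: sequences are visited in a deterministic
#' order (longest first by default, ties broken lexicographically by id); each
#' sequence joins the first existing phylotype whose representative it matches
#' at `params$threshold` global-alignment identity, otherwise it founds a new
#' phylotype and becomes its representative. Representatives are compared in
#' founding order, so the partition is reproducible.
#'
#' @param sequences named character vector or `AAStringSet` of protein
#'   sequences; ids must be unique.
#' @param params a [clustering_params()] object; the identity threshold
#'   defaults to 0.90 (phylotypes at 90% amino-acid identity).
#' @param abundance optional named numeric vector (same ids) used when
#'   `params$ordering == "abundance_desc"`.
#' @param family gene-family label carried through to outputs.
#' @return an object of class `phylotype_set`: a list with `membership`
#'   (data.frame `sequence_id`, `phylotype_id`, `representative_flag`,
#'   `identity_to_rep`), `representatives` (named character vector of
#'   representative sequences, one per phylotype in founding order),
#'   `family`, and `params`.
#' @export
greedy_cluster <- function(sequences, params = clustering_params(),
                           abundance = NULL, family = "gene") {
  seqs <- as_named_seqs(sequences)
  if (!length(seqs)) stop_param("need at least one sequence")
  validate_protein(seqs)
  ids <- names(seqs)
  key <- switch(params$ordering,
    length_desc = -nchar(seqs),
    abundance_desc = {
      if (is.null(abundance) || !all(ids %in% names(abundance)))
        stop_param("`abundance` must name every sequence id for abundance_desc ordering")
      -as.numeric(abundance[ids])
    })
  ord <- order(key, ids)
  seqs <- seqs[ord]; ids <- ids[ord]

  rep_seq <- character(0); rep_id <- character(0)
  assign_pt <- integer(length(seqs)); ident_rep <- numeric(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    if (length(rep_seq)) {
      idn <- align_identity_many(seqs[[i]], rep_seq, params)
      ok <- which(idn >= params$threshold)
      if (length(ok)) { hit <- ok[1L]; ident_rep[i] <- idn[hit] }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, seqs[[i]]); rep_id <- c(rep_id, ids[i])
      hit <- length(rep_seq); ident_rep[i] <- 1
    }
    assign_pt[i] <- hit
  }
  pt_ids <- sprintf("PT%03d", seq_along(rep_seq))
  names(rep_seq) <- rep_id
  membership <- data.frame(
    sequence_id = ids,
    phylotype_id = pt_ids[assign_pt],
    representative_flag = ids %in% rep_id,
    identity_to_rep = ident_rep,
    stringsAsFactors = FALSE)
  # invariant: every member meets the threshold against its representative
  stopifnot(all(membership$identity_to_rep >= params$threshold))
  structure(list(membership = membership, representatives = rep_seq,
                 phylotype_ids = pt_ids, family = family, params = params),
            class = "phylotype_set")
}

#' @export
print.phylotype_set <- function(x, ...) {
  cat(sprintf("phylotype_set: family '%s', %d sequences in %d phylotypes (threshold %.2f)\n",
              x$family, nrow(x$membership), length(x$representatives),
              x$params$threshold))
  invisible(x)
}

#' UPGMA guide tree over phylotype representatives
#'
#' Builds an ultrametric UPGMA (average-linkage) tree on the distance
#' `d = 1 - global_align_identity` between representatives, and returns it as
#' newick text. The tree is used only to order heatmap rows by sequence
#' similarity; branch-length fidelity is a non-goal. Leaves are sorted
#' lexicographically before clustering so merge order is deterministic under
#' tied distances.
#'
#' @param representatives named character vector or `AAStringSet` of
#'   representative protein sequences (ids become leaf labels).
#' @param params a [clustering_params()] object for the pairwise alignments.
#' @return a newick string (single-leaf input returns `"id;"`).
#' @export
build_guide_tree <- function(representatives, params = clustering_params()) {
  seqs <- as_named_seqs(representatives, "representative")
  validate_protein(seqs)
  if (length(seqs) == 1L) return(paste0(names(seqs), ";"))
  seqs <- seqs[order(names(seqs))]
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    idn <- align_identity_many(seqs[[i]], seqs[(i + 1L):n], params)
    D[i, (i + 1L):n] <- D[(i + 1L):n, i] <- 1 - idn
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}

#' Leaf order of a newick guide tree
#'
#' @param newick newick string as produced by [build_guide_tree()].
#' @return character vector of leaf labels in plotting (ladder) order.
#' @export
guide_tree_leaf_order <- function(newick) {
  if (!grepl("\\(", newick)) return(sub(";$", "", newick))
  phy <- ape::read.tree(text = newick)
  phy$tip.label[phy$edge[phy$edge[, 2] <= length(phy$tip.label), 2]]
}
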