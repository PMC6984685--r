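#' Read a FASTA file
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return named character vector of sequences; duplicate ids are an error.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- switch(type,
              AA = Biostrings::readAAStringSet(path),
              DNA = Biostrings::readDNAStringSet(path))
  s <- as.character(x)
  names(s) <- sub("\\s.*$", "", names(s))   # id = first whitespace token
  dup <- names(s)[duplicated(names(s))]
  if (length(dup))
    stop_param("duplicate FASTA id(s) in %s: %s", path,
               paste(unique(dup), collapse = ", "))
  s
}

#' Write sequences as FASTA (60-column wrap)
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  seqs <- as_named_seqs(seqs)
  x <- switch(type,
              AA = Biostrings::AAStringSet(seqs),
              DNA = Biostrings::DNAStringSet(seqs))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write reads as FASTQ (Phred+33, constant Q30)
#'
#' @param reads named character vector of reads.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(reads)) {
    qual <- vapply(nchar(reads), function(n)
      paste(rep("?", n), collapse = ""), "")   # "?" = Q30 in Phred+33
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Read a FASTQ file (sequences only)
#'
#' @param path FASTQ file.
#' @return named character vector of reads.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  s <- as.character(x)
  names(s) <- sub("\\s.*$", "", names(s))
  s
}

#' Read a TSV table
#'
#' @param path file with a header row.
#' @param required column names that must be present.
#' @return data.frame; ragged rows or missing columns are errors naming the
#'   line or column.
#' @export
read_tsv <- function(path, required = NULL) {
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop_param("ragged TSV %s: line %d has %d fields (expected %d)",
               path, which(nf != nf[1L])[1L], nf[nf != nf[1L]][1L], nf[1L])
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_param("TSV %s is missing column(s): %s", path,
               paste(miss, collapse = ", "))
  df
}

#' Write a TSV table
#'
#' @param df data.frame.
#' @param path output file.
#' @param rownames_as column name under which to emit row names, or `NULL`.
#' @export
write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                         rownames_as),
                as.data.frame(df, stringsAsFactors = FALSE))
    rownames(df) <- NULL
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write newick text to a file
#'
#' @param newick newick string.
#' @param path output file.
#' @export
write_newick <- function(newick, path) {
  writeLines(newick, path)
  invisible(path)
}
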