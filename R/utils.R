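#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rgamma rbinom rmultinom var pt pf pnorm sd runif
#'   median p.adjust setNames hclust as.dist
#' @importFrom utils read.delim write.table count.fields head combn
NULL

# use data.table [ semantics without importing its whole namespace
.datatable.aware <- TRUE

# Evaluate `code` under a temporary RNG state seeded with `seed`; restore the
# caller's RNG afterwards. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop_param("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop_param("`%s` must be a number in [%g, %g]", name, lo, hi)
  as.numeric(x)
}

# Coerce a character vector / XStringSet to a named character vector of
# sequences, requiring unique non-empty ids.
as_named_seqs <- function(x, what = "sequence") {
  ids <- names(x)
  s <- as.character(x)
  names(s) <- ids
  if (is.null(ids) || any(!nzchar(ids)))
    stop_param("all %ss must be named with non-empty ids", what)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_param("duplicate %s id(s): %s", what, paste(unique(dup), collapse = ", "))
  s
}
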