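# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that a single explicit seed per call reproduces results
#' byte-for-byte without clobbering the session RNG.
#'
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param code code to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Depth-normalize a count matrix to counts per 10,000
#'
#' Scales every column (cell or sample) to a total of 10,000 so that
#' expression values are comparable across columns of different sequencing
#' depth.  All-zero columns are left at zero.
#'
#' @param counts genes x columns non-negative matrix.
#' @return matrix of the same shape on the counts-per-10,000 scale.
#' @export
cp10k <- function(counts) {
  counts <- as.matrix(counts)
  tot <- colSums(counts)
  tot[tot == 0] <- 1  # all-zero columns stay zero
  sweep(counts, 2L, tot / 1e4, "/")
}

# Validate a genes x columns count matrix: unique ids, no negatives.
check_count_matrix <- function(counts, what = "count matrix") {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(what, " must carry gene rownames and column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop(what, ": duplicate gene id '",
         rownames(counts)[duplicated(rownames(counts))][1L], "'",
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop(what, ": duplicate column id '",
         colnames(counts)[duplicated(colnames(counts))][1L], "'",
         call. = FALSE)
  if (any(counts < 0))
    stop(what, " contains negative entries", call. = FALSE)
  invisible(counts)
}

# Column z-score with the sample (n-1) standard deviation; constant columns
# map to zeros rather than NaN.
zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  z <- sweep(x, 2L, mu, "-")
  ok <- is.finite(sdv) & sdv > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, sdv[ok], "/")
  z[, !ok] <- 0
  z
}
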