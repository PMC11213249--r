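# Signature-matrix construction from a labelled single-cell reference.
#
# The builder follows the published conventions of signature-based
# deconvolution: genes are pre-filtered on total abundance, per-type
# markers are ranked by a one-vs-rest Wilcoxon rank-sum test on
# depth-normalized expression (BH-corrected) and then by fold change, and
# the marker count per type is chosen to minimize the 2-norm condition
# number of the resulting basis.  Quantile normalization is deliberately
# not applied anywhere; all values stay on the linear scale.

#' Filter genes on total abundance
#'
#' Retains genes whose natural-log total read count lies inside
#' `[low, high]` (inclusive), removing genes that are very lowly or very
#' highly expressed.  Genes with a zero total are always removed.
#'
#' @param counts genes x cells non-negative matrix.
#' @param low,high bounds on `ln(total read count)`; defaults 4 and 10.
#' @return the retained gene ids (character vector).
#' @export
filter_genes <- function(counts, low = 4, high = 10) {
  if (low >= high) stop("low bound must be below high bound", call. = FALSE)
  check_count_matrix(counts)
  tot <- rowSums(counts)
  keep <- tot > 0 & log(pmax(tot, 1e-300)) >= low & log(pmax(tot, 1e-300)) <= high
  if (!any(keep))
    stop("no genes pass the ln(total count) filter [", low, ", ", high,
         "]; consider widening the bounds", call. = FALSE)
  rownames(counts)[keep]
}

# Vectorized one-vs-rest Wilcoxon rank-sum tests for every gene x type,
# using the normal approximation with tie correction and continuity
# correction (matching wilcox.test(exact = FALSE, correct = TRUE)).
# Returns list of genes x types matrices: p-values and group means.
rank_marker_tests <- function(norm, labels) {
  types <- sort(unique(labels))
  n <- as.numeric(ncol(norm))
  ind <- vapply(types, function(ty) as.numeric(labels == ty),
                numeric(ncol(norm)))
  n1 <- colSums(ind)

  ranks <- t(apply(norm, 1L, rank))         # genes x cells, average ranks
  # tie correction term per gene: sum over tied groups of (t^3 - t)
  tie_term <- apply(norm, 1L, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })

  R1 <- ranks %*% ind                        # genes x types rank sums
  W <- sweep(R1, 2L, n1 * (n1 + 1) / 2, "-") # Mann-Whitney U of the group
  n2 <- n - n1
  mu <- n1 * n2 / 2
  sig2 <- outer(1 - tie_term / (n * (n - 1) * (n + 1)),
                n1 * n2 * (n + 1) / 12)
  z <- sweep(W, 2L, mu, "-")
  z <- z - sign(z) * 0.5                     # continuity correction
  p <- 2 * stats::pnorm(-abs(z) / sqrt(pmax(sig2, .Machine$double.eps)))
  p[sig2 == 0] <- 1
  p <- pmin(p, 1)

  means <- (norm %*% ind) / rep(n1, each = nrow(norm))
  tot_mean <- rowMeans(norm)
  rest_means <- sweep(-sweep(means, 2L, n1, "*"), 1L, tot_mean * n, "+") /
    rep(n2, each = nrow(norm))
  dimnames(p) <- dimnames(means) <- dimnames(rest_means) <-
    list(rownames(norm), types)
  list(p = p, means = means, rest_means = rest_means, types = types)
}

#' Build a marker-gene signature matrix from a labelled reference
#'
#' For each cell type, genes are tested one-vs-rest with a two-sided
#' Wilcoxon rank-sum test on counts-per-10,000 expression, corrected by
#' Benjamini-Hochberg within type; candidates with `q < q_threshold` and
#' fold change above 1 are ranked by fold change (ties broken by gene id).
#' For every marker count `g` in `markers_range` the top-`g` markers of
#' every type form a candidate signature (per-type mean counts-per-10,000
#' over the marker union, linear scale); the `g` minimizing the 2-norm
#' condition number is kept.
#'
#' @param counts genes x cells count matrix (typically already restricted
#'   to [filter_genes()] survivors).
#' @param labels named character vector mapping each cell to its type.
#' @param markers_range integer interval `c(min, max)` of markers per type
#'   to scan.
#' @param q_threshold BH-adjusted significance cutoff for markers.
#' @return a `cell_signature` object: `values` (marker genes x types,
#'   linear scale), `condition_number`, `markers_per_type_used`,
#'   `marker_stats` (per-type candidate counts), and the parameters used.
#' @export
build_signature <- function(counts, labels, markers_range = c(50L, 150L),
                            q_threshold = 0.3) {
  check_count_matrix(counts)
  if (is.null(names(labels)))
    labels <- stats::setNames(labels, colnames(counts))
  labels <- labels[colnames(counts)]
  if (anyNA(labels)) stop("labels missing for some cells", call. = FALSE)
  types <- sort(unique(labels))
  if (length(types) < 2L) stop("need at least 2 cell types", call. = FALSE)
  sizes <- table(labels)
  if (any(sizes < 3L))
    stop("cell type '", names(sizes)[which(sizes < 3L)[1L]],
         "' has fewer than 3 cells", call. = FALSE)
  stopifnot(length(markers_range) == 2L,
            markers_range[1L] >= 1L,
            markers_range[1L] <= markers_range[2L])

  norm <- cp10k(counts)
  tst <- rank_marker_tests(norm, labels)
  q <- apply(tst$p, 2L, stats::p.adjust, method = "BH")
  fc <- (tst$means + 1) / (tst$rest_means + 1)

  candidates <- lapply(types, function(ty) {
    ok <- which(q[, ty] < q_threshold & fc[, ty] > 1)
    if (!length(ok))
      stop("cell type '", ty, "' has no significant markers at q < ",
           q_threshold, call. = FALSE)
    ids <- rownames(q)[ok]
    ids[order(-fc[ok, ty], ids)]
  })
  names(candidates) <- types

  g_max_avail <- min(vapply(candidates, length, 1L))
  g_lo <- min(markers_range[1L], g_max_avail)
  g_hi <- min(markers_range[2L], g_max_avail)
  best <- NULL
  for (g in seq.int(g_lo, g_hi)) {
    marker_union <- sort(unique(unlist(lapply(candidates, utils::head, g))))
    S <- tst$means[marker_union, , drop = FALSE]
    d <- svd(S, nu = 0, nv = 0)$d
    kap <- if (min(d) > 0) max(d) / min(d) else Inf
    if (is.null(best) || kap < best$kappa)
      best <- list(g = g, kappa = kap, S = S)
  }
  if (!is.finite(best$kappa) || best$kappa > 1e6)
    warning("signature matrix is near-singular (condition number ",
            format(best$kappa, digits = 3),
            "); cell types may be indistinguishable")
  if (any(colSums(best$S) == 0))
    stop("signature has an all-zero cell-type column", call. = FALSE)

  structure(list(values = best$S,
                 condition_number = best$kappa,
                 markers_per_type_used = best$g,
                 marker_stats = vapply(candidates, length, 1L),
                 q_threshold = q_threshold,
                 markers_range = c(g_lo, g_hi)),
            class = "cell_signature")
}

#' @exportS3Method base::print
print.cell_signature <- function(x, ...) {
  cat("Cell-type signature matrix:", nrow(x$values), "marker genes x",
      ncol(x$values), "cell types\n")
  cat("  markers per type:", x$markers_per_type_used,
      " condition number:", format(x$condition_number, digits = 4), "\n")
  invisible(x)
}

#' Write a signature matrix as TSV with a parameter header comment
#' @param signature a `cell_signature`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "cell_signature"))
  hdr <- sprintf(
    "# celldecon signature | markers_per_type=%d | q_threshold=%g | condition_number=%.6g",
    signature$markers_per_type_used, signature$q_threshold,
    signature$condition_number)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  tab <- data.frame(gene = rownames(signature$values), signature$values,
                    check.names = FALSE)
  utils::write.table(format(tab, digits = 6), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
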