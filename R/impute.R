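# Group-level cell-type expression imputation: regress each gene's bulk
# expression across samples on the fraction trajectories of the abundant
# cell types (plus a pooled "other" column), recovering per-type mean
# expression for a gene set of interest.

#' Impute group-level cell-type expression from fractions
#'
#' Cell types are ranked by mean fraction; the `n_abundant` most abundant
#' are retained and the remainder collapsed into an `other` column whose
#' fractions are summed.  For each requested gene the across-samples
#' system `bulk_gene ~ fractions_reduced %*% h_gene, h >= 0` is solved by
#' non-negative least squares.
#'
#' @param bulk genes x samples matrix.
#' @param fractions a `decon_fit` or a samples x types fraction matrix.
#' @param gene_set character vector of genes to impute (e.g. genes
#'   up-/down-regulated between bolted and unbolted plants); genes absent
#'   from `bulk` are dropped with a message.
#' @param n_abundant abundant types to retain; default 9 (plus "other").
#' @return an `imputed_profiles` object: `values` (types x genes,
#'   non-negative), `types_used`, `degenerate` flag (rank-deficient
#'   fraction design).
#' @export
impute_group_expression <- function(bulk, fractions, gene_set,
                                    n_abundant = 9L) {
  if (inherits(fractions, "decon_fit")) fractions <- coef(fractions)
  fractions <- as.matrix(fractions)
  bulk <- as.matrix(bulk)
  keep_samples <- rownames(fractions)
  if (!is.null(keep_samples) && !is.null(colnames(bulk))) {
    if (!all(keep_samples %in% colnames(bulk)))
      stop("fraction rows and bulk columns do not match", call. = FALSE)
    bulk <- bulk[, keep_samples, drop = FALSE]
  } else if (ncol(bulk) != nrow(fractions)) {
    stop("fraction rows and bulk columns do not match", call. = FALSE)
  }

  missing <- setdiff(gene_set, rownames(bulk))
  if (length(missing))
    message("impute_group_expression: ", length(missing),
            " gene(s) absent from bulk, dropped")
  genes <- intersect(gene_set, rownames(bulk))
  if (!length(genes)) stop("no requested gene found in bulk", call. = FALSE)

  ord <- order(colMeans(fractions), decreasing = TRUE)
  n_abundant <- min(n_abundant, ncol(fractions))
  keep <- colnames(fractions)[ord[seq_len(n_abundant)]]
  rest <- setdiff(colnames(fractions), keep)
  Fmat <- fractions[, keep, drop = FALSE]
  if (length(rest))
    Fmat <- cbind(Fmat, other = rowSums(fractions[, rest, drop = FALSE]))
  if (nrow(Fmat) < ncol(Fmat))
    stop("need at least as many samples (", nrow(Fmat),
         ") as retained types (", ncol(Fmat), ")", call. = FALSE)

  d <- svd(Fmat, nu = 0, nv = 0)$d
  degenerate <- min(d) <= 0 || max(d) / min(d) > 1e8
  if (degenerate)
    warning("fraction design is rank-deficient; imputed values are not ",
            "uniquely determined")

  vals <- matrix(0, ncol(Fmat), length(genes),
                 dimnames = list(colnames(Fmat), genes))
  for (g in genes)
    vals[, g] <- nnls_solve(Fmat, bulk[g, ])$x

  structure(list(values = vals, types_used = colnames(Fmat),
                 degenerate = degenerate),
            class = "imputed_profiles")
}

#' @exportS3Method base::print
print.imputed_profiles <- function(x, ...) {
  cat("Imputed cell-type profiles:", nrow(x$values), "types x",
      ncol(x$values), "genes",
      if (x$degenerate) "(degenerate design)" else "", "\n")
  invisible(x)
}

#' Assign genes to the cell types where they are expected to be expressed
#'
#' A gene is assigned to every type whose imputed expression is at least
#' `alpha` times the gene's maximum imputed expression; all-zero genes are
#' left unassigned.
#'
#' @param imputed an `imputed_profiles` object (or types x genes matrix).
#' @param alpha fraction of the row maximum required; default 0.5.
#' @return binary genes x types matrix (1 = expected in that type), with
#'   the rule parameter recorded in the `alpha` attribute.
#' @export
assign_gene_to_celltype <- function(imputed, alpha = 0.5) {
  vals <- if (inherits(imputed, "imputed_profiles")) imputed$values
          else as.matrix(imputed)
  if (any(vals < 0)) stop("imputed values must be non-negative",
                          call. = FALSE)
  stopifnot(alpha > 0, alpha <= 1)
  out <- matrix(0L, ncol(vals), nrow(vals),
                dimnames = list(colnames(vals), rownames(vals)))
  for (g in seq_len(ncol(vals))) {
    m <- max(vals[, g])
    if (m > 0) out[g, ] <- as.integer(vals[, g] >= alpha * m)
  }
  attr(out, "alpha") <- alpha
  out
}
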