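# Fraction estimation: the central model fit of the package.
#
# The model is bulk ~ signature %*% f with f >= 0: each bulk profile is a
# non-negative mixture of cell-type expression programs, and the
# normalized coefficients are the share of transcripts attributable to
# each program ("cell-type transcriptional activity").  Inputs stay on the
# linear scale and no quantile normalization is applied.

#' Deconvolve bulk expression against a cell-type signature
#'
#' Per sample, the bulk profile is restricted to the signature genes
#' shared with the bulk matrix and the mixture model `bulk ~ signature %*%
#' f, f >= 0` is solved by non-negative least squares (default) or
#' nu-support-vector regression.  Coefficients are clamped at zero and
#' normalized to sum to one.  Fit significance is assessed by permuting
#' the gene labels of the bulk profile `n_perm` times and comparing the
#' Pearson correlation between observed and reconstructed profiles, with
#' +1 smoothing so that p lies in (0, 1].
#'
#' @param bulk genes x samples matrix (counts or TPM, linear scale).
#' @param signature a [build_signature()] result, or a genes x types
#'   matrix.
#' @param method `"nnls"` (deterministic default) or `"svr"`.
#' @param n_perm permutations for the significance test; default 100,
#'   `0` skips the test.
#' @param seed integer seed (used by the permutation test and svr).
#' @return a `decon_fit` object; see [coef.decon_fit()],
#'   [fitted.decon_fit()], [residuals.decon_fit()], [predict.decon_fit()].
#' @export
deconvolve <- function(bulk, signature, method = c("nnls", "svr"),
                       n_perm = 100L, seed = NULL) {
  method <- match.arg(method)
  S_all <- if (inherits(signature, "cell_signature")) signature$values
           else as.matrix(signature)
  check_count_matrix(bulk, "bulk matrix")
  shared <- intersect(rownames(S_all), rownames(bulk))
  if (length(shared) < 10L)
    stop("only ", length(shared),
         " signature genes shared with the bulk matrix (need >= 10)",
         call. = FALSE)
  message("deconvolve: using ", length(shared), " of ", nrow(S_all),
          " signature genes")
  S <- S_all[shared, , drop = FALSE]
  B <- as.matrix(bulk)[shared, , drop = FALSE]
  types <- colnames(S)
  n_samp <- ncol(B)

  engine <- switch(method,
                   nnls = function(b) nnls_solve(S, b)$x,
                   svr = function(b) svr_solve(S, b)$x)

  with_seed(seed, {
    fractions <- matrix(NA_real_, n_samp, ncol(S),
                        dimnames = list(colnames(B), types))
    rmse <- r <- p_perm <- rep(NA_real_, n_samp)
    flagged <- logical(n_samp)
    for (j in seq_len(n_samp)) {
      b <- B[, j]
      if (all(b == 0)) { flagged[j] <- TRUE; next }
      coefs <- engine(b)
      tot <- sum(coefs)
      fractions[j, ] <- if (tot > 0) coefs / tot else 0
      recon <- as.numeric(S %*% coefs)
      rmse[j] <- sqrt(mean((b - recon)^2))
      r[j] <- if (stats::sd(recon) > 0) stats::cor(b, recon) else 0
      if (n_perm > 0L) {
        hits <- 0L
        for (i in seq_len(n_perm)) {
          bp <- sample(b)
          cp <- engine(bp)
          rp_recon <- as.numeric(S %*% cp)
          rp <- if (stats::sd(rp_recon) > 0) stats::cor(bp, rp_recon) else 0
          if (rp >= r[j]) hits <- hits + 1L
        }
        p_perm[j] <- (hits + 1L) / (n_perm + 1L)
      }
    }
    structure(list(fractions = fractions, fit_rmse = rmse,
                   fit_correlation = r, permutation_p = p_perm,
                   flagged = flagged, method = method,
                   n_perm = as.integer(n_perm),
                   signature = S, bulk = B, shared_genes = shared,
                   call = match.call()),
              class = "decon_fit")
  })
}

#' @exportS3Method base::print
print.decon_fit <- function(x, ...) {
  cat("Cell-type deconvolution fit (", x$method, ")\n", sep = "")
  cat("  ", nrow(x$fractions), " samples x ", ncol(x$fractions),
      " cell types on ", length(x$shared_genes), " signature genes\n",
      sep = "")
  if (any(x$flagged))
    cat("  ", sum(x$flagged), " all-zero sample(s) flagged\n", sep = "")
  invisible(x)
}

#' Extract estimated cell-type fractions
#' @param object a `decon_fit`.
#' @param ... unused.
#' @return samples x types matrix of fractions (rows on the simplex).
#' @export
coef.decon_fit <- function(object, ...) object$fractions

#' Reconstructed bulk expression from the fitted mixture
#' @param object a `decon_fit`.
#' @param ... unused.
#' @return genes x samples matrix over the shared signature genes, scaled
#'   to each sample's observed total.
#' @export
fitted.decon_fit <- function(object, ...) {
  out <- matrix(NA_real_, nrow(object$bulk), ncol(object$bulk),
                dimnames = dimnames(object$bulk))
  for (j in seq_len(ncol(object$bulk))) {
    if (object$flagged[j]) next
    f <- object$fractions[j, ]
    recon <- as.numeric(object$signature %*% f)
    tot <- sum(recon)
    if (tot > 0)
      recon <- recon * sum(object$bulk[, j]) / tot
    out[, j] <- recon
  }
  out
}

#' @export
residuals.decon_fit <- function(object, ...) object$bulk - fitted(object)

#' Estimate fractions for new bulk samples with the fitted signature
#' @param object a `decon_fit`.
#' @param newdata genes x samples matrix.
#' @param ... passed to [deconvolve()].
#' @return a new `decon_fit` for `newdata`.
#' @export
predict.decon_fit <- function(object, newdata, ...) {
  deconvolve(newdata, object$signature, method = object$method, ...)
}

#' @exportS3Method base::summary
summary.decon_fit <- function(object, ...) {
  fr <- object$fractions[!object$flagged, , drop = FALSE]
  out <- list(
    n_samples = nrow(object$fractions),
    n_flagged = sum(object$flagged),
    method = object$method,
    n_genes = length(object$shared_genes),
    type_summary = data.frame(
      type = colnames(fr),
      mean_fraction = colMeans(fr),
      sd_fraction = apply(fr, 2L, stats::sd),
      row.names = NULL),
    mean_fit_correlation = mean(object$fit_correlation, na.rm = TRUE),
    mean_rmse = mean(object$fit_rmse, na.rm = TRUE),
    permutation_p = object$permutation_p)
  class(out) <- "summary.decon_fit"
  out
}

#' @exportS3Method base::print
print.summary.decon_fit <- function(x, ...) {
  cat("Deconvolution summary (", x$method, "): ", x$n_samples,
      " samples, ", x$n_genes, " genes\n", sep = "")
  cat("  mean reconstruction r = ",
      format(x$mean_fit_correlation, digits = 4), "\n", sep = "")
  print(transform(x$type_summary,
                  mean_fraction = signif(mean_fraction, 4),
                  sd_fraction = signif(sd_fraction, 4)))
  invisible(x)
}

#' Stacked-bar view of estimated cell-type composition
#' @param x a `decon_fit`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.decon_fit <- function(x, ...) {
  fr <- t(x$fractions[!x$flagged, , drop = FALSE])
  graphics::barplot(fr, col = grDevices::hcl.colors(nrow(fr), "Dynamic"),
                    border = NA, las = 2,
                    ylab = "estimated fraction",
                    legend.text = rownames(fr),
                    args.legend = list(x = "topright", cex = 0.6,
                                       bg = "white"), ...)
  invisible(x)
}
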