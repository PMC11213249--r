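# Non-negative least squares by the Lawson-Hanson active-set algorithm.
# This is the deterministic default engine for fraction estimation; it is
# exact on noiseless mixtures, which the test suite exploits.

#' Solve min ||A x - b|| subject to x >= 0
#'
#' Lawson-Hanson active-set iteration.  The passive-set subproblems are
#' solved by QR on the original columns (not the normal equations) for
#' numerical stability with collinear signatures.
#'
#' @param A numeric matrix (m x n, m >= 1).
#' @param b numeric vector (length m).
#' @param tol dual-feasibility tolerance, scaled by `max(|A^T b|)`.
#' @return list: `x` (coefficients, >= 0), `residual` vector,
#'   `passive` (indices of the final passive set).
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b))
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  Atb <- crossprod(A, b)
  scale <- max(abs(Atb), 1)
  max_iter <- 30L * n

  for (iter in seq_len(max_iter)) {
    w <- crossprod(A, b - A %*% x)
    w[passive] <- -Inf
    j <- which.max(w)
    if (w[j] <= tol * scale) break
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      s <- numeric(n)
      if (length(P)) {
        s[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
        s[P][is.na(s[P])] <- 0  # rank-deficient passive set: drop dimension
      }
      if (!length(P) || all(s[P] > 0)) break
      neg <- P[s[P] <= 0]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    x[!passive] <- 0
  }
  list(x = pmax(x, 0), residual = as.numeric(b - A %*% x),
       passive = which(passive))
}

# nu-SVR engine in the style of the SVR-based deconvolution family:
# mixture and signature are globally standardized, a linear-kernel
# nu-regression is fitted for nu in {0.25, 0.5, 0.75}, the primal weights
# are recovered from the support vectors, negatives are clamped, and the
# nu with the lowest reconstruction RMSE is kept.
svr_solve <- function(A, b, nus = c(0.25, 0.5, 0.75)) {
  As <- (A - mean(A)) / stats::sd(as.vector(A))
  bs <- (b - mean(b)) / stats::sd(b)
  best <- NULL
  for (nu in nus) {
    fit <- e1071::svm(x = As, y = bs, type = "nu-regression",
                      kernel = "linear", nu = nu, scale = FALSE)
    w <- as.numeric(crossprod(fit$coefs, fit$SV))
    w <- pmax(w, 0)
    recon <- as.numeric(As %*% w)
    rmse <- sqrt(mean((bs - recon)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(x = w, rmse = rmse, nu = nu)
  }
  best
}
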