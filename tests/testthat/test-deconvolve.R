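test_that("the active-set solver agrees with an independent NNLS oracle", {
  set.seed(41)
  for (i in 1:20) {
    m <- sample(10:40, 1); n <- sample(2:6, 1)
    A <- matrix(rgamma(m * n, 2), m, n)
    b <- as.numeric(A %*% runif(n, -0.2, 1)) + rnorm(m, sd = 0.1)
    ours <- nnls_solve(A, b)
    oracle <- pracma::lsqnonneg(A, b)
    expect_equal(ours$x, oracle$x, tolerance = 1e-6)
    expect_lt(sum(ours$residual^2), sum(oracle$resid.norm) + 1e-8)
  }
})

test_that("noiseless mixtures of orthogonal signatures are recovered exactly", {
  S <- make_orthogonal_signature(n_types = 2)
  bulk <- cbind(mix1 = as.numeric(S %*% c(0.3, 0.7)))
  rownames(bulk) <- rownames(S)
  fit <- suppressMessages(deconvolve(bulk, S, method = "nnls", n_perm = 0))
  expect_equal(unname(coef(fit)[1, ]), c(0.3, 0.7), tolerance = 1e-6)
})

test_that("a bulk equal to one signature column maps to that type alone", {
  S <- make_orthogonal_signature(n_types = 3)
  bulk <- cbind(pure = S[, "B"])
  fit <- suppressMessages(deconvolve(bulk, S, n_perm = 0))
  expect_equal(unname(coef(fit)[1, ]), c(0, 1, 0), tolerance = 1e-9)
})

test_that("fractions are scale invariant and live on the simplex", {
  set.seed(42)
  S <- make_orthogonal_signature(n_types = 4)
  S <- S + matrix(runif(length(S), 0, 2), nrow(S))  # correlated columns
  f <- random_fractions(6, 4, seed = 5)
  bulk <- S %*% t(f) + matrix(rnorm(nrow(S) * 6, sd = 0.5), nrow(S))
  bulk <- pmax(bulk, 0)
  colnames(bulk) <- paste0("s", 1:6)
  fit1 <- suppressMessages(deconvolve(bulk, S, n_perm = 0))
  fit17 <- suppressMessages(deconvolve(bulk * 17, S, n_perm = 0))
  expect_equal(coef(fit1), coef(fit17), tolerance = 1e-10)
  expect_equal(unname(rowSums(coef(fit1))), rep(1, 6), tolerance = 1e-9)
  expect_true(all(coef(fit1) >= 0))
})

test_that("jointly permuting gene order leaves fractions unchanged", {
  set.seed(43)
  S <- make_orthogonal_signature(n_types = 3)
  bulk <- cbind(s1 = as.numeric(S %*% c(0.2, 0.5, 0.3)) + abs(rnorm(nrow(S))))
  rownames(bulk) <- rownames(S)
  perm <- sample(nrow(S))
  fit <- suppressMessages(deconvolve(bulk, S, n_perm = 0))
  fitp <- suppressMessages(deconvolve(bulk[perm, , drop = FALSE], S[perm, ],
                                      n_perm = 0))
  expect_equal(coef(fit), coef(fitp), tolerance = 1e-10)
})

test_that("the nu-SVR engine recovers noiseless mixtures within 0.02", {
  S <- make_orthogonal_signature(n_types = 3)
  truth <- c(0.3, 0.5, 0.2)
  bulk <- cbind(s1 = as.numeric(S %*% truth))
  rownames(bulk) <- rownames(S)
  fit <- suppressMessages(deconvolve(bulk, S, method = "svr", n_perm = 0,
                                     seed = 1))
  expect_true(all(abs(coef(fit)[1, ] - truth) < 0.02))
})

test_that("permutation p-values respect the +1 smoothing floor and detect fits", {
  S <- make_orthogonal_signature(n_types = 3)
  bulk <- cbind(s1 = as.numeric(S %*% c(0.6, 0.3, 0.1)))
  rownames(bulk) <- rownames(S)
  fit <- suppressMessages(deconvolve(bulk, S, n_perm = 50, seed = 2))
  expect_gte(fit$permutation_p[1], 1 / 51)
  expect_lt(fit$permutation_p[1], 0.05)  # genuine mixture: highly significant
})

test_that("all-zero samples are flagged, empty intersections rejected", {
  S <- make_orthogonal_signature(n_types = 2)
  bulk <- cbind(zero = rep(0, nrow(S)),
                ok = as.numeric(S %*% c(0.5, 0.5)))
  rownames(bulk) <- rownames(S)
  fit <- suppressMessages(deconvolve(bulk, S, n_perm = 0))
  expect_true(fit$flagged[1])
  expect_true(all(is.na(coef(fit)[1, ])))
  expect_false(any(is.na(coef(fit)[2, ])))

  other <- matrix(1, 20, 1, dimnames = list(paste0("x", 1:20), "s"))
  expect_error(suppressMessages(deconvolve(other, S)), "shared")
})

test_that("model methods expose fractions, reconstruction and residuals", {
  S <- make_orthogonal_signature(n_types = 2)
  bulk <- cbind(s1 = as.numeric(S %*% c(0.25, 0.75)))
  rownames(bulk) <- rownames(S)
  fit <- suppressMessages(deconvolve(bulk, S, n_perm = 0))
  expect_s3_class(fit, "decon_fit")
  expect_equal(dim(coef(fit)), c(1L, 2L))
  expect_equal(fitted(fit)[, 1], bulk[, 1], tolerance = 1e-8)
  expect_equal(unname(residuals(fit)[, 1]), rep(0, nrow(S)),
               tolerance = 1e-6)
  s <- summary(fit)
  expect_s3_class(s, "summary.decon_fit")
  expect_equal(s$type_summary$mean_fraction, c(0.25, 0.75),
               tolerance = 1e-6)
  newfit <- suppressMessages(predict(fit, bulk * 3, n_perm = 0))
  expect_equal(coef(newfit), coef(fit), tolerance = 1e-8)
})
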