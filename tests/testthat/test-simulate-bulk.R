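two_type_profiles <- function() {
  matrix(c(5, 1, 0, 1, 4, 2), nrow = 3,
         dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
}

test_that("constant weights normalize to fixed fractions before noise", {
  spec <- trajectory_spec(list(A = traj_constant(1), B = traj_constant(3)),
                          replicate_noise_sd = 0, n_replicates = 2)
  sim <- simulate_bulk_series(two_type_profiles(), spec,
                              timepoints = c(0, 6, 12), depth = 1e5,
                              seed = 1)
  expect_equal(unname(sim$true_fractions[, "A"]), rep(0.25, 6))
  expect_equal(unname(sim$true_fractions[, "B"]), rep(0.75, 6))
})

test_that("a single-type series is proportional to that type's profile", {
  p <- two_type_profiles()[, "A", drop = FALSE]
  spec <- trajectory_spec(list(A = traj_constant(2)),
                          replicate_noise_sd = 0, n_replicates = 1)
  sim <- simulate_bulk_series(p, spec, timepoints = c(0, 12), depth = 1e6,
                              seed = 2)
  expect_true(all(sim$true_fractions == 1))
  # expected expression is depth * profile / sum(profile); Poisson noise
  expected <- 1e6 * p[, 1] / sum(p[, 1])
  expect_true(all(abs(sim$counts - expected) < 4 * sqrt(expected + 1)))
})

test_that("a zero profile row yields zero counts in every sample", {
  p <- two_type_profiles(); p["g3", ] <- 0
  spec <- trajectory_spec(list(A = traj_constant(1), B = traj_constant(1)),
                          replicate_noise_sd = 0.05, n_replicates = 3)
  sim <- simulate_bulk_series(p, spec, timepoints = 0:3, depth = 1e5,
                              seed = 3)
  expect_true(all(sim$counts["g3", ] == 0))
})

test_that("sinusoid fractions peak at the planted phase on the grid", {
  spec <- trajectory_spec(
    list(A = traj_sinusoid(amplitude = 0.5, phase_hours = 6, baseline = 1),
         B = traj_constant(1)),
    replicate_noise_sd = 0, n_replicates = 1)
  tp <- seq(0, 22, by = 2)
  sim <- simulate_bulk_series(two_type_profiles(), spec, timepoints = tp,
                              depth = 1e5, seed = 4)
  expect_equal(tp[which.max(sim$true_fractions[, "A"])], 6)
})

test_that("negative trajectory weights are rejected", {
  spec <- trajectory_spec(
    list(A = traj_sinusoid(amplitude = 2, phase_hours = 6, baseline = 1),
         B = traj_constant(1)),
    replicate_noise_sd = 0, n_replicates = 1)
  expect_error(
    simulate_bulk_series(two_type_profiles(), spec, timepoints = seq(0, 22, 2),
                         depth = 1e4, seed = 1),
    "negative")
})

test_that("true fractions stay on the simplex under replicate noise", {
  spec <- trajectory_spec(
    list(A = traj_sinusoid(0.4, 3, baseline = 0.6), B = traj_monotone(2, 0.5)),
    replicate_noise_sd = 0.2, n_replicates = 4)
  for (seed in 1:5) {
    sim <- simulate_bulk_series(two_type_profiles(), spec,
                                timepoints = seq(0, 20, 4), depth = 1e4,
                                seed = seed)
    expect_true(all(sim$true_fractions >= 0))
    expect_equal(unname(rowSums(sim$true_fractions)),
                 rep(1, nrow(sim$true_fractions)), tolerance = 1e-9)
  }
})

test_that("bulk counts are Poisson-like: variance/mean near 1 across replicates", {
  set.seed(10)
  p <- matrix(rgamma(1000 * 2, 2, 1), 1000, 2,
              dimnames = list(sprintf("g%04d", 1:1000), c("A", "B")))
  spec <- trajectory_spec(list(A = traj_constant(1), B = traj_constant(2)),
                          replicate_noise_sd = 0, n_replicates = 40)
  sim <- simulate_bulk_series(p, spec, timepoints = 0, depth = 2e5, seed = 6)
  mu <- rowMeans(sim$counts)
  vm <- apply(sim$counts, 1, var) / pmax(mu, 1e-9)
  expect_lt(abs(mean(vm[mu > 5]) - 1), 0.05)
})

test_that("age-axis series carries monotone traits and replicate metadata", {
  spec <- trajectory_spec(list(A = traj_monotone(1, 3), B = traj_monotone(3, 1)),
                          replicate_noise_sd = 0.01, n_replicates = 2)
  sim <- simulate_bulk_series(two_type_profiles(), spec,
                              timepoints = seq(10, 40, 5), depth = 1e4,
                              axis = "age", seed = 7)
  md <- sim$metadata
  expect_true(all(c("age_days", "replicate", "pseudotime", "biomass",
                    "leaf_area") %in% names(md)))
  expect_gt(cor(md$age_days, md$pseudotime), 0.95)
  expect_gt(cor(md$age_days, md$biomass), 0.9)
  # A rises, B falls along age
  expect_gt(cor(md$age_days, sim$true_fractions[, "A"]), 0.9)
  expect_lt(cor(md$age_days, sim$true_fractions[, "B"]), -0.9)
})

test_that("identical seeds reproduce identical series", {
  spec <- trajectory_spec(list(A = traj_constant(1), B = traj_constant(1)),
                          replicate_noise_sd = 0.1, n_replicates = 2)
  a <- simulate_bulk_series(two_type_profiles(), spec, 0:3, depth = 1e4,
                            seed = 11)
  b <- simulate_bulk_series(two_type_profiles(), spec, 0:3, depth = 1e4,
                            seed = 11)
  expect_identical(a, b)
})
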