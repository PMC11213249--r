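test_that("train/test split is stratified with the rounding rule", {
  labels <- setNames(rep(c("A", "B", "C"), c(4, 100, 7)),
                     sprintf("c%03d", 1:111))
  sp <- split_train_test(labels, seed = 1)
  pt <- sp$per_type
  expect_equal(pt$n_train[pt$type == "A"], 3L)  # round(0.75 * 4)
  expect_equal(pt$n_test[pt$type == "A"], 1L)
  expect_equal(pt$n_train[pt$type == "B"], 75L) # 75% of 100 cells
  expect_equal(pt$n_test[pt$type == "B"], 25L)
  expect_equal(pt$n_train[pt$type == "C"], 5L)  # round(5.25)
  expect_setequal(c(sp$train_cells, sp$test_cells), names(labels))
  expect_length(intersect(sp$train_cells, sp$test_cells), 0)
  # per-type train share within rounding of the target
  expect_true(all(abs(pt$n_train - 0.75 * pt$n_total) <= 0.5))
  expect_error(split_train_test(setNames("A", "c1")), "fewer than 2")
})

test_that("single-type pseudobulks conserve counts and halve the pool", {
  ref <- make_tiny_reference(n_types = 2, cells_per_type = 5, seed = 2)
  st <- simulate_single_type_bulks(ref$counts, ref$labels, seed = 3)
  expect_equal(sort(unique(st$info$type)), c("type1", "type2"))
  expect_setequal(st$info$n_cells[st$info$type == "type1"], c(3L, 2L))
  for (ty in c("type1", "type2")) {
    tot <- rowSums(ref$counts[, ref$labels == ty])
    reps <- st$counts[, st$info$sample[st$info$type == ty]]
    expect_equal(unname(rowSums(reps)), unname(tot))
  }
})

test_that("a two-cell type yields its two cells as the replicates", {
  counts <- matrix(c(1, 2, 3, 40, 50, 60), nrow = 3,
                   dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  labels <- setNames(c("A", "A"), c("c1", "c2"))
  st <- simulate_single_type_bulks(counts, labels, seed = 4)
  got <- lapply(1:2, function(r) unname(st$counts[, paste0("A_rep", r)]))
  expect_setequal(lapply(seq_len(2), function(j) unname(counts[, j])), got)
})

test_that("cell counts follow the clamp-then-round rule", {
  expect_equal(celldecon:::draw_cell_counts(c(0.5, -0.2, 0.7), 600),
               c(300, 0, 420))
  # realized fractions from those counts
  expect_equal(c(300, 0, 420) / 720, c(0.41666667, 0, 0.58333333),
               tolerance = 1e-6)
})

test_that("mixtures record realized composition and conserve counts", {
  ref <- make_tiny_reference(n_types = 3, cells_per_type = 40, seed = 5)
  mix <- simulate_mixed_bulks(ref$counts, ref$labels, n_samples = 20,
                              mean_cells = 30, return_cells = TRUE, seed = 6)
  expect_equal(unname(rowSums(mix$realized_fractions)), rep(1, 20),
               tolerance = 1e-12)
  expect_true(all(mix$realized_fractions >= 0))
  for (s in c(1, 7, 20)) {
    expect_equal(unname(mix$counts[, s]),
                 unname(rowSums(ref$counts[, mix$cells[[s]], drop = FALSE])))
    expect_equal(sum(mix$cells_used[s, ]), length(mix$cells[[s]]))
  }
})

test_that("a single-type pool gives realized fraction one", {
  ref <- make_tiny_reference(n_types = 2, cells_per_type = 30, seed = 7)
  keep <- ref$labels == "type1"
  mix <- simulate_mixed_bulks(ref$counts[, keep], ref$labels[keep],
                              n_samples = 10, mean_cells = 10, seed = 8)
  expect_true(all(mix$realized_fractions[, "type1"] == 1))
})

test_that("mean realized fractions track reference proportions", {
  ref <- make_tiny_reference(n_types = 3, cells_per_type = 300, seed = 9)
  mix <- simulate_mixed_bulks(ref$counts, ref$labels, n_samples = 300,
                              mean_cells = 60, seed = 10)
  for (ty in colnames(mix$realized_fractions)) {
    x <- mix$realized_fractions[, ty]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 1 / 3), 3 * se)
  }
})

test_that("default-scale invocation averages about 600 cells per sample", {
  ref <- simulate_reference(reference_sim_config(
    cells_per_type = c(120, 80, 70, 60, 50, 40, 30, 30, 30, 20),
    n_genes = 700, markers_per_type = 10, seed = 11))
  mix <- simulate_mixed_bulks(ref$counts, ref$labels, n_samples = 150,
                              mean_cells = 600, replace = TRUE, seed = 12)
  mean_cells <- mean(rowSums(mix$cells_used))
  expect_gt(mean_cells, 480)
  expect_lt(mean_cells, 750)
})

test_that("identical seeds reproduce identical mixtures", {
  ref <- make_tiny_reference(n_types = 2, cells_per_type = 20, seed = 13)
  a <- simulate_mixed_bulks(ref$counts, ref$labels, n_samples = 5,
                            mean_cells = 15, seed = 99)
  b <- simulate_mixed_bulks(ref$counts, ref$labels, n_samples = 5,
                            mean_cells = 15, seed = 99)
  expect_identical(a, b)
})
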