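# Shared fixtures, all built in code at test time.

# Orthogonal signature: each type expresses its own disjoint gene block.
make_orthogonal_signature <- function(n_types = 2, genes_per_type = 20,
                                      lo = 5, hi = 50, seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) .Random.seed else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    n_genes <- n_types * genes_per_type
    S <- matrix(0, n_genes, n_types,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                LETTERS[seq_len(n_types)]))
    for (k in seq_len(n_types)) {
      idx <- seq.int((k - 1) * genes_per_type + 1, k * genes_per_type)
      S[idx, k] <- stats::runif(genes_per_type, lo, hi)
    }
    S
  })
}

# Small labelled reference where each type exclusively expresses its own
# marker block (plus a shared baseline), with exact Poisson-free counts.
make_tiny_reference <- function(n_types = 2, cells_per_type = 20,
                                markers_per_type = 5, seed = 7) {
  cfg <- reference_sim_config(
    n_cell_types = n_types,
    cells_per_type = rep(cells_per_type, n_types),
    n_genes = max(60, n_types * markers_per_type * 2),
    markers_per_type = markers_per_type,
    marker_fold_change = 10,
    baseline_mean = 1,
    dispersion = 5,
    confusable_pairs = list(),
    type_names = paste0("type", seq_len(n_types)),
    seed = seed)
  simulate_reference(cfg)
}

# Random points on the simplex.
random_fractions <- function(n, k, seed = 1) {
  set.seed(seed)
  f <- matrix(stats::rgamma(n * k, 1), n, k)
  f / rowSums(f)
}
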