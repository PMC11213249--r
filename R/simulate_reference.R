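# Synthetic labelled single-cell reference with planted cell-type profiles.
#
# The generator emulates the structure of a leaf single-cell atlas: a
# multi-cluster reference in which a few cluster pairs are deliberately
# confusable (a rare cluster whose expression program largely mimics a
# mesophyll group), so that recovery tests can probe both the easy and the
# hard regime of signature-based deconvolution.

#' Configuration for the synthetic single-cell reference
#'
#' The default roster mimics a mature leaf: ten clusters including three
#' mesophyll groups, common structural types, and one rare hydathode-like
#' cluster whose profile is mixed 80% toward mesophyll group 1, making it
#' deliberately confusable with that group.
#'
#' @param n_cell_types number of clusters.
#' @param cells_per_type integer vector of cells per cluster
#'   (length `n_cell_types`).
#' @param n_genes number of genes.
#' @param markers_per_type planted marker genes per cluster; the marker
#'   blocks are disjoint, so `markers_per_type * n_cell_types <= n_genes`.
#' @param marker_fold_change fold increase of a marker in its own cluster.
#' @param baseline_mean expected counts per gene per cell off-marker.
#' @param dispersion negative-binomial size parameter of the per-cell
#'   count noise (smaller = more overdispersed).
#' @param confusable_pairs list of `list(a =, b =, w =)` entries: the
#'   profile of cluster `b` is replaced by `(1-w)*profile_b + w*profile_a`.
#' @param type_names cluster names (length `n_cell_types`).
#' @param seed integer seed.
#' @return a `reference_sim_config` list.
#' @export
reference_sim_config <- function(n_cell_types = 10L,
                                 cells_per_type = c(500L, 300L, 250L, 250L,
                                                    150L, 120L, 120L, 120L,
                                                    100L, 90L),
                                 n_genes = 3000L,
                                 markers_per_type = 60L,
                                 marker_fold_change = 8,
                                 baseline_mean = 0.5,
                                 dispersion = 1,
                                 confusable_pairs = list(
                                   list(a = "mesophyll_1", b = "hydathode",
                                        w = 0.8)),
                                 type_names = c("mesophyll_1", "mesophyll_2",
                                                "mesophyll_3", "epidermis",
                                                "vascular",
                                                "phloem_parenchyma",
                                                "companion", "guard",
                                                "sieve", "hydathode"),
                                 seed = 1L) {
  cfg <- list(n_cell_types = as.integer(n_cell_types),
              cells_per_type = as.integer(cells_per_type),
              n_genes = as.integer(n_genes),
              markers_per_type = as.integer(markers_per_type),
              marker_fold_change = marker_fold_change,
              baseline_mean = baseline_mean,
              dispersion = dispersion,
              confusable_pairs = confusable_pairs,
              type_names = type_names,
              seed = seed)
  class(cfg) <- "reference_sim_config"
  validate_reference_sim_config(cfg)
  cfg
}

validate_reference_sim_config <- function(cfg) {
  if (length(cfg$cells_per_type) != cfg$n_cell_types)
    stop("cells_per_type: length ", length(cfg$cells_per_type),
         " does not match n_cell_types = ", cfg$n_cell_types, call. = FALSE)
  if (length(cfg$type_names) != cfg$n_cell_types)
    stop("type_names: length must equal n_cell_types", call. = FALSE)
  if (anyDuplicated(cfg$type_names))
    stop("type_names: duplicate names", call. = FALSE)
  if (cfg$markers_per_type * cfg$n_cell_types > cfg$n_genes)
    stop("markers_per_type: markers_per_type * n_cell_types exceeds n_genes",
         call. = FALSE)
  if (cfg$marker_fold_change <= 0)
    stop("marker_fold_change: must be positive", call. = FALSE)
  if (cfg$baseline_mean <= 0)
    stop("baseline_mean: must be positive", call. = FALSE)
  if (cfg$dispersion <= 0)
    stop("dispersion: must be positive", call. = FALSE)
  for (p in cfg$confusable_pairs) {
    if (!all(c("a", "b", "w") %in% names(p)))
      stop("confusable_pairs: entries need fields a, b, w", call. = FALSE)
    if (!all(c(p$a, p$b) %in% cfg$type_names))
      stop("confusable_pairs: unknown type in pair (", p$a, ", ", p$b, ")",
           call. = FALSE)
    if (p$w < 0 || p$w > 1)
      stop("confusable_pairs: weight w must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Simulate a labelled single-cell reference with planted profiles
#'
#' Each cluster has a planted expected-count profile: `baseline_mean`
#' everywhere, lifted by `marker_fold_change` on that cluster's disjoint
#' marker block.  Confusable pairs then mix profiles (`profile_b <-
#' (1-w) profile_b + w profile_a`) *before* sampling, so the planted ground
#' truth stays well defined.  Counts are negative-binomial around the
#' profile with the configured dispersion.
#'
#' @param config a [reference_sim_config()].
#' @return a `synthetic_reference` list with elements `counts` (genes x
#'   cells integer matrix), `labels` (named character vector, cell -> type),
#'   `true_profiles` (genes x types expected counts per cell),
#'   `confusable` (named vector mapping each confusable type to its
#'   partner), and `config`.
#' @export
simulate_reference <- function(config = reference_sim_config()) {
  validate_reference_sim_config(config)
  cfg <- config
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  profiles <- matrix(cfg$baseline_mean, cfg$n_genes, cfg$n_cell_types,
                     dimnames = list(genes, cfg$type_names))
  marker_of <- rep(NA_character_, cfg$n_genes)
  for (k in seq_len(cfg$n_cell_types)) {
    idx <- seq.int((k - 1L) * cfg$markers_per_type + 1L,
                   k * cfg$markers_per_type)
    profiles[idx, k] <- cfg$baseline_mean * cfg$marker_fold_change
    marker_of[idx] <- cfg$type_names[k]
  }
  confusable <- character(0)
  for (p in cfg$confusable_pairs) {
    profiles[, p$b] <- (1 - p$w) * profiles[, p$b] + p$w * profiles[, p$a]
    confusable[p$b] <- p$a
  }

  n_cells <- sum(cfg$cells_per_type)
  cells <- sprintf("c%05d", seq_len(n_cells))
  labels <- stats::setNames(rep(cfg$type_names, cfg$cells_per_type), cells)
  counts <- with_seed(cfg$seed, {
    blocks <- lapply(seq_len(cfg$n_cell_types), function(k) {
      nc <- cfg$cells_per_type[k]
      matrix(stats::rnbinom(cfg$n_genes * nc,
                            mu = rep(profiles[, k], nc),
                            size = cfg$dispersion),
             nrow = cfg$n_genes, ncol = nc)
    })
    do.call(cbind, blocks)
  })
  dimnames(counts) <- list(genes, cells)

  structure(list(counts = counts, labels = labels,
                 true_profiles = profiles, marker_of = marker_of,
                 confusable = confusable, config = cfg),
            class = "synthetic_reference")
}

#' @exportS3Method base::print
print.synthetic_reference <- function(x, ...) {
  cat("Synthetic single-cell reference:",
      nrow(x$counts), "genes x", ncol(x$counts), "cells,",
      ncol(x$true_profiles), "cell types\n")
  if (length(x$confusable))
    cat("  confusable:",
        paste(names(x$confusable), "->", x$confusable, collapse = ", "),
        "\n")
  invisible(x)
}
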