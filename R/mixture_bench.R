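# Per-type cell counts from raw normal draws: negatives clamp to zero,
# then the draw is scaled by the average cells per sample and rounded.
draw_cell_counts <- function(draws, mean_cells) {
  round(pmax(draws, 0) * mean_cells)
}

# Simulated bulk RNA-seq benchmark: stratified train/test split of the
# labelled reference, single-type pseudobulk replicates, and mixed
# pseudobulks whose per-type cell counts follow normal draws with mean and
# standard deviation equal to the reference cell-type proportion (negative
# draws clamped to zero) scaled by the average cells per sample.

#' Stratified train/test split of labelled cells
#'
#' Per cell type, `round(train_fraction * n)` cells go to the training set
#' and the remainder to the test set, with at least one test cell per
#' type.
#'
#' @param labels named character vector (cell id -> type).
#' @param train_fraction training share per type; default 0.75.
#' @param seed integer seed.
#' @return a `split_result` list: `train_cells`, `test_cells` (id
#'   vectors) and `per_type` (data.frame of per-type counts).
#' @export
split_train_test <- function(labels, train_fraction = 0.75, seed = 1L) {
  stopifnot(!is.null(names(labels)), train_fraction > 0, train_fraction < 1)
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("cell type '", names(sizes)[which(sizes < 2L)[1L]],
         "' has fewer than 2 cells; cannot split", call. = FALSE)
  with_seed(seed, {
    train <- character(0)
    for (ty in names(sizes)) {
      ids <- names(labels)[labels == ty]
      n_tr <- round(train_fraction * length(ids))
      n_tr <- min(max(n_tr, 1L), length(ids) - 1L)  # >= 1 test cell
      train <- c(train, sample(ids, n_tr))
    }
    test <- setdiff(names(labels), train)
    per_type <- data.frame(
      type = names(sizes),
      n_total = as.integer(sizes),
      n_train = as.integer(table(labels[train])[names(sizes)]),
      n_test = as.integer(table(labels[test])[names(sizes)]),
      stringsAsFactors = FALSE)
    structure(list(train_cells = train, test_cells = test,
                   per_type = per_type),
              class = "split_result")
  })
}

#' Single-cell-type pseudobulk replicates
#'
#' Per type, the cells are randomly partitioned into two equal groups
#' (sizes differing by one when odd) and each group is summed gene-wise,
#' forming replicates 1 and 2.
#'
#' @param counts genes x cells matrix (e.g. the test cells).
#' @param labels named character vector (cell id -> type) covering the
#'   columns of `counts`.
#' @param seed integer seed.
#' @return list: `counts` (genes x pseudobulks), `info` (data.frame with
#'   sample, type, replicate, n_cells).
#' @export
simulate_single_type_bulks <- function(counts, labels, seed = 1L) {
  check_count_matrix(counts)
  labels <- labels[colnames(counts)]
  types <- sort(unique(labels))
  with_seed(seed, {
    cols <- list(); info <- list()
    for (ty in types) {
      ids <- colnames(counts)[labels == ty]
      if (length(ids) < 2L) {
        warning("type '", ty, "' has fewer than 2 cells; skipped")
        next
      }
      ids <- sample(ids)
      half <- ceiling(length(ids) / 2)
      groups <- list(ids[seq_len(half)], ids[-seq_len(half)])
      for (r in 1:2) {
        cols[[paste0(ty, "_rep", r)]] <-
          rowSums(counts[, groups[[r]], drop = FALSE])
        info[[paste0(ty, "_rep", r)]] <-
          data.frame(sample = paste0(ty, "_rep", r), type = ty,
                     replicate = r, n_cells = length(groups[[r]]),
                     stringsAsFactors = FALSE)
      }
    }
    if (!length(cols)) stop("no type had >= 2 cells", call. = FALSE)
    m <- do.call(cbind, cols)
    rownames(m) <- rownames(counts)
    list(counts = m, info = do.call(rbind, c(info, make.row.names = FALSE)))
  })
}

#' Mixed pseudobulk samples with recorded ground-truth composition
#'
#' Per sample and type, a proportion is drawn from
#' `Normal(p_k, sd = p_k)` where `p_k` is the type's share among the
#' supplied cells (or `proportions`); negative draws are clamped to zero.
#' The per-type cell count is `round(draw * mean_cells)`, capped at the
#' available pool when sampling without replacement.  Cells are drawn
#' uniformly and summed gene-wise.  Samples whose draws all clamp to zero
#' are redrawn (logged).  The scoring ground truth is the realized
#' fraction of cells actually drawn, not the raw normal draw.
#'
#' @param counts genes x cells matrix (typically the test cells).
#' @param labels named character vector (cell id -> type).
#' @param n_samples number of mixtures; default 500.
#' @param mean_cells average cells per sample; default 600.
#' @param proportions optional named per-type proportions to draw around;
#'   defaults to the proportions within `labels`.
#' @param replace sample cells with replacement (default `FALSE`; the cap
#'   at the available pool is logged when it binds).
#' @param return_cells keep the per-sample cell id draws (for audits).
#' @param seed integer seed.
#' @return a `mixture_bench` list: `counts` (genes x samples),
#'   `realized_fractions` and `intended_draws` (samples x types),
#'   `cells_used` (samples x types integer), optionally `cells`.
#' @export
simulate_mixed_bulks <- function(counts, labels, n_samples = 500L,
                                 mean_cells = 600L, proportions = NULL,
                                 replace = FALSE, return_cells = FALSE,
                                 seed = 1L) {
  check_count_matrix(counts)
  labels <- labels[colnames(counts)]
  if (anyNA(labels)) stop("labels missing for some cells", call. = FALSE)
  types <- sort(unique(labels))
  pool <- split(colnames(counts), labels)[types]
  avail <- vapply(pool, length, 1L)
  if (is.null(proportions)) {
    proportions <- as.numeric(table(labels)[types]) / length(labels)
    names(proportions) <- types
  } else {
    stopifnot(all(types %in% names(proportions)))
    proportions <- proportions[types]
  }

  with_seed(seed, {
    Tn <- length(types)
    draws <- matrix(0, n_samples, Tn, dimnames = list(NULL, types))
    used <- matrix(0L, n_samples, Tn, dimnames = list(NULL, types))
    bulk <- matrix(0, nrow(counts), n_samples)
    cells <- if (return_cells) vector("list", n_samples) else NULL
    n_capped <- 0L; n_redrawn <- 0L
    for (s in seq_len(n_samples)) {
      repeat {
        d <- stats::rnorm(Tn, mean = proportions, sd = proportions)
        n_cells <- draw_cell_counts(d, mean_cells)
        if (sum(n_cells) > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      if (!replace && any(n_cells > avail)) {
        n_capped <- n_capped + 1L
        n_cells <- pmin(n_cells, avail)
      }
      picked <- character(0)
      for (k in seq_len(Tn)) {
        if (n_cells[k] == 0) next
        picked <- c(picked,
                    sample(pool[[k]], n_cells[k], replace = replace))
      }
      draws[s, ] <- d
      used[s, ] <- as.integer(n_cells)
      bulk[, s] <- rowSums(counts[, picked, drop = FALSE])
      if (return_cells) cells[[s]] <- picked
    }
    if (n_capped) message("simulate_mixed_bulks: cell-count cap bound in ",
                          n_capped, " sample(s)")
    if (n_redrawn) message("simulate_mixed_bulks: redrew ", n_redrawn,
                           " all-zero sample(s)")
    sample_ids <- sprintf("mix%04d", seq_len(n_samples))
    dimnames(bulk) <- list(rownames(counts), sample_ids)
    rownames(draws) <- rownames(used) <- sample_ids
    realized <- used / pmax(rowSums(used), 1L)
    structure(list(counts = bulk, realized_fractions = realized,
                   intended_draws = draws, cells_used = used,
                   cells = cells, proportions = proportions),
              class = "mixture_bench")
  })
}

#' @exportS3Method base::print
print.mixture_bench <- function(x, ...) {
  cat("Mixed pseudobulk benchmark:", ncol(x$counts), "samples,",
      ncol(x$realized_fractions), "cell types, mean",
      round(mean(rowSums(x$cells_used))), "cells/sample\n")
  invisible(x)
}
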