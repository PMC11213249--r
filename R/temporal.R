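# Temporal and trait profiling of cell-type activity: z-scored fraction
# trajectories, replicate averaging, trait correlations, gene-set cluster
# profiles, and peak-time extraction.

#' Z-score fraction trajectories per cell type
#'
#' Each type column is centred and scaled by the sample (n-1) standard
#' deviation; constant columns map to zeros.
#'
#' @param fractions samples x types matrix (or `decon_fit`).
#' @return samples x types z-score matrix (an activity matrix).
#' @export
zscore_by_celltype <- function(fractions) {
  if (inherits(fractions, "decon_fit")) fractions <- coef(fractions)
  fractions <- as.matrix(fractions)
  if (nrow(fractions) < 2L) stop("need at least 2 samples", call. = FALSE)
  zscore_cols(fractions)
}

#' Average fractions over replicates, then z-score per type
#'
#' Fractions are predicted independently for each biological replicate and
#' then averaged per timepoint before z-scoring, mirroring how replicated
#' diurnal series are summarized.
#'
#' @param fractions samples x types matrix (or `decon_fit`).
#' @param metadata data.frame with a `sample` column matching the fraction
#'   rows, a time column (`time_hours` or `age_days`), and `replicate`.
#' @param time_col time column name; auto-detected by default.
#' @return list: `activity` (timepoints x types z-scores), `mean_fractions`
#'   (same shape, pre-z-score), `time` (ordered timepoints).
#' @export
average_replicates <- function(fractions, metadata, time_col = NULL) {
  if (inherits(fractions, "decon_fit")) fractions <- coef(fractions)
  fractions <- as.matrix(fractions)
  stopifnot(is.data.frame(metadata), "sample" %in% names(metadata))
  if (is.null(time_col))
    time_col <- intersect(c("time_hours", "age_days"), names(metadata))[1L]
  if (is.na(time_col) || !time_col %in% names(metadata))
    stop("metadata has no usable time column", call. = FALSE)
  md <- metadata[match(rownames(fractions), metadata$sample), ]
  if (anyNA(md$sample))
    stop("metadata missing for some samples", call. = FALSE)
  tp <- sort(unique(md[[time_col]]))
  mean_fr <- t(vapply(tp, function(t0) {
    colMeans(fractions[md[[time_col]] == t0, , drop = FALSE])
  }, numeric(ncol(fractions))))
  rownames(mean_fr) <- as.character(tp)
  act <- if (nrow(mean_fr) >= 2L) zscore_cols(mean_fr) else mean_fr * 0
  list(activity = act, mean_fractions = mean_fr, time = tp)
}

#' Spearman correlation between cell-type fractions and plant traits
#'
#' For each type and trait, the Spearman rank correlation (average-rank
#' tie handling) and its two-sided p-value across plants.
#'
#' @param fractions samples x types matrix (or `decon_fit`).
#' @param traits data.frame of numeric traits (rows matching the fraction
#'   rows; e.g. pseudotime, biomass, leaf area).
#' @return data.frame with `type`, `trait`, `rho`, `p`; constant traits
#'   give `NA`.
#' @export
trait_correlation <- function(fractions, traits) {
  if (inherits(fractions, "decon_fit")) fractions <- coef(fractions)
  fractions <- as.matrix(fractions)
  traits <- as.data.frame(traits)
  stopifnot(nrow(traits) == nrow(fractions))
  if (nrow(fractions) < 4L)
    stop("need at least 4 plants with trait values", call. = FALSE)
  out <- list()
  for (ty in colnames(fractions)) {
    for (tr in names(traits)) {
      x <- fractions[, ty]; y <- traits[[tr]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 4L || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
        out[[length(out) + 1L]] <-
          data.frame(type = ty, trait = tr, rho = NA_real_, p = NA_real_)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      out[[length(out) + 1L]] <-
        data.frame(type = ty, trait = tr, rho = unname(ct$estimate),
                   p = ct$p.value)
    }
  }
  do.call(rbind, out)
}

#' Mean expression of a gene set per cluster, z-scored per gene
#'
#' Computes each gene's mean depth-normalized expression in every cluster
#' of the single-cell reference, then z-scores across clusters per gene,
#' showing in which clusters the set is preferentially expressed.
#'
#' @param sc_counts genes x cells count matrix.
#' @param labels named character vector (cell -> cluster).
#' @param gene_set character vector of genes; genes absent from the
#'   reference are dropped and listed in the `missing` attribute.
#' @return clusters x genes matrix of z-scores.
#' @export
geneset_cluster_profile <- function(sc_counts, labels, gene_set) {
  check_count_matrix(sc_counts)
  labels <- labels[colnames(sc_counts)]
  missing <- setdiff(gene_set, rownames(sc_counts))
  genes <- intersect(gene_set, rownames(sc_counts))
  if (!length(genes))
    stop("no gene of the set is present in the reference", call. = FALSE)
  if (length(missing))
    message("geneset_cluster_profile: ", length(missing),
            " gene(s) absent from the reference, dropped")
  norm <- cp10k(sc_counts)[genes, , drop = FALSE]
  clusters <- sort(unique(labels))
  means <- vapply(clusters, function(cl) {
    rowMeans(norm[, labels == cl, drop = FALSE])
  }, numeric(length(genes)))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, clusters))
  z <- t(zscore_cols(t(means)))  # z-score across clusters, per gene
  out <- t(z)                    # clusters x genes
  attr(out, "missing") <- missing
  out
}

#' Peak timepoint of each cell type's activity trajectory
#'
#' @param activity timepoints x types matrix (e.g. from
#'   [average_replicates()]).
#' @param time numeric vector of ordered timepoints (defaults to the
#'   activity rownames).
#' @return named numeric vector: per type, the timepoint of maximum
#'   activity (ties resolved to the earliest).
#' @export
peak_time <- function(activity, time = NULL) {
  activity <- as.matrix(activity)
  if (is.null(time)) time <- as.numeric(rownames(activity))
  stopifnot(length(time) == nrow(activity), !anyNA(time))
  ord <- order(time)
  activity <- activity[ord, , drop = FALSE]
  time <- time[ord]
  vapply(colnames(activity), function(ty)
    time[which.max(activity[, ty])], numeric(1L))
}
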