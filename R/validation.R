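# Scoring deconvolution output against known composition: per-type
# correlation and best-fit slope across samples, and argmax classification
# of single-type pseudobulks into a confusion matrix.

#' Per-type Pearson correlation between true and predicted fractions
#'
#' @param true_fractions,predicted_fractions matched samples x types
#'   matrices (same row and column names).
#' @return data.frame with `type`, `pearson_r`, `pearson_p`, and the
#'   accuracy flag `r_gt_0.8`; constant columns give `NA` (reported as
#'   missing rather than zero).
#' @export
per_type_correlation <- function(true_fractions, predicted_fractions) {
  tp <- align_fraction_tables(true_fractions, predicted_fractions)
  if (nrow(tp$true) < 3L)
    stop("need at least 3 samples for correlation", call. = FALSE)
  res <- lapply(colnames(tp$true), function(ty) {
    x <- tp$true[, ty]; y <- tp$pred[, ty]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(type = ty, pearson_r = NA_real_,
                        pearson_p = NA_real_))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(type = ty, pearson_r = unname(ct$estimate),
               pearson_p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$r_gt_0.8 <- !is.na(out$pearson_r) & out$pearson_r > 0.8
  out
}

#' Per-type slope of the line of best fit (predicted on true)
#'
#' Ordinary least squares with intercept; slopes close to 1 indicate
#' well-calibrated predictions, while systematic over-/under-prediction
#' shows up as slopes away from 1.
#'
#' @inheritParams per_type_correlation
#' @return data.frame with `type`, `slope`, `intercept`; zero-variance
#'   truth gives `NA`.
#' @export
fit_slope <- function(true_fractions, predicted_fractions) {
  tp <- align_fraction_tables(true_fractions, predicted_fractions)
  if (nrow(tp$true) < 3L)
    stop("need at least 3 samples for a slope", call. = FALSE)
  res <- lapply(colnames(tp$true), function(ty) {
    x <- tp$true[, ty]; y <- tp$pred[, ty]
    if (stats::sd(x) == 0)
      return(data.frame(type = ty, slope = NA_real_,
                        intercept = NA_real_))
    co <- stats::coef(stats::lm(y ~ x))
    data.frame(type = ty, slope = unname(co[2L]),
               intercept = unname(co[1L]))
  })
  do.call(rbind, res)
}

#' Classify single-type pseudobulks by their largest predicted fraction
#'
#' The predicted label is the argmax fraction, with exact ties broken by
#' lexicographic type id.
#'
#' @param predicted_fractions samples x types matrix for single-type
#'   pseudobulks.
#' @param true_label character vector (length = samples) of the type each
#'   pseudobulk was built from.
#' @return list: `predicted` labels and `confusion` (true x predicted
#'   contingency table over all types).
#' @export
classify_single_type <- function(predicted_fractions, true_label) {
  fr <- as.matrix(predicted_fractions)
  stopifnot(nrow(fr) == length(true_label))
  types <- colnames(fr)
  ord <- order(types)  # lexicographic tie-break
  pred <- apply(fr[, ord, drop = FALSE], 1L, function(row)
    types[ord][which.max(row)])
  lev <- sort(unique(c(types, true_label)))
  confusion <- table(true = factor(true_label, lev),
                     predicted = factor(pred, lev))
  list(predicted = pred, confusion = confusion)
}

#' Full benchmark report for a deconvolution run
#'
#' Bundles per-type correlation, best-fit slope, and (when single-type
#' pseudobulk predictions are supplied) the argmax confusion matrix, the
#' way a simulated-mixture validation of a deconvolution engine is
#' usually summarized.
#'
#' @inheritParams per_type_correlation
#' @param single_type_pred optional samples x types fractions of
#'   single-type pseudobulks.
#' @param single_type_label their true type labels.
#' @return a `benchmark_report` list: `per_type` (r, p, slope per type),
#'   `confusion` (or `NULL`).
#' @export
benchmark_report <- function(true_fractions, predicted_fractions,
                             single_type_pred = NULL,
                             single_type_label = NULL) {
  per_type <- merge(
    per_type_correlation(true_fractions, predicted_fractions),
    fit_slope(true_fractions, predicted_fractions),
    by = "type", sort = TRUE)
  confusion <- NULL
  if (!is.null(single_type_pred))
    confusion <- classify_single_type(single_type_pred,
                                      single_type_label)$confusion
  structure(list(per_type = per_type, confusion = confusion),
            class = "benchmark_report")
}

#' @exportS3Method base::print
print.benchmark_report <- function(x, ...) {
  cat("Deconvolution benchmark report\n")
  df <- x$per_type
  df$pearson_r <- signif(df$pearson_r, 4)
  df$slope <- signif(df$slope, 4)
  print(df[, c("type", "pearson_r", "slope", "r_gt_0.8")])
  if (!is.null(x$confusion)) {
    correct <- sum(diag(x$confusion)) / sum(x$confusion)
    cat("single-type argmax accuracy:", signif(correct, 4), "\n")
  }
  invisible(x)
}

align_fraction_tables <- function(true_fractions, predicted_fractions) {
  tf <- as.matrix(true_fractions)
  pf <- as.matrix(predicted_fractions)
  if (!is.null(rownames(tf)) && !is.null(rownames(pf))) {
    shared <- intersect(rownames(tf), rownames(pf))
    if (!length(shared)) stop("no shared samples", call. = FALSE)
    tf <- tf[shared, , drop = FALSE]
    pf <- pf[shared, , drop = FALSE]
  } else if (nrow(tf) != nrow(pf)) {
    stop("fraction tables have different sample counts", call. = FALSE)
  }
  if (is.null(colnames(tf)) || is.null(colnames(pf)) ||
      !all(colnames(tf) %in% colnames(pf)))
    stop("fraction tables must share type columns", call. = FALSE)
  pf <- pf[, colnames(tf), drop = FALSE]
  list(true = tf, pred = pf)
}
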