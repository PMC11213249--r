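# Context-specific regulatory subnetworks: expression-threshold filtering
# of a directed TF->target network, a functional-term pair enrichment
# statistic over the network topology, a threshold scan for local maxima /
# inflection points in network size, and cross-condition comparison.

#' Expression context for network filtering
#'
#' @param sc_expression gene x cell-type expression table (e.g. per-type
#'   mean counts-per-10,000).
#' @param bulk_expression gene x sample expression table.
#' @param sc_types selected cell types (non-empty subset of the columns).
#' @param bulk_samples selected time/age samples (non-empty subset).
#' @param sc_threshold,bulk_threshold expression thresholds (strict `>`).
#' @param quantifier `"any"` (default): a gene passes if it exceeds the
#'   threshold in at least one selected column; `"all"` requires every
#'   selected column.
#' @return an `expression_context` list.
#' @export
expression_context <- function(sc_expression, bulk_expression,
                               sc_types = colnames(sc_expression),
                               bulk_samples = colnames(bulk_expression),
                               sc_threshold, bulk_threshold,
                               quantifier = c("any", "all")) {
  quantifier <- match.arg(quantifier)
  sc_expression <- as.matrix(sc_expression)
  bulk_expression <- as.matrix(bulk_expression)
  if (!length(sc_types) || !length(bulk_samples))
    stop("selection sets must be non-empty", call. = FALSE)
  if (!all(sc_types %in% colnames(sc_expression)))
    stop("unknown cell type in selection", call. = FALSE)
  if (!all(bulk_samples %in% colnames(bulk_expression)))
    stop("unknown bulk sample in selection", call. = FALSE)
  if (is.na(sc_threshold) || is.na(bulk_threshold))
    stop("thresholds must not be NA", call. = FALSE)
  structure(list(sc_expression = sc_expression,
                 bulk_expression = bulk_expression,
                 sc_types = sc_types, bulk_samples = bulk_samples,
                 sc_threshold = sc_threshold,
                 bulk_threshold = bulk_threshold,
                 quantifier = quantifier),
            class = "expression_context")
}

context_pass <- function(context, genes) {
  agg <- if (context$quantifier == "any") function(m) apply(m, 1L, max)
         else function(m) apply(m, 1L, min)
  pass_one <- function(expr, cols, thr) {
    known <- intersect(genes, rownames(expr))
    p <- stats::setNames(rep(FALSE, length(genes)), genes)
    if (length(known))
      p[known] <- agg(expr[known, cols, drop = FALSE]) > thr
    p  # genes absent from the table fail (conservative)
  }
  pass_one(context$sc_expression, context$sc_types, context$sc_threshold) &
    pass_one(context$bulk_expression, context$bulk_samples,
             context$bulk_threshold)
}

#' Filter a network to edges expressed in a context
#'
#' A gene passes when its expression strictly exceeds the single-cell
#' threshold in at least one selected cell type AND the bulk threshold in
#' at least one selected sample (quantifier configurable); an edge
#' survives iff both endpoints pass.  Genes absent from an expression
#' table fail the filter and are logged.
#'
#' @param edges data.frame with `source`, `target` columns.
#' @param context an [expression_context()].
#' @return the surviving edges (same shape as `edges`), with the set of
#'   genes that passed in the `passed_genes` attribute.
#' @export
filter_network <- function(edges, context) {
  stopifnot(inherits(context, "expression_context"),
            all(c("source", "target") %in% names(edges)))
  genes <- unique(c(edges$source, edges$target))
  uncovered <- setdiff(genes, union(rownames(context$sc_expression),
                                    rownames(context$bulk_expression)))
  if (length(uncovered))
    message("filter_network: ", length(uncovered),
            " edge gene(s) absent from the expression tables fail the filter")
  pass <- context_pass(context, genes)
  keep <- pass[edges$source] & pass[edges$target]
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "passed_genes") <- genes[pass[genes]]
  out
}

#' Functional-term pair enrichment over a network's topology
#'
#' For every ordered term pair (A, B), counts the edges whose source
#' carries A and whose target carries B.  Under the null that edges fall
#' independently of annotation, the count is Binomial(N, p0) with
#' `p0 = frac(A) * frac(B)`, the term frequencies being computed over the
#' genes present in the network; the p-value is the exact upper binomial
#' tail at the observed count.
#'
#' @param edges data.frame with `source`, `target` (e.g. a
#'   [filter_network()] result).
#' @param annotations named list term -> gene id vector (GMT-shaped, see
#'   [read_gmt()]).
#' @return a `term_network` data.frame: `termA`, `termB`, `observed`,
#'   `expected`, `p`, with the total edge count in the `n_edges`
#'   attribute.  A term annotating no network gene yields observed 0 and
#'   p = 1.
#' @export
pafway_term_network <- function(edges, annotations) {
  stopifnot(all(c("source", "target") %in% names(edges)))
  if (!nrow(edges)) stop("network has no edges", call. = FALSE)
  if (!length(annotations)) stop("no annotation terms", call. = FALSE)
  genes <- unique(c(edges$source, edges$target))
  terms <- names(annotations)
  M <- vapply(annotations, function(g) genes %in% g,
              logical(length(genes)))
  M <- matrix(M, nrow = length(genes), dimnames = list(genes, terms))
  if (!any(M)) stop("no annotated gene in the network", call. = FALSE)

  N <- nrow(edges)
  storage.mode(M) <- "numeric"
  observed <- t(M[edges$source, , drop = FALSE]) %*%
    M[edges$target, , drop = FALSE]           # termA (source) x termB (target)
  frac <- colSums(M) / length(genes)
  p0 <- outer(frac, frac)                     # frac(A) * frac(B)
  expected <- N * p0
  # exact upper tail P[X >= observed], X ~ Binomial(N, p0)
  p <- matrix(stats::pbinom(as.vector(observed) - 1, N, as.vector(p0),
                            lower.tail = FALSE),
              nrow = length(terms), dimnames = dimnames(observed))
  p[observed == 0] <- 1

  out <- data.frame(
    termA = rep(terms, times = length(terms)),
    termB = rep(terms, each = length(terms)),
    observed = as.vector(observed),
    expected = as.vector(expected),
    p = as.vector(p),
    stringsAsFactors = FALSE)
  attr(out, "n_edges") <- N
  class(out) <- c("term_network", "data.frame")
  out
}

#' Scan expression thresholds for turning points in network size
#'
#' For every grid point the network is filtered, the term network is
#' computed, and the number of significant term pairs (`p < alpha`,
#' optionally BH-corrected) is recorded.  Along each 1-D slice (one
#' threshold varying, the other fixed) a point is flagged a local maximum
#' when strictly greater than both neighbours, and an inflection point
#' when the discrete second difference changes sign there; such turning
#' points are natural threshold choices.
#'
#' @param edges data.frame with `source`, `target`.
#' @param context an [expression_context()] (its thresholds are
#'   overridden by the grid).
#' @param annotations term -> genes list.
#' @param sc_grid,bulk_grid numeric threshold grids.
#' @param alpha significance level on the term-pair p-values; default 0.05.
#' @param bh apply Benjamini-Hochberg correction before thresholding
#'   (default `FALSE`, matching the raw-p criterion).
#' @return a `threshold_scan` data.frame: `sc_threshold`,
#'   `bulk_threshold`, `n_edges`, `n_significant`, `local_maximum`,
#'   `inflection_point`.
#' @export
threshold_scan <- function(edges, context, annotations, sc_grid, bulk_grid,
                           alpha = 0.05, bh = FALSE) {
  stopifnot(length(sc_grid) >= 1L, length(bulk_grid) >= 1L)
  grid <- expand.grid(sc_threshold = sort(sc_grid),
                      bulk_threshold = sort(bulk_grid),
                      KEEP.OUT.ATTRS = FALSE)
  n_sig <- n_edge <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ctx <- context
    ctx$sc_threshold <- grid$sc_threshold[i]
    ctx$bulk_threshold <- grid$bulk_threshold[i]
    sub <- suppressMessages(filter_network(edges, ctx))
    n_edge[i] <- nrow(sub)
    if (!nrow(sub)) { n_sig[i] <- 0L; next }
    tn <- tryCatch(pafway_term_network(sub, annotations),
                   error = function(e) NULL)
    if (is.null(tn)) { n_sig[i] <- 0L; next }
    pv <- if (bh) stats::p.adjust(tn$p, "BH") else tn$p
    n_sig[i] <- sum(pv < alpha)
  }
  grid$n_edges <- n_edge
  grid$n_significant <- n_sig
  grid$local_maximum <- FALSE
  grid$inflection_point <- FALSE
  for (b in unique(grid$bulk_threshold)) {
    idx <- which(grid$bulk_threshold == b)
    idx <- idx[order(grid$sc_threshold[idx])]
    tp <- turning_points(grid$n_significant[idx])
    grid$local_maximum[idx] <- grid$local_maximum[idx] | tp$local_maximum
    grid$inflection_point[idx] <- grid$inflection_point[idx] | tp$inflection
  }
  for (s in unique(grid$sc_threshold)) {
    idx <- which(grid$sc_threshold == s)
    idx <- idx[order(grid$bulk_threshold[idx])]
    tp <- turning_points(grid$n_significant[idx])
    grid$local_maximum[idx] <- grid$local_maximum[idx] | tp$local_maximum
    grid$inflection_point[idx] <- grid$inflection_point[idx] | tp$inflection
  }
  class(grid) <- c("threshold_scan", "data.frame")
  grid
}

#' Turning points of a 1-D count profile
#'
#' @param x numeric vector (e.g. significant-edge counts along one
#'   threshold axis).
#' @return list of logical vectors `local_maximum` (strictly greater than
#'   both neighbours) and `inflection` (discrete second difference changes
#'   sign).
#' @export
turning_points <- function(x) {
  n <- length(x)
  lm_ <- infl <- rep(FALSE, n)
  if (n >= 3L) {
    interior <- 2:(n - 1L)
    lm_[interior] <- x[interior] > x[interior - 1L] &
      x[interior] > x[interior + 1L]
    d2 <- diff(x, differences = 2L)       # defined at points 2..n-1
    if (n >= 4L) {
      for (i in seq_len(n - 3L)) {        # compare d2 at points i+1, i+2
        if (d2[i] * d2[i + 1L] < 0) infl[i + 1L] <- TRUE
      }
    }
  }
  list(local_maximum = lm_, inflection = infl)
}

#' Compare significant term edges across conditions
#'
#' @param term_networks named list of [pafway_term_network()] results
#'   (one per condition, >= 2).
#' @param alpha significance level; default 0.05.
#' @return list: `significant` (per-condition sets of "A->B" edges),
#'   `shared` (present in every condition), `unique` (per condition, in
#'   that condition only), `venn` (counts per membership pattern).
#' @export
compare_condition_networks <- function(term_networks, alpha = 0.05) {
  stopifnot(length(term_networks) >= 2L, !is.null(names(term_networks)))
  sig <- lapply(term_networks, function(tn) {
    stopifnot(inherits(tn, "term_network"))
    paste0(tn$termA, "->", tn$termB)[tn$p < alpha]
  })
  all_edges <- unique(unlist(sig))
  membership <- vapply(sig, function(s) all_edges %in% s,
                       logical(length(all_edges)))
  membership <- matrix(membership, nrow = length(all_edges),
                       dimnames = list(all_edges, names(sig)))
  pattern <- apply(membership, 1L, function(m)
    paste(names(sig)[m], collapse = "&"))
  venn <- if (length(all_edges)) table(pattern) else table(character(0))
  uniq <- lapply(names(sig), function(nm) {
    others <- unique(unlist(sig[setdiff(names(sig), nm)]))
    setdiff(sig[[nm]], others)
  })
  names(uniq) <- names(sig)
  list(significant = sig,
       shared = Reduce(intersect, sig),
       unique = uniq,
       venn = venn)
}
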