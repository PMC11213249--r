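# Synthetic TF->target network with term annotations and planted
# functional-term-pair enrichment, for calibrating and power-testing the
# term-pair enrichment statistic.

#' Configuration for the synthetic annotated network
#'
#' @param n_tfs,n_targets numbers of source (TF) and target genes.
#' @param n_edges number of directed edges to draw
#'   (`<= n_tfs * n_targets`).
#' @param n_terms number of functional terms.
#' @param annotation_prob probability that a gene carries any given term
#'   (independent per gene and term).
#' @param planted_pairs list of `list(a =, b =, factor =)`: edges from a
#'   gene carrying term `a` to a gene carrying term `b` are oversampled by
#'   `factor` (>= 1).
#' @param seed integer seed.
#' @return a `network_sim_config` list.
#' @export
network_sim_config <- function(n_tfs, n_targets, n_edges, n_terms,
                               annotation_prob, planted_pairs = list(),
                               seed = 1L) {
  cfg <- list(n_tfs = as.integer(n_tfs), n_targets = as.integer(n_targets),
              n_edges = as.integer(n_edges), n_terms = as.integer(n_terms),
              annotation_prob = annotation_prob,
              planted_pairs = planted_pairs, seed = seed)
  class(cfg) <- "network_sim_config"
  if (cfg$n_edges > cfg$n_tfs * cfg$n_targets)
    stop("n_edges: exceeds n_tfs * n_targets", call. = FALSE)
  if (annotation_prob < 0 || annotation_prob >= 1)
    stop("annotation_prob: must lie in [0, 1)", call. = FALSE)
  for (p in planted_pairs) {
    if (!all(c("a", "b", "factor") %in% names(p)))
      stop("planted_pairs: entries need fields a, b, factor", call. = FALSE)
    if (p$factor < 1)
      stop("planted_pairs: enrichment factor must be >= 1", call. = FALSE)
    if (p$factor * annotation_prob^2 > 1)
      stop("planted_pairs: enrichment factor times base pair rate exceeds 1",
           call. = FALSE)
  }
  cfg
}

#' Simulate an annotated TF->target network with planted term-pair signal
#'
#' Every gene receives each term independently with `annotation_prob`.
#' Edges are then drawn without replacement from all TF x target pairs
#' with probability proportional to a weight that is 1 except for pairs
#' hit by a planted term pair, whose weight is multiplied by the
#' enrichment factor; the expected count of a planted A->B pair is thus
#' about `factor * p0 * n_edges` for small base rates `p0`.
#'
#' @param config a [network_sim_config()].
#' @return a `synthetic_network` list: `edges` (data.frame source/target),
#'   `annotations` (term -> gene vector list, GMT-shaped),
#'   `planted_pairs`, `config`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "network_sim_config"))
  cfg <- config
  tfs <- sprintf("TF%04d", seq_len(cfg$n_tfs))
  tgs <- sprintf("G%05d", seq_len(cfg$n_targets))
  genes <- c(tfs, tgs)
  terms <- sprintf("term%02d", seq_len(cfg$n_terms))

  with_seed(cfg$seed, {
    ann_mat <- matrix(stats::runif(length(genes) * cfg$n_terms) <
                        cfg$annotation_prob,
                      nrow = length(genes),
                      dimnames = list(genes, terms))
    annotations <- lapply(terms, function(tm) genes[ann_mat[, tm]])
    names(annotations) <- terms

    # pair index p = (j - 1) * n_tfs + i  <->  source i, target j
    n_pairs <- cfg$n_tfs * cfg$n_targets
    if (length(cfg$planted_pairs)) {
      # weight factorizes only per planted pair, so build it multiplicatively
      w <- rep(1, n_pairs)
      for (p in cfg$planted_pairs) {
        src_hit <- ann_mat[tfs, p$a]
        tgt_hit <- ann_mat[tgs, p$b]
        bump <- as.numeric(outer(src_hit, tgt_hit)) * (p$factor - 1) + 1
        w <- w * bump
      }
      if (cfg$n_edges * max(w) / sum(w) > 1)
        stop("enrichment pushes a pair's sampling probability above 1",
             call. = FALSE)
      picks <- sample.int(n_pairs, cfg$n_edges, prob = w)
    } else {
      picks <- sample.int(n_pairs, cfg$n_edges)
    }
    src <- tfs[(picks - 1L) %% cfg$n_tfs + 1L]
    tgt <- tgs[(picks - 1L) %/% cfg$n_tfs + 1L]
    edges <- data.frame(source = src, target = tgt,
                        stringsAsFactors = FALSE)

    structure(list(edges = edges, annotations = annotations,
                   planted_pairs = cfg$planted_pairs, config = cfg),
              class = "synthetic_network")
  })
}

#' @exportS3Method base::print
print.synthetic_network <- function(x, ...) {
  cat("Synthetic network:", nrow(x$edges), "edges,",
      length(x$annotations), "terms,",
      length(x$planted_pairs), "planted pair(s)\n")
  invisible(x)
}
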