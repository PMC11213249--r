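toy_context <- function(sc_thr, bulk_thr, quantifier = "any") {
  sc <- cbind(meso = c(g1 = 5, g2 = 0.2, g3 = 3, g4 = 2))
  blk <- cbind(s1 = c(g1 = 2, g2 = 2, g3 = 0.1, g4 = 2))
  expression_context(sc, blk, sc_threshold = sc_thr,
                     bulk_threshold = bulk_thr, quantifier = quantifier)
}

toy_edges <- function() {
  data.frame(source = c("g1", "g1", "g3", "g2"),
             target = c("g2", "g4", "g4", "g3"),
             stringsAsFactors = FALSE)
}

test_that("the hand-traced four-gene filter keeps exactly g1->g4", {
  # pass rule: sc > 1 in some selected type AND bulk > 1 in some sample
  # g1 (5, 2) passes; g2 (0.2, 2) fails sc; g3 (3, 0.1) fails bulk;
  # g4 (2, 2) passes -> only g1->g4 survives
  out <- filter_network(toy_edges(), toy_context(1, 1))
  expect_equal(nrow(out), 1L)
  expect_equal(out$source, "g1")
  expect_equal(out$target, "g4")
  expect_setequal(attr(out, "passed_genes"), c("g1", "g4"))
})

test_that("threshold extremes return the full and the empty network", {
  all_in <- filter_network(toy_edges(), toy_context(-Inf, -Inf))
  expect_equal(nrow(all_in), 4L)
  none <- filter_network(toy_edges(), toy_context(100, 100))
  expect_equal(nrow(none), 0L)
})

test_that("genes missing from expression tables fail the filter", {
  edges <- rbind(toy_edges(),
                 data.frame(source = "g1", target = "ghost"))
  expect_message(out <- filter_network(edges, toy_context(-Inf, -Inf)),
                 "absent")
  expect_false(any(out$target == "ghost"))
})

test_that("raising either threshold never adds edges (monotonicity)", {
  set.seed(81)
  genes <- sprintf("g%02d", 1:40)
  sc <- matrix(rgamma(40 * 3, 2), 40, 3,
               dimnames = list(genes, c("t1", "t2", "t3")))
  blk <- matrix(rgamma(40 * 4, 2), 40, 4,
                dimnames = list(genes, paste0("s", 1:4)))
  edges <- data.frame(source = sample(genes, 60, TRUE),
                      target = sample(genes, 60, TRUE))
  edges <- unique(edges)
  key <- function(e) paste(e$source, e$target)
  for (grid in list(seq(0, 4, 0.5))) {
    prev <- NULL
    for (thr in grid) {
      ctx <- expression_context(sc, blk, sc_threshold = thr,
                                bulk_threshold = 0.5)
      cur <- key(filter_network(edges, ctx))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
    prev <- NULL
    for (thr in grid) {
      ctx <- expression_context(sc, blk, sc_threshold = 0.5,
                                bulk_threshold = thr)
      cur <- key(filter_network(edges, ctx))
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("term-pair p-values equal the exact binomial tail", {
  # worked example: 100 network genes, 10 carry A, 20 carry B,
  # N = 100 edges, observed 8, p0 = 0.02
  genes <- sprintf("g%03d", 1:100)
  set.seed(82)
  # build an edge list on 100 genes with exactly 100 edges, 8 of them A->B
  A_genes <- genes[1:10]; B_genes <- genes[11:30]
  src <- c(rep(A_genes[1:8], 1), sample(genes[31:100], 92, TRUE))
  tgt <- c(B_genes[1:8], sample(genes[31:100], 92, TRUE))
  edges <- data.frame(source = src, target = tgt)
  # keep only pairs leaving exactly the planted A->B edges
  ann <- list(A = A_genes, B = B_genes)
  tn <- pafway_term_network(edges, ann)
  net_genes <- unique(c(edges$source, edges$target))
  fa <- sum(net_genes %in% A_genes) / length(net_genes)
  fb <- sum(net_genes %in% B_genes) / length(net_genes)
  p0 <- fa * fb
  obs <- tn$observed[tn$termA == "A" & tn$termB == "B"]
  expect_equal(obs, 8L)
  # brute-force tail sum oracle
  N <- nrow(edges)
  oracle <- sum(choose(N, obs:N) * p0^(obs:N) * (1 - p0)^(N - obs:N))
  expect_equal(tn$p[tn$termA == "A" & tn$termB == "B"], oracle,
               tolerance = 1e-10)
  expect_equal(tn$expected[tn$termA == "A" & tn$termB == "B"], N * p0,
               tolerance = 1e-12)
})

test_that("zero observed edges give p = 1 and unannotated terms are inert", {
  edges <- data.frame(source = c("x", "y"), target = c("y", "z"))
  ann <- list(A = "x", B = character(0))
  tn <- pafway_term_network(edges, ann)
  expect_equal(tn$p[tn$termA == "B" & tn$termB == "A"], 1)
  expect_equal(tn$observed[tn$termA == "B"], c(0L, 0L))
  expect_true(all(tn$p > 0 & tn$p <= 1))
})

test_that("expected counts sum to N times the total pair probability", {
  net <- simulate_network(network_sim_config(60, 80, 150, 5, 0.3, seed = 83))
  tn <- pafway_term_network(net$edges, net$annotations)
  genes <- unique(c(net$edges$source, net$edges$target))
  frac <- vapply(net$annotations, function(g) mean(genes %in% g), 0)
  expect_equal(sum(tn$expected), nrow(net$edges) * sum(outer(frac, frac)),
               tolerance = 1e-9)
})

test_that("threshold scans flag local maxima and inflection points", {
  tp <- turning_points(c(1, 5, 3))
  expect_equal(tp$local_maximum, c(FALSE, TRUE, FALSE))
  expect_equal(turning_points(c(2, 2, 2, 2))$local_maximum, rep(FALSE, 4))
  expect_equal(turning_points(c(2, 2, 2, 2))$inflection, rep(FALSE, 4))
  # convex then concave: second difference changes sign
  x <- c(0, 1, 4, 6, 7, 7.5)
  tp2 <- turning_points(x)
  expect_true(any(tp2$inflection))

  sc <- cbind(meso = c(g1 = 5, g2 = 3, g3 = 2, g4 = 1))
  blk <- cbind(s1 = c(g1 = 5, g2 = 3, g3 = 2, g4 = 1))
  ctx <- expression_context(sc, blk, sc_threshold = 0, bulk_threshold = 0)
  edges <- data.frame(source = c("g1", "g2", "g1"),
                      target = c("g2", "g3", "g4"))
  ann <- list(A = c("g1", "g2"), B = c("g2", "g3", "g4"))
  scan <- threshold_scan(edges, ctx, ann, sc_grid = c(0, 1.5, 2.5),
                         bulk_grid = 0, alpha = 0.05)
  expect_equal(nrow(scan), 3L)
  expect_true(all(diff(scan$n_edges[order(scan$sc_threshold)]) <= 0))
  # alpha = 0 can never call significance since p > 0 always
  scan0 <- threshold_scan(edges, ctx, ann, sc_grid = c(0, 2.5),
                          bulk_grid = 0, alpha = 0)
  expect_true(all(scan0$n_significant == 0))
})

test_that("condition comparison partitions shared and unique term edges", {
  mk <- function(sig_pairs) {
    tn <- data.frame(termA = c("a", "b", "c"), termB = c("b", "c", "d"),
                     observed = 5L, expected = 1,
                     p = ifelse(paste0(c("a", "b", "c"), "->",
                                       c("b", "c", "d")) %in% sig_pairs,
                                0.01, 0.9))
    class(tn) <- c("term_network", "data.frame")
    tn
  }
  cmp <- compare_condition_networks(
    list(young = mk(c("a->b", "b->c")), old = mk(c("b->c", "c->d"))))
  expect_equal(cmp$shared, "b->c")
  expect_equal(cmp$unique$young, "a->b")
  expect_equal(cmp$unique$old, "c->d")
  expect_equal(sort(unname(as.vector(cmp$venn))), c(1, 1, 1))

  same <- compare_condition_networks(list(a = mk("a->b"), b = mk("a->b")))
  expect_length(same$unique$a, 0)
  expect_length(same$unique$b, 0)
})
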