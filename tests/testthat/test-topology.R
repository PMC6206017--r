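# worked examples with hand-derived values, then randomized oracle checks
adj <- function(n, edges, labels = NULL) {
  A <- matrix(0, n, n)
  for (e in edges) A[e[1], e[2]] <- 1
  if (!is.null(labels)) dimnames(A) <- list(labels, labels)
  A
}

path3 <- adj(3, list(c(1, 2), c(2, 3)), c("A", "B", "C"))
cycle3 <- adj(3, list(c(1, 2), c(2, 3), c(3, 1)), c("A", "B", "C"))

test_that("degrees on hand-worked graphs", {
  net <- net_from_adj(cycle3)
  d <- degrees(net)
  expect_equal(unname(as.numeric(d$k_in)), c(1, 1, 1))
  expect_equal(unname(as.numeric(d$k_out)), c(1, 1, 1))
  expect_equal(unname(as.numeric(d$k)), c(2, 2, 2))
  expect_equal(d$mean_degree, 1)

  # A + B => C style fan-in
  fan <- net_from_adj(adj(3, list(c(1, 3), c(2, 3)), c("A", "B", "C")))
  df <- degrees(fan)
  expect_equal(unname(df$k_out["A"]), 1)
  expect_equal(unname(df$k_in["C"]), 2)
  expect_equal(unname(df$k["C"]), 2)
})

test_that("directed path lengths use the zero-for-unreachable convention", {
  sp <- shortest_distances(net_from_adj(path3))
  expect_equal(sp$D["A", "C"], 2)
  expect_equal(sp$D["C", "A"], 0)
  expect_equal(sp$L, 4 / 6)
  expect_equal(shortest_distances(net_from_adj(cycle3))$L, 1.5)
  # no edges at all: every pair unreachable, L = 0
  empty <- net_from_adj(matrix(0, 3, 3))
  expect_equal(shortest_distances(empty)$L, 0)
  one <- net_from_adj(matrix(0, 1, 1))
  expect_error(shortest_distances(one), "2 nodes")
})

test_that("directed clustering counts ordered neighbor pairs", {
  # leaf node: k = 1 forces C = 0
  expect_equal(unname(local_clustering(net_from_adj(path3))["A"]), 0)
  # fully bidirectional triangle: k = 4, e = 2 ordered linked pairs
  tri <- adj(3, list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)))
  expect_equal(unname(as.numeric(local_clustering(net_from_adj(tri)))),
               rep(2 / 12, 3))
  # out-star with one cross edge: k(A) = 3, e(A) = 1
  star <- adj(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3)),
              c("A", "B", "C", "D"))
  expect_equal(unname(local_clustering(net_from_adj(star))["A"]), 1 / 6)
})

test_that("HITS converges to the known fixed points", {
  # two hubs feeding one authority
  fan <- net_from_adj(adj(3, list(c(1, 3), c(2, 3)), c("A", "B", "C")))
  hs <- hits_scores(fan)
  expect_equal(unname(as.numeric(hs$hub)), c(1 / sqrt(2), 1 / sqrt(2), 0),
               tolerance = 1e-8)
  expect_equal(unname(as.numeric(hs$authority)), c(0, 0, 1),
               tolerance = 1e-8)
  expect_true(hs$converged)
  # rotational symmetry of the 3-cycle
  hc <- hits_scores(net_from_adj(cycle3))
  expect_equal(diff(range(hc$hub)), 0, tolerance = 1e-7)
  expect_equal(diff(range(hc$authority)), 0, tolerance = 1e-7)
  expect_error(hits_scores(net_from_adj(matrix(0, 2, 2))), "edgeless")
})

test_that("hub and authority coincide on bidirectional graphs", {
  set.seed(5)
  for (i in 1:5) {
    A <- random_digraph(6, 0.35)
    S <- pmax(A, t(A))
    hs <- hits_scores(net_from_adj(S))
    expect_equal(as.numeric(hs$hub), as.numeric(hs$authority),
                 tolerance = 1e-6)
  }
})

test_that("betweenness on hand-worked graphs", {
  b <- betweenness_scores(net_from_adj(path3))
  expect_equal(unname(b), c(0, 0.5, 0))
  expect_equal(unname(betweenness_scores(net_from_adj(cycle3))),
               rep(0.5, 3))
  expect_error(betweenness_scores(net_from_adj(matrix(0, 2, 2))), "3 nodes")
})

test_that("eigencentrality matches the closed-form 3-path eigenpair", {
  # undirected path a-b-c encoded as one directed arc per link
  eig <- eigencentrality(net_from_adj(path3))
  expect_equal(eig$lambda, sqrt(2), tolerance = 1e-8)
  v <- c(1, sqrt(2), 1)
  expect_equal(unname(as.numeric(eig$centrality)), v / sqrt(sum(v^2)),
               tolerance = 1e-6)
  # complete symmetric triangle: all equal by symmetry
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(diff(range(eigencentrality(net_from_adj(tri))$centrality)),
               0, tolerance = 1e-8)
})

test_that("local efficiency on hand-worked graphs", {
  # neighbors of B (A and C) share no edge
  expect_equal(unname(local_efficiency(net_from_adj(path3))$F_i["B"]), 0)
  tri <- adj(3, list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)))
  expect_equal(unname(as.numeric(local_efficiency(net_from_adj(tri))$F_i)),
               rep(1, 3))
})

test_that("nine metrics agree with brute-force oracles on random digraphs", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(3:7, 1)
    expect_metrics_match_oracles(random_digraph(n, stats::runif(1, 0.15, 0.5)))
  }
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(77)
  A <- random_digraph(6, 0.4)
  rownames(A) <- colnames(A) <- c("b", "d", "a", "f", "c", "e")
  net <- net_from_adj(A)   # nodes get sorted internally by name
  perm <- order(rownames(A))
  B <- A[perm, perm]
  netp <- net_from_adj(B)
  for (f in list(function(x) node_metrics(x))) {
    m1 <- f(net)[sort(rownames(A)), ]
    m2 <- f(netp)[sort(rownames(A)), ]
    expect_equal(m1, m2, tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("discrete power-law MLE recovers a known exponent", {
  set.seed(2024)
  kmax <- 1e5
  pk <- (1:kmax)^(-2.5)
  x <- sample.int(kmax, 1e4, replace = TRUE, prob = pk)
  g <- metnetphylo:::powerlaw_mle(x)
  expect_gt(g, 2.4)
  expect_lt(g, 2.6)
  # degenerate all-equal sample is flagged not estimable
  expect_true(is.na(metnetphylo:::powerlaw_mle(rep(1, 100))))
  expect_true(is.na(metnetphylo:::powerlaw_mle(1:5)))  # too few
  # permutation invariance
  expect_equal(metnetphylo:::powerlaw_mle(rev(x)), g)
})

test_that("node_metrics assembles all nine columns with finite values", {
  set.seed(9)
  net <- net_from_adj(random_digraph(7, 0.4))
  tab <- node_metrics(net)
  expect_equal(colnames(tab), metric_names())
  expect_true(all(is.finite(as.matrix(tab))))
  expect_equal(rownames(tab), net$nodes)
  gm <- global_metrics(net)
  expect_equal(gm$mean_degree, net$E / net$N)
})
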