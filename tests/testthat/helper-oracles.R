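# Independent brute-force oracles over a dense adjacency matrix.
# Deliberately naive (loops, Floyd-Warshall, dense eigendecomposition,
# matrix-power path counting) so they share no code path with the package.

# metabolic_network object from a dense 0/1 adjacency matrix
net_from_adj <- function(A, taxon = "toy") {
  n <- nrow(A)
  nodes <- if (is.null(rownames(A))) sprintf("n%02d", seq_len(n))
           else rownames(A)
  dimnames(A) <- list(nodes, nodes)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  structure(list(taxon_id = taxon, nodes = nodes, graph = g,
                 N = n, E = sum(A)),
            class = "metabolic_network")
}

random_digraph <- function(n, p) {
  repeat {
    A <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
    diag(A) <- 0
    if (sum(A) >= 1) return(A)
  }
}

oracle_degrees <- function(A) {
  n <- nrow(A)
  k_in <- k_out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    k_out[i] <- k_out[i] + A[i, j]
    k_in[i] <- k_in[i] + A[j, i]
  }
  list(k = k_in + k_out, k_in = k_in, k_out = k_out)
}

# Floyd-Warshall; Inf for unreachable
oracle_dist_inf <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_distances <- function(A) {
  D <- oracle_dist_inf(A)
  D[is.infinite(D)] <- 0
  list(D = D, L = sum(D) / (nrow(A) * (nrow(A) - 1)))
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  k <- oracle_degrees(A)$k
  vapply(seq_len(n), function(i) {
    if (k[i] <= 1) return(0)
    nb <- setdiff(which(A[i, ] == 1 | A[, i] == 1), i)
    e_i <- 0
    for (u in nb) for (w in nb) if (u != w && A[u, w] == 1) e_i <- e_i + 1
    e_i / (k[i] * (k[i] - 1))
  }, numeric(1))
}

# geodesic path counts via matrix powers: a length-d(j,k) walk is a path
oracle_sigma <- function(A) {
  n <- nrow(A)
  D <- oracle_dist_inf(A)
  pows <- vector("list", n)
  pows[[1]] <- A
  if (n > 1) for (d in 2:n) pows[[d]] <- pows[[d - 1]] %*% A
  sigma <- function(j, k) {
    if (j == k) return(1)
    d <- D[j, k]
    if (is.infinite(d)) return(0)
    pows[[d]][j, k]
  }
  list(D = D, sigma = sigma)
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  s <- oracle_sigma(A)
  vapply(seq_len(n), function(i) {
    tot <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == k || j == i || k == i) next
      d <- s$D[j, k]
      if (is.infinite(d)) next
      if (is.infinite(s$D[j, i]) || is.infinite(s$D[i, k])) next
      if (s$D[j, i] + s$D[i, k] == d)
        tot <- tot + s$sigma(j, i) * s$sigma(i, k) / s$sigma(j, k)
    }
    tot / ((n - 1) * (n - 2))
  }, numeric(1))
}

principal_unit <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  v <- abs(e$vectors[, 1])
  list(vec = v / sqrt(sum(v^2)), value = e$values[1],
       gap = e$values[1] - ifelse(length(e$values) > 1, e$values[2], -Inf))
}

oracle_hits <- function(A) {
  list(hub = principal_unit(A %*% t(A)),
       authority = principal_unit(t(A) %*% A))
}

oracle_eigencentrality <- function(A) {
  S <- pmax(A, t(A))
  principal_unit(S)
}

oracle_efficiency_of <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_dist_inf(A)
  tot <- 0
  for (u in seq_len(n)) for (w in seq_len(n))
    if (u != w && is.finite(D[u, w])) tot <- tot + 1 / D[u, w]
  tot / (n * (n - 1))
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- setdiff(which(A[i, ] == 1 | A[, i] == 1), i)
    if (length(nb) < 2) return(0)
    oracle_efficiency_of(A[nb, nb, drop = FALSE])
  }, numeric(1))
}

# Check all nine local metrics of `net_from_adj(A)` against the oracles.
expect_metrics_match_oracles <- function(A, tol = 1e-8) {
  net <- net_from_adj(A)
  d <- degrees(net)
  od <- oracle_degrees(A)
  expect_equal(unname(as.numeric(d$k)), od$k)
  expect_equal(unname(as.numeric(d$k_in)), od$k_in)
  expect_equal(unname(as.numeric(d$k_out)), od$k_out)
  # the three expressions for the mean degree agree
  expect_equal(d$mean_degree, mean(od$k_in))
  expect_equal(d$mean_degree, mean(od$k_out))
  expect_equal(d$mean_degree, sum(A) / nrow(A))

  sp <- shortest_distances(net)
  osp <- oracle_distances(A)
  expect_equal(unname(sp$D), unname(osp$D))
  expect_equal(sp$L, osp$L)

  expect_equal(unname(as.numeric(local_clustering(net))),
               oracle_clustering(A), tolerance = tol)

  hits <- hits_scores(net)
  oh <- oracle_hits(A)
  # fixed point must satisfy the principal-eigenvector equation; compare
  # vectors directly whenever the eigenvalue is simple
  HH <- A %*% t(A)
  h <- as.numeric(hits$hub)
  expect_lt(sqrt(sum((HH %*% h - oh$hub$value * h)^2)), 1e-5)
  a <- as.numeric(hits$authority)
  AA <- t(A) %*% A
  expect_lt(sqrt(sum((AA %*% a - oh$authority$value * a)^2)), 1e-5)
  if (oh$hub$gap > 1e-6)
    expect_equal(h, oh$hub$vec, tolerance = 1e-5)
  if (oh$authority$gap > 1e-6)
    expect_equal(a, oh$authority$vec, tolerance = 1e-5)
  expect_true(all(h >= -tol) && all(a >= -tol))
  expect_equal(sum(h^2), 1, tolerance = tol)
  expect_equal(sum(a^2), 1, tolerance = tol)

  if (nrow(A) >= 3)
    expect_equal(unname(as.numeric(betweenness_scores(net))),
                 oracle_betweenness(A), tolerance = tol)

  eig <- eigencentrality(net)
  oe <- oracle_eigencentrality(A)
  S <- pmax(A, t(A))
  x <- as.numeric(eig$centrality)
  expect_equal(eig$lambda, oe$value, tolerance = 1e-6)
  expect_lt(sqrt(sum((S %*% x - oe$value * x)^2)), 1e-5)
  if (oe$gap > 1e-6)
    expect_equal(x, oe$vec, tolerance = 1e-5)

  eff <- local_efficiency(net)
  expect_equal(unname(as.numeric(eff$F_i)), oracle_local_efficiency(A),
               tolerance = tol)
  expect_equal(eff$global, oracle_efficiency_of(A), tolerance = tol)

  # range invariants
  expect_true(all(local_clustering(net) >= 0 & local_clustering(net) <= 1))
  expect_true(all(eff$F_i >= 0 & eff$F_i <= 1))
  invisible(NULL)
}

# ultrametric three-point condition on every triple of a cophenetic matrix
expect_ultrametric <- function(C, tol = 1e-9) {
  n <- nrow(C)
  for (a in seq_len(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    trio <- sort(c(C[a, b], C[a, cc], C[b, cc]), decreasing = TRUE)
    expect_lte(trio[1] - trio[2], tol)
  }
  invisible(NULL)
}
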