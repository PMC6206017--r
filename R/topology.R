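#' Degree measures
#'
#' In-degree is the number of incoming links (column sums of the
#' adjacency), out-degree the number of outgoing links (row sums), and
#' the degree their sum. The mean degree of the network equals the
#' common value of mean in-degree, mean out-degree and E/N.
#'
#' @param net A [build_network()] result.
#' @return List with numeric vectors `k`, `k_in`, `k_out` (named by node)
#'   and the scalar `mean_degree`.
#' @export
degrees <- function(net) {
  k_in <- igraph::degree(net$graph, mode = "in")
  k_out <- igraph::degree(net$graph, mode = "out")
  list(k = k_in + k_out, k_in = k_in, k_out = k_out,
       mean_degree = sum(k_in) / net$N)
}

#' Directed shortest-path distances and average path length
#'
#' Geodesic distances follow edge direction. Unreachable pairs take
#' distance zero (they still count in the average's denominator), so the
#' average path length is `L = sum_{i != j} D(i, j) / (N (N - 1))` with
#' zeros included.
#'
#' @param net A `metabolic_network` with at least 2 nodes.
#' @return List with the `N x N` matrix `D` and the scalar `L`.
#' @export
shortest_distances <- function(net) {
  if (net$N < 2L) stop_input("need at least 2 nodes for path lengths")
  D <- igraph::distances(net$graph, mode = "out")
  D[is.infinite(D)] <- 0
  diag(D) <- 0
  list(D = D, L = sum(D) / (net$N * (net$N - 1)))
}

#' Local clustering coefficient of a directed network
#'
#' For node i with total degree `k_i` (in plus out), the neighborhood is
#' the union of in- and out-neighbors (excluding i itself); `e_i` counts
#' the ordered neighbor pairs (u, w) joined by an arc u -> w, and
#' `C_i = e_i / (k_i (k_i - 1))`, with `C_i = 0` when `k_i <= 1`. With
#' `undirected = TRUE` the computation runs on the undirected projection
#' (unordered neighbor pairs, denominator `k (k - 1) / 2` with k the
#' projected degree), provided for sensitivity analysis.
#'
#' @param net A `metabolic_network`.
#' @param undirected Use the undirected-projection variant.
#' @return Named numeric vector `C_i` per node.
#' @export
local_clustering <- function(net, undirected = FALSE) {
  A <- adjacency(net)
  if (undirected) {
    U <- 1 * ((A + Matrix::t(A)) > 0)
    k <- Matrix::rowSums(U)
    ci <- vapply(seq_len(net$N), function(i) {
      nb <- which(U[i, ] > 0)
      if (length(nb) < 2L) return(0)
      links <- sum(U[nb, nb, drop = FALSE]) / 2
      links / (length(nb) * (length(nb) - 1) / 2)
    }, numeric(1))
  } else {
    k <- Matrix::rowSums(A) + Matrix::colSums(A)
    ci <- vapply(seq_len(net$N), function(i) {
      if (k[i] <= 1) return(0)
      nb <- setdiff(union(which(A[i, ] > 0), which(A[, i] > 0)), i)
      if (length(nb) < 2L) return(0)
      e_i <- sum(A[nb, nb, drop = FALSE])
      e_i / (k[i] * (k[i] - 1))
    }, numeric(1))
  }
  stats::setNames(ci, net$nodes)
}

#' HITS hub and authority scores
#'
#' Kleinberg's mutual-reinforcement scheme: authorities accumulate the hub
#' scores of their in-neighbors, hubs the authority scores of their
#' out-neighbors. Iteration starts from the all-ones condition, both
#' vectors are renormalized to unit Euclidean norm after each sweep, and
#' the fixed point makes the hub vector the principal eigenvector of
#' `A %*% t(A)` and the authority vector that of `t(A) %*% A`.
#'
#' @param net A `metabolic_network` with at least one edge.
#' @param tol Convergence tolerance on the max absolute change per sweep.
#' @param max_iter Iteration cap; non-convergence raises a warning and
#'   returns the last iterate.
#' @return List with unit-norm non-negative vectors `hub` and
#'   `authority`, plus `iterations` and `converged`.
#' @export
hits_scores <- function(net, tol = 1e-8, max_iter = 1000L) {
  if (net$E < 1L) stop_input("HITS undefined on an edgeless network")
  A <- adjacency(net)
  h <- rep(1, net$N)
  a <- rep(1, net$N)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    a_new <- as.numeric(Matrix::crossprod(A, h))   # A(v_j) = sum over in-edges
    h_new <- as.numeric(A %*% a_new)               # H(v_i) = sum over out-edges
    a_new <- a_new / max(sqrt(sum(a_new^2)), .Machine$double.eps)
    h_new <- h_new / max(sqrt(sum(h_new^2)), .Machine$double.eps)
    delta <- max(abs(a_new - a), abs(h_new - h))
    a <- a_new
    h <- h_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("HITS did not converge in ", max_iter, " iterations")
  list(hub = stats::setNames(h, net$nodes),
       authority = stats::setNames(a, net$nodes),
       iterations = it, converged = converged)
}

#' Betweenness centrality
#'
#' Fraction of directed geodesics between ordered node pairs (j, k),
#' both different from i, that pass through i, normalized by
#' `(N - 1)(N - 2)` so values lie in `[0, 1]`. Pairs with no connecting
#' path contribute nothing.
#'
#' @param net A `metabolic_network` with at least 3 nodes.
#' @return Named numeric vector per node.
#' @export
betweenness_scores <- function(net) {
  if (net$N < 3L) stop_input("betweenness needs at least 3 nodes")
  b <- igraph::betweenness(net$graph, directed = TRUE, normalized = TRUE)
  stats::setNames(as.numeric(b), net$nodes)
}

#' Eigenvector centrality
#'
#' Principal eigenpair of the symmetrized adjacency (an undirected link
#' wherever an arc exists in either direction). The substrate-product
#' digraph has large acyclic regions where the directed spectral radius
#' vanishes, so symmetrization is what guarantees a well-defined
#' non-negative Perron vector. Computed by shifted power iteration
#' (iterating `S + I` avoids oscillation on bipartite components) from
#' the all-ones start; the returned vector has unit Euclidean norm and
#' `lambda` is its Rayleigh quotient with `S`.
#'
#' @inheritParams hits_scores
#' @return List with the named vector `centrality` and scalar `lambda`.
#' @export
eigencentrality <- function(net, tol = 1e-10, max_iter = 10000L) {
  if (net$E < 1L) stop_input("eigencentrality undefined on an edgeless network")
  A <- adjacency(net)
  S <- (A + Matrix::t(A))
  S@x[S@x > 0] <- 1
  x <- rep(1, net$N)
  x <- x / sqrt(sum(x^2))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    y <- as.numeric(S %*% x) + x     # (S + I) x
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) < tol) {
      x <- y
      converged <- TRUE
      break
    }
    x <- y
  }
  if (!converged)
    warning("eigencentrality power iteration did not converge")
  lambda <- as.numeric(x %*% (S %*% x))
  list(centrality = stats::setNames(x, net$nodes), lambda = lambda)
}

# Efficiency (mean reciprocal geodesic distance, unreachable -> 0) of an
# igraph object; shared by local and global efficiency.
graph_efficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  D <- igraph::distances(g, mode = "out")
  inv <- 1 / D
  inv[is.infinite(D) | D == 0] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local and global efficiency
#'
#' The local efficiency of node i is the efficiency (mean reciprocal
#' directed geodesic distance, zero for unreachable pairs) of the
#' subgraph induced by i's neighbors — a proxy for the network's
#' tolerance to removal of i. Nodes with fewer than two distinct
#' neighbors score zero. The global efficiency applies the same
#' reciprocal-distance convention to the whole graph.
#'
#' @param net A `metabolic_network`.
#' @return List with named vector `F_i` and scalar `global`.
#' @export
local_efficiency <- function(net) {
  g <- net$graph
  fi <- vapply(seq_len(net$N), function(i) {
    nb <- igraph::neighbors(g, i, mode = "all")
    nb <- setdiff(unique(as.integer(nb)), i)
    if (length(nb) < 2L) return(0)
    graph_efficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1))
  list(F_i = stats::setNames(fi, net$nodes), global = graph_efficiency(g))
}

#' Discrete power-law exponents of the degree distributions
#'
#' Fits `P(k) ~ k^(-gamma)` to the nonzero in-degree and out-degree
#' samples by discrete maximum likelihood with `x_min = 1` (zeta-function
#' normalization). Samples with fewer than 10 nonzero degrees, or
#' degenerate all-equal samples, are flagged not estimable (`NA`).
#'
#' @param net A `metabolic_network`.
#' @param gamma_max Upper bound of the search interval.
#' @return List with scalars `gamma_in` and `gamma_out` (`NA` when not
#'   estimable).
#' @export
powerlaw_exponents <- function(net, gamma_max = 20) {
  d <- degrees(net)
  list(gamma_in = powerlaw_mle(d$k_in[d$k_in > 0], gamma_max),
       gamma_out = powerlaw_mle(d$k_out[d$k_out > 0], gamma_max))
}

# Discrete power-law MLE at x_min = 1: minimize
#   n log zeta(gamma) + gamma sum(log x).
powerlaw_mle <- function(x, gamma_max = 20) {
  x <- x[x > 0]
  if (length(x) < 10L || length(unique(x)) < 2L) return(NA_real_)
  slog <- sum(log(x))
  nll <- function(g) length(x) * log(pracma::zeta(g)) + g * slog
  opt <- stats::optimize(nll, interval = c(1 + 1e-6, gamma_max))
  if (opt$minimum > gamma_max - 0.01) return(NA_real_)  # boundary: degenerate
  opt$minimum
}

#' All nine local metrics of a network
#'
#' Computes degree, in-degree, out-degree, local clustering, hub score,
#' authority score, local efficiency, betweenness and eigencentrality for
#' every metabolite.
#'
#' @param net A `metabolic_network`.
#' @param undirected_clustering Use the undirected clustering variant.
#' @return Data frame with class `"node_metric_table"`; one row per node
#'   (rownames are metabolite names), one column per metric, plus the
#'   taxon id in attribute `"taxon_id"`.
#' @export
node_metrics <- function(net, undirected_clustering = FALSE) {
  d <- degrees(net)
  hits <- hits_scores(net)
  eig <- eigencentrality(net)
  eff <- local_efficiency(net)
  out <- data.frame(
    degree = as.numeric(d$k),
    in_degree = as.numeric(d$k_in),
    out_degree = as.numeric(d$k_out),
    clustering = as.numeric(local_clustering(net, undirected_clustering)),
    hub = as.numeric(hits$hub),
    authority = as.numeric(hits$authority),
    efficiency = as.numeric(eff$F_i),
    betweenness = as.numeric(betweenness_scores(net)),
    eigencentrality = as.numeric(eig$centrality),
    row.names = net$nodes)
  attr(out, "taxon_id") <- net$taxon_id
  class(out) <- c("node_metric_table", "data.frame")
  out
}

#' Metric names understood by the feature pipeline
#' @return Character vector of the nine local metric names.
#' @export
metric_names <- function() {
  c("degree", "in_degree", "out_degree", "clustering", "hub",
    "authority", "efficiency", "betweenness", "eigencentrality")
}

#' Network-level summary measures
#'
#' @param net A `metabolic_network`.
#' @return List with `mean_degree`, average path length `L`, global
#'   efficiency, and power-law exponents `gamma_in`, `gamma_out`.
#' @export
global_metrics <- function(net) {
  d <- degrees(net)
  sp <- shortest_distances(net)
  pw <- powerlaw_exponents(net)
  list(mean_degree = d$mean_degree, L = sp$L,
       global_efficiency = graph_efficiency(net$graph),
       gamma_in = pw$gamma_in, gamma_out = pw$gamma_out)
}
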