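# Independent oracles used across the suite. Each is deliberately a
# different route from the implementation it checks: exhaustive
# enumeration instead of closed forms, direct linear solves instead of
# iteration, matrix-power reachability instead of BFS.

# P(X >= k) for hypergeometric X by enumerating all C(N, n) draws of an
# n-subset from a universe with M marked elements.
enum_hyper_tail <- function(N, M, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= M)  # elements 1..M are the marked ones
  mean(hits >= k)
}

# Benjamini-Hochberg step-up written out longhand.
stepup_bh <- function(p) {
  K <- length(p)
  ord <- order(p)
  q <- p[ord] * K / seq_len(K)
  for (i in rev(seq_len(K - 1))) q[i] <- min(q[i], q[i + 1])
  pmin(q, 1)[order(ord)]
}

# Steady state of r = cWr + (1-c)e by direct linear solve.
solve_rwr <- function(W, e, c) {
  as.vector(solve(diag(nrow(W)) - c * W, (1 - c) * e))
}

# All-pairs hop distances by matrix powers of the adjacency matrix:
# dist(i, j) is the smallest power with a nonzero (i, j) entry.
power_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  diag(d) <- 0
  reach <- diag(n)
  for (k in seq_len(n)) {
    reach <- reach %*% adj
    d[reach > 0 & !is.finite(d)] <- k
  }
  d
}

# Random valid similarity matrix for round-trip and fusion tests.
random_sim_matrix <- function(n, ids = sprintf("mir-%02d", seq_len(n))) {
  v <- matrix(stats::runif(n * n), n)
  v <- (v + t(v)) / 2
  diag(v) <- 1
  sim_matrix(v, ids)
}

# Random DAG plus igraph-free BFS hop distances from a start node
# following child -> parent edges, for the semantic-contribution oracle.
bfs_up_distances <- function(dag, start) {
  edges <- igraph::as_data_frame(dag$graph, what = "edges")
  dist <- stats::setNames(rep(Inf, length(dag$terms)), dag$terms)
  dist[[start]] <- 0
  frontier <- start
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (p in edges$to[edges$from == v]) {
        if (!is.finite(dist[[p]])) {
          dist[[p]] <- dist[[v]] + 1
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist[is.finite(dist)]
}
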