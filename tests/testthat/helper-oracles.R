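# Independent oracles and small fixture builders used across the suite.

# Literal double-loop Newman modularity:
# Q = (1/2L) sum_ij (A_ij - d_i d_j / 2L) delta(c_i, c_j)
modularity_double_loop <- function(A, labels) {
  A <- 1 * (A > 0)
  diag(A) <- 0
  L2 <- sum(A)
  d <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) q <- q + A[i, j] - d[i] * d[j] / L2
    }
  }
  q / L2
}

# Brute-force percolation threshold: the largest candidate cutoff (over the
# distinct positive weights) whose surviving graph is still connected.
percolation_brute_force <- function(A) {
  ws <- sort(unique(A[upper.tri(A) & A > 0]))
  connected_at <- function(tau) {
    B <- A
    B[B < tau] <- 0
    g <- igraph::graph_from_adjacency_matrix(1 * (B > 0), mode = "undirected",
                                             diag = FALSE)
    igraph::is_connected(g)
  }
  max(ws[vapply(ws, connected_at, logical(1))])
}

# Random connected weighted graph on n nodes: a random spanning tree plus
# extra random edges, all with distinct-ish positive weights.
random_connected_graph <- function(n, extra = n) {
  A <- matrix(0, n, n)
  perm <- sample(n)
  for (k in 2:n) {
    i <- perm[k]
    j <- perm[sample(k - 1, 1)]
    A[i, j] <- A[j, i] <- runif(1)
  }
  for (e in seq_len(extra)) {
    ij <- sample(n, 2)
    A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- runif(1)
  }
  A
}

# Erdos-Renyi adjacency
er_graph <- function(n, p) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(runif(sum(up)) < p)
  A + t(A)
}

# two k-cliques joined by a single light bridge
two_cliques <- function(k, heavy = 1, light = 0.05) {
  n <- 2 * k
  A <- matrix(0, n, n)
  A[1:k, 1:k] <- heavy
  A[(k + 1):n, (k + 1):n] <- heavy
  diag(A) <- 0
  A[k, k + 1] <- A[k + 1, k] <- light
  A
}

# tiny standardized panel from raw values
panel_from <- function(X) as_panel(X)

# closed-form 2x2 graphical-lasso correlation: off-diagonal soft threshold
glasso_2x2_expected <- function(c, a) sign(c) * max(abs(c) - a, 0)
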