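#' Sparse nonnegative graph container
#'
#' @param adjacency symmetric nonnegative matrix, zero diagonal.
#' @param threshold the cutoff that produced it (`NA` if none).
#' @param source_role `"C"`, `"Jt"` or `"SC"`.
#' @return object of class `sparse_graph` with fields `adjacency`, `density`,
#'   `threshold`, `source_role`.
#' @export
sparse_graph <- function(adjacency, threshold = NA_real_, source_role = "C") {
  A <- as.matrix(adjacency)
  stopifnot(nrow(A) == ncol(A), all(A >= 0))
  diag(A) <- 0
  A <- (A + t(A)) / 2
  structure(list(adjacency = A, density = .density_of(A),
                 threshold = threshold, source_role = source_role),
            class = "sparse_graph")
}

#' @export
print.sparse_graph <- function(x, ...) {
  cat(sprintf("sparse_graph [%s]: %d nodes, density %.3f, threshold %s\n",
              x$source_role, nrow(x$adjacency), x$density,
              format(x$threshold, digits = 3)))
  invisible(x)
}

.density_of <- function(A) {
  N <- nrow(A)
  sum(A[upper.tri(A)] > 0) / (N * (N - 1) / 2)
}

.graph_adj <- function(G) if (inherits(G, "sparse_graph")) G$adjacency else as.matrix(G)

#' Absolute-value connectivity matrix
#'
#' Element-wise absolute value with zeroed diagonal: the nonnegative
#' adjacency from which sparse functional/structural graphs are cut.
#'
#' @param est a `conn_estimate` (roles `C` or `Jt`) or a raw nonnegative
#'   structural matrix.
#' @return numeric matrix, nonnegative, zero diagonal.
#' @export
to_connectivity <- function(est) {
  M <- abs(.est_matrix(est))
  diag(M) <- 0
  M
}

.is_connected <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(1 * (A > 0), mode = "undirected",
                                           diag = FALSE)
  igraph::is_connected(g)
}

#' Percolation-threshold sparsification
#'
#' Removes the weakest edges up to (but excluding) the point where the graph
#' would split into more than one connected component: keeps all edges of
#' weight `>= tau*`, where `tau*` is the largest threshold leaving the graph
#' connected. `tau*` equals the minimum edge weight on a maximum spanning
#' tree (bottleneck duality). Equal-weight edges are kept or removed
#' together.
#'
#' @param M nonnegative connectivity matrix (positive entries are edges).
#' @param source_role role tag recorded on the output.
#' @return a [sparse_graph()] with `threshold = tau*`.
#' @export
percolation_threshold <- function(M, source_role = "C") {
  A <- .graph_adj(M)
  diag(A) <- 0
  if (!.is_connected(A)) {
    stop("graph is disconnected before thresholding; percolation undefined")
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # maximum spanning tree via negated weights; bottleneck = its min weight
  mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
  tau <- min(igraph::E(mst)$weight)
  A[A < tau] <- 0
  sparse_graph(A, threshold = tau, source_role = source_role)
}

#' Fixed-density sparsification
#'
#' Keeps the `ceiling(rho * N(N-1)/2)` largest-weight edges; edges tied at
#' the cut are all kept (the realized density may slightly exceed `rho`).
#' Connectivity is not enforced.
#'
#' @param M nonnegative connectivity matrix.
#' @param rho target density in `(0, 1]`.
#' @param source_role role tag recorded on the output.
#' @return a [sparse_graph()].
#' @export
threshold_to_density <- function(M, rho, source_role = "C") {
  A <- .graph_adj(M)
  diag(A) <- 0
  stopifnot(rho > 0, rho <= 1)
  N <- nrow(A)
  w <- A[upper.tri(A)]
  pos <- w[w > 0]
  k <- ceiling(rho * N * (N - 1) / 2)
  if (k >= length(pos)) {
    if (k > length(pos)) {
      warning("requested density ", rho, " exceeds available edges; keeping all")
    }
    tau <- if (length(pos)) min(pos) else NA_real_
  } else {
    tau <- sort(pos, decreasing = TRUE)[k]
  }
  if (!is.na(tau)) A[A < tau] <- 0
  sparse_graph(A, threshold = tau, source_role = source_role)
}

#' Edge density of a sparse graph
#'
#' `2 * (number of nonzero off-diagonal pairs) / (N (N - 1))`.
#'
#' @param G a `sparse_graph` or adjacency matrix.
#' @return density in `[0, 1]`.
#' @export
graph_density <- function(G) {
  A <- .graph_adj(G)
  diag(A) <- 0
  .density_of(A)
}
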