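#' Nested hierarchical partitions of a graph
#'
#' Builds the pairwise distance `d_ij = exp(-A_ij)` from the (nonnegative)
#' adjacency, runs weighted-average (WPGMA) agglomerative linkage on the
#' condensed distance, and cuts the dendrogram at every `m` in `2..m_max`.
#' Cutting one dendrogram guarantees that consecutive partitions are nested.
#'
#' @param G a `sparse_graph` or adjacency matrix (connected).
#' @param m_max largest number of modules; default `min(50, N - 1)`.
#' @param features `"distance"` (condensed `exp(-A)`, the default recipe) or
#'   `"cosine"` (cosine distance between adjacency rows, a sensitivity
#'   alternative).
#' @return object of class `hierarchy_partitions`: `labels_by_m` (N x
#'   length(m) integer matrix, columns named by `m`), `m_values`, `m_max`,
#'   `linkage` (the `hclust` merge record).
#' @export
hierarchical_partitions <- function(G, m_max = NULL, features = c("distance", "cosine")) {
  features <- match.arg(features)
  A <- .graph_adj(G)
  N <- nrow(A)
  if (is.null(m_max)) m_max <- min(50, N - 1)
  if (m_max < 2) stop("m_max must be at least 2")
  if (m_max > N - 1) stop("m_max cannot exceed N - 1")

  if (features == "distance") {
    D <- exp(-A)
    diag(D) <- 0
    d <- stats::as.dist(D)
  } else {
    nrm <- sqrt(rowSums(A^2))
    nrm[nrm == 0] <- 1
    S <- tcrossprod(A / nrm)
    d <- stats::as.dist(1 - S)
  }
  h <- stats::hclust(d, method = "mcquitty")   # WPGMA
  ms <- 2:m_max
  labels <- stats::cutree(h, k = ms)
  labels <- matrix(as.integer(labels), nrow = N,
                   dimnames = list(NULL, colnames(labels)))
  structure(list(labels_by_m = labels, m_values = ms, m_max = m_max,
                 linkage = h),
            class = "hierarchy_partitions")
}

#' @export
print.hierarchy_partitions <- function(x, ...) {
  cat(sprintf("hierarchy_partitions: %d nodes, m = 2..%d\n",
              nrow(x$labels_by_m), x$m_max))
  invisible(x)
}

.labels_at <- function(partitions, m) {
  j <- match(m, partitions$m_values)
  if (is.na(j)) stop("no partition at m = ", m)
  partitions$labels_by_m[, j]
}

#' Newman modularity of a labeled graph
#'
#' `Q = (1/2L) sum_ij (A_ij - d_i d_j / 2L) delta(c_i, c_j)`, evaluated on
#' the binarized graph (an edge wherever the weight is positive) unless
#' `weighted = TRUE`.
#'
#' @param G a `sparse_graph` or adjacency matrix with at least one edge.
#' @param labels integer module labels covering all nodes.
#' @param weighted use edge weights instead of the binarized graph.
#' @return scalar modularity.
#' @export
newman_modularity <- function(G, labels, weighted = FALSE) {
  A <- .graph_adj(G)
  diag(A) <- 0
  if (!weighted) A <- 1 * (A > 0)
  L2 <- sum(A)
  if (L2 == 0) stop("graph has no edges; modularity undefined")
  stopifnot(length(labels) == nrow(A))
  d <- rowSums(A)
  q <- 0
  for (cc in unique(labels)) {
    idx <- labels == cc
    q <- q + sum(A[idx, idx]) / L2 - (sum(d[idx]) / L2)^2
  }
  q
}

.entropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# expected mutual information under the permutation (hypergeometric) model
.expected_mi <- function(ai, bj, n) {
  emi <- 0
  lfn <- lfactorial(n)
  for (i in seq_along(ai)) {
    a <- ai[i]
    for (j in seq_along(bj)) {
      b <- bj[j]
      lo <- max(1, a + b - n)
      hi <- min(a, b)
      if (hi < lo) next
      nij <- lo:hi
      lp <- lfactorial(a) + lfactorial(b) + lfactorial(n - a) +
        lfactorial(n - b) - lfn - lfactorial(nij) - lfactorial(a - nij) -
        lfactorial(b - nij) - lfactorial(n - a - b + nij)
      emi <- emi + sum((nij / n) * log(n * nij / (a * b)) * exp(lp))
    }
  }
  emi
}

.same_partition <- function(a, b) {
  ct <- table(a, b)
  all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
}

#' Adjusted normalized mutual information between two labelings
#'
#' `(MI - E[MI]) / (max(H_a, H_b) - E[MI])` with the expectation taken under
#' the permutation (hypergeometric) model, so that independent random
#' labelings score about 0 and identical partitions score 1. When both
#' labelings are a single module (zero entropy) the value is 1 if the
#' partitions coincide and 0 otherwise.
#'
#' @param labels_a,labels_b integer labelings of the same node set.
#' @return scalar in (approximately) `[-1, 1]`.
#' @export
adjusted_nmi <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  ct <- table(labels_a, labels_b)
  ai <- rowSums(ct)
  bj <- colSums(ct)
  ha <- .entropy(ai, n)
  hb <- .entropy(bj, n)
  nz <- ct > 0
  mi <- sum((ct[nz] / n) *
              log(n * ct[nz] / (ai[row(ct)[nz]] * bj[col(ct)[nz]])))
  emi <- .expected_mi(ai, bj, n)
  denom <- max(ha, hb) - emi
  if (abs(denom) < 1e-12) {
    return(if (.same_partition(labels_a, labels_b)) 1 else 0)
  }
  (mi - emi) / denom
}

#' Cross-modularity curve between a functional and a structural hierarchy
#'
#' For every common `m`, evaluates the Newman modularity of each graph under
#' its own partition (`Q_F`, `Q_S`), the adjusted NMI `nu` between the two
#' partitions, and the cross-modularity
#' `chi(m) = (Q_F(m) Q_S(m) nu(m))^(1/3)`. Each factor is floored at 0, so
#' `chi = 0` whenever any factor is non-positive (random or unrelated
#' partitions are expected to vanish).
#'
#' @param partitions_f,partitions_s `hierarchy_partitions` of the functional
#'   and structural graphs (same node set).
#' @param graph_f,graph_s the corresponding `sparse_graph`s.
#' @return object of class `crossmod_curve`: data.frame `curve` with columns
#'   `m, q_f, q_s, nu, chi`, plus `argmax_m` and `chi_max`.
#' @export
cross_modularity_curve <- function(partitions_f, partitions_s, graph_f, graph_s) {
  ms <- intersect(partitions_f$m_values, partitions_s$m_values)
  if (length(ms) == 0) stop("partitions share no m values")
  qf <- qs <- nu <- chi <- numeric(length(ms))
  for (k in seq_along(ms)) {
    lf <- .labels_at(partitions_f, ms[k])
    ls <- .labels_at(partitions_s, ms[k])
    qf[k] <- newman_modularity(graph_f, lf)
    qs[k] <- newman_modularity(graph_s, ls)
    nu[k] <- adjusted_nmi(lf, ls)
    f <- pmax(c(qf[k], qs[k], nu[k]), 0)
    chi[k] <- (f[1] * f[2] * f[3])^(1 / 3)
  }
  i <- which.max(chi)
  structure(list(curve = data.frame(m = ms, q_f = qf, q_s = qs, nu = nu,
                                    chi = chi),
                 argmax_m = ms[i], chi_max = chi[i]),
            class = "crossmod_curve")
}

#' @export
print.crossmod_curve <- function(x, ...) {
  cat(sprintf("crossmod_curve: m = %d..%d, chi_max = %.3f at m = %d\n",
              min(x$curve$m), max(x$curve$m), x$chi_max, x$argmax_m))
  invisible(x)
}

#' Spectral distance between two symmetric matrices
#'
#' Sum of absolute differences between the two spectra, both sorted in
#' decreasing order.
#'
#' @param M1,M2 symmetric matrices of equal dimension (or `sparse_graph`s).
#' @return nonnegative scalar.
#' @export
spectral_distance <- function(M1, M2) {
  A <- .graph_adj(M1)
  B <- .graph_adj(M2)
  if (!all(dim(A) == dim(B))) stop("dimension mismatch")
  l1 <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  l2 <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  sum(abs(l1 - l2))
}

#' Bounded normalization of structural weights
#'
#' Element-wise `(2/pi) * arctan(w)`, mapping raw streamline-count-like
#' weights into `[0, 1)` so structural spectra are comparable to functional
#' ones.
#'
#' @param M nonnegative matrix (or `sparse_graph`).
#' @return matrix of the same shape.
#' @export
normalize_sc_weights <- function(M) {
  A <- .graph_adj(M)
  stopifnot(all(A >= 0))
  (2 / pi) * atan(A)
}
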