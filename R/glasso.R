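.soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# lasso sub-problem by coordinate descent:
# min_b 0.5 b' W11 b - s12' b + rho |b|_1
.lasso_cd <- function(W11, s12, rho, beta, tol, max_inner = 200) {
  p <- length(s12)
  dW <- diag(W11)
  for (it in seq_len(max_inner)) {
    delta <- 0
    for (k in seq_len(p)) {
      r <- s12[k] - sum(W11[k, ] * beta) + dW[k] * beta[k]
      bnew <- .soft(r, rho) / dW[k]
      delta <- max(delta, abs(bnew - beta[k]))
      beta[k] <- bnew
    }
    if (delta < tol) break
  }
  beta
}

#' Graphical lasso precision estimation
#'
#' Maximizes `log det J - tr(E J) - penalty * sum_(i != j) |J_ij|` (the
#' Gaussian log-likelihood with an l1 penalty on off-diagonal precision
#' entries) by block coordinate descent on the covariance estimate `W`, with
#' each column update solved as a lasso by coordinate descent. Returns both
#' the sparse precision `J` and its inverse `C`.
#'
#' @param E sample correlation (`conn_estimate` or matrix), symmetrized.
#' @param penalty l1 penalty `> 0` on each off-diagonal precision entry.
#' @param tol convergence tolerance on the duality gap
#'   `tr(E J) + penalty * |J|_1,off - N`.
#' @param max_iter maximum number of full sweeps over the columns.
#' @return list with `C` (a `conn_estimate`, role `"C"`, carrying `J` in its
#'   `precision` field), `J` (a `conn_estimate`, role `"J"`), `objective`
#'   (per-sweep penalized log-likelihood values) and `gap` (final duality gap).
#' @export
fit_glasso <- function(E, penalty, tol = 1e-5, max_iter = 500) {
  Em <- .est_matrix(E)
  Em <- (Em + t(Em)) / 2
  N <- nrow(Em)
  stopifnot(penalty > 0)
  if (N == 1) stop("need at least 2 variables")

  W <- Em
  B <- matrix(0, N - 1, N)
  objective <- numeric(0)
  gap <- Inf

  build_J <- function(W, B) {
    J <- matrix(0, N, N)
    for (j in seq_len(N)) {
      idx <- seq_len(N)[-j]
      beta <- B[, j]
      jj <- 1 / (W[j, j] - sum(W[idx, j] * beta))
      J[j, j] <- jj
      J[idx, j] <- -beta * jj
    }
    (J + t(J)) / 2
  }

  for (sweep in seq_len(max_iter)) {
    W_old <- W
    for (j in seq_len(N)) {
      idx <- seq_len(N)[-j]
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- Em[idx, j]
      beta <- .lasso_cd(W11, s12, penalty, B[, j], tol = tol / 10)
      B[, j] <- beta
      w12 <- as.vector(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    J <- build_J(W, B)
    ld <- determinant(J, logarithm = TRUE)
    obj <- as.numeric(ld$modulus) - sum(Em * J) -
      penalty * sum(abs(J[row(J) != col(J)]))
    objective <- c(objective, obj)
    gap <- sum(Em * J) + penalty * sum(abs(J[row(J) != col(J)])) - N
    if (abs(gap) < tol) break
    if (max(abs(W - W_old)) < tol * (mean(abs(Em)) + 1e-12) && sweep > 1) break
  }
  if (abs(gap) > max(tol, 1e-4) && sweep == max_iter) {
    stop("graphical lasso did not converge in ", max_iter,
         " sweeps (duality gap ", signif(gap, 3), ")")
  }

  J <- build_J(W, B)
  Cest <- conn_estimate(W, role = "C", method = "GLASSO", alpha = penalty,
                        precision = J)
  Jest <- conn_estimate(J, role = "J", method = "GLASSO", alpha = penalty)
  list(C = Cest, J = Jest, objective = objective, gap = gap)
}
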