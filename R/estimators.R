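#' Connectivity estimate container
#'
#' A symmetric region-by-region matrix tagged with its role in the pipeline
#' (`E` sample correlation, `C` regularized correlation, `J` precision,
#' `Jt` partial correlation), the regularization method and strength, and the
#' selection mode that produced the strength.
#'
#' @param matrix symmetric numeric matrix (max asymmetry 1e-8; symmetrized).
#' @param role one of `"E"`, `"C"`, `"J"`, `"Jt"`.
#' @param method one of `"raw"`, `"IS"`, `"GS"`, `"PCA"`, `"cautPCA"`,
#'   `"GLASSO"`, `"ORIE"`.
#' @param alpha regularization strength (shrinkage weight, clipping fraction,
#'   GLASSO penalty, or ORIE eta).
#' @param subject optional subject identifier.
#' @param selection `"fixed"`, `"likelihood"` or `"chi"`.
#' @param precision optional precision matrix carried alongside a `C` estimate
#'   (GLASSO returns both).
#' @return object of class `conn_estimate`.
#' @export
conn_estimate <- function(matrix, role = c("E", "C", "J", "Jt"),
                          method = "raw", alpha = NA_real_, subject = NA,
                          selection = "fixed", precision = NULL) {
  role <- match.arg(role)
  m <- as.matrix(matrix)
  if (nrow(m) != ncol(m)) stop("connectivity matrix must be square")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) stop("matrix asymmetry ", signif(asym, 3), " exceeds 1e-8")
  m <- (m + t(m)) / 2
  structure(list(matrix = m, role = role, method = method, alpha = alpha,
                 subject = subject, selection = selection,
                 precision = precision),
            class = "conn_estimate")
}

#' @export
print.conn_estimate <- function(x, ...) {
  cat(sprintf("conn_estimate [%s] %dx%d, method = %s, alpha = %s (%s)\n",
              x$role, nrow(x$matrix), ncol(x$matrix), x$method,
              format(x$alpha, digits = 3), x$selection))
  invisible(x)
}

.est_matrix <- function(x) if (inherits(x, "conn_estimate")) x$matrix else as.matrix(x)

#' Sample correlation of a standardized panel
#'
#' `E = X X^T / T`; with standardized rows this is the sample correlation
#' matrix with exact unit diagonal.
#'
#' @param panel a `ts_panel`.
#' @return a `conn_estimate` with role `"E"`.
#' @export
sample_correlation <- function(panel) {
  stopifnot(inherits(panel, "ts_panel"))
  E <- tcrossprod(panel$values) / panel$n_times
  conn_estimate(E, role = "E", method = "raw", alpha = 0)
}

#' Linear shrinkage toward a target matrix
#'
#' Convex combination `(1 - a) E + a T` with the identity target (method
#' `"IS"`) or the across-subject mean sample correlation (method `"GS"`).
#'
#' @param E sample correlation (`conn_estimate` or matrix).
#' @param target target matrix `T`, same dimension as `E`.
#' @param a shrinkage intensity in `[0, 1]`.
#' @param method label recorded on the output (`"IS"` or `"GS"`).
#' @return a `conn_estimate` with role `"C"`.
#' @export
shrink_linear <- function(E, target, a, method = "IS") {
  Em <- .est_matrix(E)
  Tm <- as.matrix(target)
  if (!all(dim(Em) == dim(Tm))) stop("target dimension mismatch")
  stopifnot(a >= 0, a <= 1)
  C <- if (a == 0) Em else if (a == 1) Tm else (1 - a) * Em + a * Tm
  conn_estimate(C, role = "C", method = method, alpha = a)
}

#' Eigenvalue clipping (principal-component regularization)
#'
#' Keeps the `p` largest sample eigenvalues and replaces the remaining ones
#' by their mean, leaving eigenvectors (and hence the trace) unchanged.
#'
#' @param E sample correlation.
#' @param p number of retained eigenvalues, `1 <= p <= N`.
#' @param eig optional precomputed `eigen(E, symmetric = TRUE)`.
#' @return a `conn_estimate` with role `"C"`, method `"PCA"`.
#' @export
clip_eigenvalues <- function(E, p, eig = NULL) {
  Em <- .est_matrix(E)
  N <- nrow(Em)
  stopifnot(p >= 1, p <= N)
  if (p == N) return(conn_estimate(Em, role = "C", method = "PCA", alpha = 0))
  if (is.null(eig)) eig <- eigen(Em, symmetric = TRUE)
  lam <- eig$values
  lam[(p + 1):N] <- mean(lam[(p + 1):N])
  C <- eig$vectors %*% (lam * t(eig$vectors))
  conn_estimate(C, role = "C", method = "PCA", alpha = (N - p) / N)
}

#' Cautious eigenvalue clipping
#'
#' Floors all eigenvalues of rank `>= p` at the `p`-th largest one, then
#' rescales the whole spectrum multiplicatively so that the trace equals `N`.
#'
#' @inheritParams clip_eigenvalues
#' @return a `conn_estimate` with role `"C"`, method `"cautPCA"`.
#' @export
caut_clip_eigenvalues <- function(E, p, eig = NULL) {
  Em <- .est_matrix(E)
  N <- nrow(Em)
  stopifnot(p >= 1, p <= N)
  if (is.null(eig)) eig <- eigen(Em, symmetric = TRUE)
  lam <- eig$values
  lam[p:N] <- lam[p]
  lam <- lam * (N / sum(lam))
  C <- eig$vectors %*% (lam * t(eig$vectors))
  conn_estimate(C, role = "C", method = "cautPCA", alpha = (N - p) / N)
}

#' Rotationally invariant eigenvalue cleaning
#'
#' Corrects each sample eigenvalue as
#' `lambda_k / |1 - q + q z_k s(z_k)|^2` with `z_k = lambda_k - i eta` and
#' `s(z) = Tr[(z I - E)^{-1}] / N` (the sample Stieltjes transform), keeping
#' the eigenvectors; the cleaned spectrum is then rescaled to preserve the
#' trace. `eta` defaults to `N^{-1/2}`.
#'
#' @param E sample correlation.
#' @param q regions-to-timepoints ratio `N/T` of the panel that produced `E`.
#' @param eta imaginary offset of the resolvent; positive.
#' @param eig optional precomputed eigendecomposition.
#' @return a `conn_estimate` with role `"C"`, method `"ORIE"`, `alpha = eta`.
#' @export
orie_clean <- function(E, q, eta = NULL, eig = NULL) {
  Em <- .est_matrix(E)
  N <- nrow(Em)
  if (is.null(eta)) eta <- 1 / sqrt(N)
  stopifnot(q > 0, eta > 0)
  if (is.null(eig)) eig <- eigen(Em, symmetric = TRUE)
  lam <- eig$values
  z <- complex(real = lam, imaginary = -eta)
  s <- vapply(z, function(zk) mean(1 / (zk - lam)), complex(1))
  lam_clean <- lam / Mod(1 - q + q * z * s)^2
  lam_clean <- lam_clean * (sum(lam) / sum(lam_clean))
  C <- eig$vectors %*% (lam_clean * t(eig$vectors))
  conn_estimate(C, role = "C", method = "ORIE", alpha = eta)
}

#' Mean per-sample Gaussian validation log-likelihood
#'
#' `-0.5 * (log det C + tr(C^{-1} E_val) + N log 2 pi)` where `E_val` is the
#' sample correlation of the validation panel (`1/T_val` scaling). Candidates
#' that are not positive definite get `-Inf`, never an exception.
#'
#' @param C candidate correlation (`conn_estimate` or matrix).
#' @param panel_val validation `ts_panel`, or a precomputed validation sample
#'   correlation matrix.
#' @return scalar log-likelihood (or `-Inf`).
#' @export
gaussian_loglik <- function(C, panel_val) {
  Cm <- .est_matrix(C)
  Ev <- if (inherits(panel_val, "ts_panel")) {
    tcrossprod(panel_val$values) / panel_val$n_times
  } else {
    as.matrix(panel_val)
  }
  N <- nrow(Cm)
  cf <- tryCatch(chol(Cm), error = function(e) NULL)
  if (is.null(cf) || any(diag(cf)^2 <= 1e-12)) return(-Inf)
  logdet <- 2 * sum(log(diag(cf)))
  Cinv <- chol2inv(cf)
  -0.5 * (logdet + sum(Cinv * Ev) + N * log(2 * pi))
}

#' Cross-validation / regularizer specification
#'
#' @param method estimator name: `"raw"`, `"IS"`, `"GS"`, `"PCA"`,
#'   `"cautPCA"`, `"GLASSO"` or `"ORIE"`.
#' @param alpha_grid candidate strengths; `NULL` uses the method default:
#'   21 evenly spaced values in `[0, 1]` for IS/GS, every integer `p` mapped
#'   through `alpha = (N - p)/N` for PCA/cautPCA, 16 log-spaced penalties in
#'   `[1e-3, 1]` for GLASSO, and `{N^{-1/2}}` plus 8 log-spaced values in
#'   `[1e-4, 1e-1]` for ORIE.
#' @param n_folds contiguous time folds for validation (>= 2).
#' @param group_target across-subject mean sample correlation, required for
#'   `"GS"`.
#' @return object of class `regularizer_spec`.
#' @export
regularizer_spec <- function(method = c("raw", "IS", "GS", "PCA", "cautPCA",
                                        "GLASSO", "ORIE"),
                             alpha_grid = NULL, n_folds = 5,
                             group_target = NULL) {
  method <- match.arg(method)
  stopifnot(n_folds >= 2)
  if (!is.null(alpha_grid)) {
    if (method %in% c("raw", "IS", "GS", "PCA", "cautPCA")) {
      stopifnot(all(alpha_grid >= 0), all(alpha_grid <= 1))
    } else {
      stopifnot(all(alpha_grid > 0))
    }
    alpha_grid <- sort(alpha_grid)
  }
  if (method == "GS" && is.null(group_target)) {
    # caller must set it before fitting; kept NULL here so specs can be
    # declared before the cohort is available
    group_target <- NULL
  }
  structure(list(method = method, alpha_grid = alpha_grid, n_folds = n_folds,
                 group_target = group_target),
            class = "regularizer_spec")
}

.default_alpha_grid <- function(method, N) {
  switch(method,
         raw = 0,
         IS = seq(0, 1, length.out = 21),
         GS = seq(0, 1, length.out = 21),
         PCA = (N - seq_len(N)) / N,
         cautPCA = (N - seq_len(N)) / N,
         GLASSO = exp(seq(log(1e-3), log(1), length.out = 16)),
         ORIE = sort(unique(c(1 / sqrt(N),
                              exp(seq(log(1e-4), log(1e-1), length.out = 8))))),
         stop("unknown method ", method))
}

# Fit one regularized correlation estimate from a sample correlation matrix.
# `eig` lets eigenvalue-based methods reuse one decomposition across a grid.
.fit_correlation <- function(E, method, alpha, q, group_target = NULL,
                             eig = NULL) {
  N <- nrow(E)
  switch(method,
    raw = conn_estimate(E, role = "C", method = "raw", alpha = 0),
    IS = shrink_linear(E, diag(N), alpha, method = "IS"),
    GS = {
      if (is.null(group_target)) stop("GS requires a group_target matrix")
      shrink_linear(E, group_target, alpha, method = "GS")
    },
    PCA = clip_eigenvalues(E, p = max(1, round(N * (1 - alpha))), eig = eig),
    cautPCA = caut_clip_eigenvalues(E, p = max(1, round(N * (1 - alpha))),
                                    eig = eig),
    GLASSO = fit_glasso(E, penalty = alpha)$C,
    ORIE = orie_clean(E, q = q, eta = alpha, eig = eig),
    stop("unknown method ", method))
}

.contiguous_folds <- function(T, n_folds) {
  split(seq_len(T), cut(seq_len(T), n_folds, labels = FALSE))
}

#' Select the regularization strength by validation likelihood
#'
#' Splits the time axis into contiguous folds; for each candidate strength
#' the estimator is fitted on the training folds and scored by the mean
#' validation-fold Gaussian log-likelihood. Returns the maximizing strength
#' (ties broken toward stronger regularization) and the estimator refitted
#' on the full panel.
#'
#' @param panel a `ts_panel`.
#' @param spec a [regularizer_spec()].
#' @return list with `alpha` (the selected strength), `estimate` (the refit
#'   `conn_estimate`, selection tag `"likelihood"`), and `path`
#'   (data.frame of `alpha`, `loglik`).
#' @export
select_alpha <- function(panel, spec) {
  stopifnot(inherits(panel, "ts_panel"), inherits(spec, "regularizer_spec"))
  N <- panel$n_regions
  grid <- spec$alpha_grid
  if (is.null(grid)) grid <- .default_alpha_grid(spec$method, N)
  if (length(grid) == 0) stop("alpha_grid is empty")
  eigen_based <- spec$method %in% c("PCA", "cautPCA", "ORIE")

  if (length(grid) == 1) {
    ll <- NA_real_
  } else {
    folds <- .contiguous_folds(panel$n_times, spec$n_folds)
    ll_mat <- matrix(NA_real_, length(grid), length(folds))
    for (f in seq_along(folds)) {
      val <- folds[[f]]
      Xtr <- panel$values[, -val, drop = FALSE]
      Ttr <- ncol(Xtr)
      Etr <- tcrossprod(Xtr) / Ttr
      Ev <- tcrossprod(panel$values[, val, drop = FALSE]) / length(val)
      eig <- if (eigen_based) eigen(Etr, symmetric = TRUE) else NULL
      qtr <- N / Ttr
      for (a in seq_along(grid)) {
        C <- tryCatch(
          .fit_correlation(Etr, spec$method, grid[a], q = qtr,
                           group_target = spec$group_target, eig = eig),
          error = function(e) NULL)
        ll_mat[a, f] <- if (is.null(C)) -Inf else gaussian_loglik(C, Ev)
      }
    }
    ll <- rowMeans(ll_mat)
    if (all(!is.finite(ll))) {
      stop("validation likelihood is -Inf for every candidate strength; ",
           "the panel is degenerate")
    }
  }

  alpha <- if (length(grid) == 1) grid else max(grid[ll == max(ll)])
  E <- tcrossprod(panel$values) / panel$n_times
  est <- .fit_correlation(E, spec$method, alpha, q = panel$q,
                          group_target = spec$group_target,
                          eig = if (eigen_based) eigen(E, symmetric = TRUE))
  est$selection <- if (length(grid) == 1) "fixed" else "likelihood"
  list(alpha = alpha, estimate = est,
       path = data.frame(alpha = grid,
                         loglik = if (length(grid) == 1) NA_real_ else ll))
}

#' Standardized precision (partial correlation) matrix
#'
#' Inverts a correlation estimate (or reuses the precision carried by a
#' GLASSO fit) and standardizes it as `J_ij / sqrt(J_ii J_jj)`, giving unit
#' diagonal. By default the entries keep the sign of the precision entries,
#' matching the downstream use of absolute values; `signed = TRUE` applies
#' the conventional partial-correlation sign flip on the off-diagonal.
#'
#' @param est a `conn_estimate` with role `"C"` or `"E"`.
#' @param signed use the conventional `-J_ij / sqrt(J_ii J_jj)` off-diagonal.
#' @return a `conn_estimate` with role `"Jt"`.
#' @export
partial_correlation <- function(est, signed = FALSE) {
  Cm <- .est_matrix(est)
  J <- if (inherits(est, "conn_estimate") && !is.null(est$precision)) {
    est$precision
  } else {
    ev_min <- min(eigen(Cm, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 1e-12) {
      stop("correlation estimate is singular (smallest eigenvalue ",
           signif(ev_min, 3), "); cannot invert")
    }
    solve(Cm)
  }
  J <- (J + t(J)) / 2
  d <- sqrt(diag(J))
  Jt <- J / outer(d, d)
  if (signed) {
    Jt <- -Jt
    diag(Jt) <- 1
  }
  diag(Jt) <- 1
  out <- conn_estimate(Jt, role = "Jt",
                       method = if (inherits(est, "conn_estimate")) est$method else "raw",
                       alpha = if (inherits(est, "conn_estimate")) est$alpha else NA_real_,
                       subject = if (inherits(est, "conn_estimate")) est$subject else NA,
                       selection = if (inherits(est, "conn_estimate")) est$selection else "fixed")
  out
}
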