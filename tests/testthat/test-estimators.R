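test_that("sample correlation matches the brute-force definition", {
  set.seed(3)
  X <- matrix(rnorm(5 * 7), 5, 7)
  panel <- as_panel(X)
  E <- sample_correlation(panel)$matrix
  # direct summation oracle
  Eo <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    Eo[i, j] <- sum(panel$values[i, ] * panel$values[j, ]) / 7
  }
  expect_equal(E, Eo, tolerance = 1e-12)
  expect_equal(diag(E), rep(1, 5))

  # identical rows correlate at 1, orthogonal rows at 0
  X2 <- rbind(c(1, -1, 1, -1), c(1, -1, 1, -1), c(1, 1, -1, -1))
  E2 <- sample_correlation(as_panel(X2))$matrix
  expect_equal(E2[1, 2], 1)
  expect_equal(E2[1, 3], 0)
})

test_that("linear shrinkage endpoints and arithmetic are exact", {
  E <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_identical(shrink_linear(E, diag(2), 0)$matrix, E)
  expect_identical(shrink_linear(E, diag(2), 1)$matrix, diag(2))
  expect_equal(shrink_linear(E, diag(2), 0.5)$matrix,
               matrix(c(1, 0.25, 0.25, 1), 2))
  expect_error(shrink_linear(E, diag(3), 0.5), "dimension")
})

test_that("eigenvalue clipping preserves trace and follows the spectrum rule", {
  # spectrum (3, 2, 1), p = 1 -> (3, 1.5, 1.5)
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  E <- Q %*% diag(c(3, 2, 1)) %*% t(Q)
  C <- clip_eigenvalues(E, 1)$matrix
  expect_equal(sort(eigen(C, symmetric = TRUE)$values), c(1.5, 1.5, 3),
               tolerance = 1e-10)
  expect_identical(clip_eigenvalues(E, 3)$matrix, (E + t(E)) / 2)

  for (sd in 1:3) {
    set.seed(sd)
    X <- matrix(rnorm(10 * 30), 10)
    Er <- tcrossprod(X) / 30
    for (p in c(2, 5, 9)) {
      expect_lt(abs(sum(diag(clip_eigenvalues(Er, p)$matrix)) - sum(diag(Er))),
                1e-8)
    }
  }
})

test_that("cautious clipping floors the spectrum and rescales the trace to N", {
  set.seed(2)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  E <- Q %*% diag(c(3, 2, 1)) %*% t(Q)
  C <- caut_clip_eigenvalues(E, 2)$matrix
  expect_equal(sort(eigen(C, symmetric = TRUE)$values),
               c(6 / 7, 6 / 7, 9 / 7), tolerance = 1e-10)
  # p = 1 flattens the spectrum: output is the identity
  expect_equal(caut_clip_eigenvalues(E, 1)$matrix, diag(3), tolerance = 1e-10)
  set.seed(4)
  X <- matrix(rnorm(12 * 40), 12)
  Er <- tcrossprod(X) / 40
  for (p in c(1, 4, 12)) {
    expect_lt(abs(sum(diag(caut_clip_eigenvalues(Er, p)$matrix)) - 12), 1e-8)
  }
})

test_that("eigenvalue-based estimators keep the sample eigenvectors", {
  set.seed(5)
  X <- matrix(rnorm(8 * 20), 8)
  panel <- as_panel(X)
  E <- sample_correlation(panel)$matrix
  U <- eigen(E, symmetric = TRUE)$vectors
  cands <- list(clip_eigenvalues(E, 3)$matrix,
                caut_clip_eigenvalues(E, 3)$matrix,
                orie_clean(E, q = panel$q)$matrix,
                shrink_linear(E, diag(8), 0.3)$matrix)
  for (C in cands) {
    # (C - E) must be diagonal in E's eigenbasis
    off <- t(U) %*% (C - E) %*% U
    expect_lt(max(abs(off - diag(diag(off)))), 1e-8)
  }
})

test_that("graphical lasso matches the 2x2 closed-form soft threshold", {
  for (c0 in c(0.6, -0.4, 0.15)) {
    for (a in c(0.1, 0.3, 0.5)) {
      E <- matrix(c(1, c0, c0, 1), 2)
      fit <- fit_glasso(E, penalty = a)
      expect_equal(fit$C$matrix[1, 2], glasso_2x2_expected(c0, a),
                   tolerance = 1e-6)
    }
  }
})

test_that("graphical lasso limits: dominant penalty and vanishing penalty", {
  set.seed(6)
  X <- matrix(rnorm(5 * 500), 5)
  E <- tcrossprod(as_panel(X)$values) / 500
  big <- fit_glasso(E, penalty = 5)
  offd <- big$J$matrix[row(big$J$matrix) != col(big$J$matrix)]
  expect_true(all(offd == 0))
  small <- fit_glasso(E, penalty = 1e-7)
  expect_lt(max(abs(small$J$matrix - solve(E))), 1e-4)
})

test_that("graphical lasso objective is monotone and the duality gap closes", {
  set.seed(7)
  X <- matrix(rnorm(8 * 40), 8)
  E <- tcrossprod(as_panel(X)$values) / 40
  fit <- fit_glasso(E, penalty = 0.1)
  expect_true(all(diff(fit$objective) > -1e-8))
  expect_lt(abs(fit$gap), 1e-4)
})

test_that("eigenvalue cleaning obeys its limits and default", {
  # abundant data: correction leaves the spectrum within 1%
  set.seed(8)
  N <- 20
  X <- matrix(rnorm(N * N / 1e-3), N)
  E <- tcrossprod(as_panel(X)$values) / ncol(X)
  C <- orie_clean(E, q = 1e-3)$matrix
  lam_s <- sort(eigen(E, symmetric = TRUE, only.values = TRUE)$values)
  lam_c <- sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(max(abs(lam_c - lam_s) / lam_s), 0.01)

  # degenerate flat spectrum: identity maps to identity
  expect_equal(orie_clean(diag(6), q = 0.5)$matrix, diag(6), tolerance = 1e-10)

  # default eta is N^(-1/2)
  expect_equal(orie_clean(diag(9), q = 0.2)$alpha, 1 / 3)
})

test_that("gaussian log-likelihood has its closed form and dominance properties", {
  N <- 4
  ll <- gaussian_loglik(diag(N), diag(N))
  expect_equal(ll, -0.5 * N * (1 + log(2 * pi)))

  # the true covariance dominates a perturbed one at huge validation T
  m <- make_planted_model(10, 2, seed = 2)
  Ctrue <- stats::cov2cor(solve(m$precision_true))
  pv <- sample_timeseries(m, 1e5, seed = 3)
  Ev <- tcrossprod(pv$values) / pv$n_times
  wrong <- 0.5 * Ctrue + 0.5 * diag(10)
  expect_gt(gaussian_loglik(Ctrue, Ev), gaussian_loglik(wrong, Ev))

  # non-positive-definite candidate signals -Inf, never an error
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_identical(gaussian_loglik(bad, diag(2)), -Inf)
})

test_that("likelihood selection behaves across data-abundance regimes", {
  # singleton grid returns the raw estimator
  m <- make_planted_model(12, 2, seed = 4)
  p <- sample_timeseries(m, 100, seed = 5)
  sel0 <- select_alpha(p, regularizer_spec("raw"))
  expect_equal(sel0$alpha, 0)
  expect_equal(sel0$estimate$matrix, sample_correlation(p)$matrix)

  # q = 0.6: shrinkage must be selected strictly positive
  for (sd in 1:5) {
    m <- make_planted_model(60, 6, seed = sd)
    p <- sample_timeseries(m, 100, seed = sd + 100)
    sel <- select_alpha(p, regularizer_spec("IS"))
    expect_gt(sel$alpha, 0)
    # and the selected strength cannot validate worse than no regularization
    path <- sel$path
    expect_gte(path$loglik[path$alpha == sel$alpha],
               path$loglik[path$alpha == 0])
  }

  # abundant data: selected strength vanishes
  for (sd in 1:5) {
    m <- make_planted_model(10, 2, seed = sd)
    p <- sample_timeseries(m, 1e4, seed = sd + 200)
    sel <- select_alpha(p, regularizer_spec("IS"))
    expect_lte(sel$alpha, 0.05)
  }
})

test_that("partial correlation standardizes the precision with unit diagonal", {
  expect_equal(partial_correlation(conn_estimate(diag(4), "C"))$matrix, diag(4))

  # chain 1-2-3: precision has a structural zero at (1, 3), correlation does not
  J <- matrix(c(1, -0.4, 0, -0.4, 1, -0.4, 0, -0.4, 1), 3)
  C <- stats::cov2cor(solve(J))
  expect_gt(abs(C[1, 3]), 1e-3)
  Jt <- partial_correlation(conn_estimate(C, "C"))$matrix
  expect_lt(abs(Jt[1, 3]), 1e-10)
  expect_equal(diag(Jt), rep(1, 3))

  # the printed (unsigned) convention and the conventional sign flip
  expect_lt(Jt[1, 2], 0)
  Jts <- partial_correlation(conn_estimate(C, "C"), signed = TRUE)$matrix
  expect_gt(Jts[1, 2], 0)
  expect_equal(diag(Jts), rep(1, 3))

  expect_error(partial_correlation(conn_estimate(matrix(1, 2, 2), "C")),
               "singular")
})

test_that("GLASSO's carried precision is reused for partial correlation", {
  set.seed(9)
  X <- matrix(rnorm(6 * 60), 6)
  E <- tcrossprod(as_panel(X)$values) / 60
  fit <- fit_glasso(E, penalty = 0.3)
  Jt <- partial_correlation(fit$C)$matrix
  zero_in_J <- fit$J$matrix == 0
  expect_true(all(Jt[zero_in_J] == 0))
})
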