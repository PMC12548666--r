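test_that("hierarchical partitions separate two cliques and stay nested", {
  A <- two_cliques(5)
  p <- hierarchical_partitions(A, m_max = 8)
  lab2 <- p$labels_by_m[, 1]
  expect_equal(adjusted_nmi(lab2, rep(1:2, each = 5)), 1)

  # m = N - 1: exactly one merged pair, all other nodes singletons
  set.seed(21)
  B <- abs(matrix(rnorm(64), 8))
  B <- B + t(B); diag(B) <- 0
  pb <- hierarchical_partitions(B, m_max = 7)
  sizes <- sort(as.integer(table(pb$labels_by_m[, ncol(pb$labels_by_m)])))
  expect_equal(sum(sizes == 2), 1)
  expect_equal(sum(sizes == 1), 6)

  # nestedness: every module at m+1 lies inside one module at m
  for (sd in 1:20) {
    set.seed(sd)
    C <- abs(matrix(rnorm(15^2), 15))
    C <- C + t(C); diag(C) <- 0
    pc <- hierarchical_partitions(C, m_max = 14)
    L <- pc$labels_by_m
    for (k in seq_len(ncol(L) - 1)) {
      split_count <- tapply(L[, k], L[, k + 1], function(x) length(unique(x)))
      expect_true(all(split_count == 1))
    }
  }

  expect_error(hierarchical_partitions(A, m_max = 1), "at least 2")
  expect_error(hierarchical_partitions(A, m_max = 10), "exceed")
})

test_that("the cosine-feature alternative also separates clean modules", {
  A <- two_cliques(6)
  p <- hierarchical_partitions(A, m_max = 4, features = "cosine")
  expect_equal(adjusted_nmi(p$labels_by_m[, 1], rep(1:2, each = 6)), 1)
})

test_that("Newman modularity matches the literal double loop and igraph", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(newman_modularity(tri, rep(1, 3)), 0)

  # two K4 cliques joined by one bridge, planted labeling
  A <- two_cliques(4, heavy = 1, light = 1)
  labs <- rep(1:2, each = 4)
  q <- newman_modularity(A, labs)
  expect_equal(q, modularity_double_loop(A, labs), tolerance = 1e-12)
  ig <- igraph::graph_from_adjacency_matrix(1 * (A > 0), mode = "undirected",
                                            diag = FALSE)
  expect_equal(q, igraph::modularity(ig, labs), tolerance = 1e-12)

  set.seed(22)
  for (rep in 1:10) {
    n <- sample(6:25, 1)
    G <- er_graph(n, 0.4)
    if (sum(G) == 0) next
    labs <- sample(3, n, replace = TRUE)
    expect_equal(newman_modularity(G, labs),
                 modularity_double_loop(G, labs), tolerance = 1e-12)
  }

  expect_error(newman_modularity(matrix(0, 3, 3), rep(1, 3)), "no edges")
})

test_that("modularity of random labelings of a random graph averages to zero", {
  set.seed(23)
  G <- er_graph(60, 0.2)
  qs <- replicate(100, newman_modularity(G, sample(4, 60, replace = TRUE)))
  expect_lt(abs(mean(qs)), 0.02)
})

test_that("adjusted NMI is exact on coherent labelings and centered on random ones", {
  a <- rep(1:4, each = 10)
  expect_equal(adjusted_nmi(a, a), 1)
  # renaming module ids does not change the partition
  perm <- c(3, 1, 4, 2)
  expect_equal(adjusted_nmi(a, perm[a]), 1)

  set.seed(24)
  vals <- replicate(200, adjusted_nmi(sample(4, 200, replace = TRUE),
                                      sample(4, 200, replace = TRUE)))
  expect_lt(abs(mean(vals)), 0.02)

  # degenerate single-module labelings
  expect_equal(adjusted_nmi(rep(1, 5), rep(2, 5)), 1)
  expect_equal(adjusted_nmi(rep(1, 5), c(1, 1, 1, 2, 2)), 0)
})

test_that("the hypergeometric expected MI matches a permutation Monte Carlo", {
  set.seed(25)
  a <- sample(3, 30, replace = TRUE)
  b <- sample(4, 30, replace = TRUE)
  mi <- function(x, y) {
    ct <- table(x, y); n <- length(x)
    ai <- rowSums(ct); bj <- colSums(ct); nz <- ct > 0
    sum((ct[nz] / n) * log(n * ct[nz] / (ai[row(ct)[nz]] * bj[col(ct)[nz]])))
  }
  emi_mc <- mean(replicate(3000, mi(a, sample(b))))
  emi <- sfcoupling:::.expected_mi(tabulate(a), tabulate(b), 30)
  expect_lt(abs(emi - emi_mc), 0.01)
})

test_that("cross-modularity composes its factors with flooring and self-identity", {
  A <- two_cliques(5)
  g <- percolation_threshold(A)
  p <- hierarchical_partitions(g, m_max = 6)
  cm <- cross_modularity_curve(p, p, g, g)
  # self-comparison: nu is identically 1 and chi = Q^(2/3)
  expect_equal(cm$curve$nu, rep(1, nrow(cm$curve)), tolerance = 1e-10)
  expect_equal(cm$curve$chi, pmax(cm$curve$q_f, 0)^(2 / 3), tolerance = 1e-12)
  expect_equal(cm$curve$chi[cm$curve$m == cm$argmax_m], cm$chi_max)
  expect_equal(max(cm$curve$chi), cm$chi_max)
  # flooring: whenever a factor is non-positive the product is zero
  neg <- cm$curve$q_f <= 0 | cm$curve$q_s <= 0 | cm$curve$nu <= 0
  expect_true(all(cm$curve$chi[neg] == 0))
})

test_that("spectral distance is a metric on sorted spectra", {
  M <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(spectral_distance(M, M), 0)
  expect_equal(spectral_distance(diag(7), matrix(0, 7, 7)), 7)
  set.seed(26)
  for (rep in 1:50) {
    A <- matrix(rnorm(25), 5); A <- A + t(A)
    B <- matrix(rnorm(25), 5); B <- B + t(B)
    C <- matrix(rnorm(25), 5); C <- C + t(C)
    dab <- spectral_distance(A, B)
    expect_equal(dab, spectral_distance(B, A))
    expect_lte(dab, spectral_distance(A, C) + spectral_distance(C, B) + 1e-12)
    expect_gte(dab, 0)
  }
  expect_error(spectral_distance(diag(3), diag(4)), "dimension")
})

test_that("spectral distance between jittered subjects vanishes with the jitter", {
  model <- make_planted_model(20, 2, seed = 31)
  d_at <- function(jit) {
    co <- make_cohort(model, 2, subject_jitter = jit, n_times = 50, seed = 32)
    spectral_distance(co$subjects[[1]]$sc, co$subjects[[2]]$sc)
  }
  expect_equal(d_at(0), 0)
  expect_lt(d_at(0.02), d_at(0.4))
})

test_that("arctan weight normalization maps into the unit interval", {
  expect_equal(normalize_sc_weights(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(normalize_sc_weights(matrix(1, 2, 2))[1, 1], 0.5)
  big <- normalize_sc_weights(matrix(1e8, 2, 2))
  expect_true(all(big < 1) && all(big > 0.99))
})
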