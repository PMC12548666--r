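#' Generator settings for a planted modular Gaussian graphical model
#'
#' Collects the tunables of [make_planted_model()]. Defaults describe a
#' cohort-like regime: strong within-module conditional dependencies, sparse
#' between-module ones, a two-level hierarchy (each coarse module split in
#' two), heavy-tailed streamline-like structural weights, and mild
#' structure-function mismatch through edge rewiring.
#'
#' @param intra_p probability of a precision edge within a coarse module.
#' @param inter_p probability of a precision edge between modules; must be
#'   smaller than `intra_p`.
#' @param sub_p probability of a precision edge within a sub-module (only
#'   used when `levels == 2`); at least `intra_p`.
#' @param levels 1 for a flat planted partition, 2 for a two-level hierarchy
#'   in which each coarse module is split into two sub-modules.
#' @param weight_range range of the magnitude of off-diagonal precision
#'   entries assigned to sampled edges (entries are negative, so that the
#'   implied partial correlations are positive).
#' @param struct_meanlog,struct_sdlog lognormal parameters of the
#'   multiplicative structural weight noise; large `meanlog` emulates raw
#'   streamline counts.
#' @param rewire_frac fraction of structural edges moved to random non-edges,
#'   the planted structure-function mismatch.
#' @param max_cond upper bound on the condition number of the planted
#'   precision matrix after diagonal loading.
#' @return a list of class `planted_params`.
#' @export
planted_params <- function(intra_p = 0.45, inter_p = 0.01, sub_p = 0.6,
                           levels = 2, weight_range = c(0.15, 0.35),
                           struct_meanlog = 3, struct_sdlog = 0.8,
                           rewire_frac = 0.1, max_cond = 100) {
  stopifnot(intra_p > inter_p, intra_p >= 0, inter_p >= 0, sub_p <= 1,
            levels %in% c(1, 2), length(weight_range) == 2,
            weight_range[1] > 0, diff(weight_range) >= 0,
            rewire_frac >= 0, rewire_frac <= 1, max_cond > 1)
  structure(list(intra_p = intra_p, inter_p = inter_p, sub_p = sub_p,
                 levels = levels, weight_range = weight_range,
                 struct_meanlog = struct_meanlog, struct_sdlog = struct_sdlog,
                 rewire_frac = rewire_frac, max_cond = max_cond),
            class = "planted_params")
}

# Diagonal loading so that J is positive definite with condition number
# <= max_cond.  Errors if the required loading is absurd (degenerate input).
.load_to_pd <- function(J, max_cond = 1e6) {
  ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev)
  lmin <- min(ev)
  c0 <- max(0, (lmax - max_cond * lmin) / (max_cond - 1))
  if (c0 > 10 * abs(lmax) + 1) {
    stop("cannot reach positive definiteness by diagonal loading (required ",
         "loading ", signif(c0, 3), " exceeds bound); weaken edge weights ",
         "or densities")
  }
  if (c0 > 0) J <- J + diag(c0, nrow(J))
  J
}

# Chain disconnected components together with minimum-weight edges.
.connect_components <- function(S) {
  g <- igraph::graph_from_adjacency_matrix(1 * (S > 0), mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no <= 1) return(S)
  wmin <- min(S[S > 0])
  reps <- vapply(seq_len(comp$no), function(k) which(comp$membership == k)[1],
                 integer(1))
  for (k in seq_len(comp$no - 1)) {
    S[reps[k], reps[k + 1]] <- S[reps[k + 1], reps[k]] <- wmin
  }
  S
}

#' Build a planted hierarchical Gaussian graphical model
#'
#' Samples a ground-truth precision matrix with off-diagonal support
#' concentrated within planted modules (negative entries on sampled edges,
#' positive definiteness enforced by diagonal loading) and a paired
#' structural matrix that shares the precision support up to random rewiring
#' and multiplicative lognormal weight noise.
#'
#' @param n_regions number of regions (graph nodes); at least `2 * n_modules`.
#' @param n_modules number of coarse planted modules (>= 2).
#' @param params a [planted_params()] list.
#' @param seed integer seed; all randomness flows from it.
#' @param connect enforce connectedness of the structural graph by chaining
#'   components with minimum-weight edges. Disable to study the pure
#'   block-structure limit (`inter_p = 0`).
#' @return an object of class `planted_model` with fields `n_regions`,
#'   `module_labels`, `sub_labels`, `precision_true`, `structural_true`,
#'   `params`, `seed`.
#' @examples
#' m <- make_planted_model(24, 3, seed = 1)
#' min(eigen(m$precision_true, symmetric = TRUE)$values) > 0
#' @export
make_planted_model <- function(n_regions, n_modules, params = planted_params(),
                               seed = 1, connect = TRUE) {
  stopifnot(inherits(params, "planted_params"))
  if (n_modules < 2) stop("n_modules must be at least 2")
  if (n_regions < 2 * n_modules) {
    stop("n_regions must be at least 2 * n_modules (each module needs >= 2 regions)")
  }
  set.seed(as.integer(seed))
  labels <- sort(rep_len(seq_len(n_modules), n_regions))

  sub <- labels
  if (params$levels == 2) {
    for (k in seq_len(n_modules)) {
      idx <- which(labels == k)
      if (length(idx) >= 4) {
        first_half <- seq_along(idx) <= length(idx) / 2
        sub[idx] <- 2 * k - as.integer(first_half)
      }
    }
  }

  P <- matrix(params$inter_p, n_regions, n_regions)
  same_mod <- outer(labels, labels, "==")
  same_sub <- outer(sub, sub, "==")
  P[same_mod] <- params$intra_p
  if (params$levels == 2) P[same_mod & same_sub] <- params$sub_p

  up <- upper.tri(P)
  edge <- up & (matrix(stats::runif(n_regions^2), n_regions) < P)
  n_edges <- sum(edge)
  J <- diag(n_regions)
  w <- stats::runif(n_edges, params$weight_range[1], params$weight_range[2])
  J[edge] <- -w
  J <- J + t(J) - diag(diag(J))
  J <- .load_to_pd(J, params$max_cond)
  # unit-diagonal (partial-correlation) normalization of the ground truth
  dj <- sqrt(diag(J))
  J <- J / outer(dj, dj)

  # structural weights: heavy-tailed positives on the (possibly rewired)
  # precision support, magnitude coupled to the conditional dependency
  S <- matrix(0, n_regions, n_regions)
  wmag <- abs(J[edge])
  S[edge] <- (wmag / mean(wmag)) *
    stats::rlnorm(n_edges, params$struct_meanlog, params$struct_sdlog)
  if (params$rewire_frac > 0 && n_edges > 0) {
    eidx <- which(edge)
    nonedge <- which(up & !edge)
    n_rw <- min(floor(params$rewire_frac * n_edges), length(nonedge))
    if (n_rw > 0) {
      from <- sample(eidx, n_rw)
      to <- sample(nonedge, n_rw)
      S[to] <- S[from]
      S[from] <- 0
    }
  }
  S <- S + t(S)
  if (connect) S <- .connect_components(S)

  structure(list(n_regions = n_regions, module_labels = labels,
                 sub_labels = sub, precision_true = J, structural_true = S,
                 params = params, seed = as.integer(seed)),
            class = "planted_model")
}

#' @export
print.planted_model <- function(x, ...) {
  cat("planted_model:", x$n_regions, "regions,",
      length(unique(x$module_labels)), "modules",
      if (x$params$levels == 2) sprintf("(%d sub-modules)", length(unique(x$sub_labels))),
      "\n  precision edges:", sum(x$precision_true[upper.tri(x$precision_true)] != 0),
      " structural edges:", sum(x$structural_true[upper.tri(x$structural_true)] > 0),
      "\n")
  invisible(x)
}

.standardize_rows <- function(X) {
  X <- X - rowMeans(X)
  # population (1/T) scaling so the sample correlation has exact unit diagonal
  s <- sqrt(rowMeans(X^2))
  if (any(s == 0)) stop("constant row cannot be standardized")
  X / s
}

#' Wrap a region-by-time matrix as a standardized time-series panel
#'
#' Rows are demeaned and scaled to unit (population) standard deviation, so
#' that the sample correlation `X X^T / T` has exact unit diagonal.
#'
#' @param X numeric region-by-time matrix.
#' @return an object of class `ts_panel` with fields `values`, `n_regions`,
#'   `n_times`, and the regions-to-timepoints ratio `q = N/T`.
#' @export
as_panel <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X) || nrow(X) < 1 || ncol(X) < 2) {
    stop("X must be a numeric matrix with at least 2 time points")
  }
  X <- .standardize_rows(X)
  structure(list(values = X, n_regions = nrow(X), n_times = ncol(X),
                 q = nrow(X) / ncol(X)),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf("ts_panel: N = %d regions, T = %d time steps (q = %.3f)\n",
              x$n_regions, x$n_times, x$q))
  invisible(x)
}

.sample_gaussian_panel <- function(precision, n_times, ar_coeff) {
  N <- nrow(precision)
  Sigma <- solve(precision)
  Sigma <- (Sigma + t(Sigma)) / 2
  L <- chol(Sigma)                       # Sigma = t(L) %*% L
  eps <- t(L) %*% matrix(stats::rnorm(N * n_times), N, n_times)
  if (ar_coeff > 0) {
    X <- eps
    sc <- sqrt(1 - ar_coeff^2)
    for (t in 2:n_times) X[, t] <- ar_coeff * X[, t - 1] + sc * eps[, t]
  } else {
    X <- eps
  }
  as_panel(X)
}

#' Sample a time-series panel from a planted model
#'
#' Draws zero-mean Gaussian innovations with covariance `solve(precision_true)`
#' and optionally mixes them through a stationary AR(1) recursion
#' `x_t = a x_(t-1) + sqrt(1 - a^2) eps_t`, then standardizes each row.
#'
#' @param model a `planted_model`.
#' @param n_times number of time steps (>= 2).
#' @param ar_coeff AR(1) coefficient in `[0, 1)`; 0 gives i.i.d. samples.
#' @param seed integer seed.
#' @return a [as_panel()] object.
#' @export
sample_timeseries <- function(model, n_times, ar_coeff = 0, seed = 1) {
  stopifnot(inherits(model, "planted_model"), n_times >= 2,
            ar_coeff >= 0, ar_coeff < 1)
  set.seed(as.integer(seed))
  .sample_gaussian_panel(model$precision_true, n_times, ar_coeff)
}

# multiplicative lognormal jitter of the nonzero entries of a symmetric
# matrix (upper triangle jittered, mirrored)
.jitter_symmetric <- function(M, sdlog) {
  if (sdlog == 0) return(M)
  up <- upper.tri(M) & (M != 0)
  M[up] <- M[up] * stats::rlnorm(sum(up), 0, sdlog)
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

#' Generate a synthetic cohort with paired structure, function and transcriptome
#'
#' Per subject, the planted precision and structural weights are perturbed
#' multiplicatively (lognormal, `sdlog = subject_jitter`), positive
#' definiteness is re-enforced, and a time-series panel is sampled from the
#' subject's precision. A gene-by-region expression table is generated with a
#' planted mean shift: each disease gene set is over-expressed by
#' `expression_shift` in one target module (diseases assigned to modules
#' round-robin), on top of unit Gaussian noise.
#'
#' @param model a `planted_model`.
#' @param n_subjects cohort size (>= 1).
#' @param subject_jitter lognormal sd of the across-subject weight jitter.
#' @param n_times time steps per subject.
#' @param seed integer master seed; per-subject seeds are derived and recorded.
#' @param ar_coeff AR(1) coefficient passed to the sampler.
#' @param n_genes total genes in the expression table.
#' @param genes_per_set genes per disease set.
#' @param n_diseases number of planted disease sets (default: one per module).
#' @param expression_shift planted over-expression of a disease's genes inside
#'   its target module, in noise-sd units.
#' @return an object of class `sfc_cohort`: `subjects` (list of
#'   `list(panel, sc, seed)`), `model`, `expression`, `gene_sets`,
#'   `disease_groups`, `disease_targets`.
#' @export
make_cohort <- function(model, n_subjects, subject_jitter = 0.1, n_times = 200,
                        seed = 1, ar_coeff = 0, n_genes = 200,
                        genes_per_set = 12, n_diseases = NULL,
                        expression_shift = 3) {
  stopifnot(inherits(model, "planted_model"), n_subjects >= 1,
            subject_jitter >= 0)
  seed <- as.integer(seed)
  n_modules <- length(unique(model$module_labels))
  if (is.null(n_diseases)) n_diseases <- n_modules
  stopifnot(n_diseases * genes_per_set <= n_genes)

  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    seed_s <- (seed + 7919L * s) %% .Machine$integer.max
    set.seed(seed_s)
    Js <- .jitter_symmetric(model$precision_true, subject_jitter)
    Js <- .load_to_pd(Js, model$params$max_cond)
    SCs <- .jitter_symmetric(model$structural_true, subject_jitter)
    panel <- .sample_gaussian_panel(Js, n_times, ar_coeff)
    subjects[[s]] <- list(panel = panel, sc = SCs, seed = seed_s)
  }

  set.seed((seed + 104729L) %% .Machine$integer.max)
  genes <- sprintf("g%04d", seq_len(n_genes))
  regions <- sprintf("r%03d", seq_len(model$n_regions))
  expr <- matrix(stats::rnorm(n_genes * model$n_regions), n_genes,
                 model$n_regions, dimnames = list(genes, regions))
  diseases <- sprintf("disease%02d", seq_len(n_diseases))
  targets <- ((seq_len(n_diseases) - 1) %% n_modules) + 1
  gene_sets <- vector("list", n_diseases)
  names(gene_sets) <- diseases
  for (d in seq_len(n_diseases)) {
    gidx <- ((d - 1) * genes_per_set + 1):(d * genes_per_set)
    gene_sets[[d]] <- genes[gidx]
    ridx <- model$module_labels == targets[d]
    expr[gidx, ridx] <- expr[gidx, ridx] + expression_shift
  }
  groups <- rep_len(c("psychiatric", "neurodegenerative", "tumor", "movement",
                      "substance abuse", "developmental", "other"), n_diseases)
  names(groups) <- diseases
  names(targets) <- diseases

  structure(list(subjects = subjects, model = model, expression = expr,
                 gene_sets = gene_sets, disease_groups = groups,
                 disease_targets = targets, seed = seed),
            class = "sfc_cohort")
}

#' @export
print.sfc_cohort <- function(x, ...) {
  cat(sprintf("sfc_cohort: %d subjects, N = %d regions, T = %d, %d disease sets\n",
              length(x$subjects), x$model$n_regions,
              x$subjects[[1]]$panel$n_times, length(x$gene_sets)))
  invisible(x)
}
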