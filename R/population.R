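#' Population connectivity matrix
#'
#' Element-wise across-subject median of per-subject (absolute-valued,
#' pre-threshold) connectivity matrices.
#'
#' @param cohort_matrices list of matrices of identical shape.
#' @return matrix of the same shape.
#' @export
population_matrix <- function(cohort_matrices) {
  stopifnot(length(cohort_matrices) >= 1)
  dims <- dim(cohort_matrices[[1]])
  for (M in cohort_matrices) {
    if (!all(dim(M) == dims)) stop("shape mismatch across subjects")
  }
  arr <- array(unlist(cohort_matrices), dim = c(dims, length(cohort_matrices)))
  apply(arr, c(1, 2), stats::median)
}

# mean sample correlation across subjects (the GS shrinkage target)
.group_mean_correlation <- function(cohort) {
  Es <- lapply(cohort$subjects,
               function(s) sample_correlation(s$panel)$matrix)
  Reduce(`+`, Es) / length(Es)
}

# one subject, one method: select alpha, build C and Jt estimates
.fit_subject <- function(panel, spec, selection, fixed_alpha, sc_partitions,
                         sc_graph, m_max) {
  if (selection == "likelihood") {
    sel <- select_alpha(panel, spec)
    C <- sel$estimate
    alpha <- sel$alpha
  } else if (selection == "fixed") {
    E <- sample_correlation(panel)$matrix
    alpha <- fixed_alpha
    C <- .fit_correlation(E, spec$method, alpha, q = panel$q,
                          group_target = spec$group_target)
  } else { # chi: oracle grid search maximizing chi_max of the Jt graph
    grid <- spec$alpha_grid
    if (is.null(grid)) grid <- .default_alpha_grid(spec$method, panel$n_regions)
    E <- sample_correlation(panel)$matrix
    best <- -Inf; alpha <- grid[1]; C <- NULL
    for (a in grid) {
      Ca <- tryCatch(
        .fit_correlation(E, spec$method, a, q = panel$q,
                         group_target = spec$group_target),
        error = function(e) NULL)
      if (is.null(Ca)) next
      cm <- tryCatch({
        Jt <- partial_correlation(Ca)
        gj <- percolation_threshold(to_connectivity(Jt), source_role = "Jt")
        pj <- hierarchical_partitions(gj, m_max = m_max)
        cross_modularity_curve(pj, sc_partitions, gj, sc_graph)$chi_max
      }, error = function(e) -Inf)
      if (cm > best || (cm == best && a > alpha)) {
        best <- cm; alpha <- a; C <- Ca
      }
    }
    if (is.null(C)) stop("no feasible strength in the oracle grid")
    C$selection <- "chi"
  }
  list(C = C, alpha = alpha)
}

#' Per-subject estimator sweep against structural connectivity
#'
#' For every subject and requested method: selects the regularization
#' strength, builds correlation- and partial-correlation-based functional
#' graphs at the percolation threshold, cuts the subject's structural matrix
#' at percolation, and computes the cross-modularity curve of each
#' functional graph against the structural one.
#'
#' @param cohort an `sfc_cohort` (or a list with the same `subjects` layout).
#' @param methods character vector of method names and/or a list of
#'   [regularizer_spec()]s. A GS spec without a `group_target` gets the
#'   cohort mean sample correlation.
#' @param selection `"likelihood"` (validation-likelihood alpha),
#'   `"fixed"` (use `fixed_alpha`), or `"chi"` (oracle alpha maximizing the
#'   cross-modularity peak; uses the structural graph).
#' @param fixed_alpha strength used when `selection = "fixed"`.
#' @param m_max largest partition size for the hierarchies.
#' @param roles which functional roles to evaluate (`"C"`, `"Jt"`).
#' @param keep_graphs retain per-subject thresholded graphs (needed for
#'   spectral-distance summaries).
#' @param gs_loo for GS specs without an explicit target, use the
#'   leave-one-out group mean for each subject (excludes the focal subject,
#'   so the validation fold cannot leak into the shrinkage target; relevant
#'   for small cohorts, where the leakage otherwise drives the selected
#'   strength to 1).
#' @return object of class `cohort_result`: `records` (data.frame with one
#'   row per subject/method/role: `subject, method, role, alpha, chi_max,
#'   argmax_m, density`), `curves` (list of `crossmod_curve`), and if
#'   `keep_graphs` the per-role graph lists plus `sc_graphs`.
#' @export
subject_sweep <- function(cohort, methods = "GS",
                          selection = c("likelihood", "fixed", "chi"),
                          fixed_alpha = 0, m_max = 20,
                          roles = c("C", "Jt"), keep_graphs = FALSE,
                          gs_loo = FALSE) {
  selection <- match.arg(selection)
  specs <- lapply(methods, function(m) {
    if (inherits(m, "regularizer_spec")) m else regularizer_spec(m)
  })
  needs_gs <- vapply(specs, function(s) s$method == "GS" && is.null(s$group_target),
                     logical(1))
  Es <- NULL
  if (any(needs_gs)) {
    Es <- lapply(cohort$subjects,
                 function(s) sample_correlation(s$panel)$matrix)
    tgt <- Reduce(`+`, Es) / length(Es)
    for (i in which(needs_gs)) specs[[i]]$group_target <- tgt
  }

  n_sub <- length(cohort$subjects)
  records <- list()
  curves <- list()
  graphs <- list(C = vector("list", n_sub), Jt = vector("list", n_sub))
  sc_graphs <- vector("list", n_sub)

  for (s in seq_len(n_sub)) {
    sub <- cohort$subjects[[s]]
    sc_graph <- percolation_threshold(to_connectivity(sub$sc),
                                      source_role = "SC")
    sc_partitions <- hierarchical_partitions(sc_graph, m_max = m_max)
    sc_graphs[[s]] <- sc_graph
    for (k in seq_along(specs)) {
      spec <- specs[[k]]
      if (gs_loo && !is.null(Es) && needs_gs[k] && length(Es) > 1) {
        spec$group_target <- (spec$group_target * length(Es) - Es[[s]]) /
          (length(Es) - 1)
      }
      fit <- tryCatch(
        .fit_subject(sub$panel, spec, selection, fixed_alpha,
                     sc_partitions, sc_graph, m_max),
        error = function(e) e)
      if (inherits(fit, "error")) {
        records[[length(records) + 1]] <- data.frame(
          subject = s, method = spec$method, role = NA_character_,
          alpha = NA_real_, chi_max = NA_real_, argmax_m = NA_integer_,
          density = NA_real_, error = conditionMessage(fit))
        next
      }
      ests <- list()
      if ("C" %in% roles) ests$C <- fit$C
      if ("Jt" %in% roles) {
        ests$Jt <- tryCatch(partial_correlation(fit$C), error = function(e) e)
      }
      for (role in names(ests)) {
        est <- ests[[role]]
        res <- tryCatch({
          if (inherits(est, "error")) stop(conditionMessage(est))
          g <- percolation_threshold(to_connectivity(est), source_role = role)
          p <- hierarchical_partitions(g, m_max = m_max)
          cm <- cross_modularity_curve(p, sc_partitions, g, sc_graph)
          list(g = g, cm = cm)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          records[[length(records) + 1]] <- data.frame(
            subject = s, method = spec$method, role = role,
            alpha = fit$alpha, chi_max = NA_real_, argmax_m = NA_integer_,
            density = NA_real_, error = conditionMessage(res))
          next
        }
        records[[length(records) + 1]] <- data.frame(
          subject = s, method = spec$method, role = role, alpha = fit$alpha,
          chi_max = res$cm$chi_max, argmax_m = res$cm$argmax_m,
          density = res$g$density, error = NA_character_)
        curves[[paste(s, spec$method, role, sep = ".")]] <- res$cm
        if (keep_graphs) graphs[[role]][[s]] <- res$g
      }
    }
  }

  out <- list(records = do.call(rbind, records), curves = curves)
  if (keep_graphs) {
    out$graphs <- graphs
    out$sc_graphs <- sc_graphs
  }
  class(out) <- "cohort_result"
  out
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("cohort_result:", nrow(x$records), "records\n")
  print(utils::head(x$records, 10))
  invisible(x)
}

#' Pairwise spectral distances across subjects
#'
#' @param graphs list of `sparse_graph`s (one per subject, same role).
#' @param normalize apply [normalize_sc_weights()] (for raw-weight structural
#'   graphs) before computing spectra.
#' @return symmetric zero-diagonal matrix of spectral distances.
#' @export
pairwise_spectral_distance <- function(graphs, normalize = FALSE) {
  n <- length(graphs)
  mats <- lapply(graphs, function(g) {
    A <- .graph_adj(g)
    if (normalize) A <- normalize_sc_weights(A)
    A
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- spectral_distance(mats[[i]], mats[[j]])
    }
  }
  D
}

#' One-sided Mann-Whitney comparison of per-subject values
#'
#' @param values_c,values_j per-subject statistics for the correlation- and
#'   partial-correlation-based pipelines (>= 3 subjects each).
#' @param alternative `"less"` tests that `values_c` is stochastically less
#'   than `values_j`; `"greater"` the reverse.
#' @return list with `statistic` (U) and `p.value`.
#' @export
compare_distributions <- function(values_c, values_j,
                                  alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values_c) >= 3, length(values_j) >= 3)
  if (identical(values_c, values_j) || (stats::sd(c(values_c, values_j)) == 0)) {
    warning("degenerate identical samples; returning p = 0.5")
    return(list(statistic = NA_real_, p.value = 0.5))
  }
  wt <- stats::wilcox.test(values_c, values_j, alternative = alternative,
                           exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

# per-subject abs partial-correlation matrices at likelihood-selected alpha;
# the inputs to the population median and the bootstrap
.cohort_jt_matrices <- function(cohort, spec, n_folds = 5) {
  if (spec$method == "GS" && is.null(spec$group_target)) {
    spec$group_target <- .group_mean_correlation(cohort)
  }
  lapply(cohort$subjects, function(sub) {
    sel <- select_alpha(sub$panel, spec)
    to_connectivity(partial_correlation(sel$estimate))
  })
}

#' Bootstrap stability of the population partition
#'
#' The reference is the partition (into `m` modules) of the percolation
#' graph of the population median of per-subject absolute partial
#' correlations at their likelihood-selected strengths. Each bootstrap
#' replicate resamples subjects with replacement, rebuilds the population
#' matrix from the stored per-subject matrices, re-thresholds, re-partitions
#' and is scored against the reference by adjusted NMI. Per-module
#' persistence is the replicate-averaged best-match NMI of the module's
#' in/out indicator against the indicators of the replicate's modules.
#'
#' @param cohort an `sfc_cohort`.
#' @param spec a [regularizer_spec()] (method used for every subject).
#' @param m number of modules of the reference partition.
#' @param B number of bootstrap replicates.
#' @param seed integer seed for the resampling.
#' @param m_max hierarchy depth (must be >= m).
#' @return object of class `stability_report`: `overall_nmi`,
#'   `per_module_persistence` (length-`m` vector), `B`, `seed`,
#'   `reference_labels`.
#' @export
bootstrap_partition_stability <- function(cohort, spec, m, B = 100, seed = 1,
                                          m_max = max(20, m)) {
  stopifnot(B >= 1, m >= 2, m_max >= m)
  mats <- .cohort_jt_matrices(cohort, spec)
  n_sub <- length(mats)

  partition_of <- function(mat_list) {
    M <- population_matrix(mat_list)
    g <- percolation_threshold(M, source_role = "Jt")
    p <- hierarchical_partitions(g, m_max = m_max)
    .labels_at(p, m)
  }
  ref <- partition_of(mats)

  set.seed(as.integer(seed))
  nmis <- numeric(B)
  persist <- matrix(NA_real_, B, m)
  for (b in seq_len(B)) {
    idx <- sample.int(n_sub, n_sub, replace = TRUE)
    lab <- partition_of(mats[idx])
    nmis[b] <- adjusted_nmi(ref, lab)
    for (k in seq_len(m)) {
      ind_ref <- as.integer(ref == k)
      best <- 0
      for (kk in unique(lab)) {
        v <- adjusted_nmi(ind_ref, as.integer(lab == kk))
        if (v > best) best <- v
      }
      persist[b, k] <- best
    }
  }
  structure(list(overall_nmi = mean(nmis),
                 per_module_persistence = colMeans(persist),
                 B = B, seed = as.integer(seed), reference_labels = ref),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: B = %d, overall NMI = %.3f\n", x$B,
              x$overall_nmi))
  invisible(x)
}

#' Disease gene-set Z-scores across modules
#'
#' For each disease `d` and module `M`, the disease expression value
#' `e(d, M)` is the median expression over the disease's genes and the
#' module's regions; `z(d, M)` standardizes `e(d, .)` across modules
#' (sample sd, denominator `n - 1`). `|z| > 2` marks significant over- or
#' under-representation.
#'
#' @param partition integer module labels over regions (all modules
#'   nonempty).
#' @param expression gene-by-region matrix with gene-id rownames.
#' @param gene_sets named list: disease -> character vector of gene ids;
#'   diseases with no gene present in `expression` are dropped with a
#'   warning.
#' @param disease_groups optional named vector: disease -> group label.
#' @return object of class `module_disease_profile`: `z` (module x disease),
#'   `significant` (same shape, `|z| > 2`), `expression_medians`,
#'   `disease_groups`.
#' @export
disease_zscores <- function(partition, expression, gene_sets,
                            disease_groups = NULL) {
  stopifnot(is.matrix(expression), length(partition) == ncol(expression))
  modules <- sort(unique(partition))
  keep <- vapply(gene_sets, function(g) any(g %in% rownames(expression)),
                 logical(1))
  if (!all(keep)) {
    warning("dropping diseases with no mapped genes: ",
            paste(names(gene_sets)[!keep], collapse = ", "))
    gene_sets <- gene_sets[keep]
  }
  if (length(gene_sets) == 0) stop("no disease has mapped genes")

  med <- matrix(NA_real_, length(modules), length(gene_sets),
                dimnames = list(paste0("M", modules), names(gene_sets)))
  for (d in seq_along(gene_sets)) {
    g <- intersect(gene_sets[[d]], rownames(expression))
    for (k in seq_along(modules)) {
      r <- partition == modules[k]
      med[k, d] <- stats::median(expression[g, r, drop = FALSE])
    }
  }
  z <- med
  for (d in seq_len(ncol(med))) {
    s <- stats::sd(med[, d])
    if (!is.finite(s) || s == 0) {
      warning("disease ", colnames(med)[d],
              " has constant module medians; Z set to 0")
      z[, d] <- 0
    } else {
      z[, d] <- (med[, d] - mean(med[, d])) / s
    }
  }
  structure(list(z = z, significant = abs(z) > 2, expression_medians = med,
                 disease_groups = disease_groups),
            class = "module_disease_profile")
}

#' @export
print.module_disease_profile <- function(x, ...) {
  cat("module_disease_profile:", nrow(x$z), "modules x", ncol(x$z),
      "diseases;", sum(x$significant), "significant cells (|z| > 2)\n")
  invisible(x)
}
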