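# Recovery-experiment drivers: each generates synthetic cohorts under the
# package's default planted conditions, runs the pipeline, and returns the
# summary statistics of one headline contrast.

.auc_rank <- function(scores, truth) {
  # Mann-Whitney formulation of the area under the ROC curve
  r <- rank(scores)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Edge-support recovery AUC of an estimate against the planted precision
#'
#' Ranks region pairs by the absolute off-diagonal entries of `est` and
#' scores them against the planted precision support.
#'
#' @param est `conn_estimate` or matrix.
#' @param model the `planted_model` that generated the data.
#' @return area under the ROC curve in `[0, 1]`.
#' @export
support_auc <- function(est, model) {
  M <- abs(.est_matrix(est))
  up <- upper.tri(M)
  truth <- model$precision_true[up] != 0
  .auc_rank(M[up], truth)
}

#' Headline recovery: partial correlation beats correlation in cross-modularity
#'
#' Generates one synthetic cohort, runs the per-subject sweep with
#' likelihood-selected strengths, and compares the per-subject
#' cross-modularity peaks of partial-correlation-based and
#' correlation-based functional graphs with a one-sided Mann-Whitney test.
#'
#' @param seed integer seed.
#' @param n_regions,n_modules,n_subjects,n_times cohort dimensions.
#' @param method regularization method for the sweep.
#' @param m_max hierarchy depth.
#' @return list: `records`, `chi_c`, `chi_j` (per-subject peaks),
#'   `median_chi_c`, `median_chi_j`, `test` (U statistic and one-sided p for
#'   "C less than Jt").
#' @export
experiment_headline <- function(seed = 1, n_regions = 60, n_modules = 6,
                                n_subjects = 20, n_times = 200,
                                method = "GS", m_max = 20) {
  model <- make_planted_model(n_regions, n_modules, seed = seed)
  cohort <- make_cohort(model, n_subjects, n_times = n_times, seed = seed + 1)
  sw <- subject_sweep(cohort, methods = method, selection = "likelihood",
                      m_max = m_max, gs_loo = TRUE)
  rec <- sw$records
  chi_c <- rec$chi_max[rec$role == "C"]
  chi_j <- rec$chi_max[rec$role == "Jt"]
  test <- compare_distributions(chi_c, chi_j, alternative = "less")
  list(records = rec, chi_c = chi_c, chi_j = chi_j,
       median_chi_c = stats::median(chi_c, na.rm = TRUE),
       median_chi_j = stats::median(chi_j, na.rm = TRUE),
       test = test)
}

#' Support-recovery contrast across seeds
#'
#' One cohort per seed: every subject's connectivity is estimated at its
#' likelihood-selected strength and the cohort-mean area under the ROC curve
#' of edge ranking against the planted precision support is recorded for the
#' absolute correlation and the absolute partial correlation.
#'
#' @param seeds integer vector of seeds.
#' @param n_regions,n_modules,n_subjects,n_times problem size.
#' @param method regularization method.
#' @return data.frame with one row per seed: `seed, auc_c, auc_j`
#'   (cohort-mean AUCs).
#' @export
experiment_support_recovery <- function(seeds = 1:20, n_regions = 60,
                                        n_modules = 6, n_subjects = 6,
                                        n_times = 200, method = "GS") {
  rows <- lapply(seeds, function(sd) {
    model <- make_planted_model(n_regions, n_modules, seed = sd)
    cohort <- make_cohort(model, n_subjects, n_times = n_times, seed = sd + 1)
    spec <- regularizer_spec(method)
    Es <- lapply(cohort$subjects,
                 function(sub) sample_correlation(sub$panel)$matrix)
    tgt <- Reduce(`+`, Es) / length(Es)
    aucs <- vapply(seq_along(cohort$subjects), function(s) {
      if (method == "GS") {
        # leave-one-out group target: no validation leakage at small P
        spec$group_target <- (tgt * length(Es) - Es[[s]]) / (length(Es) - 1)
      }
      sel <- select_alpha(cohort$subjects[[s]]$panel, spec)
      c(support_auc(sel$estimate, model),
        support_auc(partial_correlation(sel$estimate), model))
    }, numeric(2))
    data.frame(seed = sd, auc_c = mean(aucs[1, ]), auc_j = mean(aucs[2, ]))
  })
  do.call(rbind, rows)
}

#' Regularization-is-crucial contrast at q = N/T around 0.75
#'
#' One subject per seed at `N = 90, T = 120`: the cross-modularity peak of
#' the raw (unregularized) partial correlation against structure is compared
#' with the likelihood-regularized one, paired by seed.
#'
#' @param seeds integer seeds.
#' @param n_regions,n_modules,n_times problem size (defaults give q = 0.75).
#' @param method regularization method for the regularized arm.
#' @param m_max hierarchy depth.
#' @return list: `raw`, `regularized` (per-seed chi peaks), medians, and a
#'   one-sided paired rank test (`raw` less than `regularized`).
#' @export
experiment_raw_vs_regularized <- function(seeds = 1:20, n_regions = 90,
                                          n_modules = 6, n_times = 120,
                                          method = "IS", m_max = 20) {
  chi_raw <- chi_reg <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    sd <- seeds[i]
    model <- make_planted_model(n_regions, n_modules, seed = sd)
    cohort <- list(subjects = list(list(
      panel = sample_timeseries(model, n_times, seed = sd + 1),
      sc = model$structural_true)))
    sw_raw <- subject_sweep(cohort, methods = "raw", selection = "fixed",
                            fixed_alpha = 0, m_max = m_max, roles = "Jt")
    sw_reg <- subject_sweep(cohort, methods = method,
                            selection = "likelihood", m_max = m_max,
                            roles = "Jt")
    chi_raw[i] <- sw_raw$records$chi_max[1]
    chi_reg[i] <- sw_reg$records$chi_max[1]
  }
  wt <- stats::wilcox.test(chi_raw, chi_reg, paired = TRUE,
                           alternative = "less", exact = FALSE)
  list(raw = chi_raw, regularized = chi_reg,
       median_raw = stats::median(chi_raw, na.rm = TRUE),
       median_regularized = stats::median(chi_reg, na.rm = TRUE),
       test = list(statistic = unname(wt$statistic), p.value = wt$p.value))
}

#' Likelihood-selected strength is nearly oracle-optimal for coupling
#'
#' For each subject of one cohort, compares the cross-modularity peak at the
#' likelihood-selected strength with the peak at the oracle strength that
#' maximizes coupling itself (which uses the structural graph).
#'
#' @param seed integer seed.
#' @param n_regions,n_modules,n_subjects,n_times cohort dimensions.
#' @param method regularization method.
#' @param m_max hierarchy depth.
#' @param rel_tol relative shortfall counted as "within" (default 10%).
#' @return list: per-subject `chi_lik`, `chi_oracle`, `alpha_lik`,
#'   `alpha_oracle`, and `frac_within` (fraction of subjects with
#'   `chi_lik >= (1 - rel_tol) * chi_oracle`).
#' @export
experiment_alpha_robustness <- function(seed = 1, n_regions = 60,
                                        n_modules = 6, n_subjects = 12,
                                        n_times = 200, method = "GS",
                                        m_max = 20, rel_tol = 0.10) {
  model <- make_planted_model(n_regions, n_modules, seed = seed)
  cohort <- make_cohort(model, n_subjects, n_times = n_times, seed = seed + 1)
  sw_lik <- subject_sweep(cohort, methods = method, selection = "likelihood",
                          m_max = m_max, roles = "Jt", gs_loo = TRUE)
  sw_chi <- subject_sweep(cohort, methods = method, selection = "chi",
                          m_max = m_max, roles = "Jt", gs_loo = TRUE)
  chi_lik <- sw_lik$records$chi_max
  chi_ora <- sw_chi$records$chi_max
  ok <- chi_lik >= (1 - rel_tol) * chi_ora
  list(chi_lik = chi_lik, chi_oracle = chi_ora,
       alpha_lik = sw_lik$records$alpha, alpha_oracle = sw_chi$records$alpha,
       frac_within = mean(ok, na.rm = TRUE))
}

#' Cross-modularity curve shape: interior peak near the planted module count
#'
#' One cohort per seed; the representative partition size of a cohort is the
#' across-subject median of the per-subject chi argmax (the estimator used
#' to extract a meaningful number of modules from the curve's soft maximum),
#' and is compared to the planted coarse module count.
#'
#' @param seeds integer seeds.
#' @param n_regions,n_modules,n_subjects,n_times problem size.
#' @param method regularization method.
#' @param m_max hierarchy depth.
#' @return data.frame: `seed, argmax_m` (cohort median), `target`,
#'   `interior`, `within2` (median argmax within plus/minus 2 of the planted
#'   coarse count).
#' @export
experiment_curve_shape <- function(seeds = 1:20, n_regions = 60,
                                   n_modules = 6, n_subjects = 8,
                                   n_times = 200, method = "GS",
                                   m_max = 20) {
  rows <- lapply(seeds, function(sd) {
    model <- make_planted_model(n_regions, n_modules, seed = sd)
    cohort <- make_cohort(model, n_subjects = n_subjects, n_times = n_times,
                          seed = sd + 1)
    sw <- subject_sweep(cohort, methods = method, selection = "likelihood",
                        m_max = m_max, roles = "Jt", gs_loo = TRUE)
    arg <- stats::median(sw$records$argmax_m, na.rm = TRUE)
    data.frame(seed = sd, argmax_m = arg, target = n_modules,
               interior = arg > 2 & arg < m_max,
               within2 = abs(arg - n_modules) <= 2)
  })
  do.call(rbind, rows)
}

#' Percolation density contrast and the density sweep
#'
#' Per subject: percolation densities of the correlation- and partial-
#' correlation-based graphs, plus the cross-modularity peak at a grid of
#' matched fixed densities (structural graph always at percolation).
#'
#' @param seed integer seed.
#' @param n_regions,n_modules,n_subjects,n_times cohort dimensions.
#' @param method regularization method.
#' @param rho_grid fixed FC densities to sweep.
#' @param m_max hierarchy depth.
#' @return list: `densities` (per subject, per role, at percolation) and
#'   `sweep` (data.frame `rho, role, median_chi`).
#' @export
experiment_density <- function(seed = 1, n_regions = 60, n_modules = 6,
                               n_subjects = 10, n_times = 200, method = "GS",
                               rho_grid = c(0.05, 0.1, 0.2, 0.3, 0.5),
                               m_max = 20) {
  model <- make_planted_model(n_regions, n_modules, seed = seed)
  cohort <- make_cohort(model, n_subjects, n_times = n_times, seed = seed + 1)
  spec <- regularizer_spec(method)
  Es <- lapply(cohort$subjects,
               function(sub) sample_correlation(sub$panel)$matrix)
  tgt <- Reduce(`+`, Es) / length(Es)

  dens <- list()
  sweep_rows <- list()
  for (s in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[s]]
    if (method == "GS") {
      spec$group_target <- (tgt * length(Es) - Es[[s]]) / (length(Es) - 1)
    }
    sel <- select_alpha(sub$panel, spec)
    C <- sel$estimate
    Jt <- partial_correlation(C)
    sc_graph <- percolation_threshold(to_connectivity(sub$sc),
                                      source_role = "SC")
    sc_part <- hierarchical_partitions(sc_graph, m_max = m_max)
    mats <- list(C = to_connectivity(C), Jt = to_connectivity(Jt))
    for (role in names(mats)) {
      gp <- percolation_threshold(mats[[role]], source_role = role)
      dens[[length(dens) + 1]] <- data.frame(subject = s, role = role,
                                             perc_density = gp$density)
      for (rho in rho_grid) {
        g <- threshold_to_density(mats[[role]], rho, source_role = role)
        chi <- tryCatch({
          p <- hierarchical_partitions(g, m_max = m_max)
          cross_modularity_curve(p, sc_part, g, sc_graph)$chi_max
        }, error = function(e) NA_real_)
        sweep_rows[[length(sweep_rows) + 1]] <-
          data.frame(subject = s, role = role, rho = rho, chi_max = chi)
      }
    }
  }
  dens <- do.call(rbind, dens)
  sweep <- do.call(rbind, sweep_rows)
  agg <- stats::aggregate(chi_max ~ rho + role, data = sweep,
                          FUN = stats::median, na.rm = TRUE)
  list(densities = dens, sweep = sweep, sweep_median = agg)
}
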