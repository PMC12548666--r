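#' Pipeline configuration
#'
#' Validates and normalizes the configuration of [run_pipeline()]. Every
#' stochastic stage must carry an explicit seed; the configuration
#' round-trips losslessly through YAML.
#'
#' @param x a named list, or the path of a YAML file holding one. Recognized
#'   fields: `cohort` (either synthetic parameters `n_regions, n_modules,
#'   n_subjects, n_times, subject_jitter, seed` or file paths
#'   `timeseries_files, sc_files`), `methods` (character vector), `selection`,
#'   `threshold` (`mode` = "percolation" or "density", optional `rho`),
#'   `m_max`, optional `bootstrap` (`B, m, seed`), optional `disease`
#'   (`expression_file, gene_sets_file`).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")
  if (is.null(cfg$cohort)) stop("config lacks a 'cohort' section")
  synthetic <- is.null(cfg$cohort$timeseries_files)
  if (synthetic) {
    for (f in c("n_regions", "n_modules", "n_subjects", "n_times", "seed")) {
      if (is.null(cfg$cohort[[f]])) {
        stop("synthetic cohort config lacks required field '", f, "'")
      }
    }
    if (is.null(cfg$cohort$subject_jitter)) cfg$cohort$subject_jitter <- 0.1
  } else {
    if (is.null(cfg$cohort$sc_files)) stop("cohort lacks 'sc_files'")
    if (length(cfg$cohort$timeseries_files) != length(cfg$cohort$sc_files)) {
      stop("timeseries_files and sc_files differ in length")
    }
  }
  if (is.null(cfg$methods)) cfg$methods <- "GS"
  if (is.null(cfg$selection)) cfg$selection <- "likelihood"
  if (is.null(cfg$threshold)) cfg$threshold <- list(mode = "percolation")
  if (identical(cfg$threshold$mode, "density") && is.null(cfg$threshold$rho)) {
    stop("density threshold mode requires 'rho'")
  }
  if (is.null(cfg$m_max)) cfg$m_max <- 20
  if (!is.null(cfg$bootstrap)) {
    for (f in c("B", "m", "seed")) {
      if (is.null(cfg$bootstrap[[f]])) {
        stop("bootstrap config lacks required field '", f, "'")
      }
    }
  }
  cfg$synthetic <- synthetic
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.load_cohort <- function(cfg) {
  if (cfg$synthetic) {
    model <- make_planted_model(cfg$cohort$n_regions, cfg$cohort$n_modules,
                                seed = cfg$cohort$seed)
    make_cohort(model, cfg$cohort$n_subjects,
                subject_jitter = cfg$cohort$subject_jitter,
                n_times = cfg$cohort$n_times, seed = cfg$cohort$seed + 1)
  } else {
    subjects <- lapply(seq_along(cfg$cohort$timeseries_files), function(s) {
      list(panel = read_matrix(cfg$cohort$timeseries_files[[s]], "timeseries"),
           sc = read_matrix(cfg$cohort$sc_files[[s]], "connectivity"),
           seed = NA_integer_)
    })
    structure(list(subjects = subjects, model = NULL), class = "sfc_cohort")
  }
}

#' Run the full structure-function coupling pipeline
#'
#' Stages: simulate or load the cohort, estimate connectivity with the
#' configured methods and selection mode, sparsify, compute per-subject
#' cross-modularity curves against structure, build the population partition,
#' and optionally bootstrap its stability and score disease gene sets. Every
#' artifact is written under `out_dir` together with a machine-readable run
#' manifest; identical configurations produce identical artifact trees.
#'
#' @param config a [pipeline_config()] (or list / YAML path accepted by it).
#' @param out_dir output directory.
#' @return (invisibly) a list with `records`, `population_labels`, and when
#'   configured `stability` and `disease`; all also written as TSV.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)

  message("stage 1/4: cohort (",
          if (cfg$synthetic) "synthetic" else "files", ")")
  cohort <- .load_cohort(cfg)

  message("stage 2/4: per-subject sweep (", length(cohort$subjects),
          " subjects, methods: ", paste(cfg$methods, collapse = ", "), ")")
  sw <- withCallingHandlers(
    subject_sweep(cohort, methods = cfg$methods, selection = cfg$selection,
                  m_max = cfg$m_max, keep_graphs = TRUE),
    warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  utils::write.table(sw$records, file.path(out_dir, "subject_records.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  curves <- do.call(rbind, lapply(names(sw$curves), function(nm) {
    cbind(key = nm, sw$curves[[nm]]$curve)
  }))
  utils::write.table(curves, file.path(out_dir, "chi_curves.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  message("stage 3/4: population partition")
  spec <- regularizer_spec(cfg$methods[[1]])
  mats <- .cohort_jt_matrices(cohort, spec)
  popM <- population_matrix(mats)
  pop_graph <- percolation_threshold(popM, source_role = "Jt")
  pop_part <- hierarchical_partitions(pop_graph, m_max = cfg$m_max)
  write_partitions(pop_part, file.path(out_dir, "population_partitions"))
  write_edgelist(pop_graph, file.path(out_dir, "population_graph.tsv"))

  out <- list(records = sw$records, population_labels = pop_part$labels_by_m)

  message("stage 4/4: population characterization")
  if (!is.null(cfg$bootstrap)) {
    st <- bootstrap_partition_stability(cohort, spec, m = cfg$bootstrap$m,
                                        B = cfg$bootstrap$B,
                                        seed = cfg$bootstrap$seed,
                                        m_max = max(cfg$m_max, cfg$bootstrap$m))
    utils::write.table(
      data.frame(module = seq_along(st$per_module_persistence),
                 persistence = st$per_module_persistence,
                 overall_nmi = st$overall_nmi),
      file.path(out_dir, "stability.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    out$stability <- st
  }
  has_expr <- (cfg$synthetic && !is.null(cohort$expression)) ||
    !is.null(cfg$disease$expression_file)
  if (has_expr && !is.null(cfg$bootstrap)) {
    expr <- if (cfg$synthetic) cohort$expression else
      read_matrix(cfg$disease$expression_file, "expression")
    gsets <- if (cfg$synthetic) cohort$gene_sets else
      .read_gene_sets(cfg$disease$gene_sets_file)
    labels <- .labels_at(pop_part, cfg$bootstrap$m)
    dz <- withCallingHandlers(
      disease_zscores(labels, expr, gsets,
                      disease_groups = if (cfg$synthetic) cohort$disease_groups),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    utils::write.table(dz$z, file.path(out_dir, "disease_zscores.tsv"),
                       sep = "\t", row.names = TRUE, quote = FALSE,
                       col.names = NA)
    out$disease <- dz
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sfcoupling")),
    r_version = as.character(getRversion()),
    config = unclass(cfg),
    n_subjects = length(cohort$subjects),
    warnings = warnings_log,
    artifacts = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

# two-column text: disease <tab> gene
.read_gene_sets <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("disease", "gene"))
  split(df$gene, df$disease)
}
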