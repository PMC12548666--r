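test_that("matrix reading round-trips panels, connectivity and expression", {
  td <- withr::local_tempdir()

  X <- matrix(rnorm(3 * 5), 3, 5)
  ts_path <- file.path(td, "ts.tsv")
  write.table(X, ts_path, sep = "\t", row.names = FALSE, col.names = FALSE)
  panel <- read_matrix(ts_path, "timeseries")
  expect_s3_class(panel, "ts_panel")
  expect_equal(panel$n_regions, 3)
  expect_equal(panel$n_times, 5)

  S <- matrix(c(0, 2, 2, 0), 2)
  sc_path <- file.path(td, "sc.tsv")
  write_matrix(S, sc_path)
  expect_equal(read_matrix(sc_path, "connectivity"), S)

  # tiny asymmetry is symmetrized silently; large asymmetry errors loudly
  S2 <- S; S2[1, 2] <- 2 + 1e-9 * 2
  write_matrix(S2, file.path(td, "sc2.tsv"))
  expect_silent(M2 <- read_matrix(file.path(td, "sc2.tsv"), "connectivity"))
  expect_equal(M2, (S2 + t(S2)) / 2)
  S3 <- S; S3[1, 2] <- 5
  write_matrix(S3, file.path(td, "sc3.tsv"))
  expect_error(read_matrix(file.path(td, "sc3.tsv"), "connectivity"),
               "asymmetry")

  E <- matrix(rnorm(6), 2, 3,
              dimnames = list(c("gA", "gB"), c("r1", "r2", "r3")))
  ex_path <- file.path(td, "expr.tsv")
  write.table(E, ex_path, sep = "\t", quote = FALSE, col.names = NA)
  E2 <- read_matrix(ex_path, "expression")
  expect_equal(E2, E)

  writeLines(c("1\t2", "3\tx"), file.path(td, "bad.tsv"))
  expect_error(read_matrix(file.path(td, "bad.tsv"), "timeseries"))
  expect_error(read_matrix(file.path(td, "missing.tsv"), "timeseries"),
               "not found")
})

test_that("edge lists and partitions serialize with 0-based ids", {
  td <- withr::local_tempdir()
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.5
  A[2, 3] <- A[3, 2] <- 0.7
  g <- sparse_graph(A)
  write_edgelist(g, file.path(td, "el.tsv"))
  el <- read.table(file.path(td, "el.tsv"), header = TRUE)
  expect_equal(nrow(el), 2)
  expect_equal(min(el$i), 0)
  expect_equal(sort(el$w), c(0.5, 0.7))

  p <- hierarchical_partitions(two_cliques(4), m_max = 3)
  write_partitions(p, file.path(td, "parts"))
  f <- list.files(file.path(td, "parts"))
  expect_setequal(f, c("partition_m02.tsv", "partition_m03.tsv"))
  pt <- read.table(file.path(td, "parts", "partition_m02.tsv"), header = TRUE)
  expect_equal(nrow(pt), 8)
  expect_equal(length(unique(pt$module)), 2)
})

test_that("configurations validate seeds and round-trip through YAML", {
  cfg <- list(cohort = list(n_regions = 24, n_modules = 2, n_subjects = 2,
                            n_times = 60, seed = 5),
              methods = "IS", m_max = 8)
  pc <- pipeline_config(cfg)
  expect_s3_class(pc, "pipeline_config")
  expect_equal(pc$cohort$subject_jitter, 0.1)

  td <- withr::local_tempdir()
  yml <- file.path(td, "cfg.yaml")
  yaml::write_yaml(cfg, yml)
  pc2 <- pipeline_config(yml)
  expect_equal(pc2$cohort, pc$cohort)

  expect_error(pipeline_config(list(cohort = list(n_regions = 10,
                                                  n_modules = 2,
                                                  n_subjects = 1,
                                                  n_times = 50))), "seed")
  expect_error(pipeline_config(list()), "cohort")
  expect_error(pipeline_config(list(cohort = list(n_regions = 10,
                                                  n_modules = 2,
                                                  n_subjects = 1,
                                                  n_times = 50, seed = 1),
                                    threshold = list(mode = "density"))),
               "rho")
})

test_that("the pipeline runs end to end, writes artifacts and is deterministic", {
  td <- withr::local_tempdir()
  cfg <- list(cohort = list(n_regions = 40, n_modules = 4, n_subjects = 8,
                            n_times = 120, seed = 9),
              methods = "IS", m_max = 10,
              bootstrap = list(B = 3, m = 4, seed = 10))
  out1 <- file.path(td, "run1")
  res1 <- suppressMessages(run_pipeline(cfg, out1))
  expect_true(file.exists(file.path(out1, "subject_records.tsv")))
  expect_true(file.exists(file.path(out1, "chi_curves.tsv")))
  expect_true(file.exists(file.path(out1, "stability.tsv")))
  expect_true(file.exists(file.path(out1, "disease_zscores.tsv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "population_graph.tsv")))
  expect_gt(length(list.files(file.path(out1, "population_partitions"))), 0)
  expect_equal(nrow(res1$records), 16)

  manifest <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(manifest$n_subjects, 8)
  expect_equal(manifest$config$cohort$seed, 9)

  out2 <- file.path(td, "run2")
  suppressMessages(run_pipeline(cfg, out2))
  c1 <- readLines(file.path(out1, "chi_curves.tsv"))
  c2 <- readLines(file.path(out2, "chi_curves.tsv"))
  expect_identical(c1, c2)
})

test_that("file-based cohorts feed the sweep like synthetic ones", {
  td <- withr::local_tempdir()
  model <- make_planted_model(20, 2, seed = 51)
  co <- make_cohort(model, 2, n_times = 80, seed = 52)
  ts_files <- sc_files <- character(2)
  for (s in 1:2) {
    ts_files[s] <- file.path(td, sprintf("ts%d.tsv", s))
    sc_files[s] <- file.path(td, sprintf("sc%d.tsv", s))
    write_matrix(co$subjects[[s]]$panel$values, ts_files[s])
    write_matrix(co$subjects[[s]]$sc, sc_files[s])
  }
  cfg <- pipeline_config(list(
    cohort = list(timeseries_files = as.list(ts_files),
                  sc_files = as.list(sc_files)),
    methods = "IS", m_max = 8))
  loaded <- sfcoupling:::.load_cohort(cfg)
  expect_length(loaded$subjects, 2)
  expect_equal(loaded$subjects[[1]]$panel$values,
               co$subjects[[1]]$panel$values, tolerance = 1e-10)
  sw <- subject_sweep(loaded, methods = "IS", selection = "likelihood",
                      m_max = 8)
  expect_equal(nrow(sw$records), 4)
})
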