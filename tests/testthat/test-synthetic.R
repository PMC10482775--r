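test_that("same seed gives byte-identical output files", {
  truth <- simulation_truth(cv = 0.05, seed = 42)
  d1 <- tempfile("sim1")
  d2 <- tempfile("sim2")
  simulate_experiment(truth, study_design(tissues = "pea_leaf"), out_dir = d1)
  simulate_experiment(truth, study_design(tissues = "pea_leaf"), out_dir = d2)
  for (f in c("compounds.csv", "samples.csv", "injections.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the noisy areas
  truth2 <- simulation_truth(cv = 0.05, seed = 43)
  d3 <- tempfile("sim3")
  simulate_experiment(truth2, study_design(tissues = "pea_leaf"), out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "injections.csv")),
                         readLines(file.path(d3, "injections.csv"))))
})

test_that("generated files pass data-model validation and round-trip", {
  truth <- simulation_truth(cv = 0.05, seed = 12)
  dir <- tempfile("sim")
  tab <- simulate_experiment(truth, study_design(), out_dir = dir)
  back <- load_tables(file.path(dir, "compounds.csv"),
                      file.path(dir, "samples.csv"),
                      file.path(dir, "injections.csv"))
  expect_equal(as.data.frame(back$injections), as.data.frame(tab$injections))
  expect_equal(nrow(back$samples), nrow(tab$samples))
  expect_true(all(back$samples$acquisition_index >= 0))
  truth_json <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(truth_json$parameters$seed, 12)
  expect_equal(sort(names(truth_json$parameters$rf)),
               sort(tab$registry$name))
})

test_that("noise-free generation satisfies its closed forms exactly", {
  # s = 1, r = 1, cv = 0: the pipeline returns truth to machine precision
  truth <- simulation_truth(cv = 0, matrix_factor = c(pea_leaf = 1),
                            seed = 1)
  tab <- simulate_experiment(truth, study_design(tissues = "pea_leaf"))
  models <- calibrate(tab)
  for (cmp in tab$registry$name) {
    expect_equal(models[[cmp]]$arf, truth$rf[[cmp]])
    expect_equal(models[[cmp]]$r2, 1.0)
  }
  res <- quantify_samples(tab, models = models)
  truth_tab <- tab$truth$samples
  m <- match(paste(res$sample_id, res$compound),
             paste(truth_tab$sample_id, truth_tab$compound))
  expect_equal(res$conc_tissue_ng_per_g_dw, truth_tab$conc_tissue_true[m])

  # s = 0.7: measured matrix effect is exactly -30
  truth <- simulation_truth(cv = 0, matrix_factor = c(spinach_leaf = 0.7),
                            seed = 1)
  tab <- simulate_experiment(truth, study_design(tissues = "spinach_leaf"))
  me <- matrix_effects(tab, calibrate(tab))
  expect_equal(me$me_percent, rep(-30, nrow(me)))

  # r = 0.85: measured recovery is exactly 85% at every spike level
  truth <- simulation_truth(cv = 0, extraction_recovery = 0.85,
                            matrix_factor = c(pea_leaf = 1), seed = 1)
  tab <- simulate_experiment(truth, study_design(tissues = "pea_leaf"))
  rec <- recovery_table(quantify_samples(tab), tab$samples)
  expect_equal(rec$mean_recovery, rep(85, nrow(rec)))
})

test_that("recovery_benchmark reports zero error in the noise-free world", {
  truth <- simulation_truth(cv = 0, seed = 1)
  bench <- recovery_benchmark(1, truth = truth, seed = 99)
  expect_true(all(bench$relative_error < 1e-9))
  expect_true(any(grepl("^rf_", bench$parameter)))
  expect_true(any(grepl("^me_", bench$parameter)))
  expect_true(any(grepl("^loq_", bench$parameter)))
  expect_true("recovery" %in% bench$parameter)
})

test_that("replicate RSDs under 10% noise match a Monte-Carlo oracle", {
  # ratio of two independent lognormals with CV c has
  # CV = sqrt((1+c^2)^2 - 1); an independent simulation provides the
  # reference scale for the pipeline's heptaplicate RSD estimates
  set.seed(77)
  c10 <- 0.10
  sdlog <- sqrt(log(1 + c10^2))
  oracle <- replicate(400, {
    v <- rlnorm(7, -sdlog^2 / 2, sdlog) / rlnorm(7, -sdlog^2 / 2, sdlog)
    sd(v) / mean(v) * 100
  })
  truth <- simulation_truth(cv = 0.10, matrix_factor = c(pea_leaf = 1),
                            seed = 21)
  tab <- simulate_experiment(truth, study_design(tissues = "pea_leaf"))
  rec <- recovery_table(quantify_samples(tab), tab$samples)
  # 18 groups of 7; their mean RSD should sit near the oracle mean
  expect_equal(mean(rec$rsd), mean(oracle), tolerance = 0.2)
  expect_gt(mean(rec$rsd), 9)
  expect_lt(mean(rec$rsd), 20)
})

test_that("estimates converge to truth as replication grows", {
  reg <- compound_registry(data.frame(
    name = "cbz", is_name = "cbz_d10", role = "parent", parent_name = "",
    pka = NA, pka_kind = "", stringsAsFactors = FALSE))
  truth <- simulation_truth(registry = reg, rf = c(cbz = 1.5),
                            matrix_factor = c(pea_leaf = 1), cv = 0.05,
                            extraction_recovery = 0.9, seed = 314)
  design <- study_design(tissues = "pea_leaf", spike_levels = 100,
                         n_spike_reps = 1000, n_controls = 1)
  tab <- simulate_experiment(truth, design)
  rec <- recovery_table(quantify_samples(tab), tab$samples)
  expect_equal(rec$mean_recovery, 90, tolerance = 0.02)
})

test_that("impossible designs are rejected", {
  expect_error(study_design(tissues = character(0)),
               class = "aq_schema_error")
  expect_error(study_design(cal_levels = c(1, 10)),
               class = "aq_schema_error")
  truth <- simulation_truth(cv = 0, seed = 1)
  expect_error(
    simulate_experiment(truth, study_design(tissues = "unseen_tissue")),
    class = "aq_schema_error")
})
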