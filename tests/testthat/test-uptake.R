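test_that("fraction_neutral follows Henderson-Hasselbalch", {
  expect_equal(fraction_neutral(6.16, 6.16, "acidic"), 0.5)
  expect_equal(fraction_neutral(7.55, 7.55, "basic"), 0.5)
  # sulfamethoxazole-like acid (pKa 6.16) at pH 5
  expect_equal(fraction_neutral(5, 6.16, "acidic"),
               1 / (1 + 10^(5 - 6.16)))
  expect_equal(round(fraction_neutral(5, 6.16, "acidic"), 3), 0.935)
  # clindamycin-like base (pKa 7.55) at pH 8
  expect_equal(round(fraction_neutral(8, 7.55, "basic"), 3), 0.738)
  # monotonicity across a pH grid, and complement = ionized fraction
  grid <- seq(1, 13, by = 0.25)
  fa <- fraction_neutral(grid, 6.16, "acidic")
  fb <- fraction_neutral(grid, 7.55, "basic")
  expect_true(all(diff(fa) < 0))
  expect_true(all(diff(fb) > 0))
  expect_true(all(fa > 0 & fa < 1))
  expect_equal(fa + (1 - fa), rep(1, length(grid)))
  expect_error(fraction_neutral(15, 7, "acidic"), class = "aq_schema_error")
})

make_uptake_fixture <- function(leaf_conc, root_conc, met_conc = NULL,
                                loq = 1) {
  n <- 2L
  samples <- rbind(
    sample_row(sprintf("L%d", 1:n), "unknown", tissue = "spinach_leaf",
               ph = 6.5, day = 21L, idx = 0:1),
    sample_row(sprintf("R%d", 1:n), "unknown", tissue = "spinach_root",
               ph = 6.5, day = 21L, idx = 2:3)
  )
  mk <- function(cmp, leaf, root) {
    data.frame(sample_id = samples$sample_id, compound = cmp,
               conc_extract_ng_per_mL = NA,
               conc_tissue_ng_per_g_dw = c(rep(leaf, n), rep(root, n)),
               loq_ng_per_g_dw = loq, lod_ng_per_g_dw = loq / 3,
               censored = c(rep(leaf, n), rep(root, n)) < loq,
               quantifier = "ARF", me_percent = NA, report = "",
               stringsAsFactors = FALSE)
  }
  res <- mk("cbz", leaf_conc, root_conc)
  if (!is.null(met_conc)) res <- rbind(res, mk("cbz_m", met_conc[1], met_conc[2]))
  list(results = res, samples = sample_table(samples))
}

test_that("partition_summary computes leaf fractions from uncensored values", {
  fx <- make_uptake_fixture(100, 100)
  out <- partition_summary(fx$results, fx$samples)
  expect_equal(out$leaf_fraction[out$compound == "cbz"], 0.5)

  fx <- make_uptake_fixture(900, 100)
  out <- partition_summary(fx$results, fx$samples)
  expect_equal(out$leaf_fraction[out$compound == "cbz"], 0.9)

  # censored leaf side: missing fraction with a reason code
  fx <- make_uptake_fixture(0, 400)
  out <- partition_summary(fx$results, fx$samples)
  expect_true(is.na(out$leaf_fraction[out$compound == "cbz"]))
  expect_equal(out$reason[out$compound == "cbz"], "leaf<LOQ")
})

test_that("metabolite_parent_ratio uses registered pairs and censoring rules", {
  reg <- tiny_registry()
  fx <- make_uptake_fixture(100, 100, met_conc = c(50, 20))
  out <- metabolite_parent_ratio(fx$results, fx$samples, reg, "cbz_m", "cbz")
  expect_equal(out$ratio[out$tissue == "spinach_leaf"], 0.5)
  expect_equal(out$ratio[out$tissue == "spinach_root"], 0.2)

  # censored parent yields a missing ratio with reason
  fx <- make_uptake_fixture(0.5, 100, met_conc = c(50, 20))
  out <- metabolite_parent_ratio(fx$results, fx$samples, reg, "cbz_m", "cbz")
  expect_true(is.na(out$ratio[out$tissue == "spinach_leaf"]))
  expect_equal(out$reason[out$tissue == "spinach_leaf"], "parent<LOQ")

  expect_error(metabolite_parent_ratio(fx$results, fx$samples, reg,
                                       "cbz", "cbz_m"),
               class = "aq_referential_error")
})

test_that("summaries are permutation- and scale-invariant", {
  fx <- make_uptake_fixture(900, 100, met_conc = c(45, 5))
  base <- partition_summary(fx$results, fx$samples)
  perm <- fx$results[sample(nrow(fx$results)), ]
  expect_equal(partition_summary(perm, fx$samples)$leaf_fraction,
               base$leaf_fraction)
  scaled <- fx$results
  scaled$conc_tissue_ng_per_g_dw <- scaled$conc_tissue_ng_per_g_dw * 3.7
  scaled$loq_ng_per_g_dw <- scaled$loq_ng_per_g_dw * 3.7
  expect_equal(partition_summary(scaled, fx$samples)$leaf_fraction,
               base$leaf_fraction)
  reg <- tiny_registry()
  expect_equal(
    metabolite_parent_ratio(scaled, fx$samples, reg, "cbz_m", "cbz")$ratio,
    metabolite_parent_ratio(fx$results, fx$samples, reg, "cbz_m", "cbz")$ratio)
})

test_that("a low transformation rate yields metabolite/parent ratio << 1", {
  # arugula-like simulated world: parent taken up, little metabolite formed
  unknowns <- rbind(
    data.frame(tissue = "arugula_leaf", ph_treatment = 6.5, harvest_day = 21L,
               n = 3L, compound = "carbamazepine", conc_ng_per_g_dw = 2000),
    data.frame(tissue = "arugula_leaf", ph_treatment = 6.5, harvest_day = 21L,
               n = 3L, compound = "epoxide_cbz", conc_ng_per_g_dw = 100)
  )
  truth <- simulation_truth(cv = 0.05, seed = 31)
  tab <- simulate_experiment(truth, study_design(tissues = "arugula_leaf",
                                                 unknowns = unknowns))
  res <- quantify_samples(tab)
  out <- metabolite_parent_ratio(res, tab$samples, tab$registry,
                                 "epoxide_cbz", "carbamazepine")
  expect_lt(out$ratio[out$tissue == "arugula_leaf"], 0.2)
  expect_equal(out$ratio[out$tissue == "arugula_leaf"], 0.05,
               tolerance = 0.15)
  sumtab <- uptake_summary(res, tab$samples, tab$registry)
  row <- sumtab[sumtab$compound == "epoxide_cbz" & sumtab$tissue == "leaf", ]
  expect_equal(row$metabolite_parent_ratio,
               out$ratio[out$tissue == "arugula_leaf"])
})
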