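test_that("matrix_effect sign convention and the strict 20% rule", {
  expect_equal(matrix_effect(1, 1), 0)
  expect_equal(matrix_effect(0.8, 1.0), -20)
  expect_equal(matrix_effect(1.5, 1.0), 50)
  expect_error(matrix_effect(1, 0), class = "aq_schema_error")

  expect_equal(select_quantifier(50), "RF_MST")
  expect_equal(select_quantifier(-20.0), "ARF")   # boundary: NOT exceeding
  expect_equal(select_quantifier(-35), "RF_MST")
  # antisymmetry-style property: ME(arf, arf) = 0 for any arf > 0
  for (arf in c(0.01, 0.5, 1, 7, 123)) {
    expect_identical(matrix_effect(arf, arf), 0)
  }
})

test_that("quantify_extract inverts compute_rf", {
  expect_equal(quantify_extract(3000, 1000, 1.5, 5), 10)
  expect_equal(quantify_extract(0, 1000, 1.5, 5), 0)
  expect_error(quantify_extract(10, 0, 1, 5), class = "aq_invalid_injection")
  # round trip through the pair of formulas
  set.seed(2)
  for (i in 1:20) {
    conc <- 10^runif(1, -1, 3)
    rf <- runif(1, 0.1, 3)
    area_is <- runif(1, 1e4, 1e6)
    area_ns <- rf * (conc / 5) * area_is
    expect_equal(quantify_extract(area_ns, area_is, rf, 5), conc)
  }
})

test_that("extract_to_tissue applies the volume/mass conversion", {
  expect_equal(extract_to_tissue(1000, 1, 0.05), 20000)
  expect_equal(extract_to_tissue(2.5, 1, 0.05), 50)
  expect_equal(extract_to_tissue(0, 1, 0.05), 0)
  expect_error(extract_to_tissue(1, 0, 0.05), class = "aq_schema_error")
  # round trip back to the extract scale
  set.seed(3)
  for (i in 1:20) {
    conc <- 10^runif(1, -2, 4)
    v <- runif(1, 0.5, 2)
    m <- runif(1, 0.01, 0.2)
    expect_equal(extract_to_tissue(conc, v, m) * m / v, conc)
  }
})

test_that("sample_loq responds to the sample's own IS area and quantifier", {
  low <- list(conc = 0.5, area_ns = 200)
  # neutral case: reduces to (lowest level / divisor) * volume / mass
  # (calibration IS area 1000 yields ARF consistent with area 200 at 0.5)
  arf <- compute_rf(200, 1000, 0.5, 5)
  loq <- sample_loq(low, area_is_sample = 1000, quantifier_value = arf,
                    conc_is = 5, extract_volume = 1, dry_mass = 0.05,
                    divisor = 2)
  expect_equal(loq, (0.5 / 2) * 1 / 0.05)  # 5 ng/g dw
  # halving the sample's IS area doubles the LOQ
  loq_half <- sample_loq(low, 500, arf, 5, 1, 0.05, 2)
  expect_equal(loq_half, 2 * loq)
  # homogeneity: degree -1 in IS area, degree +1 in extract volume
  set.seed(5)
  for (i in 1:10) {
    k <- runif(1, 0.2, 5)
    expect_equal(sample_loq(low, k * 1000, arf, 5, 1, 0.05, 2), loq / k)
    expect_equal(sample_loq(low, 1000, arf, 5, k * 1, 0.05, 2), loq * k)
  }
  # stronger suppression (smaller quantifier RF) raises the LOQ
  expect_gt(sample_loq(low, 1000, 0.7 * arf, 5, 1, 0.05, 2), loq)
  expect_error(sample_loq(list(area_ns = NA), 1000, arf, 5, 1, 0.05, 2),
               class = "aq_invalid_calibration")
})

test_that("lod_from_loq divides by the configured divisor", {
  expect_equal(signif(lod_from_loq(2.4), 2), 0.80)
  expect_equal(signif(lod_from_loq(27), 2), 9.0)
  expect_equal(lod_from_loq(0), 0)
})

test_that("censoring is strict and keeps the numeric value", {
  df <- data.frame(conc_tissue_ng_per_g_dw = c(3, 5, 50),
                   loq_ng_per_g_dw = c(5, 5, 5))
  out <- censor(df)
  expect_equal(out$censored, c(TRUE, FALSE, FALSE))
  expect_equal(out$report[1], "<LOQ")
  expect_equal(out$conc_tissue_ng_per_g_dw[1], 3)
})

test_that("matrix standards quantified with their own RF_MST return nominal", {
  tab <- tiny_tables(s = 0.6)  # strong suppression: RF_MST is the quantifier
  res <- quantify_samples(tab)
  mst <- res[res$sample_id == "MST1" & res$compound == "cbz", ]
  expect_equal(mst$quantifier, "RF_MST")
  expect_equal(mst$conc_extract_ng_per_mL, 100)
  expect_equal(mst$me_percent, -40)
})

test_that("suppression factor s yields me_percent = (s-1)*100 exactly", {
  for (s in c(0.7, 0.85, 1.25)) {
    tab <- tiny_tables(s = s)
    me <- matrix_effects(tab, calibrate(tab))
    expect_equal(unique(me$me_percent[me$tissue == "pea_leaf"]),
                 (s - 1) * 100)
  }
})

test_that("zero-IS injections are invalid rather than imputed", {
  tab <- tiny_tables()
  tab$injections$area_is[tab$injections$sample_id == "QC1" &
                           tab$injections$compound == "cbz"] <- 0
  res <- quantify_samples(tab)
  bad <- res[res$sample_id == "QC1" & res$compound == "cbz", ]
  expect_true(is.na(bad$conc_extract_ng_per_mL))
  expect_equal(bad$report, "invalid")
  ok <- res[res$sample_id == "QC1" & res$compound == "cbz_m", ]
  expect_false(is.na(ok$conc_extract_ng_per_mL))
})
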