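# Quantification: matrix effects, quantifier selection, concentrations,
# per-sample LOQ/LOD and censoring.

#' Matrix effect
#'
#' `ME = (rf_mst - arf) / arf * 100`, the signed percent difference between
#' the response factor measured in a matrix-matched standard and the average
#' response factor from solvent calibration. Negative values are ion
#' suppression, positive values enhancement.
#'
#' @param rf_mst response factor of the matrix-matched standard (>= 0)
#' @param arf average response factor (> 0)
#' @return signed percent
#' @export
matrix_effect <- function(rf_mst, arf) {
  check_nonneg(rf_mst, "rf_mst")
  check_positive(arf, "arf")
  (rf_mst - arf) / arf * 100
}

#' Quantifier selection under the 20% rule
#'
#' The matrix-matched standard's RF replaces the ARF when the absolute
#' matrix effect strictly exceeds the threshold.
#'
#' @param me_percent signed matrix effect in percent
#' @param threshold percent (default 20)
#' @return character vector, `"RF_MST"` or `"ARF"`
#' @export
select_quantifier <- function(me_percent, threshold = 20) {
  check_positive(threshold, "threshold")
  ifelse(abs(me_percent) > threshold, "RF_MST", "ARF")
}

#' Extract concentration from peak areas
#'
#' Inversion of the response-factor definition:
#' `C_NS = (area_ns / area_is) * conc_is / rf`.
#'
#' @param area_ns native-analyte peak area (>= 0)
#' @param area_is internal-standard peak area (> 0)
#' @param rf quantifier response factor (ARF or RF_MST, > 0)
#' @param conc_is internal-standard concentration in the extract (ng/mL)
#' @return concentration in ng/mL
#' @export
quantify_extract <- function(area_ns, area_is, rf, conc_is) {
  check_nonneg(area_ns, "area_ns")
  if (any(!is.finite(area_is) | area_is <= 0)) {
    aq_invalid_injection("quantify_extract: area_is must be > 0 (invalid injection)")
  }
  check_positive(rf, "rf")
  check_positive(conc_is, "conc_is")
  (area_ns / area_is) * conc_is / rf
}

#' Extract concentration to dry-tissue concentration
#'
#' `conc_tissue = conc_extract * extract_volume / dry_mass`; with the
#' standard 50 mg / 1 mL preparation a 1000 ng/mL extract corresponds to
#' 20,000 ng/g dry weight.
#'
#' @param conc_extract ng/mL
#' @param extract_volume mL (> 0)
#' @param dry_mass g (> 0)
#' @return ng/g dry weight
#' @export
extract_to_tissue <- function(conc_extract, extract_volume, dry_mass) {
  check_nonneg(conc_extract, "conc_extract")
  check_positive(extract_volume, "extract_volume")
  check_positive(dry_mass, "dry_mass")
  conc_extract * extract_volume / dry_mass
}

#' Per-sample limit of quantification
#'
#' The NS peak area of the lowest retained calibration point, divided by
#' `divisor`, is substituted into the quantification chain in place of the
#' sample's NS area — but with the sample's own IS area, quantifier and
#' preparation constants. The LOQ therefore responds to the sample itself:
#' lower IS recovery (smaller IS area) raises it, as does stronger matrix
#' suppression (smaller quantifier RF).
#'
#' @param lowest_cal list with `conc` and `area_ns` of the lowest retained
#'   calibration level
#' @param area_is_sample the sample's internal-standard peak area (> 0)
#' @param quantifier_value the RF used for this sample (ARF or RF_MST)
#' @param conc_is IS concentration in this sample's extract (ng/mL)
#' @param extract_volume,dry_mass this sample's preparation constants
#' @param divisor peak-area divisor (default 2)
#' @return LOQ in ng/g dry weight
#' @export
sample_loq <- function(lowest_cal, area_is_sample, quantifier_value, conc_is,
                       extract_volume, dry_mass, divisor = 2) {
  if (is.null(lowest_cal$area_ns) || !is.finite(lowest_cal$area_ns)) {
    aq_invalid_calibration("sample_loq: no retained calibration level")
  }
  check_positive(divisor, "divisor")
  loq_extract <- quantify_extract(lowest_cal$area_ns / divisor,
                                  area_is_sample, quantifier_value, conc_is)
  extract_to_tissue(loq_extract, extract_volume, dry_mass)
}

#' Limit of detection from limit of quantification
#'
#' @param loq ng/g dry weight (>= 0)
#' @param lod_divisor LOQ/LOD ratio (default 3)
#' @return ng/g dry weight
#' @export
lod_from_loq <- function(loq, lod_divisor = 3) {
  check_nonneg(loq, "loq")
  check_positive(lod_divisor, "lod_divisor")
  loq / lod_divisor
}

#' Censor quantification results against their LOQ
#'
#' Marks rows with `conc_tissue < loq` (strict) as censored and sets the
#' textual `report` column to `"<LOQ"`; the numeric value is retained.
#' LOQ and LOD are reported at 2 significant figures in `report`-facing
#' summaries; full precision is kept in the numeric columns.
#'
#' @param results results data.frame (columns `conc_tissue_ng_per_g_dw`,
#'   `loq_ng_per_g_dw`)
#' @return results with updated `censored` and `report` columns
#' @export
censor <- function(results) {
  results$censored <- results$conc_tissue_ng_per_g_dw < results$loq_ng_per_g_dw
  results$report <- ifelse(results$censored, "<LOQ",
                           sprintf("%.6g", results$conc_tissue_ng_per_g_dw))
  results
}

#' Matrix-effect table from matrix-matched standards
#'
#' One row per compound x tissue with a matrix standard: RF_MST, signed
#' matrix effect against the compound's ARF, and whether the matrix standard
#' is used as quantifier (`|ME| > me_threshold`, strict).
#'
#' @param tables `aq_tables`
#' @param models `calibration_set` from [calibrate()]
#' @param config `aq_run_config`
#' @return data.frame of class `aq_matrix_effects`
#' @export
matrix_effects <- function(tables, models, config = run_config()) {
  samples <- tables$samples
  mst <- samples[samples$role == "matrix_standard", , drop = FALSE]
  inj <- tables$injections
  rows <- inj[inj$sample_id %in% mst$sample_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    out <- data.frame(compound = character(), tissue = character(),
                      rf_mst = numeric(), me_percent = numeric(),
                      use_matrix_standard = logical())
    class(out) <- c("aq_matrix_effects", "data.frame")
    return(out)
  }
  m <- match(rows$sample_id, mst$sample_id)
  if (any(rows$area_is <= 0)) {
    aq_invalid_injection("matrix standard injection with zero IS area")
  }
  conc_is <- mst$is_amount_ng[m] / mst$extract_volume_mL[m]
  rf_mst <- compute_rf(rows$area_ns, rows$area_is,
                       mst$nominal_conc_ng_per_mL[m], conc_is)
  arf <- vapply(rows$compound, function(cmp) models[[cmp]]$arf, numeric(1))
  me <- matrix_effect(rf_mst, arf)
  out <- data.frame(compound = rows$compound, tissue = mst$tissue[m],
                    rf_mst = rf_mst, me_percent = me,
                    use_matrix_standard = abs(me) > config$me_threshold,
                    row.names = NULL)
  # replicate matrix standards per tissue would be ambiguous; keep one each
  key <- paste(out$compound, out$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    aq_uniqueness_error("multiple matrix standards for the same compound and tissue")
  }
  class(out) <- c("aq_matrix_effects", "data.frame")
  out
}

#' Quantify all non-calibration samples
#'
#' End-to-end quantification: fits (or reuses) the calibration, evaluates
#' matrix effects, selects the quantifier per compound x tissue, computes
#' extract and dry-tissue concentrations, the per-sample LOQ/LOD, and
#' censoring. Injections with zero IS area yield `NA` concentrations and are
#' flagged `"invalid"` in the `report` column.
#'
#' @param tables `aq_tables`
#' @param config `aq_run_config`
#' @param models optional pre-fitted `calibration_set`
#' @param me optional pre-computed `aq_matrix_effects`
#' @return data.frame of class `aq_results` (the `results.csv` contract)
#' @export
quantify_samples <- function(tables, config = run_config(), models = NULL,
                             me = NULL) {
  models <- models %||% calibrate(tables, config)
  me <- me %||% matrix_effects(tables, models, config)
  samples <- tables$samples
  targets <- samples[samples$role != "calibration", , drop = FALSE]
  inj <- tables$injections
  rows <- inj[inj$sample_id %in% targets$sample_id, , drop = FALSE]
  if (nrow(rows) == 0) aq_schema_error("quantify_samples: nothing to quantify")
  m <- match(rows$sample_id, targets$sample_id)
  tissue <- targets$tissue[m]
  conc_is <- targets$is_amount_ng[m] / targets$extract_volume_mL[m]
  vol <- targets$extract_volume_mL[m]
  mass <- targets$dry_mass_g[m]

  me_key <- paste(me$compound, me$tissue, sep = "\r")
  row_key <- paste(rows$compound, tissue, sep = "\r")
  me_idx <- match(row_key, me_key)
  me_percent <- ifelse(is.na(me_idx), NA_real_, me$me_percent[me_idx])
  use_mst <- !is.na(me_idx) & me$use_matrix_standard[me_idx]
  arf <- vapply(rows$compound, function(cmp) models[[cmp]]$arf, numeric(1))
  quant_value <- ifelse(use_mst, me$rf_mst[me_idx], arf)
  quantifier <- ifelse(use_mst, "RF_MST", "ARF")

  valid <- rows$area_is > 0
  conc_extract <- rep(NA_real_, nrow(rows))
  loq <- rep(NA_real_, nrow(rows))
  if (any(valid)) {
    conc_extract[valid] <- quantify_extract(rows$area_ns[valid],
                                            rows$area_is[valid],
                                            quant_value[valid],
                                            conc_is[valid])
    low_conc <- vapply(rows$compound, function(cmp) models[[cmp]]$lowest_level,
                       numeric(1))
    low_area <- vapply(rows$compound, function(cmp) models[[cmp]]$area_ns_lowest,
                       numeric(1))
    loq_extract <- quantify_extract(low_area[valid] / config$loq_area_divisor,
                                    rows$area_is[valid], quant_value[valid],
                                    conc_is[valid])
    loq[valid] <- extract_to_tissue(loq_extract, vol[valid], mass[valid])
  }
  conc_tissue <- conc_extract * vol / mass
  res <- data.frame(
    sample_id = rows$sample_id,
    compound = rows$compound,
    conc_extract_ng_per_mL = conc_extract,
    conc_tissue_ng_per_g_dw = conc_tissue,
    loq_ng_per_g_dw = loq,
    lod_ng_per_g_dw = lod_from_loq(ifelse(is.na(loq), 0, loq),
                                   config$lod_divisor),
    censored = FALSE,
    quantifier = quantifier,
    me_percent = me_percent,
    report = NA_character_,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  res$lod_ng_per_g_dw[is.na(loq)] <- NA_real_
  res[valid, ] <- censor(res[valid, , drop = FALSE])
  res$censored[!valid] <- NA
  res$report[!valid] <- "invalid"
  class(res) <- c("aq_results", "data.frame")
  res
}
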