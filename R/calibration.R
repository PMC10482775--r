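# Response-factor calibration from solvent standards.
#
# A compound's response factor (RF) at a calibration level is the
# IS-normalized response per unit concentration ratio,
#   RF = (A_NS / A_IS) / (C_NS / C_IS),
# with C_IS taken as is_amount / extract_volume. The average response factor
# (ARF) over retained levels is the default quantifier; linearity (r^2 of the
# area ratio against concentration) is reported as a separate check, not used
# for quantification.

#' Response factor
#'
#' `RF = (area_ns / area_is) / (conc_ns / conc_is)`; dimensionless, equal to
#' 1 when the area ratio matches the concentration ratio.
#'
#' @param area_ns,area_is peak areas (detector counts); `area_is` must be > 0
#' @param conc_ns,conc_is concentrations (ng/mL); both must be > 0
#' @return dimensionless response factor(s)
#' @export
compute_rf <- function(area_ns, area_is, conc_ns, conc_is) {
  check_nonneg(area_ns, "area_ns")
  if (any(!is.finite(area_is) | area_is <= 0)) {
    aq_invalid_injection("compute_rf: area_is must be > 0 (invalid injection)")
  }
  check_positive(conc_ns, "conc_ns")
  check_positive(conc_is, "conc_is")
  (area_ns / area_is) / (conc_ns / conc_is)
}

#' Trim calibration levels against the average response factor
#'
#' Deterministic fixed point of the published rule that only calibration
#' points deviating less than `rsd_threshold` percent from the ARF are used:
#' iteratively drop the single worst-deviating level (ties broken toward the
#' lower concentration, where failures are expected) and recompute the mean;
#' after convergence, any excluded level that deviates less than the
#' threshold from the final mean is re-admitted. The result is independent of
#' input order: every retained RF deviates `< threshold` from the mean of
#' retained RFs and every excluded RF deviates `>= threshold`.
#'
#' @param levels numeric vector of nominal concentrations (ng/mL)
#' @param rfs numeric vector of per-level response factors
#' @param rsd_threshold percent deviation at or above which a level is dropped
#' @param compound compound name, used in error messages
#' @return list with `retained` (logical), `arf` (mean RF over retained)
#' @export
trim_calibration <- function(levels, rfs, rsd_threshold = 30,
                             compound = "<compound>") {
  if (length(levels) != length(rfs)) {
    aq_schema_error("trim_calibration: levels and rfs differ in length")
  }
  if (length(rfs) < 3) {
    aq_invalid_calibration(sprintf(
      "invalid calibration for %s: fewer than 3 levels", compound))
  }
  retained <- rep(TRUE, length(rfs))
  deviation <- function(keep) {
    arf <- mean(rfs[keep])
    abs(rfs - arf) / arf * 100
  }
  for (iter in seq_len(2L * length(rfs) + 10L)) {
    dev <- deviation(retained)
    # re-admit any excluded level now inside the band (fixed-point property)
    back <- !retained & dev < rsd_threshold
    if (any(back)) {
      retained[back] <- TRUE
      next
    }
    worst <- retained & dev >= rsd_threshold
    if (!any(worst)) break
    if (sum(retained) <= 3) {
      aq_invalid_calibration(sprintf(
        "invalid calibration for %s: fewer than 3 levels survive trimming",
        compound))
    }
    # drop the single worst deviator; ties -> lower concentration level
    cand <- which(retained)[order(-dev[retained], levels[retained])][1]
    retained[cand] <- FALSE
  }
  arf <- mean(rfs[retained])
  if (!is.finite(arf) || arf <= 0) {
    aq_invalid_calibration(sprintf(
      "invalid calibration for %s: non-positive average response factor",
      compound))
  }
  list(retained = retained, arf = arf)
}

#' Linearity of the calibration curve
#'
#' Ordinary (unweighted) least squares of the NS/IS area ratio on
#' concentration over the retained levels; returns `r2` and the retained
#' concentration range. Used as a linearity check only — quantification goes
#' through the ARF.
#'
#' @param conc numeric vector of concentrations (ng/mL)
#' @param area_ratio numeric vector of NS/IS area ratios
#' @return list with `r2`, `linear_range = c(lo, hi)`, `slope`, `intercept`
#' @export
assess_linearity <- function(conc, area_ratio) {
  if (length(conc) != length(area_ratio)) {
    aq_schema_error("assess_linearity: input lengths differ")
  }
  if (length(conc) < 3) {
    aq_schema_error("assess_linearity: need at least 3 points")
  }
  if (length(unique(conc)) < 2) {
    aq_schema_error("assess_linearity: degenerate input (all concentrations equal)")
  }
  fit <- stats::lm(area_ratio ~ conc)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((area_ratio - mean(area_ratio))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(r2 = r2,
       linear_range = range(conc),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Fit per-compound calibration models
#'
#' For each registered compound, takes the solvent calibration standards
#' (optionally restricted to `sample_ids`, e.g. the first or last calibration
#' set of a sequence), computes the RF at each level (replicate standards at
#' the same level are averaged), trims levels via [trim_calibration()], and
#' assesses linearity of the retained levels. The mean NS area at the lowest
#' retained level is stored for the LOQ substitution.
#'
#' @param tables `aq_tables` from [load_tables()] / [make_tables()]
#' @param config `aq_run_config`
#' @param sample_ids optional character vector restricting which calibration
#'   samples are used
#' @return named list of `calibration_model` objects (class
#'   `calibration_set`); each model has fields `compound`, `levels`
#'   (data.frame level/rf/retained), `arf`, `r2`, `linear_range`,
#'   `lowest_level`, `area_ns_lowest`
#' @export
calibrate <- function(tables, config = run_config(), sample_ids = NULL) {
  samples <- tables$samples
  cal <- samples[samples$role == "calibration", , drop = FALSE]
  if (!is.null(sample_ids)) {
    cal <- cal[cal$sample_id %in% sample_ids, , drop = FALSE]
  }
  if (nrow(cal) == 0) {
    aq_invalid_calibration("no calibration samples available")
  }
  inj <- tables$injections
  models <- lapply(tables$registry$name, function(cmp) {
    ci <- inj[inj$compound == cmp & inj$sample_id %in% cal$sample_id, ,
              drop = FALSE]
    if (nrow(ci) < 3) {
      aq_invalid_calibration(sprintf(
        "invalid calibration for %s: fewer than 3 calibration injections", cmp))
    }
    m <- match(ci$sample_id, cal$sample_id)
    conc <- cal$nominal_conc_ng_per_mL[m]
    conc_is <- cal$is_amount_ng[m] / cal$extract_volume_mL[m]
    if (any(ci$area_is <= 0)) {
      aq_invalid_injection(sprintf(
        "calibration injection with zero IS area for %s (sample %s)",
        cmp, ci$sample_id[ci$area_is <= 0][1]))
    }
    rf <- compute_rf(ci$area_ns, ci$area_is, conc, conc_is)
    ratio <- ci$area_ns / ci$area_is
    # replicate standards at the same nominal level: average before trimming
    lev <- sort(unique(conc))
    rf_lev <- vapply(lev, function(l) mean(rf[conc == l]), numeric(1))
    ratio_lev <- vapply(lev, function(l) mean(ratio[conc == l]), numeric(1))
    ans_lev <- vapply(lev, function(l) mean(ci$area_ns[conc == l]), numeric(1))
    trim <- trim_calibration(lev, rf_lev, config$cal_rsd_threshold, cmp)
    lin <- assess_linearity(lev[trim$retained], ratio_lev[trim$retained])
    lowest <- min(lev[trim$retained])
    structure(list(
      compound = cmp,
      levels = data.frame(level = lev, rf = rf_lev, retained = trim$retained),
      arf = trim$arf,
      r2 = lin$r2,
      linear_range = lin$linear_range,
      lowest_level = lowest,
      area_ns_lowest = ans_lev[lev == lowest]
    ), class = "calibration_model")
  })
  names(models) <- tables$registry$name
  structure(models, class = "calibration_set")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration model for %s\n", x$compound))
  cat(sprintf("  ARF %.4g over %d/%d retained levels; r2 = %.4f; range %g-%g ng/mL\n",
              x$arf, sum(x$levels$retained), nrow(x$levels), x$r2,
              x$linear_range[1], x$linear_range[2]))
  invisible(x)
}

#' Export a calibration set as a flat table
#'
#' @param models `calibration_set` from [calibrate()]
#' @return data.frame with one row per compound x level (`compound, level,
#'   rf, retained, arf, r2, range_lo, range_hi`)
#' @export
calibration_table <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(compound = m$compound, level = m$levels$level,
               rf = m$levels$rf, retained = m$levels$retained,
               arf = m$arf, r2 = m$r2,
               range_lo = m$linear_range[1], range_hi = m$linear_range[2],
               row.names = NULL)
  }))
}
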