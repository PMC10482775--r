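# Method validation: recovery/trueness, precision, solvent-comparison
# summaries, and response-factor stability over an injection sequence.

#' Recovery
#'
#' `(measured - background) / nominal_spike * 100`. Background is the mean
#' concentration in unspiked control samples of the same tissue (0 when the
#' compound is absent from controls).
#'
#' @param measured measured concentration (ng/g dw)
#' @param background control-sample background (ng/g dw, >= 0)
#' @param nominal_spike spike level (ng/g dw, > 0)
#' @return percent
#' @export
recovery <- function(measured, background, nominal_spike) {
  check_nonneg(background, "background")
  check_positive(nominal_spike, "nominal_spike")
  (measured - background) / nominal_spike * 100
}

#' Relative standard deviation
#'
#' Sample (n-1) standard deviation over the mean, in percent.
#'
#' @param values numeric vector, length >= 2, non-zero mean
#' @return percent
#' @export
precision_rsd <- function(values) {
  if (length(values) < 2) aq_schema_error("precision_rsd: need n >= 2")
  m <- mean(values)
  if (m == 0) aq_schema_error("precision_rsd: undefined for zero mean")
  stats::sd(values) / m * 100
}

#' Per-solvent summary of a recovery grid
#'
#' For a complete compound x solvent grid of (recovery, RSD) pairs, returns
#' the arithmetic mean recovery and the mean of the per-compound RSDs for
#' each solvent, rounded half-up to integer percent for reporting (matching
#' the convention of printed method-comparison tables).
#'
#' @param grid data.frame with columns `compound, solvent, recovery, rsd`
#' @return data.frame with columns `solvent, mean_recovery, mean_rsd`
#' @export
solvent_summary <- function(grid) {
  check_columns(grid, c("compound", "solvent", "recovery", "rsd"),
                "solvent grid")
  compounds <- unique(grid$compound)
  solvents <- unique(grid$solvent)
  key <- paste(grid$compound, grid$solvent, sep = "\r")
  full <- expand.grid(compound = compounds, solvent = solvents,
                      stringsAsFactors = FALSE)
  missing <- !(paste(full$compound, full$solvent, sep = "\r") %in% key)
  if (any(missing)) {
    aq_schema_error(sprintf("solvent_summary: missing cell(s): %s",
      paste(sprintf("%s/%s", full$compound[missing], full$solvent[missing]),
            collapse = ", ")))
  }
  if (anyDuplicated(key)) {
    aq_uniqueness_error("solvent_summary: duplicate compound/solvent cell")
  }
  out <- do.call(rbind, lapply(solvents, function(s) {
    sub <- grid[grid$solvent == s, , drop = FALSE]
    data.frame(solvent = s,
               mean_recovery = round_half_up(mean(sub$recovery)),
               mean_rsd = round_half_up(mean(sub$rsd)),
               row.names = NULL)
  }))
  out
}

#' Recovery and precision of spiked QC samples
#'
#' Per compound x tissue x spike level over the spiked QC replicates:
#' mean recovery against the nominal spike (after subtracting the mean
#' background of uncensored control samples of the same tissue), RSD of the
#' replicate recoveries, and the 60--130% acceptance flag.
#'
#' @param results `aq_results` from [quantify_samples()]
#' @param samples `aq_samples`
#' @param config `aq_run_config`
#' @return data.frame with one row per compound x tissue x spike level
#' @export
recovery_table <- function(results, samples, config = run_config()) {
  qc <- samples[samples$role == "spiked_qc", , drop = FALSE]
  if (nrow(qc) == 0) aq_schema_error("recovery_table: no spiked_qc samples")
  ctl <- samples[samples$role == "control", , drop = FALSE]
  res <- merge(results, samples[, c("sample_id", "role", "tissue",
                                    "spike_level_ng_per_g_dw")],
               by = "sample_id")
  qc_res <- res[res$role == "spiked_qc", , drop = FALSE]
  ctl_res <- res[res$role == "control", , drop = FALSE]

  background_of <- function(cmp, tis) {
    b <- ctl_res[ctl_res$compound == cmp & ctl_res$tissue == tis &
                   !is.na(ctl_res$censored) & !ctl_res$censored, , drop = FALSE]
    if (nrow(b) == 0) 0 else mean(b$conc_tissue_ng_per_g_dw)
  }

  groups <- unique(qc_res[, c("compound", "tissue", "spike_level_ng_per_g_dw")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- qc_res[qc_res$compound == g$compound & qc_res$tissue == g$tissue &
                    qc_res$spike_level_ng_per_g_dw ==
                      g$spike_level_ng_per_g_dw, , drop = FALSE]
    bg <- background_of(g$compound, g$tissue)
    rec <- recovery(sub$conc_tissue_ng_per_g_dw, bg,
                    g$spike_level_ng_per_g_dw)
    mean_rec <- mean(rec)
    rsd <- if (length(rec) >= 2 && mean(rec) != 0) precision_rsd(rec) else NA_real_
    data.frame(compound = g$compound, tissue = g$tissue,
               spike_level = g$spike_level_ng_per_g_dw,
               n_replicates = length(rec),
               mean_recovery = mean_rec, rsd = rsd,
               within_acceptance = mean_rec >= config$recovery_accept_lo &
                 mean_rec <= config$recovery_accept_hi,
               row.names = NULL)
  }))
  out
}

#' Response-factor drift between two calibration sets
#'
#' Compares the first and last calibration of an injection sequence level by
#' level: for each level retained in both models, the ratio
#' `rf_last / rf_first` is computed and judged against a `band` percent
#' window around 1 (`|ratio - 1| <= band/100`). A compound with every shared
#' level inside the band is considered stable over the sequence.
#'
#' @param first_cal,last_cal `calibration_model` objects for the same compound
#' @param band percent band (default 30)
#' @return list with `compound`, `levels` (data.frame level/rf_first/rf_last/
#'   ratio/within_band), `fraction_within_band`, `flagged`
#' @export
rf_drift <- function(first_cal, last_cal, band = 30) {
  check_positive(band, "band")
  f <- first_cal$levels[first_cal$levels$retained, , drop = FALSE]
  l <- last_cal$levels[last_cal$levels$retained, , drop = FALSE]
  shared <- intersect(f$level, l$level)
  if (length(shared) == 0) {
    aq_invalid_calibration(sprintf(
      "rf_drift: no shared retained levels for %s", first_cal$compound))
  }
  ratio <- l$rf[match(shared, l$level)] / f$rf[match(shared, f$level)]
  within <- abs(ratio - 1) <= band / 100
  list(compound = first_cal$compound,
       levels = data.frame(level = shared,
                           rf_first = f$rf[match(shared, f$level)],
                           rf_last = l$rf[match(shared, l$level)],
                           ratio = ratio, within_band = within,
                           row.names = NULL),
       fraction_within_band = mean(within),
       flagged = any(!within))
}

#' Full method-validation report
#'
#' Assembles the recovery table, precision summaries per spike level, and
#' (when two calibration sets are identified) the per-compound drift
#' reports, as a JSON-serialisable list.
#'
#' @param results `aq_results`
#' @param samples `aq_samples`
#' @param config `aq_run_config`
#' @param drift optional list of [rf_drift()] reports
#' @return list with elements `recovery`, `precision`, `drift`
#' @export
validate_method <- function(results, samples, config = run_config(),
                            drift = NULL) {
  rec <- recovery_table(results, samples, config)
  prec <- do.call(rbind, lapply(split(rec, rec$spike_level), function(sub) {
    data.frame(spike_level = sub$spike_level[1],
               n_groups = nrow(sub),
               median_rsd = stats::median(sub$rsd, na.rm = TRUE),
               max_rsd = max(sub$rsd, na.rm = TRUE),
               row.names = NULL)
  }))
  drift_df <- NULL
  if (!is.null(drift)) {
    drift_df <- do.call(rbind, lapply(drift, function(d) {
      data.frame(compound = d$compound,
                 fraction_within_band = d$fraction_within_band,
                 flagged = d$flagged, row.names = NULL)
    }))
  }
  list(recovery = rec, precision = prec, drift = drift_df)
}
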