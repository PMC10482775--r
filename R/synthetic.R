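# Seeded synthetic instrument-data generator.
#
# Emulates the study design end to end — nine-point solvent calibration
# (0.1 to 1000 ng/mL), a matrix-matched standard at the top level per
# tissue, heptaplicate spiked QCs at 10/100/1000 ng/g dw, unspiked controls,
# optional unknown samples, 50 mg dry tissue in 1 mL extract with 5 ng IS —
# with known ground truth, so that every pipeline stage is testable by
# parameter recovery.
#
# Area model, per sample x compound (C_IS = is_amount / extract_volume):
#   area_is = area_is_base * is_recovery * drift(i) * noise
#   area_ns = rf_true * (C_extract_true / C_IS) * area_is_base
#             * s(tissue) * drift(i) * rf_drift(i) * noise
# Matrix suppression/enhancement s acts on the NS area only and IS recovery
# on the IS area only, so the matrix-effect and IS-recovery corrections can
# be exercised independently. Two drift knobs exist: `drift_per10` is a
# shared instrument-sensitivity ramp that cancels in every response factor
# (which is why isotope-dilution quantification is robust to it), while
# `rf_drift_per10` acts on the NS area only and produces the response-factor
# drift that a first-versus-last calibration comparison measures. Noise is
# multiplicative lognormal with mean 1 and the stated CV.

#' Default compound registry for simulations
#'
#' Three parent pharmaceuticals with contrasting ionization (carbamazepine,
#' neutral over the environmental pH range; sulfamethoxazole, strongest
#' acidic pKa 6.16; clindamycin, strongest basic pKa 7.55) and one primary
#' metabolite each, sharing the parent's labeled internal standard.
#'
#' @return `aq_compounds`
#' @export
default_registry <- function() {
  compound_registry(data.frame(
    name = c("carbamazepine", "epoxide_cbz", "sulfamethoxazole",
             "n4_acetyl_sul", "clindamycin", "clindamycin_sulfoxide"),
    is_name = c("carbamazepine_d10", "carbamazepine_d10",
                "sulfamethoxazole_d4", "sulfamethoxazole_d4",
                "clindamycin_d3", "clindamycin_d3"),
    role = c("parent", "metabolite", "parent", "metabolite", "parent",
             "metabolite"),
    parent_name = c("", "carbamazepine", "", "sulfamethoxazole", "",
                    "clindamycin"),
    pka = c(NA, NA, 6.16, NA, 7.55, NA),
    pka_kind = c("", "", "acidic", "", "basic", ""),
    stringsAsFactors = FALSE
  ))
}

#' Simulation ground truth
#'
#' Defaults state the simulated world: compound response factors spread over
#' an order of magnitude (metabolites at the low end, mirroring their weak
#' electrospray response), per-tissue matrix factors with stronger effects
#' in leaves than roots (suppression below 1, enhancement above), complete
#' extraction recovery, full IS recovery, 5% multiplicative noise (the
#' method's typical replicate RSD scale), and no sequence drift.
#'
#' @param registry `aq_compounds`
#' @param rf named numeric, true response factor per compound
#' @param matrix_factor named numeric, multiplicative NS-area factor per
#'   tissue (1 = no matrix effect); solvent is always 1
#' @param extraction_recovery scalar or named-per-compound recovery in (0, 1]
#'   applied to extracted samples
#' @param is_recovery scalar IS recovery in (0, 1] for extracted samples
#'   (calibration and matrix standards receive IS directly, recovery 1)
#' @param cv coefficient of variation of the lognormal area noise (0 = none)
#' @param drift_per10 shared sensitivity drift per 10 injections
#' @param rf_drift_per10 NS-only response drift per 10 injections
#' @param area_is_base base IS peak area (detector counts)
#' @param seed integer RNG seed (< 2^31)
#' @return list of class `aq_truth`
#' @export
simulation_truth <- function(registry = default_registry(),
                             rf = NULL, matrix_factor = NULL,
                             extraction_recovery = 1, is_recovery = 1,
                             cv = 0.05, drift_per10 = 0, rf_drift_per10 = 0,
                             area_is_base = 1e6, seed = 1L) {
  if (is.null(rf)) {
    base_rf <- c(1.2, 0.8, 0.9, 0.3, 1.0, 0.6)
    rf <- stats::setNames(rep_len(base_rf, nrow(registry)), registry$name)
  }
  if (is.null(names(rf)) || !all(registry$name %in% names(rf))) {
    aq_schema_error("truth: rf must be named for every registered compound")
  }
  if (is.null(matrix_factor)) {
    matrix_factor <- c(spinach_leaf = 0.70, spinach_root = 0.90,
                       arugula_leaf = 1.25, arugula_root = 1.10,
                       pea_leaf = 0.85)
  }
  check_positive(rf, "rf")
  check_positive(matrix_factor, "matrix_factor")
  if (any(extraction_recovery <= 0 | extraction_recovery > 1.5)) {
    aq_schema_error("truth: extraction_recovery must be in (0, 1.5]")
  }
  if (any(is_recovery <= 0 | is_recovery > 1)) {
    aq_schema_error("truth: is_recovery must be in (0, 1]")
  }
  check_nonneg(cv, "cv")
  structure(list(registry = registry, rf = rf, matrix_factor = matrix_factor,
                 extraction_recovery = extraction_recovery,
                 is_recovery = is_recovery, cv = cv,
                 drift_per10 = drift_per10, rf_drift_per10 = rf_drift_per10,
                 area_is_base = area_is_base, seed = as.integer(seed)),
            class = "aq_truth")
}

#' Study design for the simulator
#'
#' Defaults are the emulated study's stated constants: nine calibration
#' levels 0.1--1000 ng/mL, a matrix standard at the top level per tissue,
#' heptaplicate spiked QCs at 10/100/1000 ng/g dw, triplicate unspiked
#' controls, 50 mg dry tissue extracted into 1 mL with 5 ng IS.
#'
#' @param tissues character vector of matrix tissues (`"<plant>_<organ>"`)
#' @param cal_levels calibration concentrations (ng/mL)
#' @param spike_levels QC spike levels (ng/g dw)
#' @param n_spike_reps replicates per spike level (7 = heptaplicate)
#' @param n_controls unspiked control samples per tissue
#' @param unknowns optional data.frame defining unknown-sample groups in
#'   long format: `tissue, ph_treatment, harvest_day, n, compound,
#'   conc_ng_per_g_dw` (true tissue concentration; unlisted compounds are 0)
#' @param second_calibration append a replicate calibration set at the end
#'   of the sequence (for drift assessment)
#' @param second_cal_start acquisition index of the first level of the
#'   second calibration set (default places a nine-level set at 161--169,
#'   closing a 170-injection sequence)
#' @param dry_mass_g,extract_volume_mL,is_amount_ng preparation constants
#' @return list of class `aq_design`
#' @export
study_design <- function(tissues = c("spinach_leaf", "spinach_root",
                                     "arugula_leaf", "arugula_root"),
                         cal_levels = c(0.1, 0.5, 1, 5, 10, 50, 100, 500, 1000),
                         spike_levels = c(10, 100, 1000),
                         n_spike_reps = 7, n_controls = 3, unknowns = NULL,
                         second_calibration = FALSE, second_cal_start = 161L,
                         dry_mass_g = 0.05, extract_volume_mL = 1,
                         is_amount_ng = 5) {
  if (length(cal_levels) < 3) aq_schema_error("design: need >= 3 calibration levels")
  check_positive(cal_levels, "cal_levels")
  check_positive(dry_mass_g, "dry_mass_g")
  check_positive(extract_volume_mL, "extract_volume_mL")
  check_positive(is_amount_ng, "is_amount_ng")
  if (length(spike_levels) && (n_controls < 1 || !length(tissues))) {
    aq_schema_error("design: spiked QCs require control tissue samples")
  }
  structure(list(tissues = tissues, cal_levels = sort(cal_levels),
                 spike_levels = spike_levels, n_spike_reps = n_spike_reps,
                 n_controls = n_controls, unknowns = unknowns,
                 second_calibration = second_calibration,
                 second_cal_start = as.integer(second_cal_start),
                 dry_mass_g = dry_mass_g,
                 extract_volume_mL = extract_volume_mL,
                 is_amount_ng = is_amount_ng),
            class = "aq_design")
}

# sample sheet rows, one role at a time
design_samples <- function(design) {
  n_cal <- length(design$cal_levels)
  rows <- list()
  add <- function(id, role, tissue, nominal = NA, spike = NA, ph = NA,
                  day = NA) {
    data.frame(sample_id = id, role = role, tissue = tissue,
               nominal_conc_ng_per_mL = nominal,
               spike_level_ng_per_g_dw = spike,
               dry_mass_g = design$dry_mass_g,
               extract_volume_mL = design$extract_volume_mL,
               is_amount_ng = design$is_amount_ng,
               ph_treatment = ph, harvest_day = day,
               acquisition_index = NA_integer_, stringsAsFactors = FALSE)
  }
  rows$cal1 <- add(sprintf("CAL1_%02d", seq_len(n_cal)), "calibration",
                   "solvent", nominal = design$cal_levels)
  top <- max(design$cal_levels)
  for (t in design$tissues) {
    rows[[paste0("mst_", t)]] <- add(paste0("MST_", t), "matrix_standard", t,
                                     nominal = top)
  }
  for (t in design$tissues) {
    for (lv in design$spike_levels) {
      rows[[paste0("qc_", t, lv)]] <- add(
        sprintf("QC_%s_L%g_R%d", t, lv, seq_len(design$n_spike_reps)),
        "spiked_qc", t, spike = lv)
    }
    if (design$n_controls > 0) {
      rows[[paste0("ctl_", t)]] <- add(
        sprintf("CTL_%s_R%d", t, seq_len(design$n_controls)), "control", t)
    }
  }
  if (!is.null(design$unknowns)) {
    u <- unique(design$unknowns[, c("tissue", "ph_treatment", "harvest_day",
                                    "n")])
    for (i in seq_len(nrow(u))) {
      rows[[paste0("unk_", i)]] <- add(
        sprintf("UNK_%s_pH%g_d%d_R%d", u$tissue[i], u$ph_treatment[i],
                u$harvest_day[i], seq_len(u$n[i])),
        "unknown", u$tissue[i], ph = u$ph_treatment[i], day = u$harvest_day[i])
    }
  }
  df <- do.call(rbind, rows)
  df$acquisition_index <- seq_len(nrow(df)) - 1L
  if (design$second_calibration) {
    cal2 <- add(sprintf("CAL2_%02d", seq_len(n_cal)), "calibration",
                "solvent", nominal = design$cal_levels)
    start <- max(design$second_cal_start, nrow(df))
    cal2$acquisition_index <- start + seq_len(n_cal) - 1L
    df <- rbind(df, cal2)
  }
  rownames(df) <- NULL
  df
}

# true analyte concentration in the final extract, before matrix effects
true_extract_conc <- function(samples, compound, truth, design) {
  r <- if (length(truth$extraction_recovery) > 1) {
    truth$extraction_recovery[[compound]]
  } else {
    truth$extraction_recovery
  }
  m_over_v <- samples$dry_mass_g / samples$extract_volume_mL
  conc <- numeric(nrow(samples))
  is_std <- samples$role %in% c("calibration", "matrix_standard")
  conc[is_std] <- samples$nominal_conc_ng_per_mL[is_std]
  qc <- samples$role == "spiked_qc"
  conc[qc] <- samples$spike_level_ng_per_g_dw[qc] * m_over_v[qc] * r
  if (!is.null(design$unknowns)) {
    u <- design$unknowns[design$unknowns$compound == compound, , drop = FALSE]
    for (i in seq_len(nrow(u))) {
      sel <- samples$role == "unknown" & samples$tissue == u$tissue[i] &
        identical_or_both_na(samples$ph_treatment, u$ph_treatment[i]) &
        identical_or_both_na(samples$harvest_day, u$harvest_day[i])
      conc[sel] <- u$conc_ng_per_g_dw[i] * m_over_v[sel] * r
    }
  }
  conc
}

#' Simulate a complete injection sequence
#'
#' Generates samples, injections and a ground-truth record under the area
#' model documented above. With `cv = 0` and no drift the generation is
#' deterministic and the pipeline recovers every true parameter exactly;
#' the same seed always yields byte-identical output files.
#'
#' @param truth `aq_truth` from [simulation_truth()]
#' @param design `aq_design` from [study_design()]
#' @param out_dir optional directory; when given, writes `compounds.csv`,
#'   `samples.csv`, `injections.csv` and `truth.json`
#' @return `aq_tables` with an extra `truth` element (invisibly when writing)
#' @export
simulate_experiment <- function(truth, design = study_design(),
                                out_dir = NULL) {
  unknown_tissues <- if (is.null(design$unknowns)) character(0) else
    unique(design$unknowns$tissue)
  all_tissues <- unique(c(design$tissues, unknown_tissues))
  missing_s <- setdiff(all_tissues, c(names(truth$matrix_factor), "solvent"))
  if (length(missing_s)) {
    aq_schema_error(sprintf("truth: no matrix_factor for tissue(s): %s",
                            paste(missing_s, collapse = ", ")))
  }
  set.seed(truth$seed)
  samples <- design_samples(design)
  registry <- truth$registry
  n_s <- nrow(samples)
  idx <- samples$acquisition_index
  drift <- (1 + truth$drift_per10)^(idx / 10)
  rf_drift_f <- (1 + truth$rf_drift_per10)^(idx / 10)
  extracted <- !(samples$role %in% c("calibration", "matrix_standard"))
  is_rec <- ifelse(extracted, truth$is_recovery, 1)
  s_fac <- ifelse(samples$tissue == "solvent", 1,
                  truth$matrix_factor[samples$tissue])
  conc_is <- samples$is_amount_ng / samples$extract_volume_mL
  sdlog <- sqrt(log(1 + truth$cv^2))
  noise <- function(n) {
    if (truth$cv == 0) rep(1, n) else
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  inj <- list()
  truth_rows <- list()
  for (cmp in registry$name) {
    c_ext <- true_extract_conc(samples, cmp, truth, design)
    area_is <- truth$area_is_base * is_rec * drift * noise(n_s)
    area_ns <- truth$rf[[cmp]] * (c_ext / conc_is) * truth$area_is_base *
      s_fac * drift * rf_drift_f * noise(n_s)
    inj[[cmp]] <- data.frame(sample_id = samples$sample_id, compound = cmp,
                             area_ns = area_ns, area_is = area_is,
                             stringsAsFactors = FALSE)
    truth_rows[[cmp]] <- data.frame(
      sample_id = samples$sample_id, compound = cmp,
      conc_extract_true = c_ext,
      conc_tissue_true = c_ext * samples$extract_volume_mL /
        samples$dry_mass_g,
      stringsAsFactors = FALSE)
  }
  injections <- do.call(rbind, inj)
  rownames(injections) <- NULL
  tables <- make_tables(registry, samples, injections)
  tables$truth <- list(
    parameters = lapply(
      truth[c("rf", "matrix_factor", "extraction_recovery", "is_recovery",
              "cv", "drift_per10", "rf_drift_per10", "area_is_base", "seed")],
      function(x) if (is.null(names(x))) x else as.list(x)),
    samples = do.call(rbind, truth_rows)
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_plain_csv(registry, file.path(out_dir, "compounds.csv"))
    write_plain_csv(samples, file.path(out_dir, "samples.csv"),
                    num_cols = c("nominal_conc_ng_per_mL",
                                 "spike_level_ng_per_g_dw", "dry_mass_g",
                                 "extract_volume_mL", "is_amount_ng",
                                 "ph_treatment"))
    write_plain_csv(injections, file.path(out_dir, "injections.csv"),
                    num_cols = c("area_ns", "area_is"))
    jsonlite::write_json(tables$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(tables))
  }
  tables
}

write_plain_csv <- function(df, path, num_cols = character(0)) {
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in num_cols) out[[col]] <- fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8", na = "")
}

#' Parameter-recovery benchmark
#'
#' Runs simulate -> calibrate -> quantify -> validate end to end `n_reps`
#' times under seeds derived from `seed` and reports, per repetition, the
#' true and estimated values of the response factors, per-tissue matrix
#' effects, the grand mean spiked-QC recovery, and the mean per-tissue LOQ
#' (against its noise-free closed form). The default design is a scaled-down
#' single-tissue version of the full study so many repetitions stay cheap;
#' the noise model is unchanged.
#'
#' @param n_reps number of independent simulated experiments
#' @param truth `aq_truth` (its seed field is overridden per repetition)
#' @param design `aq_design`
#' @param config `aq_run_config`
#' @param seed master seed
#' @return data.frame with columns `rep, parameter, true, estimated,
#'   relative_error`
#' @export
recovery_benchmark <- function(n_reps,
                               truth = simulation_truth(),
                               design = study_design(tissues = "pea_leaf"),
                               config = run_config(), seed = 1L) {
  if (n_reps < 1) aq_schema_error("recovery_benchmark: n_reps must be >= 1")
  reps <- lapply(seq_len(n_reps), function(i) {
    truth$seed <- as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
    tab <- simulate_experiment(truth, design)
    models <- calibrate(tab, config)
    me <- matrix_effects(tab, models, config)
    results <- quantify_samples(tab, config, models, me)
    rec <- recovery_table(results, tab$samples, config)

    # the estimand is the method's noise-free asymptote conditional on the
    # quantifier decision actually taken: residual matrix bias (ARF kept)
    # is a property of the decision rule, not recovery-estimation error
    s_true <- truth$matrix_factor[me$tissue]
    s_resid <- ifelse(me$use_matrix_standard, 1, s_true)
    true_recovery <- 100 * mean(truth$extraction_recovery) /
      truth$is_recovery * mean(s_resid)
    rows <- list()
    for (cmp in names(models)) {
      rows[[paste0("rf_", cmp)]] <- c(true = truth$rf[[cmp]],
                                      estimated = models[[cmp]]$arf)
    }
    for (t in design$tissues) {
      s <- truth$matrix_factor[[t]]
      est <- mean(me$me_percent[me$tissue == t])
      rows[[paste0("me_", t)]] <- c(true = (s - 1) * 100, estimated = est)
    }
    rows[["recovery"]] <- c(true = true_recovery,
                            estimated = mean(rec$mean_recovery))
    low <- min(design$cal_levels)
    for (t in design$tissues) {
      s <- truth$matrix_factor[[t]]
      use_mst_t <- me$use_matrix_standard[me$tissue == t]
      s_q <- mean(ifelse(use_mst_t, 1 / s, 1))  # conditional on decisions taken
      loq_true <- (low / config$loq_area_divisor) / truth$is_recovery * s_q *
        design$extract_volume_mL / design$dry_mass_g
      qc_ids <- tab$samples$sample_id[tab$samples$role == "spiked_qc" &
                                        tab$samples$tissue == t]
      est <- mean(results$loq_ng_per_g_dw[results$sample_id %in% qc_ids],
                  na.rm = TRUE)
      rows[[paste0("loq_", t)]] <- c(true = loq_true, estimated = est)
    }
    df <- data.frame(rep = i, parameter = names(rows),
                     true = vapply(rows, `[[`, numeric(1), "true"),
                     estimated = vapply(rows, `[[`, numeric(1), "estimated"),
                     row.names = NULL)
    df$relative_error <- ifelse(df$true == 0,
                                abs(df$estimated - df$true),
                                abs(df$estimated - df$true) / abs(df$true))
    df
  })
  do.call(rbind, reps)
}
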