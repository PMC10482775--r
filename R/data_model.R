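# Data model: typed tables, delimited-text readers/writers, run configuration.
#
# Input boundary is peak areas (one record per injection x compound), not raw
# spectra: peak detection and integration are assumed done upstream by the
# acquisition software. All files are UTF-8, comma-delimited, "." decimal
# separator, and all downstream modules consume only the validated tables
# produced here.

COMPOUND_COLS  <- c("name", "is_name", "role", "parent_name", "pka", "pka_kind")
SAMPLE_COLS    <- c("sample_id", "role", "tissue", "nominal_conc_ng_per_mL",
                    "spike_level_ng_per_g_dw", "dry_mass_g", "extract_volume_mL",
                    "is_amount_ng", "ph_treatment", "harvest_day",
                    "acquisition_index")
INJECTION_COLS <- c("sample_id", "compound", "area_ns", "area_is")
RESULT_COLS    <- c("sample_id", "compound", "conc_extract_ng_per_mL",
                    "conc_tissue_ng_per_g_dw", "loq_ng_per_g_dw",
                    "lod_ng_per_g_dw", "censored", "quantifier", "me_percent",
                    "report")

SAMPLE_ROLES <- c("calibration", "matrix_standard", "spiked_qc", "control",
                  "unknown")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    aq_schema_error(sprintf("%s: missing column(s): %s", what,
                            paste(missing, collapse = ", ")),
                    columns = missing)
  }
  invisible(df)
}

#' Run configuration
#'
#' Thresholds and divisors governing the quantification rules. Defaults are
#' the method's published decision rules: a calibration level is dropped when
#' its response factor deviates 30% or more from the running average
#' (`cal_rsd_threshold`); a matrix-matched standard replaces the average
#' response factor as quantifier when the absolute matrix effect exceeds 20%
#' (`me_threshold`); the per-sample LOQ substitutes half the lowest retained
#' calibration peak area (`loq_area_divisor`); LOD is LOQ divided by 3
#' (`lod_divisor`); recoveries are acceptable within 60--130%
#' (`recovery_accept_lo`/`hi`); sequence response-factor drift is judged
#' against a 30% band (`drift_band`).
#'
#' @param me_threshold percent, matrix-effect switch threshold (strict `>`)
#' @param cal_rsd_threshold percent, calibration trimming threshold (`>=` drops)
#' @param loq_area_divisor divisor applied to the lowest retained calibration
#'   peak area in the LOQ substitution
#' @param lod_divisor LOQ/LOD ratio
#' @param recovery_accept_lo,recovery_accept_hi percent, recovery acceptance
#'   window
#' @param drift_band percent, response-factor stability band
#' @return object of class `aq_run_config`
#' @export
run_config <- function(me_threshold = 20, cal_rsd_threshold = 30,
                       loq_area_divisor = 2, lod_divisor = 3,
                       recovery_accept_lo = 60, recovery_accept_hi = 130,
                       drift_band = 30) {
  cfg <- list(me_threshold = me_threshold,
              cal_rsd_threshold = cal_rsd_threshold,
              loq_area_divisor = loq_area_divisor,
              lod_divisor = lod_divisor,
              recovery_accept_lo = recovery_accept_lo,
              recovery_accept_hi = recovery_accept_hi,
              drift_band = drift_band)
  for (nm in names(cfg)) check_positive(cfg[[nm]], nm)
  if (recovery_accept_lo >= recovery_accept_hi) {
    aq_schema_error("recovery_accept_lo must be < recovery_accept_hi")
  }
  structure(cfg, class = "aq_run_config")
}

#' Read a run configuration file
#'
#' Accepts either JSON or a flat text file of `key = value` / `key: value`
#' lines (`#` comments allowed). Unknown keys are rejected.
#'
#' @param path file path
#' @return `aq_run_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) aq_io_error(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.+)$", lines))
    bad <- lines[vapply(kv, length, 1L) != 3L]
    if (length(bad)) {
      aq_schema_error(sprintf("config: cannot parse line(s): %s",
                              paste(bad, collapse = "; ")))
    }
    vals <- stats::setNames(
      lapply(kv, function(m) as.numeric(m[3])),
      vapply(kv, `[[`, character(1), 2)
    )
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    aq_schema_error(sprintf("config: unknown key(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  do.call(run_config, lapply(vals, as.numeric))
}

#' Validate a compound registry
#'
#' The registry lists every target analyte with its assigned isotopically
#' labeled internal standard, its role (`parent` or `metabolite`, with
#' `parent_name` linking a metabolite to its registered parent), and optional
#' ionization constants (`pka` in pH units together with `pka_kind`,
#' `acidic` or `basic`) used by the uptake layer. Internal standards are
#' registered implicitly as the set of distinct `is_name` values.
#'
#' @param df data.frame with columns `name, is_name, role, parent_name, pka,
#'   pka_kind`
#' @return validated data.frame of class `aq_compounds`
#' @export
compound_registry <- function(df) {
  check_columns(df, COMPOUND_COLS, "compounds")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("name", "is_name", "role", "parent_name", "pka_kind")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df$pka <- suppressWarnings(as.numeric(df$pka))
  if (anyDuplicated(df$name)) {
    aq_uniqueness_error(sprintf("compounds: duplicate name(s): %s",
      paste(unique(df$name[duplicated(df$name)]), collapse = ", ")))
  }
  if (any(!nzchar(df$name))) aq_schema_error("compounds: empty name")
  if (any(!nzchar(df$is_name))) {
    aq_referential_error(sprintf(
      "compounds: no internal standard assigned for: %s",
      paste(df$name[!nzchar(df$is_name)], collapse = ", ")))
  }
  bad_role <- setdiff(unique(df$role), c("parent", "metabolite"))
  if (length(bad_role)) {
    aq_schema_error(sprintf("compounds: role must be parent|metabolite, got: %s",
                            paste(bad_role, collapse = ", ")))
  }
  met <- df$role == "metabolite"
  if (any(met & !nzchar(df$parent_name))) {
    aq_schema_error(sprintf("compounds: metabolite(s) lacking parent_name: %s",
      paste(df$name[met & !nzchar(df$parent_name)], collapse = ", ")))
  }
  parents <- df$name[df$role == "parent"]
  orphan <- met & nzchar(df$parent_name) & !(df$parent_name %in% parents)
  if (any(orphan)) {
    aq_referential_error(sprintf(
      "compounds: parent_name does not resolve to a registered parent: %s",
      paste(sprintf("%s -> %s", df$name[orphan], df$parent_name[orphan]),
            collapse = ", ")))
  }
  has_pka <- !is.na(df$pka)
  if (any(has_pka & (df$pka < 0 | df$pka > 14))) {
    aq_schema_error("compounds: pka outside [0, 14]")
  }
  bad_kind <- has_pka & !(df$pka_kind %in% c("acidic", "basic"))
  if (any(bad_kind)) {
    aq_schema_error(sprintf("compounds: pka present without valid pka_kind: %s",
                            paste(df$name[bad_kind], collapse = ", ")))
  }
  class(df) <- c("aq_compounds", "data.frame")
  df
}

#' Validate a sample table
#'
#' One row per prepared sample (one injection per sample; replicates are
#' distinct samples). `role` drives which fields are required: calibration
#' and matrix standards carry `nominal_conc_ng_per_mL`, spiked QCs carry
#' `spike_level_ng_per_g_dw`. Calibration standards are prepared in solvent
#' (`tissue == "solvent"`); every sample records its dry mass (g), extract
#' volume (mL), internal-standard amount (ng) and acquisition order.
#'
#' @param df data.frame with the `samples.csv` column contract
#' @return validated data.frame of class `aq_samples`
#' @export
sample_table <- function(df) {
  check_columns(df, SAMPLE_COLS, "samples")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$role <- as.character(df$role)
  df$tissue <- as.character(df$tissue)
  for (col in c("nominal_conc_ng_per_mL", "spike_level_ng_per_g_dw",
                "dry_mass_g", "extract_volume_mL", "is_amount_ng",
                "ph_treatment")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$harvest_day <- suppressWarnings(as.integer(df$harvest_day))
  df$acquisition_index <- suppressWarnings(as.integer(df$acquisition_index))

  if (anyDuplicated(df$sample_id)) {
    aq_uniqueness_error(sprintf("samples: duplicate sample_id(s): %s",
      paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  }
  bad_role <- setdiff(unique(df$role), SAMPLE_ROLES)
  if (length(bad_role)) {
    aq_schema_error(sprintf("samples: unknown role(s): %s",
                            paste(bad_role, collapse = ", ")))
  }
  for (col in c("dry_mass_g", "extract_volume_mL", "is_amount_ng")) {
    if (any(is.na(df[[col]]) | df[[col]] <= 0)) {
      aq_schema_error(sprintf("samples: %s must be > 0 for every sample", col))
    }
  }
  if (any(is.na(df$acquisition_index) | df$acquisition_index < 0)) {
    aq_schema_error("samples: acquisition_index must be an integer >= 0")
  }
  need_nom <- df$role %in% c("calibration", "matrix_standard")
  if (any(need_nom & (is.na(df$nominal_conc_ng_per_mL) |
                      df$nominal_conc_ng_per_mL <= 0))) {
    aq_schema_error(
      "samples: calibration/matrix_standard require nominal_conc_ng_per_mL > 0")
  }
  if (any(df$role == "spiked_qc" & (is.na(df$spike_level_ng_per_g_dw) |
                                    df$spike_level_ng_per_g_dw <= 0))) {
    aq_schema_error("samples: spiked_qc require spike_level_ng_per_g_dw > 0")
  }
  bad_cal <- df$role == "calibration" & df$tissue != "solvent"
  if (any(bad_cal)) {
    aq_schema_error(sprintf(
      "samples: calibration standards must have tissue 'solvent': %s",
      paste(df$sample_id[bad_cal], collapse = ", ")))
  }
  class(df) <- c("aq_samples", "data.frame")
  df
}

#' Validate an injection table
#'
#' One row per compound per injected sample: native-analyte peak area and
#' internal-standard peak area in the same (arbitrary) detector units. An
#' IS area of zero marks the injection invalid downstream rather than being
#' imputed, since IS normalization is undefined without it.
#'
#' @param df data.frame with columns `sample_id, compound, area_ns, area_is`
#' @param registry optional `aq_compounds` for cross-reference checks
#' @param samples optional `aq_samples` for cross-reference checks
#' @return validated data.frame of class `aq_injections`
#' @export
injection_table <- function(df, registry = NULL, samples = NULL) {
  check_columns(df, INJECTION_COLS, "injections")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$compound <- as.character(df$compound)
  df$area_ns <- suppressWarnings(as.numeric(df$area_ns))
  df$area_is <- suppressWarnings(as.numeric(df$area_is))
  if (any(is.na(df$area_ns) | df$area_ns < 0)) {
    aq_schema_error("injections: area_ns must be numeric >= 0")
  }
  if (any(is.na(df$area_is) | df$area_is < 0)) {
    aq_schema_error("injections: area_is must be numeric >= 0")
  }
  key <- paste(df$sample_id, df$compound, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("sample_id", "compound"), drop = FALSE]
    aq_uniqueness_error(sprintf(
      "injections: duplicate (sample_id, compound) pair(s): %s",
      paste(sprintf("(%s, %s)", dup$sample_id, dup$compound), collapse = ", ")))
  }
  if (!is.null(registry)) {
    unknown <- setdiff(unique(df$compound), registry$name)
    if (length(unknown)) {
      aq_referential_error(sprintf("injections: unknown compound(s): %s",
                                   paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(samples)) {
    unknown <- setdiff(unique(df$sample_id), samples$sample_id)
    if (length(unknown)) {
      aq_referential_error(sprintf("injections: unknown sample_id(s): %s",
                                   paste(unknown, collapse = ", ")))
    }
  }
  class(df) <- c("aq_injections", "data.frame")
  df
}

read_table_file <- function(path, what) {
  if (!file.exists(path)) aq_io_error(sprintf("%s file not found: %s", what, path))
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = c("NA", ""), fileEncoding = "UTF-8")
}

#' Read a compound registry file
#' @param path path to `compounds.csv`
#' @return `aq_compounds`
#' @export
read_compounds <- function(path) compound_registry(read_table_file(path, "compounds"))

#' Read a sample metadata file
#' @param path path to `samples.csv`
#' @return `aq_samples`
#' @export
read_samples <- function(path) sample_table(read_table_file(path, "samples"))

#' Read an injection (peak-area) file
#' @param path path to `injections.csv`
#' @inheritParams injection_table
#' @return `aq_injections`
#' @export
read_injections <- function(path, registry = NULL, samples = NULL) {
  injection_table(read_table_file(path, "injections"), registry, samples)
}

#' Load and cross-validate the three input tables
#'
#' @param registry_path,samples_path,injections_path file paths
#' @return list with elements `registry`, `samples`, `injections`
#'   (class `aq_tables`)
#' @export
load_tables <- function(registry_path, samples_path, injections_path) {
  registry <- read_compounds(registry_path)
  samples <- read_samples(samples_path)
  injections <- read_injections(injections_path, registry, samples)
  structure(list(registry = registry, samples = samples,
                 injections = injections),
            class = "aq_tables")
}

#' Assemble in-memory tables
#'
#' Same validation as [load_tables()] but from data frames already in memory
#' (the synthetic generator and the tests use this path).
#'
#' @param registry,samples,injections data frames
#' @return `aq_tables`
#' @export
make_tables <- function(registry, samples, injections) {
  registry <- compound_registry(registry)
  samples <- sample_table(samples)
  injections <- injection_table(injections, registry, samples)
  structure(list(registry = registry, samples = samples,
                 injections = injections),
            class = "aq_tables")
}

#' Write a quantification results table
#'
#' One row per sample x compound. Numeric columns are written at full double
#' precision so that read -> write -> read is the identity; the `report`
#' column carries the formatted concentration or the textual flag `"<LOQ"`
#' for censored results (the numeric value is always retained).
#'
#' @param results data.frame as produced by [quantify_samples()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_results <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) {
    aq_schema_error("write_results: empty results collection")
  }
  check_columns(results, RESULT_COLS, "results")
  out <- results[RESULT_COLS]
  num_cols <- c("conc_extract_ng_per_mL", "conc_tissue_ng_per_g_dw",
                "loq_ng_per_g_dw", "lod_ng_per_g_dw", "me_percent")
  for (col in num_cols) out[[col]] <- fmt_num(out[[col]])
  out$censored <- ifelse(results$censored, "TRUE", "FALSE")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) aq_io_error(sprintf("write_results: cannot write to %s", path))
  invisible(path)
}

#' Read a quantification results table
#' @param path path to a `results.csv` written by [write_results()]
#' @return data.frame of class `aq_results`
#' @export
read_results <- function(path) {
  df <- read_table_file(path, "results")
  check_columns(df, RESULT_COLS, "results")
  for (col in c("conc_extract_ng_per_mL", "conc_tissue_ng_per_g_dw",
                "loq_ng_per_g_dw", "lod_ng_per_g_dw", "me_percent")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$censored <- df$censored == "TRUE"
  class(df) <- c("aq_results", "data.frame")
  df
}
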