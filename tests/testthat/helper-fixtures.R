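# Tiny in-code fixtures shared across test files.

tiny_registry <- function() {
  compound_registry(data.frame(
    name = c("cbz", "cbz_m"),
    is_name = c("cbz_d10", "cbz_d10"),
    role = c("parent", "metabolite"),
    parent_name = c("", "cbz"),
    pka = c(NA, NA),
    pka_kind = c("", ""),
    stringsAsFactors = FALSE
  ))
}

sample_row <- function(sample_id, role, tissue = "solvent", nominal = NA,
                       spike = NA, mass = 0.05, vol = 1, is_ng = 5,
                       ph = NA, day = NA, idx = 0L) {
  data.frame(sample_id = sample_id, role = role, tissue = tissue,
             nominal_conc_ng_per_mL = nominal,
             spike_level_ng_per_g_dw = spike, dry_mass_g = mass,
             extract_volume_mL = vol, is_amount_ng = is_ng,
             ph_treatment = ph, harvest_day = day, acquisition_index = idx,
             stringsAsFactors = FALSE)
}

# Noise-free hand-built experiment: 1 compound (plus metabolite), 3-level
# calibration with true RF = 2, one matrix standard with suppression s,
# one spiked QC. C_IS = 5 ng / 1 mL = 5 ng/mL; base IS area 1000.
tiny_tables <- function(s = 0.7, rf_true = 2, spike = 100, is_area = 1000) {
  cal_levels <- c(1, 10, 100)
  samples <- rbind(
    sample_row(sprintf("CAL%d", 1:3), "calibration", nominal = cal_levels,
               idx = 0:2),
    sample_row("MST1", "matrix_standard", tissue = "pea_leaf", nominal = 100,
               idx = 3L),
    sample_row("QC1", "spiked_qc", tissue = "pea_leaf", spike = spike,
               idx = 4L),
    sample_row("CTL1", "control", tissue = "pea_leaf", idx = 5L)
  )
  conc_is <- 5
  area_for <- function(conc, s_fac = 1) rf_true * conc / conc_is * is_area * s_fac
  mk_inj <- function(cmp) {
    data.frame(
      sample_id = samples$sample_id,
      compound = cmp,
      area_ns = c(area_for(cal_levels), area_for(100, s),
                  area_for(spike * 0.05 / 1, s), 0),
      area_is = is_area,
      stringsAsFactors = FALSE
    )
  }
  make_tables(tiny_registry(), samples, rbind(mk_inj("cbz"), mk_inj("cbz_m")))
}

write_tiny_files <- function(dir, tables = tiny_tables()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tables$registry, file.path(dir, "compounds.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(tables$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(tables$injections, file.path(dir, "injections.csv"),
                   row.names = FALSE, na = "")
  dir
}

solvent_grid_fixture <- function() {
  utils::read.csv(system.file("extdata", "solvent_recovery_pea_leaf.csv",
                              package = "aeroquant"),
                  stringsAsFactors = FALSE)
}

loq_lod_fixture <- function() {
  utils::read.csv(system.file("extdata", "loq_lod_ranges.csv",
                              package = "aeroquant"),
                  stringsAsFactors = FALSE)
}
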