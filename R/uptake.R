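# Uptake analysis: ionization state, tissue partitioning, and
# metabolite-to-parent ratios on quantified concentrations.
#
# Tissue labels follow the "<plant>_<organ>" convention (spinach_leaf,
# arugula_root, ...); partitioning uses the leaf and root organs.

#' Neutral fraction of an ionizable compound (Henderson--Hasselbalch)
#'
#' Monoprotic form with a single "strongest" pKa, as used when reasoning
#' about membrane permeability of weak acids and bases:
#' acidic `f = 1/(1 + 10^(ph - pka))` (neutral below the pKa),
#' basic  `f = 1/(1 + 10^(pka - ph))` (neutral above the pKa).
#' `f = 0.5` at `ph == pka`; the ionized fraction is `1 - f`.
#'
#' @param ph solution pH in `[0, 14]`
#' @param pka acid dissociation constant in `[0, 14]`
#' @param kind `"acidic"` or `"basic"`
#' @return neutral fraction in (0, 1)
#' @export
fraction_neutral <- function(ph, pka, kind) {
  if (any(ph < 0 | ph > 14) || any(pka < 0 | pka > 14)) {
    aq_schema_error("fraction_neutral: ph and pka must lie in [0, 14]")
  }
  kind <- match.arg(kind, c("acidic", "basic"))
  if (kind == "acidic") 1 / (1 + 10^(ph - pka)) else 1 / (1 + 10^(pka - ph))
}

split_tissue <- function(tissue) {
  parts <- regmatches(tissue, regexec("^(.*)_([^_]+)$", tissue))
  plant <- vapply(parts, function(p) if (length(p) == 3) p[2] else NA_character_,
                  character(1))
  organ <- vapply(parts, function(p) if (length(p) == 3) p[3] else tissue[1],
                  character(1))
  data.frame(plant = plant, organ = organ, stringsAsFactors = FALSE)
}

# mean over uncensored rows; NA when none
mean_uncensored <- function(df) {
  ok <- !is.na(df$censored) & !df$censored
  if (!any(ok)) NA_real_ else mean(df$conc_tissue_ng_per_g_dw[ok])
}

uptake_groups <- function(results, samples, roles = "unknown") {
  keep <- samples[samples$role %in% roles, , drop = FALSE]
  res <- merge(results, keep[, c("sample_id", "tissue", "ph_treatment",
                                 "harvest_day")], by = "sample_id")
  cbind(res, split_tissue(res$tissue))
}

#' Leaf/root partition summary
#'
#' For each compound x plant x pH treatment x harvest day with quantified
#' (uncensored) leaf and root samples, the leaf fraction
#' `conc_leaf / (conc_leaf + conc_root)` of the mean concentrations.
#' Groups with a censored or absent side carry a missing fraction and a
#' reason code instead of an imputed value.
#'
#' @param results `aq_results`
#' @param samples `aq_samples`
#' @param roles sample roles to summarise (default `"unknown"`)
#' @return data.frame with one row per compound x plant x ph x day
#' @export
partition_summary <- function(results, samples, roles = "unknown") {
  res <- uptake_groups(results, samples, roles)
  res <- res[res$organ %in% c("leaf", "root"), , drop = FALSE]
  if (nrow(res) == 0) aq_schema_error("partition_summary: no leaf/root samples")
  groups <- unique(res[, c("compound", "plant", "ph_treatment", "harvest_day")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- res[res$compound == g$compound & res$plant %in% g$plant &
                 identical_or_both_na(res$ph_treatment, g$ph_treatment) &
                 identical_or_both_na(res$harvest_day, g$harvest_day), ,
               drop = FALSE]
    leaf <- mean_uncensored(sub[sub$organ == "leaf", , drop = FALSE])
    root <- mean_uncensored(sub[sub$organ == "root", , drop = FALSE])
    frac <- if (!is.na(leaf) && !is.na(root)) leaf / (leaf + root) else NA_real_
    reason <- if (!is.na(frac)) "" else if (is.na(leaf) && is.na(root)) {
      "leaf<LOQ;root<LOQ"
    } else if (is.na(leaf)) "leaf<LOQ" else "root<LOQ"
    data.frame(compound = g$compound, plant = g$plant,
               ph_treatment = g$ph_treatment, harvest_day = g$harvest_day,
               conc_leaf = leaf, conc_root = root, leaf_fraction = frac,
               reason = reason, row.names = NULL)
  }))
  out
}

identical_or_both_na <- function(x, v) {
  if (is.na(v)) is.na(x) else !is.na(x) & x == v
}

#' Metabolite-to-parent concentration ratio
#'
#' Per group (tissue x pH x harvest day), the ratio of the mean uncensored
#' metabolite concentration to the mean uncensored parent concentration.
#' The pairing must be registered (the metabolite's `parent_name` equals
#' `parent`). Groups whose parent or metabolite is entirely censored yield a
#' missing ratio with a reason code (`"parent<LOQ"` / `"metabolite<LOQ"`);
#' no LOQ/2 imputation is applied.
#'
#' @param results `aq_results`
#' @param samples `aq_samples`
#' @param registry `aq_compounds`
#' @param metabolite,parent compound names
#' @param roles sample roles to use (default `"unknown"`)
#' @return data.frame with one row per tissue x ph x day
#' @export
metabolite_parent_ratio <- function(results, samples, registry, metabolite,
                                    parent, roles = "unknown") {
  reg_row <- registry[registry$name == metabolite, , drop = FALSE]
  if (nrow(reg_row) == 0 || reg_row$role != "metabolite" ||
      reg_row$parent_name != parent) {
    aq_referential_error(sprintf(
      "'%s' is not a registered metabolite of '%s'", metabolite, parent))
  }
  res <- uptake_groups(results, samples, roles)
  res <- res[res$compound %in% c(metabolite, parent), , drop = FALSE]
  groups <- unique(res[, c("tissue", "ph_treatment", "harvest_day")])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- res[res$tissue == g$tissue &
                 identical_or_both_na(res$ph_treatment, g$ph_treatment) &
                 identical_or_both_na(res$harvest_day, g$harvest_day), ,
               drop = FALSE]
    met <- mean_uncensored(sub[sub$compound == metabolite, , drop = FALSE])
    par <- mean_uncensored(sub[sub$compound == parent, , drop = FALSE])
    ratio <- if (!is.na(met) && !is.na(par)) met / par else NA_real_
    reason <- if (!is.na(ratio)) "" else if (is.na(par) && is.na(met)) {
      "parent<LOQ;metabolite<LOQ"
    } else if (is.na(par)) "parent<LOQ" else "metabolite<LOQ"
    data.frame(tissue = g$tissue, ph_treatment = g$ph_treatment,
               harvest_day = g$harvest_day, metabolite = metabolite,
               parent = parent, mean_metabolite = met, mean_parent = par,
               ratio = ratio, reason = reason, row.names = NULL)
  }))
  out
}

#' Uptake summary table
#'
#' Per-group mean concentrations joined with leaf fractions and, for every
#' registered metabolite, its metabolite-to-parent ratio. This is the
#' `uptake_summary.csv` product of the pipeline.
#'
#' @param results `aq_results`
#' @param samples `aq_samples`
#' @param registry `aq_compounds`
#' @param roles sample roles to summarise (default `"unknown"`)
#' @return data.frame, one row per compound x plant x tissue x ph x day
#' @export
uptake_summary <- function(results, samples, registry, roles = "unknown") {
  res <- uptake_groups(results, samples, roles)
  if (nrow(res) == 0) aq_schema_error("uptake_summary: no samples to summarise")
  groups <- unique(res[, c("compound", "plant", "organ", "ph_treatment",
                           "harvest_day")])
  base <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- res[res$compound == g$compound & res$plant %in% g$plant &
                 res$organ == g$organ &
                 identical_or_both_na(res$ph_treatment, g$ph_treatment) &
                 identical_or_both_na(res$harvest_day, g$harvest_day), ,
               drop = FALSE]
    data.frame(compound = g$compound, plant = g$plant, tissue = g$organ,
               ph_treatment = g$ph_treatment, harvest_day = g$harvest_day,
               n = nrow(sub), n_censored = sum(sub$censored, na.rm = TRUE),
               mean_conc = mean_uncensored(sub), row.names = NULL)
  }))
  part <- partition_summary(results, samples, roles)
  base$leaf_fraction <- part$leaf_fraction[match(
    paste(base$compound, base$plant, base$ph_treatment, base$harvest_day),
    paste(part$compound, part$plant, part$ph_treatment, part$harvest_day))]
  mets <- registry[registry$role == "metabolite", , drop = FALSE]
  base$metabolite_parent_ratio <- NA_real_
  for (i in seq_len(nrow(mets))) {
    mp <- metabolite_parent_ratio(results, samples, registry,
                                  mets$name[i], mets$parent_name[i], roles)
    tis <- paste(split_tissue(mp$tissue)$plant, split_tissue(mp$tissue)$organ)
    idx <- match(paste(base$plant, base$tissue, base$ph_treatment,
                       base$harvest_day)[base$compound == mets$name[i]],
                 paste(tis, mp$ph_treatment, mp$harvest_day))
    base$metabolite_parent_ratio[base$compound == mets$name[i]] <-
      mp$ratio[idx]
  }
  base
}
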