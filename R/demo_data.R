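# Published group-level summaries from a piglet BCAA-supplementation
# arteriovenous infusion study, included as worked-example inputs. Only
# group means/SEMs are public; individual animals are not, which is exactly
# why the package computes kinetics per animal and treats these tables as
# illustration and consistency anchors, not as reanalysis inputs.

#' Example steady-state group means
#'
#' Plateau concentrations and enrichments (mole percent excess) of leucine,
#' KIC and CO2 in carotid-arterial and femoral-venous plasma for a control
#' and a BCAA-supplemented (treatment) group of six fed piglets, as printed
#' in the source study's steady-state table. CO2 concentrations are in
#' mmol/L (unit tag included); all others in umol/L.
#'
#' @return data.frame with columns `group`, `analyte`, `site`,
#'   `concentration`, `conc_unit`, `enrichment_mpe`, `pooled_sem_conc`,
#'   `pooled_sem_mpe`.
#' @export
demo_steady_state_means <- function() {
  rows <- rbind(
    c("control",   "leucine", "artery", 135.80, "umol/L", 4.68),
    c("control",   "leucine", "vein",   124.67, "umol/L", 3.94),
    c("control",   "KIC",     "artery",  46.84, "umol/L", 1.43),
    c("control",   "KIC",     "vein",    47.86, "umol/L", 1.58),
    c("control",   "CO2",     "artery",  18.64, "mmol/L", 0.0290),
    c("control",   "CO2",     "vein",    22.98, "mmol/L", 0.0259),
    c("treatment", "leucine", "artery", 187.81, "umol/L", 6.41),
    c("treatment", "leucine", "vein",   154.30, "umol/L", 4.97),
    c("treatment", "KIC",     "artery",  64.88, "umol/L", 2.10),
    c("treatment", "KIC",     "vein",    72.42, "umol/L", 2.46),
    c("treatment", "CO2",     "artery",  18.62, "mmol/L", 0.0333),
    c("treatment", "CO2",     "vein",    20.70, "mmol/L", 0.0329))
  out <- data.frame(group = rows[, 1], analyte = rows[, 2], site = rows[, 3],
                    concentration = as.numeric(rows[, 4]), conc_unit = rows[, 5],
                    enrichment_mpe = as.numeric(rows[, 6]),
                    stringsAsFactors = FALSE)
  sem <- data.frame(
    analyte = c("leucine", "leucine", "KIC", "KIC", "CO2", "CO2"),
    site = rep(c("artery", "vein"), 3),
    pooled_sem_conc = c(21.63, 18.82, 4.77, 6.28, 1.07, 1.47),
    pooled_sem_mpe = c(1.05, 0.61, 0.53, 0.54, 0.0056, 0.0060),
    stringsAsFactors = FALSE)
  merge(out, sem, by = c("analyte", "site"), sort = FALSE)[
    , c("group", "analyte", "site", "concentration", "conc_unit",
        "enrichment_mpe", "pooled_sem_conc", "pooled_sem_mpe")]
}

#' Example leucine-kinetics group means
#'
#' The published hindlimb flux panel (umol/kg/h) for the same two groups of
#' six fed piglets: group means, pooled SEM (SE of the difference) and
#' two-tailed p-values. These are means of per-animal values; plugging the
#' steady-state group means of [demo_steady_state_means()] into the flux
#' formulas does not reproduce them (means of ratios vs ratios of means).
#'
#' @return data.frame with columns `variable`, `control`, `treatment`,
#'   `pooled_sem`, `p_value`.
#' @export
demo_kinetics_means <- function() {
  data.frame(
    variable = c("arterial_input", "net_uptake", "utilization",
                 "net_transamination", "oxidation", "protein_synthesis",
                 "protein_degradation", "protein_deposition"),
    control = c(176.52, 14.90, 38.60, 2.44, 8.96, 27.21, 23.71, 3.50),
    treatment = c(329.01, 57.35, 106.26, 14.38, 17.06, 74.82, 48.91, 25.91),
    pooled_sem = c(53.28, 10.92, 14.57, 5.21, 7.47, 10.92, 11.21, 8.51),
    p_value = c(0.017, 0.003, 0.001, 0.045, 0.304, 0.001, 0.048, 0.025),
    stringsAsFactors = FALSE)
}

#' Example published group summaries (mean, SEM, n)
#'
#' Two published two-group comparisons reported as mean +/- SEM with n = 6
#' per group, used as worked examples for [t_from_summary()]: the gracilis
#' muscle relative weight (%) and the fasted plasma insulin concentration
#' (mU/L), with the p-values printed in the source study.
#'
#' @return data.frame with one row per comparison.
#' @export
demo_group_summaries <- function() {
  data.frame(
    variable = c("gracilis_relative_weight", "insulin"),
    mean_control = c(0.249, 30.5), sem_control = c(0.008, 3.6),
    n_control = c(6, 6),
    mean_treatment = c(0.288, 35.3), sem_treatment = c(0.015, 2.8),
    n_treatment = c(6, 6),
    printed_p = c(0.047, 0.322),
    stringsAsFactors = FALSE)
}
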