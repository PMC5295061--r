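# Two-pool arteriovenous tracer-balance model for limb leucine kinetics.
#
# With plasma flow PF (L/kg/h), arterial/venous plateau concentrations C_a,
# C_v (umol/L) and fractional enrichments E_a, E_v:
#
#   arterial input   Ra_in = C_a * PF
#   net uptake       NB    = PF * (C_a - C_v)
#   tracer uptake    U13   = PF * (C_a E_a - C_v E_v)
#   utilization      Rd    = U13 / E_a
#   degradation      PD    = Rd - NB
#   net transamination T   = PF * (C_v,KIC - C_a,KIC)
#   13C-KIC production P13 = PF * (C_v,KIC E_v,KIC - C_a,KIC E_a,KIC)
#   oxidation        Ox    = F13CO2 / (E_precursor * recovery)
#   synthesis        PS    = Rd - Ox - T
#   deposition       PDep  = PS - PD  ( = NB - Ox - T )
#
# Four identities hold exactly on every panel: PDep = PS - PD, PD = Rd - NB,
# Rd = PS + Ox + T, PDep = NB - Ox - T.

#' Arterial leucine input to the limb
#'
#' `Ra_in = c_art * PF`.
#'
#' @param c_art_leu Arterial plateau leucine concentration, umol/L.
#' @param pf Plasma flow, L/kg/h.
#' @return Flux in umol/kg/h.
#' @export
arterial_input <- function(c_art_leu, pf) {
  check_numeric(c_art_leu, "arterial leucine", lower = 0)
  c_art_leu * pf
}

#' Net substrate uptake by the limb
#'
#' `NB = PF * (c_art - c_ven)`; negative values (net release) are allowed
#' and flagged via the `"negative"` attribute.
#'
#' @param c_art,c_ven Arterial and venous concentrations, umol/L.
#' @param pf Plasma flow, L/kg/h.
#' @return Flux in umol/kg/h.
#' @export
net_uptake <- function(c_art, c_ven, pf) {
  check_numeric(c(c_art, c_ven), "concentrations", lower = 0)
  out <- pf * (c_art - c_ven)
  structure(out, negative = out < 0)
}

#' Net labeled-leucine uptake by the limb
#'
#' `U13 = PF * (c_art * e_art - c_ven * e_ven)`, in tracer umol/kg/h.
#'
#' @inheritParams net_uptake
#' @param e_art,e_ven Fractional enrichments in `[0, 1)`.
#' @export
tracer_leucine_uptake <- function(c_art, e_art, c_ven, e_ven, pf) {
  check_enrichment_fraction(c(e_art, e_ven))
  pf * (c_art * e_art - c_ven * e_ven)
}

check_enrichment_fraction <- function(e) {
  if (any(e < 0 | e >= 1, na.rm = TRUE)) {
    leuflux_abort("enrichments must be fractions in [0, 1)", "invalid_measurement")
  }
  invisible(e)
}

#' Total leucine utilization (rate of disposal) by the limb
#'
#' `Rd = U13 / e_art`: labeled-leucine extraction scaled by arterial
#' enrichment. When venous enrichment equals arterial (no isotopic
#' dilution), `Rd` reduces to the net uptake.
#'
#' @inheritParams tracer_leucine_uptake
#' @export
utilization <- function(c_art, e_art, c_ven, e_ven, pf) {
  if (any(e_art <= 0)) {
    leuflux_abort("arterial enrichment must be positive", "division_guard")
  }
  tracer_leucine_uptake(c_art, e_art, c_ven, e_ven, pf) / e_art
}

#' Protein degradation (unlabeled leucine release from proteolysis)
#'
#' `PD = utilization - net_uptake`.
#'
#' @param utilization,net_uptake Fluxes in umol/kg/h.
#' @export
protein_degradation <- function(utilization, net_uptake) {
  as.numeric(utilization) - as.numeric(net_uptake)
}

#' Net transamination (net limb KIC release)
#'
#' `T_net = PF * (c_ven_kic - c_art_kic)`.
#'
#' @param c_art_kic,c_ven_kic KIC concentrations, umol/L.
#' @param pf Plasma flow, L/kg/h.
#' @export
net_transamination <- function(c_art_kic, c_ven_kic, pf) {
  check_numeric(c(c_art_kic, c_ven_kic), "KIC concentrations", lower = 0)
  pf * (c_ven_kic - c_art_kic)
}

#' Labeled KIC production by the limb
#'
#' `P13 = PF * (c_ven_kic * e_ven_kic - c_art_kic * e_art_kic)`, in tracer
#' umol/kg/h.
#'
#' @inheritParams net_transamination
#' @param e_art_kic,e_ven_kic KIC fractional enrichments in `[0, 1)`.
#' @export
kic13_production <- function(c_art_kic, e_art_kic, c_ven_kic, e_ven_kic, pf) {
  check_enrichment_fraction(c(e_art_kic, e_ven_kic))
  pf * (c_ven_kic * e_ven_kic - c_art_kic * e_art_kic)
}

#' Leucine oxidation by the limb
#'
#' `Ox = F13CO2 / (e_precursor * recovery)`. The precursor enrichment is by
#' convention the venous \[1-13C\]KIC MPE (reciprocal-pool surrogate for the
#' intracellular leucine pool); arterial leucine enrichment is an
#' alternative. `recovery` (default 1) optionally corrects for incomplete
#' recovery of labeled CO2 across the limb.
#'
#' @param f13co2 Labeled CO2 release, umol/kg/h (see [limb_13co2_release()]).
#' @param e_precursor Precursor fractional enrichment.
#' @param recovery Fractional label recovery in `(0, 1]`.
#' @export
oxidation <- function(f13co2, e_precursor, recovery = 1) {
  if (any(e_precursor <= 0)) {
    leuflux_abort("precursor enrichment must be positive", "division_guard")
  }
  if (any(recovery <= 0 | recovery > 1)) {
    leuflux_abort("recovery must be in (0, 1]", "format")
  }
  as.numeric(f13co2) / (e_precursor * recovery)
}

#' Protein synthesis from the disposal balance
#'
#' `PS = utilization - oxidation - net_transamination`: disposal not
#' accounted for by catabolism is retained in protein.
#'
#' @param utilization,oxidation,net_transamination Fluxes in umol/kg/h.
#' @export
protein_synthesis <- function(utilization, oxidation, net_transamination) {
  as.numeric(utilization) - as.numeric(oxidation) - as.numeric(net_transamination)
}

#' Protein deposition (net protein balance)
#'
#' `PDep = PS - PD`, identically equal to `NB - Ox - T_net`.
#'
#' @param protein_synthesis,protein_degradation Fluxes in umol/kg/h.
#' @export
protein_deposition <- function(protein_synthesis, protein_degradation) {
  as.numeric(protein_synthesis) - as.numeric(protein_degradation)
}

#' Partition fractions of leucine disposal
#'
#' `utilization_of_input = 100 * Rd / Ra_in` (percent of arterial input);
#' synthesis, transamination and oxidation fractions are percents of
#' utilization and sum to exactly 100.
#'
#' @param kinetics A `leucine_kinetics` object or any list/data.frame with
#'   `arterial_input`, `utilization`, `protein_synthesis`,
#'   `net_transamination` and `oxidation` components.
#' @return List (or data.frame columns) of the four percentages.
#' @export
partition_fractions <- function(kinetics) {
  k <- kinetics
  if (any(k$arterial_input <= 0) || any(k$utilization <= 0)) {
    leuflux_abort("arterial input and utilization must be positive for fractions",
                  "division_guard")
  }
  list(
    utilization_of_input = 100 * k$utilization / k$arterial_input,
    synthesis_of_utilization = 100 * k$protein_synthesis / k$utilization,
    transamination_of_utilization = 100 * k$net_transamination / k$utilization,
    oxidation_of_utilization = 100 * k$oxidation / k$utilization
  )
}

# Vectorized core: one row per animal of wide plateau values -> flux panel.
# Required columns: pf, leucine_artery_conc, leucine_artery_enrich, ...
compute_kinetics_wide <- function(w, precursor = c("venous_kic", "arterial_leucine"),
                                  recovery = 1, bicarb_rate = 10) {
  precursor <- match.arg(precursor)
  pf <- w$pf
  ra_in <- arterial_input(w$leucine_artery_conc, pf)
  nb <- as.numeric(net_uptake(w$leucine_artery_conc, w$leucine_vein_conc, pf))
  u13 <- tracer_leucine_uptake(w$leucine_artery_conc, w$leucine_artery_enrich,
                               w$leucine_vein_conc, w$leucine_vein_enrich, pf)
  rd <- utilization(w$leucine_artery_conc, w$leucine_artery_enrich,
                    w$leucine_vein_conc, w$leucine_vein_enrich, pf)
  pd <- protein_degradation(rd, nb)
  tnet <- net_transamination(w$KIC_artery_conc, w$KIC_vein_conc, pf)
  p13 <- kic13_production(w$KIC_artery_conc, w$KIC_artery_enrich,
                          w$KIC_vein_conc, w$KIC_vein_enrich, pf)
  f13co2 <- as.numeric(limb_13co2_release(pf, w$CO2_artery_conc, w$CO2_artery_enrich,
                                          w$CO2_vein_conc, w$CO2_vein_enrich))
  e_prec <- switch(precursor,
                   venous_kic = w$KIC_vein_enrich,
                   arterial_leucine = w$leucine_artery_enrich)
  ox <- oxidation(f13co2, e_prec, recovery)
  ps <- protein_synthesis(rd, ox, tnet)
  pdep <- protein_deposition(ps, pd)
  out <- data.frame(
    animal_id = w$animal_id,
    plasma_flow = pf,
    arterial_input = ra_in, net_uptake = nb, utilization = rd,
    net_transamination = tnet, oxidation = ox,
    protein_synthesis = ps, protein_degradation = pd, protein_deposition = pdep,
    leu13_uptake = u13, kic13_production = p13, f13co2 = f13co2,
    co2_production_wb = whole_body_co2_production(bicarb_rate, w$CO2_artery_enrich),
    co2_recovery_limb = f13co2 / bicarb_rate,
    stringsAsFactors = FALSE)
  if (!is.null(w$group)) out <- cbind(out[1], group = w$group, out[-1])
  # fractions are undefined when utilization or input is non-positive (can
  # happen for single noisy animals); such rows get NA and a flag
  ok <- ra_in > 0 & rd > 0
  frac <- function(num, den) ifelse(ok, 100 * num / den, NA_real_)
  out$utilization_of_input <- frac(rd, ra_in)
  out$synthesis_of_utilization <- frac(ps, rd)
  out$transamination_of_utilization <- frac(tnet, rd)
  out$oxidation_of_utilization <- frac(ox, rd)
  out$flag_undefined_fractions <- !ok
  out$flag_net_release <- nb < 0
  out$flag_negative_f13co2 <- f13co2 < 0
  attr(out, "options") <- list(precursor = precursor, recovery = recovery,
                               bicarb_rate = bicarb_rate)
  out
}

ss_to_wide <- function(ss) {
  dt <- data.table::as.data.table(ss)
  w <- data.table::dcast(dt, animal_id ~ analyte + site,
                         value.var = c("mean_concentration", "mean_enrichment"))
  names(w) <- sub("^mean_concentration_(.*)_(artery|vein)$", "\\1_\\2_conc", names(w))
  names(w) <- sub("^mean_enrichment_(.*)_(artery|vein)$", "\\1_\\2_enrich", names(w))
  expected <- unlist(lapply(.analytes, function(a) {
    unlist(lapply(.sites, function(s) paste0(a, "_", s, c("_conc", "_enrich"))))
  }))
  for (col in setdiff(expected, names(w))) w[[col]] <- NA_real_
  if (!is.null(ss$group)) {
    grp <- unique(ss[, c("animal_id", "group")])
    w <- merge(w, grp, by = "animal_id", sort = FALSE)
  }
  as.data.frame(w)
}

# Names the gaps ("KIC@vein" style) for one wide row.
missing_cells <- function(w_row) {
  cells <- c(leucine_artery_conc = "leucine@artery", leucine_vein_conc = "leucine@vein",
             KIC_artery_conc = "KIC@artery", KIC_vein_conc = "KIC@vein",
             CO2_artery_conc = "CO2@artery", CO2_vein_conc = "CO2@vein",
             leucine_artery_enrich = "leucine@artery (enrichment)",
             leucine_vein_enrich = "leucine@vein (enrichment)",
             KIC_artery_enrich = "KIC@artery (enrichment)",
             KIC_vein_enrich = "KIC@vein (enrichment)",
             CO2_artery_enrich = "CO2@artery (enrichment)",
             CO2_vein_enrich = "CO2@vein (enrichment)")
  missing <- vapply(names(cells), function(nm) {
    is.null(w_row[[nm]]) || is.na(w_row[[nm]])
  }, logical(1))
  unname(cells[missing])
}

#' Full kinetic panel for one animal
#'
#' Orchestrates the per-animal calculation: plasma flow, tracer fluxes,
#' utilization, degradation, synthesis, deposition and partition fractions,
#' from steady-state summaries for leucine, KIC and CO2 at both sites.
#'
#' @param steady_states Steady-state table ([summarize_steady_state()]) for
#'   one animal, covering leucine, KIC and CO2 at artery and vein.
#' @param pf Plasma flow (L/kg/h), e.g. from [plasma_flow_pah()].
#' @param protocol [infusion_protocol()]; supplies the bicarbonate rate for
#'   whole-body CO2 production.
#' @param precursor Oxidation precursor pool: `"venous_kic"` (default,
#'   reciprocal-pool surrogate) or `"arterial_leucine"`.
#' @param recovery Fractional 13CO2 recovery used as oxidation divisor
#'   (default 1, i.e. no correction).
#' @return A `leucine_kinetics` object: a one-row data.frame of the flux
#'   panel (umol/kg/h), tracer fluxes, partition fractions (percent) and
#'   flags, with the analysis options in `attr(, "options")`.
#' @export
analyze_animal <- function(steady_states, pf, protocol = infusion_protocol(),
                           precursor = c("venous_kic", "arterial_leucine"),
                           recovery = 1) {
  precursor <- match.arg(precursor)
  if (length(unique(steady_states$animal_id)) != 1) {
    leuflux_abort("analyze_animal expects steady states for exactly one animal",
                  "format")
  }
  w <- ss_to_wide(steady_states)
  w$pf <- pf
  gaps <- missing_cells(w[1, ])
  if (length(gaps) > 0) {
    leuflux_abort(sprintf("incomplete input for animal %s: missing %s",
                          w$animal_id[1], paste(gaps, collapse = ", ")),
                  "incomplete_input", gaps = gaps)
  }
  out <- compute_kinetics_wide(w, precursor = precursor, recovery = recovery,
                               bicarb_rate = protocol$NaH13CO3$rate)
  class(out) <- c("leucine_kinetics", class(out))
  out
}

#' Kinetic panels for a whole cohort
#'
#' Runs plateau summarization, per-animal plasma flow and the tracer-balance
#' model over a long-format sample table. Animals with incomplete data
#' (missing analyte/site cells or no PAH gradient) are excluded with a
#' warning naming the gaps; kinetics are computed per animal and never from
#' group means.
#'
#' @param samples Long-format sample table (see [read_samples()]).
#' @param animals data.frame with `animal_id`, `group`, `body_weight_kg`.
#' @param protocol [infusion_protocol()].
#' @inheritParams analyze_animal
#' @inheritParams summarize_steady_state
#' @return data.frame, one row per analyzed animal, with the flux panel,
#'   tracer fluxes, fractions and flags; options in `attr(, "options")`.
#' @export
analyze_cohort <- function(samples, animals, protocol = infusion_protocol(),
                           precursor = c("venous_kic", "arterial_leucine"),
                           recovery = 1, rule = c("last_k", "detect"), k = 3,
                           co2_time = 2) {
  precursor <- match.arg(precursor)
  rule <- match.arg(rule)
  if (is.null(animals$animal_id) || is.null(animals$body_weight_kg)) {
    leuflux_abort("animals table needs animal_id and body_weight_kg", "schema")
  }
  ss <- summarize_steady_state(samples, rule = rule, k = k, co2_time = co2_time)
  w <- ss_to_wide(ss)
  w <- merge(w, animals[, c("animal_id", "body_weight_kg",
                            intersect("group", names(animals)))],
             by = "animal_id", sort = TRUE, suffixes = c("", ".animals"))
  if (is.null(w$group) && !is.null(w$group.animals)) w$group <- w$group.animals

  # plasma flow from the PAH plateau; missing/inverted gradients disqualify
  pah_ok <- !is.na(w$PAH_artery_conc) & !is.na(w$PAH_vein_conc) &
    w$PAH_vein_conc > w$PAH_artery_conc
  w$pf <- NA_real_
  if (any(pah_ok)) {
    w$pf[pah_ok] <- plasma_flow_pah(pah_infusion_mg_h(protocol),
                                    w$PAH_artery_conc[pah_ok],
                                    w$PAH_vein_conc[pah_ok],
                                    w$body_weight_kg[pah_ok])
  }

  gaps <- lapply(seq_len(nrow(w)), function(i) {
    g <- missing_cells(w[i, ])
    if (is.na(w$pf[i])) g <- c(g, "PAH plasma-flow gradient")
    g
  })
  bad <- lengths(gaps) > 0
  if (any(bad)) {
    msg <- paste(sprintf("%s: %s", w$animal_id[bad],
                         vapply(gaps[bad], paste, "", collapse = ", ")),
                 collapse = "; ")
    leuflux_warn(sprintf("excluding %d animal(s) with incomplete input — %s",
                         sum(bad), msg), "incomplete_animals")
    w <- w[!bad, , drop = FALSE]
  }
  if (nrow(w) == 0) leuflux_abort("no analyzable animals", "incomplete_input")

  out <- compute_kinetics_wide(w, precursor = precursor, recovery = recovery,
                               bicarb_rate = protocol$NaH13CO3$rate)
  out$body_weight_kg <- w$body_weight_kg

  # A single animal per group is the signature of group-mean (aggregated)
  # input: means of per-animal ratios differ from ratios of means, so the
  # result is not comparable to a per-animal analysis.
  if (!is.null(out$group)) {
    n_per_group <- table(out$group)
    if (any(n_per_group == 1)) {
      out$flag_group_mean_input <- out$group %in% names(n_per_group)[n_per_group == 1]
      leuflux_warn(paste("some group(s) contain a single record: input looks like",
                         "group means, not per-animal measurements; kinetics on",
                         "group means do not equal means of per-animal kinetics"),
                   "group_mean_input")
    } else {
      out$flag_group_mean_input <- FALSE
    }
  }
  attr(out, "options") <- list(precursor = precursor, recovery = recovery,
                               bicarb_rate = protocol$NaH13CO3$rate,
                               rule = rule, k = k, co2_time = co2_time)
  out
}

#' Kinetics computed directly from group-mean plateau values
#'
#' Convenience for plugging group-level mean concentrations and enrichments
#' into the flux formulas. The result is the "ratio of means", which does
#' **not** equal the mean of per-animal kinetics; the returned panel is
#' flagged accordingly and should be used for illustration only.
#'
#' @param means data.frame with columns `group`, `analyte`, `site`,
#'   `concentration`, `conc_unit`, `enrichment_mpe` (one row per cell).
#' @param pf Named plasma flow per group, L/kg/h.
#' @inheritParams analyze_animal
#' @return Flux panel per group with `flag_group_mean_input = TRUE`.
#' @export
kinetics_from_means <- function(means, pf, protocol = infusion_protocol(),
                                precursor = c("venous_kic", "arterial_leucine"),
                                recovery = 1) {
  precursor <- match.arg(precursor)
  means$animal_id <- means$group
  means$time_h <- 0
  means <- normalize_units(means)
  dt <- data.table::as.data.table(means)
  ss <- dt[, list(mean_concentration = mean(concentration),
                  mean_enrichment = mean(enrichment_frac)),
           by = c("animal_id", "group", "site", "analyte")]
  w <- ss_to_wide(as.data.frame(ss))
  w$pf <- pf[w$animal_id]
  out <- compute_kinetics_wide(w, precursor = precursor, recovery = recovery,
                               bicarb_rate = protocol$NaH13CO3$rate)
  out$flag_group_mean_input <- TRUE
  leuflux_warn("kinetics computed from group means: not equal to the mean of per-animal kinetics",
               "group_mean_input")
  out
}
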