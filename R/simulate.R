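# Forward simulation of the infusion study from ground-truth kinetics.
#
# A SimTruth fixes, per animal: plasma flow, arterial plateau concentrations
# and enrichments (leucine, KIC, CO2, plus arterial PAH and the venous CO2
# concentration), and the true fluxes {NB, Rd, T_net, Ox, P13}. Venous
# plateaus are the exact algebraic inverse of the tracer-balance equations,
# so analysing a noise-free simulation returns the truth. Time courses rise
# exponentially to plateau after each infusate starts (the primed-continuous
# design); noise is multiplicative Gaussian on concentrations and additive
# Gaussian on MPE, truncated at physical bounds.

#' Ground truth for one simulated animal
#'
#' Default parameter values reproduce the magnitudes of the worked-example
#' study ([demo_steady_state_means()], [demo_kinetics_means()]): arterial
#' plateaus from the published steady-state table, plasma flow back-solved
#' as arterial input / arterial concentration (control 1.29985, treatment
#' 1.75182 L/kg/h), and true fluxes from the published kinetic panel.
#'
#' @param group `"control"` or `"treatment"`; selects the default set.
#' @param plasma_flow L/kg/h. @param body_weight kg.
#' @param c_art Named arterial plateau concentrations: `leucine`, `KIC`
#'   (umol/L), `CO2` (umol/L), `PAH` (mg/L).
#' @param e_art Named arterial plateau enrichments (fractions): `leucine`,
#'   `KIC`, `CO2`.
#' @param c_ven_co2 Venous CO2 plateau concentration, umol/L.
#' @param fluxes Named true fluxes (umol/kg/h): `NB` (net uptake), `Rd`
#'   (utilization), `T_net` (net transamination), `Ox` (oxidation), `P13`
#'   (labeled KIC production, tracer umol/kg/h).
#' @param k_rise Named rise constants (1/h) of the exponential approach to
#'   plateau: `leucine`, `KIC`, `CO2`, `conc`.
#' @param noise List with `conc_cv` (relative SD of concentrations) and
#'   `mpe_sd_frac` (additive MPE SD as a fraction of the plateau MPE),
#'   each either a scalar or a per-analyte named vector. Defaults reflect
#'   the two instrument classes involved: 8% concentration CV and 10% MPE
#'   SD for the chromatographic leucine/KIC (and PAH) assays, 1% for the
#'   IRMS 13CO2 enrichment and total-CO2 measurements.
#' @param baseline_frac Pre-plateau concentration level as a fraction of the
#'   plateau (default 0.8); enrichment baselines are 0.
#' @return A `sim_truth` list.
#' @export
sim_truth <- function(group = c("control", "treatment"),
                      plasma_flow = NULL, body_weight = 20,
                      c_art = NULL, e_art = NULL, c_ven_co2 = NULL,
                      fluxes = NULL,
                      k_rise = c(leucine = 1.5, KIC = 1.2, CO2 = 3, conc = 1.5),
                      noise = list(conc_cv = c(leucine = 0.08, KIC = 0.08,
                                               CO2 = 0.01, PAH = 0.08),
                                   mpe_sd_frac = c(leucine = 0.10, KIC = 0.10,
                                                   CO2 = 0.01, PAH = 0)),
                      baseline_frac = 0.8) {
  group <- match.arg(group)
  defaults <- if (group == "control") {
    list(pf = 176.52 / 135.80,
         c_art = c(leucine = 135.80, KIC = 46.84, CO2 = 18640, PAH = 10),
         e_art = c(leucine = 0.0468, KIC = 0.0143, CO2 = 0.000290),
         c_ven_co2 = 22980,
         fluxes = c(NB = 14.90, Rd = 38.60, T_net = 2.44, Ox = 8.96,
                    P13 = 0.1123))
  } else {
    list(pf = 329.01 / 187.81,
         c_art = c(leucine = 187.81, KIC = 64.88, CO2 = 18620, PAH = 10),
         e_art = c(leucine = 0.0641, KIC = 0.0210, CO2 = 0.000333),
         c_ven_co2 = 20700,
         fluxes = c(NB = 57.35, Rd = 106.26, T_net = 14.38, Ox = 17.06,
                    P13 = 0.7341))
  }
  truth <- list(
    group = group,
    plasma_flow = if (is.null(plasma_flow)) defaults$pf else plasma_flow,
    body_weight = body_weight,
    c_art = if (is.null(c_art)) defaults$c_art else c_art,
    e_art = if (is.null(e_art)) defaults$e_art else e_art,
    c_ven_co2 = if (is.null(c_ven_co2)) defaults$c_ven_co2 else c_ven_co2,
    fluxes = if (is.null(fluxes)) defaults$fluxes else fluxes,
    k_rise = k_rise, noise = noise, baseline_frac = baseline_frac)
  validate_truth(truth)
  structure(truth, class = "sim_truth")
}

validate_truth <- function(truth) {
  if (any(truth$c_art <= 0) || truth$c_ven_co2 <= 0 || truth$plasma_flow <= 0) {
    leuflux_abort("plateau concentrations and plasma flow must be positive",
                  "infeasible_truth")
  }
  if (any(truth$e_art <= 0 | truth$e_art >= 1)) {
    leuflux_abort("arterial enrichments must be fractions in (0, 1)",
                  "infeasible_truth")
  }
  invisible(truth)
}

#' Derived true flux panel for a simulated animal
#'
#' Expands a [sim_truth()] into the full eight-flux panel (plus tracer
#' fluxes and plasma flow) implied by the tracer-balance identities.
#'
#' @param truth A `sim_truth`.
#' @return One-row data.frame.
#' @export
truth_panel <- function(truth) {
  f <- truth$fluxes
  ra_in <- truth$c_art[["leucine"]] * truth$plasma_flow
  pd <- f[["Rd"]] - f[["NB"]]
  ps <- f[["Rd"]] - f[["Ox"]] - f[["T_net"]]
  data.frame(
    plasma_flow = truth$plasma_flow,
    arterial_input = ra_in, net_uptake = f[["NB"]], utilization = f[["Rd"]],
    net_transamination = f[["T_net"]], oxidation = f[["Ox"]],
    protein_synthesis = ps, protein_degradation = pd,
    protein_deposition = ps - pd,
    leu13_uptake = f[["Rd"]] * truth$e_art[["leucine"]],
    kic13_production = f[["P13"]])
}

#' Invert ground-truth fluxes to venous plateau values
#'
#' The exact algebraic inverse of the tracer-balance model: venous
#' concentrations and enrichments such that the analysis recovers the true
#' fluxes. With PF the plasma flow and arterial plateaus fixed:
#' `c_ven = c_art - NB/PF`; `e_ven = (c_art e_art - Rd e_art / PF) / c_ven`;
#' `c_ven_kic = c_art_kic + T_net/PF`;
#' `e_ven_kic = (c_art_kic e_art_kic + P13/PF) / c_ven_kic`; and the venous
#' CO2 enrichment places the labeled CO2 release implied by `Ox` under the
#' configured precursor convention. Venous PAH follows from the indicator
#' dilution at the configured infusion rate.
#'
#' @param truth A [sim_truth()].
#' @param protocol [infusion_protocol()] (for the PAH infusion rate).
#' @param precursor Oxidation precursor convention the analysis will use.
#' @param recovery Fractional 13CO2 recovery assumed by the analysis.
#' @return Named list with `c_ven` (leucine, KIC, CO2, PAH) and `e_ven`
#'   (leucine, KIC, CO2), fractions.
#' @export
invert_truth_to_venous <- function(truth, protocol = infusion_protocol(),
                                   precursor = c("venous_kic", "arterial_leucine"),
                                   recovery = 1) {
  precursor <- match.arg(precursor)
  validate_truth(truth)
  pf <- truth$plasma_flow
  f <- truth$fluxes
  ca <- truth$c_art; ea <- truth$e_art

  c_ven_leu <- ca[["leucine"]] - f[["NB"]] / pf
  if (c_ven_leu <= 0) {
    leuflux_abort("net uptake exceeds arterial delivery: venous leucine would be <= 0",
                  "infeasible_truth")
  }
  u13 <- f[["Rd"]] * ea[["leucine"]]
  e_ven_leu <- (ca[["leucine"]] * ea[["leucine"]] - u13 / pf) / c_ven_leu
  c_ven_kic <- ca[["KIC"]] + f[["T_net"]] / pf
  if (c_ven_kic <= 0) {
    leuflux_abort("net KIC uptake exceeds arterial delivery", "infeasible_truth")
  }
  e_ven_kic <- (ca[["KIC"]] * ea[["KIC"]] + f[["P13"]] / pf) / c_ven_kic
  e_prec <- switch(precursor, venous_kic = e_ven_kic,
                   arterial_leucine = ea[["leucine"]])
  if (e_prec <= 0) {
    leuflux_abort("precursor enrichment is not positive", "infeasible_truth")
  }
  f13co2 <- f[["Ox"]] * e_prec * recovery
  e_ven_co2 <- (truth$c_art[["CO2"]] * ea[["CO2"]] + f13co2 / pf) / truth$c_ven_co2
  c_ven_pah <- ca[["PAH"]] +
    pah_infusion_mg_h(protocol) / (pf * truth$body_weight)

  e_ven <- c(leucine = e_ven_leu, KIC = e_ven_kic, CO2 = e_ven_co2)
  if (any(e_ven < 0 | e_ven >= 1)) {
    leuflux_abort("inverted venous enrichment outside [0, 1): infeasible truth",
                  "infeasible_truth")
  }
  list(c_ven = c(leucine = c_ven_leu, KIC = c_ven_kic, CO2 = truth$c_ven_co2,
                 PAH = c_ven_pah),
       e_ven = e_ven)
}

# Exponential approach to plateau; start_h is the infusate start, baseline
# the pre-infusion value.
rise_curve <- function(t, plateau, k, start_h, baseline = 0) {
  ifelse(t <= start_h, baseline,
         baseline + (plateau - baseline) * (1 - exp(-k * (t - start_h))))
}

# Long-format noise-free expectation for one animal; returns the building
# blocks shared by simulate_animal() and the vectorized cohort simulator.
expected_series <- function(truth, ven, protocol, times) {
  leu_w <- protocol$leucine_1_13C$window
  bic_w <- protocol$NaH13CO3$window
  grid <- expand.grid(site = .sites, time_h = times,
                      analyte = c("leucine", "KIC", "CO2", "PAH"),
                      stringsAsFactors = FALSE)
  conc_plat <- ifelse(grid$site == "artery",
                      truth$c_art[grid$analyte], ven$c_ven[grid$analyte])
  e_plat <- ifelse(grid$analyte == "PAH", NA_real_,
                   ifelse(grid$site == "artery",
                          truth$e_art[grid$analyte], ven$e_ven[grid$analyte]))
  kr <- truth$k_rise
  # concentrations: feeding-driven rise from baseline_frac * plateau from 0 h;
  # CO2 and PAH pools are at steady state throughout
  conc <- ifelse(grid$analyte %in% c("CO2", "PAH"), conc_plat,
                 rise_curve(grid$time_h, conc_plat, kr[["conc"]], 0,
                            truth$baseline_frac * conc_plat))
  # enrichments: rise after the infusate start; CO2 decays after the
  # bicarbonate window toward a leucine-oxidation-supported level
  e_start <- ifelse(grid$analyte == "CO2", bic_w[1], leu_w[1])
  enrich <- rise_curve(grid$time_h, e_plat, kr[ifelse(grid$analyte == "PAH",
                                                      "conc", grid$analyte)],
                       e_start)
  co2_after <- grid$analyte == "CO2" & grid$time_h > bic_w[2]
  if (any(co2_after)) {
    at_end <- e_plat[co2_after] * (1 - exp(-kr[["CO2"]] * (bic_w[2] - bic_w[1])))
    floor_e <- 0.3 * e_plat[co2_after]
    enrich[co2_after] <- floor_e +
      (at_end - floor_e) * exp(-kr[["CO2"]] * (grid$time_h[co2_after] - bic_w[2]))
  }
  grid$conc <- conc
  grid$enrich <- enrich
  grid
}

#' Simulate one animal's sample records
#'
#' Forward-simulates the infusion protocol for a single animal: each
#' analyte/site series approaches its plateau exponentially after its
#' infusate starts, with multiplicative Gaussian noise on concentrations
#' (truncated at 0) and additive Gaussian noise on MPE (truncated to
#' `[0, 100)`). Uses the current RNG state; seed at the cohort level for
#' reproducibility. CO2 concentrations are emitted in mmol/L and PAH in
#' mg/L, as assays report them.
#'
#' @param truth A [sim_truth()].
#' @param protocol [infusion_protocol()].
#' @param times Sampling times (h), default hourly 0-8.
#' @param animal_id,group Identifiers stamped on the records.
#' @inheritParams invert_truth_to_venous
#' @param noise_scale Multiplier on both noise SDs (0 = noise-free).
#' @return Long-format sample table in the dialect [read_samples()] reads.
#' @export
simulate_animal <- function(truth, protocol = infusion_protocol(),
                            times = 0:8, animal_id = "pig1",
                            group = truth$group,
                            precursor = c("venous_kic", "arterial_leucine"),
                            recovery = 1, noise_scale = 1) {
  precursor <- match.arg(precursor)
  if (any(diff(times) <= 0)) {
    leuflux_abort("sampling times must be strictly increasing", "format")
  }
  win <- range(protocol$PAH$window, protocol$NaH13CO3$window,
               protocol$leucine_1_13C$window)
  if (any(times > win[2])) {
    leuflux_warn("sampling times extend beyond the protocol window; plateau values persist",
                 "times_outside_protocol")
  }
  ven <- invert_truth_to_venous(truth, protocol, precursor, recovery)
  g <- expected_series(truth, ven, protocol, times)
  n <- nrow(g)
  per_analyte <- function(x) {
    if (length(x) == 1 && is.null(names(x))) rep(x, n) else {
      out <- unname(x[g$analyte])
      out[is.na(out)] <- 0
      out
    }
  }
  cv <- per_analyte(truth$noise$conc_cv) * noise_scale
  mpe_sdf <- per_analyte(truth$noise$mpe_sd_frac) * noise_scale
  conc <- pmax(g$conc * (1 + cv * rnorm(n)), 0)
  mpe <- 100 * g$enrich
  mpe_plat <- 100 * ifelse(g$site == "artery", truth$e_art[g$analyte],
                           ven$e_ven[g$analyte])
  mpe <- mpe + mpe_sdf * mpe_plat * rnorm(n)
  mpe <- pmin(pmax(mpe, 0), 100 - 1e-9)
  mpe[g$analyte == "PAH"] <- NA_real_
  is_co2 <- g$analyte == "CO2"
  data.frame(
    animal_id = animal_id, group = group, site = g$site, time_h = g$time_h,
    analyte = g$analyte,
    concentration = ifelse(is_co2, conc / 1000, conc),
    conc_unit = ifelse(is_co2, "mmol/L",
                       ifelse(g$analyte == "PAH", "mg/L", "umol/L")),
    enrichment_mpe = mpe, stringsAsFactors = FALSE)
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the worked-example study design: two diet groups of six
#' pigs, hourly arterial/venous sampling 0-8 h, bicarbonate phase 0-2 h and
#' leucine phase 2-8 h, group truths at the published magnitudes. Animals
#' within a group vary around the group truth by a truncated log-normal
#' factor (`between_animal_cv`, default 0.25, truncated at +/- 2 SD) applied
#' to flows, plateaus and fluxes, which reproduces published pooled-SEM
#' magnitudes; assay noise comes on top via the truth's noise model.
#'
#' @param n_per_group Animals per group (>= 2).
#' @param groups Named list of group [sim_truth()]s; defaults to the
#'   control/treatment pair. A null configuration reuses the control truth
#'   for both groups.
#' @param times Sampling times (h).
#' @param seed Integer seed; every simulation from this config is
#'   reproducible.
#' @param between_animal_cv Coefficient of variation of the per-animal
#'   truth jitter (0 disables it).
#' @param noise_scale Multiplier on assay noise SDs (0 = noise-free).
#' @return A `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(n_per_group = 6,
                              groups = list(control = sim_truth("control"),
                                            treatment = sim_truth("treatment")),
                              times = 0:8, seed = 1,
                              between_animal_cv = 0.25, noise_scale = 1) {
  if (n_per_group < 2) {
    leuflux_abort("n_per_group must be at least 2", "config")
  }
  if (any(diff(times) <= 0)) {
    leuflux_abort("sampling times must be strictly increasing", "config")
  }
  structure(list(n_per_group = n_per_group, groups = groups, times = times,
                 seed = seed, between_animal_cv = between_animal_cv,
                 noise_scale = noise_scale),
            class = "sim_cohort_config")
}

# Truncated log-normal jitter with unit mean (approximately): multiplier
# exp(sdlog * z) with |z| <= 2.
jitter_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  z <- pmin(pmax(rnorm(n), -2), 2)
  exp(sdlog * z - sdlog^2 / 2)
}

# Per-animal truth drawn around a group truth.
draw_animal_truth <- function(group_truth, cv) {
  t2 <- group_truth
  t2$plasma_flow <- group_truth$plasma_flow * jitter_factor(1, cv)
  t2$c_art <- group_truth$c_art * jitter_factor(length(group_truth$c_art), cv)
  t2$e_art <- pmin(group_truth$e_art * jitter_factor(length(group_truth$e_art), cv),
                   0.99)
  t2$c_ven_co2 <- group_truth$c_ven_co2 * jitter_factor(1, cv)
  t2$fluxes <- group_truth$fluxes * jitter_factor(length(group_truth$fluxes), cv)
  # feasibility guard: disposal cannot exceed 90% of arterial delivery
  cap <- 0.9 * t2$c_art[["leucine"]] * t2$plasma_flow
  if (t2$fluxes[["Rd"]] > cap) t2$fluxes[["Rd"]] <- cap
  t2
}

#' Simulate a full cohort
#'
#' Draws per-animal truths around each group truth, forward-simulates every
#' animal's sample records, and returns the sample table together with the
#' animal metadata and the ground-truth registry used for recovery scoring.
#' Deterministic: identical config (including seed) gives byte-identical
#' tables.
#'
#' @param config A [sim_cohort_config()].
#' @param protocol [infusion_protocol()].
#' @inheritParams invert_truth_to_venous
#' @return List with `samples` (long sample table), `animals` (`animal_id`,
#'   `group`, `body_weight_kg`) and `truth` (per-animal true flux panel).
#' @export
simulate_cohort <- function(config = sim_cohort_config(),
                            protocol = infusion_protocol(),
                            precursor = c("venous_kic", "arterial_leucine"),
                            recovery = 1) {
  precursor <- match.arg(precursor)
  set.seed(config$seed)
  samples <- vector("list", config$n_per_group * length(config$groups))
  truth_rows <- vector("list", length(samples))
  animals <- vector("list", length(samples))
  i <- 0
  for (gname in names(config$groups)) {
    gtruth <- config$groups[[gname]]
    for (a in seq_len(config$n_per_group)) {
      i <- i + 1
      id <- sprintf("%s_%02d", gname, a)
      truth_i <- draw_animal_truth(gtruth, config$between_animal_cv)
      samples[[i]] <- simulate_animal(truth_i, protocol, config$times,
                                      animal_id = id, group = gname,
                                      precursor = precursor,
                                      recovery = recovery,
                                      noise_scale = config$noise_scale)
      truth_rows[[i]] <- cbind(animal_id = id, group = gname,
                               truth_panel(truth_i))
      animals[[i]] <- data.frame(animal_id = id, group = gname,
                                 body_weight_kg = truth_i$body_weight,
                                 stringsAsFactors = FALSE)
    }
  }
  list(samples = do.call(rbind, samples),
       animals = do.call(rbind, animals),
       truth = do.call(rbind, truth_rows))
}

#' Parameter-recovery report
#'
#' Scores pipeline estimates against a ground-truth registry: bias, relative
#' bias and RMSE per flux, over matched animals.
#'
#' @param truth Ground-truth registry (`truth` from [simulate_cohort()]).
#' @param estimates Per-animal kinetics table ([analyze_cohort()]).
#' @param variables Fluxes to score; defaults to the eight-panel plus tracer
#'   fluxes and plasma flow.
#' @return data.frame: `variable`, `truth_mean`, `bias`, `rel_bias`, `rmse`,
#'   `n`.
#' @export
recovery_report <- function(truth, estimates, variables = NULL) {
  if (is.null(variables)) {
    variables <- c("plasma_flow", "arterial_input", "net_uptake", "utilization",
                   "net_transamination", "oxidation", "protein_synthesis",
                   "protein_degradation", "protein_deposition",
                   "leu13_uptake", "kic13_production")
    variables <- intersect(variables, intersect(names(truth), names(estimates)))
  }
  m <- merge(truth, estimates, by = "animal_id",
             suffixes = c("_truth", "_est"))
  if (nrow(m) != nrow(truth) || nrow(m) != nrow(estimates)) {
    leuflux_abort("animal ids in truth and estimates do not align", "alignment")
  }
  rows <- lapply(variables, function(v) {
    tr <- m[[paste0(v, "_truth")]]
    es <- m[[paste0(v, "_est")]]
    err <- es - tr
    data.frame(variable = v, truth_mean = mean(tr), bias = mean(err),
               rel_bias = mean(err) / mean(tr), rmse = sqrt(mean(err^2)),
               n = length(err), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
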