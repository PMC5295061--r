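# Shared fixtures: property-based truth sampler and fast-rise settings.
#
# Fast rise constants put the last-3-h (leucine/KIC) and 2-h (CO2) windows
# >= ~28 time constants past the infusate start, so the sampled plateau is
# the asymptote to double precision and forward-then-analyze is an exact
# algebraic round trip.
fast_rise <- c(leucine = 8, KIC = 8, CO2 = 15, conc = 8)

# Draw a random feasible ground truth. Ranges span both dietary groups of
# the emulated design with generous margins; rise constants keep sampling
# windows at plateau (see above).
random_truth <- function(group = "control") {
  pf <- runif(1, 0.8, 2.5)
  c_art <- c(leucine = runif(1, 80, 250), KIC = runif(1, 30, 90),
             CO2 = runif(1, 12000, 30000), PAH = runif(1, 5, 20))
  e_art <- c(leucine = runif(1, 0.02, 0.09), KIC = runif(1, 0.008, 0.03),
             CO2 = runif(1, 1e-4, 6e-4))
  ra_in <- c_art[["leucine"]] * pf
  rd <- runif(1, 0.1, 0.6) * ra_in
  nb <- runif(1, -0.2, 0.9) * rd            # net release allowed
  t_net <- runif(1, -0.1, 0.3) * rd
  ox <- runif(1, 0.05, 0.5) * rd
  p13 <- runif(1, 0.01, 0.1) * rd * e_art[["leucine"]]
  sim_truth(group,
            plasma_flow = pf, body_weight = runif(1, 15, 25),
            c_art = c_art, e_art = e_art,
            c_ven_co2 = runif(1, 15000, 30000),
            fluxes = c(NB = nb, Rd = rd, T_net = t_net, Ox = ox, P13 = p13),
            k_rise = c(leucine = runif(1, 7, 10), KIC = runif(1, 7, 10),
                       CO2 = runif(1, 14, 18), conc = runif(1, 7, 10)))
}

# Noise-free cohort config at fast rise for exact end-to-end checks.
exact_config <- function(n_per_group = 3, seed = 1) {
  sim_cohort_config(
    n_per_group = n_per_group,
    groups = list(control = sim_truth("control", k_rise = fast_rise),
                  treatment = sim_truth("treatment", k_rise = fast_rise)),
    seed = seed, between_animal_cv = 0, noise_scale = 0)
}

expect_leuflux_error <- function(expr, type) {
  expect_error(expr, class = paste0("leuflux_", type))
}
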