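# Forward simulator and parameter recovery.

test_that("truth inversion reduces to arterial values when nothing is exchanged", {
  truth <- sim_truth("control",
                     fluxes = c(NB = 0, Rd = 0, T_net = 0, Ox = 0, P13 = 0))
  ven <- invert_truth_to_venous(truth)
  expect_equal(ven$c_ven[["leucine"]], truth$c_art[["leucine"]])
  expect_equal(ven$e_ven[["leucine"]], truth$e_art[["leucine"]])
  expect_equal(ven$c_ven[["KIC"]], truth$c_art[["KIC"]])
  expect_equal(ven$e_ven[["KIC"]], truth$e_art[["KIC"]])
  expect_equal(ven$e_ven[["CO2"]],
               truth$c_art[["CO2"]] * truth$e_art[["CO2"]] / truth$c_ven_co2)
})

test_that("complete tracer extraction puts venous enrichment at zero", {
  truth <- sim_truth("control")
  # Rd e_a / PF = c_a e_a  <=>  Rd = c_a PF: every labeled molecule extracted
  truth$fluxes[["Rd"]] <- truth$c_art[["leucine"]] * truth$plasma_flow
  ven <- invert_truth_to_venous(truth)
  expect_equal(ven$e_ven[["leucine"]], 0, tolerance = 1e-12)
})

test_that("infeasible truths are rejected", {
  truth <- sim_truth("control")
  truth$fluxes[["NB"]] <- truth$c_art[["leucine"]] * truth$plasma_flow * 1.1
  expect_leuflux_error(invert_truth_to_venous(truth), "infeasible_truth")
  truth2 <- sim_truth("control")
  truth2$fluxes[["Rd"]] <- truth2$c_art[["leucine"]] * truth2$plasma_flow * 1.5
  expect_leuflux_error(invert_truth_to_venous(truth2), "infeasible_truth")
})

test_that("noise-free series reach plateau with the exponential remainder", {
  truth <- sim_truth("control", k_rise = c(leucine = 4, KIC = 4, CO2 = 4, conc = 4))
  rec <- simulate_animal(truth, times = 0:8, noise_scale = 0)
  ven <- invert_truth_to_venous(truth)
  # leucine enrichment at 5-8 h after a 2-h start with k = 4/h: within 1e-5
  art <- rec[rec$analyte == "leucine" & rec$site == "artery", ]
  late <- art$enrichment_mpe[art$time_h >= 7] / 100
  expect_equal(late, rep(truth$e_art[["leucine"]], length(late)),
               tolerance = 1e-6)
  p <- last_k_plateau(art$enrichment_mpe / 100, k = 3,
                      times = art$time_h)
  expect_equal(p$mean, truth$e_art[["leucine"]], tolerance = 1e-6)
  # before the leucine infusate starts there is no enrichment
  expect_true(all(art$enrichment_mpe[art$time_h <= 2] == 0))
  # venous PAH sits above arterial by the dilution offset
  pah <- rec[rec$analyte == "PAH", ]
  expect_true(all(pah$concentration[pah$site == "vein"] >
                    pah$concentration[pah$site == "artery"]))
  expect_equal(unique(pah$concentration[pah$site == "vein"]),
               ven$c_ven[["PAH"]], tolerance = 1e-12)
})

test_that("simulation is deterministic given the config seed", {
  cfg <- sim_cohort_config(n_per_group = 3, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  cfg2 <- sim_cohort_config(n_per_group = 3, seed = 124)
  expect_false(identical(simulate_cohort(cfg2)$samples, a$samples))
})

test_that("config validation rejects degenerate designs", {
  expect_leuflux_error(sim_cohort_config(n_per_group = 1), "config")
  expect_leuflux_error(sim_cohort_config(times = c(0, 2, 2, 3)), "config")
})

test_that("forward-then-analyze is the identity at zero noise (property)", {
  set.seed(2024)
  for (i in 1:50) {
    truth <- random_truth()
    rec <- simulate_animal(truth, times = 0:8, animal_id = "px", noise_scale = 0)
    kin <- analyze_animal(summarize_steady_state(rec), pf = truth$plasma_flow)
    want <- truth_panel(truth)
    for (v in names(want)) {
      expect_equal(kin[[v]], want[[v]], tolerance = 1e-9,
                   label = sprintf("%s (draw %d)", v, i))
    }
  }
})

test_that("recovery report scores bias and alignment", {
  sim <- simulate_cohort(exact_config(n_per_group = 3, seed = 5))
  kin <- suppressWarnings(analyze_cohort(sim$samples, sim$animals))
  rep0 <- recovery_report(sim$truth, kin)
  expect_true(all(abs(rep0$bias) < 1e-9))
  expect_true(all(abs(rep0$rmse) < 1e-9))
  # estimates shifted by a constant show exactly that bias
  shifted <- kin
  for (v in rep0$variable) shifted[[v]] <- shifted[[v]] + 2.5
  rep_s <- recovery_report(sim$truth, shifted, variables = rep0$variable)
  expect_equal(rep_s$bias, rep(2.5, nrow(rep_s)), tolerance = 1e-9)
  # id mismatch is an alignment error
  bad <- kin
  bad$animal_id[1] <- "intruder"
  expect_leuflux_error(recovery_report(sim$truth, bad), "alignment")
})

test_that("recovery RMSE is non-decreasing in the noise level", {
  scales <- c(0.25, 1, 3)
  rmse <- sapply(scales, function(s) {
    per_rep <- sapply(1:60, function(r) {
      # common random numbers across scales: same seed, noise scaled
      sim <- simulate_cohort(sim_cohort_config(n_per_group = 4, seed = r,
                                               noise_scale = s))
      kin <- suppressWarnings(analyze_cohort(sim$samples, sim$animals))
      rep <- recovery_report(sim$truth, kin)
      rep$rmse[rep$variable %in% c("net_uptake", "utilization")]
    })
    rowMeans(per_rep)
  })
  expect_true(all(diff(rmse[1, ]) > 0))   # net uptake
  expect_true(all(diff(rmse[2, ]) > 0))   # utilization
})

test_that("simulated group spreads sit near the emulated study's pooled SEMs", {
  # pooled SEM (SE of the difference) of the simulated fluxes should be
  # within about 2x of the published magnitudes the generator emulates
  sems <- sapply(1:40, function(r) {
    sim <- simulate_cohort(sim_cohort_config(seed = r))
    kin <- suppressWarnings(analyze_cohort(sim$samples, sim$animals))
    rep <- suppressWarnings(group_report(kin))
    setNames(rep$pooled_sem, rep$variable)
  })
  km <- demo_kinetics_means()
  got <- rowMeans(sems)[km$variable]
  ratio <- got / km$pooled_sem
  expect_true(all(ratio > 0.4 & ratio < 2.5),
              info = paste(names(got), round(ratio, 2), collapse = "; "))
})
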