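# The AV tracer-balance flux panel.

pf_c <- 176.52 / 135.80   # flow implied by the worked-example control group

test_that("individual flux operations match hand arithmetic", {
  expect_equal(arterial_input(100, 2.0), 200)
  expect_equal(arterial_input(0, 3), 0)
  expect_equal(arterial_input(135.80, 1.2999), 176.53, tolerance = 1e-4)

  expect_equal(as.numeric(net_uptake(100, 80, 1.0)), 20)
  expect_equal(as.numeric(net_uptake(55, 55, 1.7)), 0)
  expect_equal(as.numeric(net_uptake(135.80, 124.67, 1.2999)), 14.47,
               tolerance = 1e-3)

  expect_equal(tracer_leucine_uptake(100, 0, 80, 0, 1.3), 0)
  e <- 0.05
  expect_equal(tracer_leucine_uptake(100, e, 80, e, 1.2),
               e * as.numeric(net_uptake(100, 80, 1.2)))
  expect_equal(tracer_leucine_uptake(135.80, 0.0468, 124.67, 0.0394, 1.2999),
               1.876, tolerance = 1e-3)

  expect_equal(utilization(100, 0.05, 80, 0.04, 1.0), 36)
  # equal enrichments on both sides: no dilution, Rd equals net uptake
  expect_equal(utilization(100, 0.05, 80, 0.05, 1.4),
               as.numeric(net_uptake(100, 80, 1.4)))
  expect_equal(utilization(135.80, 0.0468, 124.67, 0.0394, 1.2999), 40.09,
               tolerance = 1e-3)
  expect_leuflux_error(utilization(100, 0, 80, 0, 1), "division_guard")

  expect_equal(protein_degradation(106.26, 57.35), 48.91)
  expect_equal(protein_degradation(36, 36), 0)
  expect_equal(protein_degradation(38.60, 14.90), 23.70)

  expect_equal(net_transamination(50, 50, 1.1), 0)
  expect_equal(net_transamination(50, 60, 1.0), 10)
  expect_equal(net_transamination(46.84, 47.86, 1.2999), 1.33, tolerance = 1e-2)

  expect_equal(kic13_production(40, 0, 50, 0, 1.2), 0)
  expect_equal(kic13_production(50, 0.02, 40, 0.025, 1.5), 0)  # equal content
  expect_equal(kic13_production(46.84, 0.0143, 47.86, 0.0158, 1.2999),
               0.1123, tolerance = 1e-3)

  expect_equal(oxidation(0, 0.02, 1), 0)
  expect_equal(oxidation(1.0, 0.02, 1), 50)
  expect_equal(oxidation(0.7100, 0.0158, 1), 44.94, tolerance = 1e-3)
  expect_leuflux_error(oxidation(1, 0), "division_guard")
  expect_leuflux_error(oxidation(1, 0.02, recovery = 0), "format")
  # recovery correction scales inversely
  expect_equal(oxidation(1.0, 0.02, recovery = 0.5), 100)

  expect_equal(protein_synthesis(106.26, 17.06, 14.38), 74.82)
  expect_equal(protein_synthesis(40, 0, 0), 40)
  expect_equal(protein_synthesis(38.60, 8.96, 2.44), 27.20)

  expect_equal(protein_deposition(27.21, 23.71), 3.50)
  expect_equal(protein_deposition(74.82, 48.91), 25.91)
  expect_equal(protein_deposition(12.3, 12.3), 0)
})

test_that("balance identities hold exactly on any panel and on printed means", {
  # property: random panels built from the primitive operations
  set.seed(42)
  for (i in 1:50) {
    pf <- runif(1, 0.5, 3)
    ca <- runif(1, 80, 250); cv <- runif(1, 60, 240)
    ea <- runif(1, 0.02, 0.09); ev <- runif(1, 0.01, 0.09)
    ka <- runif(1, 30, 90); kv <- runif(1, 30, 95)
    eka <- runif(1, 0.008, 0.03); ekv <- runif(1, 0.008, 0.035)
    ox <- runif(1, 0, 30)
    rd <- utilization(ca, ea, cv, ev, pf)
    nb <- as.numeric(net_uptake(ca, cv, pf))
    tn <- net_transamination(ka, kv, pf)
    pd <- protein_degradation(rd, nb)
    ps <- protein_synthesis(rd, ox, tn)
    pdep <- protein_deposition(ps, pd)
    expect_equal(pdep, ps - pd, tolerance = 1e-9)
    expect_equal(pd, rd - nb, tolerance = 1e-9)
    expect_equal(rd, ps + ox + tn, tolerance = 1e-9)
    expect_equal(pdep, nb - ox - tn, tolerance = 1e-9)
  }
  # the published group-mean panel satisfies them to its printed rounding
  km <- demo_kinetics_means()
  g <- function(v, col) km[km$variable == v, col]
  for (col in c("control", "treatment")) {
    expect_equal(g("protein_deposition", col),
                 g("protein_synthesis", col) - g("protein_degradation", col),
                 tolerance = 0.011)
    expect_equal(g("protein_degradation", col),
                 g("utilization", col) - g("net_uptake", col),
                 tolerance = 0.011)
    expect_equal(g("protein_synthesis", col),
                 g("utilization", col) - g("oxidation", col) -
                   g("net_transamination", col),
                 tolerance = 0.011)
  }
})

test_that("all fluxes scale linearly with plasma flow", {
  ca <- 135.8; cv <- 124.67; ea <- 0.0468; ev <- 0.0394
  for (s in c(0.5, 2, 3.7)) {
    expect_equal(utilization(ca, ea, cv, ev, pf_c * s),
                 s * utilization(ca, ea, cv, ev, pf_c))
    expect_equal(as.numeric(net_uptake(ca, cv, pf_c * s)),
                 s * as.numeric(net_uptake(ca, cv, pf_c)))
    expect_equal(net_transamination(46.84, 47.86, pf_c * s),
                 s * net_transamination(46.84, 47.86, pf_c))
  }
})

test_that("partition fractions sum to 100 and match the worked example", {
  km <- demo_kinetics_means()
  panel <- function(col) {
    v <- setNames(km[[col]], km$variable)
    as.list(v)
  }
  fr_c <- partition_fractions(panel("control"))
  fr_t <- partition_fractions(panel("treatment"))
  expect_equal(round(fr_c$utilization_of_input), 22)
  expect_equal(round(fr_t$synthesis_of_utilization, -1), 70)
  expect_equal(round(fr_c$synthesis_of_utilization, -1), 70)
  # printed panels carry 0.01-level rounding, so the three fractions sum to
  # 100 only to that precision ...
  expect_equal(fr_c$synthesis_of_utilization + fr_c$transamination_of_utilization +
                 fr_c$oxidation_of_utilization, 100, tolerance = 5e-4)
  expect_equal(fr_t$synthesis_of_utilization + fr_t$transamination_of_utilization +
                 fr_t$oxidation_of_utilization, 100, tolerance = 5e-4)
  # ... and exactly when synthesis is derived from the balance identity
  set.seed(9)
  for (i in 1:20) {
    rd <- runif(1, 10, 120); ox <- runif(1, 0, 30); tn <- runif(1, -5, 15)
    k <- list(arterial_input = runif(1, 100, 400), utilization = rd,
              oxidation = ox, net_transamination = tn,
              protein_synthesis = protein_synthesis(rd, ox, tn))
    fr <- partition_fractions(k)
    expect_equal(fr$synthesis_of_utilization + fr$transamination_of_utilization +
                   fr$oxidation_of_utilization, 100, tolerance = 1e-9)
  }
  expect_leuflux_error(
    partition_fractions(list(arterial_input = 0, utilization = 10,
                             protein_synthesis = 7, net_transamination = 1,
                             oxidation = 2)),
    "division_guard")
})

test_that("analyze_animal recovers a known truth from noise-free records", {
  set.seed(101)
  truth <- random_truth()
  rec <- simulate_animal(truth, times = 0:8, animal_id = "px", noise_scale = 0)
  ss <- summarize_steady_state(rec)
  kin <- analyze_animal(ss, pf = truth$plasma_flow)
  want <- truth_panel(truth)
  for (v in c("arterial_input", "net_uptake", "utilization", "net_transamination",
              "oxidation", "protein_synthesis", "protein_degradation",
              "protein_deposition", "leu13_uptake", "kic13_production")) {
    expect_equal(kin[[v]], want[[v]], tolerance = 1e-9, label = v)
  }
})

test_that("analyze_animal names missing analyte/site cells", {
  set.seed(102)
  truth <- random_truth()
  rec <- simulate_animal(truth, times = 0:8, animal_id = "px", noise_scale = 0)
  rec <- rec[!(rec$analyte == "KIC" & rec$site == "vein"), ]
  ss <- summarize_steady_state(rec)
  err <- tryCatch(analyze_animal(ss, pf = truth$plasma_flow),
                  leuflux_incomplete_input = function(e) e)
  expect_s3_class(err, "leuflux_incomplete_input")
  expect_match(conditionMessage(err), "KIC@vein")
})

test_that("kinetics from group means are flagged as non-equivalent", {
  means <- demo_steady_state_means()
  expect_warning(
    kin <- kinetics_from_means(means,
                               pf = c(control = 176.52 / 135.80,
                                      treatment = 329.01 / 187.81)),
    class = "leuflux_group_mean_input")
  expect_true(all(kin$flag_group_mean_input))
  km <- demo_kinetics_means()
  # ratio of means does not reproduce the mean of per-animal ratios
  nb_means <- kin$net_uptake[kin$animal_id == "control"]
  expect_equal(nb_means, 14.47, tolerance = 1e-2)
  expect_gt(abs(nb_means - km$control[km$variable == "net_uptake"]), 0.1)
})
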