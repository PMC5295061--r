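# Group statistics.

test_that("pooled t-test handles identical and degenerate groups", {
  x <- c(1.2, 3.4, 2.2, 5.0)
  same <- students_t(x, x)
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  expect_warning(deg <- students_t(c(0, 0, 0), c(1, 1, 1)),
                 class = "leuflux_degenerate_sample")
  expect_true(deg$degenerate)
  flat <- students_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$p_value, 1)
  expect_leuflux_error(students_t(1, c(1, 2)), "format")
})

test_that("pooled t agrees with the base oracle and with the summary form", {
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(6, 10, 2)
    b <- rnorm(6, 11, 3)
    got <- students_t(a, b)
    ref <- t.test(b, a, var.equal = TRUE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    # round trip: summary-stat form from the raw samples (equal n)
    s <- t_from_summary(mean(a), sd(a) / sqrt(6), 6, mean(b), sd(b) / sqrt(6), 6)
    expect_equal(s$t_stat, got$t_stat, tolerance = 1e-12)
    expect_equal(s$p_value, got$p_value, tolerance = 1e-12)
  }
  a <- rnorm(6); b <- rnorm(8, sd = 4)
  got <- students_t(a, b, variant = "welch")
  ref <- t.test(b, a)
  expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
})

test_that("summary-statistic t behaves under scaling and equal means", {
  eq <- t_from_summary(5, 1, 6, 5, 1, 6)
  expect_equal(eq$t_stat, 0)
  expect_equal(eq$p_value, 1)
  one <- t_from_summary(30.5, 3.6, 6, 35.3, 2.8, 6)
  two <- t_from_summary(30.5, 7.2, 6, 35.3, 5.6, 6)
  expect_equal(two$t_stat, one$t_stat / 2, tolerance = 1e-12)
  expect_leuflux_error(t_from_summary(1, 0, 6, 2, 1, 6), "format")
})

test_that("the t-test holds its nominal size under the null", {
  set.seed(99)
  reps <- 10000
  a <- matrix(rnorm(reps * 6), reps)
  b <- matrix(rnorm(reps * 6), reps)
  p <- vapply(seq_len(reps), function(i) students_t(a[i, ], b[i, ])$p_value,
              numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.01)
})

test_that("Pearson matrix is symmetric, unit-diagonal and affine-invariant", {
  set.seed(7)
  tbl <- data.frame(a = rnorm(12), b = rnorm(12), c = rnorm(12))
  tbl$d <- tbl$a * 2 + rnorm(12, sd = 0.3)
  cm <- pearson_matrix(tbl)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_true(all(abs(cm$r) <= 1))
  # affine rescaling of any column leaves r unchanged
  tbl2 <- tbl
  tbl2$b <- -3 * tbl2$b + 17
  cm2 <- pearson_matrix(tbl2)
  expect_equal(abs(cm2$r), abs(cm$r), tolerance = 1e-12)
  expect_equal(cm2$r["a", "d"], cm$r["a", "d"], tolerance = 1e-12)
  # oracle: p-values agree with cor.test
  ct <- cor.test(tbl$a, tbl$d)
  expect_equal(cm$p["a", "d"], ct$p.value, tolerance = 1e-9)
  # collinear and anti-collinear pairs
  col_tbl <- data.frame(x = 1:8, y = 2 * (1:8) + 3, z = -(1:8))
  cmx <- pearson_matrix(col_tbl)
  expect_equal(cmx$r["x", "y"], 1)
  expect_equal(cmx$r["x", "z"], -1)
  expect_leuflux_error(pearson_matrix(data.frame(a = 1:5, b = rep(2, 5))),
                       "undefined_correlation")
  expect_leuflux_error(pearson_matrix(data.frame(a = 1:2, b = 2:1)), "format")
})

test_that("correlation recovery matches an analytic target in simulation", {
  # synthesis = degradation + independent noise: analytic correlation
  set.seed(21)
  n <- 12; reps <- 400
  sd_pd <- 10; sd_eps <- 6
  rho <- sd_pd / sqrt(sd_pd^2 + sd_eps^2)
  rs <- replicate(reps, {
    pd <- rnorm(n, 40, sd_pd)
    ps <- pd + rnorm(n, 5, sd_eps)
    pearson_matrix(data.frame(ps = ps, pd = pd))$r["ps", "pd"]
  })
  # mean recovered correlation (Fisher-z averaged) near the analytic value
  expect_lt(abs(tanh(mean(atanh(rs))) - rho), 0.05)
})

test_that("group report mirrors the two-group table layout", {
  sim <- simulate_cohort(sim_cohort_config(seed = 3))
  kin <- suppressWarnings(analyze_cohort(sim$samples, sim$animals))
  rep <- group_report(kin)
  expect_true(all(c("variable", "mean_control", "mean_treatment",
                    "pooled_sem", "p_value") %in% names(rep)))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1))
  expect_true(all(rep$df == 10))
  # pooled SEM is the SE of the difference: |t| = |diff| / SEM
  expect_equal(abs(rep$mean_treatment - rep$mean_control) / rep$pooled_sem,
               abs(rep$t_stat), tolerance = 1e-12)
})
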