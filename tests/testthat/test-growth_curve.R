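test_that("anchor scheme presets and validation", {
  e5 <- anchor_scheme("E500")
  expect_equal(e5$window_max, 625)
  expect_equal(e5$anchors, c(200, 300, 500))
  expect_equal(e5$r2_gate, 0.94)
  e8 <- anchor_scheme("E800")
  expect_equal(e8$anchors, c(300, 500, 800))
  expect_equal(e8$r2_gate, 0.95)
  expect_error(anchor_scheme("bogus"), class = "hc_config_error")
  expect_error(anchor_scheme("x", 500, c(100, 600), 0.9),
               class = "hc_config_error")
})

test_that("exact cubic data is reproduced perfectly", {
  tau <- c(100, 200, 300, 400, 500, 600)
  curve <- fit_growth_curve(tau, 2e-7 * tau^3, anchor_scheme("E500"))
  expect_equal(curve$r2, 1, tolerance = 1e-12)
  expect_lt(max(abs(curve$coefficients - c(0, 0, 0, 2e-7))), 1e-10)
  expect_true(curve$qc_pass)
  expect_true(curve$monotone_flag)
  anch <- anchor_sizes(curve, anchor_scheme("E500"))
  expect_equal(unname(anch["E_500"]), 25, tolerance = 1e-9)

  # cubic nests the straight line
  line <- fit_growth_curve(tau, 0.2 * tau, anchor_scheme("E500"))
  expect_equal(line$r2, 1, tolerance = 1e-12)
})

test_that("noisy fits match the brute-force normal-equation oracle", {
  set.seed(11)
  sch <- anchor_scheme("E800")
  for (i in 1:25) {
    tau <- sort(runif(12, 30, 880))
    y <- pmax(runif(1, 50, 200) * plogis(0.01 * (tau - 400)) + rnorm(12, 0, 2), 0)
    curve <- fit_growth_curve(tau, y, sch)
    oracle <- cubic_normal_equations(tau, y)
    expect_equal(curve$coefficients, oracle, tolerance = 1e-8)
    if (curve$qc_pass) {
      anch <- anchor_sizes(curve, sch)
      expect_equal(as.numeric(anch),
                   power_sum_poly(curve$coefficients, sch$anchors),
                   tolerance = 1e-12)
    }
  }
})

test_that("the window filter is applied and idempotent", {
  set.seed(3)
  tau <- seq(50, 880, by = 60)
  y <- 150 * plogis(0.01 * (tau - 400)) + rnorm(length(tau), 0, 1)
  sch <- anchor_scheme("E500")
  full <- fit_growth_curve(tau, y, sch)
  pre <- fit_growth_curve(tau[tau < 625], y[tau < 625], sch)
  expect_equal(full$coefficients, pre$coefficients)
  expect_equal(full$n_obs, sum(tau < 625))
})

test_that("fit preconditions raise typed errors", {
  sch <- anchor_scheme("E500")
  expect_error(fit_growth_curve(c(100, 200, 700), c(1, 2, 3), sch),
               class = "hc_insufficient_data")
  expect_error(fit_growth_curve(c(100, 200, 300, 400), rep(30, 4), sch),
               class = "hc_degenerate_error")
  expect_error(fit_growth_curve(c(-5, 100, 200, 300), c(1, 2, 3, 4), sch),
               class = "hc_domain_error")
})

test_that("gated curves refuse anchor evaluation; flat curves evaluate flat", {
  sch <- anchor_scheme("E500")
  gated <- structure(list(coefficients = c(1, 0, 0, 0), r2 = 0.5, n_obs = 6,
                          window_max = 625, qc_pass = FALSE,
                          monotone_flag = TRUE, min_tau = 100),
                     class = "growth_curve")
  expect_error(anchor_sizes(gated, sch), class = "hc_gated_error")

  flat <- gated
  flat$qc_pass <- TRUE
  flat$coefficients <- c(30, 0, 0, 0)
  flat$min_tau <- 400
  anch <- anchor_sizes(flat, sch)
  expect_equal(as.numeric(anch), c(30, 30, 30))
  expect_true(attr(anch, "nonincreasing"))
  # anchors at 200 and 300 precede the first observation at tau = 400
  expect_equal(attr(anch, "extrapolated"), c(TRUE, TRUE, FALSE))
})

test_that("raising the r2 gate never admits more fruits", {
  set.seed(9)
  n_pass <- sapply(c(0.5, 0.8, 0.94, 0.99, 0.999), function(gate) {
    sch <- anchor_scheme("g", window_max = 625, anchors = c(200, 300, 500),
                         r2_gate = gate)
    passes <- 0L
    for (i in 1:40) {
      set.seed(1000 + i)
      tau <- sort(runif(9, 60, 600))
      y <- pmax(140 * plogis(0.01 * (tau - 400)) + rnorm(9, 0, 6), 0)
      if (fit_growth_curve(tau, y, sch)$qc_pass) passes <- passes + 1L
    }
    passes
  })
  expect_true(all(diff(n_pass) <= 0))
})

test_that("anchor table reproduces noiseless simulated trajectories", {
  cohort <- simulate_cohort(sim_config_noiseless(n_fruits = 12, seed = 21))
  sch <- anchor_scheme("E500")
  dens <- lapply(split(cohort$calibration, cohort$calibration$cultivar),
                 function(d) calibrate_density(d$volume_cm3, d$mass_g))
  tbl <- anchor_table(cohort$measurements, cohort$temperature, dens, sch)
  expect_true(all(tbl$qc_pass))
  truth <- cohort$truth[match(tbl$fruit_id, cohort$truth$fruit_id), ]
  for (a in c(200, 300, 500)) {
    u <- a / 1100
    expected <- truth$asymptotic_mass_g * (3 * u^2 - 2 * u^3)
    expect_equal(tbl[[paste0("E_", a)]], expected, tolerance = 1e-9)
  }
  counts <- attr(tbl, "counts")
  expect_equal(counts$fruits_in, 36L)
  expect_equal(counts$excluded_r2_gate, 0L)
})

test_that("gate exclusions stay below 10% at realistic noise", {
  cohort <- simulate_cohort(sim_config(n_fruits = 80, seed = 14))
  dens <- lapply(split(cohort$calibration, cohort$calibration$cultivar),
                 function(d) calibrate_density(d$volume_cm3, d$mass_g))
  tbl <- anchor_table(cohort$measurements, cohort$temperature, dens,
                      anchor_scheme("E500"))
  expect_lt(attr(tbl, "counts")$gate_fraction, 0.10)
})
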