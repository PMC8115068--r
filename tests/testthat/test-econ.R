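test_that("scenario validation and documented defaults", {
  sc <- econ_scenario()
  expect_equal(sc$annual_saving, 39141 - 15086)   # 24055, not the rounded 24k
  expect_equal(sc$scan_cost, 3000)
  expect_equal(sc$prevalence, 0.33)
  expect_error(econ_scenario(prevalence = 1.2), "probabilities")
  expect_error(econ_scenario(scan_cost = -5), ">= 0")
})

test_that("econ_outcome closed form: boundary and homogeneity cases", {
  # nothing detected, nobody misclassified: only the scans are paid for
  out <- econ_outcome(econ_scenario(sensitivity = 0, specificity = 1))
  expect_equal(out$net_per_patient, -3000)
  expect_equal(out$tp + out$fp + out$tn + out$fn, 1000)
  # zero saving and zero treatment costs: net = -scan cost at any point
  for (se in c(0, 0.4, 1)) for (sp in c(0.2, 1)) {
    sc <- econ_scenario(annual_saving = 0, clozapine_annual_cost = 0,
                        neutropenia_cost = 0, sensitivity = se,
                        specificity = sp)
    expect_equal(econ_outcome(sc)$net_per_patient, -3000)
  }
  # per-capita homogeneity in cohort size
  a <- econ_outcome(econ_scenario(cohort_size = 1000, sensitivity = 0.6))
  b <- econ_outcome(econ_scenario(cohort_size = 2000, sensitivity = 0.6))
  expect_equal(a$net_per_patient, b$net_per_patient)
})

test_that("bisection breakeven equals the closed-form affine root", {
  sc <- econ_scenario()
  # net(s) is affine: root from two evaluations
  n0 <- econ_outcome(econ_scenario(sensitivity = 0))$net_per_patient
  n1 <- econ_outcome(econ_scenario(sensitivity = 1))$net_per_patient
  root <- -n0 / (n1 - n0)
  expect_equal(breakeven_sensitivity(sc), root, tolerance = 2e-6)
  # and matches a 1e4-point grid scan within grid resolution
  grid <- seq(0, 1, length.out = 10001)
  nets <- vapply(grid, function(s)
    econ_outcome(econ_scenario(sensitivity = s))$net_per_patient, 0)
  expect_lt(abs(breakeven_sensitivity(sc) - grid[which(nets >= 0)[1L]]), 1e-4)
})

test_that("breakeven edge cases", {
  # benefit identically zero, no per-positive costs: never breaks even
  expect_true(is.na(breakeven_sensitivity(
    econ_scenario(annual_saving = 0, clozapine_annual_cost = 0,
                  neutropenia_cost = 0))))
  # free scan, positive benefit, no treatment costs: breaks even immediately
  expect_equal(breakeven_sensitivity(
    econ_scenario(scan_cost = 0, clozapine_annual_cost = 0,
                  neutropenia_cost = 0, specificity = 1)), 0)
  # decreasing configuration directs the user to the surface scan
  expect_error(breakeven_sensitivity(
    econ_scenario(annual_saving = 0)), "not increasing")
})

test_that("savings surface is monotone in sensitivity and specificity", {
  surf <- savings_surface(econ_scenario(), seq(0, 1, by = 0.25),
                          seq(0, 1, by = 0.25))
  for (sp in unique(surf$specificity)) {
    v <- surf$net_per_patient[surf$specificity == sp]
    expect_true(all(diff(v) >= 0))      # increasing in sensitivity
  }
  for (se in unique(surf$sensitivity)) {
    v <- surf$net_per_patient[surf$sensitivity == se]
    expect_true(all(diff(v) >= 0))      # increasing in specificity
  }
  # all costs zero, positive benefit: proportional to sensitivity only
  sc0 <- econ_scenario(scan_cost = 0, clozapine_annual_cost = 0,
                       neutropenia_cost = 0)
  s2 <- savings_surface(sc0, c(0, 1), c(0, 1))
  expect_equal(s2$net_per_patient[s2$sensitivity == 0], c(0, 0))
  expect_equal(length(unique(s2$net_per_patient[s2$sensitivity == 1])), 1L)
})

test_that("a large false-positive penalty makes a chance-level test unfavourable", {
  sc <- econ_scenario(sensitivity = 0.5, specificity = 0.5,
                      false_positive_penalty = 1e5)
  expect_lt(econ_outcome(sc)$net_per_patient, 0)
})
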