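#' Screening-economics scenario
#'
#' Parameters of the illustrative model for biomarker-guided clozapine
#' fast-tracking: every patient in the cohort is scanned; patients the test
#' flags as non-responders start clozapine immediately instead of after the
#' current mean delay.  Each true positive who responds to clozapine
#' (probability `clozapine_response`) avoids `delay_years` of active
#' psychosis, saving `annual_saving` per year; every flagged patient incurs
#' clozapine treatment and monitoring costs for those years plus expected
#' neutropenia-management costs, and false positives may carry an extra
#' penalty (e.g. harm of unnecessary clozapine exposure).
#'
#' Defaults follow the published assumptions: £3000 per scan, 33% of
#' patients non-responsive to conventional antipsychotics, annual saving of
#' £39,141 - £15,086 = £24,055 (active psychosis vs. remitted healthcare
#' costs; the rounded ~£24,000 is selectable by passing it explicitly),
#' 4-year mean delay to clozapine avoided, 50% clozapine response, 3%
#' neutropenia incidence.  Clozapine annual cost, neutropenia-management
#' cost and the false-positive penalty have no published values; the
#' defaults here (£2500/yr, £5000/event, £0) are illustrative and should be
#' reviewed for any real use.
#'
#' @param cohort_size Patients screened (default 1000).
#' @param scan_cost Cost per scan, GBP (default 3000).
#' @param prevalence Non-response prevalence (default 0.33).
#' @param annual_cost_active,annual_cost_remitted Annual healthcare cost of
#'   active psychosis / remission, GBP (defaults 39141 / 15086).
#' @param annual_saving Annual saving per remitted patient-year, GBP
#'   (default `annual_cost_active - annual_cost_remitted`).
#' @param delay_years Years of delay to clozapine avoided (default 4).
#' @param clozapine_response Probability a treatment-resistant patient
#'   responds to clozapine (default 0.5).
#' @param clozapine_annual_cost Annual clozapine treatment + monitoring cost,
#'   GBP (illustrative default 2500).
#' @param neutropenia_incidence Neutropenia incidence under clozapine
#'   (default 0.03).
#' @param neutropenia_cost Cost per neutropenia event, GBP (illustrative
#'   default 5000).
#' @param false_positive_penalty Extra cost per false positive, GBP
#'   (default 0).
#' @param sensitivity,specificity Operating point of the screening test.
#' @return An `econ_scenario` list.
#' @export
econ_scenario <- function(cohort_size = 1000, scan_cost = 3000,
                          prevalence = 0.33,
                          annual_cost_active = 39141,
                          annual_cost_remitted = 15086,
                          annual_saving = annual_cost_active -
                            annual_cost_remitted,
                          delay_years = 4, clozapine_response = 0.5,
                          clozapine_annual_cost = 2500,
                          neutropenia_incidence = 0.03,
                          neutropenia_cost = 5000,
                          false_positive_penalty = 0,
                          sensitivity = 0.5, specificity = 0.95) {
  probs <- c(prevalence, clozapine_response, neutropenia_incidence,
             sensitivity, specificity)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  costs <- c(cohort_size, scan_cost, annual_saving, delay_years,
             clozapine_annual_cost, neutropenia_cost, false_positive_penalty)
  if (any(costs < 0)) stop("costs, sizes and durations must be >= 0")
  structure(list(cohort_size = cohort_size, scan_cost = scan_cost,
                 prevalence = prevalence, annual_saving = annual_saving,
                 delay_years = delay_years,
                 clozapine_response = clozapine_response,
                 clozapine_annual_cost = clozapine_annual_cost,
                 neutropenia_incidence = neutropenia_incidence,
                 neutropenia_cost = neutropenia_cost,
                 false_positive_penalty = false_positive_penalty,
                 sensitivity = sensitivity, specificity = specificity),
            class = "econ_scenario")
}

#' Expected outcome of a screening scenario
#'
#' Closed-form expected confusion counts, benefit, cost and net saving per
#' screened patient:
#' \deqn{TP = p\,se\,N, \quad FP = (1-p)(1-sp)N,}
#' \eqn{benefit = TP \cdot r \cdot s \cdot d}, and
#' \eqn{cost = N\,c_{scan} + (TP+FP)(c_{cloz} d + i_{neu} c_{neu}) +
#' FP\,c_{fp}}, where \eqn{p} is prevalence, \eqn{se/sp}
#' sensitivity/specificity, \eqn{r} the clozapine response probability,
#' \eqn{s} the annual saving and \eqn{d} the delay avoided.
#'
#' @param scenario An [econ_scenario()].
#' @return An `econ_outcome`: `tp`, `fp`, `tn`, `fn`, `total_benefit`,
#'   `total_cost`, `net_per_patient` (all GBP except counts).
#' @export
econ_outcome <- function(scenario) {
  stopifnot(inherits(scenario, "econ_scenario"))
  N <- scenario$cohort_size
  p <- scenario$prevalence
  tp <- p * scenario$sensitivity * N
  fn <- p * N - tp
  fp <- (1 - p) * (1 - scenario$specificity) * N
  tn <- (1 - p) * N - fp
  benefit <- tp * scenario$clozapine_response * scenario$annual_saving *
    scenario$delay_years
  cost <- N * scenario$scan_cost +
    (tp + fp) * (scenario$clozapine_annual_cost * scenario$delay_years +
                   scenario$neutropenia_incidence * scenario$neutropenia_cost) +
    fp * scenario$false_positive_penalty
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 total_benefit = benefit, total_cost = cost,
                 net_per_patient = (benefit - cost) / N),
            class = "econ_outcome")
}

#' @export
print.econ_outcome <- function(x, ...) {
  cat(sprintf(
    "<econ_outcome> net %+.0f GBP/patient (benefit %.0f, cost %.0f; TP %.1f FP %.1f)\n",
    x$net_per_patient, x$total_benefit, x$total_cost, x$tp, x$fp))
  invisible(x)
}

net_at <- function(scenario, sensitivity, specificity = scenario$specificity) {
  scenario$sensitivity <- sensitivity
  scenario$specificity <- specificity
  econ_outcome(scenario)$net_per_patient
}

#' Breakeven sensitivity at a fixed specificity
#'
#' Sensitivity at which the net saving per patient crosses zero, found by
#' bisection to 1e-6 (the model is affine in sensitivity, so the root is
#' unique when net saving is strictly increasing).  Returns `NA` when the
#' model never breaks even on `[0, 1]`, and 0 when it is already favourable
#' at zero sensitivity.
#'
#' @param scenario An [econ_scenario()]; its `sensitivity` field is ignored.
#' @param specificity Specificity to evaluate at (default from scenario).
#' @param tol Bisection tolerance (default 1e-6).
#' @return Breakeven sensitivity in `[0, 1]`, or `NA_real_`.
#' @export
breakeven_sensitivity <- function(scenario,
                                  specificity = scenario$specificity,
                                  tol = 1e-6) {
  stopifnot(inherits(scenario, "econ_scenario"))
  n0 <- net_at(scenario, 0, specificity)
  n1 <- net_at(scenario, 1, specificity)
  if (n1 < n0)
    stop("net saving not increasing in sensitivity; use savings_surface()")
  if (n0 >= 0) return(0)
  if (n1 < 0 || n1 == n0) return(NA_real_)
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_at(scenario, mid, specificity) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Net-saving surface over sensitivity and specificity grids
#'
#' @param scenario An [econ_scenario()].
#' @param sensitivity_grid,specificity_grid Numeric grids in `[0, 1]`.
#' @return Data frame: `sensitivity`, `specificity`, `net_per_patient`.
#' @export
savings_surface <- function(scenario,
                            sensitivity_grid = seq(0, 1, by = 0.05),
                            specificity_grid = seq(0, 1, by = 0.05)) {
  stopifnot(inherits(scenario, "econ_scenario"),
            all(sensitivity_grid >= 0 & sensitivity_grid <= 1),
            all(specificity_grid >= 0 & specificity_grid <= 1))
  g <- expand.grid(sensitivity = sensitivity_grid,
                   specificity = specificity_grid)
  g$net_per_patient <- mapply(function(se, sp) net_at(scenario, se, sp),
                              g$sensitivity, g$specificity)
  g
}
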