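test_that("dosing regimens validate their fields", {
  expect_error(dosing_regimen(6, 12), "24 or 48")
  expect_error(dosing_regimen(6, 24, 0), "infusion_duration_h")
  expect_error(dosing_regimen(6, 24, 25), "infusion_duration_h")
  expect_error(dosing_regimen(6, 24, 0.5, 0), "n_doses")
  expect_error(dosing_regimen(-1), ">= 0")
  reg <- dosing_regimen(6, 48, 2 / 60, 3)
  expect_equal(reg$infusion_duration_h, 2 / 60)
})

test_that("closed-form profile matches an independent numerical integrator", {
  skip_if_not_installed("deSolve")
  adult <- ref_adult()
  drug <- drug_parameters()
  cm <- ref_adult_clearance()
  reg <- dosing_regimen(6, 24, 0.5, 2)
  prof <- simulate_regimen(adult, drug, cm, reg, grid_step_h = 0.05)

  vss <- drug$vss_per_kg * adult$weight_kg
  v1 <- drug$central_fraction * vss
  v2 <- vss - v1
  q <- drug$q_per_kg * adult$weight_kg
  cl <- cm$cl_total
  dose <- reg$dose_mg_per_kg * adult$weight_kg
  r0 <- dose / reg$infusion_duration_h
  rhs <- function(t, y, p) {
    infusing <- (t %% reg$interval_h) < reg$infusion_duration_h &
      t < reg$n_doses * reg$interval_h
    rate <- if (infusing) r0 else 0
    dA1 <- rate - (cl / v1) * y[1] - (q / v1) * y[1] + (q / v2) * y[2]
    dA2 <- (q / v1) * y[1] - (q / v2) * y[2]
    list(c(dA1, dA2))
  }
  sol <- deSolve::lsoda(c(0, 0), prof$time_h, rhs, NULL, rtol = 1e-10,
                        atol = 1e-10)
  num <- sol[, 2] / v1
  scale <- max(num)
  expect_lt(max(abs(num - prof$conc_mg_L)) / scale, 1e-3)
})

test_that("single-dose AUC to infinity equals dose/CL in the one-compartment limit", {
  adult <- ref_adult()
  drug <- drug_parameters(central_fraction = 1)  # Vss 7 L, one compartment
  cm <- ref_adult_clearance()                    # CL 0.7241 L/h
  reg <- dosing_regimen(6, 24, 0.5, 1)
  prof <- simulate_regimen(adult, drug, cm, reg, grid_step_h = 0.02)
  # integrate the simulated interval and add the analytic tail
  k <- cm$cl_total / (drug$vss_per_kg * adult$weight_kg)
  auc24 <- pk_metrics(prof, reg, 1)$auc_interval
  tail <- prof$conc_mg_L[nrow(prof)] / k
  expect_equal(auc24 + tail, 580, tolerance = 0.005 * 580)
})

test_that("the simulator is linear in dose and zero dose gives a zero profile", {
  adult <- ref_adult()
  drug <- drug_parameters()
  cm <- ref_adult_clearance()
  reg1 <- dosing_regimen(5, 24, 0.5, 3)
  reg2 <- dosing_regimen(10, 24, 0.5, 3)
  p1 <- simulate_regimen(adult, drug, cm, reg1)
  p2 <- simulate_regimen(adult, drug, cm, reg2)
  expect_equal(p2$conc_mg_L, 2 * p1$conc_mg_L, tolerance = 1e-12)

  reg0 <- dosing_regimen(0, 24, 0.5, 3)
  p0 <- simulate_regimen(adult, drug, cm, reg0)
  expect_true(all(p0$conc_mg_L == 0))
  # pre-first-dose concentration is zero
  expect_equal(p1$conc_mg_L[1], 0)
  expect_true(all(p1$conc_mg_L >= 0))
})

test_that("simulation refuses uncalibrated models and coarse grids", {
  adult <- ref_adult()
  drug <- drug_parameters()
  raw <- clearance_model(0.5)
  reg <- dosing_regimen(6, 24, 0.5, 1)
  expect_error(simulate_regimen(adult, drug, raw, reg), "calibrated")
  expect_error(
    simulate_regimen(adult, drug, ref_adult_clearance(), reg,
                     grid_step_h = 0.2), "too coarse")
})

test_that("pk metrics reproduce hand-computable cases", {
  reg <- dosing_regimen(6, 24, 0.5, 1)
  flat <- manual_profile(seq(0, 24, 0.5), rep(3, 49), reg)
  m <- pk_metrics(flat, reg, 1)
  expect_equal(m$auc_0_24, 72)      # 24 h x 3 mg/L
  expect_equal(m$auc_interval, 72)
  expect_equal(m$cmax, 3)
  expect_equal(m$cmin_ss, 3)

  # q48h daily AUC is half the interval AUC
  reg48 <- dosing_regimen(6, 48, 0.5, 1)
  flat48 <- manual_profile(seq(0, 48, 0.5), rep(3, 97), reg48)
  m48 <- pk_metrics(flat48, reg48, 1)
  expect_equal(m48$auc_interval, 144)
  expect_equal(m48$auc_0_24, 72)

  expect_error(pk_metrics(flat, reg, 2), "beyond")
})

test_that("steady-state interval AUC equals dose/CL and metrics are ordered", {
  adult <- ref_adult()
  drug <- drug_parameters()
  cm <- ref_adult_clearance()
  reg <- dosing_regimen(6, 24, 0.5, 10)
  prof <- simulate_regimen(adult, drug, cm, reg)
  m <- pk_metrics(prof, reg, "last")
  expect_equal(m$auc_interval, 420 / cm$cl_total,
               tolerance = 0.005 * 420 / cm$cl_total)
  expect_gte(m$cmax, m$cmin_ss)
  expect_gte(m$cmin_ss, 0)
  expect_gte(m$accumulation_index, 1)
  # terminal half-life of the calibrated adult sits in the 8-9 h range
  expect_gt(m$t_half_effective, 8)
  expect_lt(m$t_half_effective, 9)
})

test_that("steady state is approached within three daily doses in health and later with impairment", {
  adult <- ref_adult()
  cm <- ref_adult_clearance()
  reg <- dosing_regimen(6, 24)
  expect_lte(steady_state_dose_number(cm, reg, adult, 0.9), 3)
  # a vanishing tolerance needs a single dose
  expect_equal(steady_state_dose_number(cm, reg, adult, 1e-6), 1)
  # dose number is non-decreasing as clearance falls (worsening renal
  # function), cross-checked by brute-force simulation
  cats <- c("HEALTHY", "MILD", "MODERATE", "SEVERE", "ESRD")
  ns <- vapply(cats, function(cat) {
    m <- apply_renal_impairment(cm, make_subject(35, 70, 25.71, cat,
                                                 "ADULT"))
    steady_state_dose_number(m, reg, adult, 0.9)
  }, numeric(1))
  expect_true(all(diff(ns) >= 0))

  # brute force: simulate many doses and find the first trough at 90% of
  # the final trough
  drug <- drug_parameters()
  esrd <- apply_renal_impairment(cm, make_subject(35, 70, 25.71, "ESRD",
                                                  "ADULT"))
  prof <- simulate_regimen(adult, drug, esrd,
                           dosing_regimen(6, 24, 0.5, 40))
  troughs <- vapply(1:40, function(k) {
    prof$conc_mg_L[which.min(abs(prof$time_h - k * 24))]
  }, numeric(1))
  brute <- which(troughs >= 0.9 * troughs[40])[1]
  expect_equal(unname(ns["ESRD"]), brute)
})

test_that("clearance calibration against a simulated AUC round-trips", {
  adult <- ref_adult()
  drug <- drug_parameters()
  cm <- ref_adult_clearance()
  reg <- dosing_regimen(6, 24, 0.5, 5)
  cal <- calibrate_total_clearance(adult, drug, cm, reg, 580)
  m <- pk_metrics(simulate_regimen(adult, drug, cal, reg), reg)
  expect_equal(m$auc_interval, 580, tolerance = 1e-6)
  # renal:hepatic split preserved
  expect_equal(cal$cl_hepatic / cal$cl_renal,
               cm$cl_hepatic / cm$cl_renal)
  # dose/AUC recovers the calibrated total within 1%
  expect_equal(420 / m$auc_interval, cal$cl_total,
               tolerance = 0.01 * cal$cl_total)
})

test_that("central-fraction calibration hits a target Cmax", {
  adult <- ref_adult()
  drug <- drug_parameters()
  cm <- ref_adult_clearance()
  reg <- dosing_regimen(6, 24, 0.5, 5)
  fitted <- calibrate_central_fraction(adult, drug, cm, reg, 86.347)
  m <- pk_metrics(simulate_regimen(adult, fitted, cm, reg), reg)
  expect_equal(m$cmax, 86.347, tolerance = 1e-6)
  expect_true(fitted$central_fraction > 0 && fitted$central_fraction <= 1)
})
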