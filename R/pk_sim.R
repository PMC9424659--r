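#' Intravenous dosing regimen
#'
#' @param dose_mg_per_kg dose in mg per kg body weight, positive.
#' @param interval_h dosing interval, 24 or 48 h.
#' @param infusion_duration_h infusion duration in hours, in
#'   `(0, interval_h)`; 0.5 h (the standard 30-min infusion) by default.
#'   Use `2/60` for the 2-min injection.
#' @param n_doses number of administered doses, >= 1.
#' @return an object of class `dosing_regimen`.
#' @examples
#' dosing_regimen(6, 24, n_doses = 5)
#' @export
dosing_regimen <- function(dose_mg_per_kg, interval_h = 24,
                           infusion_duration_h = 0.5, n_doses = 1L) {
  if (dose_mg_per_kg < 0) stop("dose must be >= 0", call. = FALSE)
  if (!interval_h %in% c(24, 48)) {
    stop("interval_h must be 24 or 48", call. = FALSE)
  }
  if (infusion_duration_h <= 0 || infusion_duration_h >= interval_h) {
    stop("infusion_duration_h must lie in (0, interval_h)", call. = FALSE)
  }
  if (n_doses < 1) stop("n_doses must be >= 1", call. = FALSE)
  structure(
    list(dose_mg_per_kg = dose_mg_per_kg, interval_h = interval_h,
         infusion_duration_h = infusion_duration_h,
         n_doses = as.integer(n_doses)),
    class = "dosing_regimen"
  )
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("%g mg/kg q%gh x %d (%.0f-min infusion)\n",
              x$dose_mg_per_kg, x$interval_h, x$n_doses,
              60 * x$infusion_duration_h))
  invisible(x)
}

# Macro-constant parameterisation of the linear disposition system.
# Two-compartment: V1 = fc * Vss, V2 = (1-fc) * Vss, Q inter-compartmental.
# Unit-bolus central concentration is (1/V1) * sum(coef_i * exp(-lambda_i t))
# with coef summing to 1. fc = 1 (or Q = 0) degenerates to one compartment.
disposition_params <- function(subject, drug, clearance) {
  stopifnot(inherits(subject, "subject"), inherits(drug, "drug_parameters"))
  if (!is_calibrated(clearance)) {
    stop("clearance model must be calibrated before simulation",
         call. = FALSE)
  }
  cl <- clearance$cl_total
  vss <- drug$vss_per_kg * subject$weight_kg
  fc <- drug$central_fraction
  q <- drug$q_per_kg * subject$weight_kg
  v1 <- fc * vss
  v2 <- (1 - fc) * vss
  if (v2 < 1e-9 * vss || q < 1e-12) {
    k <- cl / vss
    return(list(cl = cl, vss = vss, v1 = vss, v2 = 0, q = 0,
                lambda = k, coef = 1))
  }
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  a <- (alpha - k21) / (alpha - beta)
  b <- (k21 - beta) / (alpha - beta)
  list(cl = cl, vss = vss, v1 = v1, v2 = v2, q = q,
       lambda = c(alpha, beta), coef = c(a, b))
}

# Central concentration at `times` for a single zero-order infusion of
# `dose_mg` over `tinf` starting at t = 0 (0 before the start).
infusion_conc <- function(times, dose_mg, tinf, dp) {
  r0 <- dose_mg / tinf
  out <- numeric(length(times))
  for (i in seq_along(dp$lambda)) {
    lam <- dp$lambda[i]
    co <- dp$coef[i]
    during <- (1 - exp(-lam * pmin(pmax(times, 0), tinf))) / lam
    after <- exp(-lam * pmax(times - tinf, 0))
    out <- out + co * during * after
  }
  out * (r0 / dp$v1) * (times > 0)
}

#' Simulate a multi-dose infusion concentration-time profile
#'
#' Linear two-compartment disposition with zero-order infusion input,
#' solved in closed form per dose and combined by superposition; the
#' profile is therefore exact on the grid (no integration error) and
#' deterministic. Total distribution volume is `vss_per_kg * weight`,
#' split between central and peripheral compartments by the drug's
#' `central_fraction`.
#'
#' @param subject a [make_subject()] individual.
#' @param drug [drug_parameters()].
#' @param clearance a calibrated [clearance_model()].
#' @param regimen a [dosing_regimen()].
#' @param grid_step_h output grid step (h); must be at most one third of
#'   the infusion duration so the infusion phase is resolved.
#' @return an object of class `conc_profile`: a data.frame with `time_h`
#'   and `conc_mg_L` plus attributes `regimen`, `dose_mg`, and
#'   `disposition` (the macro constants, including the terminal slope).
#' @examples
#' adult <- make_subject(35, 70, 25.71, "HEALTHY", "ADULT")
#' cm <- build_clearance_model(adult, 420 / 580)
#' prof <- simulate_regimen(adult, drug_parameters(), cm,
#'                          dosing_regimen(6, 24, n_doses = 5))
#' @export
simulate_regimen <- function(subject, drug, clearance, regimen,
                             grid_step_h = 0.05) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (grid_step_h > regimen$infusion_duration_h / 3) {
    stop("grid_step_h too coarse: must be <= infusion_duration_h / 3",
         call. = FALSE)
  }
  dp <- disposition_params(subject, drug, clearance)
  dose_mg <- regimen$dose_mg_per_kg * subject$weight_kg
  t_end <- regimen$interval_h * regimen$n_doses
  times <- seq(0, t_end, by = grid_step_h)
  conc <- numeric(length(times))
  if (dose_mg > 0) {
    for (j in seq_len(regimen$n_doses)) {
      start <- (j - 1) * regimen$interval_h
      conc <- conc + infusion_conc(times - start, dose_mg,
                                   regimen$infusion_duration_h, dp)
    }
  }
  out <- data.frame(time_h = times, conc_mg_L = conc)
  structure(out, class = c("conc_profile", "data.frame"),
            regimen = regimen, dose_mg = dose_mg, disposition = dp)
}

#' @export
print.conc_profile <- function(x, ...) {
  reg <- attr(x, "regimen")
  cat(sprintf(
    "concentration-time profile: %d points over %.0f h (%g mg/kg q%gh x %d)\n",
    nrow(x), max(x$time_h), reg$dose_mg_per_kg, reg$interval_h,
    reg$n_doses))
  cat(sprintf("  Cmax %.2f mg/L at %.2f h\n",
              max(x$conc_mg_L), x$time_h[which.max(x$conc_mg_L)]))
  invisible(x)
}

#' Write a profile as CSV
#'
#' Columns `time_h`, `conc_mg_L`.
#' @param x a `conc_profile`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("time_h", "conc_mg_L")], path,
                   row.names = FALSE)
  invisible(path)
}

# log-linear trapezoid: linear where concentration rises or is flat/zero,
# log where it declines between positive points
auc_loglin <- function(t, c) {
  dt <- diff(t)
  c1 <- c[-length(c)]
  c2 <- c[-1]
  seg <- (c1 + c2) / 2 * dt
  declining <- c2 < c1 & c2 > 0 & c1 > 0
  seg[declining] <- (c1[declining] - c2[declining]) /
    log(c1[declining] / c2[declining]) * dt[declining]
  sum(seg)
}

#' Pharmacokinetic metrics of one dose interval
#'
#' Extracts the exposure metrics of the requested dose interval: the
#' interval AUC by log-linear trapezoid on the simulation grid, Cmax as the
#' maximum within the interval, the trough `cmin_ss` as the concentration
#' at the end of the interval (immediately before the next dose), the
#' terminal ("effective") half-life from the disposition macro constants,
#' and the accumulation index `1 / (1 - exp(-lambda_z * tau))`.
#'
#' For 48-h intervals `auc_0_24` is defined as half the interval AUC, i.e.
#' the average daily exposure; for 24-h intervals it equals the interval
#' AUC.
#'
#' @param profile a [simulate_regimen()] profile.
#' @param regimen the regimen used (defaults to the one stored in the
#'   profile).
#' @param which_dose dose index or `"last"`.
#' @return an object of class `pk_metrics`: a list with `auc_0_24`,
#'   `auc_interval`, `cmax`, `cmin_ss`, `t_half_effective`,
#'   `accumulation_index`.
#' @export
pk_metrics <- function(profile, regimen = attr(profile, "regimen"),
                       which_dose = "last") {
  stopifnot(inherits(profile, "conc_profile"))
  k <- if (identical(which_dose, "last")) regimen$n_doses
       else as.integer(which_dose)
  if (k < 1 || k > regimen$n_doses) {
    stop("requested dose ", k, " is beyond the simulated ",
         regimen$n_doses, " doses", call. = FALSE)
  }
  t0 <- (k - 1) * regimen$interval_h
  t1 <- k * regimen$interval_h
  if (max(profile$time_h) < t1 - 1e-9) {
    stop("profile does not span the requested dose interval", call. = FALSE)
  }
  sel <- profile$time_h >= t0 - 1e-9 & profile$time_h <= t1 + 1e-9
  tt <- profile$time_h[sel]
  cc <- profile$conc_mg_L[sel]
  auc_int <- auc_loglin(tt, cc)
  dp <- attr(profile, "disposition")
  lambda_z <- min(dp$lambda)
  structure(
    list(auc_0_24 = auc_int * 24 / regimen$interval_h,
         auc_interval = auc_int,
         cmax = max(cc),
         cmin_ss = cc[length(cc)],
         t_half_effective = log(2) / lambda_z,
         accumulation_index = 1 / (1 - exp(-lambda_z * regimen$interval_h))),
    class = "pk_metrics"
  )
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("AUC(0-24) %.1f ug.h/mL, interval AUC %.1f ug.h/mL, ",
           "Cmax %.2f ug/mL,\n  trough %.2f ug/mL, t1/2 %.1f h, ",
           "accumulation index %.2f\n"),
    x$auc_0_24, x$auc_interval, x$cmax, x$cmin_ss, x$t_half_effective,
    x$accumulation_index))
  invisible(x)
}

#' Write PK metrics as JSON
#' @param x a `pk_metrics` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pk_metrics <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Analytic trough immediately before dose k+1 (i.e. at time k * tau),
# from the superposed closed form; k = Inf gives the steady-state trough.
trough_after_dose <- function(k, dp, dose_mg, regimen) {
  tau <- regimen$interval_h
  tinf <- regimen$infusion_duration_h
  r0 <- dose_mg / tinf
  tot <- 0
  for (i in seq_along(dp$lambda)) {
    lam <- dp$lambda[i]
    single <- dp$coef[i] * (1 - exp(-lam * tinf)) / lam *
      exp(-lam * (tau - tinf))
    accum <- if (is.infinite(k)) 1 / (1 - exp(-lam * tau))
             else (1 - exp(-lam * k * tau)) / (1 - exp(-lam * tau))
    tot <- tot + single * accum
  }
  tot * r0 / dp$v1
}

#' Number of doses needed to approach the steady-state trough
#'
#' Smallest dose index `k` such that the trough after dose `k` reaches at
#' least `tolerance` times the steady-state trough, evaluated with the
#' analytic accumulation formula (no simulation grid involved).
#'
#' @param clearance a calibrated [clearance_model()].
#' @param regimen a [dosing_regimen()] (its `n_doses` is ignored).
#' @param subject a [make_subject()] individual.
#' @param tolerance fraction of the steady-state trough to reach, in
#'   (0, 1).
#' @param drug [drug_parameters()].
#' @return integer dose count.
#' @examples
#' adult <- make_subject(35, 70, 25.71, "HEALTHY", "ADULT")
#' cm <- build_clearance_model(adult, 420 / 580)
#' steady_state_dose_number(cm, dosing_regimen(6, 24), adult, 0.9)
#' @export
steady_state_dose_number <- function(clearance, regimen, subject,
                                     tolerance = 0.9,
                                     drug = drug_parameters()) {
  if (tolerance <= 0 || tolerance >= 1) {
    stop("tolerance must be in (0, 1)", call. = FALSE)
  }
  dp <- disposition_params(subject, drug, clearance)
  dose_mg <- regimen$dose_mg_per_kg * subject$weight_kg
  ss <- trough_after_dose(Inf, dp, dose_mg, regimen)
  k <- 1L
  while (trough_after_dose(k, dp, dose_mg, regimen) < tolerance * ss) {
    k <- k + 1L
    if (k > 1000L) stop("steady state not approached within 1000 doses",
                        call. = FALSE)
  }
  k
}

# Analytic steady-state interval AUC (exact): dose / CL.
steady_state_auc_interval <- function(clearance, regimen, subject) {
  regimen$dose_mg_per_kg * subject$weight_kg / clearance$cl_total
}

#' Calibrate total clearance against a target interval AUC
#'
#' Finds the total clearance for which the simulated interval AUC of dose
#' `which_dose` matches `target_auc`, by root finding on the full
#' simulation (so the result absorbs any residual accumulation and grid
#' effects). The renal:non-renal split of `clearance` is preserved by
#' scaling the hepatic term.
#'
#' @param subject,drug,regimen as in [simulate_regimen()].
#' @param clearance a calibrated starting [clearance_model()].
#' @param target_auc target interval AUC, ug.h/mL.
#' @param which_dose dose index or `"last"`.
#' @param grid_step_h simulation grid step.
#' @return a calibrated `clearance_model` whose simulated AUC matches the
#'   target.
#' @export
calibrate_total_clearance <- function(subject, drug, clearance, regimen,
                                      target_auc, which_dose = "last",
                                      grid_step_h = 0.05) {
  sim_auc <- function(cl_total) {
    scaled <- rescale_total(clearance, cl_total)
    prof <- simulate_regimen(subject, drug, scaled, regimen, grid_step_h)
    pk_metrics(prof, regimen, which_dose)$auc_interval
  }
  guess <- regimen$dose_mg_per_kg * subject$weight_kg / target_auc
  root <- stats::uniroot(function(cl) sim_auc(cl) - target_auc,
                         interval = c(guess * 0.5, guess * 2),
                         tol = 1e-10)
  rescale_total(clearance, root$root)
}

# scale both routes so cl_total hits a value while keeping their ratio
rescale_total <- function(clearance, cl_total) {
  f <- cl_total / clearance$cl_total
  clearance_model(cl_filt = clearance$cl_filt * f,
                  cl_hepatic = clearance$cl_hepatic * f,
                  cl_sec = clearance$cl_sec * f,
                  cl_reabs = clearance$cl_reabs * f,
                  population = clearance$population,
                  healthy_cl_renal = clearance$healthy_cl_renal)
}

#' Calibrate the central-volume split against a target Cmax
#'
#' With clearance fixed, adjusts the drug's `central_fraction` (the share
#' of Vss in the central compartment) so the simulated Cmax of dose
#' `which_dose` matches `target_cmax`. A smaller central fraction
#' concentrates the infusion peak and raises Cmax.
#'
#' @param subject,clearance,regimen as in [simulate_regimen()].
#' @param drug starting [drug_parameters()].
#' @param target_cmax target peak concentration, ug/mL.
#' @param which_dose dose index or `"last"`.
#' @param grid_step_h simulation grid step.
#' @return a `drug_parameters` object with the fitted `central_fraction`.
#' @export
calibrate_central_fraction <- function(subject, drug, clearance, regimen,
                                       target_cmax, which_dose = "last",
                                       grid_step_h = 0.05) {
  sim_cmax <- function(fc) {
    d2 <- drug
    d2$central_fraction <- fc
    prof <- simulate_regimen(subject, d2, clearance, regimen, grid_step_h)
    pk_metrics(prof, regimen, which_dose)$cmax
  }
  root <- stats::uniroot(function(fc) sim_cmax(fc) - target_cmax,
                         interval = c(0.05, 0.999), tol = 1e-9)
  drug$central_fraction <- root$root
  drug
}
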