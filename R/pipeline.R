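#' Default run configuration
#'
#' The configuration object consumed by the `run_*` pipeline entry points
#' and by the command-line front-end (`inst/cli/daptosim.R`). All defaults
#' are the published study values: the healthy 35-y/70-kg adult, 6 mg/kg
#' daily 30-min infusions calibrated to a steady-state AUC of 580
#' ug.h/mL, 10,000 Monte-Carlo subjects, AUC/MIC targets 666 (MRSA) and
#' 143 (E. faecium), 2-fold validation threshold, 24.3 mg/L trough
#' threshold and 1.8 exposure-ratio threshold.
#'
#' @return a nested list; see the field names in the function body.
#' @export
default_run_config <- function() {
  list(
    population = list(age_years = 35, weight_kg = 70, bmi = 25.71,
                      category = "HEALTHY", population = "ADULT"),
    drug_parameter_file = NULL,
    regimen = list(dose_mg_per_kg = 6, interval_h = 24,
                   infusion_duration_h = 0.5, n_doses = 5),
    calibration = list(reference_dose_mg_per_kg = 6, reference_auc = 580),
    monte_carlo = list(n = 10000L, seed = 1L, cv_cl = 0.25, cv_v = 0.15),
    mic_file = NULL,
    mic_preset = "MRSA_LIKE",
    thresholds = list(fold_error = 2, auc_mic_mrsa = 666,
                      auc_mic_efaecium = 143, cmin = 24.3, ratio = 1.8,
                      cfr = 0.90)
  )
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override [default_run_config()]; missing
#' fields keep their defaults. Referenced files must exist and thresholds
#' must be positive.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return a validated configuration list.
#' @export
read_run_config <- function(path = NULL) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    config <- modify_list_deep(config, user)
  }
  validate_run_config(config)
  config
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

validate_run_config <- function(config) {
  th <- config$thresholds
  if (any(unlist(th) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  for (f in c("drug_parameter_file", "mic_file")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]])) {
      stop("configured file does not exist: ", config[[f]], call. = FALSE)
    }
  }
  if (config$monte_carlo$n < 1) stop("monte_carlo n must be >= 1",
                                     call. = FALSE)
  invisible(config)
}

config_subject <- function(config) {
  p <- config$population
  make_subject(p$age_years, p$weight_kg, p$bmi, p$category, p$population)
}

config_drug <- function(config) {
  if (is.null(config$drug_parameter_file)) {
    read_drug_parameters(daptosim_extdata("daptomycin_parameters.json"))
  } else {
    read_drug_parameters(config$drug_parameter_file)
  }
}

config_clearance <- function(config, subject) {
  cal <- config$calibration
  cl_ref <- cal$reference_dose_mg_per_kg * subject$weight_kg /
    cal$reference_auc
  healthy <- if (subject$category$label == "HEALTHY") subject else
    make_subject(subject$age_years, subject$weight_kg,
                 subject$weight_kg / subject$height_m^2, "HEALTHY",
                 subject$population, subject$sex)
  model <- build_clearance_model(healthy, cl_ref)
  if (subject$category$label == "HEALTHY") model
  else apply_renal_impairment(model, subject)
}

config_mic_dist <- function(config) {
  if (!is.null(config$mic_file)) read_mic_distribution(config$mic_file)
  else generate_mic_distribution(config$mic_preset,
                                 seed = config$monte_carlo$seed)
}

write_config_echo <- function(config, out_dir) {
  yaml::write_yaml(config, file.path(out_dir, "config_used.yaml"))
}

#' Run the simulation pipeline
#'
#' Builds the configured subject, drug and calibrated clearance model,
#' simulates the configured regimen and writes `profile.csv`,
#' `metrics.json` and a `config_used.yaml` echo into `out_dir`.
#'
#' @param config a [read_run_config()] configuration.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `subject`, `drug`, `clearance`,
#'   `profile` and `metrics`.
#' @export
run_simulate <- function(config = read_run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subject <- config_subject(config)
  drug <- config_drug(config)
  clearance <- config_clearance(config, subject)
  reg <- config$regimen
  regimen <- dosing_regimen(reg$dose_mg_per_kg, reg$interval_h,
                            reg$infusion_duration_h, reg$n_doses)
  profile <- simulate_regimen(subject, drug, clearance, regimen)
  metrics <- pk_metrics(profile, regimen, "last")
  write_profile(profile, file.path(out_dir, "profile.csv"))
  write_pk_metrics(metrics, file.path(out_dir, "metrics.json"))
  write_clearance_model(clearance, file.path(out_dir, "clearance.json"))
  write_config_echo(config, out_dir)
  message(sprintf(
    "simulated %g mg/kg q%gh x %d: CL %.4f L/h, interval AUC %.1f ug.h/mL",
    regimen$dose_mg_per_kg, regimen$interval_h, regimen$n_doses,
    clearance$cl_total, metrics$auc_interval))
  invisible(list(subject = subject, drug = drug, clearance = clearance,
                 profile = profile, metrics = metrics))
}

#' Run the fold-error validation pipeline
#'
#' Validates a CSV of observed/predicted records (default: the packaged
#' pediatric table) against the configured fold-error threshold.
#'
#' @param config a [read_run_config()] configuration.
#' @param reference_csv CSV of records; default is the packaged pediatric
#'   observed/predicted table.
#' @param out_dir optional output directory for the report (CSV + JSON).
#' @return the [validate_table()] report.
#' @export
run_validate <- function(config = read_run_config(),
                         reference_csv = daptosim_extdata("child_pk_validation.csv"),
                         out_dir = NULL) {
  records <- read_validation_records(reference_csv)
  report <- validate_table(records,
                           threshold = config$thresholds$fold_error)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_validation_report(report, file.path(out_dir,
                                              "validation_report.csv"))
    write_validation_report(report, file.path(out_dir,
                                              "validation_report.json"))
    write_config_echo(config, out_dir)
  }
  report
}

#' Run the Monte-Carlo PTA/CFR pipeline
#'
#' Samples the configured virtual population, computes the PTA curve over
#' the MIC grid for both pathogen targets, the CFR against the configured
#' MIC distribution, and the trough safety fraction; writes
#' `pta_cfr.json` stamped with `n` and `seed`.
#'
#' @param config a [read_run_config()] configuration.
#' @param out_dir optional output directory.
#' @return invisibly, a list with `exposures`, `pta_mrsa`,
#'   `pta_efaecium`, `cfr_mrsa`, `cfr_efaecium`, `cmin`.
#' @export
run_pta_cfr <- function(config = read_run_config(), out_dir = NULL) {
  subject <- config_subject(config)
  drug <- config_drug(config)
  clearance <- config_clearance(config, subject)
  reg <- config$regimen
  regimen <- dosing_regimen(reg$dose_mg_per_kg, reg$interval_h,
                            reg$infusion_duration_h, reg$n_doses)
  mc <- config$monte_carlo
  exposures <- monte_carlo_exposures(subject, clearance, regimen,
                                     n = mc$n, seed = mc$seed,
                                     cv_cl = mc$cv_cl, cv_v = mc$cv_v,
                                     drug = drug)
  mic_dist <- config_mic_dist(config)
  tgt_m <- pd_target("MRSA", config$thresholds$auc_mic_mrsa)
  tgt_e <- pd_target("EFAECIUM", config$thresholds$auc_mic_efaecium)
  pta_m <- pta_curve(exposures, mic_dist$mics, tgt_m)
  pta_e <- pta_curve(exposures, mic_dist$mics, tgt_e)
  cfr_m <- cfr(pta_m, mic_dist)
  cfr_e <- cfr(pta_e, mic_dist)
  cmin <- cmin_safety_flag(exposures, config$thresholds$cmin)
  out <- list(exposures = exposures, pta_mrsa = pta_m,
              pta_efaecium = pta_e, cfr_mrsa = cfr_m,
              cfr_efaecium = cfr_e, cmin = cmin)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(n = mc$n, seed = mc$seed,
           median_auc_0_24 = stats::median(exposures$auc_0_24),
           pta_mrsa = as.data.frame(pta_m),
           pta_efaecium = as.data.frame(pta_e),
           cfr_mrsa = cfr_m$cfr, cfr_efaecium = cfr_e$cfr,
           cmin_fraction_exceeding = cmin$fraction_exceeding,
           cmin_flag = cmin$flag),
      file.path(out_dir, "pta_cfr.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    write_config_echo(config, out_dir)
  }
  invisible(out)
}

#' Run the dose-recommendation pipeline
#'
#' Produces the full pediatric recommendation grid with the configured
#' thresholds and Monte-Carlo settings and writes it as CSV and JSON.
#'
#' @param config a [read_run_config()] configuration.
#' @param out_dir optional output directory.
#' @param ... passed through to [recommend_grid()].
#' @return the recommendation grid data.frame.
#' @export
run_recommend <- function(config = read_run_config(), out_dir = NULL,
                          ...) {
  mc <- config$monte_carlo
  grid <- recommend_grid(
    ratio_threshold = config$thresholds$ratio,
    cfr_threshold = config$thresholds$cfr,
    cmin_threshold = config$thresholds$cmin,
    n = mc$n, seed = mc$seed, cv_cl = mc$cv_cl, cv_v = mc$cv_v, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_recommendations(grid, file.path(out_dir, "recommendations.csv"))
    write_recommendations(grid, file.path(out_dir, "recommendations.json"))
    write_config_echo(config, out_dir)
  }
  grid
}

#' Run the synthetic-data pipeline
#'
#' Generates a seeded virtual trial for the configured subject and
#' regimen plus the two synthetic MIC fixtures, and writes them as CSV.
#'
#' @param config a [read_run_config()] configuration.
#' @param out_dir output directory.
#' @param times sampling times (h); default hourly over the final dose
#'   interval.
#' @return invisibly, a list with `trial`, `mrsa_mic`, `efaecium_mic`.
#' @export
run_synth <- function(config = read_run_config(), out_dir = ".",
                      times = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subject <- config_subject(config)
  drug <- config_drug(config)
  clearance <- config_clearance(config, subject)
  reg <- config$regimen
  regimen <- dosing_regimen(reg$dose_mg_per_kg, reg$interval_h,
                            reg$infusion_duration_h, reg$n_doses)
  if (is.null(times)) {
    times <- seq((regimen$n_doses - 1) * regimen$interval_h,
                 regimen$n_doses * regimen$interval_h, by = 1)
  }
  seed <- config$monte_carlo$seed
  trial <- generate_virtual_trial(subject, clearance, regimen, times,
                                  seed = seed, drug = drug)
  mrsa <- generate_mic_distribution("MRSA_LIKE", seed = seed)
  efm <- generate_mic_distribution("EFAECIUM_LIKE", seed = seed)
  write_virtual_trial(trial, file.path(out_dir, "virtual_trial.csv"))
  write_mic_distribution(mrsa, file.path(out_dir,
                                         "mic_mrsa_like_synthetic.csv"))
  write_mic_distribution(efm, file.path(out_dir,
                                        "mic_efaecium_like_synthetic.csv"))
  write_config_echo(config, out_dir)
  invisible(list(trial = trial, mrsa_mic = mrsa, efaecium_mic = efm))
}
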