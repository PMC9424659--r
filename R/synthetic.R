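#' Generate a synthetic concentration-time trial
#'
#' Simulates noisy observations around the closed-form model prediction
#' with the standard proportional-plus-additive residual model:
#' `obs = pred * exp(eps_prop) + eps_add`, truncated at zero. The
#' proportional term is mean-one log-normal (meanlog `-sigma^2/2`) so the
#' expected observation equals the noise-free prediction. Predictions are
#' evaluated exactly at the requested times (no grid).
#'
#' @param subject a [make_subject()] individual.
#' @param clearance a calibrated [clearance_model()].
#' @param regimen a [dosing_regimen()].
#' @param times sampling times (h) within the simulated span
#'   `[0, n_doses * interval]`.
#' @param prop_cv proportional residual coefficient of variation
#'   (default 0.15).
#' @param add_sd additive residual SD, mg/L (default 0.5).
#' @param seed integer seed; identical seeds give identical trials.
#' @param n_replicates number of replicate observation series.
#' @param drug [drug_parameters()].
#' @return an object of class `virtual_trial`: a data.frame with
#'   `replicate_id`, `time_h`, `conc_mg_L` (observed) and `pred_mg_L`,
#'   plus attributes `regimen`, `subject`, `clearance`, `seed`,
#'   `prop_cv`, `add_sd`.
#' @export
generate_virtual_trial <- function(subject, clearance, regimen, times,
                                   prop_cv = 0.15, add_sd = 0.5, seed = 1L,
                                   n_replicates = 1L,
                                   drug = drug_parameters()) {
  if (prop_cv < 0 || add_sd < 0) {
    stop("prop_cv and add_sd must be >= 0", call. = FALSE)
  }
  span <- regimen$interval_h * regimen$n_doses
  if (any(times < 0) || any(times > span + 1e-9)) {
    stop("sampling times must lie within the simulated span [0, ",
         span, "] h", call. = FALSE)
  }
  dp <- disposition_params(subject, drug, clearance)
  dose_mg <- regimen$dose_mg_per_kg * subject$weight_kg
  pred <- numeric(length(times))
  for (j in seq_len(regimen$n_doses)) {
    pred <- pred + infusion_conc(times - (j - 1) * regimen$interval_h,
                                 dose_mg, regimen$infusion_duration_h, dp)
  }
  sdlog <- sqrt(log(1 + prop_cv^2))
  m <- length(times)
  obs <- withr_seed({
    vapply(seq_len(n_replicates), function(r) {
      e_prop <- if (sdlog > 0) stats::rlnorm(m, -sdlog^2 / 2, sdlog)
                else rep(1, m)
      e_add <- if (add_sd > 0) stats::rnorm(m, 0, add_sd) else numeric(m)
      pmax(pred * e_prop + e_add, 0)
    }, numeric(m))
  }, seed)
  out <- data.frame(
    replicate_id = rep(seq_len(n_replicates), each = m),
    time_h = rep(times, n_replicates),
    conc_mg_L = as.vector(obs),
    pred_mg_L = rep(pred, n_replicates))
  structure(out, class = c("virtual_trial", "data.frame"),
            regimen = regimen, subject = subject, clearance = clearance,
            seed = as.integer(seed), prop_cv = prop_cv, add_sd = add_sd,
            dose_mg = dose_mg)
}

#' @export
print.virtual_trial <- function(x, ...) {
  cat(sprintf(
    "virtual trial: %d replicate(s) x %d samples (seed %d, CV %.0f%%, add SD %.2g)\n",
    max(x$replicate_id), sum(x$replicate_id == 1L), attr(x, "seed"),
    100 * attr(x, "prop_cv"), attr(x, "add_sd")))
  invisible(x)
}

#' Write a virtual trial as CSV
#'
#' Columns `time_h`, `conc_mg_L`, `replicate_id`.
#' @param x a `virtual_trial`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_virtual_trial <- function(x, path) {
  utils::write.csv(
    as.data.frame(x)[, c("time_h", "conc_mg_L", "replicate_id")], path,
    row.names = FALSE)
  invisible(path)
}

#' Recover total clearance from a virtual trial
#'
#' Non-compartmental estimate: `CL = dose / AUC` with the AUC taken by
#' linear trapezoid over the observations of the final dose interval
#' (replicates averaged pointwise first). The trial must sample the full
#' final interval, including points near both interval ends.
#'
#' @param trial a [generate_virtual_trial()] result.
#' @return estimated total clearance, L/h.
#' @export
recover_clearance <- function(trial) {
  stopifnot(inherits(trial, "virtual_trial"))
  regimen <- attr(trial, "regimen")
  t0 <- (regimen$n_doses - 1) * regimen$interval_h
  t1 <- regimen$n_doses * regimen$interval_h
  agg <- stats::aggregate(conc_mg_L ~ time_h, data = trial, FUN = mean)
  sel <- agg$time_h >= t0 - 1e-9 & agg$time_h <= t1 + 1e-9
  tt <- agg$time_h[sel]
  cc <- agg$conc_mg_L[sel]
  tol <- 0.05 * regimen$interval_h
  if (length(tt) < 5L || min(tt) > t0 + tol || max(tt) < t1 - tol) {
    stop("insufficient sampling: the final dose interval [", t0, ", ", t1,
         "] h must be covered by at least 5 observations including both ",
         "interval ends", call. = FALSE)
  }
  auc <- sum(diff(tt) * (cc[-length(cc)] + cc[-1]) / 2)
  attr(trial, "dose_mg") / auc
}

#' Synthetic MIC frequency distributions
#'
#' Deterministic (seeded) stand-in distributions on the doubling-dilution
#' grid 0.125-8 mg/L, emulating the qualitative shape of surveillance
#' data: `MRSA_LIKE` concentrates at least 90% of its mass at MIC <= 0.5
#' mg/L (daptomycin is highly active against staphylococci at low MICs);
#' `EFAECIUM_LIKE` is shifted one to two dilutions higher. A small
#' seed-controlled log-normal jitter is applied to the base frequencies
#' and the result renormalized, so different seeds give slightly different
#' but structurally identical fixtures.
#'
#' These are synthetic fixtures, not surveillance data; absolute CFR
#' values computed from them are illustrative only.
#'
#' @param preset `"MRSA_LIKE"` or `"EFAECIUM_LIKE"`.
#' @param seed integer seed; the same seed reproduces the distribution.
#' @param jitter_sd SD of the log-normal jitter (0 gives the base shape).
#' @return a [mic_distribution()].
#' @examples
#' generate_mic_distribution("MRSA_LIKE", seed = 1)
#' @export
generate_mic_distribution <- function(preset = c("MRSA_LIKE", "EFAECIUM_LIKE"),
                                      seed = 1L, jitter_sd = 0.05) {
  preset <- match.arg(preset)
  base <- switch(preset,
    MRSA_LIKE = c(0.30, 0.38, 0.25, 0.055, 0.013, 0.002, 0),
    EFAECIUM_LIKE = c(0.02, 0.06, 0.17, 0.45, 0.25, 0.04, 0.01))
  f <- withr_seed({
    if (jitter_sd > 0) base * stats::rlnorm(length(base), 0, jitter_sd)
    else base
  }, seed)
  mic_distribution(frequencies = f / sum(f))
}
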