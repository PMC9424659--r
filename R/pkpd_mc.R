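#' MIC distribution on a doubling-dilution grid
#'
#' @param mics strictly increasing MIC grid, mg/L. Default is the
#'   doubling-dilution grid 0.125-8 mg/L used for the Monte-Carlo
#'   evaluation.
#' @param frequencies non-negative frequencies summing to 1 (within 1e-9).
#' @return an object of class `mic_distribution`.
#' @examples
#' mic_distribution(frequencies = c(.2, .3, .4, .08, .02, 0, 0))
#' @export
mic_distribution <- function(mics = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                             frequencies) {
  if (any(diff(mics) <= 0)) stop("mics must be strictly increasing",
                                 call. = FALSE)
  if (length(frequencies) != length(mics)) {
    stop("frequencies must match mics in length", call. = FALSE)
  }
  if (any(frequencies < 0)) stop("frequencies must be >= 0", call. = FALSE)
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must sum to 1", call. = FALSE)
  }
  structure(list(mics = mics, frequencies = frequencies),
            class = "mic_distribution")
}

#' @export
print.mic_distribution <- function(x, ...) {
  cat("MIC distribution (mg/L : frequency)\n")
  for (i in seq_along(x$mics)) {
    cat(sprintf("  %7.3f : %.4f\n", x$mics[i], x$frequencies[i]))
  }
  invisible(x)
}

#' Read or write a MIC distribution as CSV
#'
#' Columns `mic_mg_L`, `frequency`.
#' @param path CSV path.
#' @param x a `mic_distribution`.
#' @return `read_mic_distribution()` returns a `mic_distribution`;
#'   `write_mic_distribution()` returns `path` invisibly.
#' @export
read_mic_distribution <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mic_distribution(df$mic_mg_L, df$frequency)
}

#' @rdname read_mic_distribution
#' @export
write_mic_distribution <- function(x, path) {
  stopifnot(inherits(x, "mic_distribution"))
  utils::write.csv(data.frame(mic_mg_L = x$mics, frequency = x$frequencies),
                   path, row.names = FALSE)
  invisible(path)
}

#' Pharmacodynamic target presets
#'
#' Total-drug AUC/MIC targets: 666 for MRSA and 143 for *E. faecium*.
#'
#' @param pathogen `"MRSA"`, `"EFAECIUM"`, or a custom label if `target`
#'   is supplied.
#' @param target custom AUC/MIC target (overrides the preset).
#' @return an object of class `pd_target` with `pathogen` and
#'   `auc_mic_target`.
#' @examples
#' pd_target("MRSA")
#' @export
pd_target <- function(pathogen = c("MRSA", "EFAECIUM"), target = NULL) {
  if (is.null(target)) {
    pathogen <- match.arg(pathogen)
    target <- c(MRSA = 666, EFAECIUM = 143)[[pathogen]]
  }
  if (target <= 0) stop("target must be positive", call. = FALSE)
  structure(list(pathogen = pathogen, auc_mic_target = target),
            class = "pd_target")
}

#' Monte-Carlo steady-state exposure samples
#'
#' Draws a virtual population around the typical subject (log-normal
#' clearance and volume multipliers, see [sample_virtual_population()])
#' and computes each subject's steady-state exposure from the closed-form
#' solution: interval AUC is `dose / CL_i` (exact for a linear system),
#' reported as the average daily AUC(0-24), and the trough is the analytic
#' steady-state pre-dose concentration.
#'
#' @param base_subject the typical [make_subject()] individual.
#' @param clearance a calibrated [clearance_model()].
#' @param regimen a [dosing_regimen()].
#' @param n number of virtual subjects (default 10000).
#' @param seed integer seed.
#' @param cv_cl,cv_v population coefficients of variation.
#' @param drug [drug_parameters()].
#' @return an object of class `exposure_sample`: a data.frame with columns
#'   `auc_0_24`, `auc_interval`, `cmin_ss`, `cl_multiplier`,
#'   `v_multiplier`, and attributes `n`, `seed`, `regimen`,
#'   `deterministic` (the cv = 0 metrics).
#' @export
monte_carlo_exposures <- function(base_subject, clearance, regimen,
                                  n = 10000L, seed = 1L, cv_cl = 0.25,
                                  cv_v = 0.15, drug = drug_parameters()) {
  stopifnot(inherits(base_subject, "subject"))
  pop <- sample_virtual_population(base_subject, n, cv_cl, cv_v, seed)
  dose_mg <- regimen$dose_mg_per_kg * base_subject$weight_kg

  expose <- function(cl_mult, v_mult) {
    cl_i <- clearance$cl_total * cl_mult
    vss_i <- drug$vss_per_kg * base_subject$weight_kg * v_mult
    auc_int <- dose_mg / cl_i
    cmin <- ss_trough_vec(cl_i, vss_i, drug$central_fraction,
                          drug$q_per_kg * base_subject$weight_kg,
                          dose_mg, regimen)
    data.frame(auc_0_24 = auc_int * 24 / regimen$interval_h,
               auc_interval = auc_int, cmin_ss = cmin,
               cl_multiplier = cl_mult, v_multiplier = v_mult)
  }

  out <- expose(pop$cl_multipliers, pop$v_multipliers)
  det <- expose(1, 1)
  structure(out, class = c("exposure_sample", "data.frame"),
            n = as.integer(n), seed = as.integer(seed), regimen = regimen,
            deterministic = det)
}

# vectorised analytic steady-state trough for the two-compartment
# infusion model (scalar fallback to one compartment when fc = 1 / q = 0)
ss_trough_vec <- function(cl, vss, fc, q, dose_mg, regimen) {
  tau <- regimen$interval_h
  tinf <- regimen$infusion_duration_h
  r0 <- dose_mg / tinf
  if (fc >= 1 - 1e-9 || q < 1e-12) {
    k <- cl / vss
    return(r0 / cl * (1 - exp(-k * tinf)) * exp(-k * (tau - tinf)) /
             (1 - exp(-k * tau)))
  }
  v1 <- fc * vss
  v2 <- (1 - fc) * vss
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  a <- (alpha - k21) / (alpha - beta)
  b <- (k21 - beta) / (alpha - beta)
  term <- function(coef, lam) {
    coef * (1 - exp(-lam * tinf)) / lam * exp(-lam * (tau - tinf)) /
      (1 - exp(-lam * tau))
  }
  (r0 / v1) * (term(a, alpha) + term(b, beta))
}

#' Probability of target attainment at one MIC
#'
#' Fraction of simulated subjects whose AUC/MIC ratio meets the
#' pharmacodynamic target.
#'
#' @param auc_samples numeric vector of AUC(0-24) samples (ug.h/mL), or an
#'   [monte_carlo_exposures()] result.
#' @param mic MIC, mg/L, positive.
#' @param target a [pd_target()] (or a bare numeric target).
#' @return attainment fraction in `[0, 1]`.
#' @examples
#' pta(c(600, 700, 800), 1, pd_target("MRSA")) # 2/3
#' @export
pta <- function(auc_samples, mic, target = pd_target("MRSA")) {
  if (inherits(auc_samples, "exposure_sample")) {
    auc_samples <- auc_samples$auc_0_24
  }
  if (length(auc_samples) == 0L) stop("auc_samples is empty", call. = FALSE)
  if (mic <= 0) stop("mic must be positive", call. = FALSE)
  tgt <- if (inherits(target, "pd_target")) target$auc_mic_target else target
  mean(auc_samples / mic >= tgt)
}

#' PTA across a MIC grid
#'
#' @inheritParams pta
#' @param mics MIC grid, mg/L.
#' @return an object of class `pta_result`: data.frame with `mic` and
#'   `pta` columns (plus `n` and `seed` attributes when available).
#' @export
pta_curve <- function(auc_samples, mics = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                      target = pd_target("MRSA")) {
  n <- if (inherits(auc_samples, "exposure_sample")) {
    attr(auc_samples, "n")
  } else {
    length(auc_samples)
  }
  seed <- if (inherits(auc_samples, "exposure_sample")) {
    attr(auc_samples, "seed")
  } else {
    NA_integer_
  }
  out <- data.frame(mic = mics,
                    pta = vapply(mics, function(m) pta(auc_samples, m, target),
                                 numeric(1)))
  structure(out, class = c("pta_result", "data.frame"), n = n, seed = seed,
            target = target)
}

#' Cumulative fraction of response
#'
#' PTA weighted by the pathogen's MIC frequency distribution:
#' `CFR = sum_i PTA(mic_i) * freq_i`. Every MIC with non-zero frequency
#' must have a PTA value.
#'
#' @param pta_by_mic a [pta_curve()] result, or a named numeric vector of
#'   PTA values with MICs as names.
#' @param mic_dist a [mic_distribution()].
#' @return an object of class `cfr_result`: a list with `cfr`, the PTA
#'   table and the distribution used.
#' @examples
#' d <- mic_distribution(c(0.5, 1, 2), c(0.6, 0.3, 0.1))
#' cfr(c("0.5" = 1, "1" = 0.5, "2" = 0), d)$cfr # 0.75
#' @export
cfr <- function(pta_by_mic, mic_dist) {
  stopifnot(inherits(mic_dist, "mic_distribution"))
  if (inherits(pta_by_mic, "pta_result")) {
    ptas <- stats::setNames(pta_by_mic$pta, pta_by_mic$mic)
  } else {
    ptas <- pta_by_mic
  }
  mic_key <- as.character(mic_dist$mics)
  active <- mic_dist$frequencies > 0
  missing <- setdiff(mic_key[active], names(ptas))
  if (length(missing) > 0L) {
    stop("no PTA available for MIC(s) with non-zero frequency: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- rep(0, length(mic_key))
  p[active] <- unname(ptas[mic_key[active]])
  structure(
    list(cfr = sum(p * mic_dist$frequencies),
         pta = stats::setNames(p, mic_key), mic_dist = mic_dist),
    class = "cfr_result"
  )
}

#' @export
print.cfr_result <- function(x, ...) {
  cat(sprintf("CFR = %.4f (%.2f%%)\n", x$cfr, 100 * x$cfr))
  invisible(x)
}

#' Trough-concentration safety flag
#'
#' Steady-state troughs at or above 24.3 mg/L are associated with elevated
#' creatine phosphokinase; this reports the fraction of simulated subjects
#' at or above the threshold and flags the typical (deterministic)
#' subject.
#'
#' @param cmin_samples numeric vector of steady-state troughs (mg/L), or a
#'   [monte_carlo_exposures()] result.
#' @param threshold trough threshold, mg/L (default 24.3).
#' @param deterministic_cmin the cv = 0 typical trough; taken from the
#'   exposure sample when available.
#' @return a list with `fraction_exceeding`, `flag` (typical subject at or
#'   above threshold) and `threshold`.
#' @examples
#' cmin_safety_flag(c(10, 20, 30)) # fraction 1/3
#' @export
cmin_safety_flag <- function(cmin_samples, threshold = 24.3,
                             deterministic_cmin = NULL) {
  if (inherits(cmin_samples, "exposure_sample")) {
    if (is.null(deterministic_cmin)) {
      deterministic_cmin <- attr(cmin_samples, "deterministic")$cmin_ss
    }
    cmin_samples <- cmin_samples$cmin_ss
  }
  if (length(cmin_samples) == 0L) stop("cmin_samples is empty",
                                       call. = FALSE)
  if (is.null(deterministic_cmin)) deterministic_cmin <- NA_real_
  list(fraction_exceeding = mean(cmin_samples >= threshold),
       flag = isTRUE(deterministic_cmin >= threshold),
       threshold = threshold)
}
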