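#' Renal function staging used throughout the package
#'
#' Renal function is staged on normalized glomerular filtration rate
#' (GFR, mL/min/1.73 m2) using the conventional chronic-kidney-disease
#' bands: HEALTHY >= 90, MILD 60 to <90, MODERATE 30 to <60, SEVERE
#' 15 to <30, ESRD (end-stage renal disease) <15. The bands partition
#' `[0, Inf)` with no gaps or overlaps.
#'
#' Because only the band edges are conventional, each category carries a
#' representative normalized GFR used when constructing typical subjects:
#' the band midpoint for the impaired stages (MILD 75, MODERATE 45,
#' SEVERE 22.5, ESRD 7.5) and 120 for healthy adults. These are
#' configurable via the `representative` argument.
#'
#' @param label one of `"HEALTHY"`, `"MILD"`, `"MODERATE"`, `"SEVERE"`,
#'   `"ESRD"`.
#' @param representative optional named numeric vector overriding the
#'   default representative normalized GFR (mL/min/1.73 m2) per category.
#' @return an object of class `renal_category`: a list with `label`,
#'   `gfr_band_lo`, `gfr_band_hi` and `representative_gfr_norm`.
#' @examples
#' renal_category("MODERATE")
#' @export
renal_category <- function(label, representative = NULL) {
  label <- match.arg(label, renal_category_labels())
  bands <- renal_category_bands()
  rep_gfr <- c(HEALTHY = 120, MILD = 75, MODERATE = 45, SEVERE = 22.5,
               ESRD = 7.5)
  if (!is.null(representative)) {
    stopifnot(all(names(representative) %in% names(rep_gfr)))
    rep_gfr[names(representative)] <- representative
  }
  lo <- bands[[label]][1L]
  hi <- bands[[label]][2L]
  g <- unname(rep_gfr[[label]])
  if (g < lo || (is.finite(hi) && g >= hi)) {
    stop("representative GFR ", g, " lies outside the ", label, " band [",
         lo, ", ", hi, ")", call. = FALSE)
  }
  structure(
    list(label = label, gfr_band_lo = lo, gfr_band_hi = hi,
         representative_gfr_norm = g),
    class = "renal_category"
  )
}

renal_category_labels <- function() {
  c("HEALTHY", "MILD", "MODERATE", "SEVERE", "ESRD")
}

renal_category_bands <- function() {
  list(HEALTHY = c(90, Inf), MILD = c(60, 90), MODERATE = c(30, 60),
       SEVERE = c(15, 30), ESRD = c(0, 15))
}

#' @export
print.renal_category <- function(x, ...) {
  cat(sprintf("renal category %s: GFR [%s, %s) mL/min/1.73m2, typical %.1f\n",
              x$label, format(x$gfr_band_lo), format(x$gfr_band_hi),
              x$representative_gfr_norm))
  invisible(x)
}

#' Recover height from weight and body-mass index
#'
#' Published demographic tables often print weight and BMI but not height;
#' height follows from the BMI definition `bmi = weight / height^2`.
#'
#' @param weight_kg body weight (kg), positive.
#' @param bmi body-mass index (kg/m2), positive.
#' @return height in metres.
#' @examples
#' derive_height_from_bmi(70, 25.71) # 1.65 m
#' @export
derive_height_from_bmi <- function(weight_kg, bmi) {
  if (any(weight_kg <= 0) || any(bmi <= 0)) {
    stop("weight_kg and bmi must be positive", call. = FALSE)
  }
  sqrt(weight_kg / bmi)
}

#' Body surface area
#'
#' Du Bois formula by default (`0.007184 * W^0.425 * Hcm^0.725`); the
#' Haycock formula is available as an alternative. BSA converts normalized
#' GFR (per 1.73 m2) into absolute GFR.
#'
#' @param weight_kg body weight (kg), positive.
#' @param height_m height (m), positive.
#' @param method `"dubois"` (default) or `"haycock"`.
#' @return body surface area in m2.
#' @examples
#' body_surface_area(70, 1.65) # about 1.77 m2
#' @export
body_surface_area <- function(weight_kg, height_m, method = c("dubois", "haycock")) {
  method <- match.arg(method)
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight_kg and height_m must be positive", call. = FALSE)
  }
  h_cm <- 100 * height_m
  switch(method,
    dubois = 0.007184 * weight_kg^0.425 * h_cm^0.725,
    haycock = 0.024265 * weight_kg^0.5378 * h_cm^0.3964
  )
}

#' Normal pediatric GFR by age
#'
#' Healthy normalized GFR matures rapidly after birth and is close to the
#' adult value by about two years of age. The default maturation curve is a
#' Hill function of postmenstrual age (PMA, weeks),
#' `adult_gfr * PMA^h / (PMA^h + tm50^h)` with `h = 3.4` and
#' `tm50 = 47.7` weeks, a standard renal-maturation description. PMA is
#' taken as `40 + 52.14 * age_years` (term birth assumed).
#'
#' @param age_years postnatal age in years (>= 0).
#' @param adult_gfr normalized adult GFR plateau (mL/min/1.73 m2).
#' @param hill Hill coefficient of the maturation curve.
#' @param tm50_weeks PMA at half-maturation (weeks).
#' @return normalized GFR, mL/min/1.73 m2.
#' @examples
#' pediatric_gfr_normal(c(1, 2, 5, 15))
#' @export
pediatric_gfr_normal <- function(age_years, adult_gfr = 120, hill = 3.4,
                                 tm50_weeks = 47.7) {
  if (any(age_years < 0)) stop("age_years must be >= 0", call. = FALSE)
  pma <- 40 + 52.14 * age_years
  adult_gfr * pma^hill / (pma^hill + tm50_weeks^hill)
}

fup_for_category <- function(label, population) {
  # unbound fraction in plasma: 8% healthy, 9% mild impairment, 10% from
  # moderate impairment through ESRD; healthy elderly corrected to 9%
  # (lower serum albumin in the elderly reference cohort)
  fup <- switch(label,
    HEALTHY = 0.08, MILD = 0.09, MODERATE = 0.10, SEVERE = 0.10, ESRD = 0.10)
  if (identical(population, "ELDERLY_RI_COHORT") && label == "HEALTHY") {
    fup <- 0.09
  }
  fup
}

#' Construct a virtual subject
#'
#' Builds one typical individual from the printed demographics (age,
#' weight, BMI), a renal-function category and a population tag. Height is
#' recovered from BMI, body surface area via Du Bois, normalized GFR is the
#' category's representative value (for healthy children, capped by the
#' age-appropriate normal from [pediatric_gfr_normal()]), and absolute GFR
#' is `gfr_norm * bsa / 1.73`. The unbound plasma fraction follows the
#' renal stage: 0.08 healthy, 0.09 mild, 0.10 moderate through ESRD, with
#' healthy corrected to 0.09 for the elderly renal-impairment cohort.
#'
#' @param age_years age in years; subjects below 1 year are not supported.
#' @param weight_kg body weight (kg).
#' @param bmi body-mass index (kg/m2).
#' @param category a [renal_category()] or its label.
#' @param population `"ADULT"`, `"CHILD"` or `"ELDERLY_RI_COHORT"`.
#' @param sex `"M"` or `"F"` (metadata only).
#' @param bsa_method passed to [body_surface_area()].
#' @return an object of class `subject`.
#' @examples
#' make_subject(35, 70, 25.71, "HEALTHY", "ADULT")
#' make_subject(5, 18, 15.68, "ESRD", "CHILD")
#' @export
make_subject <- function(age_years, weight_kg, bmi, category,
                         population = c("ADULT", "CHILD", "ELDERLY_RI_COHORT"),
                         sex = c("M", "F"), bsa_method = "dubois") {
  population <- match.arg(population)
  sex <- match.arg(sex)
  if (age_years < 1) {
    stop("subjects under 1 year of age are not supported", call. = FALSE)
  }
  if (age_years > 100) stop("age_years implausibly large", call. = FALSE)
  if (is.character(category)) category <- renal_category(category)
  stopifnot(inherits(category, "renal_category"))

  height_m <- derive_height_from_bmi(weight_kg, bmi)
  bsa_m2 <- body_surface_area(weight_kg, height_m, method = bsa_method)

  gfr_norm <- category$representative_gfr_norm
  if (population == "CHILD" && category$label == "HEALTHY") {
    gfr_norm <- pediatric_gfr_normal(age_years, adult_gfr = gfr_norm)
  }
  gfr_abs <- gfr_norm * bsa_m2 / 1.73

  structure(
    list(age_years = age_years, weight_kg = weight_kg, height_m = height_m,
         bsa_m2 = bsa_m2, gfr_norm = gfr_norm, gfr_abs = gfr_abs,
         fup = fup_for_category(category$label, population),
         category = category, population = population, sex = sex),
    class = "subject"
  )
}

#' @export
print.subject <- function(x, ...) {
  cat(sprintf(
    "virtual subject (%s, %s): %.0f y, %.1f kg, %.2f m, BSA %.3f m2\n",
    x$population, x$sex, x$age_years, x$weight_kg, x$height_m, x$bsa_m2))
  cat(sprintf(
    "  renal: %s, GFR %.1f mL/min/1.73m2 (%.1f mL/min absolute), fup %.2f\n",
    x$category$label, x$gfr_norm, x$gfr_abs, x$fup))
  invisible(x)
}

#' Sample a virtual population around a typical subject
#'
#' Inter-individual variability enters as per-subject log-normal
#' multiplicative factors on clearance and on distribution volume with
#' median 1 (meanlog 0), the standard population-PK parameterisation. With
#' zero coefficients of variation every factor is exactly 1.
#'
#' @param base_subject the typical [make_subject()] individual.
#' @param n number of virtual subjects (>= 1).
#' @param cv_cl,cv_v coefficients of variation (e.g. 0.25 for 25%) of the
#'   clearance and volume multipliers; must be >= 0.
#' @param seed integer seed; the same seed reproduces identical samples.
#' @return an object of class `population_sample` with `cl_multipliers`,
#'   `v_multipliers`, `n` and `seed`.
#' @examples
#' pop <- sample_virtual_population(
#'   make_subject(35, 70, 25.71, "HEALTHY", "ADULT"), 100, seed = 1)
#' @export
sample_virtual_population <- function(base_subject, n, cv_cl = 0.25,
                                      cv_v = 0.15, seed = 1L) {
  stopifnot(inherits(base_subject, "subject"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (cv_cl < 0 || cv_v < 0) stop("cv values must be >= 0", call. = FALSE)
  sdlog_cl <- sqrt(log(1 + cv_cl^2))
  sdlog_v <- sqrt(log(1 + cv_v^2))
  cl_mult <- v_mult <- rep(1, n)
  withr_seed({
    if (sdlog_cl > 0) cl_mult <- stats::rlnorm(n, 0, sdlog_cl)
    if (sdlog_v > 0) v_mult <- stats::rlnorm(n, 0, sdlog_v)
  }, seed)
  structure(
    list(n = as.integer(n), base_subject = base_subject,
         cl_multipliers = cl_mult, v_multipliers = v_mult,
         cv_cl = cv_cl, cv_v = cv_v, seed = as.integer(seed)),
    class = "population_sample"
  )
}

# evaluate expr under a local RNG seed without disturbing the caller's
# RNG state
withr_seed <- function(expr, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @export
print.population_sample <- function(x, ...) {
  cat(sprintf(
    "virtual population: n = %d (seed %d), CL CV %.0f%%, V CV %.0f%%\n",
    x$n, x$seed, 100 * x$cv_cl, 100 * x$cv_v))
  invisible(x)
}

#' Convert a subject or population to a data frame
#'
#' One row per subject with documented column names; suitable for
#' [utils::write.csv()].
#'
#' @param x a `subject` or `population_sample`.
#' @param row.names,optional,... standard [as.data.frame()] arguments.
#' @return a data.frame with columns `age_years`, `weight_kg`, `height_m`,
#'   `bsa_m2`, `gfr_norm`, `gfr_abs`, `fup`, `category`, `population`,
#'   `sex`, and for populations additionally `cl_multiplier` and
#'   `v_multiplier`.
#' @export
as.data.frame.subject <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(age_years = x$age_years, weight_kg = x$weight_kg,
             height_m = x$height_m, bsa_m2 = x$bsa_m2,
             gfr_norm = x$gfr_norm, gfr_abs = x$gfr_abs, fup = x$fup,
             category = x$category$label, population = x$population,
             sex = x$sex, row.names = row.names,
             stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.subject
#' @export
as.data.frame.population_sample <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  base <- as.data.frame(x$base_subject)
  out <- base[rep(1L, x$n), , drop = FALSE]
  out$cl_multiplier <- x$cl_multipliers
  out$v_multiplier <- x$v_multipliers
  rownames(out) <- NULL
  out
}
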