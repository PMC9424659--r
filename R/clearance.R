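#' Clearance decomposition model
#'
#' Total clearance is split into a renal and a non-renal route. Renal
#' clearance is treated as pure glomerular filtration of unbound drug:
#' `CL_renal = CL_filt + CL_sec - CL_reabs` with secretion and reabsorption
#' structurally present but fixed at zero (no evidence of tubular handling
#' for daptomycin), so `CL_renal = fup * GFR`. The non-renal route is
#' modeled as a constant first-order hepatic (biliary) clearance `CL_H`,
#' giving `CL = fup * GFR + CL_H`.
#'
#' A model is *calibrated* once `cl_hepatic` is known (see
#' [calibrate_hepatic_clearance()]); simulation refuses uncalibrated
#' models.
#'
#' @param cl_filt filtration clearance, L/h.
#' @param cl_hepatic non-renal (hepatic/biliary) clearance, L/h, or `NA`
#'   before calibration.
#' @param cl_sec,cl_reabs tubular secretion and reabsorption clearances,
#'   L/h; zero in this model but kept so the renal identity stays testable.
#' @param population population tag of the subject the model describes.
#' @param healthy_cl_renal the healthy renal clearance (L/h) of the
#'   population this model was calibrated on; retained so impairment and
#'   pediatric scaling can preserve the renal:non-renal split.
#' @return an object of class `clearance_model` with elements `cl_filt`,
#'   `cl_sec`, `cl_reabs`, `cl_renal`, `cl_hepatic`, `cl_total`.
#' @export
clearance_model <- function(cl_filt, cl_hepatic = NA_real_, cl_sec = 0,
                            cl_reabs = 0, population = "ADULT",
                            healthy_cl_renal = NA_real_) {
  stopifnot(cl_filt >= 0, cl_sec >= 0, cl_reabs >= 0)
  if (!is.na(cl_hepatic) && cl_hepatic < 0) {
    stop("cl_hepatic must be >= 0", call. = FALSE)
  }
  cl_renal <- cl_filt + cl_sec - cl_reabs
  if (cl_renal < 0) stop("renal clearance terms give a negative CL_renal",
                         call. = FALSE)
  structure(
    list(cl_filt = cl_filt, cl_sec = cl_sec, cl_reabs = cl_reabs,
         cl_renal = cl_renal, cl_hepatic = cl_hepatic,
         cl_total = cl_renal + cl_hepatic, population = population,
         healthy_cl_renal = healthy_cl_renal),
    class = "clearance_model"
  )
}

#' @export
print.clearance_model <- function(x, ...) {
  cat(sprintf("clearance model (%s):\n", x$population))
  cat(sprintf("  renal %.4f L/h (filt %.4f, sec %.4f, reabs %.4f)\n",
              x$cl_renal, x$cl_filt, x$cl_sec, x$cl_reabs))
  cat(sprintf("  hepatic %.4f L/h, total %.4f L/h%s\n",
              x$cl_hepatic, x$cl_total,
              if (is_calibrated(x)) "" else "  [uncalibrated]"))
  invisible(x)
}

is_calibrated <- function(model) {
  inherits(model, "clearance_model") && !is.na(model$cl_hepatic)
}

#' Renal filtration clearance of a subject
#'
#' `CL_renal = fup * GFR_abs`, converted from mL/min to L/h. Only the
#' unbound fraction of drug is filtered at the glomerulus.
#'
#' @param subject a [make_subject()] individual.
#' @return renal clearance in L/h.
#' @examples
#' adult <- make_subject(35, 70, 25.71, "HEALTHY", "ADULT")
#' renal_filtration_clearance(adult) # about 0.59 L/h
#' @export
renal_filtration_clearance <- function(subject) {
  stopifnot(inherits(subject, "subject"))
  subject$fup * subject$gfr_abs * 60 / 1000
}

#' Calibrate the non-renal clearance against a total-clearance reference
#'
#' Non-renal clearance is not identifiable on its own; it is estimated by
#' subtracting the renal (filtration) clearance from a reference total
#' clearance, typically `dose / AUC` from the healthy multiple-dose
#' exposure. The result is attached to the model as a constant thereafter.
#'
#' @param cl_total_ref reference total clearance, L/h; must be >= the
#'   renal clearance.
#' @param cl_renal renal clearance, L/h.
#' @return non-renal (hepatic) clearance, L/h.
#' @examples
#' calibrate_hepatic_clearance(420 / 580, 0.5897) # about 0.134 L/h
#' @export
calibrate_hepatic_clearance <- function(cl_total_ref, cl_renal) {
  if (cl_total_ref < 0 || cl_renal < 0) {
    stop("clearances must be >= 0", call. = FALSE)
  }
  if (cl_total_ref < cl_renal) {
    stop("calibration error: reference total clearance (", cl_total_ref,
         ") is below the renal clearance (", cl_renal, ")", call. = FALSE)
  }
  cl_total_ref - cl_renal
}

#' Build a calibrated clearance model for a healthy subject
#'
#' Convenience wrapper: computes the filtration clearance from the subject
#' and calibrates the hepatic route against `cl_total_ref`.
#'
#' @param subject a healthy [make_subject()] individual.
#' @param cl_total_ref reference total clearance, L/h (e.g. dose/AUC).
#' @return a calibrated `clearance_model`.
#' @examples
#' adult <- make_subject(35, 70, 25.71, "HEALTHY", "ADULT")
#' build_clearance_model(adult, 420 / 580)
#' @export
build_clearance_model <- function(subject, cl_total_ref) {
  stopifnot(inherits(subject, "subject"))
  cl_renal <- renal_filtration_clearance(subject)
  clearance_model(
    cl_filt = cl_renal,
    cl_hepatic = calibrate_hepatic_clearance(cl_total_ref, cl_renal),
    population = subject$population,
    healthy_cl_renal = cl_renal
  )
}

#' Modify a calibrated model for renal impairment
#'
#' Renal clearance is recomputed from the impaired subject's `fup * GFR`
#' while the non-renal (biliary) clearance is left unchanged -- renal
#' disease alters filtration, not the hepatic route in this model -- and
#' the total is re-summed.
#'
#' @param model a calibrated `clearance_model`.
#' @param subject_impaired the impaired [make_subject()] individual; must
#'   belong to the same population the model was calibrated on.
#' @return a new calibrated `clearance_model`.
#' @export
apply_renal_impairment <- function(model, subject_impaired) {
  stopifnot(inherits(subject_impaired, "subject"))
  if (!is_calibrated(model)) {
    stop("model must be calibrated before applying renal impairment",
         call. = FALSE)
  }
  if (!identical(model$population, subject_impaired$population)) {
    stop("population mismatch: model is ", model$population,
         " but subject is ", subject_impaired$population, call. = FALSE)
  }
  clearance_model(
    cl_filt = renal_filtration_clearance(subject_impaired),
    cl_hepatic = model$cl_hepatic,
    population = model$population,
    healthy_cl_renal = model$healthy_cl_renal
  )
}

#' Scale a calibrated adult model to a child
#'
#' Pediatric renal clearance follows the child's own `fup * GFR`
#' (age-dependent maturation enters through the subject's normalized GFR).
#' Pediatric non-renal clearance is scaled by holding the adult
#' non-renal:renal ratio fixed: `CL_H,child = (CL_H,adult /
#' CL_renal,adult,healthy) * CL_renal,child,healthy`, and is then frozen
#' across the child's impairment categories (use
#' [apply_renal_impairment()] on the returned model).
#'
#' @param adult_model a calibrated healthy-adult `clearance_model`.
#' @param adult_subject the healthy adult the model was calibrated on.
#' @param child_subject the pediatric [make_subject()] individual
#'   (population `"CHILD"`, age >= 1 y).
#' @param child_healthy_subject optional healthy counterpart of
#'   `child_subject` (same body size) used to anchor the renal:non-renal
#'   split; defaults to `child_subject` if it is healthy, otherwise it is
#'   rebuilt with a HEALTHY category.
#' @return a calibrated pediatric `clearance_model`.
#' @export
scale_to_pediatric <- function(adult_model, adult_subject, child_subject,
                               child_healthy_subject = NULL) {
  stopifnot(inherits(adult_subject, "subject"),
            inherits(child_subject, "subject"))
  if (!is_calibrated(adult_model)) {
    stop("adult model must be calibrated", call. = FALSE)
  }
  if (child_subject$age_years < 1) {
    stop("subjects under 1 year of age are not supported", call. = FALSE)
  }
  if (is.null(child_healthy_subject)) {
    child_healthy_subject <- if (child_subject$category$label == "HEALTHY") {
      child_subject
    } else {
      make_subject(child_subject$age_years, child_subject$weight_kg,
                   child_subject$weight_kg / child_subject$height_m^2,
                   "HEALTHY", child_subject$population,
                   child_subject$sex)
    }
  }
  adult_healthy_renal <- adult_model$healthy_cl_renal
  if (is.na(adult_healthy_renal)) {
    adult_healthy_renal <- renal_filtration_clearance(adult_subject)
  }
  ratio <- adult_model$cl_hepatic / adult_healthy_renal
  child_healthy_renal <- renal_filtration_clearance(child_healthy_subject)
  clearance_model(
    cl_filt = renal_filtration_clearance(child_subject),
    cl_hepatic = ratio * child_healthy_renal,
    population = child_subject$population,
    healthy_cl_renal = child_healthy_renal
  )
}

#' Read or write a clearance model as JSON
#'
#' @param path file path.
#' @param x a `clearance_model`.
#' @return `read_clearance_model()` returns a `clearance_model`;
#'   `write_clearance_model()` returns `path` invisibly.
#' @export
write_clearance_model <- function(x, path) {
  stopifnot(inherits(x, "clearance_model"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_clearance_model
#' @export
read_clearance_model <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  clearance_model(cl_filt = vals$cl_filt, cl_hepatic = vals$cl_hepatic,
                  cl_sec = vals$cl_sec, cl_reabs = vals$cl_reabs,
                  population = vals$population,
                  healthy_cl_renal = vals$healthy_cl_renal %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
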