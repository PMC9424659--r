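# shared fixtures: the calibrated healthy reference adult and a standard
# steady-state sampling design that resolves the 30-min infusion

ref_adult <- function() make_subject(35, 70, 25.71, "HEALTHY", "ADULT")

ref_adult_clearance <- function() {
  build_clearance_model(ref_adult(), 420 / 580)
}

# sampling times over the final interval of a q24h x 5 regimen, dense
# around the infusion so trapezoid AUC carries little design bias
ss_sampling_times <- function(t0 = 96) {
  t0 + c(0, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24)
}

# hand-built profile (e.g. a constant curve) for metric unit tests
manual_profile <- function(time_h, conc, regimen,
                           lambda = 0.1, coef = 1) {
  structure(data.frame(time_h = time_h, conc_mg_L = conc),
            class = c("conc_profile", "data.frame"),
            regimen = regimen, dose_mg = NA_real_,
            disposition = list(lambda = lambda, coef = coef))
}
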