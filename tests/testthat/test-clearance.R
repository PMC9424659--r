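test_that("renal clearance is filtration of unbound drug with unit conversion", {
  adult <- ref_adult()
  # fup 0.08 x gfr_abs 122.84 mL/min -> L/h
  expect_equal(renal_filtration_clearance(adult),
               0.08 * adult$gfr_abs * 60 / 1000)
  expect_equal(renal_filtration_clearance(adult), 0.58965,
               tolerance = 1e-4)
  # proportionality in fup at equal GFR
  a10 <- make_subject(35, 70, 25.71, "MODERATE", "ADULT")
  a08 <- ref_adult()
  scaled <- renal_filtration_clearance(a10) * (a08$gfr_abs / a10$gfr_abs)
  expect_equal(scaled / renal_filtration_clearance(a08), 0.10 / 0.08)
})

test_that("hepatic calibration subtracts renal from the reference total", {
  expect_equal(calibrate_hepatic_clearance(420 / 580, 0.58965),
               420 / 580 - 0.58965)
  expect_equal(calibrate_hepatic_clearance(0.5, 0.5), 0)
  expect_error(calibrate_hepatic_clearance(0.4, 0.5), "calibration error")
  expect_error(calibrate_hepatic_clearance(-1, 0.5), ">= 0")
})

test_that("the clearance identities hold exactly for constructed models", {
  cm <- ref_adult_clearance()
  expect_equal(cm$cl_renal, cm$cl_filt + cm$cl_sec - cm$cl_reabs)
  expect_equal(cm$cl_total, cm$cl_renal + cm$cl_hepatic)
  expect_equal(cm$cl_total, 420 / 580, tolerance = 1e-12)
  expect_equal(cm$cl_hepatic, 0.134486, tolerance = 1e-4)
  expect_equal(cm$cl_sec, 0)
  expect_equal(cm$cl_reabs, 0)
})

test_that("renal impairment rescales filtration only and lowers total monotonically", {
  cm <- ref_adult_clearance()
  cats <- c("HEALTHY", "MILD", "MODERATE", "SEVERE", "ESRD")
  models <- lapply(cats, function(cat) {
    apply_renal_impairment(cm, make_subject(35, 70, 25.71, cat, "ADULT"))
  })
  totals <- vapply(models, `[[`, numeric(1), "cl_total")
  hepatics <- vapply(models, `[[`, numeric(1), "cl_hepatic")
  expect_true(all(diff(totals) < 0))
  expect_equal(hepatics, rep(cm$cl_hepatic, 5))
  # HEALTHY -> HEALTHY is the identity
  expect_equal(models[[1]]$cl_total, cm$cl_total)
  # ESRD renal clearance shrinks by more than 90% despite the higher fup
  expect_lt(models[[5]]$cl_renal / cm$cl_renal, 0.1)
  # population mismatch refused
  child <- make_subject(5, 18, 15.68, "ESRD", "CHILD")
  expect_error(apply_renal_impairment(cm, child), "population mismatch")
  # uncalibrated model refused
  raw <- clearance_model(0.5)
  expect_error(apply_renal_impairment(raw, ref_adult()), "calibrated")
})

test_that("pediatric scaling preserves the adult non-renal:renal ratio", {
  adult <- ref_adult()
  cm <- ref_adult_clearance()
  child <- make_subject(5, 18, 15.68, "HEALTHY", "CHILD")
  ped <- scale_to_pediatric(cm, adult, child)
  adult_ratio <- cm$cl_hepatic / cm$cl_renal
  expect_equal(ped$cl_hepatic, adult_ratio * ped$cl_renal)
  expect_equal(ped$cl_renal, renal_filtration_clearance(child))

  # a child with adult-equal fup, GFR and weight reproduces the adult model
  twin <- make_subject(17, 70, 25.71, "HEALTHY", "CHILD")
  twin$gfr_norm <- adult$gfr_norm
  twin$gfr_abs <- adult$gfr_abs
  twin$fup <- adult$fup
  ped_twin <- scale_to_pediatric(cm, adult, twin,
                                 child_healthy_subject = twin)
  expect_equal(ped_twin$cl_total, cm$cl_total, tolerance = 1e-12)

  # hepatic clearance frozen across the child's impairment categories
  sick <- make_subject(5, 18, 15.68, "ESRD", "CHILD")
  ped_sick <- apply_renal_impairment(ped, sick)
  expect_equal(ped_sick$cl_hepatic, ped$cl_hepatic)

  expect_error(scale_to_pediatric(cm, adult,
    structure(list(age_years = 0.5), class = "subject")), "under 1 year")
})

test_that("per-kg total clearance decreases with age in children", {
  adult <- ref_adult()
  cm <- ref_adult_clearance()
  young <- make_subject(1, 10.23, 17.1, "HEALTHY", "CHILD")
  old <- make_subject(15, 70.6, 22.8, "HEALTHY", "CHILD")
  cl_kg_young <- scale_to_pediatric(cm, adult, young)$cl_total /
    young$weight_kg
  cl_kg_old <- scale_to_pediatric(cm, adult, old)$cl_total /
    old$weight_kg
  expect_gt(cl_kg_young, cl_kg_old)
})

test_that("clearance models survive a JSON round trip", {
  cm <- ref_adult_clearance()
  path <- withr::local_tempfile(fileext = ".json")
  write_clearance_model(cm, path)
  back <- read_clearance_model(path)
  expect_equal(back$cl_total, cm$cl_total)
  expect_equal(back$cl_hepatic, cm$cl_hepatic)
  expect_equal(back$population, cm$population)
})

test_that("drug parameters default to the validated compound set and round-trip", {
  d <- drug_parameters()
  expect_equal(d$molecular_weight, 1620.7)
  expect_equal(d$log_p, 1.2)
  expect_equal(d$solubility, 17.89)
  expect_equal(d$pka_acid, 2.98)
  expect_equal(d$pka_base, 9.59)
  expect_equal(d$blood_to_plasma_ratio, 0.2)
  expect_equal(d$vss_per_kg, 0.1)
  expect_equal(d$binding_protein, "human serum albumin")

  packaged <- read_drug_parameters(
    daptosim_extdata("daptomycin_parameters.json"))
  expect_equal(packaged[names(d)], unclass(d)[names(d)])

  path <- withr::local_tempfile(fileext = ".json")
  write_drug_parameters(d, path)
  expect_equal(unclass(read_drug_parameters(path)), unclass(d))
  expect_error(read_drug_parameters("no/such/file.json"), "not found")
})
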