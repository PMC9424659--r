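test_that("MIC distributions validate their grid and frequencies", {
  d <- mic_distribution(frequencies = c(.2, .3, .4, .08, .02, 0, 0))
  expect_equal(d$mics, c(0.125, 0.25, 0.5, 1, 2, 4, 8))
  expect_error(mic_distribution(c(1, 0.5), c(0.5, 0.5)),
               "strictly increasing")
  expect_error(mic_distribution(c(0.5, 1), c(0.6, 0.6)), "sum to 1")
  expect_error(mic_distribution(c(0.5, 1), c(-0.1, 1.1)), ">= 0")

  path <- withr::local_tempfile(fileext = ".csv")
  write_mic_distribution(d, path)
  expect_equal(read_mic_distribution(path)$frequencies, d$frequencies)
})

test_that("PTA counts attaining subjects and behaves at the limits", {
  expect_equal(pta(c(600, 700, 800), 1, pd_target("MRSA")), 2 / 3)
  expect_equal(pta(rep(500, 10), 1, pd_target("MRSA")), 0)
  expect_equal(pta(c(100, 200), 1e-9, pd_target("MRSA")), 1)
  expect_error(pta(numeric(0), 1), "empty")
  expect_error(pta(c(1, 2), 0), "positive")
  expect_equal(pd_target("EFAECIUM")$auc_mic_target, 143)
})

test_that("PTA is monotone in MIC and dose and matches brute-force enumeration", {
  adult <- ref_adult()
  cm <- ref_adult_clearance()
  ex <- monte_carlo_exposures(adult, cm, dosing_regimen(6, 24), n = 100,
                              seed = 3)
  mics <- c(0.125, 0.25, 0.5, 1, 2, 4, 8)
  curve <- pta_curve(ex, mics, pd_target("MRSA"))
  expect_true(all(diff(curve$pta) <= 0))
  # brute force over every (subject, MIC) pair
  brute <- vapply(mics, function(m) {
    hits <- 0L
    for (auc in ex$auc_0_24) if (auc / m >= 666) hits <- hits + 1L
    hits / length(ex$auc_0_24)
  }, numeric(1))
  expect_equal(curve$pta, brute)

  # monotone non-decreasing in dose
  ex12 <- monte_carlo_exposures(adult, cm, dosing_regimen(12, 24),
                                n = 100, seed = 3)
  curve12 <- pta_curve(ex12, mics, pd_target("MRSA"))
  expect_true(all(curve12$pta >= curve$pta))
})

test_that("CFR is the frequency-weighted PTA and sits between the PTA extremes", {
  d <- mic_distribution(c(0.5, 1, 2), c(0.6, 0.3, 0.1))
  res <- cfr(c("0.5" = 1, "1" = 0.5, "2" = 0), d)
  expect_equal(res$cfr, 0.75)
  expect_equal(cfr(c("0.5" = 1, "1" = 1, "2" = 1), d)$cfr, 1)
  # degenerate distribution returns the PTA at that MIC
  deg <- mic_distribution(c(0.5, 1), c(0, 1))
  expect_equal(cfr(c("0.5" = 0.9, "1" = 0.37), deg)$cfr, 0.37)
  expect_error(cfr(c("0.5" = 1), d), "non-zero frequency")

  adult <- ref_adult()
  cm <- ref_adult_clearance()
  ex <- monte_carlo_exposures(adult, cm, dosing_regimen(6, 24), n = 200,
                              seed = 5)
  mic_d <- generate_mic_distribution("MRSA_LIKE", seed = 1)
  curve <- pta_curve(ex, mic_d$mics, pd_target("MRSA"))
  res2 <- cfr(curve, mic_d)
  active <- mic_d$frequencies > 0
  expect_gte(res2$cfr, min(curve$pta[active]))
  expect_lte(res2$cfr, max(curve$pta[active]))
  # brute force: average over subjects of the frequency-weighted indicator
  brute <- mean(vapply(ex$auc_0_24, function(auc) {
    sum(mic_d$frequencies * as.numeric(auc / mic_d$mics >= 666))
  }, numeric(1)))
  expect_equal(res2$cfr, brute)
})

test_that("Monte-Carlo exposures are seeded, centred and anti-correlated with clearance", {
  adult <- ref_adult()
  cm <- ref_adult_clearance()
  reg <- dosing_regimen(6, 24)
  ex1 <- monte_carlo_exposures(adult, cm, reg, n = 2000, seed = 9)
  ex2 <- monte_carlo_exposures(adult, cm, reg, n = 2000, seed = 9)
  expect_identical(ex1$auc_0_24, ex2$auc_0_24)

  # cv = 0 collapses on the deterministic subject
  ex0 <- monte_carlo_exposures(adult, cm, reg, n = 5, seed = 1,
                               cv_cl = 0, cv_v = 0)
  det <- attr(ex0, "deterministic")
  expect_equal(unique(ex0$auc_0_24), det$auc_0_24)
  expect_equal(det$auc_0_24, 420 / cm$cl_total)

  big <- monte_carlo_exposures(adult, cm, reg, n = 10000, seed = 1)
  expect_equal(stats::median(big$auc_0_24),
               attr(big, "deterministic")$auc_0_24, tolerance = 0.03)
  expect_equal(
    stats::cor(big$auc_0_24, big$cl_multiplier, method = "spearman"), -1)
})

test_that("the Monte-Carlo trough agrees with the grid simulation at cv = 0", {
  adult <- ref_adult()
  drug <- drug_parameters()
  cm <- ref_adult_clearance()
  reg <- dosing_regimen(6, 24, 0.5, 12)
  det <- attr(monte_carlo_exposures(adult, cm, dosing_regimen(6, 24),
                                    n = 1, seed = 1, cv_cl = 0, cv_v = 0),
              "deterministic")
  m <- pk_metrics(simulate_regimen(adult, drug, cm, reg), reg)
  expect_equal(det$cmin_ss, m$cmin_ss, tolerance = 0.01 * m$cmin_ss)
})

test_that("PTA rises as renal function deteriorates at a fixed regimen", {
  ped <- pediatric_models("2-6")
  reg <- dosing_regimen(9, 24)
  p <- vapply(c("HEALTHY", "MILD", "MODERATE", "SEVERE", "ESRD"),
              function(cat) {
                pta(monte_carlo_exposures(ped[[cat]]$subject,
                                          ped[[cat]]$model, reg,
                                          n = 2000, seed = 2),
                    1, pd_target("MRSA"))
              }, numeric(1))
  expect_true(all(diff(p) >= 0))
})

test_that("trough safety fractions and flags are counted correctly", {
  res <- cmin_safety_flag(c(10, 20, 30))
  expect_equal(res$fraction_exceeding, 1 / 3)
  expect_false(res$flag)
  expect_equal(cmin_safety_flag(rep(0, 4))$fraction_exceeding, 0)
  expect_equal(cmin_safety_flag(c(1, 2), threshold = 0)$fraction_exceeding,
               1)
  res2 <- cmin_safety_flag(c(10, 30), deterministic_cmin = 25)
  expect_true(res2$flag)
  expect_error(cmin_safety_flag(numeric(0)), "empty")
})
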