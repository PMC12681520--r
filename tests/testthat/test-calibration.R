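test_that("an exact line is fitted exactly and R-squared is 1", {
  curve <- fit_calibration(exact_standards(slope = 2, intercept = 0))
  expect_equal(curve$slope, 2)
  expect_equal(curve$intercept, 0)
  expect_equal(curve$r_squared, 1)
  expect_equal(curve$lod, 0)   # perfect line: zero residual SD
  expect_equal(curve$loq, 0)
  expect_false(curve$failed)
  expect_equal(curve$flag, "")
})

test_that("calibration fails gracefully with too few usable levels", {
  std <- exact_standards()
  std$analyte_area <- NA_real_  # everything censored
  curve <- fit_calibration(std)
  expect_true(curve$failed)
  expect_equal(curve$flag, "insufficient_levels")
  # a failed curve propagates to back-calculation, not an error
  bc <- back_calculate(exact_standards()[1, ], curve)
  expect_equal(bc$status, "no_curve")
})

test_that("slope is recovered within 5% from noisy synthetic standards", {
  panel <- default_panel()
  instr <- instrument_model(panel, cv_intra = 0.05, cv_inter = 0,
                            cv_injection = 0)
  std <- simulate_calibration_series(panel, instr, "plasma", seed = 21)
  curves <- fit_panel_calibrations(std, panel)
  # generating ratio slope: slope_analyte * ME / (slope_is * ME_is * nominal)
  an <- panel$analytes
  for (a in c("IS", "LCA", "ImP")) {
    i <- match(a, instr$analyte_id)
    is_id <- an$internal_standard[an$id == a]
    j <- match(is_id, instr$analyte_id)
    nominal <- panel$intstd_nominal[an$esi_mode[an$id == a]]
    gen_slope <- (instr$slope[i] * instr$matrix_effect$plasma[i]) /
      (instr$slope[j] * instr$matrix_effect$plasma[j] * nominal)
    fit_slope <- curves$slope[curves$analyte_id == a]
    expect_lt(abs(fit_slope - gen_slope) / gen_slope, 0.05)
  }
})

test_that("LOD/LOQ follow the 3.3/10 sigma-over-slope estimator", {
  # direct formula: residual SD 0.1, slope 1 -> LOD 0.33, LOQ 1.0
  set.seed(42)
  lev <- rep(c(1, 2, 4, 6, 8, 10), each = 10)
  ratio <- lev + rnorm(length(lev), 0, 0.1)
  std <- data.frame(nominal_conc = lev)
  fit <- lm(ratio ~ conc, data = data.frame(ratio = ratio, conc = lev))
  ll <- estimate_lod_loq(fit, std)
  s <- sd(residuals(fit))
  expect_equal(unname(ll["lod"]), 3.3 * s / abs(coef(fit)[2]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(ll["loq"] / ll["lod"]), 10 / 3.3, tolerance = 1e-12)
  # across a whole synthetic panel the ratio is the estimator identity
  panel <- default_panel()
  std2 <- simulate_calibration_series(panel, instrument_model(panel),
                                      "feces", seed = 22)
  curves <- fit_panel_calibrations(std2, panel)
  ok <- !curves$failed & curves$lod > 0
  expect_true(all(abs(curves$loq[ok] / curves$lod[ok] - 10 / 3.3) < 1e-9))
})

test_that("back-calculation inverts the curve and applies the dilution factor", {
  curve <- fit_calibration(exact_standards(slope = 2, intercept = 1))
  rec <- function(ratio, dil) data.frame(
    sample_id = "s1", analyte_id = "A", matrix = "plasma",
    dilution_factor = dil, analyte_area = ratio, intstd_area = 1,
    batch = "b", day = "d", role = "cohort", nominal_conc = NA_real_,
    stringsAsFactors = FALSE)
  expect_equal(back_calculate(rec(5, 1), curve)$extract_conc, 2)
  expect_equal(back_calculate(rec(5, 10), curve)$extract_conc, 20)
  expect_equal(back_calculate(rec(NA, 1), curve)$status, "not_detected")
  # below the LOQ-equivalent threshold: censored marker
  curve$loq <- 5
  expect_equal(back_calculate(rec(5, 1), curve)$status, "below_loq")
})

test_that("dilution selection follows the least-diluted-in-range rule", {
  curve <- fit_calibration(exact_standards(slope = 1,
                                           levels = c(0.1, 1, 5, 10, 20)))
  cand <- function(extract, dil, status = "measured")
    data.frame(extract_conc = extract, dilution_factor = dil, status = status,
               stringsAsFactors = FALSE)
  # both in range -> neat wins
  sel <- select_dilution(rbind(cand(5, 1), cand(5, 10)), curve)
  expect_equal(sel$dilution_factor, 1)
  # neat above the top standard, diluted in range -> diluted wins
  sel <- select_dilution(rbind(cand(30, 1), cand(30, 10)), curve)
  expect_equal(sel$dilution_factor, 10)
  # everything above range -> most diluted
  sel <- select_dilution(rbind(cand(300, 1), cand(300, 10)), curve)
  expect_equal(sel$dilution_factor, 10)
  # all censored -> censored marker
  sel <- select_dilution(rbind(cand(NA, 1, "below_loq"), cand(NA, 10, "below_loq")),
                         curve)
  expect_equal(sel$status, "below_loq")
  expect_true(is.na(sel$extract_conc))
})

test_that("unit conversion implements the extraction arithmetic", {
  expect_equal(to_specimen_units(1, "feces"), 0.008)   # 1 uM * 2 mL / 250 mg
  expect_equal(to_specimen_units(1, "plasma"), 10)     # 100 uL into 1 mL
  expect_equal(to_specimen_units(0, "feces"), 0)
  expect_equal(to_specimen_units(0, "plasma"), 0)
  expect_error(to_specimen_units(1, "urine"), "unknown matrix")
  bad <- default_prep()
  bad$plasma$specimen_volume <- -1
  expect_error(to_specimen_units(1, "plasma", bad), "positive")
})

test_that("noise-free simulate -> calibrate -> back-calculate -> convert is the identity", {
  panel <- default_panel()
  instr <- noise_free(instrument_model(panel))
  cohort <- simulate_cohort(cohort_spec(n_hc = 3, n_pd = 3), seed = 23)
  cm <- concentration_model(panel)
  for (m in c("plasma", "feces")) {
    truth <- sample_true_concentrations(cohort, cm, m, seed = 24)
    std <- simulate_calibration_series(panel, instr, m, seed = 25)
    curves <- fit_panel_calibrations(std, panel)
    peaks <- simulate_peak_table(cohort, truth, panel, instr, m, seed = 26)
    for (a in unique(truth$analyte_id[truth$present])) {
      bc <- back_calculate(peaks[peaks$analyte_id == a, , drop = FALSE],
                           curves[curves$analyte_id == a, , drop = FALSE])
      spec <- to_specimen_units(bc$extract_conc, m)
      tr <- truth$true_conc[truth$analyte_id == a][
        match(bc$sample_id, truth$subject_id[truth$analyte_id == a])]
      rel <- abs(spec - tr) / tr
      # identity at every dilution of the scheme
      expect_true(all(rel < 1e-9))
    }
  }
})

test_that("the reported value is invariant to dilution choice when noise-free", {
  panel <- default_panel()
  instr <- noise_free(instrument_model(panel))
  cohort <- simulate_cohort(cohort_spec(n_hc = 2, n_pd = 2), seed = 27)
  truth <- sample_true_concentrations(cohort, concentration_model(panel),
                                      "plasma", seed = 28)
  std <- simulate_calibration_series(panel, instr, "plasma", seed = 29)
  curves <- fit_panel_calibrations(std, panel)
  peaks <- simulate_peak_table(cohort, truth, panel, instr, "plasma", seed = 30)
  a <- "ImP"
  bc <- back_calculate(peaks[peaks$analyte_id == a, ],
                       curves[curves$analyte_id == a, ])
  per_sample <- split(bc$extract_conc, bc$sample_id)
  for (v in per_sample) expect_lt(diff(range(v)) / mean(v), 1e-9)
})

test_that("symmetric noise does not increase R-squared in expectation", {
  withr::with_seed(31, {
    r2 <- replicate(40, {
      std <- exact_standards(slope = 2, levels = c(0.1, 0.5, 1, 5, 10, 20),
                             reps = 2)
      std$analyte_area <- std$analyte_area * (1 + rnorm(nrow(std), 0, 0.1))
      fit_calibration(std)$r_squared
    })
    expect_true(mean(r2) < 1)
    expect_true(all(r2 <= 1))
  })
})
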