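test_that("absolute liver iodine is the 3-ROI arithmetic mean", {
  expect_equal(absolute_liver_iodine(1, 1, 1), 1)
  expect_equal(absolute_liver_iodine(0, 0, 0), 0)
  # the published all-patients ROI means average to the published
  # all-patients absolute mean at report rounding (linearity of averaging)
  expect_equal(round(absolute_liver_iodine(2.072, 2.098, 2.120), 3), 2.097)
  expect_error(absolute_liver_iodine(1, NA, 1), "finite")
  expect_error(absolute_liver_iodine(1, Inf, 1), "finite")
  expect_error(absolute_liver_iodine(-0.1, 1, 1), ">= 0")
})

test_that("mixed-supply concentration is the 75/25 weighted mean", {
  expect_equal(mixed_blood_iodine(4.0, 8.0), 5.0)
  for (x in c(0.5, 2, 7)) expect_equal(mixed_blood_iodine(x, x), x)
  # hand computation on the published vessel means
  expect_equal(round(mixed_blood_iodine(4.974, 4.382), 3), 4.826)
  expect_equal(mixed_blood_iodine(4, 8, weights = c(0.5, 0.5)), 6)
  expect_error(mixed_blood_iodine(4, 8, weights = c(0.75, 0.35)), "sum to 1")
  expect_error(mixed_blood_iodine(4, 8, weights = c(1.5, -0.5)), "non-negative")
})

test_that("blood reference: per-vessel means and the mixed linearity identity", {
  one <- random_cohort(1, 1)
  one$records$portal_vein <- 4; one$records$aorta <- 8
  ref <- blood_reference(one)
  expect_equal(c(ref$mean_portal_vein, ref$mean_aorta, ref$mean_mixed),
               c(4, 8, 5))

  two <- random_cohort(2, 2)
  two$records$portal_vein <- c(4, 6); two$records$aorta <- c(2, 6)
  ref <- blood_reference(two)
  expect_equal(c(ref$mean_portal_vein, ref$mean_aorta, ref$mean_mixed),
               c(5, 4, 4.75))

  # linearity: derived mean_mixed equals the mean of per-patient mixed values
  for (seed in 1:10) {
    co <- random_cohort(sample(2:60, 1), seed)
    ref <- blood_reference(co)
    per_patient <- mixed_blood_iodine(co$records$portal_vein, co$records$aorta)
    expect_equal(ref$mean_mixed, mean(per_patient), tolerance = 1e-12)
  }

  expect_error(blood_reference(new_cohort(one$records[0, ])), "empty")
})

test_that("normalization identities: constant blood, hand case, scale invariance", {
  # constant vessel profile: normalized == absolute exactly
  co <- random_cohort(12, 3)
  co$records$aorta <- 4.4; co$records$portal_vein <- 5.1
  norm <- normalize_cohort(co)
  abs_l <- absolute_liver_iodine(co$records$roi_s3, co$records$roi_s4b,
                                 co$records$roi_s7)
  expect_equal(norm$i_pv_n, abs_l, tolerance = 1e-14)
  expect_equal(norm$i_a_n, abs_l, tolerance = 1e-14)
  expect_equal(norm$i_mixed_n, abs_l, tolerance = 1e-14)

  # two-patient hand computation: abs = (2, 2), pv = (4, 8), mean pv = 6
  co2 <- random_cohort(2, 4)
  co2$records[ROI_COLS <- c("roi_s3", "roi_s4b", "roi_s7")] <- 2
  co2$records$portal_vein <- c(4, 8)
  norm2 <- normalize_cohort(co2)
  expect_equal(norm2$i_pv_n, c(3.0, 1.5))

  # joint rescaling of all vessel concentrations cancels
  co3 <- random_cohort(25, 5)
  base <- normalize_cohort(co3)
  for (c_scale in c(0.25, 3, 17)) {
    sc <- co3
    sc$records$aorta <- sc$records$aorta * c_scale
    sc$records$portal_vein <- sc$records$portal_vein * c_scale
    scaled <- normalize_cohort(sc)
    for (col in c("i_pv_n", "i_a_n", "i_mixed_n"))
      expect_equal(scaled[[col]], base[[col]], tolerance = 1e-12)
  }
})

test_that("degenerate mixed weights reduce to single-vessel normalization", {
  co <- random_cohort(30, 6)
  norm_pv <- normalize_cohort(co, weights = c(1, 0))
  norm_a  <- normalize_cohort(co, weights = c(0, 1))
  base    <- normalize_cohort(co)
  expect_equal(norm_pv$i_mixed_n, base$i_pv_n, tolerance = 1e-12)
  expect_equal(norm_a$i_mixed_n, base$i_a_n, tolerance = 1e-12)
})

test_that("mixed blood lies between the vessels; positivity and order preserved", {
  co <- random_cohort(50, 7)
  norm <- normalize_cohort(co)
  lo <- pmin(co$records$portal_vein, co$records$aorta)
  hi <- pmax(co$records$portal_vein, co$records$aorta)
  expect_true(all(norm$i_mixed_blood >= lo & norm$i_mixed_blood <= hi))
  expect_true(all(norm[c("i_l_abs", "i_pv_n", "i_a_n", "i_mixed_n")] > 0))
  expect_identical(norm$patient_id, co$records$patient_id)
})

test_that("an external blood reference applies a fixed calibration", {
  co <- random_cohort(10, 8)
  ref <- external_blood_reference(4.974, 4.382, n_patients = 105)
  expect_equal(ref$mean_mixed, 0.75 * 4.974 + 0.25 * 4.382)
  expect_equal(ref$source, "externally_supplied")
  norm <- normalize_cohort(co, reference = ref)
  expect_equal(norm$i_pv_n, norm$i_l_abs / co$records$portal_vein * 4.974)
  # weights must agree between call and reference
  expect_error(normalize_cohort(co, reference = ref, weights = c(0.5, 0.5)),
               "disagree")
})
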