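test_that("cohort ratios from samples and panels", {
  s <- blood_samples(2, whole_blood = 1000, plasma = 1200,
                     plasma_free = 960)
  p <- amino_acid_panel(leucine = 231)
  r <- compute_ratios(s, list(p))
  expect_equal(r$plasma_over_wb, 1.2)
  expect_equal(r$free_fraction, 0.8)
  expect_equal(r$leucine_conc, 231)

  # mean of the two arterial group means
  r2 <- compute_ratios(s, list(amino_acid_panel(leucine = 231),
                               amino_acid_panel(leucine = 225)))
  expect_equal(r2$leucine_conc, 228)
})

test_that("ratio computation is permutation-invariant and warns on bad samples", {
  s <- blood_samples(c(2, 5, 10), whole_blood = c(1000, 900, 800),
                     plasma = c(1150, 1100, 1000),
                     plasma_free = c(900, 850, 790))
  p <- list(amino_acid_panel(leucine = 220))
  r_fwd <- compute_ratios(s, p)
  r_rev <- compute_ratios(s[3:1, ], p)
  expect_equal(r_rev$plasma_over_wb, r_fwd$plasma_over_wb)
  expect_equal(r_rev$free_fraction, r_fwd$free_fraction)

  s_bad <- s
  s_bad$whole_blood[2] <- 0
  expect_warning(r_drop <- compute_ratios(s_bad, p), "excluding 1")
  expect_equal(r_drop$plasma_over_wb,
               mean(c(1150 / 1000, 1000 / 800)))
  s_all_bad <- s
  s_all_bad$whole_blood <- 0
  expect_error(suppressWarnings(compute_ratios(s_all_bad, p)), "no usable")
  expect_error(compute_ratios(s, list(amino_acid_panel(leucine = 220,
                                                       site = "venous"))),
               "arterial")
})

test_that("all-identical samples give zero-variance cohort ratios", {
  s <- blood_samples(rep(5, 4), whole_blood = rep(1000, 4),
                     plasma = rep(1200, 4), plasma_free = rep(840, 4))
  r <- compute_ratios(s, list(amino_acid_panel(leucine = 200)))
  expect_equal(r$plasma_over_wb, 1.2)
  expect_equal(r$free_fraction, 0.7)
})

test_that("online-curve calibration recovers gain and delay", {
  true_wb <- bolus_cp()
  true_wb <- sampled_curve(true_wb$time_min, true_wb$value / 0.96,
                           role = "whole_blood")
  samples <- blood_samples(c(2, 5, 10, 20, 30, 40, 60),
                           whole_blood = curve_interp(
                             true_wb, c(2, 5, 10, 20, 30, 40, 60)),
                           plasma = curve_interp(
                             true_wb, c(2, 5, 10, 20, 30, 40, 60)) * 1.2,
                           plasma_free = curve_interp(
                             true_wb, c(2, 5, 10, 20, 30, 40, 60)) * 0.96)
  marker <- leupet:::rise_time_10pct(true_wb$time_min, true_wb$value)

  # online detector at half the true gain
  online <- sampled_curve(true_wb$time_min, true_wb$value * 0.5,
                          role = "whole_blood")
  cal <- calibrate_online_curve(online, samples,
                                injection_start_min = marker)
  expect_equal(attr(cal, "calibration_factor"), 2, tolerance = 1e-9)
  expect_equal(attr(cal, "time_shift_min"), 0, tolerance = 1e-9)
  expect_equal(curve_interp(cal, 30), curve_interp(true_wb, 30),
               tolerance = 1e-9)

  # already-calibrated curve: factor 1
  cal1 <- calibrate_online_curve(true_wb, samples,
                                 injection_start_min = marker)
  expect_equal(attr(cal1, "calibration_factor"), 1, tolerance = 1e-9)

  # synthetic delay of 0.2 min is recovered within a sampling interval
  delayed <- sampled_curve(true_wb$time_min + 0.2, true_wb$value,
                           role = "whole_blood")
  cal_d <- calibrate_online_curve(delayed, samples,
                                  injection_start_min = marker)
  expect_lt(abs(attr(cal_d, "time_shift_min") - 0.2), 0.05)

  expect_error(calibrate_online_curve(online, samples[samples$time_min > 70, ],
                                      injection_start_min = marker),
               ">= 2")
})

test_that("calibrated output is independent of detector gain", {
  wb <- bolus_cp()
  wb <- sampled_curve(wb$time_min, wb$value, role = "whole_blood")
  st <- c(2, 5, 10, 20, 30, 40, 60)
  samples <- blood_samples(st, curve_interp(wb, st),
                           curve_interp(wb, st) * 1.2,
                           curve_interp(wb, st) * 0.96)
  marker <- leupet:::rise_time_10pct(wb$time_min, wb$value)
  for (gain in c(0.2, 1, 4.8)) {
    online <- sampled_curve(wb$time_min, wb$value * gain,
                            role = "whole_blood")
    cal <- calibrate_online_curve(online, samples,
                                  injection_start_min = marker)
    expect_equal(curve_interp(cal, c(5, 30, 55)),
                 curve_interp(wb, c(5, 30, 55)), tolerance = 1e-9)
  }
})

test_that("plasma-free conversion is a scalar product with AUC linearity", {
  wb <- sampled_curve(seq(0, 60, 0.5),
                      1000 * exp(-0.05 * seq(0, 60, 0.5)),
                      role = "whole_blood")
  r <- ratio_set(1.2, 0.8, 228)
  cp <- to_plasma_free(wb, r)
  expect_equal(cp$value, wb$value * 0.96)
  expect_identical(attr(cp, "role"), "plasma_free")
  expect_equal(curve_auc(cp), curve_auc(wb) * 0.96)

  cp_id <- to_plasma_free(wb, ratio_set(1, 1, 228))
  expect_equal(cp_id$value, wb$value)
  expect_error(to_plasma_free(wb, NULL), "required")
})

test_that("time-varying ratio conversion interpolates between samples", {
  wb <- sampled_curve(seq(0, 60, 1), rep(1000, 61), role = "whole_blood")
  s <- blood_samples(c(0, 60), whole_blood = c(1000, 1000),
                     plasma = c(1000, 1500), plasma_free = c(800, 1500))
  cp <- to_plasma_free(wb, ratios = NULL, time_varying = s)
  expect_equal(cp$value[1], 800)             # ratio 0.8 at t = 0
  expect_equal(cp$value[61], 1500)           # ratio 1.5 at t = 60
  expect_equal(cp$value[31], mean(c(800, 1500)))  # linear midpoint
})
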