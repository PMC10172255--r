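test_that("PBIF template: unit area, donor-order and donor-gain invariance", {
  aif <- bolus_cp()
  d1 <- aif
  d2 <- sampled_curve(aif$time_min, aif$value * 3.1, role = "plasma_free")
  d3 <- make_aif(within(default_aif_params(), l2 <- 0.45), pbif_grid())

  tmpl <- build_pbif(list(a = d1, b = d2, c = d3))
  expect_equal(curve_auc(tmpl), 1, tolerance = 1e-8)
  expect_true(all(tmpl$value >= 0))

  # identical donors: template is any donor normalized to unit area
  tmpl_id <- build_pbif(list(d1, d1))
  expect_equal(tmpl_id$value, d1$value / curve_auc(d1), tolerance = 1e-10)

  # gain-only differences collapse to the same template
  tmpl_gain <- build_pbif(list(d1, d2))
  expect_equal(tmpl_gain$value, tmpl_id$value, tolerance = 1e-10)

  # donor order does not matter
  tmpl_rev <- build_pbif(list(c = d3, b = d2, a = d1))
  expect_equal(tmpl_rev$value, tmpl$value, tolerance = 1e-12)

  bad <- sampled_curve(c(0, 60), c(0, 0), role = "plasma_free")
  expect_error(build_pbif(list(ok = d1, flat = bad)), "flat")
  expect_error(build_pbif(list(d1)), "at least 2")
})

test_that("two triangular toy donors average to the hand-computed template", {
  tri1 <- sampled_curve(c(0, 10, 60), c(0, 12, 0), role = "plasma_free")
  tri2 <- sampled_curve(c(0, 20, 60), c(0, 6, 0), role = "plasma_free")
  tmpl <- build_pbif(list(tri1, tri2))
  # hand trapezoids: AUC1 = 360, AUC2 = 180; template = mean of unit forms
  grid <- pbif_grid()
  hand <- (curve_interp(tri1, grid) / 360 +
             curve_interp(tri2, grid) / 180) / 2
  expect_equal(tmpl$value, hand, tolerance = 1e-10)
})

test_that("PBIF scaling: linearity, identity window, donor round trip", {
  aif <- bolus_cp()
  d2 <- make_aif(within(default_aif_params(), l2 <- 0.45), pbif_grid())
  tmpl <- build_pbif(list(aif, d2))
  r <- ratio_set(1.2, 0.8, 228)

  # donor converted back to whole blood: its plasma-free window AUC returns
  idif <- sampled_curve(aif$time_min, aif$value / 0.96,
                        role = "whole_blood")
  scaled <- scale_pbif(tmpl, idif, r, window = c(10, 60))
  expect_equal(curve_auc(scaled, 10, 60), curve_auc(aif, 10, 60),
               tolerance = 1e-6)

  # doubling the IDIF doubles the scaled input
  scaled2 <- scale_pbif(tmpl, curve_update(idif, value = idif$value * 2),
                        r, window = c(10, 60))
  expect_equal(scaled2$value, scaled$value * 2, tolerance = 1e-12)

  # idif = template / (por * ff) over the full window gives S = 1
  idif_unit <- sampled_curve(tmpl$time_min, tmpl$value / 0.96,
                             role = "whole_blood")
  s1 <- scale_pbif(tmpl, idif_unit, r, window = c(0, 60))
  expect_equal(attr(s1, "pbif_scale"), 1, tolerance = 1e-10)

  expect_error(scale_pbif(tmpl, idif, r, window = c(50, 70)), "support")
})

test_that("PBIF templates round-trip through TSV with provenance", {
  tmpl <- build_pbif(list(bolus_cp(),
                          make_aif(within(default_aif_params(),
                                          l2 <- 0.45), pbif_grid())))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pbif(tmpl, path)
  back <- read_pbif(path)
  expect_equal(back$value, tmpl$value, tolerance = 1e-9)
  expect_equal(attr(back, "n_donors"), 2)
})
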