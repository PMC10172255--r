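test_that("bolus model: degenerate, equivariant and well-shaped", {
  p <- default_aif_params()
  grid <- pbif_grid()

  zero <- make_aif(within(p, {A1 <- 0; A2 <- 0; A3 <- 0}), grid)
  expect_equal(zero$value, rep(0, length(grid)))

  aif <- make_aif(p, grid)
  expect_true(all(aif$value >= 0))
  auc <- curve_auc(aif)
  expect_true(is.finite(auc) && auc > 0)
  # quadrature oracle on a 10x finer grid agrees
  fine <- make_aif(p, seq(0, 60, 0.005))
  expect_equal(auc, curve_auc(fine), tolerance = 5e-3)

  # peak lands 0.3-1.5 min after appearance
  tpk <- aif$time_min[which.max(aif$value)]
  expect_gt(tpk - p$tau, 0.3)
  expect_lt(tpk - p$tau, 1.5)

  # translation equivariance
  shifted <- make_aif(within(p, tau <- tau + 0.5), grid + 0.5)
  expect_equal(shifted$value, aif$value, tolerance = 1e-12)

  expect_error(make_aif(within(p, l2 <- 3), grid), "l1 > l2 > l3")
  expect_error(make_aif(within(p, A3 <- -2e4), grid), "negative value at")
})

test_that("subjects are deterministic in the seed and isolate the RNG", {
  spec <- cohort_spec(seed = 12)
  set.seed(999); before <- runif(1)
  b1 <- generate_subject(spec, 3)
  b2 <- generate_subject(spec, 3)
  expect_identical(b1, b2)
  # different subjects and arms differ
  expect_false(identical(b1$tacs, generate_subject(spec, 4)$tacs))
  expect_false(identical(
    b1$truth$regions$k3,
    generate_subject(spec, 3, "anisomycin")$truth$regions$k3))
  # generator does not disturb the caller's RNG stream
  set.seed(999); expect_identical(runif(1), before)
})

test_that("noiseless TACs equal exact frame means; noise follows duration scaling", {
  spec0 <- noise_free(cohort_spec(seed = 4))
  b <- generate_subject(spec0, 1)
  for (rg in unique(b$tacs$region)) {
    sub <- b$tacs[b$tacs$region == rg, ]
    tr <- b$truth$regions[b$truth$regions$region == rg, ]
    mu <- solve_model_frames(rate_constants(tr$K1, tr$k2, tr$k3),
                             b$aif, b$schedule)
    expect_equal(sub$activity_Bq_per_ml, mu, tolerance = 1e-12)
    expect_equal(sub$true_mean, mu, tolerance = 1e-12)
  }

  # noisy: pooled z-scores over subjects are standard-normal-ish
  spec <- cohort_spec(seed = 4)
  z <- unlist(lapply(1:8, function(i) {
    bi <- generate_subject(spec, i)
    hip <- bi$tacs[bi$tacs$region == "hippocampus", ]
    sdv <- spec$noise_sigma * sqrt(pmax(hip$true_mean, 0) /
                                     bi$schedule$dur_min)
    ((hip$activity_Bq_per_ml - hip$true_mean) / sdv)[sdv > 0]
  }))
  expect_lt(abs(mean(z)), 0.15)
  expect_lt(abs(sd(z) - 1), 0.15)
})

test_that("anisomycin arm scales k3 and PSR by the configured multiplier", {
  spec <- noise_free(cohort_spec(seed = 6))
  base <- generate_subject(spec, 1)
  trt <- generate_subject(spec, 1, "anisomycin")
  # same subject seed draws differ across arms, so compare the spec-level
  # deterministic quantities: k3 ratio and PSR/leu ratio
  expect_equal(trt$truth$regions$k3 /
                 spec$regions$k3, rep(0.14, 3))
  expect_equal(trt$truth$regions$PSR / trt$truth$leucine,
               spec$regions$K1 * spec$regions$k3 * 0.14 /
                 spec$regions$k2, tolerance = 1e-12)
  expect_equal(base$truth$regions$k3, spec$regions$k3)
})

test_that("subject bundles round-trip through the on-disk dialects", {
  spec <- cohort_spec(seed = 8)
  b <- generate_subject(spec, 2)
  dir <- withr::local_tempdir()
  write_subject(b, dir)
  back <- read_subject(dir)
  expect_equal(back$tacs$activity_Bq_per_ml, b$tacs$activity_Bq_per_ml,
               tolerance = 1e-9)
  expect_equal(back$samples$whole_blood, b$samples$whole_blood,
               tolerance = 1e-9)
  expect_equal(back$online$value, b$online$value, tolerance = 1e-9)
  expect_false(attr(back$online, "decay_corrected"))
  expect_equal(back$injection_marker_min, b$injection_marker_min,
               tolerance = 1e-9)
  expect_equal(back$schedule$end_min, b$schedule$end_min)
  expect_equal(nrow(dplyr::bind_rows(back$panels)), 2)
})

test_that("k3 multiplier helper inverts the PSR linearity exactly", {
  spec <- cohort_spec(seed = 1)
  m <- k3_multiplier_for_psr(spec, "hippocampus", 0.81)
  r <- spec$regions[spec$regions$region == "hippocampus", ]
  expect_equal(r$K1 * (r$k3 * m) * spec$leucine_mean / r$k2, 0.81)
  expect_error(k3_multiplier_for_psr(spec, "nonexistent", 1), "unknown")
})
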