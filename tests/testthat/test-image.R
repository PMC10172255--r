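test_that("ROI extraction: uniform frames, singleton masks, grid checks", {
  sch <- frame_schedule(c(0, 1, 2), c(1, 2, 3))
  img <- array(0, c(4, 4, 2, 3))
  img[, , , 1] <- 5; img[, , , 2] <- 7; img[, , , 3] <- 2
  mask <- array(FALSE, c(4, 4, 2)); mask[2:3, 2:3, 1] <- TRUE
  tac <- roi_tac(img, mask, sch)
  expect_equal(tac$value, c(5, 7, 2))
  expect_equal(tac$time_min, sch$mid_min)

  img[2, 2, 1, ] <- c(10, 20, 30)
  single <- array(FALSE, c(4, 4, 2)); single[2, 2, 1] <- TRUE
  expect_equal(roi_tac(img, single, sch)$value, c(10, 20, 30))

  expect_error(roi_tac(img, array(FALSE, c(4, 4, 2)), sch), "empty")
  expect_error(roi_tac(img, array(TRUE, c(3, 3, 2)), sch), "grid")
  expect_error(roi_tac(img[, , , 1:2], mask, sch), "frames")
})

test_that("phantom round trip: noiseless exact, noisy within tolerance", {
  spec <- noise_free(cohort_spec(seed = 2))
  b <- generate_subject(spec, 1)
  ph <- generate_phantom(b)

  hip <- roi_tac(ph$image, ph$masks$hippocampus, ph$schedule)
  expect_equal(hip$value,
               b$tacs$activity_Bq_per_ml[b$tacs$region == "hippocampus"],
               tolerance = 1e-12)
  idif <- extract_idif(ph$image, ph$masks$left_ventricle, ph$schedule)
  expect_equal(idif$value, frame_average(b$wb, ph$schedule),
               tolerance = 1e-12)
  expect_identical(attr(idif, "role"), "whole_blood")

  ph_n <- generate_phantom(b, noise_sd = 50, seed = 9)
  hip_n <- roi_tac(ph_n$image, ph_n$masks$hippocampus, ph_n$schedule)
  nvox <- sum(ph_n$masks$hippocampus)
  expect_lt(max(abs(hip_n$value - hip$value)), 6 * 50 / sqrt(nvox))

  expect_error(generate_phantom(b, dim = c(64, 16, 8)), "32")
})

test_that("phantom NIfTI files reload to the same curves", {
  spec <- noise_free(cohort_spec(seed = 2))
  ph <- generate_phantom(generate_subject(spec, 1), dim = c(8, 8, 4))
  dir <- withr::local_tempdir()
  paths <- write_phantom(ph, dir)
  tac_mem <- roi_tac(ph$image, ph$masks$hippocampus, ph$schedule)
  tac_file <- roi_tac(paths[["image"]], paths[["hippocampus"]],
                      ph$schedule)
  expect_equal(tac_file$value, tac_mem$value, tolerance = 1e-6)
  frames <- readr::read_tsv(paths[["frames"]], show_col_types = FALSE)
  expect_equal(nrow(frames), nrow(ph$schedule))
})

test_that("SUV formula and its linearity", {
  meta <- subject_meta(300, 37.7)
  expect_equal(suv(0, meta), 0)
  expect_equal(suv(1e6, meta), 7.9576, tolerance = 1e-4)
  expect_equal(suv(37.7e6 / 300, meta), 1)           # unit-SUV construction
  expect_equal(suv(c(1, 2, 4) * 1e5, meta),
               suv(1e5, meta) * c(1, 2, 4))          # linear in activity
  expect_error(subject_meta(-1, 37.7), "body weight")
  expect_error(subject_meta(300, 0), "dose")
})

test_that("summed image: single frame, constant image, two-frame oracle", {
  sch <- frame_schedule(c(0, 30), c(30, 60))
  img <- array(0, c(2, 2, 1, 2))
  img[, , , 1] <- 3; img[, , , 2] <- 5

  one <- summed_image(img, sch, window = c(35, 60))
  expect_equal(one[1, 1, 1], 5 * 30)                 # frame x duration

  both <- summed_image(img, sch, window = c(0, 60))
  expect_equal(both[2, 2, 1], 3 * 30 + 5 * 30)       # hand-summed

  const <- array(4, c(2, 2, 1, 2))
  expect_equal(summed_image(const, sch, c(0, 60))[1, 1, 1], 4 * 60)

  expect_error(summed_image(img, sch, window = c(61, 70)), "no frames")
})

test_that("window mean matches hand-weighted averages", {
  sch <- frame_schedule(c(0, 10, 30), c(10, 30, 60))
  tac <- c(100, 50, 20)
  expect_equal(window_mean(tac, sch, c(20, 60)),
               (50 * 20 + 20 * 30) / 50)
  expect_error(window_mean(tac, sch, c(70, 80)), "no frames")
})
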