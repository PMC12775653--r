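test_that("tac validates value length against the schedule", {
  expect_error(tac(default_sched, 1:10), "does not match frame count")
  x <- tac(default_sched, rep(1, 34), roi = "tumor")
  expect_s3_class(x, "tac")
  expect_false(x$decay_corrected)
})

test_that("decay correction applies the exact exponential factor", {
  sch <- schedule_from_frames(c(0, 100), c(100, 100))
  x <- tac(sch, c(10, 10))
  y <- decay_correct(x, half_life_s = 200, reference_time_s = 0)
  # frame mids at 50 s and 150 s with a 200-s half-life
  expect_equal(y$values, 10 * 2^(c(50, 150) / 200))
  expect_true(y$decay_corrected)
  # a frame mid exactly one half-life after the reference doubles
  sch2 <- schedule_from_frames(0, 2 * CU64_HALF_LIFE_S)
  z <- decay_correct(tac(sch2, 5))
  expect_equal(z$values, 10, tolerance = 1e-12)
  # at the reference itself, nothing changes
  w <- decay_correct(tac(sch, c(3, 4)), half_life_s = 200,
                     reference_time_s = 50)
  expect_equal(w$values[1], 3)
})

test_that("double decay correction is refused", {
  x <- decay_correct(tac(default_sched, rep(1, 34)))
  expect_error(decay_correct(x), "already decay-corrected")
})

test_that("SUV conversion matches the dose/weight formula", {
  sch <- schedule_from_frames(0, 60)
  x <- tac(sch, 50000, unit = "Bq_mL", decay_corrected = TRUE,
           reference_time_s = 0)
  s <- to_suv(x, dose_bq = 3.7e6, weight_g = 25)
  expect_equal(s$values, 50000 * 25 / 3.7e6)  # 0.33784...
  expect_identical(s$unit, "SUV")
  # homogeneity: doubling the concentration doubles the SUV
  x2 <- x; x2$values <- 2 * x$values
  expect_equal(to_suv(x2, 3.7e6, 25)$values, 2 * s$values)
})

test_that("SUV conversion enforces its preconditions", {
  sch <- schedule_from_frames(0, 60)
  raw <- tac(sch, 1)
  expect_error(to_suv(raw, 3.7e6, 25), "decay-correct")
  cor <- decay_correct(raw)
  expect_error(to_suv(cor, 0, 25), "dose_bq")
  expect_error(to_suv(cor, 3.7e6, -1), "weight_g")
  suv <- to_suv(cor, 3.7e6, 25)
  expect_error(to_suv(suv, 3.7e6, 25), "Bq/mL")
})

test_that("ROI extraction equals a per-frame loop over mask voxels", {
  sch <- schedule_from_frames(c(0, 10, 20), c(10, 10, 10))
  set.seed(11)
  img <- array(runif(4 * 4 * 2 * 3), dim = c(4, 4, 2, 3))
  mask <- array(0L, dim = c(4, 4, 2))
  mask[2:3, 2:3, 1] <- 1L
  mask[1, 1, 2] <- 2L
  x <- extract_roi_tac(img, mask, sch, roi = "tumor", label = 1L)
  oracle <- vapply(1:3, function(f) {
    sl <- img[, , , f]
    mean(sl[mask == 1L])
  }, numeric(1))
  expect_equal(x$values, oracle)
  # default: any nonzero voxel
  y <- extract_roi_tac(img, mask, sch)
  oracle2 <- vapply(1:3, function(f) mean(img[, , , f][mask != 0]),
                    numeric(1))
  expect_equal(y$values, oracle2)
})

test_that("ROI extraction validates grids, masks and frame counts", {
  sch <- schedule_from_frames(c(0, 10), c(10, 10))
  img <- array(1, dim = c(2, 2, 2, 2))
  expect_error(extract_roi_tac(array(1, dim = c(2, 2, 2)),
                               array(1, dim = c(2, 2, 2)), sch), "4D")
  expect_error(extract_roi_tac(img, array(1, dim = c(3, 2, 2)), sch),
               "grids differ")
  expect_error(extract_roi_tac(img, array(0, dim = c(2, 2, 2)), sch),
               "no voxels")
  sch3 <- schedule_from_frames(c(0, 10, 20), c(10, 10, 10))
  expect_error(extract_roi_tac(img, array(1, dim = c(2, 2, 2)), sch3),
               "frame count")
})

test_that("ROI extraction reads NIfTI files", {
  sch <- schedule_from_frames(c(0, 10), c(10, 10))
  img <- array(seq_len(2 * 2 * 2 * 2), dim = c(2, 2, 2, 2))
  mask <- array(c(1, rep(0, 7)), dim = c(2, 2, 2))
  fi <- tempfile(fileext = ".nii.gz")
  fm <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(fi, fm)))
  RNifti::writeNifti(img, fi)
  RNifti::writeNifti(mask, fm)
  x <- extract_roi_tac(fi, fm, sch)
  expect_equal(x$values, c(img[1, 1, 1, 1], img[1, 1, 1, 2]))
})

test_that("TAC CSV round-trips values, units and the schedule", {
  a <- tac(default_sched, seq_len(34) / 10, roi = "tumor",
           decay_corrected = TRUE, reference_time_s = 0)
  b <- tac(default_sched, rev(seq_len(34)) / 20, roi = "contra",
           decay_corrected = TRUE, reference_time_s = 0)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_tac_csv(list(a, b), path)
  back <- read_tac_csv(path)
  expect_named(back, c("tumor", "contra"))
  expect_equal(back$tumor$values, a$values)
  expect_equal(back$contra$values, b$values)
  expect_equal(back$tumor$schedule$start_s, default_sched$start_s)
  expect_identical(back$tumor$unit, "Bq_mL")
  expect_true(back$tumor$decay_corrected)
})

test_that("SUV-unit curves round-trip through the suv CSV column", {
  s <- tac(default_sched, rep(0.2, 34), roi = "tumor", unit = "SUV",
           decay_corrected = TRUE)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_tac_csv(s, path)
  d <- utils::read.csv(path)
  expect_true("suv" %in% names(d))
  back <- read_tac_csv(path)
  expect_identical(back$tumor$unit, "SUV")
  expect_equal(back$tumor$values, s$values)
})
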