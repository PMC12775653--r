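small_cfg <- function(...) {
  phantom_config(n_per_arm = c(treated = 3, control = 2),
                 n_responders = c(treated = 1, control = 0),
                 seed = 77L, ...)
}

test_that("subject generation is deterministic and seed-sensitive", {
  cfg <- small_cfg()
  s1 <- generate_subject(cfg, "treated", "responder", seed = 5L, id = "a")
  s2 <- generate_subject(cfg, "treated", "responder", seed = 5L, id = "a")
  s3 <- generate_subject(cfg, "treated", "responder", seed = 6L, id = "a")
  expect_identical(s1, s2)
  expect_false(identical(s1$truth, s3$truth))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1)
  invisible(generate_subject(cfg, "treated", "responder", 5L, "a"))
  expect_identical(runif(3), before)
})

test_that("zero noise reproduces the noise-free forward curves", {
  cfg <- small_cfg(noise_c = 0)
  s <- generate_subject(cfg, "treated", "non-responder", seed = 3L)
  for (day in c("day4", "day7")) {
    ses <- s$sessions[[day]]
    expect_identical(ses$tumor$values, ses$tumor_noise_free$values)
    truth_curve <- forward_model(s$truth[[day]]$tumor, s$aif,
                                 cfg$schedule)
    expect_equal(ses$tumor_noise_free$values, truth_curve$values)
  }
})

test_that("drawn rates stay within two standard deviations of the mean", {
  cfg <- small_cfg()
  ks <- t(vapply(1:40, function(i) {
    s <- generate_subject(cfg, "treated", "non-responder", seed = 100L + i)
    s$truth$day4$tumor$k[1:4]
  }, numeric(4)))
  mu <- cfg$kinetics_tumor$mean[1:4]
  sd4 <- cfg$kinetics_tumor$sd[1:4]
  for (j in 1:4) {
    expect_true(all(ks[, j] >= mu[j] - 2 * sd4[j] - 1e-12))
    expect_true(all(ks[, j] <= mu[j] + 2 * sd4[j] + 1e-12))
    expect_true(all(ks[, j] > 0))
  }
})

test_that("the responder uplift raises day-7 tumor influx", {
  cfg <- small_cfg()
  s <- generate_subject(cfg, "treated", "responder", seed = 9L)
  expect_equal(s$truth$day7$tumor$k[["k1"]],
               min(s$truth$day4$tumor$k[["k1"]] * 2.5, 5))
  expect_identical(s$truth$day4$contra$k, s$truth$day7$contra$k)
})

test_that("bioluminescence series match their response labels", {
  for (i in 1:25) {
    r <- generate_bli_series("responder", seed = i)
    n <- generate_bli_series("non-responder", seed = i)
    expect_identical(classify_response(r$days, r$flux), "responder")
    expect_identical(classify_response(n$days, n$flux), "non-responder")
  }
  # a noiseless responder trajectory declines monotonically
  r0 <- generate_bli_series("responder", seed = 1, noise_sd = 0)
  expect_true(all(diff(r0$flux) < 0))
  expect_error(generate_bli_series("maybe"), "response label")
})

test_that("the noise calibration hits the endpoint signal-to-noise target", {
  cfg <- small_cfg()
  s <- generate_subject(cfg, "treated", "non-responder", seed = 4L)
  nf <- s$sessions$day4$tumor_noise_free
  cc <- s$sessions$day4$tumor_noise_c
  expect_equal(cc, noise_coef_for_snr(nf, 10))
  nfv <- nf$values[34]
  sigma_end <- cc * sqrt(nfv / (1200 / 60))
  expect_equal(nfv / sigma_end, 10)
})

test_that("cohorts have the configured sizes and responder counts", {
  co <- generate_cohort(small_cfg())
  expect_length(co, 5)
  arms <- vapply(co, `[[`, "", "arm")
  resp <- vapply(co, `[[`, "", "response")
  expect_identical(sum(arms == "treated"), 3L)
  expect_identical(sum(arms == "control"), 2L)
  expect_identical(sum(resp == "responder" & arms == "treated"), 1L)
  expect_identical(sum(resp == "responder" & arms == "control"), 0L)
  expect_identical(vapply(co, `[[`, "", "id")[1], "treated_01")
  # subjects differ from one another
  k1s <- vapply(co, function(s) s$truth$day4$tumor$k[["k1"]], numeric(1))
  expect_identical(length(unique(k1s)), 5L)
  # bit-identical on regeneration
  expect_identical(generate_cohort(small_cfg()), co)
})

test_that("a written cohort round-trips through CSV and JSON", {
  dir <- tempfile("cohort")
  on.exit(unlink(dir, recursive = TRUE))
  co <- generate_cohort(small_cfg())
  write_cohort(co, dir)
  s <- co[[1]]
  csvs <- list.files(dir, pattern = "\\.csv$", recursive = TRUE,
                     full.names = TRUE)
  expect_true(length(csvs) >= 2 * length(co))
  day4_csv <- grep(paste0(s$id, ".*day4"), csvs, value = TRUE)
  expect_length(day4_csv, 1)
  tacs <- read_tac_csv(day4_csv)
  expect_true(all(c("tumor", "contra") %in% names(tacs)))
  # CSV values are in Bq/mL: internal SUV scale times dose/weight
  expect_equal(tacs$tumor$values,
               s$sessions$day4$tumor$values * s$dose_bq / s$weight_g)
  # and convert back to the stored SUV curve
  suv_back <- to_suv(tacs$tumor, s$dose_bq, s$weight_g)
  expect_equal(suv_back$values, s$sessions$day4$tumor$values)
})

test_that("voxel images average back to the generating curves", {
  cfg <- small_cfg(noise_c = 0)
  s <- generate_subject(cfg, "treated", "non-responder", seed = 8L)
  vox <- generate_voxel_image(s, dims = c(8, 8, 4), day = "day4")
  tum <- extract_roi_tac(vox$image, vox$mask, cfg$schedule,
                         label = 1L, unit = "SUV")
  expect_equal(tum$values, s$sessions$day4$tumor$values,
               tolerance = 1e-10)
})

test_that("invalid arm or response labels are rejected", {
  cfg <- small_cfg()
  expect_error(generate_subject(cfg, "placebo", "responder", 1L), "arm")
  expect_error(generate_subject(cfg, "treated", "cured", 1L),
               "response label")
  expect_error(phantom_config(n_per_arm = c(treated = 2),
                              n_responders = c(treated = 3)),
               "more responders")
})
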