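# Cohort generator: schema, determinism, ground-truth calibration.

test_that("default cohort matches the stated design", {
  co <- gen_cohort(cohort_params(seed = 2))
  expect_s3_class(co, "cohort_table")
  expect_equal(nrow(co), 124)
  expect_equal(sum(co$group == "MS"), 80)
  expect_equal(sum(co$group == "control"), 44)
  expect_equal(sum(co$subtype == "RR", na.rm = TRUE), 45)
  expect_equal(sum(co$subtype == "P", na.rm = TRUE), 35)
  expect_equal(sum(co$sex == "M" & co$group == "MS"), 30)
  expect_equal(sum(co$sex == "M" & co$group == "control"), 10)
  expect_true(all(is.na(co$edss[co$group == "control"])))
  expect_true(all(co$edss[co$group == "MS"] >= 1 & co$edss[co$group == "MS"] <= 9.5))
  expect_true(all(co$duration_y[co$group == "MS"] >= 2 &
                    co$duration_y[co$group == "MS"] <= 41))
  # readings quantized to the frame interval
  expect_true(all(abs(co$cct_r1_right / 0.25 - round(co$cct_r1_right / 0.25)) < 1e-9))
})

test_that("generator is deterministic and rejects degenerate sizes", {
  a <- gen_cohort(cohort_params(seed = 3))
  b <- gen_cohort(cohort_params(seed = 3))
  expect_identical(a, b)
  expect_error(cohort_params(n_ms = 1), "n >= 2")
})

test_that("zero rater noise and side offset give perfect agreement", {
  co <- gen_cohort(cohort_params(rater_noise_sd = 0, side_offset_s = 0, seed = 4))
  expect_identical(co$cct_r1_right, co$cct_r2_right)
  expect_identical(co$cct_r1_right, co$cct_r1_left)  # side symmetry
  ms <- co[co$group == "MS", ]
  expect_equal(icc_a1(cbind(ms$cct_r1_right, ms$cct_r2_right))$icc, 1.0)
})

test_that("sample moments converge to the stated parameters (n = 10000)", {
  p <- cohort_params(n_ms = 10000, n_control = 10000, n_rr = 5000,
                     rater_noise_sd = 0, seed = 6)
  co <- gen_cohort(p)
  ms <- co$cct_r1_right[co$group == "MS"]
  ctrl <- co$cct_r1_right[co$group == "control"]
  expect_lt(abs(mean(ms) - 4.87) / 4.87, 0.02)
  expect_lt(abs(sd(ms) - 1.27) / 1.27, 0.02)
  expect_lt(abs(mean(ctrl) - 2.78) / 2.78, 0.02)
  expect_lt(abs(sd(ctrl) - 0.51) / 0.51, 0.02)
})

test_that("rater-noise calibration hits the target ICC in expectation", {
  # closed form: sigma_e^2 = sigma_b^2 (1/ICC - 1), minus quantization share
  expect_equal(calibrate_rater_noise(0.8, 2, quantum = 0),
               sqrt(4 * 0.25), tolerance = 1e-12)
  sd_noise <- calibrate_rater_noise(0.98, 1.27, quantum = 0.25)
  expect_equal(sd_noise^2 + 0.25^2 / 12, 1.27^2 * (1 / 0.98 - 1), tolerance = 1e-12)
  expect_error(calibrate_rater_noise(0.9999, 0.1, quantum = 0.25), "quantization")

  # simulation check of the additive-noise ICC model at the calibrated SD
  set.seed(99)
  iccs <- replicate(60, {
    latent <- rnorm(300, 4.87, 1.27)
    r1 <- round((latent + rnorm(300, 0, sd_noise)) / 0.25) * 0.25
    r2 <- round((latent + rnorm(300, 0, sd_noise)) / 0.25) * 0.25
    icc_a1(cbind(r1, r2))$icc
  })
  expect_lt(abs(mean(iccs) - 0.98), 0.01)
})

test_that("cohort CSV round-trip validates the schema", {
  co <- gen_cohort(cohort_params(seed = 8))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$cct_r1_right, co$cct_r1_right)
  broken <- co; broken$cct_r2_left <- NULL
  bpath <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(broken), bpath, row.names = FALSE)
  expect_error(read_cohort(bpath), "cct_r2_left")
  unlink(c(path, bpath))
})
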