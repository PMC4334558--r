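# DSA timing: subtraction, peak finding, TTP maps, CCT, color coding.

test_that("subtracted_contrast removes the mask frame", {
  frames <- array(7, c(4, 4, 5))
  s <- dsa_sequence(frames, 0:4)
  out <- subtracted_contrast(s)
  expect_true(all(out$frames == 0))

  frames2 <- array(1, c(4, 4, 6))
  frames2[2, 3, 5:6] <- 9  # single pixel brightens from frame 5 on
  out2 <- subtracted_contrast(dsa_sequence(frames2, 0:5))
  nz <- which(out2$frames != 0, arr.ind = TRUE)
  expect_true(all(nz[, 1] == 2 & nz[, 2] == 3 & nz[, 3] >= 5))

  # generator background: residual mean ~ 0 within noise SEM
  g <- gen_dsa_sequence(dsa_preset("control"), noise_sd = 2, seed = 5, dim = c(32, 32))
  sub <- subtracted_contrast(g$seq)
  bg <- circtime:::dsa_region_masks(c(32, 32))$background
  bg_resid <- apply(sub$frames, 3, function(f) mean(f[bg]))
  expect_lt(max(abs(bg_resid)), 3 * 2 / sqrt(sum(bg)) + 0.5)
})

test_that("peak_time: argmax, ties, parabolic refinement, boundaries, errors", {
  expect_equal(as.numeric(peak_time(c(0, 1, 3, 9, 3, 1), seq(0, 2.5, 0.5))), 1.5)
  # first frame on ties
  expect_equal(as.numeric(peak_time(c(0, 9, 9, 1), 0:3)), 1)
  # symmetric neighbors: vertex at the central sample
  expect_equal(as.numeric(peak_time(c(0, 1, 3, 9, 3, 1), seq(0, 2.5, 0.5),
                                    interpolate = TRUE)), 1.5)
  # asymmetric neighbors (3, 9, 7): hand-computed quadratic vertex
  expect_equal(as.numeric(peak_time(c(0, 1, 3, 9, 7, 1), seq(0, 2.5, 0.5),
                                    interpolate = TRUE)), 1.625)
  # boundary maximum: un-interpolated, flagged
  pt <- peak_time(c(9, 3, 1), 0:2, interpolate = TRUE)
  expect_equal(as.numeric(pt), 0)
  expect_true(attr(pt, "boundary"))
  expect_error(peak_time(c(2, 2, 2, 2), 0:3), "no contrast arrival")
})

test_that("peak_time interpolation equals a closed-form quadratic fit", {
  set.seed(42)
  for (i in 1:20) {
    y <- sort(runif(3, 1, 10)); y <- c(y[1], y[3], y[2])  # max in middle
    ts <- c(0, 0.5, 1)
    fit <- lm(y ~ poly(ts, 2, raw = TRUE))
    vertex <- -coef(fit)[2] / (2 * coef(fit)[3])
    got <- peak_time(c(0, y), c(-0.5, ts), interpolate = TRUE)
    expect_equal(as.numeric(got), unname(min(max(vertex, 0), 1)), tolerance = 1e-8)
  }
})

test_that("TTP map matches generator ground truth and threshold semantics", {
  g <- gen_dsa_sequence(dsa_preset("ms"), frame_rate_hz = 4, noise_sd = 0,
                        seed = 1, dim = c(48, 48))
  ttp <- estimate_ttp_map(g$seq)
  sip <- ttp$ttp_s[g$truth$roi_siphon]
  expect_true(all(abs(sip - g$truth$siphon_peak_s) <= 0.125 + 1e-9))
  vein <- ttp$ttp_s[g$truth$roi_vein]
  expect_true(all(abs(vein - g$truth$vein_peak_s) <= 0.125 + 1e-9))

  # arrival_threshold = 1: only globally brightest pixel(s)
  t1 <- estimate_ttp_map(g$seq, arrival_threshold = 1.0)
  expect_true(sum(t1$valid) >= 1)
  sub <- subtracted_contrast(g$seq)
  pixmax <- apply(sub$frames, c(1, 2), max)
  expect_identical(which(t1$valid), which(pixmax == max(pixmax)))

  expect_error(estimate_ttp_map(dsa_sequence(array(0, c(4, 4, 4)), 0:3)),
               "no contrast")
})

test_that("compute_cct recovers truth and honors its invariants", {
  g <- gen_dsa_sequence(dsa_preset("ms"), frame_rate_hz = 4, noise_sd = 0,
                        seed = 1, dim = c(48, 48))
  m <- compute_cct(g$seq, g$truth$roi_siphon, g$truth$roi_vein)
  expect_lte(abs(m$cct_s - g$truth$cct_true_s), 0.125)
  expect_equal(m$cct_s, m$vein_peak_s - m$siphon_peak_s)

  # identical ROIs -> zero
  m0 <- compute_cct(g$seq, g$truth$roi_siphon, g$truth$roi_siphon)
  expect_equal(m0$cct_s, 0)

  # invariance to constant offset and uniform scaling
  shifted <- g$seq; shifted$frames <- shifted$frames + 123
  scaled <- g$seq; scaled$frames <- scaled$frames * 3.7
  expect_equal(compute_cct(shifted, g$truth$roi_siphon, g$truth$roi_vein)$cct_s, m$cct_s)
  expect_equal(compute_cct(scaled, g$truth$roi_siphon, g$truth$roi_vein)$cct_s, m$cct_s)

  # non-physiological ordering: flagged with a warning
  expect_warning(
    mneg <- compute_cct(g$seq, g$truth$roi_vein, g$truth$roi_siphon),
    "non-physiological")
  expect_true("non_physiological_order" %in% mneg$flags)
  expect_error(compute_cct(g$seq, g$truth$roi_siphon & FALSE, g$truth$roi_vein),
               "empty")
})

test_that("quantization bound holds for frame rates 2-4 Hz (noiseless)", {
  for (fps in c(2, 3, 4)) {
    for (preset in c("ms", "control")) {
      g <- gen_dsa_sequence(dsa_preset(preset), frame_rate_hz = fps,
                            noise_sd = 0, seed = 1, dim = c(32, 32))
      m <- compute_cct(g$seq, g$truth$roi_siphon, g$truth$roi_vein)
      expect_lte(abs(m$cct_s - g$truth$cct_true_s), 1 / fps + 1e-9)
      expect_lte(abs(m$siphon_peak_s - g$truth$siphon_peak_s), 0.5 / fps + 1e-9)
      expect_lte(abs(m$vein_peak_s - g$truth$vein_peak_s), 0.5 / fps + 1e-9)
    }
  }
})

test_that("color coding is monotone and places veins in the expected bands", {
  g <- gen_dsa_sequence(dsa_preset("ms"), frame_rate_hz = 4, noise_sd = 0,
                        seed = 1, dim = c(48, 48))
  ttp <- estimate_ttp_map(g$seq)
  # constant map -> single hue
  const <- ttp; const$ttp_s[const$valid] <- 3
  rgb <- color_code(const, 0, 6)
  cols <- unique(matrix(rgb[rep(const$valid, 3)], ncol = 3))
  expect_equal(nrow(cols), 1)

  # monotone: earlier TTP -> earlier hue
  hue_of <- function(t) {
    tm <- ttp; tm$ttp_s[] <- NA; tm$valid[] <- FALSE
    tm$ttp_s[1, 1] <- t; tm$valid[1, 1] <- TRUE
    px <- color_code(tm, 0, 6)[1, 1, ]
    grDevices::rgb2hsv(px[1] * 255, px[2] * 255, px[3] * 255)[1]
  }
  hues <- vapply(c(0.5, 2, 3.5, 5.5), hue_of, 1)
  expect_true(all(diff(hues) > 0))

  # MS veins land in the final (blue) quartile, control veins in green
  ms_rgb <- color_code(ttp, 0, 6)
  frac_ms <- (g$truth$vein_peak_s - 0) / 6
  expect_gt(frac_ms, 0.75)
  gc <- gen_dsa_sequence(dsa_preset("control"), frame_rate_hz = 4, noise_sd = 0,
                         seed = 1, dim = c(48, 48))
  frac_ctrl <- (gc$truth$vein_peak_s - 0) / 6
  expect_true(frac_ctrl > 0.375 && frac_ctrl < 0.75)
  # invalid pixels are black
  expect_true(all(ms_rgb[rep(!ttp$valid, 3)] == 0))
})
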