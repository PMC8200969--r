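cheek <- function(n) roi(0, n, 0, n, label = "cheek")

test_that("hemoglobin map is log10(R/G) with ratio invariance", {
  img <- uniform_image(128, 128, c(0.5, 0.5, 0.5))
  expect_equal(max(abs(hemoglobin_map(img, cheek(128)))), 0)
  pink <- uniform_image(128, 128, c(0.6, 0.3, 0.4))
  expect_equal(hemoglobin_map(pink, cheek(128))[1, 1], log10(2))
  # equal per-channel gain cancels in the ratio
  dim_img <- uniform_image(128, 128, c(0.3, 0.15, 0.2))
  expect_equal(hemoglobin_map(dim_img, cheek(128)),
               hemoglobin_map(pink, cheek(128)), tolerance = 1e-12)
})

test_that("uniform pink gives the closed-form brightness, zero variation", {
  img <- uniform_image(256, 256, c(0.55, 0.45, 0.40))
  r <- redness_score(img, cheek(256))
  expect_equal(r$variation_component_au, 0)
  expect_equal(r$brightness_component_au, 100 * log10(11 / 9))
  expect_equal(r$redness_au,
               r$brightness_component_au + r$variation_component_au)
  # neutral gray: both components zero
  g <- redness_score(uniform_image(256, 256, c(0.5, 0.5, 0.5)), cheek(256))
  expect_equal(g$redness_au, 0)
})

test_that("a constant h shift moves brightness only (DC orthogonality)", {
  g0 <- generate_patch(patch_params(n_pores = 0L, texture_rms = 0,
                                    blotch_rms = 0.02, h_shift = 0,
                                    illum_gradient = 0, bit_depth = NULL,
                                    seed = 15, size = c(256L, 256L)))
  g1 <- generate_patch(patch_params(n_pores = 0L, texture_rms = 0,
                                    blotch_rms = 0.02, h_shift = 0.05,
                                    illum_gradient = 0, bit_depth = NULL,
                                    seed = 15, size = c(256L, 256L)))
  r0 <- redness_score(g0$image, cheek(256))
  r1 <- redness_score(g1$image, cheek(256))
  expect_equal(r1$brightness_component_au - r0$brightness_component_au,
               100 * 0.05, tolerance = 1e-8)
  expect_lt(abs(r1$variation_component_au - r0$variation_component_au), 1e-6)
})

test_that("in-band blotch RMS is recovered and scores are monotone", {
  for (a in c(0.01, 0.04)) {
    scores <- vapply(1:3, function(s) {
      g <- generate_patch(patch_params(n_pores = 0L, texture_rms = 0,
                                       blotch_rms = a, seed = s))
      redness_score(g$image, cheek(512))$variation_component_au
    }, numeric(1))
    expect_true(all(abs(scores - 100 * a) / (100 * a) < 0.05))
  }
  # monotone in blotch amplitude and in global red shift
  blotch_means <- vapply(c(0.005, 0.01, 0.02, 0.04, 0.08), function(a) {
    mean(vapply(1:3, function(s) {
      g <- generate_patch(patch_params(n_pores = 0L, texture_rms = 0,
                                       blotch_rms = a, seed = s,
                                       size = c(256L, 256L)))
      redness_score(g$image, cheek(256))$variation_component_au
    }, numeric(1)))
  }, numeric(1))
  expect_identical(order(blotch_means), 1:5)
  shift_scores <- vapply(c(-0.04, -0.02, 0, 0.02, 0.04), function(sh) {
    g <- generate_patch(patch_params(n_pores = 0L, texture_rms = 0,
                                     blotch_rms = 0.02, h_shift = sh,
                                     seed = 16, size = c(256L, 256L)))
    redness_score(g$image, cheek(256))$redness_au
  }, numeric(1))
  expect_identical(order(shift_scores), 1:5)
})

test_that("an uncalibrated red cast shifts the score; calibration removes it", {
  lay <- patch_layout(c(256L, 256L))
  mkraw <- function(gains) {
    g <- generate_patch(patch_params(size = c(256L, 256L), n_pores = 0L,
                                     texture_rms = 0, blotch_rms = 0.02,
                                     tip_roi = lay$tip, gains = gains,
                                     bit_depth = NULL, seed = 17))
    img <- g$image
    img$color_state <- "raw"
    img
  }
  neutral <- mkraw(c(1, 1, 1))
  cast <- mkraw(c(1.3, 1, 1))
  ck <- lay$cheek
  raw_neutral <- redness_score(calibrate(neutral,
                                         gray_reference(c(0.5, 0.5, 0.5))),
                               ck)$redness_au
  raw_cast <- redness_score(calibrate(cast, gray_reference(c(0.5, 0.5, 0.5))),
                            ck)$redness_au
  expect_gt(raw_cast - raw_neutral, 5)     # 100*log10(1.3) ~ 11.4 au shift
  cal_cast <- calibrate(mkraw(c(1.3, 1, 1)),
                        measure_gray(mkraw(c(1.3, 1, 1)), lay$tip))
  expect_lt(abs(redness_score(cal_cast, ck)$redness_au - raw_neutral), 0.1)
})
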