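test_that("enhance_edges is DC-free, dark-positive, and size-checked", {
  const <- matrix(0.5, 64, 64)
  expect_lt(max(abs(enhance_edges(const))), 1e-12)
  # adding a constant leaves the response unchanged
  set.seed(5)
  x <- matrix(runif(64 * 64, 0.3, 0.7), 64, 64)
  expect_equal(enhance_edges(x), enhance_edges(x + 0.1), tolerance = 1e-10)
  # dark disk of radius ~ sigma_small * sqrt(2): maximal response at center
  lum <- mask_from(64, 64, function(r, c) TRUE) * 0.6
  disk <- mask_from(64, 64, function(r, c) (r - 32)^2 + (c - 32)^2 <= 2.1^2)
  lum[disk] <- 0.3
  resp <- enhance_edges(lum)
  expect_equal(as.integer(which(resp == max(resp))),
               as.integer((32 - 1) * 64 + 32))   # center, column-major
  expect_error(enhance_edges(matrix(0.5, 30, 64)), "smaller")
})

test_that("binarize uses the robust threshold and degrades to empty", {
  expect_false(any(binarize(matrix(0, 32, 32))))
  # one extreme blob above median + 3 * 1.4826 * MAD, nothing else: bounded
  # background noise (max 0.005) stays below the threshold (~0.011)
  set.seed(6)
  resp <- matrix(runif(64 * 64, -0.005, 0.005), 64, 64)
  blob <- mask_from(64, 64, function(r, c) (r - 20)^2 + (c - 40)^2 <= 9)
  resp[blob] <- 1
  m <- binarize(resp, k = 3)
  expect_true(all(m[blob]))
  expect_identical(sum(m), sum(blob))
  expect_false(any(binarize(resp, k = 1e9)))
})

test_that("connected components are 8-connected", {
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- m[3, 3] <- m[4, 4] <- TRUE     # diagonal chain: one component
  m[8, 8] <- TRUE                           # far pixel: its own component
  comps <- dermaflux:::label_components(m)
  expect_identical(length(comps), 2L)
  expect_identical(sort(unname(lengths(comps))), c(1L, 3L))
})

test_that("detect_pores screens by circularity, contrast, and border", {
  params <- pore_params(min_area = 5L)
  lum <- matrix(1, 60, 60)
  disk <- mask_from(60, 60, function(r, c) (r - 30)^2 + (c - 30)^2 <= 36)
  lum[disk] <- 0.5
  cands <- detect_pores(disk, lum, params)
  expect_length(cands, 1L)
  expect_gte(cands[[1]]$circularity, 0.85)
  expect_lte(cands[[1]]$circularity, 1)
  expect_equal(cands[[1]]$centroid, c(row = 29, col = 29), tolerance = 1e-9)

  # 30x4 rectangle (axis ratio 7.5): 4*pi*A/P^2 < 0.6, rejected
  rect <- mask_from(60, 60, function(r, c) r >= 10 & r <= 13 & c >= 10 & c <= 39)
  lumr <- matrix(1, 60, 60); lumr[rect] <- 0.5
  expect_length(detect_pores(rect, lumr, params), 0L)
  loose <- detect_pores(rect, lumr, pore_params(min_area = 5L,
                                                circularity_min = 0.1))
  expect_length(loose, 1L)
  expect_lt(loose[[1]]$circularity, 0.6)

  # low-contrast blob is rejected by the contrast gate
  lumc <- matrix(1, 60, 60); lumc[disk] <- 0.995
  expect_length(detect_pores(disk, lumc, params), 0L)

  # border-touching component contributes nothing
  edge <- mask_from(60, 60, function(r, c) (r - 3)^2 + (c - 30)^2 <= 36)
  lume <- matrix(1, 60, 60); lume[edge] <- 0.5
  expect_length(detect_pores(edge, lume, params), 0L)

  # ordering: area descending, centroid tie-break
  two <- disk | mask_from(60, 60, function(r, c) (r - 12) ^2 + (c - 48)^2 <= 16)
  lum2 <- matrix(1, 60, 60); lum2[two] <- 0.5
  got <- detect_pores(two, lum2, params)
  areas <- vapply(got, function(p) p$area_px, numeric(1))
  expect_identical(areas, sort(areas, decreasing = TRUE))
})

test_that("circularity equals the independent brute-force 4*pi*A/P^2", {
  set.seed(7)
  for (rep in 1:5) {
    resp <- gaussian_blur(matrix(rnorm(96 * 96), 96, 96), 2.5)
    mask <- resp > quantile(resp, 0.93)
    lum <- matrix(1, 96, 96); lum[mask] <- 0.4
    cands <- detect_pores(mask, lum, pore_params(min_area = 5L,
                                                 circularity_min = 0.05,
                                                 max_area = 5000L))
    expect_gt(length(cands), 0)
    for (cand in cands) {
      expect_lt(abs(cand$circularity -
                    oracle_circularity(cand$pixels, 96)), 1e-9)
    }
  }
})

test_that("pore-free patches score zero and radius monotonicity holds", {
  g <- generate_patch(patch_params(n_pores = 0L, texture_rms = 0,
                                   blotch_rms = 0, seed = 9,
                                   size = c(256L, 256L)))
  pr <- pore_area(g$image, roi(0, 256, 0, 256, "cheek"))
  expect_identical(pr$total_area_au, 0)
  expect_length(pr$candidates, 0L)

  # mean total area strictly increases with generated radius (reduced grid)
  means <- vapply(c(3, 5, 7, 9), function(r) {
    mean(vapply(1:4, function(s) {
      g <- generate_patch(patch_params(pore_radius_px = c(r, 0), seed = s,
                                       size = c(256L, 256L), n_pores = 8L))
      pore_area(g$image, roi(0, 256, 0, 256, "cheek"))$total_area_au
    }, numeric(1)))
  }, numeric(1))
  expect_identical(order(means), 1:4)     # Spearman rho = 1 on means
})

test_that("pore_area enforces its preconditions", {
  img <- uniform_image(128, 128, c(0.5, 0.4, 0.35), state = "raw")
  expect_error(pore_area(img, roi(0, 128, 0, 128, "cheek")), "calibrated")
  cal <- uniform_image(128, 128, c(0.5, 0.4, 0.35))
  expect_error(pore_area(cal, roi(0, 128, 0, 128, "eye_to_cheek")), "cheek")
  expect_error(pore_area(cal, roi(0, 16, 0, 16, "cheek")), "floor")
})
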