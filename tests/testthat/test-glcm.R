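# Co-occurrence matrices and second-order features against hand counts and
# a brute-force oracle.

test_that("quantization follows floor(v * Ng / 256)", {
  img <- matrix(c(0L, 127L, 128L, 255L), 2, 2)
  expect_identical(quantize(img, 256L), matrix(c(0L, 127L, 128L, 255L), 2, 2))
  expect_identical(quantize(img, 2L), matrix(c(0L, 0L, 1L, 1L), 2, 2))
  expect_equal(quantize(matrix(255L, 1, 1), 64L)[1, 1], 63L)
  expect_error(quantize(img, 1L), "n_levels")
})

test_that("co-occurrence pair counting matches hand-derived cases", {
  # constant image: single diagonal entry 1
  g <- compute_glcm(matrix(3L, 4, 4), d = 1, angle = 0, n_levels = 4)
  expect_equal(g$P[4, 4], 1)
  expect_equal(sum(g$P), 1)

  # 1x4 [0,1,0,1]: 3 adjacent pairs, both orders, all cross-level
  g <- compute_glcm(matrix(c(0L, 1L, 0L, 1L), 1, 4), d = 1, angle = 0)
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(g$n_pairs, 6)

  # checkerboard at d=1, 0 degrees: Contrast 1, Energy 0.5
  cb <- quantize(make_toy_image("checkerboard", 8, levels = c(0L, 255L)), 2L)
  fv <- glcm_features(compute_glcm(cb, d = 1, angle = 0))
  expect_equal(unname(fv["Contrast"]), 1)
  expect_equal(unname(fv["Energy"]), 0.5)

  # constant image features: Energy 1, Contrast 0, Entropy 0
  fv0 <- glcm_features(compute_glcm(matrix(7L, 5, 5), d = 1, angle = 45))
  expect_equal(unname(fv0[c("Energy", "Contrast", "Entropy")]), c(1, 0, 0))
})

test_that("all 11 features match the brute-force oracle on random rasters", {
  set.seed(101)
  for (i in 1:50) {
    img <- random_raster(8, 8, 8)
    d <- sample(1:3, 1)
    ang <- sample(c(0, 45, 90, 135), 1)
    g <- compute_glcm(img, d = d, angle = ang, n_levels = 8)
    expect_equal(g$P, oracle_glcm(img, d, ang, 8), tolerance = 1e-14)
    got <- glcm_features(g)
    want <- oracle_glcm_features(oracle_glcm(img, d, ang, 8))
    expect_true(max(abs(got - want)) < 1e-10)
  }
})

test_that("normalization holds on random rasters and masks", {
  set.seed(7)
  for (i in 1:100) {
    img <- random_raster(10, 10, 16)
    mask <- matrix(runif(100) > 0.3, 10, 10)
    g <- tryCatch(compute_glcm(img, mask, d = 1, angle = 0, n_levels = 16),
                  error = function(e) NULL)
    if (is.null(g)) next  # mask left no pair: allowed degenerate error
    expect_lt(abs(sum(g$P) - 1), 1e-12)
    expect_equal(g$P, t(g$P))  # symmetric accumulation
  }
})

test_that("features ignore pixels outside the mask", {
  set.seed(12)
  img <- random_raster(12, 12, 16)
  mask <- matrix(FALSE, 12, 12); mask[3:9, 3:9] <- TRUE
  g1 <- glcm_features(compute_glcm(img, mask, d = 1, angle = 0, n_levels = 16))
  img2 <- img
  img2[!mask] <- random_raster(12, 12, 16)[!mask]
  g2 <- glcm_features(compute_glcm(img2, mask, d = 1, angle = 0, n_levels = 16))
  expect_identical(g1, g2)
})

test_that("a mask with no admissible pair raises a degenerate-matrix error", {
  img <- random_raster(6, 6, 4)
  mask <- matrix(FALSE, 6, 6); mask[1, 1] <- TRUE
  expect_error(compute_glcm(img, mask, d = 1, angle = 0), "degenerate")
})
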