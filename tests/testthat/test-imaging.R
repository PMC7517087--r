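# Preprocessing: equalization, Gaussian smoothing, Gabor bank.

test_that("histogram equalization follows the CDF mapping and is monotone", {
  # hand-computed: CDF {0: 0.5, 128: 0.75, 255: 1.0} scaled to 0..255
  img <- matrix(c(0L, 0L, 128L, 255L), 2, 2)
  e <- equalize(img)
  expect_equal(sort(unique(as.vector(e))), c(127L, 191L, 255L))
  expect_equal(e[img == 0], c(127L, 127L))
  expect_equal(e[img == 128], 191L)
  expect_equal(e[img == 255], 255L)

  # constant image maps to a (single) constant
  ce <- equalize(matrix(42L, 3, 3))
  expect_length(unique(as.vector(ce)), 1L)

  # an exactly uniform histogram is a fixed point
  u <- matrix(0:255, 16, 16)
  expect_identical(equalize(u), as_gray_image(u))

  # monotonicity of the level mapping, random image
  set.seed(11)
  r <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  er <- equalize(r)
  lut <- tapply(as.vector(er), as.vector(r), unique)
  expect_true(all(diff(as.numeric(lut)) >= 0))
})

test_that("Gaussian smoothing: normalized kernel, constant fixed point, impulse response", {
  k <- fundustex:::gaussian_kernel_1d(1.7)
  expect_lt(abs(sum(k) - 1), 1e-12)
  expect_lt(abs(sum(outer(k, k)) - 1), 1e-12)

  cimg <- matrix(77L, 10, 10)
  expect_identical(gaussian_smooth(cimg, sigma = 2), as_gray_image(cimg))

  # unit impulse: response proportional to the sampled 2-D Gaussian
  n <- 31L
  imp <- make_toy_image("impulse", n, level = 255L)
  sm <- gaussian_smooth(imp, sigma = 1)
  k1 <- fundustex:::gaussian_kernel_1d(1)
  r <- (length(k1) - 1L) %/% 2L
  expected <- matrix(0, n, n)
  ctr <- (n + 1L) %/% 2L
  expected[(ctr - r):(ctr + r), (ctr - r):(ctr + r)] <- 255 * outer(k1, k1)
  expect_true(max(abs(sm - expected)) <= 0.5 + 1e-9)  # quantization only

  expect_error(gaussian_smooth(cimg, sigma = 0), "positive")
})

test_that("Gabor bank has 8 x 5 = 40 magnitude responses in scale-major order", {
  img <- make_toy_image("constant", 32, level = 100L)
  bank <- gabor_bank(img)
  expect_length(bank$responses, 40L)
  expect_equal(bank$scale, rep(1:5, each = 8L))
  expect_equal(bank$orientation, rep(1:8, times = 5L))
  expect_true(all(vapply(bank$responses, function(m) all(m >= 0), logical(1))))
})

test_that("Gabor orientation selectivity: grating matches its orientation", {
  lam <- 8
  n <- 64L
  grating <- requant(matrix(127.5 + 120 * sin(2 * pi * (1:n) / lam), n, n))
  bank <- gabor_bank(grating, gabor_params(wavelength = lam, scales = 1))
  # grating varies along rows -> carrier direction theta = 0
  means <- vapply(bank$responses, mean, numeric(1))
  expect_equal(which.max(means), 1L)
})

test_that("rotating the image 90 degrees permutes the Gabor orientation axis by 4", {
  set.seed(5)
  img <- requant(matrix(runif(48^2, 0, 255), 48, 48))
  rot <- t(img)[, 48:1]  # 90 degree rotation
  p <- gabor_params(wavelength = 6, scales = 1)
  m1 <- vapply(gabor_bank(img, p)$responses, mean, numeric(1))
  m2 <- vapply(gabor_bank(rot, p)$responses, mean, numeric(1))
  perm <- ((seq_len(8) - 1L + 4L) %% 8L) + 1L
  expect_equal(m2, m1[perm], tolerance = 0.05)
})

test_that("preprocess is deterministic, respects invariants, keeps constants constant", {
  set.seed(3)
  img <- requant(matrix(runif(32^2, 0, 255), 32, 32))
  a <- preprocess(img, sigma = 1.2)
  b <- preprocess(img, sigma = 1.2)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 255))
  cst <- preprocess(make_toy_image("constant", 16, level = 9L))
  expect_length(unique(as.vector(cst)), 1L)
  gb <- preprocess(img, gabor = TRUE)
  expect_length(attr(gb, "gabor")$responses, 40L)
})
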