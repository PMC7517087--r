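# Preprocessing for fundus rasters: histogram equalization, Gaussian
# denoising, and an optional Gabor filter bank for edge/texture diagnostics.

#' Histogram equalization
#'
#' Classic CDF-based equalization. Each intensity level r with empirical
#' probability p(r) = K_r / K is mapped to floor(255 * CDF(r)), which
#' normalizes non-uniform illumination and stretches contrast. The mapping
#' is monotone non-decreasing in the input intensity, and an image whose
#' histogram is already exactly uniform over 0..255 is a fixed point.
#'
#' @param img gray image matrix.
#' @return equalized gray image matrix.
#' @export
equalize <- function(img) {
  img <- as_gray_image(img)
  counts <- tabulate(as.vector(img) + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(img)
  lut <- as.integer(pmin(255, pmax(0, floor(255 * cdf + 1e-9))))
  out <- matrix(lut[as.vector(img) + 1L], nrow = nrow(img))
  as_gray_image(out)
}

# Discrete 1-D Gaussian kernel, truncated at +/- 3 sigma and renormalized
# to sum exactly 1.
gaussian_kernel_1d <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("`sigma` must be a single positive number", call. = FALSE)
  }
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq.int(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with replicate (edge-clamp) padding, so a constant
# image is a fixed point.
conv_separable <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  padded <- m[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * padded[i:(i + h - 1L), , drop = FALSE]
  padded <- out[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out2 <- matrix(0, h, w)
  for (i in seq_along(k)) out2 <- out2 + k[i] * padded[, i:(i + w - 1L), drop = FALSE]
  out2
}

#' Gaussian smoothing
#'
#' Convolution with a zero-mean isotropic 2-D Gaussian of standard
#' deviation `sigma` (pixels), separably applied, truncated at three
#' standard deviations and renormalized. Noisy values are replaced with a
#' weighted neighborhood average; edges use replicate padding. The result
#' is re-quantized to \[0, 255\] (round half away from zero).
#'
#' @param img gray image matrix.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return smoothed gray image matrix.
#' @export
gaussian_smooth <- function(img, sigma = 1) {
  img <- as_gray_image(img)
  k <- gaussian_kernel_1d(sigma)
  requantize(conv_separable(matrix(as.numeric(img), nrow(img)), k))
}

#' Gabor filter bank parameters
#'
#' The default bank has 8 orientations theta = k*pi/8 (k = 0..7) and 5
#' scales, realised as wavelength multipliers {1..5} applied to the base
#' wavelength. The envelope sigma follows the common half-response
#' bandwidth-of-one convention sigma = 0.56 * lambda.
#'
#' @param wavelength base wavelength of the sinusoidal carrier, pixels.
#' @param n_orientations number of orientations spanning \[0, pi).
#' @param scales integer multipliers applied to `wavelength`.
#' @param gamma spatial aspect ratio of the Gaussian envelope.
#' @param eta phase offset of the carrier, radians.
#' @param sigma_factor envelope sigma as a fraction of the wavelength.
#' @return object of class `gabor_params`.
#' @export
gabor_params <- function(wavelength = 4, n_orientations = 8L, scales = 1:5,
                         gamma = 0.5, eta = 0, sigma_factor = 0.56) {
  stopifnot(wavelength > 0, n_orientations >= 1, all(scales > 0),
            gamma > 0, sigma_factor > 0)
  structure(list(wavelength = wavelength,
                 orientations = (seq_len(n_orientations) - 1L) * pi / n_orientations,
                 scales = as.numeric(scales),
                 gamma = gamma, eta = eta, sigma_factor = sigma_factor),
            class = "gabor_params")
}

# Complex Gabor kernel on a centered grid, rows = y, cols = z.
gabor_kernel <- function(lambda, theta, gamma, eta, sigma) {
  r <- max(2L, as.integer(ceiling(3 * sigma)))
  y <- matrix(seq.int(-r, r), 2L * r + 1L, 2L * r + 1L)
  z <- t(y)
  yp <- y * cos(theta) + z * sin(theta)
  zp <- -y * sin(theta) + z * cos(theta)
  exp(-(yp^2 + gamma^2 * zp^2) / (2 * sigma^2)) *
    exp(1i * (2 * pi * yp / lambda + eta))
}

# Linear "same" 2-D convolution via FFT with zero padding.
conv2d_fft <- function(m, k) {
  hm <- nrow(m); wm <- ncol(m); hk <- nrow(k); wk <- ncol(k)
  H <- hm + hk - 1L; W <- wm + wk - 1L
  pm <- matrix(0 + 0i, H, W); pm[1:hm, 1:wm] <- m
  pk <- matrix(0 + 0i, H, W); pk[1:hk, 1:wk] <- k
  full <- stats::fft(stats::fft(pm) * stats::fft(pk), inverse = TRUE) / (H * W)
  r0 <- (hk - 1L) %/% 2L; c0 <- (wk - 1L) %/% 2L
  full[(r0 + 1L):(r0 + hm), (c0 + 1L):(c0 + wm)]
}

#' Gabor filter bank responses
#'
#' Convolves the image with a bank of complex Gabor filters and returns
#' magnitude rasters, one per (scale, orientation) pair, scale-major order
#' (all orientations of scale 1, then scale 2, ...). The carrier of the
#' filter at orientation theta varies along y' = y cos(theta) + z sin(theta)
#' with (y, z) = (row, col), so theta = 0 responds to intensity variation
#' across rows.
#'
#' @param img gray image matrix.
#' @param params a [gabor_params()] object.
#' @return list with `responses` (list of numeric magnitude matrices),
#'   `scale` and `orientation` index vectors, and `params`.
#' @export
gabor_bank <- function(img, params = gabor_params()) {
  img <- as_gray_image(img)
  stopifnot(inherits(params, "gabor_params"))
  m <- matrix(as.numeric(img), nrow(img))
  responses <- list()
  scale_ix <- integer(0); orient_ix <- integer(0)
  for (s in seq_along(params$scales)) {
    lambda <- params$wavelength * params$scales[s]
    sigma <- params$sigma_factor * lambda
    for (o in seq_along(params$orientations)) {
      k <- gabor_kernel(lambda, params$orientations[o], params$gamma,
                        params$eta, sigma)
      responses[[length(responses) + 1L]] <- Mod(conv2d_fft(m, k))
      scale_ix <- c(scale_ix, s); orient_ix <- c(orient_ix, o)
    }
  }
  list(responses = responses, scale = scale_ix, orientation = orient_ix,
       params = params)
}

#' Standard preprocessing pipeline
#'
#' Grayscale conversion happens at load time; this applies histogram
#' equalization then Gaussian smoothing, in that order. A Gabor bank can be
#' attached as a diagnostic (it does not feed the texture features).
#'
#' @param img gray image matrix.
#' @param sigma Gaussian smoothing sigma in pixels; `0` disables smoothing.
#' @param equalize_first apply histogram equalization.
#' @param gabor if `TRUE`, attach the default Gabor bank responses as the
#'   `"gabor"` attribute of the result.
#' @return preprocessed gray image matrix.
#' @export
preprocess <- function(img, sigma = 1, equalize_first = TRUE, gabor = FALSE) {
  img <- as_gray_image(img)
  if (isTRUE(equalize_first)) img <- equalize(img)
  if (sigma > 0) img <- gaussian_smooth(img, sigma)
  if (isTRUE(gabor)) attr(img, "gabor") <- gabor_bank(img)
  img
}
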