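# First-order histogram statistics and Haar wavelet subband energies.

#' First-order histogram features
#'
#' Six statistics of the raw 0-255 intensity distribution inside the
#' region of interest: Mean, Variance, Skewness (third standardized
#' moment; defined as 0 for a zero-variance region), Energy (sum of
#' squared histogram probabilities), Entropy (bits), and `Perc.01%`, the
#' 1st percentile by the nearest-rank rule.
#'
#' @param img gray image matrix (raw intensities, not quantized).
#' @param mask optional logical region-of-interest matrix.
#' @return named numeric vector of length 6.
#' @export
histogram_features <- function(img, mask = NULL) {
  img <- as_gray_image(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  stopifnot(identical(dim(mask), dim(img)))
  v <- as.vector(img[mask])
  if (length(v) == 0L) stop("mask is empty", call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / length(v)
  lev <- 0:255
  mu <- sum(lev * p)
  va <- sum((lev - mu)^2 * p)
  sk <- if (va > 0) sum((lev - mu)^3 * p) / va^1.5 else 0
  en <- sum(p^2)
  et <- -sum(plogp2(p))
  pc <- sort(v)[max(1L, ceiling(0.01 * length(v)))]
  c(Mean = mu, Variance = va, Skewness = sk, Energy = en, Entropy = et,
    "Perc.01%" = as.numeric(pc))
}

#' Pearson mode skewness
#'
#' Auxiliary asymmetry measure (mean - mode) / sd of the masked intensity
#' histogram; the mode is the most frequent level (lowest level on ties).
#' Not part of the default hybrid feature vector.
#'
#' @inheritParams histogram_features
#' @return single numeric value (0 for a zero-variance region).
#' @export
pearson_mode_skewness <- function(img, mask = NULL) {
  img <- as_gray_image(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  v <- as.vector(img[mask])
  if (length(v) == 0L) stop("mask is empty", call. = FALSE)
  counts <- tabulate(v + 1L, nbins = 256L)
  mo <- which.max(counts) - 1L
  mu <- mean(v)
  s <- stats::sd(v) * sqrt((length(v) - 1) / length(v))
  if (is.na(s) || s == 0) return(0)
  (mu - mo) / s
}

# One level of the orthonormal 2-D Haar transform. Odd trailing rows or
# columns are dropped before pairing (standard truncation). Returns the
# four subbands; LL can be decomposed further.
haar_dwt2 <- function(m) {
  h <- nrow(m) - nrow(m) %% 2L
  w <- ncol(m) - ncol(m) %% 2L
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  odd_r <- seq.int(1L, h, by = 2L); evn_r <- odd_r + 1L
  lo_r <- (m[odd_r, , drop = FALSE] + m[evn_r, , drop = FALSE]) / sqrt(2)
  hi_r <- (m[odd_r, , drop = FALSE] - m[evn_r, , drop = FALSE]) / sqrt(2)
  odd_c <- seq.int(1L, w, by = 2L); evn_c <- odd_c + 1L
  list(
    LL = (lo_r[, odd_c, drop = FALSE] + lo_r[, evn_c, drop = FALSE]) / sqrt(2),
    LH = (lo_r[, odd_c, drop = FALSE] - lo_r[, evn_c, drop = FALSE]) / sqrt(2),
    HL = (hi_r[, odd_c, drop = FALSE] + hi_r[, evn_c, drop = FALSE]) / sqrt(2),
    HH = (hi_r[, odd_c, drop = FALSE] - hi_r[, evn_c, drop = FALSE]) / sqrt(2)
  )
}

#' Haar wavelet subband energies
#'
#' Orthonormal Haar decomposition to the requested scale; the energy of a
#' subband is the mean squared coefficient, sum(d^2) / k, taken over the k
#' coefficients whose spatial support (a 2^scale x 2^scale pixel block)
#' intersects the region of interest. Subbands are admissible only while
#' both their dimensions are at least 8; deeper scales raise an error.
#'
#' @param img gray image matrix.
#' @param mask optional logical region-of-interest matrix.
#' @param scale decomposition level (>= 1).
#' @return named numeric vector `WavEnLL_s-<scale>`, `WavEnHL_s-<scale>`,
#'   `WavEnLH_s-<scale>`, `WavEnHH_s-<scale>`.
#' @export
haar_subband_energies <- function(img, mask = NULL, scale = 4L) {
  img <- as_gray_image(img)
  scale <- as.integer(scale)
  stopifnot(scale >= 1L)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  stopifnot(identical(dim(mask), dim(img)))
  m <- matrix(as.numeric(img), nrow(img))
  for (s in seq_len(scale)) {
    if (nrow(m) %/% 2L < 8L || ncol(m) %/% 2L < 8L) {
      stop("subbands at scale ", s, " would be smaller than 8 x 8 ",
           "(image ", nrow(img), " x ", ncol(img),
           " admits scales 1..", s - 1L, ")", call. = FALSE)
    }
    bands <- haar_dwt2(m)
    m <- bands$LL
  }
  # which coefficients are covered by the ROI: block-maximum of the mask
  block <- 2L^scale
  hb <- nrow(bands$LL); wb <- ncol(bands$LL)
  covered <- matrix(FALSE, hb, wb)
  for (i in seq_len(hb)) {
    rows <- ((i - 1L) * block + 1L):min(nrow(mask), i * block)
    sub <- mask[rows, , drop = FALSE]
    for (j in seq_len(wb)) {
      cols <- ((j - 1L) * block + 1L):min(ncol(mask), j * block)
      if (any(sub[, cols])) covered[i, j] <- TRUE
    }
  }
  k <- sum(covered)
  if (k == 0L) stop("mask covers no wavelet coefficient at scale ", scale,
                    call. = FALSE)
  e <- vapply(c("LL", "HL", "LH", "HH"),
              function(b) sum(bands[[b]][covered]^2) / k, numeric(1))
  names(e) <- sprintf("WavEn%s_s-%d", c("LL", "HL", "LH", "HH"), scale)
  e
}
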