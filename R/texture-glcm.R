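# Gray-level co-occurrence matrices and the 11 second-order (Haralick-type)
# statistics computed from them.

#' Reduce gray-level resolution by uniform binning
#'
#' Maps an 8-bit value v to floor(v * n_levels / 256), giving levels
#' 0 .. n_levels - 1. Texture matrices default to 64 levels, the common
#' texture-analysis convention; first-order histogram features stay on the
#' raw 0-255 scale.
#'
#' @param img gray image matrix.
#' @param n_levels number of gray levels after reduction (2..256).
#' @return integer matrix with values in 0 .. n_levels - 1.
#' @export
quantize <- function(img, n_levels = 64L) {
  img <- as_gray_image(img)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L || n_levels > 256L) {
    stop("`n_levels` must be in [2, 256]", call. = FALSE)
  }
  out <- matrix(as.integer((as.vector(img) * n_levels) %/% 256L), nrow = nrow(img))
  out
}

glcm_offset <- function(angle, d) {
  # (row, col) displacement; rows grow downward
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("`angle` must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels at displacement `d` along `angle`, with
#' symmetric accumulation (each pair contributes in both orders), and
#' normalizes by the total pair count so the entries sum to one. Both
#' pixels of a pair must fall inside the mask.
#'
#' @param img integer raster of gray levels (typically from [quantize()]).
#' @param mask optional logical matrix restricting the region of interest.
#' @param d pair distance in pixels, 1..5.
#' @param angle direction in degrees: 0, 45, 90 or 135.
#' @param n_levels number of gray levels; defaults to `max(img) + 1`.
#' @return object of class `glcm`: list with `P` (normalized matrix),
#'   `d`, `angle`, `n_levels`, and `n_pairs` (the normalization constant).
#' @export
compute_glcm <- function(img, mask = NULL, d = 1L, angle = 0,
                         n_levels = NULL) {
  stopifnot(is.matrix(img))
  d <- as.integer(d)
  if (d < 1L || d > 5L) stop("`d` must be in 1..5", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  stopifnot(identical(dim(mask), dim(img)))
  if (is.null(n_levels)) n_levels <- max(img) + 1L
  n_levels <- as.integer(n_levels)
  off <- glcm_offset(angle, d)
  h <- nrow(img); w <- ncol(img)
  r1 <- max(1L, 1L - off[1]):min(h, h - off[1])
  c1 <- max(1L, 1L - off[2]):min(w, w - off[2])
  if (length(r1) < 1L || length(c1) < 1L) {
    stop("raster too small for distance ", d, " at angle ", angle, call. = FALSE)
  }
  a <- img[r1, c1, drop = FALSE]
  b <- img[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + off[1], c1 + off[2], drop = FALSE]
  if (!any(ok)) {
    stop("mask contains no pixel pair at distance ", d, " along ", angle,
         " degrees (degenerate co-occurrence matrix)", call. = FALSE)
  }
  av <- a[ok]; bv <- b[ok]
  counts <- tabulate(av * n_levels + bv + 1L, nbins = n_levels^2)
  P <- matrix(counts, n_levels, n_levels, byrow = TRUE)
  P <- P + t(P)  # symmetric accumulation: both pair orders
  n_pairs <- sum(P)
  structure(list(P = P / n_pairs, d = d, angle = angle,
                 n_levels = n_levels, n_pairs = n_pairs),
            class = "glcm")
}

#' Second-order texture statistics from a co-occurrence matrix
#'
#' Returns the 11 features {Energy (angular second moment), Contrast,
#' Correlation, Variance, inverse difference moment, difference variance,
#' sum average, sum variance, Entropy, sum entropy, difference entropy}.
#' Entropies use log base 2 with 0*log(0) := 0. Gray-level indices are
#' 0-based. When a marginal standard deviation is zero, Correlation is
#' defined as 0.
#'
#' @param glcm a `glcm` object from [compute_glcm()], or a normalized
#'   co-occurrence matrix.
#' @return named numeric vector of length 11.
#' @export
glcm_features <- function(glcm) {
  P <- if (inherits(glcm, "glcm")) glcm$P else glcm
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  ng <- nrow(P)
  lev <- seq_len(ng) - 1L
  px <- rowSums(P); py <- colSums(P)
  mu_h <- sum(lev * px); mu_v <- sum(lev * py)
  sd_h <- sqrt(sum((lev - mu_h)^2 * px)); sd_v <- sqrt(sum((lev - mu_v)^2 * py))
  A <- matrix(lev, ng, ng); B <- t(A)
  # sum (k = a + b) and difference (k = |a - b|) marginal distributions
  p_sum <- vapply(0:(2L * ng - 2L), function(k) sum(P[A + B == k]), numeric(1))
  p_dif <- vapply(0:(ng - 1L), function(k) sum(P[abs(A - B) == k]), numeric(1))
  ks <- 0:(2L * ng - 2L); kd <- 0:(ng - 1L)
  energy <- sum(P^2)
  contrast <- sum(kd^2 * p_dif)
  correlation <- if (sd_h == 0 || sd_v == 0) 0 else
    (sum(A * B * P) - mu_h * mu_v) / (sd_h * sd_v)
  variance <- sum((A - mu_h)^2 * P)
  idm <- sum(P / (1 + (A - B)^2))
  mu_dif <- sum(kd * p_dif)
  dif_var <- sum((kd - mu_dif)^2 * p_dif)
  sum_avg <- sum(ks * p_sum)
  sum_var <- sum((ks - sum_avg)^2 * p_sum)
  entropy <- -sum(plogp2(P))
  sum_entropy <- -sum(plogp2(p_sum))
  dif_entropy <- -sum(plogp2(p_dif))
  c(Energy = energy, Contrast = contrast, Correlation = correlation,
    Variance = variance, InvDfMom = idm, DifVarnc = dif_var,
    SumAverg = sum_avg, SumVarnc = sum_var, Entropy = entropy,
    SumEntrp = sum_entropy, DifEntrp = dif_entropy)
}
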