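# Internal helpers shared across modules.

#' Validate a grayscale image raster
#'
#' A gray image is an integer-valued matrix with all values in \[0, 255\].
#' Most functions in the package accept a plain numeric matrix and validate
#' it through this helper.
#'
#' @param img matrix to validate.
#' @param arg name used in error messages.
#' @return the validated matrix, with storage mode `integer`.
#' @export
as_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg), call. = FALSE)
  }
  if (anyNA(img)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  v <- as.vector(img)
  if (any(v < 0 | v > 255)) {
    stop(sprintf("`%s` has values outside [0, 255]", arg), call. = FALSE)
  }
  if (any(v != round(v))) {
    stop(sprintf("`%s` must be integer-valued (quantize or round first)", arg), call. = FALSE)
  }
  storage.mode(img) <- "integer"
  img
}

# Round half away from zero, then clip to [0, 255]. Base round() rounds half
# to even, which is not what 8-bit re-quantization conventionally does.
requantize <- function(x) {
  r <- trunc(abs(x) + 0.5) * sign(x)
  m <- matrix(as.integer(pmin(255, pmax(0, r))), nrow = nrow(x))
  m
}

round_half_up <- function(x) trunc(abs(x) + 0.5) * sign(x)

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a base seed and an index, staying below 2^31.
derive_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

# 8-connected component labelling of a logical mask. Iterative flood fill
# (no recursion) so it scales to full rasters.
label_components <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  current <- 0L
  idx <- which(mask & labels == 0L)
  offs_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  offs_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in idx) {
    if (labels[start] != 0L) next
    current <- current + 1L
    stack <- start
    labels[start] <- current
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      nr <- r + offs_r; nc <- cc + offs_c
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      np <- (nc[ok] - 1L) * h + nr[ok]
      np <- np[mask[np] & labels[np] == 0L]
      if (length(np)) {
        labels[np] <- current
        stack <- c(stack, np)
      }
    }
  }
  labels
}

# log2 with the 0 * log 0 := 0 convention, applied to probabilities.
plogp2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}
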