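# Gray-level run-length matrices (Galloway) and the 15 run statistics
# computed from them.

# Extract the pixel sequences ("lines") of a raster along a direction,
# with off-mask pixels set to NA so they break runs.
direction_lines <- function(img, mask, direction) {
  h <- nrow(img); w <- ncol(img)
  vals <- img
  vals[!mask] <- NA_integer_
  switch(as.character(direction),
    "0"   = lapply(seq_len(h), function(r) vals[r, ]),
    "90"  = lapply(seq_len(w), function(c) vals[, c]),
    "45"  = {  # up-right diagonals: constant row + col
      rr <- matrix(seq_len(h), h, w); cc <- t(matrix(seq_len(w), w, h))
      key <- rr + cc
      ord <- order(key, cc)  # within a diagonal, advance along columns
      unname(split(vals[ord], key[ord]))
    },
    "135" = {  # down-right diagonals: constant col - row
      rr <- matrix(seq_len(h), h, w); cc <- t(matrix(seq_len(w), w, h))
      key <- cc - rr
      ord <- order(key, cc)
      unname(split(vals[ord], key[ord]))
    },
    stop("`direction` must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

#' Gray-level run-length matrix
#'
#' Counts maximal runs of equal gray level along one direction. Runs are
#' truncated at mask boundaries. The entry P\[l, m\] is the number of runs
#' of level l (1-based row = level 0) and length m.
#'
#' @param img integer raster of gray levels (typically from [quantize()]).
#' @param mask optional logical region-of-interest matrix.
#' @param direction degrees: 0 (along rows), 45, 90 (along columns), 135.
#' @param n_levels number of gray levels; defaults to `max(img) + 1`.
#' @return object of class `glrlm`: list with `P` (count matrix, levels x
#'   run lengths), `direction`, `n_runs`, `n_pixels`.
#' @export
compute_glrlm <- function(img, mask = NULL, direction = 0, n_levels = NULL) {
  stopifnot(is.matrix(img))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  stopifnot(identical(dim(mask), dim(img)))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (is.null(n_levels)) n_levels <- max(img) + 1L
  n_levels <- as.integer(n_levels)
  max_run <- max(nrow(img), ncol(img))
  runs <- lapply(direction_lines(img, mask, direction), function(line) {
    r <- rle(as.vector(line))
    keep <- !is.na(r$values)
    cbind(level = r$values[keep] + 1L, len = r$lengths[keep])
  })
  runs <- do.call(rbind, runs)
  P <- matrix(tabulate((runs[, "len"] - 1L) * n_levels + runs[, "level"],
                       nbins = n_levels * max_run),
              n_levels, max_run)
  structure(list(P = P, direction = direction,
                 n_runs = sum(P), n_pixels = sum(mask)),
            class = "glrlm")
}

#' Run-length texture statistics
#'
#' The 15 statistics of the run-length matrix: short/long run emphasis
#' (SRE, LRE), gray-level and run-length non-uniformity and their
#' normalized versions (GLN, GLNN, RLN, RLNN), run percentage (RP), low and
#' high gray-level run emphasis (LGLRE, HGLRE), the four joint short/long x
#' low/high emphases, and the gray-level and run-length variances (GLV,
#' RLV). Gray-level indices are 1-based so the l^2 divisors are well
#' defined; the two variances each use their own marginal mean.
#'
#' @param glrlm a `glrlm` object from [compute_glrlm()].
#' @return named numeric vector of length 15.
#' @export
glrlm_features <- function(glrlm) {
  stopifnot(inherits(glrlm, "glrlm"))
  P <- glrlm$P
  N <- glrlm$n_runs
  Np <- glrlm$n_pixels
  if (N < 1) stop("run-length matrix has no runs", call. = FALSE)
  ng <- nrow(P); nr <- ncol(P)
  l <- seq_len(ng)   # 1-based gray level
  m <- seq_len(nr)   # run length
  L <- matrix(l, ng, nr); M <- matrix(m, ng, nr, byrow = TRUE)
  row_tot <- rowSums(P); col_tot <- colSums(P)
  p <- P / N
  mu_l <- sum(p * L); mu_m <- sum(p * M)
  c(
    ShrtREmph       = sum(P / M^2) / N,
    LngREmph        = sum(P * M^2) / N,
    GLevNonU        = sum(row_tot^2) / N,
    GLevNonUNorm    = sum(row_tot^2) / N^2,
    RLNonUni        = sum(col_tot^2) / N,
    RLNonUniNorm    = sum(col_tot^2) / N^2,
    Fraction        = N / Np,
    LowGREmph       = sum(P / L^2) / N,
    HighGREmph      = sum(P * L^2) / N,
    ShrtRLowGREmph  = sum(P / (L^2 * M^2)) / N,
    ShrtRHighGREmph = sum(P * L^2 / M^2) / N,
    LngRLowGREmph   = sum(P * M^2 / L^2) / N,
    LngRHighGREmph  = sum(P * L^2 * M^2) / N,
    GLevVar         = sum(p * (L - mu_l)^2),
    RLenVar         = sum(p * (M - mu_m)^2)
  )
}
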