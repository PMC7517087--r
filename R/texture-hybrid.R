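# The fused hybrid feature vector: 220 co-occurrence + 15 run-length + 6
# histogram + 4 wavelet features = 245 per region of interest.

GLCM_ANGLES <- c(0, 45, 90, 135)
RLM_DIR_PREFIX <- c("0" = "Horzl_", "90" = "Vertl_", "45" = "45dgr_", "135" = "135dr_")
RLM_DIRECTIONS <- c(0, 45, 90, 135)

glcm_feature_basenames <- function() {
  c("Energy", "Contrast", "Correlation", "Variance", "InvDfMom", "DifVarnc",
    "SumAverg", "SumVarnc", "Entropy", "SumEntrp", "DifEntrp")
}

glrlm_feature_basenames <- function() {
  c("ShrtREmph", "LngREmph", "GLevNonU", "GLevNonUNorm", "RLNonUni",
    "RLNonUniNorm", "Fraction", "LowGREmph", "HighGREmph", "ShrtRLowGREmph",
    "ShrtRHighGREmph", "LngRLowGREmph", "LngRHighGREmph", "GLevVar", "RLenVar")
}

# MaZda-style co-occurrence name: S(dcol, drow-as-signed) + feature, e.g.
# S(5,0)Entropy (0 deg), S(5,-5)Contrast (45 deg), S(0,5)... (90 deg),
# S(5,5)... (135 deg).
glcm_block_names <- function(distances = 1:5) {
  out <- character(0)
  for (d in distances) {
    for (ang in GLCM_ANGLES) {
      tag <- switch(as.character(ang),
        "0"   = sprintf("S(%d,0)", d),
        "45"  = sprintf("S(%d,-%d)", d, d),
        "90"  = sprintf("S(0,%d)", d),
        "135" = sprintf("S(%d,%d)", d, d))
      out <- c(out, paste0(tag, glcm_feature_basenames()))
    }
  }
  out
}

#' Names of the hybrid feature vector
#'
#' Fixed deterministic order: the co-occurrence block (11 features x 5
#' distances x 4 angles = 220), the run-length block (15 features, either
#' direction-averaged or 4 x 15 per-direction), the histogram block (6),
#' and the wavelet block (4).
#'
#' @param rlm_mode `"averaged"` (default, total 245) or `"per_direction"`
#'   (total 290, with `Horzl_`/`Vertl_`/`45dgr_`/`135dr_` prefixes).
#' @param distances co-occurrence pair distances.
#' @param wavelet_scale wavelet decomposition level used in the names.
#' @return character vector of feature names.
#' @export
hybrid_feature_names <- function(rlm_mode = c("averaged", "per_direction"),
                                 distances = 1:5, wavelet_scale = 4L) {
  rlm_mode <- match.arg(rlm_mode)
  rlm <- if (rlm_mode == "averaged") {
    glrlm_feature_basenames()
  } else {
    unlist(lapply(RLM_DIRECTIONS, function(dir) {
      paste0(RLM_DIR_PREFIX[[as.character(dir)]], glrlm_feature_basenames())
    }))
  }
  c(glcm_block_names(distances),
    rlm,
    c("Mean", "Variance", "Skewness", "Energy", "Entropy", "Perc.01%"),
    sprintf("WavEn%s_s-%d", c("LL", "HL", "LH", "HH"), wavelet_scale))
}

#' Extract the fused hybrid texture feature vector
#'
#' Computes, per region of interest: 11 co-occurrence statistics at pair
#' distances 1..5 and angles 0/45/90/135 degrees on the gray-level-reduced
#' raster (220 features); the 15 run-length statistics, by default averaged
#' over the four directions (15 features); the 6 first-order histogram
#' statistics on raw intensities; and the 4 Haar subband energies at the
#' requested scale. Total 245 features in a fixed order with MaZda-style
#' names.
#'
#' @param img gray image matrix (preprocessed).
#' @param mask optional logical region-of-interest matrix; `NULL` uses the
#'   whole raster.
#' @param n_levels gray levels for the co-occurrence and run-length
#'   matrices (histogram features always use raw 0-255).
#' @param distances co-occurrence pair distances.
#' @param wavelet_scale Haar decomposition level.
#' @param rlm_mode `"averaged"` or `"per_direction"` run-length block.
#' @return named numeric vector (length 245 under the defaults).
#' @export
#' @examples
#' img <- make_fundus_like(synthetic_spec(2, rng_seed = 7))$image
#' fv <- extract_hybrid(img)
#' length(fv)  # 245
extract_hybrid <- function(img, mask = NULL, n_levels = 64L, distances = 1:5,
                           wavelet_scale = 4L,
                           rlm_mode = c("averaged", "per_direction")) {
  rlm_mode <- match.arg(rlm_mode)
  img <- as_gray_image(img)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  q <- quantize(img, n_levels)
  com <- numeric(0)
  for (d in distances) {
    for (ang in GLCM_ANGLES) {
      g <- compute_glcm(q, mask, d = d, angle = ang, n_levels = n_levels)
      com <- c(com, glcm_features(g))
    }
  }
  rlm_per_dir <- vapply(RLM_DIRECTIONS, function(dir) {
    glrlm_features(compute_glrlm(q, mask, direction = dir, n_levels = n_levels))
  }, numeric(15L))
  rlm <- if (rlm_mode == "averaged") rowMeans(rlm_per_dir) else as.vector(rlm_per_dir)
  hist6 <- histogram_features(img, mask)
  wav <- haar_subband_energies(img, mask, scale = wavelet_scale)
  out <- c(com, rlm, hist6, wav)
  names(out) <- hybrid_feature_names(rlm_mode, distances, wavelet_scale)
  out
}
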