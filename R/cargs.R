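# Clustering-based automated region-growing segmentation (CARGS):
# quadrant partition, irregular-polygon seed groups, homogeneity region
# growing, and K-means refinement on the grown region's intensities.

#' Partition a raster into four quadrants
#'
#' Tiles are half-open in neither sense: each pixel belongs to exactly one
#' tile; for odd dimensions the extra row/column goes to the bottom/right
#' tiles.
#'
#' @param img gray image matrix (at least 2 x 2).
#' @return list of four tiles (`top_left`, `top_right`, `bottom_left`,
#'   `bottom_right`), each a list with `pixels` (sub-matrix) and `offset`
#'   (0-based row/col of the tile's top-left corner in the full raster).
#' @export
quadrant_partition <- function(img) {
  img <- as_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 2L || w < 2L) stop("image must be at least 2 x 2", call. = FALSE)
  hr <- h %/% 2L; hc <- w %/% 2L
  tile <- function(rows, cols) {
    list(pixels = img[rows, cols, drop = FALSE],
         offset = c(row = rows[1] - 1L, col = cols[1] - 1L))
  }
  list(
    top_left     = tile(1:hr, 1:hc),
    top_right    = tile(1:hr, (hc + 1L):w),
    bottom_left  = tile((hr + 1L):h, 1:hc),
    bottom_right = tile((hr + 1L):h, (hc + 1L):w)
  )
}

#' Sample irregular seed polygons
#'
#' Each polygon has a vertex count drawn uniformly from 5..12, a centroid
#' drawn uniformly from the central half of the raster, sorted angular
#' vertex positions, and per-vertex radii drawn uniformly from 20-100% of
#' the centroid's distance to the nearest image border. Star-shaped by
#' construction, hence simple; degenerate (zero-area) draws are rejected
#' and resampled. Deterministic for a fixed seed.
#'
#' @param img gray image matrix.
#' @param n_polygons number of polygons to sample.
#' @param rng_seed integer seed.
#' @return list of polygons, each a list with `vertices` (n x 2 matrix of
#'   0-based (row, col)), `centroid`, and `rng_seed`.
#' @export
generate_seed_polygons <- function(img, n_polygons = 1L, rng_seed = 1L) {
  img <- as_gray_image(img)
  stopifnot(n_polygons >= 1L)
  h <- nrow(img); w <- ncol(img)
  with_seed(rng_seed, {
    polys <- vector("list", n_polygons)
    for (i in seq_len(n_polygons)) {
      repeat {
        nv <- sample(5:12, 1L)
        cr <- stats::runif(1, 0.25 * h, 0.75 * h)
        cc <- stats::runif(1, 0.25 * w, 0.75 * w)
        budget <- min(cr, h - cr, cc, w - cc)  # distance to nearest border
        ang <- sort(stats::runif(nv, 0, 2 * pi))
        rad <- stats::runif(nv, 0.2, 1.0) * budget
        vr <- cr + rad * sin(ang)
        vc <- cc + rad * cos(ang)
        vr <- pmin(h - 1e-9, pmax(1, vr))
        vc <- pmin(w - 1e-9, pmax(1, vc))
        area <- abs(sum(vc * c(vr[-1], vr[1]) - c(vc[-1], vc[1]) * vr)) / 2
        if (area > 0) break
      }
      polys[[i]] <- list(vertices = cbind(row = vr - 1, col = vc - 1),
                         centroid = c(row = cr - 1, col = cc - 1),
                         rng_seed = rng_seed)
    }
    polys
  })
}

# Even-odd rule point-in-polygon test for all pixel centers, vectorized
# over pixels. vertices are 0-based (row, col); pixel centers at integer
# coordinates. Thin polygon spikes can rasterize to stray pixels detached
# from the body, so only the largest 8-connected component is kept - the
# seed group must be connected for region growing to stay connected.
polygon_mask <- function(polygon, h, w) {
  v <- polygon$vertices
  nv <- nrow(v)
  px_r <- as.vector(matrix(seq_len(h) - 1L, h, w))
  px_c <- as.vector(matrix(seq_len(w) - 1L, h, w, byrow = TRUE))
  inside <- rep(FALSE, h * w)
  j <- nv
  for (i in seq_len(nv)) {
    yi <- v[i, 1]; xi <- v[i, 2]
    yj <- v[j, 1]; xj <- v[j, 2]
    crosses <- ((yi > px_r) != (yj > px_r)) &
      (px_c < (xj - xi) * (px_r - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  mask <- matrix(inside, h, w)
  if (any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    mask <- lab == which.max(sizes)
  }
  mask
}

#' Homogeneity-based region growing from a seed polygon
#'
#' All pixels inside the polygon seed the region. Growth proceeds in
#' breadth-first waves over 8-connected neighbors: every frontier pixel
#' whose intensity differs from the current region mean by at most `tau`
#' joins, the mean is updated, and the process repeats until no frontier
#' pixel qualifies. With `tau = 0` this reduces to the connected component
#' of the seed's intensity plateau.
#'
#' @param img gray image matrix.
#' @param seed a polygon from [generate_seed_polygons()], or a logical
#'   seed mask of the same shape as `img`.
#' @param tau homogeneity tolerance in gray levels (>= 0).
#' @return logical region mask (class `roi_mask`, with attribute
#'   `region_id`).
#' @export
region_grow <- function(img, seed, tau = 10) {
  img <- as_gray_image(img)
  stopifnot(tau >= 0)
  h <- nrow(img); w <- ncol(img)
  seed_mask <- if (is.matrix(seed) && is.logical(seed)) seed
               else polygon_mask(seed, h, w)
  if (!any(seed_mask)) stop("seed polygon covers no pixel", call. = FALSE)
  region <- seed_mask
  total <- sum(as.numeric(img[region])); count <- sum(region)
  repeat {
    frontier <- dilate8(region) & !region
    if (!any(frontier)) break
    mu <- total / count
    accept <- frontier & abs(as.numeric(img) - mu) <= tau
    if (!any(accept)) break
    region <- region | accept
    total <- total + sum(as.numeric(img[accept]))
    count <- count + sum(accept)
  }
  structure(region, class = c("roi_mask", class(region)), region_id = 1L)
}

# 8-neighborhood binary dilation.
dilate8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  shifts <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                 c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (s in shifts) {
    sr <- s[1]; sc <- s[2]
    src_r <- max(1L, 1L - sr):min(h, h - sr)
    src_c <- max(1L, 1L - sc):min(w, w - sc)
    out[src_r + sr, src_c + sc] <- out[src_r + sr, src_c + sc] |
      mask[src_r, src_c]
  }
  out
}

#' K-means refinement of a region's intensities
#'
#' Lloyd iterations on the pixel intensities inside a mask: assign each
#' pixel to the nearest center by Euclidean (absolute) distance, then
#' recompute each center as the mean of its pixels; stop when the largest
#' center shift falls below `tol` or after `max_iter` iterations. The
#' working range for K on fundus images is 7..12 (results degrade above
#' 12); values outside it draw a warning, and K above 12 is clamped.
#'
#' Determinism: centers are initialized at K evenly spaced quantiles of
#' the masked intensities unless `init = "random"`, in which case
#' `rng_seed` drives the draw. Distance ties go to the lowest center
#' index; an emptied cluster is re-seeded at the pixel farthest from its
#' assigned center.
#'
#' @param img gray image matrix.
#' @param mask logical region mask (e.g. from [region_grow()]).
#' @param K number of clusters.
#' @param tol convergence tolerance on the maximum center shift, gray
#'   levels.
#' @param max_iter iteration cap.
#' @param init `"quantile"` (deterministic, default) or `"random"`.
#' @param rng_seed seed used only for random initialization.
#' @param warn_range warn when K is outside 7..12.
#' @return object of class `cluster_model`: list with `K`, `centers`,
#'   `labels` (integer raster, 0 outside the mask, 1..K inside),
#'   `objective` (per-iteration within-cluster sum of squares), `iterations`.
#' @export
kmeans_refine <- function(img, mask, K = 8L, tol = 0.5, max_iter = 100L,
                          init = c("quantile", "random"), rng_seed = 1L,
                          warn_range = TRUE) {
  img <- as_gray_image(img)
  init <- match.arg(init)
  stopifnot(is.matrix(mask), is.logical(mask), identical(dim(mask), dim(img)))
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (warn_range && (K < 7L || K > 12L)) {
    warning("K = ", K, " is outside the 7..12 working range", call. = FALSE)
  }
  if (K > 12L) {
    warning("clamping K from ", K, " to 12 (quality degrades above 12)",
            call. = FALSE)
    K <- 12L
  }
  x <- as.numeric(img[mask])
  n_distinct <- length(unique(x))
  if (K > n_distinct) {
    warning("K reduced from ", K, " to ", n_distinct,
            " (number of distinct masked intensities)", call. = FALSE)
    K <- n_distinct
  }
  centers <- if (init == "quantile" || K == 1L) {
    as.numeric(stats::quantile(x, probs = (seq_len(K) - 0.5) / K, type = 7))
  } else {
    with_seed(rng_seed, sort(sample(x, K)))
  }
  assign_lab <- function(centers) {
    D <- abs(outer(x, centers, "-"))
    max.col(-D, ties.method = "first")
  }
  objective <- numeric(0)
  lab <- assign_lab(centers)
  for (it in seq_len(max_iter)) {
    # empty-cluster rescue: re-seed at the pixel farthest from its center
    for (k in seq_len(K)) {
      if (!any(lab == k)) {
        far <- which.max(abs(x - centers[lab]))
        centers[k] <- x[far]
        lab <- assign_lab(centers)
      }
    }
    objective <- c(objective, sum((x - centers[lab])^2))
    new_centers <- vapply(seq_len(K), function(k) mean(x[lab == k]), numeric(1))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    lab <- assign_lab(centers)
    if (shift < tol) break
  }
  labels <- matrix(0L, nrow(img), ncol(img))
  labels[mask] <- lab
  structure(list(K = K, centers = centers, labels = labels,
                 objective = objective, iterations = length(objective)),
            class = "cluster_model")
}

#' Full CARGS segmentation
#'
#' Quadrant partition, then per quadrant: sample seed polygons, grow a
#' homogeneous region from each, take the union, and refine it with
#' K-means on intensities. Cluster masks are mapped back to full-image
#' coordinates and (by default) split into 8-connected components so every
#' returned region is connected. Deterministic given the configuration.
#'
#' @param img gray image matrix.
#' @param K clusters per quadrant (reduced automatically when a quadrant
#'   has fewer distinct intensities; no range warning in this composite).
#' @param tau region-growing homogeneity tolerance, gray levels.
#' @param n_polygons seed polygons per quadrant.
#' @param rng_seed integer seed.
#' @param split_components split each cluster into connected components.
#' @param min_region_px drop regions smaller than this many pixels.
#' @return list of region masks (logical matrices, full-image shape), each
#'   with attributes `region_id` and `quadrant`.
#' @export
segment_cargs <- function(img, K = 8L, tau = 10, n_polygons = 2L,
                          rng_seed = 1L, split_components = TRUE,
                          min_region_px = 1L) {
  img <- as_gray_image(img)
  tiles <- quadrant_partition(img)
  regions <- list()
  rid <- 0L
  for (qi in seq_along(tiles)) {
    tile <- tiles[[qi]]
    timg <- tile$pixels
    polys <- generate_seed_polygons(timg, n_polygons,
                                    rng_seed = derive_seed(rng_seed, qi))
    grown <- matrix(FALSE, nrow(timg), ncol(timg))
    for (p in polys) grown <- grown | region_grow(timg, p, tau = tau)
    model <- suppressWarnings(
      kmeans_refine(timg, grown, K = K, warn_range = FALSE)
    )
    for (k in seq_len(model$K)) {
      cl_mask <- model$labels == k
      if (!any(cl_mask)) next
      parts <- if (split_components) {
        lab <- label_components(cl_mask)
        lapply(seq_len(max(lab)), function(i) lab == i)
      } else list(cl_mask)
      for (part in parts) {
        if (sum(part) < min_region_px) next
        full <- matrix(FALSE, nrow(img), ncol(img))
        full[tile$offset["row"] + seq_len(nrow(timg)),
             tile$offset["col"] + seq_len(ncol(timg))] <- part
        rid <- rid + 1L
        attr(full, "region_id") <- rid
        attr(full, "quadrant") <- names(tiles)[qi]
        regions[[rid]] <- full
      }
    }
  }
  regions
}

#' Write a label image for a set of region masks
#'
#' Encodes regions as an 8-bit label raster (0 = background, k = region
#' index, capped at 255) and writes it as a PNG.
#'
#' @param regions list of logical masks (same shape).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(regions, path) {
  stopifnot(length(regions) >= 1L)
  lab <- matrix(0L, nrow(regions[[1]]), ncol(regions[[1]]))
  for (i in seq_along(regions)) lab[regions[[i]]] <- min(i, 255L)
  write_png(lab, path)
}
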