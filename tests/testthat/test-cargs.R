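# Segmentation: quadrant partition, seed polygons, region growing, K-means
# refinement, and the composite CARGS procedure.

test_that("quadrant partition tiles the raster exactly", {
  img <- requant(matrix(runif(256^2, 0, 255), 256, 256))
  q <- quadrant_partition(img)
  expect_true(all(vapply(q, function(t) all(dim(t$pixels) == c(128, 128)),
                         logical(1))))
  # 5x5: floor rule gives 2x2, 2x3, 3x2, 3x3
  q5 <- quadrant_partition(matrix(0L, 5, 5))
  expect_equal(lapply(q5, function(t) unname(dim(t$pixels))),
               list(top_left = c(2L, 2L), top_right = c(2L, 3L),
                    bottom_left = c(3L, 2L), bottom_right = c(3L, 3L)))
  # union = all pixels, pairwise disjoint
  seen <- matrix(0L, 256, 256)
  for (t in q) {
    rows <- t$offset["row"] + seq_len(nrow(t$pixels))
    cols <- t$offset["col"] + seq_len(ncol(t$pixels))
    seen[rows, cols] <- seen[rows, cols] + 1L
  }
  expect_true(all(seen == 1L))
  expect_error(quadrant_partition(matrix(0L, 1, 5)), "2 x 2")
})

test_that("seed polygons are deterministic, in-bounds, and non-degenerate", {
  img <- matrix(0L, 64, 48)
  a <- generate_seed_polygons(img, 5, rng_seed = 99)
  b <- generate_seed_polygons(img, 5, rng_seed = 99)
  expect_identical(a, b)
  polys <- generate_seed_polygons(img, 1000, rng_seed = 1)
  for (p in polys) {
    v <- p$vertices
    expect_true(all(v[, "row"] >= 0 & v[, "row"] <= 63))
    expect_true(all(v[, "col"] >= 0 & v[, "col"] <= 47))
    expect_true(nrow(v) >= 5 && nrow(v) <= 12)
  }
  # every polygon must cover at least one pixel of a modest raster
  covered <- vapply(generate_seed_polygons(img, 50, rng_seed = 2),
                    function(p) sum(fundustex:::polygon_mask(p, 64, 48)),
                    numeric(1))
  expect_true(all(covered > 0))
})

test_that("region growing matches connected components on plateau images", {
  # constant image: everything joins
  cimg <- matrix(100L, 16, 16)
  seed <- matrix(FALSE, 16, 16); seed[8, 8] <- TRUE
  expect_true(all(region_grow(cimg, seed, tau = 0)))

  # two flat plateaus, tau = 0: exactly the seed's plateau component
  img <- matrix(0L, 20, 20)
  img[, 11:20] <- 200L
  img[5, 15] <- 0L  # isolated 0-level pixel inside the 200 plateau
  seed <- matrix(FALSE, 20, 20); seed[10, 3] <- TRUE
  grown <- region_grow(img, seed, tau = 0)
  comp <- igraph_components(img == 0L)
  expect_equal(matrix(as.logical(grown), 20, 20), comp == comp[10, 3])

  # random cases: mask contains the seeds and is 8-connected
  set.seed(4)
  for (i in 1:20) {
    rimg <- requant(matrix(runif(24^2, 0, 255), 24, 24))
    poly <- generate_seed_polygons(rimg, 1, rng_seed = i)[[1]]
    seeds <- fundustex:::polygon_mask(poly, 24, 24)
    if (!any(seeds)) next
    g <- region_grow(rimg, seeds, tau = 30)
    expect_true(all(g[seeds]))
    comp <- igraph_components(matrix(as.logical(g), 24, 24))
    expect_equal(max(comp), 1L)
  }
})

test_that("K-means refinement: exact recovery, K=1 mean, monotone objective", {
  # two delta-separated intensity populations -> centers exactly {10, 240}
  img <- matrix(c(rep(10L, 50), rep(240L, 50)), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  km <- suppressWarnings(kmeans_refine(img, mask, K = 2))
  expect_equal(sort(km$centers), c(10, 240))
  lab10 <- unique(km$labels[img == 10L])
  lab240 <- unique(km$labels[img == 240L])
  expect_length(lab10, 1L); expect_length(lab240, 1L)
  expect_true(lab10 != lab240)

  # K = 1: single center equals the masked mean
  km1 <- suppressWarnings(kmeans_refine(img, mask, K = 1))
  expect_equal(km1$centers, mean(c(rep(10, 50), rep(240, 50))))

  # objective trace non-increasing on random images
  set.seed(17)
  for (i in 1:100) {
    rimg <- requant(matrix(runif(16^2, 0, 255), 16, 16))
    km <- suppressWarnings(kmeans_refine(rimg, matrix(TRUE, 16, 16), K = 3,
                                         warn_range = FALSE))
    expect_true(all(diff(km$objective) <= 1e-9))
  }

  # K above the distinct-intensity count is reduced with a warning
  expect_warning(kmeans_refine(matrix(5L, 4, 4), matrix(TRUE, 4, 4), K = 8),
                 "reduced")
  # K outside the 7..12 working range warns; K > 12 is clamped
  w <- capture_warnings(kmeans_refine(img, mask, K = 14))
  expect_true(any(grepl("clamping", w)))
  expect_true(any(grepl("working range", w)))
})

test_that("CARGS segmentation: disjoint in-quadrant regions, constant case, texture purity", {
  img <- make_fundus_like(synthetic_spec(2, rng_seed = 8))$image
  regs <- segment_cargs(img, rng_seed = 2)
  expect_gt(length(regs), 0L)
  # no pixel belongs to two regions (regions never cross quadrants)
  acc <- matrix(0L, nrow(img), ncol(img))
  for (r in regs) acc <- acc + r
  expect_true(all(acc <= 1L))

  cimg <- matrix(50L, 64, 64)
  cregs <- segment_cargs(cimg, rng_seed = 1)
  expect_length(cregs, 4L)  # one region per quadrant
  expect_equal(sort(unique(vapply(cregs, attr, character(1), "quadrant"))),
               sort(c("top_left", "top_right", "bottom_left", "bottom_right")))

  # two textures with disjoint intensity ranges: regions are texture-pure
  set.seed(6)
  fine <- requant(matrix(runif(64 * 32, 90, 110), 64, 32))
  coarse <- requant(matrix(runif(64 * 32, 180, 220), 64, 32))
  two <- cbind(fine, coarse)
  truth <- cbind(matrix(1L, 64, 32), matrix(2L, 64, 32))
  regs <- segment_cargs(two, K = 2, tau = 60, n_polygons = 3, rng_seed = 5)
  n_pure <- 0; n_tot <- 0
  for (r in regs) {
    t_in <- truth[r]
    n_tot <- n_tot + length(t_in)
    if (length(unique(t_in)) == 1L) n_pure <- n_pure + length(t_in)
  }
  expect_gte(n_pure / n_tot, 0.9)
})
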