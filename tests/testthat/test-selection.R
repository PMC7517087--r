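# Feature ranking and subset selection: Fisher, POE+AC, mutual
# information, the pooled pre-optimization stage, and CFS.

make_table <- function(x, y) {
  df <- as.data.frame(x)
  df$class_label <- y
  df
}

test_that("Fisher scores: zero for equal means, infinite sentinel, hand value", {
  y <- rep(c("a", "b"), each = 20)
  set.seed(1)
  same <- rnorm(40)                       # identical class distributions
  x <- cbind(f_same_mean = c(same[1:20], same[1:20]),
             f_perfect = as.numeric(y == "b"),   # zero within-class variance
             f_noise = rnorm(40))
  r <- fisher_scores(make_table(x, y))
  expect_equal(r$features[1], "f_perfect")
  expect_true(is.infinite(r$scores[1]))
  expect_equal(r$scores[r$features == "f_same_mean"], 0)

  # two balanced classes, means 0/1, common within variance:
  # F = p1*p2*(m1-m2)^2 / (p1*v1 + p2*v2)
  set.seed(2)
  g <- rnorm(30)
  x2 <- cbind(f = c(g, g + 1))
  y2 <- rep(c("a", "b"), each = 30)
  v <- var(g)
  expected <- (0.5 * 0.5 * 1) / (0.5 * v + 0.5 * v)
  r2 <- fisher_scores(make_table(x2, y2))
  expect_equal(r2$scores[1], expected, tolerance = 1e-12)
})

test_that("POE+AC: perfect feature first, duplicates penalized, hand-enumerated order", {
  y <- rep(c("a", "b"), each = 10)
  perfect <- as.numeric(y == "b")
  set.seed(3)
  x <- cbind(dup = perfect, perfect = perfect, other = rnorm(20))
  # duplicate of the first pick is never second while a less correlated
  # feature with equal-or-better criterion exists
  r <- poe_ac_select(make_table(x, y), quota = 3)
  expect_equal(r$features[1], "dup")  # tie with `perfect`: earlier column wins
  expect_equal(r$features[2], "other")

  # 3-feature toy case enumerated by hand
  xa <- c(0, 0, 0, 1, 1, 1)
  xb <- c(0, 1, 0, 1, 0, 1)
  xc <- c(0, 0, 1, 1, 1, 0)
  ya <- c("u", "u", "u", "v", "v", "v")
  tab <- make_table(cbind(A = xa, B = xb, C = xc), ya)
  # POE: A separates perfectly (0); B errs 2/6; C errs 2/6
  # second pick: B -> 2/6 + |cor(B,A)| = 1/3 + 1/3 = 2/3
  #              C -> 2/6 + |cor(C,A)| = 1/3 + 1/3 = 2/3 -> tie, B earlier
  r3 <- poe_ac_select(tab, quota = 3)
  expect_equal(r3$features, c("A", "B", "C"))
  expect_equal(r3$scores[1], 0)
  expect_equal(r3$scores[2], 1 / 3 + abs(cor(xb, xa)), tolerance = 1e-12)
})

test_that("mutual information: exact identities and independence", {
  # feature equal to the class index of 5 balanced classes: MI = log2(5)
  y <- rep(0:4, each = 20)
  x <- cbind(ident = as.numeric(y), junk = rep(c(0, 1), 50))
  r <- mi_scores(make_table(x, y), n_bins = 5)
  expect_equal(unname(r$scores[r$features == "ident"]), log2(5), tolerance = 1e-12)

  # permuted labels at n = 10000: MI below 0.01 bits
  set.seed(4)
  y2 <- sample(rep(0:4, each = 2000))
  x2 <- cbind(f = rnorm(10000))
  r2 <- mi_scores(make_table(cbind(x2, g = rnorm(10000)), y2))
  expect_lt(max(r2$scores), 0.01)

  # 2x2 joint-count toy table evaluated by hand:
  # counts (a=0,b=0)=4, (0,1)=1, (1,0)=1, (1,1)=4
  a <- c(rep(0, 5), rep(1, 5))
  b <- c(rep(0, 4), 1, 0, rep(1, 4))
  mi_hand <- 0
  for (va in 0:1) for (vb in 0:1) {
    pj <- mean(a == va & b == vb)
    mi_hand <- mi_hand + pj * log2(pj / (mean(a == va) * mean(b == vb)))
  }
  r3 <- mi_scores(make_table(cbind(f = a), b), n_bins = 2)
  expect_equal(unname(r3$scores[1]), mi_hand, tolerance = 1e-12)
})

test_that("pre-optimization returns exactly 3 x quota distinct features", {
  set.seed(5)
  n <- 60
  y <- rep(0:4, each = n / 5)
  x <- matrix(rnorm(n * 250), n, 250)
  # make some features informative so rankings differ
  for (j in 1:30) x[, j] <- x[, j] + y * (0.2 + j / 30)
  colnames(x) <- sprintf("feat_%03d", 1:250)
  r <- pre_optimize(make_table(x, y))
  expect_length(r$features, 30L)
  expect_length(unique(r$features), 30L)
  expect_true(all(r$features %in% colnames(x)))

  # all-identical features cannot fill three quotas
  dup <- matrix(rep(rnorm(n), 30), n, 30)
  colnames(dup) <- sprintf("d%02d", 1:30)
  expect_error(pre_optimize(make_table(dup, y), quota_per_method = 10),
               "distinct")
})

test_that("scores are invariant to affine feature rescaling", {
  set.seed(6)
  y <- rep(0:2, each = 30)
  x <- matrix(rnorm(90 * 4), 90, 4)
  x[, 1] <- x[, 1] + y
  colnames(x) <- paste0("f", 1:4)
  x2 <- sweep(sweep(x, 2, c(3, 0.5, 10, 2), "*"), 2, c(1, -5, 0, 100), "+")
  colnames(x2) <- colnames(x)
  f1 <- fisher_scores(make_table(x, y));  f2 <- fisher_scores(make_table(x2, y))
  expect_equal(f1$scores, f2$scores, tolerance = 1e-9)
  expect_equal(f1$features, f2$features)
  m1 <- mi_scores(make_table(x, y)); m2 <- mi_scores(make_table(x2, y))
  expect_equal(m1$scores, m2$scores, tolerance = 1e-12)
  c1 <- cfs_select(make_table(x, y)); c2 <- cfs_select(make_table(x2, y))
  expect_equal(c1$features, c2$features)
  expect_equal(c1$scores, c2$scores, tolerance = 1e-12)
})

test_that("symmetric uncertainty of a variable with itself is 1", {
  set.seed(7)
  x <- sample(1:5, 200, replace = TRUE)
  expect_equal(fundustex:::symmetric_uncertainty(x, x), 1)
  expect_equal(fundustex:::symmetric_uncertainty(rep(1, 50), rep(2, 50)), 0)
})

test_that("CFS recovers planted informative features among noise", {
  set.seed(8)
  n <- 500
  y <- rep(0:4, each = n / 5)
  info <- vapply(1:5, function(j) y * 2 + rnorm(n), numeric(n))  # shift = 2 SD
  noise <- matrix(rnorm(n * 45), n, 45)
  x <- cbind(info, noise)
  colnames(x) <- c(sprintf("info_%d", 1:5), sprintf("noise_%02d", 1:45))
  sel <- cfs_select(make_table(x, y))
  expect_gte(sum(grepl("^info_", sel$features)), 4L)
})

test_that("best-first CFS equals exhaustive search on small tables", {
  set.seed(9)
  for (rep in 1:3) {
    n <- 120
    y <- rep(0:2, each = n / 3)
    x <- matrix(rnorm(n * 7), n, 7)
    x[, 1] <- x[, 1] + y * 1.5
    x[, 2] <- x[, 2] + y * 0.8
    x[, 3] <- x[, 1] + rnorm(n, sd = 0.2)  # redundant with 1
    colnames(x) <- paste0("f", 1:7)
    sel <- cfs_select(make_table(x, y))
    disc <- apply(x, 2, fundustex:::discretize_ef, n_bins = 10L)
    want <- oracle_cfs_exhaustive(disc, y)
    expect_equal(sort(match(sel$features, colnames(x))), want)
  }
})
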