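# Cross-validation harness and the metric panel.

test_that("stratified folds are balanced, exhaustive, and seed-driven", {
  y <- rep(letters[1:5], each = 150)
  f <- stratified_kfold(y, k = 10, rng_seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  # 150 per class / 10 folds = 15 of each class in every fold
  for (k in 1:10) expect_true(all(table(y[f == k]) == 15))
  expect_length(f, length(y))

  expect_identical(stratified_kfold(y, 10, rng_seed = 7),
                   stratified_kfold(y, 10, rng_seed = 7))
  others <- vapply(1:10, function(s)
    identical(stratified_kfold(y, 10, rng_seed = 1000 + s),
              stratified_kfold(y, 10, rng_seed = 1)), logical(1))
  expect_false(any(others))

  expect_error(stratified_kfold(rep(c("a", "b"), c(5, 50)), k = 10),
               "fewer than k")
})

test_that("a perfect diagonal confusion matrix gives kappa 1, FP 0, OA 100", {
  cm <- diag(c(30, 40, 30))
  m <- metrics_from_confusion(cm)
  expect_equal(m$kappa, 1)
  expect_equal(m$fp_rate, 0)
  expect_equal(m$overall_accuracy, 100)
  expect_equal(m$tp_rate, 1)
})

test_that("kappa is invariant to class relabeling and OA is the prevalence-weighted mean", {
  set.seed(10)
  cm <- matrix(rpois(16, 20), 4, 4) + diag(4) * 50
  m <- metrics_from_confusion(cm)
  perm <- c(3, 1, 4, 2)
  m2 <- metrics_from_confusion(cm[perm, perm])
  expect_equal(m$kappa, m2$kappa)
  w <- rowSums(cm) / sum(cm)
  expect_equal(m$overall_accuracy, sum(w * m$per_class_accuracy))
})

test_that("probability-based metrics behave at the extremes", {
  truth <- rep(c("a", "b"), each = 10)
  probs <- cbind(a = c(rep(1, 10), rep(0, 10)), b = c(rep(0, 10), rep(1, 10)))
  cm <- confusion_matrix(truth, truth)
  m <- metrics_from_confusion(cm, probs = probs, truth = truth)
  expect_equal(m$roc_area, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$rmse, 0)
})

test_that("cross-validation: separable data scores 100%, permuted labels score chance", {
  set.seed(11)
  n <- 100
  y <- rep(c("neg", "pos"), each = n / 2)
  x <- cbind(f1 = rnorm(n) + 10 * (y == "pos"), f2 = rnorm(n))
  tab <- data.frame(x, class_label = y)
  m <- crossvalidate(tab, "logistic", k = 10, rng_seed = 1)
  expect_equal(m$overall_accuracy, 100)

  # 5 balanced classes with permuted labels: OA within 3 SD of 20%
  set.seed(12)
  n2 <- 500
  y2 <- sample(rep(0:4, each = n2 / 5))
  x2 <- matrix(rnorm(n2 * 3), n2, 3, dimnames = list(NULL, paste0("f", 1:3)))
  tab2 <- data.frame(x2, class_label = y2)
  m2 <- crossvalidate(tab2, "centroid", k = 10, rng_seed = 2)
  sd3 <- 3 * sqrt(0.2 * 0.8 / n2) * 100
  expect_lt(abs(m2$overall_accuracy - 20), sd3 + 1e-9)
  expect_lt(abs(m2$kappa), 0.1)

  # determinism with a fixed seed and deterministic adapter
  ma <- crossvalidate(tab, "centroid", k = 5, rng_seed = 3)
  mb <- crossvalidate(tab, "centroid", k = 5, rng_seed = 3)
  expect_equal(ma$confusion, mb$confusion)
  expect_equal(ma$overall_accuracy, mb$overall_accuracy)
})

test_that("pooled confusion total equals the sample count", {
  set.seed(13)
  y <- rep(0:2, each = 30)
  x <- matrix(rnorm(90 * 2), 90, 2, dimnames = list(NULL, c("a", "b")))
  m <- crossvalidate(data.frame(x, class_label = y), "centroid", k = 3,
                     rng_seed = 1)
  expect_equal(sum(m$confusion), 90)
})
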