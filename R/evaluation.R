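# Stratified cross-validation harness and the metric panel: Cohen's kappa,
# prevalence-weighted TP/FP rates, one-vs-rest ROC area, MAE, RMSE, and
# overall accuracy, all derived from a pooled confusion matrix.

#' Stratified k-fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' into k folds, so per-fold class counts differ from exact
#' proportionality by at most one. Deterministic for a fixed seed.
#'
#' @param labels vector of class labels.
#' @param k number of folds.
#' @param rng_seed integer seed.
#' @return integer vector of fold ids (1..k), one per sample.
#' @export
stratified_kfold <- function(labels, k = 10L, rng_seed = 1L) {
  y <- factor(labels)
  k <- as.integer(k)
  stopifnot(k >= 2L)
  small <- table(y) < k
  if (any(small)) {
    stop("class(es) ", paste(names(which(small)), collapse = ", "),
         " have fewer than k = ", k,
         " members; reduce k or merge/augment the class", call. = FALSE)
  }
  folds <- integer(length(y))
  with_seed(rng_seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Build a confusion matrix
#'
#' @param truth true class labels.
#' @param predicted predicted class labels (same level set).
#' @return `confusion_matrix`: counts with rows = true class, columns =
#'   predicted class.
#' @export
confusion_matrix <- function(truth, predicted) {
  lev <- levels(factor(c(as.character(truth), as.character(predicted))))
  cm <- table(factor(truth, levels = lev), factor(predicted, levels = lev))
  structure(unclass(cm), class = "confusion_matrix")
}

#' Metric panel from a confusion matrix
#'
#' Computes overall accuracy (percent), per-class accuracy, Cohen's kappa,
#' prevalence-weighted true- and false-positive rates, and - when
#' per-sample class probabilities are supplied - the prevalence-weighted
#' one-vs-rest ROC area, MAE and RMSE (mean absolute / root-mean-square
#' difference between probability vectors and 0/1 class indicators).
#'
#' `row_totals` supports tables whose printed rows under-sum their stated
#' class sizes: per-class accuracies and overall accuracy then use the
#' stated totals as denominators while kappa and the rates use the matrix
#' counts as given.
#'
#' @param cm `confusion_matrix` or a plain counts matrix (rows = truth).
#' @param probs optional numeric matrix (samples x classes) of predicted
#'   probabilities, with one row per prediction.
#' @param truth optional vector of true labels aligned with `probs`.
#' @param row_totals optional stated per-class totals overriding the row
#'   sums as accuracy denominators.
#' @return object of class `metrics_report` (a named list).
#' @export
metrics_from_confusion <- function(cm, probs = NULL, truth = NULL,
                                   row_totals = NULL) {
  cm <- as.matrix(unclass(cm))
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0), sum(cm) > 0)
  C <- nrow(cm)
  cls <- rownames(cm)
  if (is.null(cls)) cls <- as.character(seq_len(C))
  rs <- rowSums(cm); cs <- colSums(cm); n <- sum(cm)
  denom <- if (is.null(row_totals)) rs else {
    stopifnot(length(row_totals) == C)
    as.numeric(row_totals)
  }
  per_class <- ifelse(denom > 0, 100 * diag(cm) / denom, NA_real_)
  names(per_class) <- cls
  oa <- 100 * sum(diag(cm)) / sum(denom)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rs * cs) / n^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 1
  w <- rs / n
  tp_rate <- sum(w * ifelse(rs > 0, diag(cm) / rs, 0))
  fp_c <- cs - diag(cm)
  fp_rate <- sum(w * ifelse(n - rs > 0, fp_c / (n - rs), 0))
  roc <- mae <- rmse <- NA_real_
  if (!is.null(probs)) {
    stopifnot(!is.null(truth), nrow(probs) == length(truth),
              ncol(probs) == C)
    y <- factor(truth, levels = cls)
    ind <- outer(as.integer(y), seq_len(C), function(a, b) as.numeric(a == b))
    diffs <- probs - ind
    mae <- mean(abs(diffs))
    rmse <- sqrt(mean(diffs^2))
    aucs <- vapply(seq_len(C), function(c0) {
      pos <- as.integer(y) == c0
      n1 <- sum(pos); n0 <- sum(!pos)
      if (n1 == 0 || n0 == 0) return(NA_real_)
      r <- rank(probs[, c0])
      (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    }, numeric(1))
    wr <- as.numeric(table(y)) / length(y)
    ok <- !is.na(aucs)
    roc <- sum(wr[ok] * aucs[ok]) / sum(wr[ok])
  }
  structure(list(confusion = cm, overall_accuracy = oa,
                 per_class_accuracy = per_class, kappa = kappa,
                 tp_rate = tp_rate, fp_rate = fp_rate, roc_area = roc,
                 mae = mae, rmse = rmse, n = n, elapsed = NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  overall accuracy: %.2f%%  kappa: %.4f\n",
              x$overall_accuracy, x$kappa))
  cat(sprintf("  weighted TP rate: %.3f  FP rate: %.3f\n",
              x$tp_rate, x$fp_rate))
  if (!is.na(x$roc_area)) {
    cat(sprintf("  ROC area: %.3f  MAE: %.4f  RMSE: %.4f\n",
                x$roc_area, x$mae, x$rmse))
  }
  cat("  per-class accuracy (%):\n")
  print(round(x$per_class_accuracy, 2))
  invisible(x)
}

#' Reference classifier adapters
#'
#' A classifier adapter is a list with `fit(x, y) -> model` and
#' `predict_prob(model, x) -> matrix` (samples x classes, columns in
#' `levels(y)` order). `classifier_adapter("logistic")` is the reference
#' multinomial (simple) logistic model, a ridge-stabilized fit;
#' `"centroid"` is a dependency-free nearest-class-centroid baseline with
#' softmax pseudo-probabilities.
#'
#' @param name `"logistic"` or `"centroid"`.
#' @return adapter list with elements `name`, `fit`, `predict_prob`.
#' @export
classifier_adapter <- function(name = c("logistic", "centroid")) {
  name <- match.arg(name)
  if (name == "logistic") {
    list(
      name = "logistic",
      fit = function(x, y) {
        y <- factor(y)
        # fit down a short ridge-to-light path; warm starts keep the small
        # final lambda numerically reachable
        fit <- suppressWarnings(
          glmnet::glmnet(as.matrix(x), y, family = "multinomial",
                         lambda = 10^seq(0, -3, length.out = 20L),
                         standardize = TRUE, maxit = 2e5))
        list(fit = fit, lambda = min(fit$lambda), levels = levels(y))
      },
      predict_prob = function(model, x) {
        p <- stats::predict(model$fit, as.matrix(x), type = "response",
                            s = model$lambda)
        p <- p[, , 1L]
        if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
        colnames(p) <- model$levels
        p
      }
    )
  } else {
    list(
      name = "centroid",
      fit = function(x, y) {
        y <- factor(y)
        x <- as.matrix(x)
        mu <- colMeans(x); sd <- apply(x, 2, stats::sd); sd[sd == 0] <- 1
        xs <- scale(x, mu, sd)
        centers <- t(vapply(levels(y), function(cl)
          colMeans(xs[y == cl, , drop = FALSE]), numeric(ncol(xs))))
        list(centers = centers, mu = mu, sd = sd, levels = levels(y))
      },
      predict_prob = function(model, x) {
        xs <- scale(as.matrix(x), model$mu, model$sd)
        d2 <- vapply(seq_len(nrow(model$centers)), function(k)
          rowSums(sweep(xs, 2, model$centers[k, ])^2), numeric(nrow(xs)))
        d2 <- matrix(d2, nrow = nrow(xs))
        ex <- exp(-(d2 - apply(d2, 1, min)))
        p <- ex / rowSums(ex)
        colnames(p) <- model$levels
        p
      }
    )
  }
}

#' Stratified k-fold cross-validation
#'
#' Fits the adapter on each training split and pools the out-of-fold
#' predictions into a single confusion matrix, from which the full metric
#' panel is computed. Deterministic given the seed and a deterministic
#' adapter.
#'
#' @param table feature data.frame with a `class_label` column.
#' @param classifier an adapter from [classifier_adapter()] (or a
#'   compatible list), or an adapter name.
#' @param k number of folds.
#' @param rng_seed integer seed for the fold assignment.
#' @return `metrics_report` with the pooled confusion matrix and elapsed
#'   seconds.
#' @export
crossvalidate <- function(table, classifier = "logistic", k = 10L,
                          rng_seed = 1L) {
  if (is.character(classifier)) classifier <- classifier_adapter(classifier)
  ft <- check_feature_table(table)
  t0 <- proc.time()[["elapsed"]]
  folds <- stratified_kfold(ft$y, k = k, rng_seed = rng_seed)
  n <- length(ft$y)
  lev <- levels(ft$y)
  probs <- matrix(NA_real_, n, length(lev))
  pred <- character(n)
  for (f in seq_len(k)) {
    test <- folds == f
    model <- tryCatch(
      classifier$fit(ft$x[!test, , drop = FALSE], ft$y[!test]),
      error = function(e) stop("classifier failed on fold ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    p <- classifier$predict_prob(model, ft$x[test, , drop = FALSE])
    probs[test, ] <- p[, lev, drop = FALSE]
    pred[test] <- lev[max.col(p[, lev, drop = FALSE], ties.method = "first")]
  }
  cm <- confusion_matrix(factor(ft$y, levels = lev),
                         factor(pred, levels = lev))
  rep <- metrics_from_confusion(cm, probs = probs, truth = ft$y)
  rep$elapsed <- proc.time()[["elapsed"]] - t0
  rep
}
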