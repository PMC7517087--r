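# Three-stage feature selection: Fisher discriminant ratio, probability of
# error plus average correlation (POE+AC), and mutual information rankings
# feed a pre-optimized pool; correlation-based feature selection (CFS) with
# symmetric uncertainty then picks the post-optimized subset.

# Validate a feature table: data.frame of numeric feature columns plus a
# class label column. Returns list(x = numeric matrix, y = factor).
check_feature_table <- function(table, label_col = "class_label") {
  stopifnot(is.data.frame(table))
  if (!label_col %in% names(table)) {
    stop("feature table lacks a `", label_col, "` column", call. = FALSE)
  }
  meta_cols <- intersect(c(label_col, "source_image", "roi_id"), names(table))
  feat_cols <- setdiff(names(table), meta_cols)
  if (anyDuplicated(feat_cols)) stop("duplicate feature names", call. = FALSE)
  x <- as.matrix(table[, feat_cols, drop = FALSE])
  if (!is.numeric(x)) stop("feature columns must be numeric", call. = FALSE)
  if (anyNA(x)) stop("feature table contains missing values", call. = FALSE)
  y <- factor(table[[label_col]])
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  list(x = x, y = y, features = feat_cols)
}

ranked <- function(names, scores, method) {
  structure(list(features = names, scores = scores, method = method),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, n = 10L, ...) {
  cat(sprintf("<ranked_features: %s, %d features>\n", x$method,
              length(x$features)))
  k <- min(n, length(x$features))
  df <- utils::head(data.frame(feature = x$features, score = x$scores), k)
  rownames(df) <- NULL
  print(df)
  invisible(x)
}

#' Fisher discriminant ratio ranking
#'
#' Multi-class Fisher score per feature: between-class over within-class
#' variance, F = sum_{i<j} p_i p_j (m_i - m_j)^2 / sum_i p_i v_i, with
#' class priors p, class means m and class variances v. Features with zero
#' within-class variance but separated means receive an infinite score and
#' rank first.
#'
#' @param table feature data.frame with a `class_label` column.
#' @return `ranked_features` (descending score order).
#' @export
fisher_scores <- function(table) {
  ft <- check_feature_table(table)
  cls <- levels(ft$y)
  if (any(table(ft$y) < 2L)) {
    stop("every class needs >= 2 samples to estimate a within-class variance",
         call. = FALSE)
  }
  prior <- as.numeric(table(ft$y)) / length(ft$y)
  mns <- matrix(vapply(cls, function(cl)
    colMeans(ft$x[ft$y == cl, , drop = FALSE]), numeric(ncol(ft$x))),
    ncol = length(cls))
  vrs <- matrix(vapply(cls, function(cl)
    apply(ft$x[ft$y == cl, , drop = FALSE], 2, stats::var),
    numeric(ncol(ft$x))), ncol = length(cls))
  between <- numeric(ncol(ft$x))
  for (i in seq_along(cls)) {
    for (j in seq_along(cls)) {
      if (i < j) between <- between +
          prior[i] * prior[j] * (mns[, i] - mns[, j])^2
    }
  }
  within <- as.numeric(vrs %*% prior)
  f <- ifelse(within > 0, between / within,
              ifelse(between > 0, Inf, 0))
  ord <- order(f, decreasing = TRUE)
  ranked(ft$features[ord], f[ord], "F")
}

# Resubstitution error of a per-feature nearest-class-mean classifier.
poe_single <- function(x, y) {
  mns <- vapply(levels(y), function(cl) mean(x[y == cl]), numeric(1))
  pred <- levels(y)[max.col(-abs(outer(x, mns, "-")), ties.method = "first")]
  mean(pred != as.character(y))
}

#' POE + average correlation sequential ranking
#'
#' The first feature minimizes the probability of error (POE) of a
#' per-feature nearest-class-mean classifier; each subsequent feature
#' minimizes POE(f) + mean |Pearson correlation| with the features already
#' selected. Correlations involving a constant feature are taken as 0.
#' Ties go to the earlier column.
#'
#' @param table feature data.frame with a `class_label` column.
#' @param quota number of features to select.
#' @return `ranked_features` in selection order; scores are the minimized
#'   criterion values.
#' @export
poe_ac_select <- function(table, quota = 10L) {
  ft <- check_feature_table(table)
  p <- ncol(ft$x)
  quota <- as.integer(quota)
  if (quota > p) stop("quota exceeds the number of features", call. = FALSE)
  poe <- apply(ft$x, 2, poe_single, y = ft$y)
  sds <- apply(ft$x, 2, stats::sd)
  cmat <- suppressWarnings(abs(stats::cor(ft$x)))
  cmat[!is.finite(cmat)] <- 0  # constant features: correlation := 0
  selected <- integer(0)
  crit <- numeric(0)
  for (k in seq_len(quota)) {
    cand <- setdiff(seq_len(p), selected)
    score <- if (k == 1L) poe[cand] else
      poe[cand] + colMeans(cmat[selected, cand, drop = FALSE])
    best <- cand[which.min(score)]
    selected <- c(selected, best)
    crit <- c(crit, min(score))
  }
  ranked(ft$features[selected], crit, "POE+AC")
}

# Equal-frequency discretization into at most n_bins levels (rank-based,
# so invariant to monotone rescaling).
discretize_ef <- function(x, n_bins = 10L) {
  qs <- unique(stats::quantile(x, probs = seq_len(n_bins - 1L) / n_bins,
                               type = 7))
  findInterval(x, qs, left.open = TRUE) + 1L
}

entropy_bits <- function(v) {
  p <- as.numeric(table(v)) / length(v)
  -sum(plogp2(p))
}

mi_bits <- function(a, b) {
  joint <- as.numeric(table(a, b)) / length(a)
  entropy_bits(a) + entropy_bits(b) + sum(plogp2(joint))
}

#' Mutual information ranking
#'
#' Each feature is discretized by equal-frequency binning, then scored by
#' its mutual information with the class label (log base 2, bits).
#'
#' @param table feature data.frame with a `class_label` column.
#' @param n_bins discretization bins (>= 2).
#' @return `ranked_features` (descending MI).
#' @export
mi_scores <- function(table, n_bins = 10L) {
  ft <- check_feature_table(table)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  mi <- apply(ft$x, 2, function(col) mi_bits(discretize_ef(col, n_bins), ft$y))
  ord <- order(mi, decreasing = TRUE)
  ranked(ft$features[ord], mi[ord], "MI")
}

#' Pre-optimization: pooled Fisher / POE+AC / MI selection
#'
#' Takes the top `quota_per_method` features from each of the Fisher,
#' POE+AC, and mutual-information rankings. A feature already contributed
#' by an earlier method is replaced by the contributing method's next-best
#' unused feature, so the pool always contains exactly
#' `3 * quota_per_method` distinct features (default 30).
#'
#' @param table feature data.frame with a `class_label` column.
#' @param quota_per_method features contributed per method.
#' @param n_bins bins for the MI discretization.
#' @return `ranked_features` with method tag `"pre-optimized"`; scores are
#'   NA (ranks are method-specific and not comparable across methods).
#' @export
pre_optimize <- function(table, quota_per_method = 10L, n_bins = 10L) {
  ft <- check_feature_table(table)
  quota <- as.integer(quota_per_method)
  if (ncol(ft$x) < 3L * quota) {
    stop("need at least ", 3L * quota, " features for quota ", quota,
         call. = FALSE)
  }
  n_distinct <- sum(!duplicated(ft$x, MARGIN = 2))
  if (n_distinct < 3L * quota) {
    stop("only ", n_distinct, " distinct feature columns; cannot return ",
         3L * quota, " distinct features", call. = FALSE)
  }
  orders <- list(
    F = fisher_scores(table)$features,
    `POE+AC` = poe_ac_select(table, quota = ncol(ft$x))$features,
    MI = mi_scores(table, n_bins = n_bins)$features
  )
  chosen <- character(0)
  for (method in names(orders)) {
    pool <- setdiff(orders[[method]], chosen)
    if (length(pool) < quota) {
      stop("not enough distinct features to fill the ", method,
           " quota (duplicated or constant features dominate)", call. = FALSE)
    }
    chosen <- c(chosen, pool[seq_len(quota)])
  }
  ranked(chosen, rep(NA_real_, length(chosen)), "pre-optimized")
}

# Symmetric uncertainty between two discrete vectors:
# SU = 2 * (H(A) + H(B) - H(A,B)) / (H(A) + H(B)); 0 when both entropies
# vanish.
symmetric_uncertainty <- function(a, b) {
  ha <- entropy_bits(a); hb <- entropy_bits(b)
  if (ha + hb == 0) return(0)
  joint <- as.numeric(table(a, b)) / length(a)
  hab <- -sum(plogp2(joint))
  2 * (ha + hb - hab) / (ha + hb)
}

cfs_merit <- function(subset, su_class, su_ff) {
  k <- length(subset)
  rcf <- mean(su_class[subset])
  rff <- if (k > 1L) mean(su_ff[subset, subset][upper.tri(diag(k))]) else 0
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Correlation-based feature selection (CFS)
#'
#' Features are discretized by equal-frequency binning; symmetric
#' uncertainty (SU) measures feature-class relevance and feature-feature
#' redundancy. A best-first forward search maximizes the merit
#' k * mean(SU_fc) / sqrt(k + k (k-1) mean(SU_ff)), stopping after
#' `max_stale` consecutive expansions without improvement. The selected
#' subset is returned ordered by feature-class SU.
#'
#' @param table feature data.frame with a `class_label` column.
#' @param n_bins discretization bins.
#' @param max_stale non-improving expansions tolerated by the search.
#' @return `ranked_features` with method tag `"CFS"`; scores are the
#'   feature-class SU values.
#' @export
cfs_select <- function(table, n_bins = 10L, max_stale = 5L) {
  ft <- check_feature_table(table)
  p <- ncol(ft$x)
  if (p < 2L) stop("CFS needs at least 2 features", call. = FALSE)
  disc <- apply(ft$x, 2, discretize_ef, n_bins = n_bins)
  su_class <- apply(disc, 2, symmetric_uncertainty, b = ft$y)
  su_ff <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      su_ff[i, j] <- su_ff[j, i] <- symmetric_uncertainty(disc[, i], disc[, j])
    }
  }
  # best-first forward search over subsets
  key <- function(s) paste(sort(s), collapse = ",")
  open <- list(integer(0))
  open_merit <- c(0)
  visited <- new.env(hash = TRUE)
  best_subset <- integer(0); best_merit <- 0
  stale <- 0L
  while (length(open) > 0L && stale < max_stale) {
    i_best <- which.max(open_merit)
    node <- open[[i_best]]
    open <- open[-i_best]; open_merit <- open_merit[-i_best]
    improved <- FALSE
    for (f in setdiff(seq_len(p), node)) {
      child <- c(node, f)
      k <- key(child)
      if (!is.null(visited[[k]])) next
      visited[[k]] <- TRUE
      m <- cfs_merit(child, su_class, su_ff)
      open <- c(open, list(child)); open_merit <- c(open_merit, m)
      if (m > best_merit + 1e-12) {
        best_merit <- m; best_subset <- child; improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  ord <- best_subset[order(su_class[best_subset], decreasing = TRUE)]
  ranked(ft$features[ord], su_class[ord], "CFS")
}
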