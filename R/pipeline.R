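# End-to-end orchestration: preprocess -> region of interest -> hybrid
# feature extraction -> pre-optimization -> CFS -> cross-validated
# classification, with tabular I/O and a run manifest.

#' Pipeline configuration
#'
#' Validated bag of parameters for [run_pipeline()]. Defaults mirror the
#' package-wide defaults of the individual stages. `roi_mode`
#' "full_image" (default) uses one whole-raster ROI per image;
#' "cargs" runs the clustering-based segmentation and keeps the
#' `rois_per_image` largest regions.
#'
#' @param sigma preprocessing Gaussian sigma (0 disables smoothing).
#' @param equalize apply histogram equalization.
#' @param roi_mode `"full_image"` or `"cargs"`.
#' @param rois_per_image regions kept per image in cargs mode.
#' @param cargs_k,cargs_tau,cargs_polygons CARGS parameters.
#' @param n_levels gray levels for the texture matrices.
#' @param wavelet_scale Haar decomposition level.
#' @param rlm_mode run-length block mode.
#' @param quota_per_method pre-optimization quota per ranking method.
#' @param folds cross-validation folds.
#' @param classifier adapter name (`"logistic"` or `"centroid"`).
#' @param rng_seed master seed for every stochastic stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sigma = 1, equalize = TRUE,
                            roi_mode = c("full_image", "cargs"),
                            rois_per_image = 3L,
                            cargs_k = 8L, cargs_tau = 10, cargs_polygons = 2L,
                            n_levels = 64L, wavelet_scale = 4L,
                            rlm_mode = c("averaged", "per_direction"),
                            quota_per_method = 10L, folds = 10L,
                            classifier = "logistic", rng_seed = 1L) {
  roi_mode <- match.arg(roi_mode)
  rlm_mode <- match.arg(rlm_mode)
  if (!classifier %in% c("logistic", "centroid")) {
    stop("unknown classifier: ", classifier,
         " (available: logistic, centroid)", call. = FALSE)
  }
  stopifnot(sigma >= 0, n_levels >= 2, n_levels <= 256, wavelet_scale >= 1,
            quota_per_method >= 1, folds >= 2, cargs_tau >= 0,
            cargs_k >= 1, rois_per_image >= 1)
  structure(list(sigma = sigma, equalize = isTRUE(equalize),
                 roi_mode = roi_mode, rois_per_image = as.integer(rois_per_image),
                 cargs_k = as.integer(cargs_k), cargs_tau = cargs_tau,
                 cargs_polygons = as.integer(cargs_polygons),
                 n_levels = as.integer(n_levels),
                 wavelet_scale = as.integer(wavelet_scale),
                 rlm_mode = rlm_mode,
                 quota_per_method = as.integer(quota_per_method),
                 folds = as.integer(folds), classifier = classifier,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Extract a labeled feature table from a set of images
#'
#' Applies preprocessing and the configured ROI policy to every image and
#' extracts the hybrid feature vector per ROI.
#'
#' @param images list of gray image matrices.
#' @param labels class label per image.
#' @param config a [pipeline_config()].
#' @param image_ids optional image identifiers (defaults to `img_<i>`).
#' @return data.frame: one row per ROI; feature columns then
#'   `class_label`, `source_image`, `roi_id`.
#' @export
extract_feature_table <- function(images, labels, config = pipeline_config(),
                                  image_ids = NULL) {
  stopifnot(length(images) == length(labels), length(images) >= 1L)
  if (is.null(image_ids)) image_ids <- sprintf("img_%04d", seq_along(images))
  rows <- list()
  for (i in seq_along(images)) {
    img <- preprocess(images[[i]], sigma = config$sigma,
                      equalize_first = config$equalize)
    masks <- if (config$roi_mode == "full_image") {
      list(NULL)
    } else {
      regs <- segment_cargs(img, K = config$cargs_k, tau = config$cargs_tau,
                            n_polygons = config$cargs_polygons,
                            rng_seed = derive_seed(config$rng_seed, i))
      sizes <- vapply(regs, sum, numeric(1))
      regs[order(sizes, decreasing = TRUE)][
        seq_len(min(config$rois_per_image, length(regs)))]
    }
    for (r in seq_along(masks)) {
      fv <- extract_hybrid(img, masks[[r]], n_levels = config$n_levels,
                           wavelet_scale = config$wavelet_scale,
                           rlm_mode = config$rlm_mode)
      rows[[length(rows) + 1L]] <- c(as.list(fv),
                                     list(class_label = labels[[i]],
                                          source_image = image_ids[[i]],
                                          roi_id = r))
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' Run the full pipeline on a labeled image set
#'
#' Steps: preprocess -> ROI -> hybrid feature extraction -> pre-optimization
#' (Fisher, POE+AC, MI) -> CFS -> stratified k-fold cross-validation with
#' the configured classifier adapter. When `out_dir` is given, the feature
#' table (CSV), selection report (JSON), confusion matrix (CSV), metrics
#' (JSON), and a run manifest are persisted.
#'
#' @param images list of gray image matrices, or a directory containing
#'   image files plus a `labels.csv` with columns `file`, `class_label`.
#' @param labels class labels (ignored when `images` is a directory).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for artifacts.
#' @return list with `feature_table`, `pre_optimized`, `selected`
#'   (`ranked_features`), `metrics` (`metrics_report`), and `config`.
#' @export
run_pipeline <- function(images, labels = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(images) && length(images) == 1L && dir.exists(images)) {
    manifest <- file.path(images, "labels.csv")
    if (!file.exists(manifest)) {
      stop("image directory needs a labels.csv (columns: file, class_label)",
           call. = FALSE)
    }
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("file", "class_label") %in% names(tab)))
    labels <- tab$class_label
    images <- lapply(file.path(dirname(manifest), tab$file), load_image)
  }
  table <- extract_feature_table(images, labels, config)
  pre <- pre_optimize(table, quota_per_method = config$quota_per_method)
  sub <- table[, c(pre$features, "class_label"), drop = FALSE]
  sel <- cfs_select(sub)
  if (length(sel$features) == 0L) {
    stop("CFS selected no features; data may be degenerate", call. = FALSE)
  }
  final <- table[, c(sel$features, "class_label"), drop = FALSE]
  metrics <- crossvalidate(final, classifier = config$classifier,
                           k = config$folds, rng_seed = config$rng_seed)
  result <- list(feature_table = table, pre_optimized = pre, selected = sel,
                 metrics = metrics, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(table, file.path(out_dir, "features.csv"))
    jsonlite::write_json(
      list(pre_optimized = pre$features,
           selected = sel$features, su_class = sel$scores),
      file.path(out_dir, "selection.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(metrics$confusion),
                     file.path(out_dir, "confusion.csv"))
    jsonlite::write_json(
      list(overall_accuracy = metrics$overall_accuracy,
           per_class_accuracy = as.list(metrics$per_class_accuracy),
           kappa = metrics$kappa, tp_rate = metrics$tp_rate,
           fp_rate = metrics$fp_rate, roc_area = metrics$roc_area,
           mae = metrics$mae, rmse = metrics$rmse,
           elapsed = metrics$elapsed),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(config = unclass(config),
                              n_images = length(images),
                              n_rois = nrow(table),
                              timestamp = format(Sys.time(), tz = "UTC")),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' Write a feature table to CSV
#'
#' Values are serialized with 15 significant digits so a write/read
#' round-trip is lossless at that precision. Tables with duplicate column
#' names are refused.
#'
#' @param table feature data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (anyDuplicated(names(table))) {
    stop("refusing to write a table with duplicate feature names",
         call. = FALSE)
  }
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) format(v, digits = 15,
                                                  trim = TRUE,
                                                  scientific = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' @param path CSV path (as written by [write_feature_table()]).
#' @return data.frame with numeric feature columns and `class_label`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- intersect(c("class_label", "source_image", "roi_id"), names(tab))
  feat <- setdiff(names(tab), meta)
  for (cn in feat) {
    v <- tab[[cn]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("missing or non-numeric value at row %d, column '%s'",
                   bad[1], cn), call. = FALSE)
    }
    tab[[cn]] <- v
  }
  tab
}
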