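#' Preprocessing configuration
#'
#' Parameters for the per-view cleanup stage: dark-noise color thresholding,
#' axis-aligned cropping and statistical outlier removal.
#'
#' The dark-point rule is conjunctive: a point is dark iff all three channels
#' fall below `channel_threshold`. This targets the black/dark-gray edge noise
#' typical of stereo reconstructions while preserving saturated marker colors
#' (a disjunctive rule would delete a pure red (200, 10, 10) sphere).
#'
#' @param channel_threshold integer in 0..255; default 50
#' @param crop_min,crop_max length-3 numeric bounds in cm, or NULL for
#'   unbounded
#' @param outlier_k neighbor count for the outlier statistic; default 20
#' @param outlier_std_ratio admission band in global standard deviations;
#'   default 2
#' @return an object of class `preprocess_config`
#' @export
preprocess_config <- function(channel_threshold = 50L, crop_min = NULL,
                              crop_max = NULL, outlier_k = 20L,
                              outlier_std_ratio = 2.0) {
  channel_threshold <- as.integer(channel_threshold)
  if (is.na(channel_threshold) || channel_threshold < 0L ||
      channel_threshold > 255L)
    sricp_stop("channel_threshold must be in [0, 255]", "sricp_invalid")
  if (!is.null(crop_min)) crop_min <- as.numeric(crop_min)
  if (!is.null(crop_max)) crop_max <- as.numeric(crop_max)
  lo <- crop_min %||% rep(-Inf, 3)
  hi <- crop_max %||% rep(Inf, 3)
  if (length(lo) != 3L || length(hi) != 3L || any(lo > hi))
    sricp_stop("crop bounds must be 3-vectors with crop_min <= crop_max",
               "sricp_invalid")
  if (outlier_k < 1L || outlier_std_ratio <= 0)
    sricp_stop("outlier_k >= 1 and outlier_std_ratio > 0 required",
               "sricp_invalid")
  structure(list(channel_threshold = channel_threshold,
                 crop_min = crop_min, crop_max = crop_max,
                 outlier_k = as.integer(outlier_k),
                 outlier_std_ratio = outlier_std_ratio),
            class = "preprocess_config")
}

#' Remove dark noise points by RGB thresholding
#'
#' Keeps every point with at least one channel at or above the threshold; a
#' point is dark iff R, G and B are all strictly below it. Survivor order is
#' preserved. Idempotent.
#'
#' @param cloud a [point_cloud()]
#' @param config a [preprocess_config()] (or a bare threshold integer)
#' @return filtered [point_cloud()]
#' @export
color_filter <- function(cloud, config = preprocess_config()) {
  thr <- if (is.numeric(config)) as.integer(config) else config$channel_threshold
  if (n_points(cloud) == 0L) return(cloud)
  dark <- cloud$colors[, 1] < thr & cloud$colors[, 2] < thr &
    cloud$colors[, 3] < thr
  pc_subset(cloud, !dark)
}

#' Crop a cloud to an axis-aligned box
#'
#' @param cloud a [point_cloud()]
#' @param config a [preprocess_config()] carrying `crop_min`/`crop_max`
#' @return cropped [point_cloud()], point order preserved
#' @export
crop_box <- function(cloud, config) {
  lo <- config$crop_min %||% rep(-Inf, 3)
  hi <- config$crop_max %||% rep(Inf, 3)
  if (n_points(cloud) == 0L) return(cloud)
  keep <- cloud$points[, 1] >= lo[1] & cloud$points[, 1] <= hi[1] &
    cloud$points[, 2] >= lo[2] & cloud$points[, 2] <= hi[2] &
    cloud$points[, 3] >= lo[3] & cloud$points[, 3] <= hi[3]
  pc_subset(cloud, keep)
}

#' Statistical outlier removal
#'
#' For each point, the mean distance to its k nearest neighbors is computed;
#' points whose statistic exceeds `global mean + std_ratio * global sd` are
#' removed. Survivors keep their original order. This is the standard
#' statistical-outlier-removal contract (the k-NN statistic is computed once,
#' over the input cloud).
#'
#' @param cloud a [point_cloud()] with more than `outlier_k` points
#' @param config a [preprocess_config()]
#' @return filtered [point_cloud()]
#' @export
remove_outliers <- function(cloud, config = preprocess_config()) {
  k <- config$outlier_k
  n <- n_points(cloud)
  if (n <= k)
    sricp_stop(sprintf(
      "remove_outliers requires more points (%d) than outlier_k (%d)", n, k),
      "sricp_precondition")
  d <- cpp_knn_dists(cloud$points, k)
  m <- rowMeans(d)
  cutoff <- mean(m) + config$outlier_std_ratio * stats::sd(m)
  # tolerance so perfectly homogeneous clouds (sd = 0) survive float jitter
  pc_subset(cloud, m <= cutoff + 1e-12 * (1 + abs(cutoff)))
}
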