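# Morphological trait extraction from the merged plant model: plant height,
# crown width, and per-leaf length/width as linear distances between two
# actual cloud points. Leaf segmentation is an input (labels), not a
# computation.

#' Plant height above a reference plane
#'
#' Maximum z of the plant points minus `reference_z` (default: the pot-rim
#' plane found during scale calibration; the trait is reported in cm).
#'
#' @param plant a non-empty [point_cloud()]
#' @param reference_z reference plane height, cm
#' @return height, cm
#' @export
plant_height <- function(plant, reference_z = 0) {
  if (n_points(plant) == 0L)
    sricp_stop("plant cloud is empty", "sricp_precondition")
  max(plant$points[, 3]) - reference_z
}

#' Crown width
#'
#' Horizontal extent of the canopy. The default is the diameter of the XY
#' projection — the maximum pairwise horizontal distance, computed on the
#' convex hull (equal to the brute-force maximum over all pairs).
#' `method = "bbox_mean"` instead averages the two orthogonal bounding
#' extents.
#'
#' @param plant a [point_cloud()] with at least 2 points
#' @param method `"hull_diameter"` (default) or `"bbox_mean"`
#' @return crown width, cm
#' @export
crown_width <- function(plant, method = c("hull_diameter", "bbox_mean")) {
  method <- match.arg(method)
  n <- n_points(plant)
  if (n < 2L)
    sricp_stop("crown width needs at least 2 points", "sricp_precondition")
  xy <- plant$points[, 1:2, drop = FALSE]
  if (method == "bbox_mean")
    return(mean(apply(xy, 2L, function(v) diff(range(v)))))
  hull <- if (n > 3L) tryCatch(unique(grDevices::chull(xy)),
                               error = function(e) seq_len(n)) else seq_len(n)
  h <- xy[hull, , drop = FALSE]
  # hull vertex count is tiny; the O(h^2) scan is the rotating-calipers
  # diameter without the bookkeeping
  d2 <- outer(h[, 1], h[, 1], `-`)^2 + outer(h[, 2], h[, 2], `-`)^2
  sqrt(max(d2))
}

#' Leaf length and width along principal axes
#'
#' Principal axes of the leaf point set from the coordinate covariance
#' (ordered by explained variance); length is the euclidean distance between
#' the two actual cloud points with extreme projections on the first axis,
#' width likewise on the second axis, so each trait is literally a linear
#' distance between two measured points. For a curved leaf this chord
#' underestimates the arc length.
#'
#' @param leaf a pre-segmented single-leaf [point_cloud()] with at least 3
#'   non-collinear points
#' @return list with `length`, `width` (cm, length >= width) and `endpoints`
#'   (list of two 2 x 3 matrices for audit)
#' @export
leaf_axes <- function(leaf) {
  pts <- leaf$points
  if (nrow(pts) < 3L)
    sricp_stop("leaf needs at least 3 points", "sricp_precondition")
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2L, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * max(ev$values[1], 1e-300))
    sricp_stop("leaf points are collinear or coincident", "sricp_degenerate")
  axis_extent <- function(axis) {
    proj <- as.numeric(cc %*% axis)
    i <- which.min(proj); j <- which.max(proj)
    ends <- pts[c(i, j), , drop = FALSE]
    list(len = sqrt(sum((ends[1, ] - ends[2, ])^2)), ends = ends)
  }
  a1 <- axis_extent(ev$vectors[, 1])
  a2 <- axis_extent(ev$vectors[, 2])
  len <- a1$len; wid <- a2$len; e1 <- a1$ends; e2 <- a2$ends
  if (wid > len) {  # pathological shells only; keep length >= width
    tmp <- len; len <- wid; wid <- tmp
    tmp <- e1; e1 <- e2; e2 <- tmp
  }
  list(length = len, width = wid, endpoints = list(e1, e2))
}

#' Assemble a trait report
#'
#' @param plant the merged plant [point_cloud()] (labels identify organs)
#' @param leaf_labels integer labels of the leaves to measure (may be empty;
#'   leaf selection is manual/ground-truth, matching the workflow)
#' @param reference_z height datum, cm (pot-rim plane)
#' @return an object of class `trait_report`: `plant_height`, `crown_width`,
#'   `leaves` (data.frame leaf_id/length/width), `reference_plane_z`
#' @export
extract_traits <- function(plant, leaf_labels = integer(0), reference_z = 0) {
  if (n_points(plant) == 0L)
    sricp_stop("plant cloud is empty", "sricp_precondition")
  leaf_labels <- as.integer(leaf_labels)
  avail <- sort(unique(plant$labels))
  missing <- setdiff(leaf_labels, avail)
  if (length(missing) > 0L)
    sricp_stop(sprintf("leaf label(s) %s not present; available labels: %s",
                       paste(missing, collapse = ", "),
                       paste(avail, collapse = ", ")),
               "sricp_missing_label")
  leaves <- data.frame(leaf_id = integer(0), length = numeric(0),
                       width = numeric(0))
  for (lab in leaf_labels) {
    leaf <- pc_subset(plant, plant$labels == lab)
    if (n_points(leaf) < 3L)
      sricp_stop(sprintf("leaf label %d selects fewer than 3 points", lab),
                 "sricp_precondition")
    ax <- leaf_axes(leaf)
    leaves <- rbind(leaves, data.frame(leaf_id = lab, length = ax$length,
                                       width = ax$width))
  }
  structure(list(plant_height = plant_height(plant, reference_z),
                 crown_width = crown_width(plant),
                 leaves = leaves, reference_plane_z = reference_z),
            class = "trait_report")
}

#' @export
print.trait_report <- function(x, ...) {
  cat(sprintf("<trait_report: height %.3f cm, crown %.3f cm (datum z = %.3f)>\n",
              x$plant_height, x$crown_width, x$reference_plane_z))
  if (nrow(x$leaves) > 0L)
    for (i in seq_len(nrow(x$leaves)))
      cat(sprintf("  leaf %d: length %.3f cm, width %.3f cm\n",
                  x$leaves$leaf_id[i], x$leaves$length[i], x$leaves$width[i]))
  invisible(x)
}

#' Write a trait report as delimited text
#'
#' One row per leaf (or a single row when no leaves were measured), columns
#' `plant_height_cm, crown_width_cm, leaf_id, leaf_length_cm, leaf_width_cm`.
#'
#' @param report a `trait_report`
#' @param path output path (tab-separated)
#' @return `path`, invisibly
#' @export
write_trait_report <- function(report, path) {
  lv <- report$leaves
  if (nrow(lv) == 0L)
    lv <- data.frame(leaf_id = NA_integer_, length = NA_real_,
                     width = NA_real_)
  df <- data.frame(plant_height_cm = report$plant_height,
                   crown_width_cm = report$crown_width,
                   leaf_id = lv$leaf_id, leaf_length_cm = lv$length,
                   leaf_width_cm = lv$width)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
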