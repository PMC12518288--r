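#' Colored point cloud
#'
#' The universal currency of the pipeline: `N` points with XYZ coordinates in
#' centimetres (z-up, pot base near z = 0), per-point RGB color in 0..255 and
#' optional integer labels (marker/organ identity; -1 = unlabeled).
#'
#' @param points numeric N x 3 matrix (or coercible) of coordinates, cm
#' @param colors integer N x 3 matrix of RGB values in 0..255; a single color
#'   may be given as a length-3 vector and is recycled; default white
#' @param labels optional integer vector of length N; default all -1
#' @return an object of class `point_cloud`
#' @export
#' @examples
#' pc <- point_cloud(matrix(rnorm(30), 10, 3))
#' n_points(pc)
point_cloud <- function(points, colors = NULL, labels = NULL) {
  points <- as.matrix(points)
  if (length(points) == 0L) points <- matrix(numeric(0), 0L, 3L)
  if (ncol(points) != 3L)
    sricp_stop("`points` must have 3 columns (x, y, z)", "sricp_invalid")
  storage.mode(points) <- "double"
  if (!all(is.finite(points)))
    sricp_stop("all coordinates must be finite", "sricp_invalid")
  n <- nrow(points)
  if (is.null(colors)) colors <- matrix(255L, n, 3L)
  if (is.vector(colors) && length(colors) == 3L)
    colors <- matrix(rep(as.integer(colors), each = n), n, 3L)
  colors <- as.matrix(colors)
  if (n == 0L) colors <- matrix(integer(0), 0L, 3L)
  storage.mode(colors) <- "integer"
  if (nrow(colors) != n || ncol(colors) != 3L)
    sricp_stop("`colors` must be an N x 3 matrix matching `points`",
               "sricp_invalid")
  if (n > 0L && (anyNA(colors) || min(colors) < 0L || max(colors) > 255L))
    sricp_stop("color channels must be integers in [0, 255]", "sricp_invalid")
  if (is.null(labels)) labels <- rep.int(-1L, n)
  labels <- as.integer(labels)
  if (length(labels) != n)
    sricp_stop("`labels` must have one entry per point", "sricp_invalid")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  dimnames(colors) <- list(NULL, c("red", "green", "blue"))
  structure(list(points = points, colors = colors, labels = labels),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`
#' @return integer count
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' @export
print.point_cloud <- function(x, ...) {
  n <- n_points(x)
  cat(sprintf("<point_cloud: %d points>\n", n))
  if (n > 0L) {
    bb <- apply(x$points, 2L, range)
    cat(sprintf("  bbox x[%.3g, %.3g] y[%.3g, %.3g] z[%.3g, %.3g] cm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
    labs <- unique(x$labels)
    if (!identical(labs, -1L))
      cat("  labels:", paste(sort(labs), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a point cloud by point index
#'
#' Preserves point order for logical or increasing integer indices; colors and
#' labels travel with their points.
#'
#' @param cloud a `point_cloud`
#' @param idx logical or integer index vector
#' @return a `point_cloud`
#' @export
pc_subset <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              cloud$colors[idx, , drop = FALSE],
              cloud$labels[idx])
}

#' Concatenate point clouds
#' @param ... `point_cloud` objects
#' @return a single `point_cloud` with points stacked in argument order
#' @export
concat_clouds <- function(...) {
  cls <- list(...)
  if (length(cls) == 1L && is.list(cls[[1]]) && !inherits(cls[[1]], "point_cloud"))
    cls <- cls[[1]]
  point_cloud(do.call(rbind, lapply(cls, `[[`, "points")),
              do.call(rbind, lapply(cls, `[[`, "colors")),
              unlist(lapply(cls, `[[`, "labels")))
}

#' Rigid transform (rotation + translation)
#'
#' A proper rigid motion: `p -> R p + t`. Construction rejects any rotation
#' matrix failing orthonormality (`||R'R - I|| <= 1e-9`) or the proper-rotation
#' determinant check (`|det(R) - 1| <= 1e-9`), so reflections never enter the
#' registration chain.
#'
#' @param rotation 3 x 3 rotation matrix
#' @param translation length-3 numeric vector, cm
#' @return an object of class `rigid_transform`
#' @export
#' @examples
#' rigid_transform(diag(3), c(0, 0, 0))
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!identical(dim(rotation), c(3L, 3L)) || length(translation) != 3L)
    sricp_stop("rotation must be 3x3 and translation length 3", "sricp_invalid")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    sricp_stop("rotation is not orthonormal within 1e-9", "sricp_invalid")
  if (abs(det(rotation) - 1) > 1e-9)
    sricp_stop("rotation must be proper (det = +1 within 1e-9)",
               "sricp_invalid")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x)
  cat(sprintf("<rigid_transform: angle %.4g deg, t = (%.4g, %.4g, %.4g) cm>\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points or a cloud
#'
#' @param x a `point_cloud` or an N x 3 coordinate matrix
#' @param tf a `rigid_transform`
#' @return object of the same kind as `x`, transformed
#' @export
apply_transform <- function(x, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  if (inherits(x, "point_cloud")) {
    out <- x
    out$points <- apply_transform(x$points, tf)
    return(out)
  }
  m <- as.matrix(x)
  sweep(m %*% t(tf$rotation), 2L, tf$translation, `+`)
}

#' Compose rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first and then `a` (matrix convention: `A %*% B`).
#'
#' @param a,b `rigid_transform` objects
#' @return a `rigid_transform`
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param tf a `rigid_transform`
#' @return the inverse `rigid_transform`
#' @export
invert_transform <- function(tf) {
  rt <- t(tf$rotation)
  rigid_transform(rt, -as.numeric(rt %*% tf$translation))
}

#' Rotation about the z axis
#' @param angle_deg rotation angle in degrees (counter-clockwise looking down)
#' @param translation optional translation, default zero
#' @return a `rigid_transform`
#' @export
rotation_z <- function(angle_deg, translation = c(0, 0, 0)) {
  a <- angle_deg * pi / 180
  rigid_transform(matrix(c(cos(a), sin(a), 0,
                           -sin(a), cos(a), 0,
                           0, 0, 1), 3L, 3L),
                  translation)
}

#' Angle of a rigid transform's rotation, in degrees
#' @param tf a `rigid_transform`
#' @return rotation angle in [0, 180] degrees
#' @export
rotation_angle_deg <- function(tf) {
  tr <- sum(diag(tf$rotation))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

#' Angular difference between two rigid transforms, degrees
#' @param a,b `rigid_transform` objects
#' @return rotation angle of `a b^-1` in degrees
#' @export
transform_rotation_error_deg <- function(a, b) {
  rotation_angle_deg(compose_transforms(a, invert_transform(b)))
}

#' Fitted calibration-sphere model
#'
#' Output of the enhanced RANSAC sphere fit: center and radius in cm, the
#' inlier index set, the consensus weight `w = (|inliers|/|P|) / (mu + sigma +
#' eps)` and the inlier residual statistics mu, sigma (cm).
#'
#' @param center length-3 numeric, cm
#' @param radius positive scalar, cm
#' @param inlier_indices integer indices into the fitted cloud
#' @param weight nonnegative scalar
#' @param residual_mean,residual_std inlier absolute-residual mean/sd, cm
#' @return an object of class `sphere_model`
#' @export
sphere_model <- function(center, radius, inlier_indices = integer(0),
                         weight = 0, residual_mean = NA_real_,
                         residual_std = NA_real_) {
  center <- as.numeric(center)
  if (length(center) != 3L || !all(is.finite(center)))
    sricp_stop("sphere center must be a finite 3-vector", "sricp_invalid")
  if (!is.finite(radius) || radius <= 0)
    sricp_stop("sphere radius must be positive", "sricp_invalid")
  if (weight < 0)
    sricp_stop("sphere weight must be nonnegative", "sricp_invalid")
  structure(list(center = center, radius = radius,
                 inlier_indices = as.integer(inlier_indices),
                 weight = weight, residual_mean = residual_mean,
                 residual_std = residual_std),
            class = "sphere_model")
}

#' @export
print.sphere_model <- function(x, ...) {
  cat(sprintf(
    "<sphere_model: C = (%.4g, %.4g, %.4g), r = %.4g cm, %d inliers, w = %.3g>\n",
    x$center[1], x$center[2], x$center[3], x$radius,
    length(x$inlier_indices), x$weight))
  invisible(x)
}
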