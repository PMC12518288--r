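# Enhanced RANSAC localization of the colored calibration spheres.
#
# Stereo/SfM reconstructions see each marker as a noisy partial (hemispheric)
# shell with outliers, where plain RANSAC sphere fitting degrades. The
# enhancements: (1) a dynamic inlier threshold that adapts the admission band
# to the local point density around the candidate surface; (2) a weighted
# consensus score w = (|inliers|/|P|) / (mu + sigma + eps) that rewards tight
# shells, not just populous ones; (3) geometric constraints (radius window
# around the known marker radius, center inside the dilated bounding box)
# applied to the top-K candidates; (4) Levenberg-Marquardt refinement of the
# surviving model on its inliers.

.RANSAC_EPS <- 1e-12

#' Enhanced-RANSAC configuration
#'
#' @param max_iterations number of sampling iterations N (default 1000; fixed
#'   count, no adaptive early exit, for reproducibility)
#' @param base_threshold baseline inlier threshold t_base, cm (default 0.1)
#' @param top_k candidates retained for constraint filtering (default 5)
#' @param density_k neighbor count for the spacing statistic (default 10)
#' @param threshold_clamp length-2 clamp on the local/global spacing ratio
#'   (default c(0.5, 2))
#' @param nominal_radius known marker radius, cm, or NULL to disable the
#'   radius constraint
#' @param radius_tolerance admissible fractional radius deviation (default 0.2)
#' @param rng_seed integer seed or NULL (use the current RNG state)
#' @param second_lm_pass run a second LM pass on the re-selected inliers
#' @return an object of class `ransac_config`
#' @export
ransac_config <- function(max_iterations = 1000L, base_threshold = 0.1,
                          top_k = 5L, density_k = 10L,
                          threshold_clamp = c(0.5, 2.0),
                          nominal_radius = NULL, radius_tolerance = 0.2,
                          rng_seed = NULL, second_lm_pass = FALSE) {
  if (max_iterations < 1L || base_threshold <= 0 || top_k < 1L ||
      density_k < 1L)
    sricp_stop("max_iterations, base_threshold, top_k, density_k must be positive",
               "sricp_invalid")
  if (length(threshold_clamp) != 2L || threshold_clamp[1] > 1 ||
      threshold_clamp[2] < 1)
    sricp_stop("threshold_clamp must satisfy low <= 1 <= high",
               "sricp_invalid")
  structure(list(max_iterations = as.integer(max_iterations),
                 base_threshold = base_threshold, top_k = as.integer(top_k),
                 density_k = as.integer(density_k),
                 threshold_clamp = as.numeric(threshold_clamp),
                 nominal_radius = nominal_radius,
                 radius_tolerance = radius_tolerance,
                 rng_seed = rng_seed, second_lm_pass = second_lm_pass),
            class = "ransac_config")
}

#' Color descriptor for one marker sphere
#'
#' @param label integer marker label (unique per scene)
#' @param rgb length-3 reference color in 0..255
#' @param max_dist admission cap on euclidean RGB distance (default 80)
#' @return an object of class `color_spec`
#' @export
color_spec <- function(label, rgb, max_dist = 80) {
  rgb <- as.numeric(rgb)
  if (length(rgb) != 3L || any(rgb < 0) || any(rgb > 255))
    sricp_stop("rgb must be three values in [0, 255]", "sricp_invalid")
  structure(list(label = as.integer(label), rgb = rgb, max_dist = max_dist),
            class = "color_spec")
}

#' Segment marker spheres by color
#'
#' Assigns each point to the nearest reference color in RGB space, within
#' that spec's distance cap; unassigned points are dropped. The sub-clouds
#' are disjoint by construction.
#'
#' @param cloud a [point_cloud()] with colors
#' @param specs non-empty list of [color_spec()]
#' @return named list of [point_cloud()], one per spec label (possibly empty)
#' @export
segment_spheres_by_color <- function(cloud, specs) {
  if (length(specs) == 0L)
    sricp_stop("at least one color spec is required", "sricp_invalid")
  labs <- vapply(specs, `[[`, integer(1), "label")
  if (anyDuplicated(labs))
    sricp_stop("color spec labels must be distinct", "sricp_invalid")
  n <- n_points(cloud)
  out <- vector("list", length(specs))
  names(out) <- as.character(labs)
  if (n == 0L) {
    for (i in seq_along(specs)) out[[i]] <- cloud
    return(out)
  }
  refs <- t(vapply(specs, `[[`, numeric(3), "rgb"))
  caps <- vapply(specs, `[[`, numeric(1), "max_dist")
  cols <- cloud$colors
  d2 <- sapply(seq_along(specs), function(j)
    (cols[, 1] - refs[j, 1])^2 + (cols[, 2] - refs[j, 2])^2 +
      (cols[, 3] - refs[j, 3])^2)
  d2 <- matrix(d2, nrow = n)
  nearest <- max.col(-d2, ties.method = "first")
  within <- sqrt(d2[cbind(seq_len(n), nearest)]) <= caps[nearest]
  for (j in seq_along(specs))
    out[[j]] <- pc_subset(cloud, within & nearest == j)
  out
}

# Sphere through 4 points via the linear system of squared-distance
# differences; returns NULL on (near-)coplanar samples so the RANSAC loop can
# resample cheaply.
.sphere4 <- function(p) {
  v <- p[2:4, , drop = FALSE] - matrix(p[1, ], 3L, 3L, byrow = TRUE)
  diag_len <- sqrt(sum((apply(p, 2, max) - apply(p, 2, min))^2))
  vol <- abs(det(v)) / 6
  if (vol <= 1e-9 * max(diag_len, 1e-9)^3) return(NULL)
  rhs <- 0.5 * (rowSums(p[2:4, , drop = FALSE]^2) - sum(p[1, ]^2))
  center <- tryCatch(solve(v, rhs), error = function(e) NULL)
  if (is.null(center)) return(NULL)
  list(center = as.numeric(center),
       radius = sqrt(sum((p[1, ] - center)^2)))
}

#' Exact sphere through four non-coplanar points
#'
#' @param p1,p2,p3,p4 length-3 numeric points
#' @return list with `center` and `radius`; all four residuals are zero to
#'   numerical precision
#' @export
#' @examples
#' sphere_from_4_points(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
sphere_from_4_points <- function(p1, p2, p3, p4) {
  s <- .sphere4(rbind(p1, p2, p3, p4))
  if (is.null(s))
    sricp_stop("the four points are coplanar (degenerate sphere)",
               "sricp_degenerate")
  s
}

# per-point spacing statistic: distance to the density_k-th nearest neighbor
.spacing <- function(points, k) {
  n <- nrow(points)
  if (n <= 1L) return(rep(0, n))
  k <- min(k, n - 1L)
  cpp_knn_dists(points, k)[, k]
}

#' Dynamic inlier threshold for a candidate sphere
#'
#' `t = t_base * clamp(local_spacing / global_spacing, clamp)` where spacing
#' is the median distance to the `density_k`-th nearest neighbor, local over
#' points within `2 * t_base` of the candidate surface (falling back to the
#' global statistic when that shell is empty) and global over the whole
#' sub-cloud. Reduces to `t_base` on uniform data.
#'
#' @param center,radius candidate sphere
#' @param cloud a non-empty [point_cloud()]
#' @param config a [ransac_config()]
#' @param spacing optional precomputed per-point spacing vector
#' @return threshold, cm
#' @export
dynamic_threshold <- function(center, radius, cloud, config = ransac_config(),
                              spacing = NULL) {
  if (is.null(spacing)) spacing <- .spacing(cloud$points, config$density_k)
  gl <- stats::median(spacing)
  if (!is.finite(gl) || gl <= 0) return(config$base_threshold)
  res <- abs(row_norms(sweep(cloud$points, 2L, center)) - radius)
  shell <- res <= 2 * config$base_threshold
  loc <- if (any(shell)) stats::median(spacing[shell]) else gl
  ratio <- min(max(loc / gl, config$threshold_clamp[1]),
               config$threshold_clamp[2])
  config$base_threshold * ratio
}

#' Score a candidate sphere
#'
#' Inliers are points with absolute surface residual at most `threshold`;
#' the weight is `(|inliers|/|P|) / (mu + sigma + eps)` with `eps = 1e-12`,
#' capped at `1/eps`, where mu and sigma are the mean and standard deviation
#' of the inlier absolute residuals. An empty inlier set scores 0.
#'
#' @param center,radius candidate sphere
#' @param cloud a [point_cloud()]
#' @param threshold admission threshold, cm
#' @return list with `inlier_indices`, `weight`, `residual_mean`,
#'   `residual_std`
#' @export
score_candidate <- function(center, radius, cloud, threshold) {
  if (threshold <= 0)
    sricp_stop("threshold must be positive", "sricp_invalid")
  res <- abs(row_norms(sweep(cloud$points, 2L, center)) - radius)
  idx <- which(res <= threshold)
  if (length(idx) == 0L)
    return(list(inlier_indices = integer(0), weight = 0,
                residual_mean = NA_real_, residual_std = NA_real_))
  mu <- mean(res[idx])
  sigma <- if (length(idx) > 1L) stats::sd(res[idx]) else 0
  w <- min((length(idx) / n_points(cloud)) / (mu + sigma + .RANSAC_EPS),
           1 / .RANSAC_EPS)
  list(inlier_indices = idx, weight = w, residual_mean = mu,
       residual_std = sigma)
}

# Levenberg-Marquardt minimization of sum((||p - C|| - r)^2) over (C, r).
.lm_sphere <- function(points, center, radius, max_iter = 50L, tol = 1e-12) {
  par <- c(center, radius)
  resid <- function(par) {
    d <- row_norms(sweep(points, 2L, par[1:3]))
    list(d = d, r = d - par[4])
  }
  cur <- resid(par)
  sse <- sum(cur$r^2)
  lambda <- 1e-3
  for (it in seq_len(max_iter)) {
    d <- pmax(cur$d, 1e-12)
    J <- cbind(-(sweep(points, 2L, par[1:3])) / d, -1)
    g <- crossprod(J, cur$r)
    H <- crossprod(J)
    improved <- FALSE
    for (tries in 1:10) {
      step <- tryCatch(solve(H + lambda * diag(diag(H) + 1e-12), -g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- par + as.numeric(step)
      if (cand[4] <= 0) { lambda <- lambda * 10; next }
      new <- resid(cand)
      new_sse <- sum(new$r^2)
      if (new_sse <= sse) {
        improved <- TRUE
        par <- cand; cur <- new
        conv <- (sse - new_sse) <= tol * (sse + tol)
        sse <- new_sse
        lambda <- max(lambda / 10, 1e-12)
        if (conv || max(abs(step)) < 1e-14) return(list(par = par, sse = sse))
        break
      }
      lambda <- lambda * 10
    }
    if (!improved) break
  }
  list(par = par, sse = sse)
}

#' Fit a calibration sphere by enhanced RANSAC
#'
#' Runs the full loop: sample 4 non-coplanar points, build the candidate
#' sphere, compute the dynamic threshold, score by weighted consensus, keep
#' the top-K candidates; filter the top-K by geometric constraints (radius
#' window around `nominal_radius` and center inside the cloud's bounding box
#' dilated by `nominal_radius`, when a nominal radius is configured) with
#' re-ranking after filtering; refine the surviving best model by
#' Levenberg-Marquardt on its inliers and re-select inliers at the refined
#' model. Deterministic given `rng_seed`.
#'
#' @param cloud a [point_cloud()] with at least 4 points
#' @param config a [ransac_config()]
#' @return a [sphere_model()]
#' @export
fit_sphere_ransac <- function(cloud, config = ransac_config()) {
  n <- n_points(cloud)
  if (n < 4L)
    sricp_stop("sphere fitting needs at least 4 points", "sricp_precondition")
  pts <- cloud$points
  spacing <- .spacing(pts, config$density_k)
  gl <- stats::median(spacing)
  with_local_seed(config$rng_seed, {
    K <- config$top_k
    cand <- list()  # each: center, radius, threshold, weight
    worst <- 0
    for (i in seq_len(config$max_iterations)) {
      idx <- sample.int(n, 4L)
      s <- .sphere4(pts[idx, , drop = FALSE])
      if (is.null(s)) next
      t_i <- if (!is.finite(gl) || gl <= 0) config$base_threshold else {
        res <- abs(row_norms(sweep(pts, 2L, s$center)) - s$radius)
        shell <- res <= 2 * config$base_threshold
        loc <- if (any(shell)) stats::median(spacing[shell]) else gl
        config$base_threshold *
          min(max(loc / gl, config$threshold_clamp[1]),
              config$threshold_clamp[2])
      }
      sc <- score_candidate(s$center, s$radius, cloud, t_i)
      if (sc$weight <= 0) next
      if (length(cand) < K || sc$weight > worst) {
        cand[[length(cand) + 1L]] <- list(center = s$center,
                                          radius = s$radius,
                                          threshold = t_i,
                                          weight = sc$weight)
        if (length(cand) > K) {
          ws <- vapply(cand, `[[`, numeric(1), "weight")
          cand <- cand[order(ws, decreasing = TRUE)[seq_len(K)]]
        }
        worst <- min(vapply(cand, `[[`, numeric(1), "weight"))
      }
    }
    if (length(cand) == 0L)
      sricp_stop("RANSAC found no candidate sphere with inliers",
                 "sricp_no_model")
    # geometric constraints over the top-K, then re-rank
    ok <- rep(TRUE, length(cand))
    fail_radius <- fail_center <- 0L
    if (!is.null(config$nominal_radius)) {
      rn <- config$nominal_radius
      bb_lo <- apply(pts, 2L, min) - rn
      bb_hi <- apply(pts, 2L, max) + rn
      for (j in seq_along(cand)) {
        if (abs(cand[[j]]$radius - rn) / rn > config$radius_tolerance) {
          ok[j] <- FALSE; fail_radius <- fail_radius + 1L
        } else if (any(cand[[j]]$center < bb_lo | cand[[j]]$center > bb_hi)) {
          ok[j] <- FALSE; fail_center <- fail_center + 1L
        }
      }
    }
    if (!any(ok)) {
      which_bad <- if (fail_radius >= fail_center) "radius window" else
        "center range"
      sricp_stop(sprintf(
        "no top-%d candidate survived the geometric constraints (%s)",
        length(cand), which_bad), "sricp_constraint")
    }
    cand <- cand[ok]
    ws <- vapply(cand, `[[`, numeric(1), "weight")
    best <- cand[[which.max(ws)]]
    sc <- score_candidate(best$center, best$radius, cloud, best$threshold)
    fit <- .lm_sphere(pts[sc$inlier_indices, , drop = FALSE],
                      best$center, best$radius)
    final <- score_candidate(fit$par[1:3], fit$par[4], cloud, best$threshold)
    if (config$second_lm_pass && length(final$inlier_indices) >= 4L) {
      fit <- .lm_sphere(pts[final$inlier_indices, , drop = FALSE],
                        fit$par[1:3], fit$par[4])
      final <- score_candidate(fit$par[1:3], fit$par[4], cloud,
                               best$threshold)
    }
    sphere_model(fit$par[1:3], fit$par[4], final$inlier_indices,
                 final$weight, final$residual_mean, final$residual_std)
  })
}

#' Labeled sphere-center set for one view
#'
#' @param view_index 0-based view index
#' @param labels integer marker labels (unique)
#' @param centers M x 3 matrix of centers, cm
#' @param models optional list of the underlying [sphere_model()]s
#' @return an object of class `sphere_center_set`
#' @export
sphere_center_set <- function(view_index, labels, centers, models = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 3L)
  labels <- as.integer(labels)
  if (anyDuplicated(labels))
    sricp_stop("labels within a center set must be unique", "sricp_invalid")
  if (nrow(centers) != length(labels))
    sricp_stop("one center per label required", "sricp_invalid")
  structure(list(view_index = as.integer(view_index), labels = labels,
                 centers = centers, models = models),
            class = "sphere_center_set")
}

#' Estimate all calibration-sphere centers in one view
#'
#' Segments the cloud by marker color and runs [fit_sphere_ransac()] per
#' marker with at least 4 points. Registration needs at least 3 homonymous
#' centers, so fewer than 3 usable spheres is an error.
#'
#' @param cloud a [point_cloud()]
#' @param specs list of [color_spec()] (one per marker)
#' @param config a [ransac_config()]
#' @param view_index 0-based view index recorded in the result
#' @return a [sphere_center_set()]
#' @export
estimate_all_centers <- function(cloud, specs, config = ransac_config(),
                                 view_index = 0L) {
  subs <- segment_spheres_by_color(cloud, specs)
  usable <- vapply(subs, n_points, integer(1)) >= 4L
  if (sum(usable) < 3L)
    sricp_stop(sprintf(
      "only %d marker(s) with >= 4 points; registration needs at least 3",
      sum(usable)), "sricp_precondition")
  models <- vector("list", sum(usable))
  labs <- as.integer(names(subs)[usable])
  ctrs <- matrix(0, sum(usable), 3L)
  j <- 0L
  for (i in which(usable)) {
    j <- j + 1L
    cfg <- config
    if (!is.null(config$rng_seed))
      cfg$rng_seed <- fan_out_seed(config$rng_seed,
                                   paste0("sphere", names(subs)[i]))
    models[[j]] <- fit_sphere_ransac(subs[[i]], cfg)
    ctrs[j, ] <- models[[j]]$center
  }
  sphere_center_set(view_index, labs, ctrs, models)
}
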