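# Marker-based self-registration (SR) + ICP fine alignment.
#
# Adjacent views share at least three homonymous sphere centers; the SVD
# (Kabsch) solution on those correspondences gives the pairwise transforms
# R_0..R_4 (view k+1 -> view k), which chain to the 0-degree reference frame.
# Each coarse-aligned view is then refined by point-to-point ICP against the
# accumulated reference before merging.

#' Match homonymous sphere centers between two views
#'
#' Pairs centers sharing a label, in ascending label order. At least three
#' shared labels are required for a rigid registration.
#'
#' @param a,b [sphere_center_set()] objects
#' @return list with `labels`, `a` (M x 3) and `b` (M x 3); row i of `a`
#'   corresponds to row i of `b`
#' @export
match_centers <- function(a, b) {
  shared <- sort(intersect(a$labels, b$labels))
  if (length(shared) < 3L)
    sricp_stop(sprintf(
      "only %d shared sphere label(s) between views %d and %d; at least 3 homonymous centers are required",
      length(shared), a$view_index, b$view_index), "sricp_precondition")
  list(labels = shared,
       a = a$centers[match(shared, a$labels), , drop = FALSE],
       b = b$centers[match(shared, b$labels), , drop = FALSE])
}

#' Least-squares rigid transform by SVD (Kabsch)
#'
#' Finds the rotation and translation minimizing
#' `sum ||R src_i + t - dst_i||^2`. The reflection case is guarded by
#' sign-correcting the smallest singular vector so `det(R) = +1`.
#'
#' @param src,dst M x 3 matrices of corresponding points (M >= 3, `src` not
#'   collinear)
#' @return a [rigid_transform()] mapping `src` onto `dst`
#' @export
svd_rigid_transform <- function(src, dst) {
  src <- matrix(as.numeric(as.matrix(src)), ncol = 3L)
  dst <- matrix(as.numeric(as.matrix(dst)), ncol = 3L)
  if (nrow(src) < 3L || nrow(dst) != nrow(src))
    sricp_stop("need at least 3 corresponding point pairs",
               "sricp_degenerate")
  cs <- colMeans(src); cd <- colMeans(dst)
  sc <- sweep(src, 2L, cs); dc <- sweep(dst, 2L, cd)
  sv <- svd(sc)
  if (sv$d[2] <= 1e-9 * max(sv$d[1], 1e-300))
    sricp_stop("source points are collinear: rotation is not determined",
               "sricp_degenerate")
  H <- crossprod(sc, dc)
  dec <- svd(H)
  d <- det(dec$v %*% t(dec$u))
  R <- dec$v %*% diag(c(1, 1, sign(d))) %*% t(dec$u)
  # polish orthonormality so rigid_transform's 1e-9 gate never trips on
  # accumulated float error
  pol <- svd(R)
  R <- pol$u %*% t(pol$v)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' Chain pairwise transforms to the reference view
#'
#' Given the five pairwise transforms (entry k maps view k to view k-1, for
#' k = 1..5), builds the cumulative transforms into the 0-degree frame:
#' `cumulative[1]` is the identity and `cumulative[k+1] = P_1 o P_2 o ... o
#' P_k` (later pairwise applied first), reproducing the R_0 x R_1 composite
#' for the 120-degree view.
#'
#' @param pairwise list of exactly 5 [rigid_transform()]s
#' @return an object of class `transform_chain` with elements `pairwise` and
#'   `cumulative` (list of 6; entry k+1 maps view k into view 0)
#' @export
build_chain <- function(pairwise) {
  if (length(pairwise) != 5L)
    sricp_stop("exactly 5 pairwise transforms are required", "sricp_invalid")
  for (tf in pairwise) stopifnot(inherits(tf, "rigid_transform"))
  cumulative <- vector("list", 6L)
  cumulative[[1]] <- rigid_transform()
  for (k in 1:5)
    cumulative[[k + 1]] <- compose_transforms(cumulative[[k]], pairwise[[k]])
  structure(list(pairwise = pairwise, cumulative = cumulative),
            class = "transform_chain")
}

# median nearest-neighbor spacing of a cloud (subsampled for speed)
.median_spacing <- function(points, max_n = 2000L) {
  n <- nrow(points)
  if (n < 2L) return(0)
  if (n > max_n) points <- points[round(seq(1L, n, length.out = max_n)), ]
  stats::median(cpp_knn_dists(points, 1L)[, 1])
}

#' Point-to-point ICP refinement
#'
#' Iterates nearest-neighbor correspondence (within `max_corr_dist`) and the
#' SVD rigid solution until the change in RMSE falls below `rmse_tol` or
#' `max_iter` is reached (defaults 100 and 1e-8). The reported RMSE sequence
#' is non-increasing: an iteration that would increase the RMSE is rejected
#' and terminates the loop. `mode = "absolute"` instead stops once the RMSE
#' itself falls below the tolerance.
#'
#' @param source,target non-empty [point_cloud()]s (or N x 3 matrices)
#' @param max_iter iteration cap (default 100)
#' @param rmse_tol stopping tolerance (default 1e-8)
#' @param max_corr_dist correspondence rejection distance, cm; default 5 x
#'   the target's median point spacing
#' @param sample_n max source points used for correspondences (subsampling
#'   keeps large clouds tractable; the returned transform applies to all)
#' @param mode `"delta"` (change in RMSE, default) or `"absolute"`
#' @param adaptive_reject additionally reject correspondences farther than
#'   3 x the current median correspondence distance, re-evaluated each
#'   iteration (robust trimmed-ICP rule; off by default, enabled by the
#'   pipeline where the marker-based coarse alignment makes residuals small
#'   and one-sided pulls from non-overlapping surface parts dominate)
#' @return list with `transform` (maps source into the target frame),
#'   `rmse`, `iterations` and `rmse_history`
#' @export
icp_refine <- function(source, target, max_iter = 100L, rmse_tol = 1e-8,
                       max_corr_dist = NULL, sample_n = 2000L,
                       mode = c("delta", "absolute"),
                       adaptive_reject = FALSE) {
  mode <- match.arg(mode)
  sp <- if (inherits(source, "point_cloud")) source$points else
    matrix(as.numeric(as.matrix(source)), ncol = 3L)
  tp <- if (inherits(target, "point_cloud")) target$points else
    matrix(as.numeric(as.matrix(target)), ncol = 3L)
  if (nrow(sp) == 0L || nrow(tp) == 0L)
    sricp_stop("ICP requires non-empty source and target clouds",
               "sricp_precondition")
  if (is.null(max_corr_dist)) {
    max_corr_dist <- 5 * .median_spacing(tp)
    if (!is.finite(max_corr_dist) || max_corr_dist <= 0)
      max_corr_dist <- Inf
  }
  if (nrow(sp) > sample_n)
    sp <- sp[round(seq(1L, nrow(sp), length.out = sample_n)), ]
  tf <- rigid_transform()
  rmse_prev <- Inf
  history <- numeric(0)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    cur <- apply_transform(sp, tf)
    nn <- cpp_nn(cur, tp)
    keep <- nn$dist <= max_corr_dist
    if (adaptive_reject && any(keep))
      keep <- keep & nn$dist <= 3 * stats::median(nn$dist[keep])
    if (sum(keep) < 3L)
      sricp_stop(sprintf(
        "ICP found %d correspondence(s) within max_corr_dist = %.4g cm",
        sum(keep), max_corr_dist), "sricp_no_correspondence")
    rmse <- sqrt(mean(nn$dist[keep]^2))
    if (rmse > rmse_prev) break  # reject non-improving step
    iterations <- it
    history <- c(history, rmse)
    done <- if (mode == "delta") is.finite(rmse_prev) &&
      abs(rmse_prev - rmse) <= rmse_tol else rmse <= rmse_tol
    rmse_prev <- rmse
    if (done) break
    inc <- svd_rigid_transform(cur[keep, , drop = FALSE],
                               tp[nn$index[keep], , drop = FALSE])
    tf <- compose_transforms(inc, tf)
  }
  list(transform = tf, rmse = rmse_prev, iterations = iterations,
       rmse_history = history)
}

#' Register six views into the reference frame and merge
#'
#' Computes the pairwise SR transforms from homonymous sphere centers, chains
#' them to the 0-degree frame, refines each coarse-aligned view by ICP
#' against the accumulated reference (or view 0 only) and concatenates the
#' aligned views.
#'
#' @param views list of 6 scale-calibrated [point_cloud()]s
#' @param centers list of 6 [sphere_center_set()]s (same order)
#' @param icp list of arguments passed on to [icp_refine()]; `list()`
#'   disables no defaults
#' @param target `"accumulated"` (default) or `"view0"`
#' @param use_icp set FALSE for SR-only registration
#' @param dedup_voxel optional voxel size, cm, for merged-cloud
#'   de-duplication (off by default; keep off for evaluation runs)
#' @return list with `chain` (the SR [build_chain()] result), `refined`
#'   (list of 6 final transforms into view 0), `merged` ([point_cloud()])
#'   and `report` (per-view data.frame: rmse, iterations, n_points)
#' @export
register_all <- function(views, centers, icp = list(),
                         target = c("accumulated", "view0"),
                         use_icp = TRUE, dedup_voxel = NULL) {
  target <- match.arg(target)
  if (length(views) != 6L || length(centers) != 6L)
    sricp_stop("exactly 6 views and 6 center sets are required",
               "sricp_invalid")
  pairwise <- vector("list", 5L)
  for (k in 1:5) {
    m <- tryCatch(match_centers(centers[[k]], centers[[k + 1]]),
                  error = function(e) sricp_stop(
                    sprintf("views %d-%d: %s", k - 1L, k, conditionMessage(e)),
                    "sricp_precondition"))
    pairwise[[k]] <- svd_rigid_transform(m$b, m$a)
  }
  chain <- build_chain(pairwise)
  refined <- vector("list", 6L)
  refined[[1]] <- rigid_transform()
  merged_list <- list(views[[1]])
  ref_pts <- views[[1]]
  rmse <- c(0, rep(NA_real_, 5)); iters <- c(0L, rep(NA_integer_, 5))
  for (k in 1:5) {
    coarse <- apply_transform(views[[k + 1]], chain$cumulative[[k + 1]])
    final_tf <- chain$cumulative[[k + 1]]
    if (use_icp) {
      tgt <- if (target == "accumulated") ref_pts else views[[1]]
      fit <- tryCatch(do.call(icp_refine, c(list(coarse, tgt), icp)),
                      error = function(e) sricp_stop(
                        sprintf("ICP failed for view %d: %s", k,
                                conditionMessage(e)), "sricp_icp"))
      final_tf <- compose_transforms(fit$transform, chain$cumulative[[k + 1]])
      coarse <- apply_transform(views[[k + 1]], final_tf)
      rmse[k + 1] <- fit$rmse; iters[k + 1] <- fit$iterations
    }
    refined[[k + 1]] <- final_tf
    merged_list[[k + 1]] <- coarse
    if (target == "accumulated") ref_pts <- concat_clouds(ref_pts, coarse)
  }
  merged <- concat_clouds(merged_list)
  if (!is.null(dedup_voxel)) merged <- voxel_dedup(merged, dedup_voxel)
  report <- data.frame(view = 0:5,
                       n_points = vapply(views, n_points, integer(1)),
                       icp_rmse = rmse, icp_iterations = iters)
  list(chain = chain, refined = refined, merged = merged, report = report)
}

#' Voxel-grid de-duplication
#'
#' Keeps the first point in every occupied voxel of an axis-aligned grid.
#'
#' @param cloud a [point_cloud()]
#' @param voxel voxel edge length, cm
#' @return thinned [point_cloud()]
#' @export
voxel_dedup <- function(cloud, voxel) {
  if (voxel <= 0) sricp_stop("voxel size must be positive", "sricp_invalid")
  if (n_points(cloud) == 0L) return(cloud)
  key <- apply(floor(sweep(cloud$points, 2L, apply(cloud$points, 2L, min)) /
                       voxel), 1L, paste, collapse = ",")
  pc_subset(cloud, !duplicated(key))
}

#' Cloud-to-cloud distance
#'
#' For each test point, the euclidean distance to its nearest reference
#' point; returned as mean and standard deviation (0 for a single point).
#'
#' @param test,reference non-empty [point_cloud()]s
#' @return list with `mean` and `std`, cm
#' @export
cloud_to_cloud_distance <- function(test, reference) {
  if (n_points(test) == 0L || n_points(reference) == 0L)
    sricp_stop("cloud-to-cloud distance requires non-empty clouds",
               "sricp_precondition")
  d <- cpp_nn(test$points, reference$points)$dist
  list(mean = mean(d), std = if (length(d) > 1L) stats::sd(d) else 0)
}
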