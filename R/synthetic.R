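# Synthetic multi-view acquisition generator with full ground truth.
#
# The emulated rig: a cylindrical pot (the top band of its lateral surface is
# the rim used for scale calibration), six colored calibration spheres on a
# ring around the plant, and a parametric plant (vertical stem + planar or
# curvature-bent elliptical leaves). Each view is the world rotated by
# -k*60 degrees about z (a rotating camera arm), shrunk by an SfM-like
# per-view scale, with hemispheric marker visibility (normal culling toward
# the camera), Gaussian surface noise, dark leaf-edge points and uniform
# outliers.

.LABEL_POT <- 100L
.LABEL_STEM <- 101L
.LABEL_LEAF0 <- 200L

#' Default marker color specs
#'
#' Six saturated, mutually distant RGB references (red, blue, yellow,
#' magenta, cyan, orange), labels 1..6.
#'
#' @param max_dist per-spec RGB distance cap (default 80)
#' @return list of six [color_spec()]s
#' @export
default_sphere_colors <- function(max_dist = 80) {
  cols <- list(c(230, 40, 40), c(40, 60, 230), c(235, 220, 40),
               c(225, 40, 220), c(40, 220, 220), c(240, 140, 30))
  lapply(1:6, function(i) color_spec(i, cols[[i]], max_dist))
}

#' Leaf specification for the synthetic plant
#'
#' @param attach_frac attachment height as a fraction of stem height
#' @param azimuth_deg azimuth of the leaf direction
#' @param tilt_deg upward tilt of the leaf plane from horizontal
#' @param length,width leaf length and width, cm (along-surface; for a curved
#'   leaf `length` is the arc length)
#' @param curvature bending curvature along the major axis, 1/cm (0 = flat)
#' @return an object of class `leaf_spec`
#' @export
leaf_spec <- function(attach_frac, azimuth_deg, tilt_deg, length, width,
                      curvature = 0) {
  if (length <= 0 || width <= 0)
    sricp_stop("leaf length and width must be positive", "sricp_invalid")
  structure(list(attach_frac = attach_frac, azimuth_deg = azimuth_deg,
                 tilt_deg = tilt_deg, length = length, width = width,
                 curvature = curvature), class = "leaf_spec")
}

#' Synthetic scene configuration
#'
#' Defaults describe a small potted seedling on the turntable rig: 16 cm
#' pot (radius 8), 4 cm markers (radius 2) on a 22 cm ring, a 30 cm plant
#' with four leaves (two flat, two curved), six views 60 degrees apart,
#' per-view scale drift in [0.9, 1.1] (SfM scale ambiguity), 0.05 cm surface
#' noise.
#'
#' @param pot_radius pot radius, cm
#' @param pot_rim_z rim height above the table, cm
#' @param marker_ring_radius radius of the marker ring, cm
#' @param sphere_radius marker radius, cm
#' @param sphere_z height of the marker centers, cm
#' @param sphere_colors list of 6 [color_spec()]
#' @param plant_height stem height above the rim, cm
#' @param leaf_specs list of [leaf_spec()]
#' @param n_views number of views (default 6)
#' @param view_step_deg angular step between views (default 60)
#' @param view_scales length-`n_views` scales, or NULL to sample from
#'   `view_scale_range`
#' @param view_scale_range sampling range of the per-view scale drift
#' @param noise_sigma Gaussian surface noise sd, cm (physical units)
#' @param outlier_fraction fraction of uniform outlier points added per view
#' @param dark_edge_fraction dark edge points per leaf, as a fraction of its
#'   surface points
#' @param visibility_culling drop points facing away from the camera
#' @param densities named list of per-surface point counts: `pot`, `rim`,
#'   `sphere`, `stem`, `leaf`
#' @param transform_jitter sd of a small random perturbation of the true
#'   view motions (deg / cm); 0 = exact turntable
#' @param rng_seed integer seed
#' @return an object of class `scene_config`
#' @export
scene_config <- function(pot_radius = 8, pot_rim_z = 12,
                         marker_ring_radius = 22, sphere_radius = 2,
                         sphere_z = 2,
                         sphere_colors = default_sphere_colors(),
                         plant_height = 30,
                         leaf_specs = list(
                           leaf_spec(0.35, 20, 25, 9, 3.5, 0),
                           leaf_spec(0.55, 150, 30, 8, 3.2, 0.06),
                           leaf_spec(0.75, 260, 35, 7, 2.8, 0),
                           leaf_spec(0.90, 80, 40, 6, 2.5, 0.08)),
                         n_views = 6L, view_step_deg = 60,
                         view_scales = NULL,
                         view_scale_range = c(0.9, 1.1),
                         noise_sigma = 0.05, outlier_fraction = 0.02,
                         dark_edge_fraction = 0.05,
                         visibility_culling = TRUE,
                         densities = list(pot = 2500L, rim = 700L,
                                          sphere = 600L, stem = 400L,
                                          leaf = 600L),
                         transform_jitter = 0, rng_seed = 1L) {
  num_pos <- c(pot_radius = pot_radius, pot_rim_z = pot_rim_z,
               marker_ring_radius = marker_ring_radius,
               sphere_radius = sphere_radius, plant_height = plant_height)
  for (nm in names(num_pos)) if (!is.finite(num_pos[[nm]]) || num_pos[[nm]] <= 0)
    sricp_stop(sprintf("scene_config field '%s' must be positive", nm),
               "sricp_invalid")
  for (nm in c("outlier_fraction", "dark_edge_fraction")) {
    v <- get(nm)
    if (v < 0 || v >= 1)
      sricp_stop(sprintf("scene_config field '%s' must be in [0, 1)", nm),
                 "sricp_invalid")
  }
  if (n_views < 2L)
    sricp_stop("scene_config field 'n_views' must be >= 2", "sricp_invalid")
  if (length(sphere_colors) != 6L)
    sricp_stop("scene_config field 'sphere_colors' must have 6 specs",
               "sricp_invalid")
  if (!is.null(view_scales) && (length(view_scales) != n_views ||
                                any(view_scales <= 0)))
    sricp_stop("scene_config field 'view_scales' must be n_views positive values",
               "sricp_invalid")
  structure(list(pot_radius = pot_radius, pot_rim_z = pot_rim_z,
                 marker_ring_radius = marker_ring_radius,
                 sphere_radius = sphere_radius, sphere_z = sphere_z,
                 sphere_colors = sphere_colors, plant_height = plant_height,
                 leaf_specs = leaf_specs, n_views = as.integer(n_views),
                 view_step_deg = view_step_deg, view_scales = view_scales,
                 view_scale_range = view_scale_range,
                 noise_sigma = noise_sigma,
                 outlier_fraction = outlier_fraction,
                 dark_edge_fraction = dark_edge_fraction,
                 visibility_culling = visibility_culling,
                 densities = densities, transform_jitter = transform_jitter,
                 rng_seed = rng_seed),
            class = "scene_config")
}

#' Uniform samples on a sphere surface
#'
#' Normalized Gaussian directions: every point is at exactly `radius` from
#' `center` (to 1e-12).
#'
#' @param center length-3 center, cm
#' @param radius sphere radius, cm
#' @param n number of points (>= 0)
#' @return list with `points` (n x 3) and outward unit `normals`
#' @export
sample_sphere_surface <- function(center, radius, n) {
  if (n < 0) sricp_stop("n must be nonnegative", "sricp_invalid")
  if (n == 0L) return(list(points = matrix(numeric(0), 0, 3),
                           normals = matrix(numeric(0), 0, 3)))
  g <- matrix(rnorm(3 * n), n, 3)
  nr <- row_norms(g)
  nr[nr < 1e-12] <- 1
  dirs <- g / nr
  list(points = sweep(dirs * radius, 2L, as.numeric(center), `+`),
       normals = dirs)
}

# cylinder lateral surface, axis along z from z0 to z1
.sample_cylinder <- function(radius, z0, z1, n, center_xy = c(0, 0)) {
  th <- runif(n, 0, 2 * pi)
  z <- runif(n, z0, z1)
  list(points = cbind(center_xy[1] + radius * cos(th),
                      center_xy[2] + radius * sin(th), z),
       normals = cbind(cos(th), sin(th), 0))
}

#' Sample one parametric leaf
#'
#' An elliptical patch with semi-axes `length/2` and `width/2`, its base at
#' the attachment point, optionally bent along the major axis with constant
#' curvature (arc length preserved, so the tip-to-base chord shrinks), then
#' tilted and rotated to its azimuth. About 12 percent of the points lie on
#' the ellipse boundary so the leaf tips are actually sampled. Ground truth
#' records both the chord (linear distance between the extreme boundary
#' points) and the arc length.
#'
#' @param spec a [leaf_spec()]
#' @param n number of surface points
#' @param attach_point length-3 attachment point on the stem, cm
#' @return list: `points`, `normals`, `truth` (list with `chord_length`,
#'   `width`, `arc_length`)
#' @export
sample_leaf <- function(spec, n, attach_point = c(0, 0, 0)) {
  a <- spec$length / 2; b <- spec$width / 2
  n_edge <- max(4L, round(0.12 * n))
  n_in <- n - n_edge
  phi <- runif(n_in, 0, 2 * pi)
  rr <- sqrt(runif(n_in))
  phi_e <- runif(n_edge, 0, 2 * pi)
  u <- c(rr * cos(phi), cos(phi_e))   # unit-disk coords
  v <- c(rr * sin(phi), sin(phi_e))
  # ellipse centered at (a, 0): base of the leaf at the local origin
  x <- a + a * u
  y <- b * v
  kap <- spec$curvature
  if (kap > 0) {
    lx <- sin(kap * x) / kap
    lz <- (1 - cos(kap * x)) / kap
    nx <- sin(kap * x); nz <- cos(kap * x)  # surface normal tilts with bend
    loc <- cbind(lx, y, lz)
    nrm <- cbind(-nx, 0, nz)
    chord <- 2 * sin(kap * spec$length / 2) / kap
  } else {
    loc <- cbind(x, y, 0)
    nrm <- matrix(rep(c(0, 0, 1), each = n), n, 3)
    chord <- spec$length
  }
  tilt <- spec$tilt_deg * pi / 180
  az <- spec$azimuth_deg * pi / 180
  # tilt about the local y axis (tip rises), then azimuth about z
  Rt <- matrix(c(cos(tilt), 0, -sin(tilt), 0, 1, 0,
                 sin(tilt), 0, cos(tilt)), 3, 3)
  Rz <- matrix(c(cos(az), sin(az), 0, -sin(az), cos(az), 0, 0, 0, 1), 3, 3)
  R <- Rz %*% Rt
  list(points = sweep(loc %*% t(R), 2L, as.numeric(attach_point), `+`),
       normals = nrm %*% t(R),
       truth = list(chord_length = chord, width = spec$width,
                    arc_length = spec$length))
}

#' Generate a multi-view synthetic scene with ground truth
#'
#' Builds the labeled world cloud (pot, six spheres, stem, leaves), then for
#' each view k applies the inverse of the true cumulative transform
#' (rotation by -k*view_step about z, optionally jittered), divides by the
#' true per-view scale, culls points facing away from the camera (direction
#' +y, tilted slightly downward; leaves are thin and kept from both sides),
#' adds Gaussian noise, dark leaf-edge points (every channel below 50) and
#' uniform outliers in the dilated bounding box. Fully reproducible from
#' `rng_seed`. In every view cloud the surviving world points come first, in
#' world order, followed by dark-edge points and outliers (labels -1).
#'
#' @param config a [scene_config()]
#' @return list with `views` (list of [point_cloud()]s) and `truth`, a list
#'   with `true_pairwise_transforms`, `true_cumulative_transforms`,
#'   `true_view_scales`, `true_sphere_centers_world` (6 x 3 matrix with
#'   labels 1..6 as rownames), `true_sphere_labels`, `true_traits`
#'   ([extract_traits()] report on the noiseless plant),
#'   `leaf_truth` (per-leaf chord/width/arc), `world_cloud`,
#'   `visible_index` (per-view indices into the world cloud) and `config`
#' @export
generate_scene <- function(config = scene_config()) {
  with_local_seed(config$rng_seed, .generate_scene_impl(config))
}

.generate_scene_impl <- function(config) {
  den <- config$densities
  pts <- list(); nrm <- list(); col <- list(); lab <- list()
  opaque <- list()  # TRUE = cull by normal, FALSE = thin surface (leaf)
  add <- function(p, n, color, label, op) {
    k <- length(pts) + 1L
    pts[[k]] <<- p; nrm[[k]] <<- n
    col[[k]] <<- matrix(rep(as.integer(color), each = nrow(p)), nrow(p), 3)
    lab[[k]] <<- rep.int(as.integer(label), nrow(p))
    opaque[[k]] <<- rep.int(op, nrow(p))
  }
  cyl <- .sample_cylinder(config$pot_radius, 0, config$pot_rim_z, den$pot)
  add(cyl$points, cyl$normals, c(180, 110, 80), .LABEL_POT, TRUE)
  rim <- .sample_cylinder(config$pot_radius, config$pot_rim_z - 0.4,
                          config$pot_rim_z, den$rim)
  add(rim$points, rim$normals, c(180, 110, 80), .LABEL_POT, TRUE)
  sphere_centers <- matrix(0, 6, 3)
  for (i in 1:6) {
    th <- (30 + 60 * (i - 1)) * pi / 180
    ctr <- c(config$marker_ring_radius * cos(th),
             config$marker_ring_radius * sin(th), config$sphere_z)
    sphere_centers[i, ] <- ctr
    sp <- sample_sphere_surface(ctr, config$sphere_radius, den$sphere)
    add(sp$points, sp$normals, config$sphere_colors[[i]]$rgb,
        config$sphere_colors[[i]]$label, TRUE)
  }
  stem_top <- config$pot_rim_z + config$plant_height
  stem <- .sample_cylinder(0.35, config$pot_rim_z, stem_top, den$stem)
  add(stem$points, stem$normals, c(120, 85, 50), .LABEL_STEM, TRUE)
  leaf_truth <- list()
  for (j in seq_along(config$leaf_specs)) {
    sp <- config$leaf_specs[[j]]
    attach <- c(0.35 * cos(sp$azimuth_deg * pi / 180),
                0.35 * sin(sp$azimuth_deg * pi / 180),
                config$pot_rim_z + sp$attach_frac * config$plant_height)
    lf <- sample_leaf(sp, den$leaf, attach)
    add(lf$points, lf$normals, c(50, 160, 60), .LABEL_LEAF0 + j, FALSE)
    leaf_truth[[j]] <- c(list(leaf_id = .LABEL_LEAF0 + j), lf$truth)
  }
  world_pts <- do.call(rbind, pts)
  world_nrm <- do.call(rbind, nrm)
  world_col <- do.call(rbind, col)
  world_lab <- unlist(lab)
  world_opq <- unlist(opaque)
  world <- point_cloud(world_pts, world_col, world_lab)
  plant_mask <- world_lab >= .LABEL_STEM
  plant <- pc_subset(world, plant_mask)
  true_traits <- extract_traits(
    plant, leaf_labels = .LABEL_LEAF0 + seq_along(config$leaf_specs),
    reference_z = config$pot_rim_z)
  # crown truth recomputed by brute force over all plant pairs (oracle-grade)
  xy <- plant$points[, 1:2]
  true_traits$crown_width <- sqrt(max(outer(xy[, 1], xy[, 1], `-`)^2 +
                                        outer(xy[, 2], xy[, 2], `-`)^2))

  nv <- config$n_views
  scales <- config$view_scales %||%
    runif(nv, config$view_scale_range[1], config$view_scale_range[2])
  cams <- vector("list", nv)
  cumulative <- vector("list", nv)
  cam_dir <- c(0, 1, 0.4); cam_dir <- cam_dir / sqrt(sum(cam_dir^2))
  views <- vector("list", nv)
  visible_index <- vector("list", nv)
  bb_lo <- apply(world_pts, 2, min); bb_hi <- apply(world_pts, 2, max)
  dil <- 0.1 * (bb_hi - bb_lo)
  for (k in seq_len(nv)) {
    tf <- rotation_z((k - 1) * config$view_step_deg)
    if (config$transform_jitter > 0) {
      jit <- compose_transforms(
        rotation_z(rnorm(1, 0, config$transform_jitter)),
        rigid_transform(diag(3), rnorm(3, 0, config$transform_jitter)))
      tf <- compose_transforms(tf, jit)
    }
    cumulative[[k]] <- tf
    inv <- invert_transform(tf)
    vp <- apply_transform(world_pts, inv)
    vn <- world_nrm %*% tf$rotation  # = R^T applied to rows
    keep <- if (config$visibility_culling)
      !world_opq | (vn %*% cam_dir)[, 1] > 0.05 else rep(TRUE, nrow(vp))
    visible_index[[k]] <- which(keep)
    vp <- vp[keep, , drop = FALSE] / scales[k]
    vc <- world_col[keep, , drop = FALSE]
    vl <- world_lab[keep]
    if (config$noise_sigma > 0)
      vp <- vp + matrix(rnorm(length(vp), 0, config$noise_sigma / scales[k]),
                        nrow(vp), 3)
    extra_p <- NULL; extra_c <- NULL
    if (config$dark_edge_fraction > 0) {
      for (j in seq_along(config$leaf_specs)) {
        lidx <- which(vl == .LABEL_LEAF0 + j)
        nd <- round(config$dark_edge_fraction * length(lidx))
        if (nd > 0L) {
          src <- vp[sample(lidx, nd, replace = TRUE), , drop = FALSE]
          extra_p <- rbind(extra_p, src +
                             matrix(rnorm(3 * nd, 0, 0.15), nd, 3))
          extra_c <- rbind(extra_c,
                           matrix(sample(5:45, 3 * nd, replace = TRUE),
                                  nd, 3))
        }
      }
    }
    if (config$outlier_fraction > 0) {
      no <- round(config$outlier_fraction * nrow(vp))
      if (no > 0L) {
        lo <- (bb_lo - dil) / scales[k]; hi <- (bb_hi + dil) / scales[k]
        extra_p <- rbind(extra_p,
                         cbind(runif(no, lo[1], hi[1]),
                               runif(no, lo[2], hi[2]),
                               runif(no, lo[3], hi[3])))
        extra_c <- rbind(extra_c,
                         matrix(sample(60:255, 3 * no, replace = TRUE),
                                no, 3))
      }
    }
    if (!is.null(extra_p)) {
      vp <- rbind(vp, extra_p)
      vc <- rbind(vc, extra_c)
      vl <- c(vl, rep.int(-1L, nrow(extra_p)))
    }
    views[[k]] <- point_cloud(vp, vc, vl)
  }
  pairwise <- vector("list", nv - 1L)
  for (k in seq_len(nv - 1L))
    pairwise[[k]] <- compose_transforms(invert_transform(cumulative[[k]]),
                                        cumulative[[k + 1]])
  rownames(sphere_centers) <- as.character(1:6)
  list(views = views,
       truth = list(true_pairwise_transforms = pairwise,
                    true_cumulative_transforms = cumulative,
                    true_view_scales = scales,
                    true_sphere_centers_world = sphere_centers,
                    true_sphere_labels = 1:6,
                    true_traits = true_traits,
                    leaf_truth = leaf_truth,
                    world_cloud = world,
                    visible_index = visible_index,
                    config = config))
}

#' Write a scene bundle to disk
#'
#' `view_0.ply .. view_{n-1}.ply`, ground-truth transforms as plain-text 4x4
#' matrices (`truth_transform_k.txt`, row-major, comment header), a sphere /
#' scale / trait truth table (`truth.json`) and the generating configuration
#' (`config.json`).
#'
#' @param scene result of [generate_scene()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_scene_bundle <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(scene$views))
    write_ply(scene$views[[k]], file.path(dir, sprintf("view_%d.ply", k - 1L)))
  for (k in seq_along(scene$truth$true_cumulative_transforms)) {
    tf <- scene$truth$true_cumulative_transforms[[k]]
    m <- rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
    path <- file.path(dir, sprintf("truth_transform_%d.txt", k - 1L))
    writeLines(c(sprintf("# view %d -> view 0 (row-major 4x4)", k - 1L),
                 apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                                collapse = " "))), path)
  }
  tr <- scene$truth$true_traits
  truth <- list(view_scales = scene$truth$true_view_scales,
                sphere_labels = scene$truth$true_sphere_labels,
                sphere_centers_world = scene$truth$true_sphere_centers_world,
                plant_height = tr$plant_height, crown_width = tr$crown_width,
                leaves = tr$leaves, leaf_truth = scene$truth$leaf_truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- scene$truth$config
  cfg$sphere_colors <- lapply(cfg$sphere_colors, unclass)
  cfg$leaf_specs <- lapply(cfg$leaf_specs, unclass)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  write_ply(scene$truth$world_cloud, file.path(dir, "world.ply"))
  invisible(dir)
}
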