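test_that("generate_scene is deterministic given its seed", {
  a <- small_scene(seed = 81, noise = 0.05, outliers = 0.02, dark = 0.05)
  b <- small_scene(seed = 81, noise = 0.05, outliers = 0.02, dark = 0.05)
  for (k in seq_along(a$views)) {
    expect_identical(a$views[[k]]$points, b$views[[k]]$points)
    expect_identical(a$views[[k]]$colors, b$views[[k]]$colors)
  }
  expect_identical(a$truth$true_view_scales, b$truth$true_view_scales)
})

test_that("scene_config validates fields by name", {
  expect_error(scene_config(pot_radius = -1), "pot_radius",
               class = "sricp_invalid")
  expect_error(scene_config(outlier_fraction = 1.2), "outlier_fraction",
               class = "sricp_invalid")
  expect_error(scene_config(n_views = 1), "n_views", class = "sricp_invalid")
  expect_error(scene_config(view_scales = c(1, 1)), "view_scales",
               class = "sricp_invalid")
})

test_that("noiseless views are exact rigid+scale images of the world", {
  sc <- small_scene(seed = 82, noise = 0)
  for (k in seq_along(sc$views)) {
    v <- sc$views[[k]]
    restored <- apply_transform(apply_scale(v, sc$truth$true_view_scales[k]),
                                sc$truth$true_cumulative_transforms[[k]])
    world_vis <- sc$truth$world_cloud$points[sc$truth$visible_index[[k]], ]
    expect_equal(restored$points, world_vis, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_identical(v$labels,
                     sc$truth$world_cloud$labels[sc$truth$visible_index[[k]]])
  }
})

test_that("noiseless per-view rim circle fit returns pot_radius / scale", {
  sc <- small_scene(seed = 83, noise = 0)
  cfgpot <- sc$truth$config
  for (k in seq_along(sc$views)) {
    v <- sc$views[[k]]
    pot <- pc_subset(v, v$labels == 100L)
    rz <- max(pot$points[, 3])
    ring <- slice_ring(pot, rz - 0.1, 0.1)
    fit <- fit_circle_2d(ring$points[, 1:2])
    expect_equal(fit$radius,
                 cfgpot$pot_radius / sc$truth$true_view_scales[k],
                 tolerance = 1e-6)
  }
})

test_that("sphere surface sampling is exact in radius and centered", {
  set.seed(84)
  s <- sample_sphere_surface(c(3, -2, 7), 2.5, 1000)
  r <- sqrt(rowSums(sweep(s$points, 2, c(3, -2, 7))^2))
  expect_lt(max(abs(r - 2.5)), 1e-12)
  expect_identical(nrow(sample_sphere_surface(c(0, 0, 0), 1, 0)$points), 0L)
  expect_error(sample_sphere_surface(c(0, 0, 0), 1, -5),
               class = "sricp_invalid")
  big <- sample_sphere_surface(c(1, 1, 1), 2, 1e5)
  expect_lt(sqrt(sum((colMeans(big$points) - c(1, 1, 1))^2)), 0.05 * 2)
})

test_that("labels are conserved and sphere points lie on their spheres", {
  sc <- small_scene(seed = 85, noise = 0)
  w <- sc$truth$world_cloud
  den <- sc$truth$config$densities
  counts <- table(w$labels)
  expect_equal(unname(counts[as.character(1:6)]), rep(den$sphere, 6),
               ignore_attr = TRUE)
  expect_equal(unname(counts[["101"]]), den$stem)
  for (lab in 1:6) {
    pts <- w$points[w$labels == lab, ]
    ctr <- sc$truth$true_sphere_centers_world[lab, ]
    expect_lt(max(abs(sqrt(rowSums(sweep(pts, 2, ctr)^2)) -
                        sc$truth$config$sphere_radius)), 1e-9)
  }
})

test_that("visibility culling yields partial (roughly hemispheric) markers", {
  full <- small_scene(seed = 86, noise = 0, culling = FALSE)
  cul <- small_scene(seed = 86, noise = 0, culling = TRUE)
  for (k in c(1, 4)) {
    n_full <- sum(full$views[[k]]$labels %in% 1:6)
    n_cul <- sum(cul$views[[k]]$labels %in% 1:6)
    expect_lt(n_cul, 0.75 * n_full)
    expect_gt(n_cul, 0.25 * n_full)
  }
})

test_that("dark edge points sit below the channel-50 threshold", {
  sc <- small_scene(seed = 87, noise = 0.02, dark = 0.1)
  v <- sc$views[[1]]
  extras <- v$labels == -1L
  expect_gt(sum(extras), 0)
  expect_true(all(v$colors[extras, ] < 50))
  # and the color filter removes exactly the unlabeled dark points
  cleaned <- color_filter(v)
  expect_false(any(cleaned$labels == -1L))
  expect_equal(n_points(cleaned), sum(!extras))
})

test_that("curved sample_leaf records chord < arc with the analytic chord", {
  set.seed(88)
  sp <- leaf_spec(0.5, 30, 10, length = 8, width = 3, curvature = 0.1)
  lf <- sample_leaf(sp, 500)
  expect_equal(lf$truth$arc_length, 8)
  expect_equal(lf$truth$chord_length, 2 * sin(0.1 * 8 / 2) / 0.1,
               tolerance = 1e-12)
  flat <- sample_leaf(leaf_spec(0.5, 0, 0, 8, 3, 0), 500)
  expect_identical(flat$truth$chord_length, 8)
  expect_error(sample_leaf(leaf_spec(0.5, 0, 0, -1, 3), 100),
               class = "sricp_invalid")
})

test_that("write_scene_bundle emits readable artifacts", {
  dir <- withr::local_tempdir()
  sc <- small_scene(seed = 89, noise = 0.02)
  write_scene_bundle(sc, dir)
  expect_true(all(file.exists(file.path(dir, sprintf("view_%d.ply", 0:5)))))
  v0 <- read_ply(file.path(dir, "view_0.ply"))
  expect_equal(v0$points, sc$views[[1]]$points, tolerance = 1e-6)
  m <- as.numeric(strsplit(readLines(
    file.path(dir, "truth_transform_2.txt"))[2], " ")[[1]])
  expect_equal(matrix(m[1:3], 1), sc$truth$true_cumulative_transforms[[3]]$rotation[1, , drop = FALSE],
               tolerance = 1e-12, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$view_scales, sc$truth$true_view_scales,
               tolerance = 1e-9)
})
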