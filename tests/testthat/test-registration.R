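test_that("match_centers pairs shared labels in ascending order", {
  a <- sphere_center_set(0, c(3, 1, 2, 5), matrix(1:12, 4, 3))
  b <- sphere_center_set(1, c(5, 2, 1, 4), matrix(13:24, 4, 3))
  m <- match_centers(a, b)
  expect_equal(m$labels, c(1, 2, 5))
  expect_equal(m$a, a$centers[match(c(1, 2, 5), a$labels), ])
  expect_equal(m$b, b$centers[match(c(1, 2, 5), b$labels), ])
  # identical sets: all pairs with zero displacement
  m2 <- match_centers(a, a)
  expect_equal(m2$a, m2$b)
  # fewer than 3 shared labels
  c2 <- sphere_center_set(2, c(1, 2, 9), matrix(1:9, 3, 3))
  d2 <- sphere_center_set(3, c(1, 2, 8), matrix(1:9, 3, 3))
  expect_error(match_centers(c2, d2), "at least 3",
               class = "sricp_precondition")
})

test_that("svd_rigid_transform recovers constructed rigid motions", {
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  ident <- svd_rigid_transform(src, src)
  expect_lt(max(abs(ident$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(ident$translation)), 1e-12)
  shift <- svd_rigid_transform(src, sweep(src, 2, c(1, 2, 3), `+`))
  expect_lt(max(abs(shift$rotation - diag(3))), 1e-12)
  expect_equal(shift$translation, c(1, 2, 3), tolerance = 1e-12)
  set.seed(61)
  for (i in 1:10) {
    tf <- random_rigid()
    pts <- matrix(rnorm(18), 6, 3)
    rec <- svd_rigid_transform(pts, apply_transform(pts, tf))
    expect_lt(max(abs(rec$rotation - tf$rotation)), 1e-10)
    expect_lt(max(abs(rec$translation - tf$translation)), 1e-10)
  }
  expect_error(svd_rigid_transform(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
                                   matrix(rnorm(9), 3, 3)),
               class = "sricp_degenerate")
})

test_that("svd_rigid_transform always returns a proper rotation", {
  set.seed(62)
  for (i in 1:20) {
    src <- matrix(rnorm(12), 4, 3)
    dst <- matrix(rnorm(12), 4, 3)  # unrelated: stresses reflection guard
    tf <- svd_rigid_transform(src, dst)
    expect_lt(max(abs(crossprod(tf$rotation) - diag(3))), 1e-9)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  }
})

test_that("build_chain composes in the documented order", {
  ids <- replicate(5, rigid_transform(), simplify = FALSE)
  ch <- build_chain(ids)
  expect_length(ch$cumulative, 6)
  for (tf in ch$cumulative) expect_lt(max(abs(tf$rotation - diag(3))), 1e-12)
  # 60-degree steps: cumulative[k+1] is rotation by 60k degrees
  step <- rotation_z(60, c(0.5, -0.2, 0.1))
  ch <- build_chain(replicate(5, step, simplify = FALSE))
  for (k in 0:5) {
    explicit <- rigid_transform()  # explicit matrix-product oracle
    for (j in seq_len(k)) explicit <- compose_transforms(explicit, step)
    expect_lt(max(abs(ch$cumulative[[k + 1]]$rotation - explicit$rotation)),
              1e-12)
    expect_equal(ch$cumulative[[k + 1]]$translation, explicit$translation,
                 tolerance = 1e-12)
    if (k > 0)
      expect_equal(rotation_angle_deg(ch$cumulative[[k + 1]]),
                   min(60 * k, 360 - 60 * k), tolerance = 1e-9)
  }
  # cumulative[3] equals the product R0 x R1 (view 2 -> 0 composite)
  p <- list(random_rigid(), random_rigid(), random_rigid(), random_rigid(),
            random_rigid())
  ch2 <- build_chain(p)
  expect_equal(ch2$cumulative[[3]]$rotation,
               p[[1]]$rotation %*% p[[2]]$rotation, tolerance = 1e-12)
  expect_error(build_chain(p[1:4]), class = "sricp_invalid")
})

test_that("icp_refine recovers a small perturbation and reports monotone RMSE", {
  set.seed(63)
  target <- make_sphere_cloud(radius = 4, n = 1200)
  perturb <- compose_transforms(rotation_z(5), rigid_transform(diag(3),
                                                               c(0.3, -0.3, 0.2)))
  source <- apply_transform(target, invert_transform(perturb))
  fit <- icp_refine(source, target, max_corr_dist = 5)
  expect_lt(fit$rmse, 1e-6)
  expect_true(all(diff(fit$rmse_history) <= 1e-12))
  expect_lte(fit$iterations, 100L)
  aligned <- apply_transform(source, fit$transform)
  expect_lt(max(abs(aligned$points - target$points)), 1e-4)
})

test_that("icp_refine degenerate contracts", {
  pc <- make_sphere_cloud(radius = 1, n = 200)
  ident <- icp_refine(pc, pc)
  expect_equal(ident$rmse, 0)
  expect_equal(ident$rmse_history[1], 0)
  expect_lt(max(abs(ident$transform$rotation - diag(3))), 1e-12)
  far <- point_cloud(sweep(pc$points, 2, c(1000, 0, 0), `+`))
  expect_error(icp_refine(far, pc, max_corr_dist = 1),
               class = "sricp_no_correspondence")
  expect_error(icp_refine(point_cloud(matrix(numeric(0), 0, 3)), pc),
               class = "sricp_precondition")
})

test_that("cloud_to_cloud_distance matches a brute-force oracle", {
  set.seed(64)
  ref <- random_cloud(400)
  test <- random_cloud(150)
  d <- cloud_to_cloud_distance(test, ref)
  # brute force all-pairs
  bf <- apply(test$points, 1, function(p)
    sqrt(min(colSums((t(ref$points) - p)^2))))
  expect_equal(d$mean, mean(bf), tolerance = 1e-12)
  expect_equal(d$std, sd(bf), tolerance = 1e-12)
  # identical clouds -> (0, 0); singleton -> (d, 0)
  same <- cloud_to_cloud_distance(ref, ref)
  expect_equal(same$mean, 0)
  expect_equal(same$std, 0)
  one <- cloud_to_cloud_distance(point_cloud(matrix(c(0, 0, 3), 1, 3)),
                                 point_cloud(matrix(0, 1, 3)))
  expect_equal(one$mean, 3)
  expect_equal(one$std, 0)
  # dense reference, uniform offset: mean bounded by the offset
  dense <- make_sphere_cloud(radius = 5, n = 1500)
  shifted <- point_cloud(sweep(dense$points, 2, c(0.1, 0, 0), `+`))
  expect_lte(cloud_to_cloud_distance(shifted, dense)$mean, 0.1 + 1e-12)
})

test_that("register_all recovers a noiseless synthetic scene exactly", {
  sc <- small_scene(seed = 65, noise = 0, scales = rep(1, 6))
  centers <- lapply(1:6, function(k)
    estimate_all_centers(sc$views[[k]], default_sphere_colors(),
                         ransac_config(rng_seed = k), view_index = k - 1L))
  reg <- register_all(sc$views, centers, use_icp = FALSE)
  for (k in 1:6)
    expect_transform_close(reg$chain$cumulative[[k]],
                           sc$truth$true_cumulative_transforms[[k]],
                           1e-4, 1e-4)
  # merged bounding box equals the ground-truth visible scene bounding box
  world_vis <- pc_subset(sc$truth$world_cloud,
                         sort(unique(unlist(sc$truth$visible_index))))
  expect_equal(apply(reg$merged$points, 2, range),
               apply(world_vis$points, 2, range), tolerance = 1e-4)
})

test_that("registration is left-invariant under a global rigid motion", {
  set.seed(66)
  sc <- small_scene(seed = 66, noise = 0, scales = rep(1, 6))
  centers <- lapply(1:6, function(k)
    estimate_all_centers(sc$views[[k]], default_sphere_colors(),
                         ransac_config(rng_seed = k), view_index = k - 1L))
  g <- random_rigid(t_scale = 3)
  views_moved <- lapply(sc$views, apply_transform, tf = g)
  centers_moved <- lapply(centers, function(s) {
    s$centers <- apply_transform(s$centers, g); s })
  reg0 <- register_all(sc$views, centers, use_icp = FALSE)
  reg1 <- register_all(views_moved, centers_moved, use_icp = FALSE)
  # per-view residuals against the (moved) reference are unchanged
  for (k in 2:6) {
    a0 <- apply_transform(sc$views[[k]], reg0$chain$cumulative[[k]])
    a1 <- apply_transform(views_moved[[k]], reg1$chain$cumulative[[k]])
    r0 <- cloud_to_cloud_distance(a0, sc$views[[1]])
    r1 <- cloud_to_cloud_distance(a1, views_moved[[1]])
    expect_equal(r1$mean, r0$mean, tolerance = 1e-8)
  }
})
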