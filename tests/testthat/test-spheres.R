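test_that("segment_spheres_by_color partitions exact color clusters", {
  specs <- default_sphere_colors()
  set.seed(41)
  parts <- lapply(specs, function(s) {
    n <- sample(20:40, 1)
    point_cloud(matrix(rnorm(3 * n), n, 3), s$rgb)
  })
  cloud <- concat_clouds(parts)
  subs <- segment_spheres_by_color(cloud, specs)
  expect_equal(vapply(subs, n_points, integer(1)),
               vapply(parts, n_points, integer(1)), ignore_attr = TRUE)
  expect_equal(sum(vapply(subs, n_points, integer(1))), n_points(cloud))
  # green foliage matches no marker spec
  foliage <- point_cloud(matrix(0, 50, 3), c(50, 160, 60))
  subs2 <- segment_spheres_by_color(foliage, specs[1:2])
  expect_true(all(vapply(subs2, n_points, integer(1)) == 0L))
})

test_that("segmentation recovers ground-truth labels on a noise-free scene", {
  sc <- small_scene(seed = 43, noise = 0)
  v <- sc$views[[1]]
  subs <- segment_spheres_by_color(v, default_sphere_colors())
  for (lab in 1:6) {
    truth_idx <- which(v$labels == lab)
    got <- subs[[as.character(lab)]]
    expect_equal(n_points(got), length(truth_idx))     # recall 1
    expect_true(all(got$points == v$points[truth_idx, , drop = FALSE]))  # precision 1
  }
})

test_that("sphere_from_4_points is exact and rejects coplanar samples", {
  s <- sphere_from_4_points(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(s$center, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(s$radius, 1, tolerance = 1e-12)
  expect_error(sphere_from_4_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                    c(1, 1, 0)), class = "sricp_degenerate")
  set.seed(44)
  for (i in 1:20) {
    dirs <- matrix(rnorm(12), 4, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    p <- sweep(dirs * 3, 2, c(5, 5, 5), `+`)
    s <- sphere_from_4_points(p[1, ], p[2, ], p[3, ], p[4, ])
    res <- abs(sqrt(rowSums(sweep(p, 2, s$center)^2)) - s$radius)
    expect_lt(max(res), 1e-9)
  }
})

test_that("dynamic_threshold reduces to t_base on uniform data and adapts", {
  set.seed(45)
  cloud <- make_sphere_cloud(radius = 2, n = 800)
  cfg <- ransac_config()
  t_uniform <- dynamic_threshold(c(0, 0, 0), 2, cloud, cfg)
  expect_equal(t_uniform, cfg$base_threshold, tolerance = 1e-9)
  # candidate far away -> empty shell -> fallback t_base
  t_far <- dynamic_threshold(c(100, 100, 100), 2, cloud, cfg)
  expect_identical(t_far, cfg$base_threshold)
  # sparse cap vs dense band: thresholds differ in the expected direction,
  # matching a brute-force spacing computation
  dense <- make_sphere_cloud(radius = 2, n = 1500)
  sparse_cap <- pc_subset(dense, dense$points[, 3] > 1.6)
  sparse_cap <- pc_subset(sparse_cap,
                          seq_len(n_points(sparse_cap)) %% 6 == 0)
  band <- pc_subset(dense, dense$points[, 3] <= 1.6)
  two <- concat_clouds(band, sparse_cap)
  # local shell around the cap region only: candidate centered so its
  # surface passes through the cap
  spacing <- apply(as.matrix(dist(two$points)), 1,
                   function(d) sort(d)[cfg$density_k + 1])
  t_cap <- dynamic_threshold(c(0, 0, 2.0), 0.35, two, cfg)
  shell <- abs(sqrt(rowSums(sweep(two$points, 2, c(0, 0, 2.0))^2)) - 0.35) <=
    2 * cfg$base_threshold
  expect_equal(t_cap, cfg$base_threshold *
                 min(max(median(spacing[shell]) / median(spacing),
                         cfg$threshold_clamp[1]), cfg$threshold_clamp[2]),
               tolerance = 1e-9)
  expect_gt(t_cap, cfg$base_threshold)
})

test_that("score_candidate matches an independent per-point recomputation", {
  set.seed(46)
  cloud <- make_sphere_cloud(center = c(1, 2, 3), radius = 2, n = 400,
                             noise = 0.03)
  sc <- score_candidate(c(1, 2, 3), 2, cloud, 0.08)
  res <- abs(sqrt(rowSums(sweep(cloud$points, 2, c(1, 2, 3))^2)) - 2)
  idx <- which(res <= 0.08)
  expect_identical(sc$inlier_indices, idx)
  mu <- mean(res[idx]); sig <- sd(res[idx])
  expect_equal(sc$weight, (length(idx) / 400) / (mu + sig + 1e-12),
               tolerance = 1e-12)
  expect_lt(max(res[sc$inlier_indices]), 0.08 + 1e-15)
  # no-inlier candidate scores zero
  far <- score_candidate(c(100, 0, 0), 1, cloud, 0.05)
  expect_identical(far$weight, 0)
  # zero-residual limit: weight at the 1/eps cap scale
  exact <- make_sphere_cloud(radius = 2, n = 100)
  w <- score_candidate(c(0, 0, 0), 2, exact, 0.1)$weight
  expect_gt(w, 0.9e12)
  expect_lte(w, 1e12)
})

test_that("fit_sphere_ransac is exact on clean spheres and errors on < 4 pts", {
  set.seed(47)
  cloud <- make_sphere_cloud(center = c(2, -1, 4), radius = 2, n = 500)
  fit <- fit_sphere_ransac(cloud, ransac_config(rng_seed = 1))
  expect_equal(fit$center, c(2, -1, 4), tolerance = 1e-6)
  expect_equal(fit$radius, 2, tolerance = 1e-6)
  expect_error(fit_sphere_ransac(point_cloud(matrix(rnorm(9), 3, 3))),
               class = "sricp_precondition")
})

test_that("fit_sphere_ransac is bit-reproducible given rng_seed", {
  set.seed(48)
  cloud <- make_sphere_cloud(radius = 2, n = 400, hemisphere = TRUE,
                             noise = 0.04, outlier_frac = 0.3)
  cfg <- ransac_config(rng_seed = 99, nominal_radius = 2)
  a <- fit_sphere_ransac(cloud, cfg)
  b <- fit_sphere_ransac(cloud, cfg)
  expect_identical(a, b)
})

test_that("noisy hemispheric fit agrees with an LM oracle on true inliers", {
  set.seed(49)
  r <- 2
  cloud <- make_sphere_cloud(center = c(1, 1, 1), radius = r, n = 500,
                             hemisphere = TRUE, noise = 0.02 * r,
                             outlier_frac = 0.3)
  fit <- fit_sphere_ransac(cloud, ransac_config(rng_seed = 5,
                                                nominal_radius = r))
  expect_lt(sqrt(sum((fit$center - c(1, 1, 1))^2)), 0.05 * r)
  # oracle: LM on the known surface points (first 500)
  oracle <- oracle_sphere_fit(cloud$points[1:500, ], c(1, 1, 1), r)
  expect_lt(sqrt(sum((fit$center - oracle$center)^2)), 0.05 * r)
})

test_that("widening the radius tolerance never lowers the best weight", {
  set.seed(50)
  cloud <- make_sphere_cloud(radius = 2, n = 300, hemisphere = TRUE,
                             noise = 0.03, outlier_frac = 0.2)
  weights <- sapply(c(0.05, 0.1, 0.3, 0.6), function(tol) {
    fit <- fit_sphere_ransac(cloud, ransac_config(rng_seed = 7,
                                                  nominal_radius = 2,
                                                  radius_tolerance = tol))
    fit$weight
  })
  expect_true(all(diff(weights) >= -1e-9))
})

test_that("geometric constraints reject implausible candidates with context", {
  set.seed(51)
  # points on a sphere of radius 5, nominal radius 1 with tight tolerance:
  # every candidate fails the radius window
  cloud <- make_sphere_cloud(radius = 5, n = 200)
  expect_error(
    fit_sphere_ransac(cloud, ransac_config(rng_seed = 3, nominal_radius = 1,
                                           radius_tolerance = 0.05)),
    "radius", class = "sricp_constraint")
})

test_that("estimate_all_centers needs >= 3 usable spheres and finds all six", {
  sc <- small_scene(seed = 52, noise = 0)
  v <- sc$views[[1]]
  truth <- apply_transform(
    sc$truth$true_sphere_centers_world,
    invert_transform(sc$truth$true_cumulative_transforms[[1]])) /
    sc$truth$true_view_scales[1]
  set <- estimate_all_centers(v, default_sphere_colors(),
                              ransac_config(rng_seed = 2), view_index = 0L)
  expect_setequal(set$labels, 1:6)
  for (i in seq_along(set$labels))
    expect_lt(sqrt(sum((set$centers[i, ] - truth[set$labels[i], ])^2)), 1e-6)
  # only two marker colors present -> error
  two <- pc_subset(v, v$labels %in% 1:2)
  expect_error(estimate_all_centers(two, default_sphere_colors(),
                                    ransac_config(rng_seed = 2)),
               class = "sricp_precondition")
})
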