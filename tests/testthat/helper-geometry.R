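# Shared fixtures, all generated in code under fixed seeds.

# random proper rotation from a random unit axis and angle
random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rigid <- function(t_scale = 10) {
  rigid_transform(orthonormalize(random_rotation()), rnorm(3, 0, t_scale))
}

# polish a rotation so it passes the 1e-9 constructor gates
orthonormalize <- function(R) {
  s <- svd(R)
  s$u %*% t(s$v)
}

# sphere test cloud: optional hemispheric coverage (z >= center z), Gaussian
# radial noise and uniform box outliers appended after the surface points
make_sphere_cloud <- function(center = c(0, 0, 0), radius = 2, n = 500,
                              hemisphere = FALSE, noise = 0,
                              outlier_frac = 0) {
  g <- matrix(rnorm(3 * n), n, 3)
  if (hemisphere) g[, 3] <- abs(g[, 3])
  dirs <- g / sqrt(rowSums(g^2))
  pts <- sweep(dirs * radius, 2, center, `+`)
  if (noise > 0) pts <- pts + matrix(rnorm(3 * n, 0, noise), n, 3)
  n_out <- round(outlier_frac * n)
  if (n_out > 0) {
    lo <- center - 2.5 * radius; hi <- center + 2.5 * radius
    pts <- rbind(pts, cbind(runif(n_out, lo[1], hi[1]),
                            runif(n_out, lo[2], hi[2]),
                            runif(n_out, lo[3], hi[3])))
  }
  point_cloud(pts)
}

random_cloud <- function(n, scale = 10) {
  point_cloud(matrix(runif(3 * n, -scale, scale), n, 3),
              matrix(sample(0:255, 3 * n, replace = TRUE), n, 3))
}

# independent LM sphere oracle on a fixed point set (stats::optim on the
# geometric SSE; used to cross-check the RANSAC+LM path)
oracle_sphere_fit <- function(points, start_center, start_radius) {
  obj <- function(p) {
    d <- sqrt(rowSums(sweep(points, 2, p[1:3])^2))
    sum((d - p[4])^2)
  }
  fit <- stats::optim(c(start_center, start_radius), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  list(center = fit$par[1:3], radius = fit$par[4])
}

expect_transform_close <- function(a, b, rot_tol_deg, trans_tol) {
  expect_lt(transform_rotation_error_deg(a, b), rot_tol_deg)
  expect_lt(sqrt(sum((a$translation - b$translation)^2)), trans_tol)
}

# small scene used by several module tests (cheap: thinned densities)
small_scene <- function(seed = 42, noise = 0, outliers = 0, dark = 0,
                        culling = TRUE, scales = NULL) {
  generate_scene(scene_config(
    rng_seed = seed, noise_sigma = noise, outlier_fraction = outliers,
    dark_edge_fraction = dark, visibility_culling = culling,
    view_scales = scales,
    densities = list(pot = 1200L, rim = 400L, sphere = 350L, stem = 200L,
                     leaf = 300L)))
}
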