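# Per-view scale calibration. SfM-MVS reconstructions carry an arbitrary
# global scale, so each view is rescaled from the fitted radius of the pot's
# top rim: slice a thin z-band at the rim, fit a circle to its XY projection,
# and scale every view so the fitted radii agree (and, given the known pot
# diameter, are metric).

#' Slice a horizontal ring out of a cloud
#'
#' Keeps points with `|z - z_center| <= z_halfwidth`, order preserved.
#'
#' @param cloud a [point_cloud()]
#' @param z_center slice center, cm
#' @param z_halfwidth positive half-thickness, cm
#' @return a [point_cloud()] (possibly empty)
#' @export
slice_ring <- function(cloud, z_center, z_halfwidth) {
  if (z_halfwidth <= 0)
    sricp_stop("z_halfwidth must be positive", "sricp_invalid")
  if (n_points(cloud) == 0L) return(cloud)
  pc_subset(cloud, abs(cloud$points[, 3] - z_center) <= z_halfwidth)
}

#' Least-squares circle fit in 2D
#'
#' Algebraic (Kasa) linear least-squares fit, followed by a Gauss-Newton
#' refinement of the geometric residuals `||p - c|| - r` (skipped with
#' `refine = FALSE`). Exact on noiseless circles.
#'
#' @param points M x 2 coordinate matrix, M >= 3, not all collinear
#' @param refine logical; run the geometric refinement (default TRUE)
#' @return list with `center` (length-2) and `radius`
#' @export
#' @examples
#' fit_circle_2d(rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1)))
fit_circle_2d <- function(points, refine = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    sricp_stop("circle fit needs at least 3 points", "sricp_degenerate")
  x <- points[, 1]; y <- points[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  qrA <- qr(cbind(x - mean(x), y - mean(y)))
  if (qrA$rank < 2L)
    sricp_stop("circle fit is degenerate: points are collinear",
               "sricp_degenerate")
  sol <- qr.coef(qr(A), x^2 + y^2)
  center <- sol[1:2]
  radius <- sqrt(max(sol[3] + sum(center^2), 0))
  if (refine) {
    # Gauss-Newton on (cx, cy, r); Kasa start is already close
    par <- c(center, radius)
    for (it in 1:30) {
      dx <- x - par[1]; dy <- y - par[2]
      d <- sqrt(dx^2 + dy^2)
      d[d < 1e-12] <- 1e-12
      res <- d - par[3]
      J <- cbind(-dx / d, -dy / d, -1)
      step <- tryCatch(qr.solve(crossprod(J), -crossprod(J, res)),
                       error = function(e) NULL)
      if (is.null(step)) break
      par <- par + as.numeric(step)
      if (max(abs(step)) < 1e-12) break
    }
    center <- par[1:2]; radius <- par[3]
  }
  list(center = as.numeric(center), radius = as.numeric(radius))
}

#' Locate the pot-rim z by histogram density peak
#'
#' The rim is the densest horizontal band of the pot cloud; this returns the
#' center of the modal bin of a z histogram, an automatable default for the
#' manual "crop the top of the pot" step.
#'
#' @param cloud a [point_cloud()] (ideally pre-restricted to the pot, e.g. by
#'   color)
#' @param z_range optional length-2 search window, cm
#' @param bin_width histogram bin width, cm (default 0.25)
#' @return z of the modal bin center, cm
#' @export
find_rim_z <- function(cloud, z_range = NULL, bin_width = 0.25) {
  z <- cloud$points[, 3]
  if (!is.null(z_range)) z <- z[z >= z_range[1] & z <= z_range[2]]
  if (length(z) == 0L)
    sricp_stop("no points in the rim search window", "sricp_precondition")
  breaks <- seq(min(z) - bin_width / 2, max(z) + bin_width, by = bin_width)
  h <- hist(z, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Per-view scale factors from fitted pot-rim radii
#'
#' Given fitted rim radii `gamma_i` for the six views and a reference view,
#' returns multipliers `s_i` such that `s_i * gamma_i = gamma_ref` for every
#' view (so `s_ref = 1` exactly). The raw ratios `mu_i = gamma_i / gamma_ref`
#' are attached as attribute `"mu"` as a diagnostic.
#'
#' @param gammas positive numeric vector of fitted rim radii (view units)
#' @param reference_index 0-based index of the reference view (default 2)
#' @return numeric vector of scale factors, with attribute `mu`
#' @export
#' @examples
#' compute_scale_factors(c(4, 2, 2, 2, 2, 2), reference_index = 2)
compute_scale_factors <- function(gammas, reference_index = 2L) {
  gammas <- as.numeric(gammas)
  if (any(!is.finite(gammas)) || any(gammas <= 0))
    sricp_stop("all gammas must be positive", "sricp_invalid")
  ref <- as.integer(reference_index)
  if (ref < 0L || ref >= length(gammas))
    sricp_stop("reference_index out of range", "sricp_invalid")
  gref <- gammas[ref + 1L]
  s <- gref / gammas
  s[ref + 1L] <- 1.0
  structure(s, mu = gammas / gref)
}

#' Metric scale factor from a known physical radius
#'
#' @param fitted_radius fitted rim radius in view units
#' @param known_radius true pot radius, cm
#' @return scalar multiplier `known_radius / fitted_radius`
#' @export
metric_scale_factor <- function(fitted_radius, known_radius) {
  if (!is.finite(fitted_radius) || fitted_radius <= 0 ||
      !is.finite(known_radius) || known_radius <= 0)
    sricp_stop("radii must be positive", "sricp_invalid")
  known_radius / fitted_radius
}

#' Uniformly scale a cloud about the origin
#'
#' Coordinates are multiplied by `factor`; colors and labels are untouched.
#' Any translation induced by scaling about the view-frame origin is absorbed
#' by the subsequent rigid registration.
#'
#' @param cloud a [point_cloud()]
#' @param factor positive scalar
#' @return scaled [point_cloud()]
#' @export
apply_scale <- function(cloud, factor) {
  if (!is.finite(factor) || factor <= 0)
    sricp_stop("scale factor must be positive", "sricp_invalid")
  cloud$points <- cloud$points * factor
  cloud
}

#' Per-view scale calibration record
#'
#' @param view_index 0-based view index
#' @param gamma fitted pot-rim radius in view units
#' @param scale_factor applied multiplier
#' @param ring_center XY center of the fitted rim circle
#' @return an object of class `view_scale_record`
#' @export
view_scale_record <- function(view_index, gamma, scale_factor, ring_center) {
  if (gamma <= 0 || scale_factor <= 0)
    sricp_stop("gamma and scale_factor must be positive", "sricp_invalid")
  structure(list(view_index = as.integer(view_index), gamma = gamma,
                 scale_factor = scale_factor,
                 ring_center = as.numeric(ring_center)),
            class = "view_scale_record")
}
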