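# End-to-end orchestration: preprocess -> scale calibration -> sphere
# centers -> SR coarse alignment -> ICP fine alignment -> merge -> traits.

#' Pipeline configuration
#'
#' Validation-first container for a full six-view run. Every nested config is
#' validated on construction; [run_pipeline()] additionally checks that all
#' input files exist before any computation.
#'
#' @param view_paths character vector of 6 PLY paths (views 0..5, in order)
#' @param out_dir output directory, or NULL to skip writing artifacts
#' @param preprocess a [preprocess_config()]
#' @param scale list: `reference_view` (0-based, default 2),
#'   `known_pot_diameter_cm` (NULL = common relative scale only),
#'   `slice_halfwidth_cm` (default 0.25), `rim_z` (fixed rim height per view,
#'   or NULL to auto-detect), `pot_color` (RGB used to restrict the rim
#'   search, or NULL), `pot_color_max_dist` (default 60)
#' @param sphere_specs list of [color_spec()]s for the six markers
#' @param ransac a [ransac_config()]
#' @param icp list of [icp_refine()] arguments plus `target` ("accumulated"
#'   or "view0") and `enabled`
#' @param traits list: `leaf_labels`, `reference_z` (NULL = scaled rim z)
#' @param seed global seed fanned out to the per-stage RNGs
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(view_paths, out_dir = NULL,
                            preprocess = preprocess_config(),
                            scale = list(), sphere_specs = default_sphere_colors(),
                            ransac = ransac_config(), icp = list(),
                            traits = list(), seed = 1L) {
  if (length(view_paths) != 6L)
    sricp_stop("exactly 6 view paths are required", "sricp_invalid")
  scale <- utils::modifyList(
    list(reference_view = 2L, known_pot_diameter_cm = NULL,
         slice_halfwidth_cm = 0.25, rim_z = NULL, pot_color = NULL,
         pot_color_max_dist = 60), scale)
  icp <- utils::modifyList(
    list(enabled = TRUE, target = "accumulated", max_iter = 100L,
         rmse_tol = 1e-8, max_corr_dist = NULL, sample_n = 2000L,
         adaptive_reject = TRUE), icp)
  traits <- utils::modifyList(list(leaf_labels = integer(0),
                                   reference_z = NULL), traits)
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(ransac, "ransac_config"))
  structure(list(view_paths = as.character(view_paths), out_dir = out_dir,
                 preprocess = preprocess, scale = scale,
                 sphere_specs = sphere_specs, ransac = ransac, icp = icp,
                 traits = traits, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full registration and phenotyping pipeline
#'
#' Stages: read and preprocess each view (color filter, optional crop,
#' statistical outlier removal); locate the pot rim and fit the rim circle
#' per view; rescale all views to the reference view's scale (and to metric
#' cm when the pot diameter is known); localize the six marker spheres per
#' view by enhanced RANSAC; compute the SR transform chain and refine by ICP;
#' merge; extract traits. Deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()]
#' @param views optional list of 6 [point_cloud()]s to use instead of reading
#'   `view_paths` (paths are then ignored)
#' @return list with `merged`, `chain`, `refined`, `traits`, `scale_records`,
#'   `centers`, `report` (list of per-stage diagnostics)
#' @export
run_pipeline <- function(config, views = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(views)) {
    missing <- config$view_paths[!file.exists(config$view_paths)]
    if (length(missing) > 0L)
      sricp_stop(sprintf("missing view file(s): %s",
                         paste(missing, collapse = ", ")),
                 "sricp_missing_file")
    views <- lapply(config$view_paths, read_ply)
  }
  if (length(views) != 6L)
    sricp_stop("exactly 6 views are required", "sricp_invalid")
  timing <- c()
  tick <- function(name) {
    now <- proc.time()[["elapsed"]]
    timing[[name]] <<- now - t0
    t0 <<- now
  }
  # -- preprocess -----------------------------------------------------------
  clean <- lapply(views, function(v) {
    v <- color_filter(v, config$preprocess)
    v <- crop_box(v, config$preprocess)
    if (n_points(v) > config$preprocess$outlier_k)
      v <- remove_outliers(v, config$preprocess)
    v
  })
  tick("preprocess")
  # -- scale calibration ----------------------------------------------------
  sc <- config$scale
  gammas <- numeric(6); rim_z <- numeric(6); ring_centers <- matrix(0, 6, 2)
  rim_top <- numeric(6)
  for (k in 1:6) {
    pot <- clean[[k]]
    if (!is.null(sc$pot_color)) {
      d <- sqrt(rowSums(sweep(pot$colors, 2L, as.numeric(sc$pot_color))^2))
      pot <- pc_subset(pot, d <= sc$pot_color_max_dist)
    }
    rz <- sc$rim_z %||% find_rim_z(pot)
    rim_z[k] <- rz
    # height datum: top edge of the pot, robust to the noise tail
    rim_top[k] <- stats::quantile(pot$points[, 3], 0.995, names = FALSE)
    ring <- slice_ring(pot, rz, sc$slice_halfwidth_cm)
    if (n_points(ring) < 3L)
      sricp_stop(sprintf("view %d: rim slice at z = %.3g has %d point(s)",
                         k - 1L, rz, n_points(ring)), "sricp_precondition")
    fit <- fit_circle_2d(ring$points[, 1:2, drop = FALSE])
    gammas[k] <- fit$radius
    ring_centers[k, ] <- fit$center
  }
  factors <- compute_scale_factors(gammas, sc$reference_view)
  metric <- if (!is.null(sc$known_pot_diameter_cm))
    metric_scale_factor(gammas[sc$reference_view + 1L],
                        sc$known_pot_diameter_cm / 2) else 1
  applied <- as.numeric(factors) * metric
  scaled <- mapply(apply_scale, clean, applied, SIMPLIFY = FALSE)
  scale_records <- lapply(1:6, function(k)
    view_scale_record(k - 1L, gammas[k], applied[k], ring_centers[k, ]))
  tick("scale")
  # -- sphere centers -------------------------------------------------------
  centers <- vector("list", 6L)
  for (k in 1:6) {
    cfg <- config$ransac
    cfg$rng_seed <- fan_out_seed(config$seed, paste0("ransac_view", k - 1L))
    centers[[k]] <- estimate_all_centers(scaled[[k]], config$sphere_specs,
                                         cfg, view_index = k - 1L)
  }
  tick("spheres")
  # -- registration ---------------------------------------------------------
  icp_args <- config$icp[setdiff(names(config$icp), c("enabled", "target"))]
  reg <- register_all(scaled, centers, icp = icp_args,
                      target = config$icp$target,
                      use_icp = isTRUE(config$icp$enabled))
  tick("register")
  # -- traits ---------------------------------------------------------------
  ref_z <- config$traits$reference_z %||% (rim_top[1] * applied[1])
  plant_mask <- reg$merged$labels >= 101L | reg$merged$labels %in%
    config$traits$leaf_labels
  plant <- if (any(plant_mask)) pc_subset(reg$merged, plant_mask) else
    reg$merged
  traits <- extract_traits(plant, config$traits$leaf_labels, ref_z)
  tick("traits")
  report <- list(timing_s = as.list(timing),
                 gammas = gammas, mu = attr(factors, "mu"),
                 scale_factors = applied, rim_z = rim_z,
                 sphere_weights = lapply(centers, function(s)
                   if (is.null(s$models)) NULL else
                     vapply(s$models, `[[`, numeric(1), "weight")),
                 icp = reg$report)
  out <- list(merged = reg$merged, chain = reg$chain, refined = reg$refined,
              traits = traits, scale_records = scale_records,
              centers = centers, report = report)
  if (!is.null(config$out_dir)) .write_pipeline_artifacts(out, config)
  out
}

.write_pipeline_artifacts <- function(out, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(out$merged, file.path(config$out_dir, "merged.ply"))
  for (k in seq_along(out$refined)) {
    tf <- out$refined[[k]]
    m <- rbind(cbind(tf$rotation, tf$translation), c(0, 0, 0, 1))
    writeLines(c(sprintf("# view %d -> view 0 (row-major 4x4)", k - 1L),
                 apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                                collapse = " "))),
               file.path(config$out_dir,
                         sprintf("transform_%d.txt", k - 1L)))
  }
  write_trait_report(out$traits, file.path(config$out_dir, "traits.tsv"))
  ctr_tab <- do.call(rbind, lapply(out$centers, function(s)
    data.frame(view = s$view_index, label = s$labels,
               x = s$centers[, 1], y = s$centers[, 2], z = s$centers[, 3])))
  utils::write.table(ctr_tab, file.path(config$out_dir, "sphere_centers.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(out$report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}
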