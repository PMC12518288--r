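# sricp — marker-based multi-view plant point-cloud registration and phenotyping

`sricp` turns six single-view, per-view-scaled colored point clouds of a
potted plant into one metric 3D model and measures it. It is written for
plant-phenotyping workflows in which each view (0°, 60°, …, 300° around the
plant) is reconstructed independently — e.g. by an offline SfM-MVS pipeline
fed by a stereo camera on a rotating arm — so the views disagree in scale,
carry dark edge noise and outliers, and see six colored calibration spheres
of known diameter placed on a ring around the plant.

The pipeline, stage by stage:

1. **Preprocess** — drop points with R, G, B all < 50 (dark edge noise),
   optional crop, statistical outlier removal (mean distance to k = 20
   nearest neighbors, cutoff mean + 2 sd).
2. **Scale calibration** — per view, fit a circle to a thin slice of the pot
   rim (Kåsa least squares + Gauss–Newton polish); with fitted radii
   γ₀..γ₅ and reference view 2, apply sᵢ = γ_ref/γᵢ so all rims agree, and
   known_radius/γ_ref to make the model metric.
3. **Sphere localization** — per marker color, an enhanced RANSAC sphere
   fit: dynamic inlier threshold t = t_base·clamp(local/global spacing,
   0.5, 2), weighted consensus w = (|inliers|/|P|)/(μ+σ+ε), geometric
   constraints (radius window, center range) on the top-K candidates,
   Levenberg–Marquardt refinement on the inliers.
4. **Self-registration (SR)** — homonymous (same-label) sphere centers in
   adjacent views give pairwise rigid transforms by SVD (Kabsch, reflection
   guarded); chaining maps every view into the 0° frame (the 120° view goes
   through the product of the first two pairwise transforms).
5. **ICP fine alignment** — point-to-point, max 100 iterations, stop when
   the RMSE change ≤ 1e−8, against the accumulated reference.
6. **Traits** — plant height above the pot rim, crown width (diameter of
   the XY convex hull), and per-leaf length/width as the euclidean distance
   between the two actual cloud points with extreme projections on the
   leaf's first/second principal axes.

A synthetic multi-view scene generator (`generate_scene()`) emulates the
whole rig — pot, marker ring, parametric plant with flat and curved leaves,
per-view scale drift, hemispheric marker visibility, Gaussian noise, dark
edge points, outliers — with complete ground truth (transforms, scales,
centers, traits), so the entire pipeline is validated without any real scan.

## Worked example

```r
library(sricp)

scene <- generate_scene(scene_config(rng_seed = 1))   # 6 views + ground truth
res <- run_pipeline(
  pipeline_config(
    view_paths = rep("in-memory", 6),
    scale  = list(known_pot_diameter_cm = 16, pot_color = c(180, 110, 80)),
    ransac = ransac_config(nominal_radius = 2),
    traits = list(leaf_labels = 201:204), seed = 1),
  views = scene$views)

res$traits
#> <trait_report: height 30.013 cm, crown 15.170 cm (datum z = 12.036)>
#>   leaf 201: length 9.184 cm, width 3.779 cm
#>   leaf 202: length 8.134 cm, width 3.525 cm
#>   leaf 203: length 7.167 cm, width 3.045 cm
#>   leaf 204: length 6.166 cm, width 2.704 cm

round(res$report$scale_factors, 4)       # recovered per-view scales
#> [1] 1.0735 0.9507 1.0347 0.9542 0.9173 1.0187
round(scene$truth$true_view_scales, 4)   # truth
#> [1] 1.0726 0.9500 1.0349 0.9537 0.9169 1.0185

cloud_to_cloud_distance(res$merged, scene$truth$world_cloud)$mean
#> [1] 0.0785   # cm, under 0.05 cm surface noise
```

Ground truth for the same scene: height 29.991 cm, crown 15.016 cm, leaf
lengths 8.99/7.92/7.00/5.94 cm — the estimates land within the noise-driven
tolerances discussed in the methods vignette; the maximum cumulative
rotation error of the recovered view transforms is 0.027°.

On files rather than in-memory clouds: point `view_paths` at six PLY files
(`element vertex` with `x y z`, optional `red green blue` and `label`
properties) and set `out_dir` to persist the merged model, per-view 4×4
transforms, sphere-center table, trait table and run report.

## Command line

```sh
inst/cli/sricp synth --seed 7 --out scene/        # synthetic bundle + truth
inst/cli/sricp register --views v0.ply,...,v5.ply --known-pot-diameter 16 --out run/
inst/cli/sricp spheres --cloud view_0.ply --nominal-diameter 4
inst/cli/sricp traits --cloud merged.ply --leaf-labels 201,202 --reference-z 12
inst/cli/sricp evaluate --test merged.ply --reference world.ply
```

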