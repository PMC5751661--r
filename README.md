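# abruptcut

Quantitative scoring of **abrupt border cutoff** in dermoscopy images of
pigmented skin lesions. A lesion whose pigment pattern terminates sharply at
its border is more likely malignant than one that fades gradually into the
surrounding skin; clinicians score this sign by eye over eight radial
sectors, which is slow and subjective. `abruptcut` computes it from a lesion
image and its binary segmentation mask, and is aimed at researchers building
or evaluating dermoscopy decision-support pipelines.

## Method

Given a binary mask (foreground = lesion):

1. **Boundary tracing.** The boundary is extracted as a Freeman 8-direction
   chain code `(start pixel, codes in 0–7)`, starting from the row-major
   minimal foreground pixel, with code 0 = east and codes increasing
   counter-clockwise.
2. **Level-set border contraction.** The border is embedded as the zero
   level of a signed distance field φ(x, y, t) (negative inside) and moved
   inward at constant unit speed by solving the Hamilton–Jacobi equation

   φ_t − ‖∇φ‖ = 0

   with the first-order Osher–Sethian upwind scheme (dt = 0.5). The upwind
   discretization enforces the entropy condition, so the contracted curve
   never self-intersects even where the naive normal offset
   X_L(s) = X_0(s) − L·N(s) develops shocks (concavities whose curvature
   radius is smaller than L). Because the speed is constant, the evolved
   zero level equals the distance-transform iso-curve, which the package
   also exposes as a fast path (`method = "distance"`); the two agree to
   sub-pixel tolerance.
3. **Peripheral texture features.** The annulus between the original and
   contracted borders (contraction distance L = 2r) is tiled with
   overlapping circles of radius r ∈ {5, 7, 10, 15} centered on the
   mid-curve at arc-length spacing r. Per patch and per channel the package
   computes GLCM homogeneity Σᵢⱼ GLCM(i, j)/(1 + |i − j|) (32 gray levels,
   offset (Δx, Δy) = (1, 0), symmetric, normalized), the color mean and the
   population standard deviation; aggregating each by mean and min over
   patches gives 18 features for RGB or HSV and 36 for RGB+HSV. Sharp
   pigment cutoffs leave high-contrast texture in the periphery and hence
   **low** homogeneity; gradual fades give **high** homogeneity.
4. **Classification.** A single-hidden-layer perceptron (ReLU, hidden width
   = input width), a fully connected 4 × 4 multi-hidden-layer network with
   softmax output, and a degree-3 polynomial-kernel SVM are evaluated under
   stratified 10-fold cross-validation repeated 10 times (learning rate
   0.001, at most 1000 epochs, epoch-improvement stop tolerance 0.001,
   standardized features), reporting precision, recall, sensitivity,
   specificity and f1.

A seeded synthetic-lesion generator (`generate_lesion()`,
`generate_cohort()`) produces irregular star-convex lesions whose border is
either an abrupt step or a gradual fade, so the whole pipeline is testable
without any dermoscopy dataset.

## Worked example

```r
library(abruptcut)

les <- generate_lesion(lesion_spec(edge_profile = "abrupt", seed = 3))
res <- contract_border(les$mask, distance_L = 20)
res
#> Level-set border contraction: L = 20 px ( distance method ), 1 contracted loop(s), 8019 annulus pixels

fv <- extract_features(les$image, res, radius_r = 10, color_space = "RGB")
round(fv$values[1:6], 3)
#> R_mean_homogeneity  R_min_homogeneity     R_mean_colmean      R_min_colmean
#>              0.572              0.506            112.102             70.982
#>      R_mean_colstd       R_min_colstd
#>             39.567             23.465
```

The `R_min_homogeneity` of 0.51 is the least homogeneous peripheral patch
in the red channel — low, because this lesion's pigment texture runs at
full contrast right up to the border. The same statistic for a
gradual-border lesion (`lesion_spec(edge_profile = "gradual", seed = 103)`)
comes out at 0.598. Cohort-level classification:

```r
co  <- generate_cohort(30, 30, seed = 5)
cfg <- pipeline_config(radii = 10, color_spaces = "RGB", n_runs = 3)
tab <- run_extract(co, cfg)
run_evaluate(tab, config = cfg)
#>  radius color_space classifier precision recall sensitivity specificity f1
#>      10         RGB mlp_single         1  1.000       1.000           1  1
#>      10         RGB  mlp_multi         1  0.967       0.933           1  1
#>      10         RGB        svm         1  1.000       1.000           1  1
```

At the generator's default class contrast the synthetic task is easy and
all three classifiers sit at or near ceiling; lowering the edge-profile
separation (narrower gradual fades, more noise) moves them off it.

## Command line

```sh
Rscript inst/cli/abruptcut.R synth    --n-benign 100 --n-malignant 100 --seed 1 --out cohort/
Rscript inst/cli/abruptcut.R features --in cohort/ --radii 10 --color-spaces RGB --out features.csv
Rscript inst/cli/abruptcut.R evaluate --features features.csv --classifier mlp-multi,svm \
                                      --radius 10 --color-space RGB --out report.json
```
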