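# hmir — multimodal human motion intention recognition

`hmir` classifies short RGB-D motion sequences into intention/condition
categories relevant to rehabilitation monitoring — e.g. a fall-like global
translation, a cough-like localized head/torso oscillation, or a held
stretch. It is aimed at researchers building activity-recognition pipelines
from paired intensity and depth video who want every stage to be testable
offline: the package ships a synthetic articulated stick-figure generator
that renders class-labeled skeletons, silhouettes, depth maps and optical
flow, so the complete pipeline runs without any external dataset.

## What the pipeline computes

1. **Preprocessing** — keyframe selection by inter-frame histogram variation
   (score `Σ_k (H_i(k) − H_{i−1}(k))²`, top-20 frames by default), median
   filtering for intensity frames, bilateral filtering for depth, min-max /
   z-score normalization, and connected-component ROI extraction.
2. **Segmentation** — geometric active-contour level sets for intensity
   frames, `φ_t = g(μκ + v)|∇φ| + λ∇g·∇φ` with edge indicator
   `g = 1/(1 + |∇I|²)`, evolved in a narrow band with periodic
   signed-distance reinitialization; depth silhouettes come from
   moments-based affine canonicalization plus Otsu-thresholded depth
   gradients `|∇D|` with border flood fill.
3. **Skeletonization** — pose-landmark assembly (14 joints including the
   computed neck, the shoulder midpoint) and, on the depth side, geodesic
   skeletonization: a k-nearest-neighbor graph over the 2.5D point cloud,
   Dijkstra geodesics `g(a,b) = Σ_{E∈P(a,b)} w(E)` from a torso source,
   iterated extremity detection via zero-weight edge insertion, path-based
   body-part labeling, and kinematic joint fitting at uniform geodesic arc
   lengths.
4. **Seven feature families** — kinetic energy
   `E = Σ_i ½ m_i v_i² + ½ k_i m_i r_i² ω_i²`; magnitude-weighted histograms
   of optical flow `H_k = Σ_p M_p δ(θ_p ∈ bin k)`; joint angles from clamped
   dot products; Freeman chain-code "eight round angles" of the silhouette
   contour; 2.5D point-cloud dynamics (velocity, acceleration, curvature
   `κ = ‖v × a‖/‖v‖³`); random occupancy patterns over a seeded voxel
   sample; and movement polygons (centroid distance profile `d_θ` over 360°
   plus the 20-value most-moving-joint trajectory).
5. **Feature optimization** — the concatenated feature vector is reduced by
   a supervised linear projection trained with mini-batch SGD
   (`θ ← θ − η·ḡ`, η = 0.01, batch 32, ≤100 epochs, early stopping) with an
   L1 penalty; a top-k selection mode is also provided.
6. **Classification** — a deep neuro-fuzzy classifier: generalized-bell
   memberships `μ(x) = 1/(1 + |(x − c)/σ|^{2m})`, product-T-norm rule
   strengths, two stacked rule banks with normalized strengths feeding the
   next layer, and weighted-average defuzzification
   `y_c = Σ_k μ_k w_{kc} / Σ_k μ_k`; trained end to end by backpropagated
   MSE with Adam (lr 0.001, 10 rules, m = 2, σ₀ = 0.5, L2 0.01).

## Worked example

```r
library(hmir)

specs <- default_class_specs(n_frames = 12)          # 3 motion classes
ds     <- make_dataset(specs, n_per_class = 6, seed = 42)
blocks <- lapply(ds$sequences, sequence_features, rop_seed = 42)
X      <- assemble_features(blocks)
attr(X, "layout")
#>   ke  hof  agf  era pc25  rop   mp
#>   12   88   96   96   40 1536  380

proj <- fit_projection(X, ds$labels, p = 32, seed = 42)
proj
#> <hmir_projection: 2248 -> 32 (projection), 3 classes, 100 epochs>

fit <- neurofuzzy(predict(proj, X), ds$labels, seed = 42)
fit
#> Deep neuro-fuzzy classifier: 2 layer(s) x 10 rules, m = 2
#>   classes: fall_like, cough_like, static_stretch
#>   trained 100 epochs (final train loss 0.26, val loss 0.2367)

table(truth = ds$labels, predicted = predict(fit, predict(proj, X)))
#>                 predicted
#> truth            fall_like cough_like static_stretch
#>   fall_like              6          0              0
#>   cough_like             0          6              0
#>   static_stretch         0          0              6
```

The layout line shows each feature family's width (here 12 frames per
sequence); the confusion matrix shows the three synthetic motion classes
are recovered exactly on this training set. `vignettes/hmir-methods.Rmd`
explains the model choices, tunable parameters and limitations.

A thin command-line front end mirrors the library
(`Rscript inst/cli/hmir.R synth --seed 4 --out data/`); see `?hmir_cli`.

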