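# macde

Segmentation of 2-D grayscale images by **multiple active contours
guided by differential evolution** over a polar coordinate system,
with the classical greedy snake as a baseline, validation metrics, and
synthetic phantoms with exact ground truth.

## The method

A snake segments an object by minimizing internal (shape) plus
external (image) energy over a closed curve of control points
(snaxels),

```
E_int = 1/2 [ α |q_i − p_{i−1}|² + β |p_{i−1} − 2 q_i + p_{i+1}|² ]
E_ext = −(γ/2) |∇I(q_i)|²    (or  γ · D(q_i)  on a distance map)
```

The classical greedy solver moves each snaxel within a small window
and is prone to local minima: it bridges boundary concavities and
depends on its initialization. This package implements a sectional,
population-based alternative:

1. **Preprocess**: 3×3 median filter → Canny edges (σ = 1.3,
   hysteresis 10/30 on the raw Sobel magnitude) → exact Euclidean
   distance map (EDM). The EDM is zero on detected edges and grows
   with distance from them — a potential surface whose minima trace
   the boundary.
2. **Polar sections**: a user seed point `(x, y)` inside the object
   anchors `floor(360/dg)` angular wedges (default `dg = 15`, 24
   sections).
3. **One DE population per section**: individuals are polar points
   `(r, θ)` confined to the wedge and a radial band, initialized from
   `n_snakes` concentric contours, and evolved by rand/1/bin
   differential evolution (`G = 10`, `F = 0.1`, `CR = 0.8`) on the
   EDM external energy.
4. **Assembly**: the best individual of each section becomes one
   snaxel; snaxels ordered by angle form the closed result. One seed
   point can be reused across an ordered stack of slices.

Validation uses the Jaccard index `J = |A∩B| / |A∪B|`, the Dice index
`D = 2|A∩B| / (|A|+|B|)` and the (directed or symmetric) Hausdorff
distance `H(A,B) = max_{a∈A} min_{b∈B} ||a−b||`.

## Worked example

```r
library(macde)

ph  <- make_star()                              # 160x160, exact mask
res <- run_macde(ph$image, seed_point = c(80, 80),
                 config = macde_config(), rng_seed = 1)
nrow(res$contour)                               # 24 snaxels, one per 15-deg wedge
#> [1] 24
mask <- rasterize_contour(res$contour, c(160, 160))
dice_index(mask, ph$mask)
#> [1] 0.9539535

acm <- run_acm(ph$image, c(79.5, 79.5), radius = 70, n_points = 42)
dice_index(rasterize_contour(acm$contour, c(160, 160)), ph$mask)
#> [1] 0.7253069
```

The sectional optimizer follows the star's concavities (Dice 0.95);
the greedy 42-point snake bridges them (Dice 0.73) — the classical
concavity failure. `res$metadata` records every parameter and the
master seed; `rerun_from_metadata()` replays a run bit-for-bit.

The same functions are scriptable from a shell:

```sh
Rscript inst/cli/macde.R phantom --kind star --out ph/
Rscript inst/cli/macde.R segment --input ph/image.png \
    --seed-x 80 --seed-y 80 --dg 15 --snakes 15 --rng-seed 42 --out seg/
Rscript inst/cli/macde.R eval --pred seg/mask.png --ref ph/mask.png
```

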