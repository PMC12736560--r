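# tubulemorph

Morphometry of microtubule bundles from single-molecule localization
microscopy (dSTORM/SMLM), with the companion confocal quantifications.

## The problem

Cortical microtubules (MTs) in growing pollen tubes associate laterally
into bundles; perturbations of the plasma-membrane sterol composition
shift the balance between thick bundles and single MTs. Diffraction-
limited microscopy cannot resolve this: a single MT has an outer diameter
of ~25 nm, and bundles of a few MTs are 50–100 nm wide. dSTORM produces a
*localization table* — a list of single-fluorophore positions with
nanometre precision — from which tubule widths can be measured directly.

`tubulemorph` implements the full analysis chain for such experiments:

1. **Reconstruction** — bin the localization list into a 2D count
   histogram at a chosen pixel size (20 nm, the conventional STORM
   rendering resolution).
2. **Segmentation** — enhance elongated structures with the multi-scale
   Hessian (Frangi) vesselness filter and binarize by global
   thresholding. For eigenvalues `|λ1| ≤ λ2|` of the scale-normalized
   Hessian, blobness `R_b = λ1/λ2` and structureness
   `S = √(λ1² + λ2²)`, the per-scale response at bright ridges (λ2 < 0)
   is

   `V = exp(−R_b²/2β²) · (1 − exp(−S²/2c²))`,

   maximized over scales σ ∈ {1, 1.5, 2} px with β = 0.5.
3. **Skeleton morphometry** — thin the mask (Zhang–Suen), split the
   skeleton into branches at junction pixels, keep straight
   (chord/path ≥ 0.9) elements, rotate the *localization list* of each
   element into grid alignment, re-render at a finer pixel (5 nm), and
   measure width, length and intensity by pixel counting. Width is the
   full-width-at-half-maximum of the transverse count profile, in
   pixels.
4. **Statistics** — compare per-condition width and intensity
   distributions with the Kruskal–Wallis rank test (χ² approximation, or
   the exact permutation null for small samples) and build normalized
   histograms.
5. **Confocal quantifications** — 3D Manders colocalization coefficients
   M1/M2, ROI percent-volume ("full object" low threshold vs
   structure-specific threshold) and mean intensity over medial planes.

A synthetic-data module generates ground-truthed localization tables
(tubules of known diameter, labeling density, localizations per emitter,
localization precision, background) and two-channel confocal stacks with
a controllable colocalized fraction, so every stage is testable without
any external data.

## Worked example

Two simulated conditions mimic the biology: a bundle-rich control (70 %
bundles of 50–100 nm, 30 % single 25-nm MTs) and a sterol-depleted-like
"treated" condition with the proportions reversed, 200 tubules each:

```r
library(tubulemorph)

cfg <- list(
  conditions = list(
    control = list(simulate = list(n_tubules = 200,
                                   diameters = c(25, 50, 75, 100),
                                   diameter_probs = c(0.3, 0.7/3, 0.7/3, 0.7/3))),
    treated = list(simulate = list(n_tubules = 200,
                                   diameters = c(25, 50, 75, 100),
                                   diameter_probs = c(0.7, 0.3/3, 0.3/3, 0.3/3)))),
  reconstruction = list(pixel_size = 20),
  morphometry    = list(measure_pixel_size = 5),
  stats          = list(bin_edges = seq(0, 160, by = 20)),
  seed = 7)

res <- run_pipeline(cfg)
res$width_test
#> Kruskal-Wallis: H = 51.8698, df = 1, p = 5.931e-13 (chisq; n = 309, 207)
round(res$width_dist$probability[, 2:6], 3)
#>         [20,40) [40,60) [60,80) [80,100) [100,120)
#> control   0.084   0.291   0.181    0.168     0.269
#> treated   0.411   0.184   0.150    0.164     0.092
tapply(res$records$width_nm, res$records$condition, median)
#> control treated
#>      75      50
```

The width distributions differ (Kruskal–Wallis p ≈ 6e-13); the treated
condition has five times the control's probability of single-MT widths
(the 20–40 nm bin) and a lower median width — the qualitative signature
of reduced MT bundling. `res$records` holds one row per measured tubule
element (width, length, localization count, straightness, orientation),
and `res$report` records every parameter used.

Confocal side, on simulated ground truth:

```r
st <- simulate_confocal_stack(confocal_spec(fraction_colocalized = 0.5,
                                            n_structures = 10, seed = 6))
manders_coefficients(st$channel_a, st$channel_b)   # M1, M2 near 0.5
```

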