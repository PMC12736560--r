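---
title: "Measuring microtubule bundle widths from SMLM localizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring microtubule bundle widths from SMLM localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tubulemorph)
```

## The measurement problem

Single-molecule localization microscopy turns a labelled microtubule
into a cloud of points: each detected fluorophore contributes one record
with nanometre coordinates and a localization precision. A single
microtubule is a hollow cylinder of ~25 nm outer diameter; lateral
association into bundles produces structures 50–100 nm wide. The
pipeline's job is to turn per-condition localization tables into a
distribution of tubule widths (and lengths and intensities) that can be
compared between a control and a perturbed condition.

The chain is: histogram reconstruction → Frangi vesselness → global
threshold → skeleton → branches → straight-element selection → per-element
rotation and re-rendering → pixel-counting morphometry → Kruskal–Wallis
comparison. This vignette explains each stage's model, its tunable
parameters, and the design decisions that were genuinely open.

## The synthetic-data model

`simulate_tubule_field()` emulates the statistical structure the
analysis assumes, not the photophysics:

* **Emitters** are a Poisson process along each tubule centerline with
  rate `labeling_density` (emitters/nm). The default 0.05 /nm with a
  mean of 4 localizations per emitter gives 0.2 localizations per nm of
  filament — a deliberately conservative density for indirect
  immunolabelling, so that anything shown to work here has headroom on
  denser real data.
* **Cross-section**: each emitter sits at a uniformly random transverse
  offset in `[-d/2, +d/2]` — a filled projected cylinder. Antibody
  geometry (primary + secondary adds ~10–15 nm of linkage error in real
  dSTORM) is deliberately not modelled; widths here estimate the
  *generator's* outer diameter, and a real experiment measures diameter
  plus linkage broadening.
* **Localizations** per emitter are Poisson distributed; each is
  displaced by isotropic Gaussian error (`loc_precision_sigma`, default
  2 nm — the scale of a bright dSTORM detection). Background
  localizations are uniform over the field.
* **Bundles** are a single tubule of larger outer diameter, because the
  pipeline reads out width only. Their labeling density is scaled by
  `diameter / 25` in `random_tubule_field()`: a bundle of k laterally
  associated microtubules presents about k times the tubulin epitopes
  per nm. This matters only for the intensity readout — width recovery
  is insensitive to it.
* **Determinism**: one RNG stream per call, seeded from the spec; draws
  happen in a documented fixed order (per tubule: emitter count, arc
  positions, offsets, per-emitter counts, x noise, y noise; then
  background; then frames/photon counts), so refactoring that preserves
  the order preserves every table bitwise.

What the generator does *not* emulate: blinking kinetics and duty
cycles, drift, multi-emitter fitting artifacts, curved tubules (the
layout helper draws straight ones), tubule crossings, and the antibody
linkage above. Tests passing on this generator therefore demonstrate
that the *estimator* is unbiased and monotone under the stated noise
model — not that real pollen-tube images are free of segmentation
errors.

The confocal generator (`simulate_confocal_stack()`) draws in-plane
filament-like structures (dilated segments) with a minimum pairwise
separation so supports are disjoint; a chosen fraction of channel-A
structures also carries channel-B signal. With PSF and noise disabled
the ground-truth colocalized signal fraction equals the Manders M1
exactly, which anchors the recovery tests.

## Reconstruction conventions

Pixels are half-open squares `[k·px, (k+1)·px)`; index = `floor(coord /
px)`, origin at the extent corner, x right, y down. The default
rendering pixel is 20 nm, the conventional STORM resolution figure.
Rotation always acts on the continuous localization list and the image
is re-rendered afterwards — never image resampling — so no
interpolation bias enters the width measurement. A quarter-turn about a
square extent's centre therefore permutes pixel counts exactly, which
the tests check.

## Vesselness and thresholding

The Hessian is computed by separable correlation with sampled
Gaussian-derivative kernels, truncated at 4σ, with reflective (half-
sample symmetric) boundary padding. The kernels are calibrated to exact
discrete moments (the smoother sums to 1; the second-derivative kernel
has zero sum, zero first moment and second moment 2), so quadratic
images produce their analytic second derivatives to rounding error —
without this, sampled kernels leak a signal-dependent bias of order
1 %. γ-normalization multiplies by σ² (γ = 2) to make scales
comparable before the maximum.

Defaults: σ ∈ {1, 1.5, 2} px (tubule widths of 1–4 px at the 20 nm
rendering), β = 0.5 (the usual blobness weight), and `c` = half the
maximum Frobenius norm S per scale. Numerically flat images (max S at
rounding-error level) return zero vesselness rather than amplifying
noise.

Global thresholding defaults to Otsu, implemented exhaustively over
midpoints of adjacent sorted unique values (the classical 256-bin
histogram version is a quantized approximation of this; the test suite
cross-checks both against an independent within-class-variance
oracle). One property of Otsu on SMLM vesselness maps deserves
emphasis: these maps are zero-inflated (most of the field is empty),
and the Otsu threshold then tends to sit high inside the response
distribution, which fragments dim ridges into short skeleton branches.
The pipeline is designed so this costs yield, not accuracy — the width
estimator below does not read the mask — but users segmenting very
sparse fields may prefer `threshold = "fixed"` with a small value,
which keeps ridges contiguous.

## Branch selection

Junction pixels are skeleton pixels with more than two 8-connected
neighbours; branches are maximal junction-free paths, with diagonal
steps counted as √2. Straightness is endpoint chord over path length.
The selection default is `min_straightness = 0.9`, not a stricter
value, for a geometric reason: an *ideal digital straight line* at an
orientation between the axis and the diagonal has chord/path as low as
≈ 0.92 (the chain-code length of a line at angle θ overestimates its
true length by the factor cos θ + (√2−1) sin θ). A cutoff of 0.95 would
silently discard perfectly straight tubules at intermediate
orientations — an orientation-dependent selection bias — which the
implementation exposed and the default avoids. Minimum branch length is
5 reconstruction pixels.

## Width measurement

Each selected branch is rotated into grid alignment and re-rendered at
`measure_pixel_size` (5 nm in the calibration tests; the coarser
default equals the reconstruction pixel). Two details proved essential:

* **Alignment refinement.** The branch's principal-axis angle is
  quantized by the skeleton staircase (errors of several degrees for
  short branches). A residual tilt φ smears the transverse profile by
  `window length × sin φ`. After the coarse rotation, the orientation
  is refined by fitting a line to the windowed localizations (two
  passes, each capped at 0.35 rad), which is the step that makes the
  local orientation "correct" rather than approximate.
* **The profile, not the mask.** Width is read from the rotated
  reconstruction itself: the transverse localization-count profile,
  pooled over all window columns. The plateau level is estimated by
  the median nonzero row of the raw profile (robust both to Poisson
  overshoot of the single peak row and to localization-error tails);
  the profile is then smoothed with a 3-row moving average (suppresses
  Poisson dropout of dim rows in wide bundles without moving a
  half-maximum edge crossing) and the width is the number of rows at or
  above half the plateau, times the pixel size. For a filled projected
  cylinder the full-width-at-half-maximum equals the true diameter, so
  the estimator is unbiased by construction; the thresholded vesselness
  mask, by contrast, traces the *ridge response*, whose above-threshold
  extent is systematically narrower than the structure (the response
  decays from the crest, and any threshold cuts inside the support).
  The mask keeps the roles it is suited for: selecting the connected
  component that identifies the element, the drop rule when it
  vanishes, and isolation from neighbours.

The measurement window is the branch bounding box padded by 10
*reconstruction* pixels (200 nm) — padding in measurement pixels would
give a 50 nm margin at the 5 nm setting, too small to contain a 100 nm
bundle. Elements whose above-threshold profile band reaches the window
border are dropped with a logged reason: that pattern means the element
is mis-oriented (typically a skeleton spur running across a tubule),
and its "width" would really be a neighbouring structure's length.

Length is the number of occupied columns within the element's
transverse support (the contiguous nonzero-profile run containing the
measured band) times the pixel size; branches touching the window
border make it a lower bound, flagged in the record. Intensity is the
number of localizations inside that support region — with zero
background and a fully covered tubule it equals the ground-truth count
exactly. A per-pixel mean (`locs_per_px`) is also emitted.

The calibration the test suite performs at these settings: median
measured widths recover generator diameters of 25–100 nm strictly
monotonically, single MTs measure at 25 nm within one 5 nm pixel (mean
over 100 simulated tubules), and the same tubules measured at 0°, 30°
and 60° orientations agree within one pixel.

## Statistics

`kruskal_wallis()` uses mid-ranks with the standard tie-correction
divisor; the χ² approximation (df = k−1) is the default p-value, which
is appropriate at the sample sizes a morphometry run produces
(hundreds to thousands of elements). For total n ≤ 10 an exact
permutation null is available, computed by full enumeration of rank
assignments; the all-ties degenerate case returns H = 0, p = 1 by
convention. No multiple-testing correction is applied: the pipeline
reports single pairwise distribution tests per readout (width,
intensity). Histograms use half-open bins with the last bin closed and
a reported overflow bin; the default edges step by 20 nm, matching the
reconstruction pixel.

Type-I error calibration is part of the acceptance suite: running the
full pipeline on two conditions simulated from the same distribution
over 50 seeds, the rejection count at α = 0.05 must fall inside the
central 99 % binomial range.

## Confocal quantifications

Manders coefficients over an ROI: `M1 = Σ A[A > t_A & B > t_B] / Σ A[A
> t_A]` and symmetrically for M2. The numerator is restricted to
voxels above both thresholds (the JACoP convention), which guarantees
M1, M2 ∈ [0, 1]; at the default thresholds of 0 the restriction is
vacuous. A zero denominator yields `NA` with an explicit `undefined`
flag, never a silent 0. Percent volume is `100 × #(v > t_structure) /
#(v > t_low)` within the ROI, invariant under any strictly monotone
intensity rescaling applied jointly with its thresholds. Mean ROI
intensity averages the five central z-planes by default (the
⌈n_z/2⌉-centred window), the usual medial-section readout; ROIs are
axis-aligned boxes, with µm widths converted to voxels rounding half
up. Costes auto-thresholding, Pearson correlation and object-based
colocalization are out of scope.

## Numerical and degenerate-input choices

* Otsu on a constant image returns threshold ∞ → empty mask (there is
  nothing to segment); a fixed threshold outside the observed range
  warns and returns an empty or full mask.
* An empty localization table renders an all-zero image; an empty mask
  skeletonizes to an empty skeleton.
* A vertical branch's orientation is π/2 by convention; orientations
  live in (−π/2, π/2].
* Exact-zero comparisons on vesselness use a relative floor of 1e-10
  against the image scale.
* The chain-code length of digital curves overestimates continuous arc
  length by ~5 % on average; straightness values of curved branches
  inherit this, which the tests account for explicitly.

## Problem sizes

The shipped tests and the acceptance script run at desk scale chosen to
exercise every code path with stable statistics: 100 simulated tubules
for the single-MT width recovery, 10–15 per diameter for monotonicity,
12 per orientation for rotation invariance, 200 per condition for the
end-to-end two-condition comparison, 50 pipeline replicates for type-I
calibration, and 8–16 px images for the brute-force Hessian oracle.

## Known limitations

* Fragmented masks on sparse fields shorten elements; widths are
  unaffected but lengths are lower bounds and one tubule can contribute
  several records, so element counts are not tubule counts.
* The measurement window isolates neighbours only beyond ~200 nm;
  dense crossings inside a window would contaminate the transverse
  profile.
* The width estimator assumes one tubule per window (a single plateau);
  parallel tubules closer than the window height would merge.
* 2D only: axial structure is projected; 3D SMLM is out of scope.
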