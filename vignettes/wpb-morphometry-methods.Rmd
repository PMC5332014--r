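---
title: "Methods: WPB morphometry and screen scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WPB morphometry and screen scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wpbscreen)
```

## The problem

Weibel-Palade bodies (WPBs) are rod-shaped secretory granules of endothelial
cells that store von Willebrand factor (vWF). Their number, size and vWF
content per cell are quantitative phenotypes for siRNA screens of WPB
biogenesis. `wpbscreen` implements the full quantification chain for such a
screen: from two fluorescence channels per field of view (Hoechst-stained
nuclei and vWF-immunostained WPBs, 12-bit intensities at 0.1615 µm/px) to
per-organelle feature tables, four per-well statistics, plate-normalized
robust scores, and a ranked hit list — together with a synthetic plate
generator that provides exact ground truth, so every stage is testable
without acquired microscopy data.

## Image-processing pipeline

**Nuclei and single-cell territories.** The nuclear channel is median
filtered (circular kernel, radius 2 px) to smooth contours, thresholded with
Otsu's method (the staining is strongly bimodal, and a parameter-free global
threshold keeps the stage deterministic), hole-filled, and split at
concavities by a watershed on the Gaussian-smoothed (σ = 1 px) Euclidean
distance transform with regional maxima detected in a 5 px neighborhood.
Components outside 50–2500 µm² are discarded as specks or staining clumps.
Single cells are then approximated by Voronoi influence zones: each pixel is
assigned to the nearest surviving nucleus centroid, and a one-pixel
separating mesh (value 0) is drawn along zone boundaries. Zone labels are
grey-shade encoded with 16-bit capacity — at most 65 535 cells with 0
reserved for the mesh; the labeler raises an error beyond that capacity.
This assumes a confluent monolayer; territories are a proof-of-concept
approximation, not membrane-accurate cell outlines.

Two conventions are worth spelling out. Ties in the nearest-centroid
assignment go to the lower nucleus label, so the tessellation is
deterministic and raster-exact (verifiable against a brute-force
nearest-centroid search). The mesh is drawn on the *higher-label* side of
each boundary using the 8-neighborhood: after deleting object pixels on the
mesh, no two pixels of different zones remain 8-adjacent, which is exactly
the property the downstream object-to-cell assignment relies on. A nucleus
itself may still straddle a midline in dense culture; such nuclei are
assigned by majority vote and flagged rather than dropped.

**WPB segmentation.** The vWF channel is processed on a working copy so
intensity features can later be read from the untouched original. The copy
is background-subtracted with the rolling-ball algorithm at radius 1 px in
its sliding-paraboloid form: a parabola of curvature 1/(2·r) is slid under
the intensity profile along rows, columns and both diagonals in turn; each
1-D pass is a grayscale opening with a parabolic structuring element,
computed in O(n) per line with lower-envelope (distance-transform)
recursions. Thin bright structures — the rods — cannot support the
paraboloid and survive subtraction; smooth shading is removed. The result is
mapped to 8 bit by the fixed linear map 0–4095 → 0–255 (content-independent,
so sensitivity is comparable across fields) and binarized with Bernsen's
local threshold: within a circular window (radius 15 px, the reference
plugin's default), `contrast = max − min` and `midgray = (max + min)/2`;
low-contrast windows (`contrast < 15`) are classified wholesale by
`midgray ≥ 128`, otherwise a pixel is foreground iff its value `≥ midgray`.
The contrast threshold is the single sensitivity tunable; for weak staining
it should be raised to 30 or 50. Mask pixels on the Voronoi mesh are then
deleted so no object crosses an approximated cell boundary, components are
labeled (8-connected, raster-scan order), and objects above 10 µm² are
removed as virtually merged clumps the optics cannot resolve.

**Morphometry.** For every object, 24 features are measured with explicit
geometric conventions: pixel centers at 0-based integer coordinates;
outlines and convex hulls built on pixel corners (center ± 0.5); areas as
pixel counts × (0.1615 µm)². Intensity statistics (mean, SD, min, max,
median, `RawIntDen` = Σ pixels, `IntDen` = area × mean) come from the raw
image. The perimeter is the length of the pixel-corner boundary polygon
(the exposed-edge count), so a 10×10 px square has perimeter 40 px and
circularity 4πA/P² = π/4; circularity is capped at 1. The best-fit ellipse
uses second central moments of the pixel centers (+1/12 per axis, the
variance of a unit pixel, which keeps 1-px-thin objects non-degenerate),
rescaled so the ellipse area equals the object area; the aspect ratio is
Major/Minor and roundness its inverse. Feret diameters come from rotating
calipers over the convex hull of corner points: the maximum caliper distance
(Feret, with its endpoint — the one with smaller x, then smaller y — and
angle) and the minimum caliper width (MinFeret, attained flush with a hull
edge). Solidity is area over hull area. The one reported-feature ambiguity
— which end of the Feret diameter is "the" endpoint — is resolved by the
smaller-x convention and documented rather than guessed.

## Per-well statistics and screen scoring

Four statistics summarize a well, each as the mean over its fields of view
of a per-field ratio: the area fraction of WPBs with Feret > 1.5 µm
(`PercentWPBarea`), WPBs per cell (`TotalWPBnrPerCellNR`), summed raw
integrated density per cell (`TotalWPBrawIntDenPerCellNR`), and the count
fraction of WPBs with Feret > 1.5 µm (`TotalFoVpercentWPBnr`). Fields with
zero WPBs leave the two fractions undefined (0/0) and are excluded from
those means while contributing zero to the per-cell features; fields with
zero cells are excluded from the per-cell features. The cell count per
field defaults to the number of influence zones; a `legacy` mode instead
counts only cells containing at least one WPB, mirroring pipelines that
derive the count from the object-to-cell table.

Plates are normalized by the B-score method: a two-way median polish (row +
column effects fitted on **all** wells — controls included, since the cited
workflow polishes plate-wide; at most 10 sweeps, convergence when the total
absolute residual changes by less than 10⁻⁶) followed by scaling the
residuals with 1.4826 × median|residual|. If that robust scale is zero —
an exactly additive plate — all B scores are defined as 0; numerically,
"zero" means below 10⁻⁹ of the plate's magnitude, so rounding dust is never
used as a divisor. Because controls enter the polish, the synthetic screen
layout scatters its 8 negative and 8 positive controls across distinct rows
and mostly distinct columns: a column filled with one control type would
fold the control effect into the column effect and erase it. Robust Z
scores are computed per replicate across the whole screen,
`z = (B − median)/(1.4826 · MAD)`, with location and scale from sample
wells only; replicate scores are averaged (arithmetic mean). Per-plate
scoring is available via configuration but screen-wide scoring is the
default. Assay quality is summarized by the Z′ factor
`1 − 3(σ₊ + σ₋)/|μ₊ − μ₋|` per replicate on the normalized control values,
and reproducibility by the per-well SD across replicates. Hits are sample
wells with mean Z strictly above 2.

## The synthetic plate generator

`field_spec()`/`generate_field()` emulate one field of a confluent HUVEC
monolayer on the 12-bit scale; `generate_plate()` renders whole plates to
16-bit TIFFs with truth tables. Defaults, chosen once as realistic for the
acquisition geometry: a 688 × 512 px field (≈ 9 200 µm² at 0.1615 µm/px)
holds 16 elliptical nuclei — about 70–100 cells across a well's five fields
of view, matching both the cell-territory area of a confluent monolayer
(~570 µm²) and the deposited screens' object density — with uniform axis
diameters 9.5–11.5 × 7.5–9 µm (areas comfortably inside the 50–2500 µm²
gate). Nucleus centers are placed by rejection sampling with a pairwise
separation of 0.9 × the sum of mean radii (deep merges never occur, grazing
contact can), plus a configurable 10% of nuclei placed as deliberately
touching partners to exercise the watershed. Per cell, a Poisson(60) number
of WPBs is drawn; rods are rectangles with semicircular caps, log-normal
total length (meanlog = log 1.4, sdlog = 0.5 µm; ≈ 0.5–3.7 µm central
range), width 0.4 µm, uniform intensity 1200 over a sloped background
(offset 100) with additive Gaussian noise (σ = 8) clipped to [0, 4095] and
rounded to integers. Shapes are rasterized at 4× supersampling and
box-downsampled, which keeps sub-pixel lengths stable around the 1.5 µm
Feret cut. Rods are placed wholly inside their cell's territory with a
2 px clearance from the territory boundary and from other rods: WPBs are
perinuclear organelles rather than membrane-apposed, and the generator's
ground truth is defined for resolvable objects — unresolvable clumps are
exercised separately by the >10 µm² clump-filter fixtures. Rods that cannot
be placed after 40 attempts are dropped from both image and truth, so the
truth is always consistent with the rendering.

What the generator does **not** emulate: intensity texture within a rod
(uniform intensity + noise is the simplest model that exercises the
thresholding), out-of-focus light, vWF-rich non-WPB artefacts, uneven
illumination beyond a linear ramp, or nucleus intensity variation. Passing
tests therefore demonstrate algorithmic correctness and recovery under the
stated conditions, not robustness to every real-data pathology.

## Numerical choices and degenerate inputs

* Circular kernels include offsets with `dx² + dy² ≤ r²`; windows are
  clipped at image borders (Bernsen) or extended by the nearest pixel
  (median filter).
* The 12→8-bit conversion rounds half to even (R's `round`), documented
  because 2047.5 maps to 128.
* Median polish: missing values are ignored by the medians; an all-missing
  plate is an error; a row or column that is entirely missing contributes a
  zero effect.
* `z_scores` refuses fewer than 2 distinct sample values or a zero MAD;
  `z_prime` refuses equal control means; `replicate_sd` needs ≥ 2
  replicates.
* Empty label maps yield empty, fully-typed feature tables, not errors; a
  field with zero surviving nuclei is logged and its well statistics are
  reported as missing.
* Per-field failures inside `run_plate()` are caught and logged; the plate
  errors only if every field fails.

## Validation strategy and problem sizes

The test suite validates each algorithm against an independent route:
Bernsen against direct per-pixel rule evaluation; Feret against exhaustive
pairwise search over all boundary-corner points and MinFeret against a
dense caliper-angle sweep (the sweep is an upper bound with discretization
error at its kinks, so the calipers value must sit just below it); the
discrete Voronoi against brute-force nearest-centroid assignment; the
median polish, iteration cap lifted, against a long-run reference polish.
Ground-truth recovery runs on noise-free fields with rods ≥ 4 px and
intensity ≥ 5× background (count precision/recall, Feret error ≤ 1 px in
mean and 90th percentile), and on default-noise fields for the long-rod
fraction (binomial 99% band at n ≥ 500 rods). The screen-level benchmark
uses a 96-well replicate pair at one 512 × 512 field per well with 12
nuclei per field, 8 scattered negative controls, 8 positive controls
(count × 0.1, intensity × 0.2 — the vWF-knockdown phenotype), and 4 planted
hits at count × 1.6, intensity × 1.3 (an order of magnitude beyond the
well-to-well spread); it must recover all planted hits at Z > 2, separate
control Z scores in the right direction, and yield Z′ > 0 for the intensity
feature. These sizes keep the full suite reproducible on a laptop while
leaving every stage load-bearing.

## Known limitations

* Voronoi territories ignore true cell shape; quantities "per cell" inherit
  that approximation.
* The corner-point Feret convention carries a small positive bias
  (≈ +0.4 px on rendered rods) relative to the geometric rod length; it is
  the standard particle-analysis convention and is reported as such.
* The rolling-ball background is exact in the interior but has one-sided
  support within ~one ball radius of the raster edge; exact edge behavior
  is explicitly out of scope.
* Object-level intensity texture, artefact classes beyond size, and HTML
  reporting of the original screen-analysis stack are out of scope; outputs
  are plain tables and ggplot figures.
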