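---
title: "Methods: crown delineation, stem alignment and species classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crown delineation, stem alignment and species classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

canopyseg implements a three-stage pipeline for individual-tree analysis of
airborne hyperspectral imagery over forests: crown delineation, alignment of
delineated crowns with field-surveyed stems, and pixel-based tree species
classification aggregated to the crown. This vignette documents the models,
their assumptions, the tunable parameters, the numerical choices, and what
the synthetic test bed does and does not demonstrate.

## 1. Crown delineation by seeded region growing

The delineation operates on a single near-infrared band of the
hyperspectral cube and rests on one physical assumption: within a sunlit
crown, radiance (or reflectance — the algorithm treats the values as a
generic intensity) is highest at the tree apex and decays toward the crown
edge. The stages are:

1. **Vegetation masking.** NDVI = (NIR − RED)/(NIR + RED) is computed from
   the bands nearest the configured red and near-infrared wavelengths
   (defaults 680 and 800 nm; the exact pair is configurable because sensor
   band grids differ). Pixels with NDVI strictly below the threshold
   (default 0.6) are masked; a pixel at exactly the threshold is kept.
2. **Band selection.** The band nearest 810 nm carries the segmentation;
   ties between two equidistant bands resolve to the lower wavelength so
   results are reproducible on regular band grids.
3. **Seed detection.** A pixel is a tree-top seed when it is unmasked and
   equals the maximum of its `window_px` × `window_px` neighborhood
   (default 3 × 3), with the window clipped at the image edge and masked
   pixels excluded from the maximum. On an intensity plateau every tied
   pixel is a seed — the local-maximum definition is taken literally, and
   the synthetic generator is built so plateaus do not occur.
4. **Region growing.** Each seed *n* starts a region with label *n*. A
   4-neighbor of a region pixel joins region *n* iff (i) the Euclidean
   distance (in pixel units, between pixel centers) from the candidate to
   seed *n* is strictly below `dist_max` (default 4) and (ii) its intensity
   strictly exceeds `perc_thresh` (default 0.4) times the seed intensity.
   Only unlabeled, unmasked pixels can be claimed, and growth stops when a
   full sweep adds nothing.
5. **Polygonization.** Each region's member pixel *centers* are collected
   in map coordinates and their 2-D convex hull is the crown polygon.

Two points were genuinely open in the underlying method description and are
fixed here as package policy:

* **Contention between regions.** Sweeps are level-synchronous: all regions
  expand by one ring per sweep against a snapshot of the label map, and a
  pixel reachable by several regions in the same sweep goes to the region
  whose seed is nearest, ties to the lower seed id. This makes the label
  map deterministic and independent of seed enumeration order, which a
  sequential per-region scan would not be.
* **Degenerate regions.** A region whose pixel centers are fewer than three
  or collinear has a zero-area hull. Such regions are emitted as the
  dissolved union of their one-pixel footprint squares instead, so that a
  one-pixel crown contributes 1 m² (at 1 m resolution) to area accounting
  rather than vanishing.

`delineation_params()` collects the tunables: `window_px` (odd, px),
`perc_thresh` (fraction of seed intensity, in (0,1)), `dist_max` (px),
`ndvi_threshold`, and the NDVI/segmentation wavelengths (nm). The defaults
are the parameter set found by supervised tuning in the challenge this
method stack was built for (3 × 3 window, 0.4, 4); `tune_parameters()`
reproduces that supervised grid search against reference crowns.

Because distances are in pixel units, `dist_max = 4` means 4 m at 1 m
resolution; crowns larger than ~8 m diameter will be truncated unless
`dist_max` is raised.

## 2. Delineation scoring

`score_dataset()` computes, for every reference crown, the Jaccard overlap
J(A,B) = |A∩B| / (|A| + |B| − |A∩B|) against each intersecting predicted
crown and keeps the best (0 when none overlaps). A predicted crown may be
the best match of several reference crowns; the scoring deliberately does
not enforce a one-to-one assignment because the challenge protocol it
mirrors did not. The reported score is a **two-level mean**: crowns are
averaged within their field plot, then plot scores are averaged — plots
with few crowns weigh as much as plots with many.

`area_confusion()` accounts crown area on *dissolved* (self-unioned)
reference and predicted sets, so overlapping polygons are not counted
twice: the reference area covered by predictions, the reference area
missed, and the predicted area in excess of all references. The challenge's
bar-chart report labelled these TruePositive, FalsePositive and
FalseNegative; because calling missed reference area a "false positive" is
non-standard, the package stores neutral names (`ref_covered_m2`,
`ref_missed_m2`, `pred_excess_m2`) and only `format_area_confusion()`
prints the historical labels for comparability.

## 3. Crown–stem alignment

Field inventories record stem position, diameter at breast height (cm) and
height (m), with crown radius measured only on a subset; delineated crowns
have geometry but no field attributes. The alignment closes both gaps with
two power-law allometries fitted by nonlinear least squares:

* field crown radius: R = a·(H·D)^b, fitted on trees with measured radius
  and predicted where it is missing (measured radii are never overwritten);
* crown height: H = a·R^b, fitted on crowns with known height, where the
  crown radius R is the radius of the equal-area circle, √(area/π), and
  crown height is the maximum canopy-height-model value among pixels whose
  centers fall inside the polygon.

The fit is initialized at the log–log ordinary-least-squares solution and
refined by Levenberg–Marquardt; this handles the zero-residual case
(noise-free data) that a plain Gauss–Newton iteration fails on. If the
refinement does not converge the log–log estimate is returned and flagged.
Note two deliberate unit choices: H·D mixes meters and centimeters (the
coefficient *a* absorbs the units), and the attribute distance below adds
meters of height to meters of radius without weighting — both follow the
method as published.

Each crown is then linked to a field tree by minimizing
D = D_pos + D_attr, where D_pos is the planimetric Euclidean distance from
the crown centroid to the stem and D_attr the Euclidean distance between
(height, radius) pairs. The default mode `"nearest"` assigns every crown
its argmin tree (a tree may be claimed twice — the literal rule);
`"one-to-one"` accepts pairs greedily in ascending D with each side used
once, a safeguard against duplicate claims. No distance cut-off is applied
by default; `max_distance` exists for inventories where unmatched trees are
expected. When a field tree carries two radii (maximum and perpendicular),
their mean should be supplied as `crown_radius_m`.

## 4. Species classification

Training and test crowns are rasterized by pixel-center membership; each
pixel's spectrum is divided by its sum over all bands (so betweeen-flightline
brightness differences cancel and only spectral shape remains), then:

1. **Band selection** by sequential forward floating selection (SFFS):
   greedy forward additions maximizing the separability criterion, each
   followed by conditional backward removals that are kept only while they
   beat the best known criterion at the smaller size. The criterion is the
   mean pairwise Jeffries–Matusita distance over class pairs,
   JM = 2(1 − e^(−B)) with B the Gaussian Bhattacharyya distance computed
   from per-class mean vectors and covariances. The JM formula is the
   standard Gaussian form used throughout the band-selection literature;
   `criterion = "min"` (worst pair) is available. Sample covariances are
   regularized with a 1e-6 diagonal ridge so singular cases (few pixels,
   or the unit row-sum constraint introduced by normalization) stay
   invertible. All labelled classes enter the criterion, including any
   catch-all "unidentifiable" class. The default `max_features = 40`
   reflects a 400+ band sensor; the full best-at-size trace is returned so
   users can pick any size after the fact.
2. **Classification** by a C-SVM with RBF kernel (kernlab). Features are
   z-scored with training statistics, and the crown's maximum CHM value is
   appended to each of its pixels as one extra feature — the height
   semantics match a tree top, and replicating it per pixel keeps the
   pixel-level classifier design. Cost and kernel width are chosen by
   seeded 5-fold cross-validation over C ∈ {1, 10, 100} and
   σ ∈ {0.1, 1, 10}/d (d = feature count), ties to the earlier grid entry;
   folds are stratified by class, falling back to unstratified with a
   warning when a class has a single pixel.
3. **Aggregation** by majority vote per crown; ties resolve to the class
   with the larger training sample, then alphabetically.

`confusion_metrics()` reports, in percent and unrounded: overall accuracy,
Cohen's kappa, producer's accuracy (column-wise recall) and user's accuracy
(row-wise precision) per class, and mean class accuracy as the unweighted
mean of producer's accuracies over classes present in the reference.
Classes with a zero denominator are reported as NaN and excluded from the
mean. On the bundled 9-species challenge test-set matrix
(`osbs_species_confusion()`), the computed user's accuracy of QULA is
21/23 = 91.3%, while the original report printed 91.4; the package reports
the value implied by the printed counts.

## 5. The synthetic scene generator

`make_scene()` builds the statistical structure every stage assumes, with
all truth known: non-overlapping circular crowns whose apex sits exactly on
a pixel center; per-pixel spectra drawn from species-specific multivariate
normals and multiplied by a radial profile exp(−k(d/R)²) with k = 0.92, so
the crown-edge intensity is ≈ 40% of the apex value (placing the default
`perc_thresh = 0.4` boundary at the true crown edge is a property of the
emulated radiance model, not a tuning of the test); a soil-like background
with NDVI ≈ 0.06 against crown NDVI ≈ 0.8; a conical CHM tapering to 40%
of the apex height; and field stems at Gaussian-jittered apex positions
whose diameters invert the configured radius allometry
(R = 0.28·(H·D)^0.4) while heights follow H = 10.5·R^0.55, giving
≈ 14–25 m canopies — around 23 m for mid-sized crowns, matching a mature
pine-oak stand. Because the radial profile is multiplicative it cancels in
NDVI and in sum normalization, which is exactly why both of those steps are
robust to within-crown brightness gradients. The apex is enforced to be
the strict within-crown NIR maximum (any noise draw exceeding it is scaled
back), so seed detection at the apex is guaranteed by construction rather
than with high probability.

Default sizes — a 120 × 120 px scene, 50 bands between 400 and 1000 nm, 25
crowns of radius 2–5 m — are the package's standing study conditions: large
enough that every stage is exercised with plots, species and allometric
gaps, small enough for exhaustive oracles (brute-force window scans,
level-synchronous BFS, full subset enumeration) to be practical in the test
suite.

What the generator does **not** emulate: crown overlap and mutual shading
(an `allow_overlap` mode exists but truth remains nearest-apex),
correlated or wavelength-dependent sensor noise, atmospheric and
illumination effects, topography, understory vegetation, and the heavy
class imbalance of real inventories. Passing the end-to-end tests
therefore shows the algorithms are implemented correctly and behave as
designed under their own assumptions; it does not certify field accuracy,
which on real challenge data was far lower (crown-level Jaccard near 0.34)
than on these idealized scenes.

## 6. Numerical choices

* Polygon booleans go through Clipper (polyclip) on an adaptive integer
  grid (spacing 1e-12 for local coordinates, coarsened for very large
  projected coordinates to avoid 64-bit overflow); rings are re-oriented
  counter-clockwise and unions use the nonzero fill rule so self-unions
  dissolve instead of cancelling. Areas below 1e-9 m² count as zero.
* Point-in-polygon tests are boundary-inclusive: crown hull vertices are
  themselves pixel centers, so a boundary-exclusive rule would drop real
  member pixels.
* Both region-growing inequalities are strict, as specified: `dist_max = 1`
  therefore yields single-pixel regions, and a neighbor exactly at
  `perc_thresh` times the seed value is rejected.
* The power-law fit converges on the relative SSE (ftol 1e-10, ≤ 200
  iterations); the JM covariance ridge is 1e-6; SVM model selection uses a
  fixed seed (default 1234) so the whole classification chain is
  deterministic given its inputs.
* Raster I/O uses the ESRI ASCII grid text format with a `.prj` sidecar
  for the CRS and a `band,wavelength_nm` CSV for cube wavelengths; layers
  with conflicting CRS strings are rejected, never silently reprojected.

## 7. Known limitations

* Delineation assumes apex-bright crowns; shaded or flat-topped broadleaf
  crowns violate the radial-decay assumption and fragment or merge.
* `dist_max` caps crown radius; a single global value cannot fit stands
  mixing very small and very large trees (a variable-window/variable-cap
  extension is out of scope).
* GeoJSON polygons with holes and multi-polygons are not supported.
* The area confusion matrix is exact for the polygon sets given to it, but
  its challenge-style labels remain non-standard; use the neutral field
  names in downstream analyses.
* SFFS is a heuristic: it is exhaustively verified on small fixtures in
  the test suite, but on hundreds of bands it offers no global-optimality
  guarantee — hence the saved criterion trace.
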