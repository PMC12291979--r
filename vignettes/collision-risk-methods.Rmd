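---
title: "Methods: shipping pressure, habitat suitability, and collision risk"
author: "shipstrike authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shipping pressure, habitat suitability, and collision risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shipstrike)
```

## The problem

Large whales are killed by collisions with vessels, and the places where
that risk concentrates are where dense shipping crosses suitable whale
habitat. `shipstrike` implements a gridded assessment of that overlap in
three coupled parts:

1. **Shipping pressure.** Per-cell vessel-activity hours (aggregated AIS
   transmissions) on a fine 0.1° grid are classified into discrete
   intensity levels and condensed into a continuous density index
   $V_i \in [0, 1]$.
2. **Habitat suitability.** Presence records and environmental predictor
   rasters on a 0.25° grid feed a weighted ensemble of presence/background
   classifiers, giving a continuous per-cell presence probability
   $D_i \in [0, 1]$ per species.
3. **Collision risk.** The per-cell risk index is the product
   $R_i = V_i \times D_i$; per-species hotspots are the cells at or above
   a stated percentile of $R_i$, and stacking hotspot masks across species
   highlights multi-species priority areas.

Alongside the risk index, the package assigns shipping pressure to
protected sites (MPAs, EBSAs, IMMAs), classifies their jurisdiction
against a high-seas boundary, and summarizes counts and areas by pressure
level.

Everything is exercised end to end on synthetic data: a seeded generator
produces worlds with the statistical structure the analysis assumes, so
every stage is testable without any external download.

## Shipping pressure

### Intensity levels

Vessel-hours $h$ are binned on the decade scale:

$$\mathrm{level}(h) = \begin{cases} 0 & h < 1 \\ \min\{7,\; 1 + \lfloor \log_{10} h \rfloor\} & h \ge 1. \end{cases}$$

Level 1 covers $[1, 10)$ hours per cell, level 2 $[10, 100)$, and so on,
capped at 7. Levels 1–3 are reported as *low*, level 4 as *moderate*, and
5–7 as *high* shipping stress; the sub-unit level 0 folds into *low*.
Level 0 exists because "no recorded traffic above noise" and "no data"
are different states: cells without traffic coverage are `NA` and stay
`NA` through every downstream step, never silently becoming zero.

### Density index

The continuous index applies a log transform with a minimum threshold
(default `floorHours = 10` vessel-hours) followed by 0–1 normalization:

$$V_i = \frac{\log_{10}\max(h_i, f) - \log_{10} f}{\log_{10} h_{\max} - \log_{10} f}.$$

Cells at or below the floor score exactly 0 — the floor is a clamp, not a
drop rule — and the global maximum-hours cell scores exactly 1. $V_i$ is
strictly increasing in $h$ above the floor, so it preserves the ordering
of the intensity levels. The log base (10) matches the decade binning of
the levels; at realistic AIS ranges this spreads seven levels across the
observed span of traffic.

## Zonation of protected sites

Sites are points or polygons with a category label (MPA, EBSA, IMMA).

* **Points** receive the *maximum* vessel-hours over the eight cells
  nearest the point — the Moore neighborhood of the containing cell,
  clipped at grid edges. The maximum (not the mean) is deliberate: a
  point site adjacent to a lane is exposed to that lane. The containing
  cell itself is excluded by default; `includeCenter = TRUE` switches to
  the nine-cell variant, which differs only when the center holds the
  maximum.
* **Polygons** receive the unweighted *mean* of hours over all
  non-missing cells whose centers fall inside the polygon (boundary
  inclusive). Cell-center membership is used rather than fractional-area
  weighting: it is deterministic, cheap, and matches the convention of
  averaging "all shipping hour data within the boundary". A polygon
  whose bounding box spans less than one fine cell in both axes carries
  no sub-cell information and is simplified to its centroid, handled as
  a point.
* Sites outside the grid or with no traffic coverage anywhere in their
  neighborhood are *excluded with a reason code* and tallied in the
  summary as `nExcluded`; they never vanish silently.

Jurisdiction is geometric: a site whose geometry intersects (or merely
touches) the high-seas boundary polygons is *transboundary*, otherwise
*national*. MPAs are assumed national throughout, reflecting their
near-absence from waters beyond national jurisdiction. Site areas for
area-share summaries are geodesic areas on the WGS84 ellipsoid
(`geosphere`), because planar areas in degrees are badly distorted away
from the equator. Percentages are rounded half away from zero to two
decimals, the convention of printed report tables. Antimeridian-crossing
geometries are a documented limitation: they must be pre-split.

## Habitat suitability

### Preprocessing

* **Spatial thinning** keeps at most one record per 0.25° cell, damping
  sampling bias from heavily surveyed areas. The earliest-dated record in
  a cell wins, with input order breaking ties — a deterministic rule, so
  thinning is idempotent and reproducible.
* **Range filtering** optionally removes records outside expert range
  polygons. An empty polygon list is an error rather than a no-op, to
  distinguish a degenerate range from "no filtering requested".
* **Collinearity screening** computes the Pearson correlation matrix of
  the predictor stack and greedily eliminates variables while any pair
  exceeds $|r| > 0.7$: at each step the variable with the largest mean
  absolute correlation to the remaining set is dropped. The choice of
  which member of a correlated pair to discard is otherwise arbitrary;
  the greedy max-mean-$|r|$ rule makes it deterministic and documented.
* **Pseudo-absences** are background cells sampled uniformly at random,
  without replacement, from sea cells holding no presence; the default
  background size equals the presence count (balanced classes). This is
  a single, configurable default rather than per-algorithm
  prescriptions.

### Learners and evaluation

The ensemble machinery is agnostic to the classifier: a *learner* is any
object with `fit(X, y)` and `predict(model, X)` returning scores in
$[0, 1]$. Two reference learners ship with the package — a
ridge-regularized logistic scorer (`glmnet`) and a
nearest-environmental-neighbor scorer (presence fraction among the $k$
nearest training points in z-scored predictor space). They are distinct
model families on purpose: the ensemble's admission and weighting logic
is what the package contributes, not any particular base algorithm, and
the learner contract accepts external ones.

Evaluation is stratified 5-fold cross-validation repeated 10 times
(80%/20% train/validation per fold). Two metrics are computed on held-out
data only:

* **AUC** by the rank (Mann–Whitney) formulation, ties counted one half —
  identical to the exhaustive mean over all presence–absence pairs.
* **TSS** = sensitivity + specificity − 1, evaluated at the
  TSS-maximizing cutoff found by exhaustive scan over the fold's own
  held-out scores (ties resolve to the smallest cutoff).

### Ensemble and binarization

Only learners with mean held-out AUC above 0.9 enter the ensemble; among
those, weights are AUC-proportional and sum to one:

$$D_i = \sum_{\ell\,:\, \mathrm{AUC}_\ell > 0.9} \frac{\mathrm{AUC}_\ell}{\sum_m \mathrm{AUC}_m}\; p_{\ell,i}.$$

If no learner clears the bar the ensemble fails loudly with advice to
relax the cutoff — never silently. The admission filter is applied to
each learner's *mean* AUC over all folds (not per repeat), and weighting
uses AUC alone; both are deliberate, documented resolutions of choices
the ensemble convention leaves open.

Binary maps threshold $D_i$ at the TSS-maximizing cutoff computed on the
calibration points; the chosen threshold is stored on the map for
provenance. Binary maps stack by cellwise summation into species
richness. Variable importance is permutation-based: the mean drop in
calibration AUC when one predictor's column is shuffled (seeded,
repeated).

## Collision risk and hotspots

The density index lives on the 0.1° traffic grid and suitability on the
0.25° predictor grid. The join aggregates $V_i$ *upward*: each fine cell
is assigned to the coarse cell containing its center and coarse $V_i$ is
the mean of its fine values. Aggregating the information-rich side is
preferable to pretending $D_i$ has sub-cell structure; center-based
assignment also handles the non-integer 0.1°→0.25° resolution ratio
exactly.

$R_i = V_i \times D_i$ with missing cells propagating. Hotspots at
percentile $p \in \{90, 95, 99, 99.5\}$ use the linear-interpolation
quantile of the *non-missing* (sea) cells, and the mask rule is
inclusive, $R_i \ge$ threshold. Inclusivity matters only under ties —
for a tie-free raster the 99th-percentile mask flags 1% of valid cells
to within interpolation error — but it makes the degenerate all-equal
raster well-defined (every cell flagged) rather than undefined. Masks
are invariant under positive rescaling of $R_i$ and nest across
percentiles. Per-species percentiles are computed globally over valid
cells, not within a species' modeled range.

Overlap maps count, per cell, how many species' hotspot masks flag it;
the summary reports the fraction of the hotspot-union cells at exactly
$k$ species and the cumulative "more than $k$" shares, to one decimal.

## The synthetic world

`syntheticWorld(seed)` builds a 40° × 40° region (400 × 400 fine cells,
160 × 160 coarse cells) with:

* a procedurally drawn coastline (one connected landmass along the
  western edge, a smooth seeded curve), so distance from shore and
  coastal traffic lanes are meaningful;
* a high-seas boundary at a fixed fraction (70%) of the zonal extent,
  standing in for the edge of national jurisdiction;
* environmental predictors as Gaussian-smoothed white noise (kernel sd 5
  coarse cells — strong, controllable spatial autocorrelation), named
  after the standard predictor set (SST, Sal, Chl, …, DS). SST carries a
  meridional gradient and Sal is constructed from SST with $|r| > 0.7$,
  so the collinearity screen always has work; DS is the true distance
  from shore, computed from the land mask (with the extent diagonal as
  the sentinel value when no land exists);
* traffic as a log-normal background spanning several orders of
  magnitude plus high-intensity corridors running parallel to the coast
  (populating every intensity level 1–7 under defaults), zero on land;
  the constructed corridor cells are recorded on the `laneMask` slot so
  recovery experiments know the ground truth;
* occurrences sampled with replacement proportional to a known
  suitability surface — the inverse-logit of a linear blend of z-scored
  predictors — with uniform within-cell jitter and random post-1993
  dates. Sampling with replacement is intentional: real sighting data
  repeat within cells, and thinning must have something to remove;
* sites as a mix of points, sub-cell polygons and multi-degree polygons,
  with one large polygon forced across the high-seas boundary.

The default synthetic species use sharp niches (logistic coefficients of
magnitude 4–8 on two or three predictors, strongly negative intercepts),
giving core habitats covering roughly 10–20% of the sea. That mirrors the
strongly structured distributions this kind of ensemble is used for, and
it is the regime in which ensembles legitimately reach held-out AUC above
the 0.9 admission bar; a nearly uniform species would be un-modelable by
construction and is not what the method targets.

### What the generator does *not* emulate

Passing tests on synthetic worlds demonstrate that the machinery is
correct, not that real-world results would replicate. The generator has
no vessel kinematics or ship-type structure, no seasonality, a single
smooth landmass rather than real bathymetry and archipelagos, isotropic
predictor autocorrelation, and occurrence sampling that is unbiased given
the surface (real sightings have strong effort bias that thinning only
partially removes). Synthetic species obey the logistic response family
exactly, which flatters the logistic learner relative to real niches.

## Numerical choices and degenerate inputs

* All stochastic steps take explicit integer seeds; child seeds are
  derived per stage, and a fixed seed reproduces every output file
  bit-for-bit (checksums in the run manifest verify this).
* Quantiles use the linear-interpolation convention; rounding of
  reported percentages is half-away-from-zero at the printed precision.
* Grid cells are half-open $[lo, hi)$ in both axes; a point on a cell's
  west/south edge belongs to that cell. Points exactly on the high-seas
  boundary count as intersecting (transboundary).
* Degenerate inputs fail loudly: single-cell extents, all-land worlds,
  all-equal suitability scores at binarization, traffic with no cell
  above the density floor, empty range polygon lists, single-class
  labels for AUC/TSS.
* Rasters travel as ESRI ASCII grids (plain text, GDAL-readable) written
  at 17 significant digits so round trips are exact; sites as GeoJSON;
  tables as CSV/JSON.

## Problem sizes

The shipped configuration defaults are the analysis constants (floor 10,
AUC cutoff 0.9, $|r|$ cutoff 0.7, percentiles 90/95/99/99.5, 5 × 10
cross-validation). Simulation sizes are chosen for seconds-to-minutes
turnaround on one CPU: the default world is 40° × 40° with 2,000
occurrences and 9 predictors per species and three species in the demo
pipeline; unit tests use 10° worlds with a few hundred occurrences. These
sizes give stable percentile statistics (≈20,000 valid coarse cells, so a
99th-percentile mask holds ≈200 cells) while keeping the full test suite
and the acceptance script fast.

## Known limitations

* Cell-center zonal statistics ignore partial cell coverage; very narrow
  polygons between cell centers fall back to the point rule only if
  their bounding box is sub-cell in both axes.
* Antimeridian-crossing geometries must be pre-split by the caller.
* The high-seas stand-in geometry in the synthetic world is a simple
  meridional boundary, not a real EEZ mosaic.
* The two reference learners are deliberately simple; for real analyses
  the learner contract is the extension point.
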