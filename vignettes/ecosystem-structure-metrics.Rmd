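---
title: "Deriving gridded ecosystem-structure metrics from classified ALS point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving gridded ecosystem-structure metrics from classified ALS point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National airborne laser scanning (ALS) campaigns deliver classified point
clouds — billions of returns, each with projected x/y coordinates, an
elevation and an ASPRS class code (1 unclassified, 2 ground, 6 building,
9 water) — but no ready-made information about vegetation structure.
`alsmetrics` turns such clouds into single-band 10 m rasters of 25
vegetation-structure metrics plus point density, the variables ecologists
use as essential biodiversity variables for the vertical profile of
ecosystems: canopy height percentiles, cover fractions by height stratum,
and measures of structural complexity.

The pipeline has four stages, each exposed as a function and jointly as
`run_pipeline()`:

1. **Retiling** (`retile()`): inputs are split onto a regular 1 km grid so
   each tile can be processed independently.
2. **Normalization** (`normalize_height()`): each point's elevation is
   converted to a height above the local surface by subtracting the lowest
   elevation among *all* points in its 1 m × 1 m cell.
3. **Feature extraction** (`extract_features()`): per 10 m × 10 m cell,
   the 26 metrics are computed from the normalized heights of the class-1
   ("unclassified", predominantly vegetation) points, plus ground counts
   for the pulse penetration ratio and all-class counts for point density.
4. **Rasterization** (`rasterize_features()`, `write_geotiff()`): per-tile
   tables merge into one single-band GeoTIFF per metric (EPSG:28992 by
   default), with an explicit nodata sentinel.

Two companion modules complete the workflow: a binary cadastral mask
(`build_mask()`, `apply_mask()`) that removes water/building/road cells
where "unclassified" returns are ships, chimneys or cars rather than
vegetation, and a validation module (`validate_plots()`) that quantifies
exactly that contamination against hand-labelled plots.

## The metrics and their conventions

All vegetation metrics consume the multiset $\{z_i\}_{i=1}^N$ of
normalized heights of class-1 points in a cell ($\bar z$ the mean).

* **Height**: `Hmax`, `Hmean`, `Hmedian`, and the percentiles `Hp25`,
  `Hp50`, `Hp75`, `Hp95`. Percentiles use the *nearest-rank* (ordinal)
  definition, rank $\lceil (p/100)\,N \rceil$ in the ascending sort, so
  they always return an observed height; `Hmedian` is identically `Hp50`.
  Linear interpolation is available (`interpolate = TRUE`) because the
  wider software family uses it, but it is not the default.
* **Cover**: the pulse penetration ratio
  $\mathrm{PPR} = N_{\text{ground}} / (N_{\text{ground}} + N)$; the
  percentage of returns strictly above $\bar z$
  (`Density_above_mean_z`); and nine band ratios — fractions of
  vegetation returns in the strata $<1$, $1$–$2$, $2$–$3$, $>3$,
  $3$–$4$, $4$–$5$, $<5$, $5$–$20$ and $>20$ m.
* **Complexity**: standard deviation/variance (`Hstd`, `Hvar`, divisor
  $N-1$), the coefficient of variation (`Coeff_var_z`), skewness and
  kurtosis (`Hskew`, `Hkurt`, standardized central moments with the
  *population* standard deviation, divisor $N$; kurtosis is raw, so a
  normal sample gives about 3), the Shannon entropy of 0.5 m height
  layers (`Entropy_z`, base 2), and the plane-fit roughness `Sigma_z` —
  the standard deviation of residuals of a least-squares plane through
  the cell's vegetation points.
* `point_density` counts **all** classes over the cell area (points/m²).

Three conventions deserve explanation because the source formulations are
ambiguous or mixed:

* **Half-open intervals everywhere.** Band definitions written with
  strict inequalities on both ends ($1 < z < 2$) would silently drop
  boundary points and break the partition identities. We use $[l, h)$
  for every band, grid cell and tile, which guarantees
  `BR_below_1 + BR_1_2 + BR_2_3 + BR_above_3 = 1` and
  `BR_below_5 + BR_5_20 + BR_above_20 = 1` exactly, and that no grid
  partition ever double-counts a point.
* **Mixed moment divisors.** `Hstd`/`Hvar` are the published
  $N-1$ sample forms while `Hskew`/`Hkurt` standardize by the
  population $\sigma$ (divisor $N$), exactly as printed in their
  formulas. The inconsistency is deliberate and preserved.
* **PPR denominator.** The "total" is ground + vegetation points only
  (classes 2 and 1). Counting building or water returns would conflate
  canopy openness with built cover.

Preconditions are explicit: a metric whose precondition fails (empty
cell for heights, $N<2$ for moments, $\sigma = 0$ for skew/kurtosis,
$\bar z = 0$ for the CV, fewer than 3 non-collinear points for
`Sigma_z`) is nodata, never a silently misleading number. `Sigma_z`
declares the plane degenerate when the centred normal-equations
determinant falls below $10^{-10} \cdot S_{xx}S_{yy}$.

## Normalization against the local minimum

Normalized height is elevation minus the minimum over *all* classes in
the 1 m cell — deliberately not a TIN or kriged terrain model, and not
restricted to ground-class points: a cell with only vegetation returns
normalizes against its own lowest return. The pipeline counts such
ground-free cells and reports them per tile, because metrics there are
systematically biased low. The per-cell minimum itself becomes exactly 0,
and the operation is idempotent and invariant (to floating-point
rounding) under constant elevation shifts.

All three grids — 1 km tiles, 10 m feature cells, 1 m normalization
cells — share one configurable origin, and the finer sizes must divide
the tile size. This nesting is what makes tiled execution *exactly*
equal to untiled execution: no 10 m cell ever straddles a tile edge.
The national anchor of the original 512 × 512 tile grid is not public,
so the default origin snaps the input bounding box down to a tile
multiple and is configurable.

## File formats

LAS (1.x, point formats 0–3) is read and written natively with a 1 mm
coordinate quantization step, below any tolerance used downstream;
compressed LAZ is detected and rejected with a pointer to decompress
first. ASCII PLY carries small fixtures, normalized clouds
(`normalized_z` property) and hand-labelled plots (`hand_label`
property). Metric rasters are written as single-band 32-bit-float
GeoTIFFs with `ModelPixelScale`/`ModelTiepoint` georeferencing, a
projected EPSG code in the GeoKey directory and the nodata sentinel
(default −9999) in the conventional GDAL tag; the reader accepts both
byte orders. Mask polygons are read from GeoJSON (Polygon/MultiPolygon,
with a surface-type property). Values survive the GeoTIFF round trip to
float32 precision; nodata placement, transform and CRS survive exactly.

The mask burn-in rule is centre-point containment — a cell is masked
iff its centre lies in the polygon union — matching the cell-centroid
semantics of the metric grids; an "any-overlap" rule (3 × 3 interior
sample) is available for conservative masking. Point-in-polygon tests
use even-odd parity within a polygon (so holes work) and a union across
polygons (so overlapping polygons never unmask).

## Validation against hand labels

`validate_plots()` reproduces the hand-label protocol: for each 10 m
plot, every metric is computed twice through the *same* production code
path — once from the class-1 points, once from the hand-labelled
vegetation points — after a single shared normalization. The
misclassification rate is the fraction of class-1 points not labelled
vegetation; per-metric accuracy is the fraction of plots where the two
values do not differ. "Did not differ" defaults to
$|\Delta| \le 10^{-6}$ because exact float equality is brittle across
summation orders; a tolerance of 0 restores the literal criterion. A
metric that is nodata under both classifications counts as agreement;
nodata under exactly one counts as a difference.

## The synthetic-scene generator

`generate_scene()` emulates the statistical structure of leaf-off
national ALS data at desk scale: uniform planimetric positions at a
Poisson-realized density of 12 points/m² by default (within the
10–20 points/m² range of such surveys), a constant or gradient terrain
sampled by ground returns, vegetation strata with uniform height
ranges, and axis-aligned clutter boxes (boats, fences, cars) emitted as
class 1 with truth label `"other"`. Uniform distributions are chosen
deliberately: they make every metric analytically checkable. An
`ensure_ground_coverage` option plants one ground return per 1 m cell
(≈ +1 point/m²), mirroring the dense ground sampling of leaf-off
flights, so that noise-free scenes yield *exact* metric truths through
the real normalization path (without it, the rare vegetation-only 1 m
cell normalizes its own returns to 0 and blurs the constructed truth).
`make_validation_plots()` plants clutter blocks with integer counts so
the per-plot misclassification rate equals the recorded planted
fraction exactly.

What the generator does *not* emulate — occlusion, beam divergence,
return intensity, phenology, spatially autocorrelated canopies — bounds
what passing tests show: they certify the pipeline's arithmetic,
conventions and exactness properties, not its behaviour on the full
complexity of real canopies.

## Testing and problem sizes

The suite cross-checks every metric against independent brute-force
oracles (`quantile(type = 1)`, `e1071` moments, `lm()` plane fits,
explicit counting loops) on 1,000 random cells with up to 500 points, to
a relative tolerance of $10^{-9}$ ($10^{-6}$ for the plane fit, which is
solved by different algebra in the two routes); checks the partition and
ordering invariants on a 10,000-cell suite at $10^{-12}$; verifies
planted-truth recovery on 100 synthetic plots; and confirms
tiled-vs-untiled equality of all 26 GeoTIFFs on a 2 km × 2 km scene at
12 points/m² (about 48 million points, processed as four 1 km tiles and
as one piece). A +57.3 m elevation shift of an entire scene leaves all
metric rasters bit-identical, guarding against any accidental dependence
on absolute elevation. `scripts/acceptance.R` recomputes the headline
quantities from scratch on smaller scenes (100 m and 300 m extents) that
exercise every stage in a few minutes.

## Known limitations

* LAZ decompression and Shapefile reading are not built in; inputs must
  be LAS/PLY and GeoJSON.
* The per-cell-minimum normalization biases heights low wherever no
  near-ground return exists in a 1 m cell (dense evergreen canopy,
  water); the ground-free-cell count is the diagnostic.
* `Sigma_z` uses all vegetation points of the 10 m cell as the plane
  neighbourhood (the cell's infinite vertical column), the natural
  reading when no explicit neighbourhood radius is given.
* Rasters store float32; values with more than ~7 significant digits
  lose precision on disk (nodata and georeferencing are exact).
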