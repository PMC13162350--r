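---
title: "Safe climate space for bioenergy crops: models and conventions"
author: "scsbec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safe climate space for bioenergy crops: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Bioenergy with carbon capture and storage (BECCS) rests on feedstock crops —
maize, cassava, oil palm, millet, rice, sorghum, soybean, sugarcane — that are
grown today under a particular range of climates. The *safe climate space*
(SCS) of a crop is the region of baseline annual mean temperature and annual
precipitation that contains a stated share (by default 95%) of the crop's
gridded production mass; the residual 5% is treated as marginal cultivation.
As climates warm, grid cells currently producing a crop can move outside that
historical envelope. The package fits the envelope per crop, classifies
future climates against it, and quantifies three consequences:

1. **Exposure** — the production-weighted share of a region's cultivation
   (default: the tropics, cell centers with |lat| <= 23.5 degrees) that falls
   outside the envelope, per crop x region x scenario x period.
2. **Carbon** — cropland net primary production (NPP) and the
   negative-emission potential attributable to bioenergy cropping, and the
   fraction of that potential sitting in cells that leave the envelope.
3. **Trade-offs** — where the land carbon (aboveground biomass, AGB) and
   vertebrate species richness that would be put at risk by compensating
   cropland expansion are concentrated, via equal-frequency class maps,
   3 x 3 bivariate codes, and intact-forest overlap summaries.

Everything operates on regular latitude-longitude grids, cell-center
registered, row 1 northernmost, with `NA` as the single nodata sentinel
(ocean cells are nodata in every layer).

## The envelope model

`fit_envelope()` is the package's estimator. Production cells with nodata
baseline climate are dropped from the fit and from the coverage denominator
(the dropped mass is recorded on the model as `excluded_mass`). Two
geometries are provided because "an envelope containing 95% of production"
admits both a per-axis and a joint reading; the classification rule that
pairs with each is stated below, and neither is labelled the canonical one.

**Rectangular mode (default).** Per-axis limits are production-weighted
empirical quantiles at `alpha/2` and `1 - alpha/2`. Because trimming both
axes jointly removes more than `alpha` of the mass, `alpha` is chosen by
bisection (60 halvings on [0, 1]) as the largest symmetric trimming whose
joint rectangle still covers the target. The four limits are then tightened
greedily — each limit is moved to the next-inner distinct data value whenever
that keeps coverage at or above target, until no single-limit shrink is
possible. The reported rectangle is therefore *minimal*: moving any one limit
to its next-inner weighted-quantile candidate drops coverage below target.
The greedy pass matters because the symmetric-`alpha` solution alone need not
be minimal on discrete data.

**Density mode.** A 2-D histogram on (T, P), by default 100 x 100 bins
spanning the production cells' climate range; bins are retained in descending
order of production mass (ties broken by bin index, stably) until the
cumulative retained mass reaches the target. This traces multimodal or
curved production climates that a rectangle overstates.

**The weighted-quantile convention** is used verbatim everywhere quantiles
appear (envelope limits, percentile class breaks): the quantile at
probability `p` is the smallest data value whose cumulative weight reaches
`p` of the total — the left-continuous inverse CDF, ties resolved toward the
smaller value. The convention is load-bearing: coverage recounts and the
minimality property are only exact because fit and recount share it.

**Classification** (`classify_cells()` / `predict()`): a cell is inside iff
`T_low <= T <= T_high` *and* `P_low <= P <= P_high` — exceeding either axis
limit alone puts a cell outside. Comparisons are inclusive, so a future value
exactly at a historical limit is inside. In density mode a cell is inside
iff its (T, P) lands in a retained bin, using the same bin-indexing as the
fit, so classifying the fit baseline reproduces the fitted coverage exactly.
The mask is climate-only: it is defined on every cell with non-nodata future
climate, whether or not the cell currently produces.

**Exposure** is a ratio of production sums over region cells with a defined
mask; production on cells whose future climate is nodata is excluded from
numerator and denominator and reported separately, and a region with zero
production yields an `NA` share with a warning rather than a silent zero.
The envelope is always fitted on the full supplied domain while exposure is
reported over a region mask; the two domains are deliberately independent
parameters, since an envelope fitted globally is the reference against which
regional exposure is judged.

A caution on the monotonicity intuition: under a spatially uniform warming
with fixed precipitation one expects exposure to grow with the warming
magnitude. That is not a theorem for a rectangular envelope — a cell whose
baseline temperature sits *below* `T_low` can re-enter the envelope as it
warms. It holds whenever production mass is concentrated toward the envelope
interior, which is both what real cropping systems look like and what the
synthetic generator produces; the property suite verifies it across seeds
and crops rather than assuming it.

## Climate preprocessing conventions

* Annual aggregation: `T_ann` is the unweighted mean of the 12 monthly
  means; `P_ann` the sum of the 12 monthly totals. Any nodata month makes
  the cell nodata.
* Projection archives often carry only monthly extremes; the monthly mean is
  taken as `(tmax + tmin) / 2`, with inverted pairs flagged (and still
  computed), since inversions usually mean mis-stacked inputs.
* Ensemble means are unweighted per cell and month; a cell is nodata iff
  *any* member is nodata, which keeps the effective model count constant
  across cells instead of letting it drift where single models have gaps.
  Ensemble averaging precedes annual aggregation; both are linear so the
  order is immaterial numerically, but it is fixed for reproducibility.
* Holdridge life zones are computed as descriptive context (they do not
  enter the SCS classification): biotemperature is the mean of monthly
  temperatures clamped per month to [0, 30] degC — clamping before averaging
  is the standard convention — binned on log2-spaced edges
  {1.5, 3, 6, 12, 24} degC, with annual precipitation binned on
  {62.5, ..., 8000} mm. Intervals are half-open `(low, high]`; a value
  exactly on an edge joins the lower class. The package carries the two axes
  the analysis uses (biotemperature, annual precipitation) and omits the
  potential-evapotranspiration ratio axis.
* Cell areas use the spherical-cap band formula
  `R^2 * dlon * (sin(lat_top) - sin(lat_bot))`, R = 6371 km; over a
  full-globe grid the areas close to `4 * pi * R^2` to rounding, and
  mirror-symmetric rows get bit-identical areas.

## Carbon accounting

Cropland NPP is the literal four-factor product: production x dry-matter
fraction x shoot fraction x carbon fraction, converted tonnes C -> Tg C. The
sentence that defines it reads as a product, but harvest-index accounting
would *divide* by the shoot fraction to scale harvested shoots up to whole
plants; since the intent is not recoverable, `shoot_as_divisor = TRUE`
exposes the alternative and the default multiplies. The per-crop fractions
shipped in `default_pipeline_config()` are documented placeholders in
realistic ranges — real analyses should supply literature values per crop.

The natural-vegetation residual subtracts total cropland NPP from total NPP
on cells holding any analyzed crop. Because the two rasters are estimated
independently, the difference can go negative; negatives are clipped to 0
and the clip count is recorded, because silently negative residuals corrupt
per-area summaries. On unclipped crop cells, residual + cropland = total to
machine rounding.

Negative-emission potential defaults to cropland NPP times a capture
efficiency of 1, i.e. "potential" equals crop carbon uptake; any life-cycle
or process discount is a user-supplied efficiency, and no fossil-displacement
credit or storage modelling is attempted. Where several crops share a cell
the combined potential is the mean over crops present. The projected change
is the fraction of regional potential in cells classified outside the SCS;
it is invariant to rescaling production (homogeneity) and non-decreasing as
the outside set grows.

## Trade-off classification

Each ecological layer is first rescaled to percent of its maximum over
non-nodata cells (idempotent, so re-running the pipeline on its own outputs
is harmless). The three-category classification follows the printed cut
points — low below the 25th percentile, high above the 75th, medium between,
ties at a threshold to medium. Note these cut points give a 25/50/25 split,
not equal thirds; the package follows the stated percentiles rather than
silently substituting terciles, and offers `terciles = TRUE` (33.3/66.7) for
a true equal-frequency split. Percentiles use the package-wide weighted
quantile convention; area weighting is off by default and available through
the `weights` argument. Bivariate codes enumerate the 3 x 3 class pairs;
intact-forest summaries report per-region intact area (additive over
disjoint regions), its share of the global intact total, and area-weighted
AGB and richness densities per 100 km^2
(`sum(stock) / sum(area) * 100`).

Whether class breaks should be computed over tropical land only or all land
is a genuine analysis choice; the classification domain is simply the extent
of the rasters passed in, so either is available by masking first.

## The synthetic generator and what passing tests mean

All tests run on synthetic data with planted ground truth; no external
downloads are required. The generator's defaults are the package's fixed
desk-scale study conditions:

* **Grid**: 50 x 50 cells spanning 30S-30N — small enough for second-scale
  tests, wide enough that tropics masking and latitude-dependent areas bite.
* **Random fields** are smoothed white noise: an i.i.d. normal matrix
  convolved along both axes with a Gaussian kernel (sd `range_cells`,
  truncated at 3 sd, replicated-edge padding), then standardized. It is the
  simplest field with a controllable autocorrelation scale, and the recipe
  is documented so tests re-draw it independently.
* **Baseline climate**: temperature falls off linearly with |lat| from 27
  degC at the equator (0.35 degC per degree) with a hemispherically opposed
  seasonal cycle (half-range 6 degC at 45 deg); precipitation follows a
  Gaussian wet belt (2400 mm/yr at the equator, 25-degree scale) with
  multiplicative noise clamped at zero; 20% of cells form a contiguous
  nodata "ocean". These are round numbers chosen once to look like a
  tropical land belt.
* **Futures**: each member is baseline plus a scenario/period warming offset
  plus a model-level N(0, 0.3 degC) perturbation, with precipitation scaled
  per period — a deliberately physics-free stand-in for a downscaled
  multimodel ensemble (two scenarios nicknamed "2C" and "2.5C", four 20-year
  periods, 14 members).
* **Crops**: production mass is placed inside a prescribed true envelope
  with a Gaussian concentration kernel in standardized envelope coordinates
  times lognormal lumpiness — crops cluster in their climatic optimum —
  and exactly the requested mass fraction (default 5%) goes to cells just
  outside the bounds, weights decaying with the distance beyond the
  envelope. Totals are conserved to renormalization exactness and the
  planted outside fraction is recorded exactly as constructed.
* **Ecology**: AGB and richness share an exactly planted sample correlation
  (the richness residual field is sample-orthogonalized against the AGB
  field before mixing, so `cor()` returns the requested coefficient to
  rounding); the intact mask takes the top cells of a smooth field, so its
  land-cell share is exact to one cell and the mask is spatially coherent;
  ecoregions are equal-count slices of another smooth field.
* **Planted exposure** for end-to-end recovery plants a known outside share
  *relative to the fitted envelope*: producing cells that start outside the
  fitted bounds are moved to the envelope center, then producing cells are
  pushed past `T_high` in seeded random order until the accumulated mass
  best approximates the requested fraction. Planting against the generator's
  true bounds instead would confound recovery with the (legitimate) up-to-5%
  of mass a 95% envelope excludes at baseline. The achieved fraction is
  recorded exactly, cell granularity included; with the default lumpiness no
  single cell carries enough mass to move the achieved fraction more than a
  few thousandths from the request.

What the synthetic data does *not* emulate: GCM physics, bias correction or
downscaling artifacts, the empirical covariance of temperature and
precipitation change, irrigation, multi-cropping calendars, or the heavy
spatial skew of real production (single river valleys holding most of a
country's output). Passing recovery tests therefore demonstrates that the
pipeline's accounting is correct — shares classified and summed as defined —
not that real-data exposure numbers would be reproduced; those depend on the
real rasters.

## Numerical choices and degenerate inputs

* Coverage feasibility is tested with a 1e-12 slack so bisection is robust
  to accumulation error; achieved coverage is always a direct recount.
* A single production cell gives a degenerate point envelope with coverage 1.
* Density-mode histogram edges degenerate to a +/-0.5 window when an axis is
  constant.
* Fewer than 4 distinct values in the three-bin classifier warns and
  degrades gracefully (a constant raster is all-medium by the tie rule).
* Seeded draws never disturb the caller's RNG stream (`.Random.seed` is
  saved and restored), and every pipeline stage derives its own sub-seed
  from the master seed and a stage label via a 32-bit FNV-1a hash, so adding
  a stage does not shift the draws of the others.
* Raster I/O is the ESRI ASCII grid — the standard plain-text raster —
  written at full double precision so round-trips are bit-identical;
  non-square cells use the `dx`/`dy` header extension. Tables are CSV,
  envelopes and manifests JSON, configurations YAML.

## Problem sizes

The test suite and the acceptance script use 30x30 to 50x50 grids, 1-3
crops, 3-14 ensemble members, and up to 500-point envelope fits; the full
default pipeline runs in about a second and the whole suite in well under a
minute. These sizes are the package's chosen desk-scale study conditions;
the code paths are identical at 5-arcminute global scale, only slower and
memory-heavier (a global 5-arcminute monthly cube is ~2 GB per variable in
doubles — feasible, but expect minutes per stage rather than seconds).

## Known limitations

* Exceeding the envelope is not a yield projection: no CO2 fertilization,
  cultivar adaptation, management change, or crop-model response is modeled.
* Only rainfed production is in scope, and the envelope axes are annual
  means — sub-annual extremes (heat spikes at anthesis, dry spells) are
  invisible to it.
* Life zones are descriptive; classification uses raw T/P bounds.
* The alignment routines handle regular lat/lon grids only; no reprojection.
* Carbon fractions ship as placeholders; the negative-emission potential
  equals crop carbon uptake unless the user supplies capture efficiencies.
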