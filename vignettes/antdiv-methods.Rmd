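---
title: "Mapping diversity of a data-poor taxon: models and design choices"
author: "antdiv"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Global diversity maps exist for vertebrates because experts have drawn
range polygons for essentially every species. For hyperdiverse
invertebrate groups no such expert layer exists: what we have are
millions of heterogeneous occurrence records — literature citations,
museum specimens, database extracts — with missing coordinates, vague
locality strings, wrong country labels, and collecting effort
concentrated wherever entomologists happen to work. `antdiv`
implements the full inference chain from such records to richness and
rarity maps, diversity centers, cross-taxon congruence, and a
machine-learning counterfactual that asks what the maps would look
like if the whole world were sampled as intensively as its
best-sampled regions.

Every stage is exercised on a seeded synthetic world, so the chain is
testable end to end with no external data. This vignette documents
the models, their assumptions, the tunable parameters, and the design
decisions that were genuinely open.

# Occurrence QC

Records are pooled into locality groups on (normalized locality
string, country label, coordinates rounded to 4 decimals, about 11 m),
so each unique locality is treated once. Candidate coordinates are
validated — longitude/latitude bounds, exact (0,0) points, and
agreement between the coordinate's country (gazetteer lookup) and the
record's country label — and one coordinate per record is then chosen
by a fixed decision tree:

1. an original (metadata-carried) coordinate with no flags wins;
2. otherwise a geocoded coordinate with an agreeing country and a
   precision radius of at most 100 km is used;
3. otherwise the record is excluded.

The tree's priorities (originals first; the 100-km geocode cutoff) are
the published workflow's; the exact three-rule form is this package's
committed interpretation, including the case of a country-mismatched
original coordinate alongside a valid geocode, which falls through to
rule 2. Precision radii are a property of geocoding, so a missing
radius on the metadata branch is treated as trusted (radius 0) while a
missing radius on the geocode branch makes the candidate unusable.
Records resolved within 1 km of a country or admin-1 centroid *and*
whose locality names exactly that unit are flagged as polygon
centroids and excluded: such coordinates carry no information beyond
the admin unit itself. Country comparison is exact string match after
case/whitespace normalization — the synthetic gazetteer is clean, and
fuzzy matching or encoding repair would add nothing testable here.

# Range estimation

Method triage is by the count of unique occurrence localities:

| localities | method | weight per cell |
|---|---|---|
| 1–2 | 30-km buffered points | 1 |
| 3–4 | alpha hull (alpha = 15), buffered 30 km | 1 |
| >= 5 | suitability model inside the buffered hull | cloglog suitability |

The alpha parameter is interpreted in degrees, i.e. in the coordinate
units the hull is built in. The alpha complex is computed from a
Bowyer–Watson Delaunay triangulation (triangles with circumradius
<= alpha are kept; boundary edges are chained into rings), which
naturally yields disjoint parts for clustered points. Degenerate
inputs fall back to the convex hull and then to a buffered multipoint,
recording which fallback fired.

Buffering is done in a Lambert azimuthal equal-area frame centered on
the geometry rather than a global equal-area projection: single points
get analytic geodesic circles, polygons get the `buffer_km` contour of
a signed distance field on a fine local grid. The contour approach is
robust for concave shapes and repeated buffering (buffering twice by
15 km agrees with once by 30 km to well under 1% in area) and avoids
antimeridian edge cases, at the cost of a small discretization error.

Rasterization uses the cell-center rule (a cell belongs to the range
iff its center lies inside the polygon), which makes the rasterized
area an unbiased estimate of the polygon area. On grids coarse
relative to a 30-km buffer a polygon can contain no cell center; the
cell holding the polygon centroid is then used so every species has
positive area. All areas are analytic spherical cell areas
(R = 6371 km), so no equal-area reprojection is ever needed.

Species on the model branch are first spatially thinned to a 10-km
minimum nearest-neighbor distance (20 seeded randomized greedy passes,
keeping the largest retained set; an exhaustive maximum-independent-set
search is used only as a test oracle). Hull-only species are not
thinned — thinning exists to reduce sampling bias in model fitting.
If thinning leaves fewer than 5 localities the species falls back to
its polygon range.

# The presence-background model

Suitability is modeled with a penalized log-linear presence-background
(Gibbs) model: `p(x) ∝ exp(eta(x))` over the background, fitted by
minimizing

```
f(beta) = -mean_presence(eta) + log mean_background(exp(eta))
          + sum_f m * lambda_f * |beta_f|
```

by proximal gradient descent (soft-thresholding, backtracking line
search, at most 500 iterations, tolerance 1e-6 on the objective). The
objective is convex, and the L1 penalty drives coefficients exactly to
zero as the regularization multiplier `m` grows. The per-feature
penalty scale `lambda_f = sd_f(background) / sqrt(n_presences)`
reproduces the standard sample-size scaling without copying any
tool-specific constant table. Feature classes are the usual L
(standardized linear), LQ (plus squares), H (8 forward hinges per
variable, knots at equal background quantiles) and LQH. Predictions
use the cloglog transform `1 - exp(-exp(eta - r))` with
`r = log mean_background(exp(eta))`, an entropy-equivalent normalizer
fitted with the model; the transform is monotone in `eta`, so it never
changes rankings.

Background is sampled with replacement proportional to a global
sampling-density surface (Gaussian kernel density of all localities,
water removed, rescaled to maximum 1), so models contrast presences
against availability *with the same spatial bias* as the data. Extents
below 10,000 cells receive the full extent as background.

Candidates are every combination of the four feature classes and
multipliers 1–5, evaluated by cross-validation: leave-one-out below 25
localities (maximizing validation data at low n), random 5-fold
otherwise. Selection is sequential: drop candidates with no nonzero
coefficients; drop candidates whose Continuous Boyce Index (computed
on the full-data fit — validation folds are too small for it at low n)
is NA or <= 0; keep minimum 10-percentile omission rate; break ties by
maximum validation AUC, then minimum coefficient count, then (a final
determinism guarantee the published procedure leaves open) the simpler
class and smaller multiplier. If nothing survives the first two
filters the species keeps its polygon range with weight 1. The CBI
uses 101 moving windows of width one tenth of the background
suitability range.

# Diversity surfaces and centers

Richness stacks the per-cell weights, `s_i = sum_j w_ij`. Rarity adds
a damping constant to the inverse-range weight,
`r_i = sum_j w_ij / (a_j + c)` with `c = 60,000 km²` (a circle of
radius ~138 km): without damping, single-locality species — usually
artifacts of sampling islands — dominate the map. Setting `c = 0`
recovers classic rarity-weighted richness. For modeled species `a_j`
is the suitability-weighted area `sum_i w_ij * area_i`, consistent
with the richness weighting (the published formula does not state this
case; using hull area instead would make a species' rarity weight
inconsistent with its stacked contribution). Continuous weights also
enter the rarity numerator for the same reason.

Diversity centers are the cells holding the top 10% of unmasked area,
found by sorting cells by value (ties broken by cell index) and
accumulating spherical areas — not by a value quantile, which would be
biased on an unprojected grid. The polar exclusion band never enters.
Realized fractions exceed 10% by less than one cell's share, and the
mask is invariant to positive rescaling of the surface.

Resolution sensitivity uses block-maximum coarsening (a 2x2 block of
0.2/0.45/0.9/0.1 becomes 0.9; binary 0/0/1/0 becomes 1): if any part
of a coarse cell is suitable, the coarse cell is.

# Congruence, upper bounds, protection

Cross-taxon congruence is Spearman correlation over jointly non-NA
cells (zeros included, exclusion band removed) plus the area fraction
of center overlap. The overlap denominator is the first mask's area;
with equal-fraction centers the statistic is symmetric, matching the
single number reported per pair in comparable studies. Community-level
observations are compared as an upper bound: per coarsening factor,
the maximum observed richness per cell (never summed across studies,
because morphospecies cannot be matched between studies) is regressed
on the modeled value by OLS, reporting R² and bound violations.
Protected-area coverage uses union membership — a center cell is
protected iff its center lies in at least one reserve polygon — so
overlapping reserves are never double-counted and dissolving is
idempotent.

# The sampling-bias counterfactual

A Random Forest predicts the empirical richness (identity response)
or rarity (natural-log response, offset of half the smallest positive
value against exact zeros) from environment, an elevation-analog,
companion-taxon diversity, one-hot biogeographic realms (k = 1
nearest-neighbor filled where unlabeled), and the sampling-density
surface. Continuous predictors are screened for collinearity at
|r| > 0.7, dropping the higher-VIF member of the worst pair
(deterministic order); the density layer and realms are exempt.
Complexity is tuned by 5-fold spatial cross-validation on a 10 x 14
checkerboard (blocks assigned to folds by row-major index mod 5, so
horizontally adjacent blocks never share a fold — the committed
reading of a "systematic" assignment): `mtry` 1–10 by minimum average
held-out MSE, ties to the smaller value, 500 trees, other
hyperparameters at their defaults, seeded. The counterfactual sets the
density predictor to 1 (the observed maximum) everywhere, re-detects
centers on both surfaces, and classifies cells as robust / drop /
enter / noncenter; log responses are back-transformed (monotone, so
centers are unaffected).

# Rarefaction cross-check

An independent richness surface comes from moving-window
incidence-based rarefaction: per window (default 60 x 60 cells,
half-window stride, overlapping footprints averaged — the compositing
rule is this package's choice), incidences `Y_j` count distinct
occupied cells per species, and richness is estimated with
bias-corrected Chao2, `S_obs + ((T-1)/T) Q1²/(2 Q2)` (the
`Q1(Q1-1)/2` form when `Q2 = 0`), with the incidence coverage
estimator alongside. Windows with fewer than 2 occupied cells, or with
every incidence a singleton (`Q1 = U`), are excluded as unstable. The
"<2" rule counts *cells* with incidences, following the wording of
the procedure this mirrors. Note the estimator targets the gamma
diversity of the window, so recovery tests compare it to true window
richness, not to per-cell richness.

# The synthetic world

The generator emulates, with controllable parameters: smooth
environmental layers (12 random low-frequency cosine components plus a
latitudinal gradient, standardized over land); species as contiguous
environmental-distance patches grown to log-normal target areas
(defaults mu = log(6e5), sigma = 1.3 — chosen so that, like real
global compilations of a ubiquitous taxon, most land cells hold at
least one species; a world dominated by empty cells is *not* the
regime the downstream bias correction assumes); purely spatial
collection bias (records per occupied cell Poisson with mean
effort x density, independent of species identity given location — the
exact assumption the background sampler and counterfactual rely on);
record noise with per-record ground-truth labels (missing coordinates,
wrong countries, precision-radius mixtures with a tail beyond 100 km,
admin-centroid placement, verbatim duplicates; classes are mutually
exclusive per record so each QC flag is scored unambiguously);
companion taxa at a target Spearman correlation via Gaussian-copula
rank mixing (`rho_pearson = 2 sin(pi rho_s / 6)`); and overlapping
rectangular reserves grown to a target land coverage.

What it does not emulate: real biogeography or taxonomy, temporal
structure, taxonomic revisions, spatially correlated identification
error, non-Poisson clumping of collecting events, or realistic
reserve shapes. Passing tests therefore demonstrate that the chain's
logic is correct under its stated assumptions — not that those
assumptions hold for any particular real dataset.

# Numerical choices and problem sizes

* Grids are half-open cell intervals, north-up, cell-center
  registered; `cell_at` maps every in-extent coordinate to exactly one
  cell.
* The default study grid is a 1-degree, ±60-degree latitude band
  (43,200 cells, ~16,000 land) — coarse enough for desk-scale runs
  while keeping latitude-dependent cell areas; the full default
  pipeline completes in under 15 minutes on one CPU. The test suite
  and the acceptance script run the same chain at 2–4-degree
  resolution with reduced forest sizes; these sizes are stated in the
  relevant helper and script headers.
* The recovery experiment (`sampling_recovery_experiment`) fixes its
  conditions as part of the design: 2-degree grid, 250 broad-ranged
  species, bias contrast 3, polygon-only ranges, mtry 1–6 with 300
  trees. Under biased sampling the high-sampling counterfactual's
  Spearman correlation with true rarity exceeds the empirical map's.
* Seeds: every stochastic stage consumes a seed derived from the
  master seed through a fixed per-stage offset table, so adding a
  stage never perturbs earlier streams and reruns are bit-identical.
* Rasters are exchanged as plain-text Esri ASCII grids and polygons as
  GeoJSON — text formats that round-trip without any binary
  dependency; occurrence tables as CSV.

# Known limitations

* Polygon union is by membership semantics, not boundary
  reconstruction; exported GeoJSON of a dissolved layer retains the
  original features.
* Buffering is planar in a local equal-area frame; ranges spanning
  more than ~90 degrees of longitude would distort (none arise at the
  synthetic scales).
* The penalized fit uses a single global optimizer configuration; it
  is not a reimplementation of any specific legacy tool, and
  coefficient paths will differ from such tools in detail even where
  selection behavior matches.
* AUC values are comparable only within a species' candidate set, as
  is standard for presence-background evaluation.
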