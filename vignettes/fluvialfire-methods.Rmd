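---
title: "Methods: quantifying wildfire impacts on fluvial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying wildfire impacts on fluvial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluvialfire)
```

## The problem and the two quantities

Wildfire damages streams in two distinct ways that this package separates and
then recombines. Inside a burn perimeter, channels are directly impacted:
**SL_BA** is the stream + river length falling within severity-filtered
burned areas. Downstream, post-fire storm runoff carries ash and sediment far
beyond the perimeter, producing transient dissolved-oxygen (DO) sags:
**SL_LE** is the longitudinal extent of that propagating disturbance. Their
sum, expressed as a fraction of total network length, is the headline
percent-of-network-impacted statistic.

## SL_BA: severity filtering, minimum area, clipping, attribution

Burn products classify each mapped unit as one of six severity classes. Only
*low*, *moderate*, and *high* count as burned; *unburned*, *increased
greenness*, and *masked* are removed before any accounting
(`severity_filter()`). Fires whose severity-filtered footprint is smaller
than 4.1 km² are dropped (`apply_min_area_filter()`); a fire at exactly the
threshold is retained, reading "fires below ~4.1 km² removed" as a strict
less-than removal. The per-fire burned area we report is the
severity-filtered footprint area, not the raw perimeter area, because SL_BA
is measured against that footprint; `compute_fire_impacts(area_basis =
"perimeter")` switches to perimeter accounting where a comparison with
perimeter-based catalogues is wanted. Re-burns are treated independently per
fire id, with no deduplication across years.

`clip_length()` cuts every network polyline at its crossings with the
footprint boundary and classifies sub-segment midpoints by point-in-polygon
— exact for simple polygons, additive over disjoint multipolygon pieces, and
dual-checked in the test suite against a dense 1 m subdivision oracle
(agreement ≤ 0.1 % over 50 random scars).

Fires spanning several ecoregions get a single ecoregion — the one holding
the largest share of the burned footprint (`assign_ecoregion()`); exact ties
break lexicographically so attribution is deterministic.
`misattribution_fraction()` quantifies the cost of this single-assignment
rule as, per ecoregion, the fraction of burned area physically inside it but
attributed elsewhere. Annual aggregation keeps empty year × ecoregion cells
as explicit zero rows flagged `no_fires`, because "no fires reported" and
"zero burned length" are different facts for downstream plotting.

## Geometry: why it is built in, and what that constrains

No polygon-clipping library (sf/GEOS) is available in the target
environment, so the package carries its own planar primitives: shoelace
areas, ray-casting point-in-polygon, Sutherland–Hodgman clipping, and the
parametric polyline clipper. Sutherland–Hodgman is exact only when the
*clip* polygon is convex, so every internal polygon-on-polygon operation
clips against a convex piece; the generators cooperate by emitting convex
scar perimeters, convex severity patches, and rectangular ecoregions.
Arbitrary *simple* polygons are fine as clip targets for polyline length
(the route real hydrography data takes); self-intersecting rings are
rejected with a diagnostic rather than silently mis-measured. All
coordinates are planar Cartesian kilometres: real inputs must be
pre-projected to an equal-length-preserving CRS, which the package does not
check because the source projection is not part of its contract.

## The synthetic world

The generators state a world once; they are not tuned to make tests pass.

**Stream networks** (`generate_network()`). Horton's laws are statements
about averages: the length ratio R_L between successive Strahler orders lies
between 1.5 and 3.5 in real networks, averaging about 2, and the mean
first-order length default of 1.3 km matches a mapped mountain-watershed
value. The generator builds the tree top-down; a stream of order ω spawns
its order-(ω−1) tributaries at its upstream tip. Tributary counts are
`max(2, Poisson(r_b))` — the lower bound is 2, not 1, because a Strahler
order only increments where at least two equal-order streams join, and the
generator guarantees assigned orders equal recomputed orders (a 1-tributary
draw would break that invariant, so the package deviates deliberately from
a max(1, ·) draw). Lengths are lognormal with mean `mean_l1 · r_l^(ω−1)`
and CV `length_cv`; `length_cv = 0` gives the fully deterministic tree (with
`round(r_b)` tributaries) used for enumerable examples. Geometry is
piecewise linear with 6° bearing jitter inside nested angular wedges, and
embeddings are rejection-sampled against segment crossings; a region too
small to embed the tree raises an explicit error — never silent clipping.
The embedding scheme is entirely this package's invention: no claim is made
that the *planform* statistics (junction angles, sinuosity) match real
rivers, only the Hortonian length/order structure, which the tests verify
(empirical R_L within 10 % of the parameter over 20 seeds at order 6).

**Burn scars** (`generate_burn_scars()`). Areas are lognormal (defaults:
log-mean log(30) km², log-sd 1 — a heavy-tailed size distribution with most
fires tens of km² and rare large ones, consistent with the 4.1 km² filter
biting from below). Perimeters are random convex polygons scaled to the
drawn area; severity patches split each perimeter by area-bisected vertical
cuts so class areas realise the requested fractions exactly. Default
fractions (15 % unburned, 35 % low, 25 % moderate, 15 % high, 5 % + 5 %
greenness/masked) put ~75 % of perimeter area in retained classes. Real burn
mosaics are neither convex nor single-piece; what a green test establishes
is the correctness of the accounting pipeline, not realism of fire shapes.

**Ecoregions** (`generate_ecoregions()`). Recursive rectangle splits at
uniform(0.35, 0.65) positions — an exact partition with convex pieces.

**DO series** (`generate_do_series()`). Four stations at 68–117 km
downstream of the source mirror the sonde-array layout the propagation
analysis assumes. Each event's sag reaches a station after
`distance / celerity` hours (default celerity 2 km/h, a monsoon-pulse
travel speed), ramps down over 2 h, holds a 2 h plateau, and recovers over
4 h; the plateau guarantees the sampled minimum equals the analytic sag
depth exactly at `noise_sd = 0`, which the generator↔detector round-trip
tests rely on. Depth decays as the two-component exponential. Series are
clipped at 0 mg/L (anoxia occurs in real post-fire records) and clippings
are counted and messaged. Sensor noise is Gaussian (default 0.1 mg/L,
typical optical-DO precision); real sensor error is autocorrelated and
drifts, which the generator does not emulate — so detector false-positive
rates here bound only the white-noise case.

## Trend statistics

`theil_sen()` is the median of pairwise slopes (breakdown ≈ 29 %), with the
intercept `median(y − slope·x)`. Significance comes from the two-sided
Mann–Kendall test with tie correction and continuity correction — the
standard companion to Theil–Sen; the normal approximation is adequate at the
n ≈ 31 annual design this serves. A constant series returns slope 0 and
p = 1. Significance tiers use strict inequalities: p < 0.05 weakly,
p < 0.01 moderately, p < 0.0001 highly significant; p = 0.05 exactly is not
significant.

`ols_binned()` regresses per-year (or per-year-per-ecoregion — both
binnings are supported, since which one underlies a pooled slope is
ambiguous in general) totals of SL_BA on burned area, reporting
`r2_adj = 1 − (1 − R²)(n − 1)/(n − 2)`. Under uniform burn placement the
slope estimates drainage density, a property the suite verifies by
simulation (median fitted slope within 15 % of the true density over 20
seeds, 31 bins).

`weighted_kde()` evaluates the weight-normalised Gaussian mixture directly
(no FFT binning), so closed-form expectations hold to 1e-9; bandwidth
defaults to Silverman's rule on the weighted sample with effective n
`(Σw)²/Σw²`, and the grid extends 5 bandwidths past the data so the curve
integrates to 1 within 1e-3.

## Propagation

`detect_sag_events()` finds, per station, runs of at least 1 h below
(median baseline − 0.5 mg/L prominence), groups candidates across stations
within a 48 h window, and keeps groups spanning ≥ 3 stations with strictly
increasing times of minimum downstream — the "consistent temporal lags"
rule. The prominence default equals the 0.5 mg/L impact threshold; the run
duration plus multi-station coincidence makes white-noise false positives
vanishingly rare (0 in 100 seeded flat-series trials at noise of one third
the prominence). Real events were identified manually in the source
analyses; this detector is an explicit, reproducible stand-in, and
overlapping candidates merge into the running window with a logged message.
Each sag is flagged when its minimum breaches the 5.4 mg/L aquatic-life
standard. `sag_magnitude()` defines the baseline as the median of a 24 h
pre-event window — "pre-sag baseline" made concrete and configurable.

`fit_decay()` reads "two-component exponential decay" as the standard
biexponential Δ(x) = a₁e^(−k₁x) + a₂e^(−k₂x) (four parameters, the model a
curve-fitting platform fits under that name); a single-exponential mode is
available for comparison. Fitting is bounded (all parameters ≥ 0) L-BFGS-B
on the residual sum of squares from four starts: a log-linear
single-component start and three fast/slow splits. Biexponentials are
notoriously ill-conditioned; two safeguards keep the reported parameters
meaningful. Among starts tying the best SSE within 1e-10 relative, the fit
with the smallest secondary amplitude wins, and components with near-equal
rates (relative gap ≤ 1e-6) collapse into one — so noiseless
single-component data returns (a₁, k₁) to 1e-4 without a spurious second
term. Constant data yields the degenerate flag (k₁ = k₂ = 0, amplitudes
summing to the constant). The covariance for the bootstrap is the
Gauss–Newton σ²(JᵀJ)⁻¹ over active parameters.

`solve_extent()` bisects Δ(x) = threshold to 1e-6 km (the decay is strictly
decreasing when any rate is positive, so the root is unique); a source
magnitude at or below the threshold returns a flagged 0, and a non-decaying
component sitting at or above the threshold returns a flagged `Inf`
(unbounded extent — this matters for bootstrap draws near k = 0).

The Horton extent model `horton_sl_le()` is the explicit geometric sum from
order 1 to ω with the R_L = 1 limit ω·L̄(1). The printed closed form
L̄(1)(1 − R_L^ω)/(1 − R_L) equals that sum only when the disturbance starts
at order 1 — which is the only case the analysis uses; a general starting
order is deliberately not guessed. `horton_invert()` rounds the continuous
solution to the nearest integer: inverting at a 344 km extent with
L̄(1) = 1.3 and R_L = 2 gives 8.05 → order 8, whereas the exact order-8 sum
is 331.5 km — the published worked numbers are consistent with rounding,
not with a ceiling.

## Upscaling and uncertainty

DO is replenished by reaeration during transport, so DO-sag extent is a
conservative lower bound for conservative solutes (metals, nutrients, ash);
that motivates SL_LE ≈ SL_BA as the upscaling rule. `upscale()` therefore
doubles each ecoregion's SL_BA exactly and divides by network length; the
doubling identity holds to machine precision and percentages are monotone
in SL_BA.

`upscale_ci()` propagates decay-fit uncertainty by parametric bootstrap:
1000 seeded multivariate-normal draws of the fit parameters (truncated at
0), each re-solved for the threshold crossing; the draw's extent relative
to the point-estimate extent is a multiplier whose 2.5/97.5 % quantiles
scale SL_LE, and hence the combined percentage, multiplicatively. The
bootstrap was chosen over the delta method because the crossing is a
nonlinear root of the parameters and the bootstrap is robust, seeded, and
bit-for-bit reproducible; coverage of the true extent is ≥ 90 % over 100
simulation replicates in the suite (98/100 at the frozen seeds). How a
fit-line CI should map onto per-ecoregion error bars is not uniquely
determined; the multiplicative multiplier is this package's explicit
construction.

## Numerical choices and degenerate inputs

* Bisection tolerances: 1e-6 km for the threshold crossing; 80 bisection
  steps (≈ 1e-24 relative) for severity-patch area cuts.
* Point-in-polygon counts boundary points as inside; clipping tolerances sit
  at 1e-9–1e-12 km, far below any stated 1e-6 contract.
* Ties: ecoregion assignment breaks ties lexicographically; the Theil–Sen
  slope of a constant series is 0 with Mann–Kendall p = 1.
* Empty cases are values, not errors: a scar with no retained severity
  classes has a zero-area footprint; zero fires yield an empty record table;
  a region with no burned area reports a missing SL_BA:area ratio.
* Reproducibility: every generator and the bootstrap take an explicit seed;
  identical seeds give byte-identical outputs.

## Known limitations

* Impoundments are ignored: a dam can delete the propagating signal
  entirely, so SL_LE estimates apply to free-flowing paths.
* No mechanistic solute/sediment transport — the decay model is an
  empirical envelope, chosen precisely because available data cannot
  constrain a transport model.
* The geometry layer targets simple polygons in planar km; geographic
  (degree) coordinates, holes, and braided (non-tree) hydrography are out
  of scope.
* Headline continental-scale magnitudes (hundreds of thousands of km of
  SL_BA) require the full national burn/hydrography extracts; the synthetic
  world validates the machinery at desk scale, not those magnitudes.
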