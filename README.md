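# fluvialfire

Wildfires burn watersheds, and the streams draining them carry the damage far
beyond the burn perimeter: post-fire storm runoff flushes ash and sediment
into channels, driving dissolved-oxygen (DO) sags and other water-quality
excursions tens to hundreds of kilometres downstream. `fluvialfire` is an R
implementation of the full analysis chain for quantifying those impacts on a
fluvial network, aimed at ecohydrologists and watershed managers:

1. **SL_BA** — the stream + river length falling *within* burned areas:
   burn-severity filtering (keep low/moderate/high, drop
   unburned/increased-greenness/masked), removal of fires burning < 4.1 km²,
   geometric clipping of the hydrography against each burned footprint, and
   ecoregion attribution by largest burned area.
2. **Trends** — Theil–Sen slopes with Mann–Kendall significance for annual
   SL_BA series, binned OLS of SL_BA against area burned, and SL_BA-weighted
   kernel densities of fire coordinates.
3. **SL_LE** — the *longitudinal extent* of downstream disturbance: DO-sag
   detection across a multi-station sonde array, a two-component exponential
   decay fit of sag magnitude vs distance,

   Δ(x) = a₁·e^(−k₁x) + a₂·e^(−k₂x),

   and the distance x\* where Δ(x\*) crosses the 0.5 mg/L impact threshold.
4. **Horton's-law validation** — with mean first-order stream length L̄(1)
   and length ratio R_L (field range 1.5–3.5, typically ≈ 2), the in-series
   extent from order-1 headwaters to order ω is the geometric sum

   SL_LE = Σᵢ₌₁..ω L̄(1)·R_L^(i−1) = L̄(1)·(1 − R_L^ω)/(1 − R_L),

   inverted to find the Strahler order a disturbance can reach.
5. **Upscaling** — the conservative assumption SL_LE ≈ SL_BA doubles the
   impacted length, expressed per ecoregion as a percentage of total network
   length, with a parametric-bootstrap 95% CI propagated from the decay fit.

Everything runs on seeded synthetic inputs (Horton-law stream networks,
lognormal convex burn scars with severity patches, rectangular ecoregion
partitions, plateau-pulse DO series), so the whole pipeline is testable
offline; the same readers accept pre-projected real extracts in the
documented GeoJSON/CSV schemas (planar km coordinates).

## Worked example

```r
library(fluvialfire)

hp    <- horton_params(r_b = 2, r_l = 2, mean_l1 = 1.3, max_order = 5, length_cv = 0.25)
net   <- generate_network(hp, seed = 7)              # 68 streams, 187.57 km
emap  <- generate_ecoregions(net$region, 3, seed = 8)
scars <- generate_burn_scars(net$region, burn_gen_spec(40, area_log_mean = log(40)), seed = 9)

rec <- compute_fire_impacts(net, scars, emap, min_area = 4.1)
sum(rec$sl_ba_km)                                    # 32.69 km of SL_BA (39 fires retained)

ds  <- do_sag_spec(c(68, 82, 99, 117), baseline_do = 7.2,
                   components = c(a1 = 5, k1 = 0.01, a2 = 0, k2 = 0),
                   event_times = c(120, 300, 480, 660), noise_sd = 0.05)
ev  <- detect_sag_events(generate_do_series(ds, seed = 10))   # 4 events x 4 stations
fit <- fit_decay(ev$distance_km, ev$delta_do)
fit
#> <decay_fit double> delta(x) = 4.871 e^(-0.009368 x) + 0 e^(-0 x), R^2 = 0.994, n = 16
est <- estimate_propagation(fit, horton_params(r_l = 2, mean_l1 = 1.3), threshold = 0.5)
#> SL_LE = 243.0 km, reaching order 8
```

The fitted decay recovers the generator's truth (a₁ = 5, k₁ = 0.01) from 16
noisy sag magnitudes; 243 km is where the fitted sag falls below 0.5 mg/L,
and inverting the Horton model says such a disturbance reaches an 8th-order
stream. Upscaling per ecoregion (regions with stream length):

```r
slba  <- tapply(rec$sl_ba_km, rec$ecoregion, sum)
netlen <- sapply(names(emap$polygons), function(nm) clip_length(net, emap$polygons[[nm]]))
keep  <- names(netlen)[netlen > 0]
up    <- upscale(slba[keep], netlen[keep])
ci    <- upscale_ci(fit, up, n_draws = 1000, seed = 11)
ci$summary[, c("ecoregion", "pct_of_network", "ci95_low", "ci95_high")]
#>   ecoregion pct_of_network ci95_low ci95_high
#> 1       E01            0.0      0.0       0.0
#> 2       E02           39.3     38.8      39.8
#> 3     study           34.9     34.4      35.3
```

The combined impacted length is exactly twice SL_BA (the SL_LE ≈ SL_BA
doubling), and the CI reflects decay-fit parameter uncertainty via a seeded
parametric bootstrap (multiplier 95% CI here: 0.974–1.027). Annual Theil–Sen
trends on this generator are correctly ≈ 0 km/yr — the synthetic world has no
built-in temporal trend, so none is detected.

A reference inversion of the Horton extent model at a 344 km extent with
L̄(1) = 1.3 km and R_L = 2 gives stream order 8 (continuous solution 8.05):

```r
horton_invert(344, horton_params(r_l = 2, mean_l1 = 1.3))   # 8
```

## Command line

A thin umbrella CLI ships in `inst/cli/fluvialfire.R`
(`simulate | slba | trends | propagate`), reading and writing the GeoJSON/CSV
schemas above; it needs the `optparse` package.
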