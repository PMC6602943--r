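# ahah — a composite index of neighbourhood access to healthy assets and hazards

Health geographers summarise how health-promoting a small area is by
combining *accessibility* measures — how far residents must travel to reach
services that help (GPs, pharmacies, dentists, A&E hospitals, leisure
centres) or harm (fast-food outlets, gambling outlets, off-licences,
tobacconists, pubs/bars) — with features of the *physical environment*
(public green space within walking reach, ambient NO₂, PM₁₀ and SO₂).
This package builds such an Access to Healthy Assets and Hazards (AHAH)
index end to end, for researchers and analysts who want a tested, fully
reproducible implementation of the construction rather than a one-off
national data product.

Because the national inputs (commercial retail registers, NHS service
lists, DEFRA pollution rasters, OSM road networks, postcode lookups) are
proprietary or bulky, the package ships a **seeded synthetic study region**
with the spatial structure the method assumes — an urban core where
services and hazards co-cluster and pollution peaks, satellite towns, a
suburban ring and a remote periphery — so every stage is testable offline.

## The construction

For each postcode, network distance (km) to the nearest facility of each of
10 categories is computed by shortest paths on a directed road graph
(one-way restrictions honoured; points snap to the nearest node). Green
space is the area (m²) of public green polygons intersecting a 900 m buffer
around the postcode centroid; pollutant values are unweighted means of the
1×1 km raster cells overlapping each zone. Postcode measures are averaged
(unweighted) to zones, giving a zone × 14 indicator table.

Each indicator is oriented so that larger = less healthy (retail distances
and green area are flipped), then standardised by the Rankit rank-based
inverse normal transform

	z_i = Φ⁻¹((r_i − ½) / N),

averaged with equal weights into three domain scores (retail, health
services, physical environment), and each domain is ranked (rank 1 = most
health-promoting) and scaled to R = rank/N ∈ (0, 1]. Following the 2015
English Index of Multiple Deprivation, each domain rank is exponentially
transformed,

	X = −23 · ln(1 − R·(1 − e^(−100/23))) ∈ (0, 100],

which weights the worst-ranked zones heavily so a very poor domain cannot
be cancelled out by good ones. The index is the equal-weight mean of the
three X scores, with ranks and deciles (decile 1 = healthiest tenth).

## Worked example

```r
library(ahah)
fit <- run_pipeline(region_config(seed = 1))
fit
#> Access to Healthy Assets and Hazards index: 50 zones
#>   polarity: higher score / decile = less healthy; rank 1 = healthiest
#>   index score: min 8.376, median 18.703, max 71.307
summary(fit)
#> AHAH index over 50 zones (higher = less healthy)
#> index score:
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   8.376  14.850  18.703  22.744  27.429  71.307
#> mean domain scores (X):
#>   retail   health physical
#>   22.744   22.744   22.744
#> zones per decile (1 = healthiest):
#>  1  2  3  4  5  6  7  8  9 10
#>  5  5  5  5  5  5  5  5  5  5
head(as.data.frame(fit)[, c("zone_code", "index_score", "index_rank",
                            "index_decile", "retail_X", "health_X", "physical_X")])
#>   zone_code index_score index_rank index_decile retail_X health_X physical_X
#> 1      Z001      27.458         38            8   3.4205    50.43     28.526
#> 2      Z002      17.243         21            5  11.5515    20.63     19.545
#> 3      Z003       9.893          3            1   8.7307    19.55      1.404
#> ...
```

Zone Z003 sits in the suburban ring: close to health services
(health_X 19.6), clean air and plenty of green space (physical_X 1.4), and
moderately far from hazardous retail — so it lands in decile 1. The three
domain X columns have equal means by construction (each is the same
exponential transform of a rank permutation); the *index* varies because
zones rarely rank equally in all three domains.

`run_pipeline(cfg, out_dir = "out")` additionally writes the region files
(CSV/GeoJSON/ESRI ASCII grid), the postcode-level measures, the zone × 14
components table with deciles, the index table and correlation diagnostics,
all in fixed 6-decimal text so reruns are byte-identical. A thin CLI over
the same functions is in `inst/cli/ahah.R`
(`simulate`, `access`, `environment`, `index`, `run-all`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch on the default synthetic region
with the given seed — region generation, routing, buffer and zonal
measures, aggregation and index construction — logs summary statistics, and
writes the JSON report to `--out`.

## Vignette

`vignettes/ahah-methods.Rmd` documents the model and its assumptions, every
tunable parameter with units and defaults, what the synthetic region does
and does not emulate, the numerical choices (tie handling, circle
approximation, quantisation), and known limitations.
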