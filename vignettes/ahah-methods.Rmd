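---
title: "Methods: building a composite access-to-healthy-assets-and-hazards index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building a composite access-to-healthy-assets-and-hazards index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahah)
```

# The model

The package constructs a small-area composite index of neighbourhood access
to health-promoting assets and health-negating hazards. Fourteen indicators
feed three domains:

* **Retail environment** (5): network distance (km) from each postcode to
  the nearest fast-food outlet, gambling outlet, off-licence, tobacconist,
  and pub/bar/nightclub. Being *nearer* to these is treated as less healthy.
* **Health services** (5): network distance (km) to the nearest GP practice,
  A&E hospital, pharmacy, dentist, and leisure centre. Being *farther* is
  less healthy.
* **Physical environment** (4): area (m²) of public green space
  intersecting a 900 m buffer around the postcode centroid (more is
  healthier), and zone-mean NO₂, PM₁₀ and SO₂ concentrations from 1×1 km
  rasters (more is less healthy).

The construction pipeline is:

1. **Routing.** Distances are shortest directed paths on a road graph with
   one-way restrictions; cost is length in km (no travel-time profile).
   Points snap to the nearest graph *node*; the Euclidean snap legs are
   reported for audit but excluded from the distance. One multi-source
   computation over the edge-reversed graph per category gives results
   identical to per-pair minima (verified exactly against a brute-force
   Dijkstra oracle in the tests).
2. **Aggregation.** Postcode measures are averaged to zones by the
   *unweighted* arithmetic mean; zone population is metadata only. Green
   space aggregates postcode→zone by the same mean for consistency with the
   distances (the published sources do not state the rule for this
   indicator).
3. **Orientation.** Indicators whose larger raw values are healthier
   (the five retail distances and green area) are negated, so after
   orientation larger always means less healthy.
4. **Rankit standardisation.** Each oriented indicator is mapped to
   standard-normal scores via `qnorm((r - 0.5)/n)` with average ranks for
   ties. Any strictly monotone transform of a raw indicator (km→miles,
   log-concentrations) therefore leaves everything downstream unchanged —
   a property the acceptance tests assert.
5. **Domains.** Equal-weight means of the domain's standardised indicators
   (weights 1/5, 1/5, 1/4, exposed via `ahah_weights()` for re-weighting).
6. **Exponential rank transform.** Each domain is ranked (rank 1 = most
   health-promoting), scaled to `R = rank/N`, and transformed with
   `X = -23*ln(1 - R*(1 - exp(-100/23)))`, the transformation used by the
   2015 English Index of Multiple Deprivation. `X` is strictly increasing,
   maps (0, 1] onto (0, 100] with `X(1) = 100` exactly, and is convex: it
   concentrates weight on the worst-ranked zones, so one very poor domain
   is *not* cancelled by two good ones (the cancellation-resistance test
   makes this precise by comparing against linear rank averaging).
7. **Index.** Equal-weight mean of the three X scores, ranked and cut into
   deciles by rank.

## Polarity and ties

The published construction fixes ranking language ("most health promoting"
= rank 1/N) but not a numeric polarity for output files. This package's
convention, stated in every output header: **higher score and higher decile
= less healthy**; rank 1 and decile 1 are the most health-promoting. Ties
use average ranks inside Rankit (standard for rank-based INT), but
*ordinal* ranks — tie-broken deterministically by zone code — for domain
ranks, R, and deciles, so rank fractions are distinct, `X` is well defined,
and deciles partition zones into groups of ⌊N/10⌋ or ⌈N/10⌉. A real data
product built with different tie handling could differ in tied regions.

## Open readings resolved

* *Clipped vs whole-polygon green area*: "area of green space intersecting
  the buffer" is ambiguous. The default computes the **clipped**
  intersection area (bounded by the buffer area, scale-consistent);
  `green_area_mode = "whole_polygon"` gives the alternative reading.
* *Cell membership for zonal means*: a raster cell contributes when its
  square footprint overlaps the zone with positive area ("overlapping"),
  with `rule = "centre"` as the switchable alternative.
* *Buffers are Euclidean*, per the stated method, although the 15-minute
  walk rationale might suggest network reach.
* *Snap legs and routing cost*: whether the original Routino distances
  include snap legs, and whether they optimise distance or a profile cost,
  is unstated; this package excludes snap legs and minimises distance.
* The exponential transformation is applied to domain ranks only; the
  combined index is ranked for deciles but not re-transformed (mirroring
  the IMD-2015 reading).

# Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `buffer_m` | 900 | m | European Environment Agency 15-minute-walk recommendation; 600/700/800 were the published sensitivity radii and are cheap to re-run |
| `segments_per_quarter` | 64 | — | buffer circles are fixed 256-gons so areas are deterministic cross-platform; area deficit < 1e-4 relative |
| `green_area_mode` | `"clipped"` | — | see above |
| `overlap_rule` | `"overlap"` | — | see above |
| weights | equal | — | no causal evidence for unequal weights; `ahah_weights()` exposes them |
| `raster_cell_km` | 1 | km | resolution of the national pollution model being emulated |

# The synthetic study region

`region_config()` describes a 20 km × 20 km planar extent (Cartesian
metres, no geographic CRS anywhere) tiled by 50 rectangular zones with
500–3,000 "residents" each, matching UK LSOA / Data Zone sizes; 5–20
postcodes per zone with 1 m-resolution centroids. The road network is a
jittered 1 km lattice with 5–25% detour factors and 10% one-way edges,
strongly connected by construction and verified. A single master seed fans
out to fixed per-component child seeds, so adding a component never
reshuffles the others, and a fixed seed gives byte-identical output files.

Service placement follows a **settlement system**: one urban core plus five
satellite towns spaced around it at 55–85% of the half-extent (stratified
angles — a central-place pattern; real towns space out to serve
hinterlands). Hazardous retail concentrates in the core (core share
`1-(1-urban_fraction)/2`, i.e. 0.85 by default, spread σ = 1.5 km);
health services follow residential population (core share
`urban_fraction/2` = 0.35, suburban spread σ = 5 km, remainder in towns).
Pollutant surfaces are a localised Gaussian plume on the core
(σ = 1.2 km) plus noise over a rural background, so suburban air differs
from rural mostly by noise. Green-space density is suppressed in the core
and saturates outside it. Category counts default to national prevalence
scaled to a 400 km² mixed region (3 A&E hospitals is already generous —
GB has roughly one per 1,000 km²).

Zone classes follow settlement geography: `core` (centroid within 35% of
the half-extent), `remote` (beyond the half-extent radius *and* >3 km from
every town — a genuine service desert; zone geographies are
population-based, so truly remote zones are a small minority), `ring`
otherwise. With these defaults the region reproduces the qualitative
national pattern: suburban-ring zones score healthiest on average, while
cores (hazards + pollution) and remote zones (catastrophic health-service
access, punished by the exponential transform) score worst. The tests
assert this on seeds 1–3; it was verified on seeds 1–15 during design.

**What a green test does and does not establish.** The generator emulates
statistical and spatial *structure* — co-clustering of services (which
also produces the positive correlations among distance indicators that the
diagnostics report), urban pollution gradients, green-space distribution —
not Great Britain. Passing tests establish that the construction machinery
is correct and that the index responds to that structure as designed; they
say nothing about agreement with the published national data product,
which depends on proprietary inputs. Small-count categories (hospitals)
can decorrelate from other indicators on some seeds, as in reality.

# Numerical choices

* **Geometry** is exact planar arithmetic: Sutherland–Hodgman clipping
  against convex windows (buffer discs, raster cells) and an exact
  union-area algorithm (vertical slab decomposition at vertex and
  edge-crossing abscissae; union length is linear within a slab, so the
  midpoint rule integrates exactly). Verified against Monte-Carlo oracles.
* **Normal quantiles** use R's `qnorm` (Wichura's AS 241, accurate to
  ~1e-15); the tests check 1e-10 agreement with an independent
  bisection-plus-Newton inversion of `pnorm`.
* **Degenerate inputs**: a single zone yields R = 1, X = 100 in every
  domain, index 100, decile 1. Zero-variance indicators yield NA
  correlation markers, never NaN propagation. Self-intersecting green
  rings, dangling edge references, nonpositive lengths, unreachable
  origins and zone/raster mismatches raise errors naming the offending
  object; an `allow_unreachable` flag turns unreachable origins into
  `Inf` distances instead.
* **Determinism**: all tabular output is fixed 6-decimal text; generated
  quantities are rounded to that precision at creation so write→read
  round-trips are lossless and reruns byte-identical.
* The fine-rasterisation oracle used in tests has a 10 m validity limit:
  it cannot see cell overlaps shallower than its own grid, so oracle
  comparisons draw zones in general position (every cell overlap either
  empty or > 200 m²).

# Known limitations

* Node snapping (not nearest-point-on-edge) biases distances upward by up
  to half an edge length; with the 1 km synthetic lattice this is ≤ ~500 m.
* No travel-time routing, turn restrictions, or barriers beyond edge
  absence.
* Unweighted postcode→zone aggregation ignores within-zone population
  distribution.
* The index polarity, tie handling, and green-space aggregation rule are
  this package's documented choices where the published description is
  silent; comparisons against the published CSVs would need to confirm
  them.
* The synthetic region's single-core geography cannot represent
  polycentric conurbations or coastlines.
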