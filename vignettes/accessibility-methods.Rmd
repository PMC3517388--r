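---
title: "Methods: travel-time accessibility and capacity-constrained coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: travel-time accessibility and capacity-constrained coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(phcatch)
```

phcatch estimates how much of a population can physically reach a primary
health care facility within a travel-time limit, and how much of that
accessible population the facilities can actually absorb given their
capacities. This vignette documents the model, every tunable parameter, the
numerical choices, and the limits of what the test suite demonstrates.

## 1. The model

The analysis runs on an aligned raster stack (90 m cells by default):

1. **Merged cost surface.** Landcover classes are overlaid by water
   polygons, then river lines, then road lines, in that fixed precedence
   (`merge_cost_surface()`). A bridge is therefore just a road cell that
   overwrote a river cell. Within the road layer, national beats district
   beats rural wherever classes share a cell, so the merge is independent of
   feature order. Water and rivers are absolute barriers in every scenario.

2. **Facility cleaning.** Facilities missing coordinates are excluded
   (no location, no travel time); facilities missing only their capacity
   are excluded from the capacity-constrained allocation; facilities
   sitting on a barrier cell are relocated to the nearest traversable cell
   (Euclidean distance from the point to cell centers, ties broken by
   ascending row then column). Exclusion tallies are reported with
   percentages rounded half up to one decimal (`clean_facilities()`).

3. **Dasymetric population mapping.** Administrative sectors carry only a
   total population. Per-landcover-class density weights are estimated from
   "pure" sectors — sectors whose every non-excluded cell shares one
   inhabited class — as population divided by total sector area, averaged
   over pure sectors and rescaled to a maximum of 1. Classes never observed
   pure receive the mean of the estimated weights. Water, river and road
   cells get exactly zero. Each sector's total is then spread over its
   cells proportionally to the weights, conserving every sector total to
   machine precision (`estimate_density_fractions()`,
   `dasymetric_redistribute()`).

4. **Anisotropic travel time.** Patients travel toward facilities over an
   8-connected grid graph. The edge entered from neighbouring cell B into
   cell A costs `(d/2) * (1/v_B + 1/v_A) * 60` minutes, where `d` is the
   cell size (axial) or `cell size * sqrt(2)` (diagonal) and the speeds are
   slope-corrected for the patient's direction of motion. A multi-source
   Dijkstra (C++, `travel_time_from()`) yields minutes-to-facility per
   cell, capped at 60 minutes; cells beyond the cap and unreachable cells
   are flagged separately.

5. **Catchment allocation.** Facilities are processed sequentially. Each
   claims unclaimed cells in ascending travel time (ties by row, then
   column) while its cumulative claimed population stays strictly below its
   capacity. The binding constraint — time cap or capacity — is recorded
   per facility. Covered plus underserved equals the total population
   exactly (`allocate_catchments()`, `coverage_report()`).

## 2. Travel scenarios and speeds

Three scenarios share the off-road walking speeds and differ on roads:

* **Scenario 1** — walking everywhere (roads walked at 5 km/h).
* **Scenario 2** — bicycle on all roads (10 km/h base), walking elsewhere.
* **Scenario 3** — motorized transport on national (50 km/h) and district
  (20 km/h) roads, walking elsewhere (rural roads at 5 km/h).

`speed_table()` prints the full class-by-scenario table. Slope corrections:

* **Walking** uses the Tobler hiking function normalized so that flat
  ground reproduces the class base speed:
  `v = base * exp(-3.5 * |s + 0.05|) / exp(-3.5 * 0.05)`.
* **Cycling** solves a constant-power balance
  `0.5 * rho * CdA * v^3 + m * g * (Crr + s) * v = P0`, with `P0`
  calibrated so flat speed is the 10 km/h base (Newton iteration,
  `cycling_speed()`). Downhill speed is capped at 1.5 times the flat speed,
  and the effective road speed is floored at the Tobler walking speed of a
  5 km/h walker — on slopes too steep to ride, the rider pushes the bike.
  The floor is what guarantees the per-cell dominance property (scenario 2
  never slower than scenario 1 on any cell).
* **Motorized** speeds are not slope-corrected.

Cycling parameters (`cycling_params()`): rider+bike mass 90 kg, g = 9.81
m/s², rolling resistance 0.008, air density 1.2 kg/m³, CdA 0.5 m². These
are ordinary utility-cycling values; the model is deliberately simple and
its role is to interpolate plausibly between the calibrated flat speed and
the walking floor.

## 3. The synthetic generator

`generate_landscape(synth_config(seed))` builds every input the pipeline
consumes from one seeded random stream: a smoothed random-field DEM
(900–3000 m relief), a lake polygon, a Voronoi sector tessellation with
integer populations apportioned by largest remainder (sums are exact),
landcover patches from a configurable class mixture with a quota of forced
single-class sectors (so density estimation is always exercised), one
spanning-tree road network per class, rivers, and a facility table with
injected missingness (both fields / coordinates only / capacity only) and
deliberate water placements. `ground_truth()` exposes the injected values
for recovery tests; `write_bundle()`/`read_bundle()` round-trip everything
through plain-text formats (ESRI ASCII, GeoJSON, CSV, JSON).

The defaults describe the study-like condition the package targets: a
mountainous province with 2,091,065 inhabitants in 97 sectors, 113
facilities of which 9 miss both coordinates and capacity, 7 coordinates
only, 3 capacity only and 3 sit on water. The default domain is 120 × 120
cells of 90 m — a desk-scale stand-in for a real province-sized extent.
The test suite's property checks additionally use a smaller 70 × 70
fixture (30 sectors, 500,000 people, 30 facilities) so that twenty full
pipeline runs stay fast; that size is this package's own choice, made
before any outcomes were inspected.

**What passing tests do not show.** The generator preserves the structural
properties the pipeline relies on (tessellation, connectivity, barrier
topology, missingness patterns) but not the morphology of real terrain,
hydrology or road networks. Coverage percentages obtained on synthetic
landscapes are not predictions for any real region; only the *invariants*
(conservation, dominance, determinism, oracle equivalence) transfer.

## 4. Numerical choices

* Shortest paths run in C++ (binary-heap Dijkstra with lazy deletion); the
  test suite checks it cell-for-cell against an independent Bellman–Ford
  relaxation oracle and against igraph.
* Percentages are rounded half up at one decimal (`round_half_up()`), the
  reporting convention throughout; R's default banker's rounding would
  differ on exact .5 boundaries.
* Grid I/O uses ESRI ASCII with fixed `\n` line endings and `%.12g`
  floating-point formatting, which is why identical runs are byte-identical
  across platforms.
* Bilinear resampling (DEM) clamps to the source extent; categorical
  resampling is nearest-neighbour only and can never invent class codes.

## 5. Known sensitivities and open questions

* **Processing order.** Sequential allocation makes results depend on
  facility order when service areas compete. The order is an input
  (default: cleaned-table order), and `coverage_order_spread()` quantifies
  the spread of covered population under random orders rather than hiding
  it.
* **Coverage need not rise with faster travel.** Per-cell travel times
  under scenario 2 are provably never worse than scenario 1, and the
  population *within the time cap* therefore never falls. But the
  capacity-constrained covered population can fall: faster travel can let
  an early-processed facility absorb high-population cells from a later
  facility's exclusive area and then hit its capacity, leaving cells only
  it could serve unserved. This occurs occasionally on capacity-starved
  synthetic landscapes (observed on 2 of 20 test seeds, at about 1% of the
  total population) and is a property of sequential capacity-constrained
  allocation itself, not an artefact of this implementation.
* **Relocation is an approximation.** Moving a water-sitting facility to
  the nearest traversable cell ignores why the coordinate was wrong in the
  first place; the `relocated` flag is carried through so downstream users
  can audit these cases.
* **Pure-sector density estimation is sensitive to which sectors happen to
  be pure**; with few pure sectors per class the class weight rests on a
  handful of observations. `tidy()` on the fraction object reports
  `n_pure_sectors` per class for exactly this reason.

## 6. Reproducing a full run

```r
bundle <- generate_landscape(synth_config(seed = 1))
run <- run_pipeline(bundle, scenarios = 1:3, out_dir = "run1")
run$coverage
```

`run_pipeline()` writes every intermediate raster, the per-facility logs
and the coverage report (CSV and JSON, both carrying a provenance hash of
all tunable parameters) into `out_dir`, and two runs with the same seed
produce byte-identical files.
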