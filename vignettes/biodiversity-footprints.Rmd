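---
title: "Methods: land- and GHG-driven biodiversity footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land- and GHG-driven biodiversity footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodivfootprint)
```

## What the package computes

Food production affects biodiversity through two channels with very
different spatial logic. Converting land to cropland or pasture removes
biodiversity *where the land is*; the loss is a one-off cost of the
conversion. Emitting greenhouse gases warms the *whole* planet; the loss is
global and recurs with every year of emissions. This package expresses both
channels as characterization factors (CFs) in a common unit — species × km²
of biodiversity loss per €1M of a sector's output — and propagates them
through an environmentally extended Leontief model, so that production,
consumption, bilateral-trade, per-capita and per-area footprints can be
compared across the two drivers and across two biodiversity metrics.

The two metrics are local **species richness** (SR: species per grid cell)
and **rarity-weighted richness** (RWR: each species weighted by the inverse
of its range area, so a cell full of narrow-ranged endemics scores far
higher than one with the same count of cosmopolitan species). SR is easy to
interpret but blind to species identity; RWR declines when rare species are
replaced by common ones, which SR misses entirely.

## The Leontief engine

With `A` the technical-coefficient matrix over (region, sector) pairs
(region-major ordering), `Y` final demand (one column per consuming region)
and `f` a CF intensity vector, consumption footprints are
`E = f (I − A)⁻¹ Y`. Assumptions inherited from input-output economics:
fixed production recipes (columns of `A`), price homogeneity, and a single
collapsed final-demand column per region (households, government, capital
formation are not distinguished).

Numerical choices:

* `(I − A)⁻¹ Y` is evaluated with a dense LU solve (`solve(I − A, Y)`),
  never by forming the inverse explicitly; `leontief_inverse()` exists for
  diagnostics and tests.
* Productivity is checked via the spectral radius of `A` (must be < 1);
  a non-productive economy is a hard error, not a warning, because every
  downstream quantity would be meaningless.
* Two attribution views are kept for consumption footprints: **stressor
  origin** (where the impact physically occurs — the default, and the basis
  of all bilateral flows and %-imported indicators) and **final product**
  (which purchased product carries the embodied impact). Production-based
  product footprints use direct territorial attribution (CF × gross
  output), so purely downstream products (e.g. processed food) carry zero
  *direct* land footprint; the final-product view is the embodied
  complement. Conflating these two conventions is the classic
  reproducibility trap in footprint studies, which is why both are explicit
  function arguments rather than a hidden default.

## Land-driven characterization factors

For land-use type *i*, biome *j*, region *k*:
`ΔS[i,j,k] = S[i,j,k] × P[j,l(i)]`, then
`ΔS[i,k] = Σ_j ΔS[i,j,k] × B[i,j,k]`, then
`CF[i,k] = −ΔS[i,k] × A[i,k]`.

* `S[i,j,k]` is the mean of the *pristine* richness layer over the stratum.
  The sensitivity coefficients `P` express change relative to primary
  vegetation, so the baseline must be the undisturbed layer — using a
  degraded richness map here would double-count the loss.
* **Stratum weighting** (an open design point: a simple cell mean is also
  defensible): the default weights each cell by its land-use area
  (fraction × cell area), so `S` reflects where the land use actually sits
  rather than treating a 1%-cropland cell like a 90%-cropland cell. Both
  modes are implemented (`weighted = FALSE` switches), and the choice is
  recorded in the run manifest.
* `B[i,j,k]` shares are renormalized over the biomes actually covered;
  masked cells (excluded biomes) drop out of both numerator and
  denominator. Strata with zero area are absent (never NaN); strata below
  one cell's worth of land are kept but flagged, not silently dropped.
* **Sign convention:** `P` and `ΔS` are negative for loss internally
  (−0.3 = 30% lower richness than primary vegetation); the final CF flips
  sign so that *positive CF = loss*, matching the reporting convention of
  footprint studies. Biodiversity gains propagate as negative CFs
  throughout rather than being clipped.
* A missing `P` for a populated (biome, class) pair is a hard error naming
  the pair; a (land-use, region) pair with land intensity but no land on
  the grid yields CF = 0 with a `no_stratum` flag.

The stratified pipeline is validated against an independent cell-level
brute force (`Σ_cells w S P(biome) / Σ_cells w` per region) to 1e-8
relative error in the test suite; the two are algebraically identical, so
this bounds accumulated floating-point error only.

## GHG-driven characterization factors

Three steps: (1) emission intensities (kg/€1M of CO₂, CH₄, N₂O) are
converted to warming at a 20-year horizon via absolute global temperature
change potentials, `ΔT[p,k] = Σ_g E[g,p,k] × C_g`, with the AR5 pulse-GTP
coefficients (CO₂ 6.84e-16, CH₄ 4.62e-14, N₂O 1.89e-13 °C/kg) as
overridable defaults. The 20-year horizon keeps short-lived methane's
potency visible; a 100-year horizon would mask it. The GTP is applied as a
*pulse* metric — the temperature in year 20 from one year's emissions — not
an integrated one. (2) Warming is spatially modulated:
`F[x] = ΔT[x] / mean(ΔT[x])`, the multi-model mean anomaly normalized by
its area-weighted global mean. The weighting domain is switchable between
land-only (default: the biodiversity response lives on land) and all cells;
on the synthetic equal-area grid the area weighting reduces to a simple
mean, and the area-weighted mean of `F` over the domain is 1 by
construction (asserted to 1e-10). A zero mean anomaly is a degenerate
climate and a hard error. (3) The biodiversity response integrates
`CF[p,k] = −ΔT[p,k] × Σ_x F[x] H[x] S[x] A[x]`, where `H[x]` is the
proportional richness change per °C of local warming.

The cell sum is interpreted as a full summation over grid cells — warming
acts globally, so every cell contributes no matter where the emission
occurred. Two consequences are load-bearing and tested: (a) the factor
`K = Σ_x F H S A` is product-independent, so the CF factorizes as
`−ΔT × K`; both the factorized ("kernel") and the literal cell-wise
implementation are provided and must agree to 1e-12 relative — pinning the
interpretation of the summation; (b) two regions with identical emission
intensities receive identical GHG CFs regardless of their own biodiversity
(locational independence).

If no rarity-specific `H` grid is supplied, the rarity pipeline reuses the
species-richness grid with a warning — mirroring the common situation where
climate-sensitivity models exist for vertebrate richness only.

## The synthetic world

The generator stands in for a real MRIO database and the global spatial
layers. Its defaults are fixed once, at values a practitioner would call
realistic for a miniature world, and are not tuned per analysis:

* **Economy**: 5 regions × 6 sectors (crops, livestock, food processing,
  fertilizer, food waste, services; the first two land-using), uniform
  random intermediate blocks with cross-region blocks scaled by
  `trade_openness` (0.3), then rescaled so the spectral radius is 80% of
  the 0.7 bound. At `trade_openness = 0` the cross-region blocks are
  exactly zero, giving a structurally autarkic economy used by the
  conservation tests. Land intensities are lognormal around 10 km²/€1M
  (roughly the area a €1M of primary crop output occupies at coarse world
  prices). Emission intensities are lognormal with food sectors
  methane-heavy (CH₄ ~3e4, CO₂ ~5e5, N₂O ~1.2e3 kg/€1M), emulating the
  structure of real agricultural accounts where enteric fermentation,
  paddy rice and manure make methane the dominant warming source of food.
* **Grid**: abstract equal-area 30 × 30 cells of 100 km² (a 10-km grid).
  Real-world analyses reproject to an equal-area grid precisely so that
  downstream math only needs areas; an abstract constant-area grid is
  therefore sufficient, and no map projection is modelled.
* **Landscape**: Voronoi trade regions; latitudinal biome bands with smooth
  jitter (up to 6 named biome groups); 5% of cells masked as excluded
  biomes. One region and one biome per cell (dominant-class rasterization,
  ties to the lowest id). Land-use fractions are smooth suitability fields
  capped so per-cell totals stay ≤ 0.95; the generator emits
  already-harmonized cropland/pasture fractions rather than modelling the
  blending of separate cropland and pasture map products.
* **Species**: 300 species with lognormal range sizes (median 25 cells,
  right-skewed — the typical empirical shape), placed as rectangles with
  equator-biased centroids, which yields the latitudinal richness gradient
  and the concentration of small-ranged species that make SR and RWR
  genuinely different metrics.
* **Climate**: a 4-model ensemble around 0.6 °C mean warming over the
  20-year horizon (a plausible near-term trajectory under a high-emission
  pathway) with smooth spatial heterogeneity; `H` averages −0.05/°C,
  strongest near the equator, with small positive excursions allowed.
  The rarity-metric `H` is 1.15× the richness one.
* **Determinism**: one master seed; every generator draws from a named
  substream (`substream_seed()`), so adding a generator never perturbs the
  draws of another, and a fixed `(config, seed)` reproduces the entire
  output bundle bit for bit.

What the generator does **not** emulate: real range-map geometry (ranges
are rectangles; no elevational or seasonal filtering), agricultural
intensity gradients, the correlation structure between land intensity and
biome, price heterogeneity, or a realistic planet-sized grid. The last
point matters for interpretation: the GHG kernel `K` integrates richness
over the whole world, so on a 900-cell world it is orders of magnitude
smaller relative to local land CFs than on Earth. Land:GHG ratios from the
synthetic world are therefore structurally much larger than the tens to
hundreds a full-scale analysis yields, and tests assert the *properties* of
the accounts (conservation, linearity, factorization, autarky recovery),
never planet-scale magnitudes.

## Indicators

Per region and metric: production (territorial), consumption (embodied in
final demand), net imports (consumption − production; sums to ~0 globally,
asserted at 1e-8 relative), %-imported
(`100 × (consumption − domestic flow)/consumption`, on stressor-origin
attribution; undefined-and-flagged for zero consumption rather than
infinite), per-capita consumption and per-km² production (hard errors on
missing or non-positive population/area, naming the region), and the
land:GHG ratio on a common metric basis. The ratio carries a
"years-to-equal" reading: at constant annual emissions, a ratio of 100
means a century of emissions equals the loss from the region's total
historic land conversion; a zero GHG footprint flags the ratio undefined.
Note that re-exports are excluded from a region's consumption by
construction of the Leontief accounting, so %-imported is a share of
*final-demand* footprint only.

Aggregation over region groups or food groups is pure summation and
preserves global totals exactly; unmapped members are a hard error unless
strict mode is disabled. A default food-group map (animal-derived,
plant-derived, other food, fertilizer, food waste) ships as an editable
named vector.

## Problem sizes and tolerances used in validation

The shipped test suite exercises: 20 random productive systems up to
10 regions × 6 sectors against a 500-term Neumann series (1e-10 absolute);
10 seeds of the default 30 × 30 world against the cell-level land-CF brute
force (1e-8 relative); kernel/cell-wise GHG duality (1e-12 relative);
range stacking against a per-cell loop (exact, including floating-point
order of the rarity sums); and bit-identical reproduction of the full
output bundle under a fixed seed. These sizes keep the whole suite in the
tens of seconds on one core while leaving each property's failure mode
detectable well above its tolerance.

## Known limitations

* Land CFs treat conversion as an immediate, one-off, reversible cost and
  ignore emissions released by the conversion itself; GHG CFs cover one
  year of emissions at a single 20-year pulse horizon. The two are
  comparable in units but not in temporal scope — the land:GHG ratio is the
  honest bridge, and it should be read crudely.
* The synthetic economy's final demand and technology are unstructured
  random draws; only the *invariants* of the accounting (not sectoral
  patterns) transfer to real data.
* Only CO₂, CH₄ and N₂O are tracked; fluorinated gases are out of scope.
* The sensitivity tables shipped are synthetic defaults shaped like
  empirical land-use-response estimates; any real analysis must supply its
  own `sensitivity_table()` and `H` grids.
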