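# biodivfootprint

Tools for quantifying the biodiversity impacts embodied in the production,
consumption and international trade of food-related commodities.

The global food system drives biodiversity loss through two very different
channels: the land it occupies (which affects biodiversity locally, where
the conversion happened) and the greenhouse gases it emits (which warm the
whole planet, affecting biodiversity everywhere, regardless of where the
emissions occurred). `biodivfootprint` expresses both channels in the same
unit — species × km² of loss — so they can be compared, traced through
supply chains, and attributed to producing or consuming regions. It is
aimed at researchers in industrial ecology and conservation who work with
environmentally extended multi-regional input-output (EEMRIO) models.

## The model

**Footprints.** Impacts are propagated through the standard environmentally
extended Leontief model

> E = f · (I − A)⁻¹ · Y

where A is the technical-coefficient matrix (€ of input per € of output for
every pair of region-sectors), Y the final-demand matrix (one column per
consuming region), and f a direct-intensity vector holding a
characterization factor (CF) per €1M of each region-sector's output. The
Leontief inverse (I − A)⁻¹ sums the infinite rounds of the supply chain;
the package solves it as a linear system, never by explicit inversion.

**Land-driven CFs** (per land-use type i and region k):

> ΔS₍ᵢⱼₖ₎ = S₍ᵢⱼₖ₎ × P₍ⱼₗ₎  — richness change in biome j
> ΔS₍ᵢₖ₎ = Σⱼ ΔS₍ᵢⱼₖ₎ × B₍ᵢⱼₖ₎  — biome-share weighted regional change
> CF₍ᵢₖ₎ = −ΔS₍ᵢₖ₎ × A₍ᵢₖ₎  — species × km² per €1M (positive = loss)

with S the mean *undisturbed* richness over the land-use footprint, P the
proportional sensitivity of the richness metric to the land-use class in
that biome (relative to primary vegetation), B the proportion of the land
use's regional area in each biome, and A₍ᵢₖ₎ the km² of land needed per €1M
of output.

**GHG-driven CFs** (per product p, region k, gas g): emissions are
converted to global warming via 20-year global temperature change
potentials (ΔT₍ₚₖ₎ = Σ₉ E₍₉ₚₖ₎ × C₉; AR5 values, °C/kg), spatially
modulated by the warming pattern F₍ₓ₎ = ΔT₍ₓ₎ / mean(ΔT₍ₓ₎) and the climate
sensitivity of biodiversity H₍ₓ₎ (proportional richness change per °C),
then integrated over the whole grid:

> CF₍ₚₖ₎ = −ΔT₍ₚₖ₎ × Σₓ F₍ₓ₎ H₍ₓ₎ S₍ₓ₎ A₍ₓ₎

Both CF families are built for two biodiversity metrics: local **species
richness** (SR) and **rarity-weighted richness** (RWR, each species
weighted by the inverse of its range area, emphasizing narrow-ranged
species of high conservation concern).

Because real MRIO databases and global rasters are large and licensed, the
package ships a deterministic **synthetic-world generator** — a miniature
economy, landscape, species pool and climate ensemble with known ground
truth — so every stage of the pipeline is testable end to end.

## Worked example

```r
library(biodivfootprint)
res <- run_pipeline(world_config(), seed = 1)
subset(res$indicators, metric == "land_SR",
       select = c(region, production, consumption, net_import,
                  pct_imported, per_capita))
```

```
  region production consumption net_import pct_imported per_capita
1    R01      27635       36922       9287        66.25   0.001199
2    R02      19469       40287      20817        76.06   0.002875
3    R03      73368       49665     -23703        43.74   0.005241
4    R04      36317       57073      20756        64.34   0.009711
5    R05      94711       67553     -27158        33.82   0.005241
```

Production is the land-driven species-richness loss (species × km²)
occurring inside each region's territory; consumption is the loss embodied
anywhere in the world in the region's final demand. R03 and R05 are net
exporters of biodiversity loss (negative net imports: their land is
degraded to feed others), while R02 imports 76% of its consumption
footprint. Per-capita values divide consumption by the region's population.

The underlying characterization factors are tidy tables, e.g. for region
R01:

```
  landuse_sector region   metric cf_value                units
1          crops    R01 richness    33.89 species.km2_per_MEUR
2      livestock    R01 richness    10.12 species.km2_per_MEUR
```

i.e. each €1M of crop output in R01 carries a one-off loss of ~34
species × km². The land:GHG ratio compares this one-off land cost with the
global cost of a single year's emissions — crudely, the number of years of
constant annual emissions needed to equal the land-driven loss (on the tiny
synthetic grid the global emissions kernel is small, so these ratios are
far larger than on a full-size planet):

```r
subset(res$ratios, metric == "SR", select = c(region, ratio))
```

```
  region  ratio
1    R01  56718
2    R02  43216
3    R03 171228
...
```

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/cli/biodivfootprint.R run      --seed 1 --out out/   # all stages
Rscript inst/cli/biodivfootprint.R generate --seed 1 --out out/   # world only
```

The remaining stages map one-to-one onto exported functions: `land_cf()` /
`ghg_cf()` (build-cf), `compute_footprints()` (footprint), and
`net_imports()`, `percent_imported()`, `normalize_footprints()`,
`land_ghg_ratio()`, `aggregate_flows()` (report).

## Documentation

The methods vignette (`vignettes/biodiversity-footprints.Rmd`) describes
the model, the synthetic-world assumptions, the numerical choices and the
package's limitations in detail. Every exported function carries roxygen
documentation.
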