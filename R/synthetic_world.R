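#' Global temperature change potential constants (20-year horizon)
#'
#' Absolute GTP coefficients: global mean surface warming at the 20-year
#' horizon per kilogram of a pulse emission. Defaults are the IPCC AR5
#' values (Table 8.A.1). A 20-year horizon captures the potency of
#' short-lived methane that a 100-year horizon masks.
#'
#' @param co2,ch4,n2o Warming per kg of emission, degrees C / kg; all > 0.
#' @return Named numeric vector of class `gtp_constants`.
#' @export
gtp_constants <- function(co2 = 6.84e-16, ch4 = 4.62e-14, n2o = 1.89e-13) {
  C <- c(co2 = co2, ch4 = ch4, n2o = n2o)
  if (any(C <= 0)) stop("GTP constants must be strictly positive")
  structure(C, class = c("gtp_constants", "numeric"))
}

#' Default land-use sensitivity table (synthetic PREDICTS-style coefficients)
#'
#' `P` is the proportional change in the richness metric in a land-use class
#' relative to primary vegetation, varying by biome group (e.g. -0.40 means
#' 40% lower richness under tropical-forest cropland). Values here are
#' synthetic but shaped like empirical estimates: losses strongest under
#' cropland in forested tropical biomes, milder under pasture and in open or
#' dry biomes. Rarity-weighted richness responds somewhat more strongly than
#' species richness.
#'
#' @param metric `"richness"` or `"rarity"`.
#' @param correspondence Tibble mapping land-use types to land-use classes
#'   (columns `landuse`, `class`); default maps `crops` to `cropland` and
#'   `livestock` to `pasture`.
#' @return Object of class `sensitivity_table`: list with tibble `P`
#'   (columns `biome`, `class`, `P`) and the `correspondence` tibble.
#' @export
default_sensitivity <- function(metric = c("richness", "rarity"),
                                correspondence = NULL) {
  metric <- match.arg(metric)
  P <- tibble::tribble(
    ~biome,                        ~class,     ~P,
    "tropical_forest",             "cropland", -0.40,
    "tropical_forest",             "pasture",  -0.30,
    "temperate_boreal_forest",     "cropland", -0.25,
    "temperate_boreal_forest",     "pasture",  -0.18,
    "tropical_grassland",          "cropland", -0.30,
    "tropical_grassland",          "pasture",  -0.12,
    "temperate_montane_grassland", "cropland", -0.20,
    "temperate_montane_grassland", "pasture",  -0.10,
    "mediterranean",               "cropland", -0.30,
    "mediterranean",               "pasture",  -0.15,
    "drylands",                    "cropland", -0.22,
    "drylands",                    "pasture",  -0.12)
  if (metric == "rarity") P$P <- pmax(-0.999, P$P * 1.15)
  if (is.null(correspondence)) {
    correspondence <- tibble::tibble(landuse = c("crops", "livestock"),
                                     class = c("cropland", "pasture"))
  }
  sensitivity_table(P, correspondence)
}

#' Construct and validate a land-use sensitivity table
#'
#' @param P Tibble with columns `biome`, `class`, `P`; all `P > -1` (a loss
#'   of 100% or more of local richness is not meaningful).
#' @param correspondence Tibble with columns `landuse`, `class` mapping
#'   every land-use type to a sensitivity class.
#' @return Object of class `sensitivity_table`.
#' @export
sensitivity_table <- function(P, correspondence) {
  stopifnot(all(c("biome", "class", "P") %in% names(P)),
            all(c("landuse", "class") %in% names(correspondence)))
  if (any(P$P <= -1)) stop("sensitivity values P must be > -1")
  structure(list(P = P, correspondence = correspondence),
            class = "sensitivity_table")
}

#' Configuration of the synthetic world
#'
#' Bundles every generator parameter with a scientifically plausible default:
#' a 30 x 30 grid of 100 km2 cells (a 10-km equal-area grid), 5 trade
#' regions, 4 biome groupings, 300 terrestrial species with lognormal range
#' sizes, a 4-model climate ensemble with 0.6 degrees C mean warming over
#' the 20-year horizon, and a moderately open trading economy.
#'
#' @param n_regions,sectors,trade_openness,spectral_bound Economy settings,
#'   see [generate_mrio()].
#' @param grid_nrow,grid_ncol,cell_area,n_biomes,mask_fraction Landscape
#'   settings, see [generate_landscape()].
#' @param n_species,range_meanlog,range_sdlog Species settings, see
#'   [generate_species_ranges()].
#' @param n_models,warming_mean,warming_spread,climate_sensitivity,rarity_scale
#'   Climate settings, see [generate_climate()].
#' @param weighting_domain Domain over which the global-mean anomaly is
#'   taken when normalizing the warming pattern: `"land"` (unmasked cells,
#'   default) or `"all"`.
#' @param stratum_weighted Whether stratum mean richness is weighted by
#'   land-use area (default) or a simple cell mean.
#' @return A named list of class `world_config`.
#' @export
world_config <- function(n_regions = 5, sectors = default_sectors(),
                         trade_openness = 0.3, spectral_bound = 0.7,
                         grid_nrow = 30, grid_ncol = 30, cell_area = 100,
                         n_biomes = 4, mask_fraction = 0.05,
                         n_species = 300, range_meanlog = log(25),
                         range_sdlog = 1,
                         n_models = 4, warming_mean = 0.6,
                         warming_spread = 0.15,
                         climate_sensitivity = list(mean = -0.05, sd = 0.02),
                         rarity_scale = 1.15,
                         weighting_domain = c("land", "all"),
                         stratum_weighted = TRUE) {
  structure(list(
    n_regions = n_regions, sectors = sectors,
    trade_openness = trade_openness, spectral_bound = spectral_bound,
    grid_nrow = grid_nrow, grid_ncol = grid_ncol, cell_area = cell_area,
    n_biomes = n_biomes, mask_fraction = mask_fraction,
    n_species = n_species, range_meanlog = range_meanlog,
    range_sdlog = range_sdlog, n_models = n_models,
    warming_mean = warming_mean, warming_spread = warming_spread,
    climate_sensitivity = climate_sensitivity, rarity_scale = rarity_scale,
    weighting_domain = match.arg(weighting_domain),
    stratum_weighted = stratum_weighted), class = "world_config")
}

#' Generate a complete self-consistent synthetic world
#'
#' Chains the economy, landscape, species and climate generators under one
#' master seed (each drawing from its own named substream) and attaches the
#' sensitivity tables, GTP constants and region attributes needed by the
#' characterization-factor and footprint stages.
#'
#' @param config A [world_config()] list.
#' @param seed Master seed; identical `(config, seed)` pairs yield
#'   bit-identical worlds.
#' @return Object of class `synthetic_world`: `mrio`, `extensions`, `grids`,
#'   `ranges`, `sensitivity` (per metric), `gtp`, `attrs` (tibble `region`,
#'   `population`, `land_area_km2`), `config`, `seed`.
#' @export
generate_world <- function(config = world_config(), seed = 1) {
  econ <- generate_mrio(config$n_regions, config$sectors,
                        config$trade_openness, config$spectral_bound, seed)
  land_types <- config$sectors$sector[config$sectors$land_using]
  grids <- generate_landscape(config$grid_nrow, config$grid_ncol,
                              config$cell_area, config$n_biomes,
                              config$n_regions, land_types,
                              config$mask_fraction, seed)
  ranges <- generate_species_ranges(
    config$n_species, grids,
    list(meanlog = config$range_meanlog, sdlog = config$range_sdlog), seed)
  layers <- stack_ranges(ranges, grids)
  grids$richness <- layers$richness
  grids$rarity <- layers$rarity
  grids <- generate_climate(grids, config$n_models, config$warming_mean,
                            config$warming_spread,
                            config$climate_sensitivity,
                            config$rarity_scale, seed)
  corr <- tibble::tibble(landuse = land_types,
                         class = ifelse(land_types == "livestock",
                                        "pasture", "cropland"))
  sensitivity <- list(richness = default_sensitivity("richness", corr),
                      rarity = default_sensitivity("rarity", corr))
  attrs <- with_substream(seed, "population", {
    tibble::tibble(
      region = econ$mrio$regions,
      population = round(rlnorm(config$n_regions, log(2e7), 0.8)),
      land_area_km2 = vapply(seq_len(config$n_regions), function(r)
        sum(grids$region_id == r) * grids$cell_area, numeric(1)))
  })
  structure(list(mrio = econ$mrio, extensions = econ$extensions,
                 grids = grids, ranges = ranges, sensitivity = sensitivity,
                 gtp = gtp_constants(), attrs = attrs, config = config,
                 seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> seed %s\n", format(x$seed)))
  print(x$mrio)
  print(x$grids)
  cat(sprintf("  species: %d\n", length(x$ranges)))
  invisible(x)
}
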