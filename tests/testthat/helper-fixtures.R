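# Hand-built fixtures: tiny grids, sensitivity tables and extension tables
# with known arithmetic, used by the worked-example tests.

make_grids <- function(values, cell_area = 10, region_id = NULL,
                       biome_id = NULL, fractions = NULL,
                       region_names = NULL, biome_names = NULL, ...) {
  v <- as.matrix(values)
  nr <- nrow(v); nc <- ncol(v)
  world_grids(
    nr, nc, cell_area,
    region_id = region_id %||% matrix(1L, nr, nc),
    biome_id = biome_id %||% matrix(1L, nr, nc),
    landuse_fraction = fractions %||% list(crops = matrix(1, nr, nc)),
    richness = v,
    region_names = region_names %||% "R01",
    biome_names = biome_names %||% "tropical_forest",
    ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_extensions <- function(land_area = NULL, emissions = NULL) {
  structure(list(
    land_area = land_area %||%
      tibble::tibble(landuse_sector = "crops", region = "R01",
                     km2_per_meur = 1),
    emissions = emissions %||%
      tibble::tibble(product = "crops", region = "R01",
                     gas = c("co2", "ch4", "n2o"), kg_per_meur = 0)),
    class = "extension_table")
}

simple_sensitivity <- function(P_value = -0.3, biome = "tropical_forest",
                               landuse = "crops", class = "cropland") {
  sensitivity_table(
    P = tibble::tibble(biome = biome, class = class, P = P_value),
    correspondence = tibble::tibble(landuse = landuse, class = class))
}

# a fast-but-complete synthetic world for unit tests
small_world_config <- function(...) {
  world_config(n_regions = 3, grid_nrow = 20, grid_ncol = 20,
               n_species = 100, n_models = 2, ...)
}
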