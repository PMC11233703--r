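#' Smooth low-frequency random field on a grid
#'
#' Sum of a few random sinusoids; used to give the synthetic landscape and
#' climate layers spatial autocorrelation.
#' @keywords internal
smooth_field <- function(nrow, ncol, n_waves = 6, scale = 3) {
  f <- matrix(0, nrow, ncol)
  for (k in seq_len(n_waves)) {
    amp <- rnorm(1)
    fr <- runif(2, 0.5, scale)
    ph <- runif(2, 0, 2 * pi)
    f <- f + amp * outer(sin(2 * pi * fr[1] * seq_len(nrow) / nrow + ph[1]),
                         sin(2 * pi * fr[2] * seq_len(ncol) / ncol + ph[2]))
  }
  f / sqrt(n_waves / 2)
}

#' Canonical biome grouping names
#' @param n Number of biomes (1..6).
#' @return Character vector of the first `n` biome-group names.
#' @export
biome_group_names <- function(n) {
  all <- c("tropical_forest", "temperate_boreal_forest", "tropical_grassland",
           "temperate_montane_grassland", "mediterranean", "drylands")
  if (n < 1 || n > length(all)) stop("n_biomes must be between 1 and 6")
  all[seq_len(n)]
}

#' Generate the synthetic landscape: trade regions, biomes, land-use fractions
#'
#' Regions partition the grid by nearest-centre (Voronoi) assignment with
#' ties broken toward the lowest region id. Biomes follow noisy latitudinal
#' bands (so tropical biomes sit near the equatorial rows), again one biome
#' per cell. A configurable fraction of cells is masked as an excluded biome
#' (standing in for tundra, mangroves, inland water etc.) and drops out of
#' every stratified statistic. Per-cell land-use fractions come from smooth
#' random suitability fields squashed to \[0, 1\] and rescaled so their
#' per-cell sum never exceeds 0.95; masked cells carry zero land use.
#'
#' @param grid_nrow,grid_ncol Grid dimensions.
#' @param cell_area Cell area, km2 (> 0).
#' @param n_biomes Number of biome groupings (1..6).
#' @param n_regions Number of trade regions (>= 1).
#' @param landuse_types Character vector of land-use type names (one layer
#'   each), typically the land-using sectors of the economy.
#' @param mask_fraction Fraction of cells masked as excluded biome.
#' @param seed Master seed; draws come from the `"landscape"` substream.
#' @return A [world_grids] object with `region_id`, `biome_id` and
#'   `landuse_fraction` populated.
#' @export
generate_landscape <- function(grid_nrow, grid_ncol, cell_area, n_biomes,
                               n_regions, landuse_types,
                               mask_fraction = 0.05, seed = 1) {
  if (cell_area <= 0) stop("cell_area must be > 0")
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (n_biomes < 1) stop("n_biomes must be >= 1")
  nr <- grid_nrow; nc <- grid_ncol
  with_substream(seed, "landscape", {
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)

    # Voronoi regions; ties to the lowest region id
    cr <- runif(n_regions, 1, nr)
    cc <- runif(n_regions, 1, nc)
    d2 <- vapply(seq_len(n_regions),
                 function(k) as.vector((rows - cr[k])^2 + (cols - cc[k])^2),
                 numeric(nr * nc))
    region_id <- matrix(apply(d2, 1, which.min), nr, nc)

    # latitudinal biome bands with smooth jitter; band order puts the
    # tropical groups around the equator (middle rows)
    jitter <- smooth_field(nr, nc) * nr * 0.08
    lat <- abs(rows + jitter - (nr + 1) / 2) / ((nr - 1) / 2 + 1e-9)
    band <- pmin(n_biomes, pmax(1L, 1L + as.integer(floor(lat * n_biomes))))
    biome_id <- matrix(as.integer(band), nr, nc)

    if (mask_fraction > 0) {
      mfield <- smooth_field(nr, nc) + rnorm(nr * nc, 0, 0.3)
      biome_id[mfield < stats::quantile(mfield, mask_fraction)] <- NA_integer_
    }

    fractions <- list()
    raw <- lapply(landuse_types, function(t) stats::plogis(smooth_field(nr, nc) * 1.5) * 0.6)
    tot <- Reduce(`+`, raw)
    scale <- ifelse(tot > 0.95, 0.95 / tot, 1)
    for (i in seq_along(landuse_types)) {
      f <- raw[[i]] * scale
      f[is.na(biome_id)] <- 0
      fractions[[landuse_types[i]]] <- f
    }

    world_grids(nr, nc, cell_area, region_id, biome_id, fractions,
                region_names = mrio_region_names(n_regions),
                biome_names = biome_group_names(n_biomes))
  })
}

#' Generate the synthetic climate: per-model anomalies and sensitivity grids
#'
#' Temperature anomalies (warming between the accounting year and the
#' 20-year GTP horizon) are spatially smooth fields around a global mean,
#' with a model-specific offset so the multi-model ensemble has spread.
#' The climate-sensitivity grid H gives the proportional change in the
#' richness metric per degree C of local warming; it is predominantly
#' negative (warming causes loss), strongest near the equatorial rows, with
#' small positive excursions permitted (gains count as negative loss).
#'
#' @param grid A [world_grids] object; anomaly and sensitivity layers are
#'   added to a copy.
#' @param n_models Number of climate models (>= 1).
#' @param warming_mean Ensemble-mean global warming, degrees C.
#' @param warming_spread Standard deviation of the per-model offsets.
#' @param sensitivity Either a single number (a spatially constant H) or a
#'   list with `mean` (negative) and `sd` controlling the generated field.
#'   Used for both richness metrics, with the rarity grid scaled by
#'   `rarity_scale`.
#' @param rarity_scale Multiplier applied to the richness H to obtain the
#'   rarity-metric H (default 1.15: narrow-ranged species respond more).
#' @param seed Master seed; draws come from the `"climate"` substream.
#' @return The input [world_grids] with `anomaly` (list of matrices) and
#'   `sensitivity` (`richness`, `rarity`) populated.
#' @export
generate_climate <- function(grid, n_models = 4, warming_mean = 0.6,
                             warming_spread = 0.15,
                             sensitivity = list(mean = -0.05, sd = 0.02),
                             rarity_scale = 1.15, seed = 1) {
  if (n_models < 1) stop("n_models must be >= 1")
  nr <- grid$nrow; nc <- grid$ncol
  with_substream(seed, "climate", {
    offsets <- rnorm(n_models, 0, warming_spread)
    anomaly <- lapply(seq_len(n_models), function(m) {
      pmax(warming_mean + offsets[m] + 0.25 * smooth_field(nr, nc), 0.05)
    })
    if (is.numeric(sensitivity) && length(sensitivity) == 1L) {
      H <- matrix(sensitivity, nr, nc)
    } else {
      lat <- abs(matrix(seq_len(nr), nr, nc) - (nr + 1) / 2) / ((nr - 1) / 2 + 1e-9)
      H <- sensitivity$mean * (1.3 - 0.8 * lat) +
        sensitivity$sd * smooth_field(nr, nc)
    }
    grid$anomaly <- anomaly
    grid$sensitivity <- list(richness = H, rarity = H * rarity_scale)
    validate_world_grids(grid)
  })
}
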