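#' Co-registered equal-area world grids
#'
#' Container for the spatial layers the characterization-factor pipelines
#' consume: trade-region and biome rasters, land-use fractions, species
#' richness and rarity-weighted richness, per-model temperature anomalies and
#' climate-sensitivity grids. All layers share one abstract equal-area grid
#' (constant `cell_area` in km2); rows index latitude bands (row 1 =
#' northernmost), columns longitude. Cells belonging to an excluded biome
#' (e.g. tundra, mangroves) carry `NA` in `biome_id` and are masked out of
#' all stratified statistics.
#'
#' @param nrow,ncol Grid dimensions.
#' @param cell_area Area of every cell, km2 (> 0).
#' @param region_id Integer matrix of trade-region ids (1..n_regions).
#' @param biome_id Integer matrix of biome ids; `NA` marks masked cells.
#' @param landuse_fraction Named list of matrices, one per land-use type,
#'   each in \[0, 1\] with per-cell sums at most 1.
#' @param richness Species-richness matrix (species per cell), or `NULL`.
#' @param rarity Rarity-weighted richness matrix (summed inverse range
#'   areas), or `NULL`.
#' @param anomaly List of per-climate-model temperature-anomaly matrices
#'   (degrees C), or `NULL`.
#' @param sensitivity Named list of climate-sensitivity grids (proportional
#'   richness change per degree C), keyed by metric (`"richness"`,
#'   `"rarity"`), or `NULL`.
#' @param region_names,biome_names Character labels for region and biome ids.
#' @return An object of class `world_grids`.
#' @export
world_grids <- function(nrow, ncol, cell_area, region_id, biome_id,
                        landuse_fraction, richness = NULL, rarity = NULL,
                        anomaly = NULL, sensitivity = NULL,
                        region_names = NULL, biome_names = NULL) {
  g <- structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         cell_area = cell_area, region_id = region_id, biome_id = biome_id,
         landuse_fraction = landuse_fraction, richness = richness,
         rarity = rarity, anomaly = anomaly, sensitivity = sensitivity,
         region_names = region_names, biome_names = biome_names),
    class = "world_grids")
  validate_world_grids(g)
}

#' @keywords internal
validate_world_grids <- function(g) {
  stopifnot(inherits(g, "world_grids"))
  if (!is.numeric(g$cell_area) || length(g$cell_area) != 1L || g$cell_area <= 0)
    stop("cell_area must be a single positive number (km2)")
  dims <- c(g$nrow, g$ncol)
  chk_dim <- function(m, what) {
    if (!is.matrix(m) || !identical(dim(m), as.integer(dims)))
      stop(sprintf("layer '%s' must be a %d x %d matrix", what, dims[1], dims[2]))
  }
  chk_dim(g$region_id, "region_id")
  chk_dim(g$biome_id, "biome_id")
  if (any(is.na(g$region_id)))
    stop("every cell must carry a trade region (region_id has NAs)")
  if (!is.list(g$landuse_fraction) || is.null(names(g$landuse_fraction)))
    stop("landuse_fraction must be a named list of matrices")
  tot <- matrix(0, g$nrow, g$ncol)
  for (nm in names(g$landuse_fraction)) {
    f <- g$landuse_fraction[[nm]]
    chk_dim(f, paste0("landuse_fraction$", nm))
    if (any(f < 0 | f > 1)) stop("land-use fractions must lie in [0, 1]")
    tot <- tot + f
  }
  if (any(tot > 1 + 1e-10)) stop("per-cell land-use fractions must sum to <= 1")
  for (nm in c("richness", "rarity")) {
    if (!is.null(g[[nm]])) {
      chk_dim(g[[nm]], nm)
      if (any(g[[nm]] < 0)) stop(sprintf("%s must be nonnegative", nm))
    }
  }
  if (!is.null(g$anomaly)) for (i in seq_along(g$anomaly))
    chk_dim(g$anomaly[[i]], paste0("anomaly[[", i, "]]"))
  if (!is.null(g$sensitivity)) for (nm in names(g$sensitivity))
    chk_dim(g$sensitivity[[nm]], paste0("sensitivity$", nm))
  g
}

#' Logical matrix of unmasked (analysis-domain) cells
#' @param grids A [world_grids] object.
#' @return Logical matrix, `TRUE` where the cell enters stratified statistics.
#' @export
unmasked <- function(grids) !is.na(grids$biome_id)

#' One row per unmasked cell, with region, biome and biodiversity layers
#'
#' @param grids A [world_grids] object.
#' @return A tibble with columns `cell`, `row`, `col`, `region`, `biome`,
#'   `area` (km2) and, when present, `richness` and `rarity`.
#' @export
cell_table <- function(grids) {
  keep <- which(unmasked(grids))
  idx <- arrayInd(keep, c(grids$nrow, grids$ncol))
  region_lab <- grids$region_names %||% paste0("R", seq_len(max(grids$region_id)))
  biome_lab <- grids$biome_names %||% paste0("biome_", seq_len(max(grids$biome_id, na.rm = TRUE)))
  out <- tibble::tibble(
    cell = keep, row = idx[, 1], col = idx[, 2],
    region = region_lab[grids$region_id[keep]],
    biome = biome_lab[grids$biome_id[keep]],
    area = grids$cell_area)
  if (!is.null(grids$richness)) out$richness <- grids$richness[keep]
  if (!is.null(grids$rarity)) out$rarity <- grids$rarity[keep]
  out
}

#' Long table of per-cell land-use fractions (unmasked cells, fraction > 0)
#'
#' @param grids A [world_grids] object.
#' @return A tibble with columns `cell`, `landuse`, `fraction` and
#'   `landuse_area` (fraction x cell_area, km2).
#' @export
landuse_table <- function(grids) {
  keep <- which(unmasked(grids))
  out <- lapply(names(grids$landuse_fraction), function(nm) {
    f <- grids$landuse_fraction[[nm]][keep]
    pos <- f > 0
    tibble::tibble(cell = keep[pos], landuse = nm, fraction = f[pos],
                   landuse_area = f[pos] * grids$cell_area)
  })
  dplyr::bind_rows(out)
}

#' @export
print.world_grids <- function(x, ...) {
  cat(sprintf("<world_grids> %d x %d cells of %.4g km2 (%d masked)\n",
              x$nrow, x$ncol, x$cell_area, sum(!unmasked(x))))
  cat(sprintf("  regions: %d  biomes: %d  land-use types: %s\n",
              max(x$region_id), max(x$biome_id, na.rm = TRUE),
              paste(names(x$landuse_fraction), collapse = ", ")))
  layers <- c(richness = !is.null(x$richness), rarity = !is.null(x$rarity),
              anomaly = !is.null(x$anomaly), sensitivity = !is.null(x$sensitivity))
  cat("  layers present:", paste(names(layers)[layers], collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
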