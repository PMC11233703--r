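metric_layer <- function(grids, metric = c("richness", "rarity")) {
  metric <- match.arg(metric)
  layer <- grids[[metric]]
  if (is.null(layer)) stop(sprintf("grids carry no '%s' layer", metric))
  layer
}

#' Mean undisturbed richness per (land-use, biome, region) stratum
#'
#' For each land-use type within each biome within each trade region,
#' averages the chosen richness metric over the cells the land use occupies.
#' By default the mean is weighted by the land-use area in the cell
#' (fraction x cell_area), so the stratum value reflects where the land use
#' actually sits; `weighted = FALSE` gives a simple mean over occupied
#' cells. The richness layer is the pristine (undisturbed) one: the
#' downstream sensitivity coefficients express change relative to primary
#' vegetation. Strata with zero land-use area are absent; strata whose area
#' falls below `min_area` are kept but flagged.
#'
#' @param grids A [world_grids] object with the metric layer present.
#' @param metric `"richness"` or `"rarity"`.
#' @param weighted Weight the mean by land-use area (default `TRUE`).
#' @param min_area Area threshold (km2) below which a stratum is flagged;
#'   defaults to one cell's area.
#' @return Tibble `landuse`, `biome`, `region`, `S` (stratum mean), `area`
#'   (km2 of the land use in the stratum), `flagged`.
#' @export
stratum_mean_richness <- function(grids, metric = c("richness", "rarity"),
                                  weighted = TRUE, min_area = NULL) {
  metric <- match.arg(metric)
  layer <- metric_layer(grids, metric)
  min_area <- min_area %||% grids$cell_area
  lu <- landuse_table(grids)
  if (nrow(lu) == 0)
    return(tibble::tibble(landuse = character(), biome = character(),
                          region = character(), S = numeric(),
                          area = numeric(), flagged = logical()))
  cells <- cell_table(grids)
  lu <- dplyr::left_join(lu, cells[c("cell", "region", "biome")], by = "cell")
  lu$value <- layer[lu$cell]
  out <- dplyr::summarise(
    dplyr::group_by(lu, .data$landuse, .data$biome, .data$region),
    S = if (weighted) sum(.data$landuse_area * .data$value) / sum(.data$landuse_area)
        else mean(.data$value),
    area = sum(.data$landuse_area), .groups = "drop")
  out$flagged <- out$area < min_area
  out
}

#' Proportion of a land use's regional area lying in each biome
#'
#' B\[i, j, k\] = (area of land-use i in biome j of region k) / (area of
#' land-use i in region k). Shares sum to one over the biomes covered;
#' masked (excluded-biome) cells contribute to neither numerator nor
#' denominator, i.e. shares are renormalized over the covered biomes.
#' Strata with zero total area are absent rather than NaN.
#'
#' @param grids A [world_grids] object.
#' @return Tibble `landuse`, `biome`, `region`, `B`.
#' @export
biome_shares <- function(grids) {
  lu <- landuse_table(grids)
  if (nrow(lu) == 0)
    return(tibble::tibble(landuse = character(), biome = character(),
                          region = character(), B = numeric()))
  cells <- cell_table(grids)
  lu <- dplyr::left_join(lu, cells[c("cell", "region", "biome")], by = "cell")
  by_stratum <- dplyr::summarise(
    dplyr::group_by(lu, .data$landuse, .data$region, .data$biome),
    area = sum(.data$landuse_area), .groups = "drop_last")
  out <- dplyr::mutate(by_stratum, B = .data$area / sum(.data$area))
  dplyr::ungroup(out)[c("landuse", "biome", "region", "B")]
}

#' Land-use-driven change in the richness metric per stratum and region
#'
#' The stratum-level change is the undisturbed stratum mean times the
#' proportional sensitivity of the land-use class in that biome,
#' dS\[i,j,k\] = S\[i,j,k\] x P\[j, l(i)\]; the regional change per land use
#' is the biome-share-weighted sum dS\[i,k\] = sum_j dS\[i,j,k\] B\[i,j,k\].
#' Negative values denote loss at this stage.
#'
#' @param strata Output of [stratum_mean_richness()].
#' @param shares Output of [biome_shares()].
#' @param sensitivity A [sensitivity_table()]; the correspondence must cover
#'   every land-use type present, and `P` every populated (biome, class)
#'   pair (a missing pair is a hard error naming it).
#' @return List with tibbles `stratum` (`landuse`, `biome`, `region`,
#'   `dS_stratum`) and `total` (`landuse`, `region`, `dS`).
#' @export
land_delta_richness <- function(strata, shares, sensitivity) {
  stopifnot(inherits(sensitivity, "sensitivity_table"))
  tab <- dplyr::inner_join(strata, shares,
                           by = c("landuse", "biome", "region"))
  tab <- dplyr::left_join(tab, sensitivity$correspondence, by = "landuse")
  if (any(is.na(tab$class))) {
    bad <- unique(tab$landuse[is.na(tab$class)])
    stop("no land-use class correspondence for: ", paste(bad, collapse = ", "))
  }
  tab <- dplyr::left_join(tab, sensitivity$P, by = c("biome", "class"))
  if (any(is.na(tab$P))) {
    bad <- unique(paste0("(", tab$biome[is.na(tab$P)], ", ",
                         tab$class[is.na(tab$P)], ")"))
    stop("missing sensitivity value P for populated pair(s): ",
         paste(bad, collapse = ", "))
  }
  tab$dS_stratum <- tab$S * tab$P
  total <- dplyr::summarise(
    dplyr::group_by(tab, .data$landuse, .data$region),
    dS = sum(.data$dS_stratum * .data$B), .groups = "drop")
  list(stratum = tab[c("landuse", "biome", "region", "dS_stratum")],
       total = total)
}

#' Land-driven characterization factors per land-use sector and region
#'
#' CF\[i,k\] = -dS\[i,k\] x A\[i,k\], where A\[i,k\] is the km2 of land-use
#' type i needed to produce EUR 1M of output in region k. The sign is
#' flipped so a positive CF is a biodiversity loss (in species x km2, or
#' range-fraction x km2 for the rarity metric, per EUR 1M); biodiversity
#' gains propagate as negative CFs. Land-use/region pairs with zero land
#' intensity get CF = 0; pairs whose land use does not occur on the grid
#' (no stratum) get CF = 0 and are flagged.
#'
#' @param delta Output of [land_delta_richness()] (its `total` element is
#'   used; passing the list or the tibble both work).
#' @param extensions An `extension_table` (uses `land_area`: columns
#'   `landuse_sector`, `region`, `km2_per_meur`, all nonnegative).
#' @param metric Richness metric label recorded in the output.
#' @return Tidy tibble `landuse_sector`, `region`, `metric`, `cf_value`,
#'   `units`, `no_stratum`.
#' @export
land_characterization_factors <- function(delta, extensions,
                                          metric = c("richness", "rarity")) {
  metric <- match.arg(metric)
  dS <- if (is.data.frame(delta)) delta else delta$total
  land <- extensions$land_area
  if (any(land$km2_per_meur < 0)) stop("land intensity A[i,k] must be nonnegative")
  out <- dplyr::left_join(
    land, dplyr::rename(dS, landuse_sector = "landuse"),
    by = c("landuse_sector", "region"))
  out$no_stratum <- is.na(out$dS)
  out$dS[out$no_stratum] <- 0
  out$cf_value <- -out$dS * out$km2_per_meur
  out$metric <- metric
  out$units <- if (metric == "richness") "species.km2_per_MEUR" else "range_fraction.km2_per_MEUR"
  out[c("landuse_sector", "region", "metric", "cf_value", "units", "no_stratum")]
}

#' Full land characterization-factor pipeline for one richness metric
#'
#' Convenience wrapper chaining [stratum_mean_richness()], [biome_shares()],
#' [land_delta_richness()] and [land_characterization_factors()].
#'
#' @inheritParams stratum_mean_richness
#' @param sensitivity A [sensitivity_table()] for this metric.
#' @param extensions An `extension_table`.
#' @return Tidy CF tibble as from [land_characterization_factors()].
#' @export
land_cf <- function(grids, sensitivity, extensions,
                    metric = c("richness", "rarity"), weighted = TRUE) {
  metric <- match.arg(metric)
  strata <- stratum_mean_richness(grids, metric, weighted = weighted)
  shares <- biome_shares(grids)
  delta <- land_delta_richness(strata, shares, sensitivity)
  land_characterization_factors(delta, extensions, metric)
}
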