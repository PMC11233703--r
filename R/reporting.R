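#' Per-region net imports from a bilateral flow matrix
#'
#' net_import\[r\] = consumption\[r\] - production\[r\]. Net imports sum to
#' zero globally: every impact consumed somewhere was produced somewhere.
#'
#' @param flows Producing x consuming region matrix (e.g. [region_flows()]).
#' @return Tibble `region`, `production`, `consumption`, `net_import`.
#' @export
net_imports <- function(flows) {
  tibble::tibble(region = rownames(flows),
                 production = unname(rowSums(flows)),
                 consumption = unname(colSums(flows)),
                 net_import = unname(colSums(flows) - rowSums(flows)))
}

#' Percentage of a region's consumption footprint that is imported
#'
#' 100 x (consumption\[r\] - domestic\[r\]) / consumption\[r\], where
#' domestic is the diagonal flow (impact both produced and consumed in r).
#' Zero-consumption regions are undefined and flagged rather than reported
#' as infinite.
#'
#' @param flows Producing x consuming region matrix.
#' @return Tibble `region`, `consumption`, `domestic`, `pct_imported`
#'   (in \[0, 100\], `NA` when undefined), `undefined`.
#' @export
percent_imported <- function(flows) {
  cons <- unname(colSums(flows))
  dom <- unname(diag(flows))
  undef <- cons == 0
  pct <- ifelse(undef, NA_real_, 100 * (cons - dom) / cons)
  tibble::tibble(region = rownames(flows), consumption = cons,
                 domestic = dom, pct_imported = pct, undefined = undef)
}

#' Per-capita consumption and per-area production footprints
#'
#' Regions differ hugely in land area and population, so raw totals are hard
#' to compare. Production is normalized by territorial land area (impact per
#' km2) and consumption by population (impact per person).
#'
#' @param indicator Tibble with `region`, `production`, `consumption`
#'   (e.g. [net_imports()]).
#' @param attrs Tibble `region`, `population`, `land_area_km2`; a missing,
#'   zero or negative entry for a referenced region is a hard error naming
#'   the region.
#' @return The indicator tibble with `per_capita` and `per_area` columns.
#' @export
normalize_footprints <- function(indicator, attrs) {
  out <- dplyr::left_join(indicator, attrs, by = "region")
  bad <- is.na(out$population) | out$population <= 0
  if (any(bad))
    stop("missing or non-positive population for region(s): ",
         paste(out$region[bad], collapse = ", "))
  bad <- is.na(out$land_area_km2) | out$land_area_km2 <= 0
  if (any(bad))
    stop("missing or non-positive land area for region(s): ",
         paste(out$region[bad], collapse = ", "))
  out$per_capita <- out$consumption / out$population
  out$per_area <- out$production / out$land_area_km2
  out
}

#' Ratio of land-driven to GHG-driven biodiversity footprint
#'
#' Compares the one-off biodiversity cost of all agricultural land in use
#' with the global biodiversity cost of a single year's emissions, on the
#' same metric basis (species richness with species richness,
#' rarity-weighted with rarity-weighted). Read crudely, a ratio of 100 means
#' that a century of emissions at the current annual rate would equal the
#' loss already caused by the region's total land conversion
#' ("years-to-equal" annotation). Regions with a zero GHG footprint are
#' undefined and flagged.
#'
#' @param land,ghg Tibbles with `region` and the chosen `value` column,
#'   on the same richness-metric basis.
#' @param value Column to compare, `"production"` (default) or
#'   `"consumption"`.
#' @return Tibble `region`, `land`, `ghg`, `ratio`, `years_to_equal`
#'   (identical to `ratio`, under the constant-annual-emissions reading),
#'   `undefined`.
#' @export
land_ghg_ratio <- function(land, ghg, value = "production") {
  out <- dplyr::inner_join(
    tibble::tibble(region = land$region, land = land[[value]]),
    tibble::tibble(region = ghg$region, ghg = ghg[[value]]),
    by = "region")
  out$undefined <- out$ghg == 0
  out$ratio <- ifelse(out$undefined, NA_real_, out$land / out$ghg)
  out$years_to_equal <- out$ratio
  out
}

#' Aggregate a bilateral flow matrix over region groups
#'
#' Sums rows and columns by group, preserving the global total exactly.
#'
#' @param flows Producing x consuming region matrix.
#' @param groups Named character vector mapping region -> group label.
#' @param strict Error on regions without a mapping (default); otherwise
#'   unmapped regions keep their own label.
#' @return Group x group flow matrix.
#' @export
aggregate_flows <- function(flows, groups, strict = TRUE) {
  regions <- rownames(flows)
  g <- unname(groups[regions])
  if (any(is.na(g))) {
    if (strict)
      stop("no group mapping for region(s): ",
           paste(regions[is.na(g)], collapse = ", "))
    g[is.na(g)] <- regions[is.na(g)]
  }
  glev <- sort(unique(g))
  M <- matrix(0, length(glev), length(regions),
              dimnames = list(glev, regions))
  M[cbind(match(g, glev), seq_along(regions))] <- 1
  out <- M %*% flows %*% t(M)
  dimnames(out) <- list(producing = glev, consuming = glev)
  out
}

#' Aggregate a tidy indicator or footprint table over grouping maps
#'
#' Pure summation of member values into group values; the global total is
#' preserved exactly. Works for any table with one or more mapped key
#' columns and a numeric `value` column (e.g. a `footprint_tensor` grouped
#' into food groups and world regions).
#'
#' @param tbl Tibble with the column named in `by` and a `value` column.
#' @param groups Named character vector mapping member -> group.
#' @param by Name of the column to map.
#' @param strict Error on unmapped members (default); otherwise they keep
#'   their own label.
#' @return Tibble grouped by every non-value column, with summed `value`.
#' @export
aggregate_by <- function(tbl, groups, by, strict = TRUE) {
  key <- tbl[[by]]
  g <- unname(groups[key])
  if (any(is.na(g))) {
    if (strict)
      stop("no group mapping for: ",
           paste(unique(key[is.na(g)]), collapse = ", "))
    g[is.na(g)] <- key[is.na(g)]
  }
  tbl[[by]] <- g
  keys <- setdiff(names(tbl), "value")
  dplyr::summarise(dplyr::group_by(tbl, dplyr::across(dplyr::all_of(keys))),
                   value = sum(.data$value), .groups = "drop")
}

#' Default food-group map for the synthetic sectors
#'
#' Mirrors the usual figure groupings of food-system studies:
#' animal-derived, plant-derived, other food, fertilizer and food waste,
#' with non-food services left as their own group. Editable: pass your own
#' named vector anywhere a `groups` argument is accepted.
#'
#' @return Named character vector sector -> food group.
#' @export
default_food_groups <- function() {
  c(crops = "plant_derived", livestock = "animal_derived",
    food_processing = "other_food", fertilizer = "fertilizer",
    food_waste = "food_waste", services = "non_food")
}
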