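#' Build an intensity vector over the MRIO ordering from a tidy CF table
#'
#' @param cf Tibble with a sector column (`landuse_sector` or `product`),
#'   `region` and a value column.
#' @param labels MRIO labels tibble from [mrio_labels()].
#' @param value Name of the value column.
#' @return Named numeric vector aligned to `labels$key`; pairs absent from
#'   `cf` are zero.
#' @export
intensity_vector <- function(cf, labels, value = "cf_value") {
  sec_col <- intersect(c("landuse_sector", "product", "sector"), names(cf))[1]
  if (is.na(sec_col)) stop("cf table needs a sector/product column")
  key <- paste(cf$region, cf[[sec_col]], sep = ".")
  if (!all(key %in% labels$key))
    stop("cf table labels are misaligned with the MRIO: ",
         paste(utils::head(setdiff(key, labels$key), 3), collapse = ", "))
  f <- setNames(numeric(nrow(labels)), labels$key)
  f[key] <- f[key] + cf[[value]]
  f
}

#' Compute the full footprint tensor for every metric and gas component
#'
#' Pushes each characterization-factor intensity through the Leontief model
#' once, retaining the stressor-origin attribution at (producing sector,
#' producing region, consuming region) resolution. Components computed:
#' `land_area` (km2 of agricultural land), `land_SR` / `land_RWR`
#' (land-driven loss of species richness / rarity-weighted richness) and
#' `ghg_SR` / `ghg_RWR` split by gas (co2, ch4, n2o).
#'
#' @param mrio An `mrio_system`.
#' @param extensions An `extension_table` (for the land-area metric).
#' @param cf_land Tidy land CF table covering both metrics (rows with
#'   `metric` "richness"/"rarity"), as from [land_cf()]; or `NULL` to skip.
#' @param cf_ghg Tidy GHG CF table covering both metrics, as from
#'   [ghg_cf()]; or `NULL` to skip.
#' @return Object of class `footprint_tensor`: tibble `metric`, `component`,
#'   `producing_region`, `producing_sector`, `consuming_region`, `value`,
#'   with the MRIO labels attached as an attribute.
#' @export
compute_footprints <- function(mrio, extensions, cf_land = NULL,
                               cf_ghg = NULL) {
  labels <- mrio$labels
  comps <- list()
  add <- function(metric, component, f) {
    fp <- consumption_footprints(f, mrio$A, mrio$Y, labels, view = "origin")
    fp$metric <- metric
    fp$component <- component
    comps[[length(comps) + 1L]] <<- fp
  }
  land_int <- dplyr::rename(extensions$land_area, cf_value = "km2_per_meur")
  add("land_area", "land", intensity_vector(land_int, labels))
  if (!is.null(cf_land)) {
    for (m in unique(cf_land$metric)) {
      nm <- if (m == "richness") "land_SR" else "land_RWR"
      add(nm, "land",
          intensity_vector(cf_land[cf_land$metric == m, ], labels))
    }
  }
  if (!is.null(cf_ghg)) {
    for (m in unique(cf_ghg$metric)) {
      nm <- if (m == "richness") "ghg_SR" else "ghg_RWR"
      for (g in unique(cf_ghg$gas)) {
        sub <- cf_ghg[cf_ghg$metric == m & cf_ghg$gas == g, ]
        add(nm, g, intensity_vector(sub, labels))
      }
    }
  }
  out <- dplyr::bind_rows(comps)
  out <- out[c("metric", "component", "producing_region", "producing_sector",
               "consuming_region", "value")]
  structure(out, class = c("footprint_tensor", class(out)),
            labels = labels, regions = mrio$regions)
}

fp_filter <- function(fp, metric, component = NULL) {
  sub <- fp[fp$metric == metric, ]
  if (!is.null(component)) sub <- sub[sub$component %in% component, ]
  if (nrow(sub) == 0) stop(sprintf("no footprint rows for metric '%s'", metric))
  sub
}

#' Region-to-region bilateral flow matrix for one metric
#'
#' @param fp A `footprint_tensor`.
#' @param metric One of the tensor's metrics, e.g. `"land_SR"`.
#' @param component Optional gas/component subset (summed); default all.
#' @return Producing x consuming region matrix.
#' @export
region_flows <- function(fp, metric, component = NULL) {
  flows_matrix(fp_filter(fp, metric, component))
}

#' Production-based marginal of a footprint tensor, by region
#' @inheritParams region_flows
#' @return Tibble `region`, `production`.
#' @export
production_by_region <- function(fp, metric, component = NULL) {
  sub <- fp_filter(fp, metric, component)
  out <- dplyr::summarise(dplyr::group_by(sub, region = .data$producing_region),
                          production = sum(.data$value), .groups = "drop")
  dplyr::arrange(out, .data$region)
}

#' Consumption-based marginal of a footprint tensor, by region
#' @inheritParams region_flows
#' @return Tibble `region`, `consumption`.
#' @export
consumption_by_region <- function(fp, metric, component = NULL) {
  sub <- fp_filter(fp, metric, component)
  out <- dplyr::summarise(dplyr::group_by(sub, region = .data$consuming_region),
                          consumption = sum(.data$value), .groups = "drop")
  dplyr::arrange(out, .data$region)
}
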