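#' Default sector specification for the synthetic economy
#'
#' Six product sectors spanning the food system's journey from field to
#' waste: two land-using primary sectors (crops, livestock), downstream food
#' processing, fertilizer production, food-waste treatment, and a non-food
#' services aggregate. Flags mark food-related and land-using sectors.
#'
#' @return Tibble with columns `sector`, `food`, `land_using`.
#' @export
default_sectors <- function() {
  tibble::tribble(
    ~sector,           ~food, ~land_using,
    "crops",           TRUE,  TRUE,
    "livestock",       TRUE,  TRUE,
    "food_processing", TRUE,  FALSE,
    "fertilizer",      TRUE,  FALSE,
    "food_waste",      TRUE,  FALSE,
    "services",        FALSE, FALSE)
}

#' Greenhouse gases tracked by the emission extensions
#' @return Character vector `c("co2", "ch4", "n2o")`.
#' @export
tracked_gases <- function() c("co2", "ch4", "n2o")

mrio_region_names <- function(n_regions) sprintf("R%02d", seq_len(n_regions))

#' Region-major (sector-minor) labels of an MRIO system
#' @param regions,sectors Character vectors of region and sector names.
#' @return Tibble with `index`, `region`, `sector` and `key`
#'   (`region.sector`), ordered region-major.
#' @export
mrio_labels <- function(regions, sectors) {
  tibble::tibble(
    index = seq_len(length(regions) * length(sectors)),
    region = rep(regions, each = length(sectors)),
    sector = rep(sectors, times = length(regions)),
    key = paste(rep(regions, each = length(sectors)),
                rep(sectors, times = length(regions)), sep = "."))
}

#' Generate a synthetic multi-regional input-output system with extensions
#'
#' Emulates the structure of a product-by-product MRIO database: a
#' nonnegative technical-coefficient matrix `A` whose spectral radius is
#' strictly below `spectral_bound` (so the economy is productive), a
#' nonnegative final-demand matrix `Y` with one column per consuming region,
#' gross output `x = (I - A)^-1 rowSums(Y)`, and environmental extensions
#' per EUR 1M of output: agricultural land intensity for the land-using
#' sectors and CO2/CH4/N2O emission intensities for every sector. Emission
#' intensity defaults are skewed so that methane dominates the warming of
#' food sectors, as in real agricultural emission accounts (enteric
#' fermentation, paddy rice, manure).
#'
#' At `trade_openness = 0` the economy is autarkic: every cross-region block
#' of `A` and every cross-region entry of `Y` is exactly zero, so all
#' downstream footprints are purely domestic.
#'
#' @param n_regions Number of trade regions (>= 1).
#' @param sectors Sector specification tibble as from [default_sectors()];
#'   must flag at least one food-related and one land-using sector.
#' @param trade_openness Fraction in \[0, 1\] scaling cross-region
#'   intermediate and final-demand flows.
#' @param spectral_bound Upper bound for the spectral radius of `A`
#'   (default 0.7); the generated radius is scaled to 80% of the bound.
#' @param seed Master seed; draws come from the `"mrio"` substream.
#' @return List with elements `mrio` (class `mrio_system`: `regions`,
#'   `sectors`, `A`, `Y`, `x`, `labels`) and `extensions` (class
#'   `extension_table`: tibbles `land_area` and `emissions`).
#' @export
generate_mrio <- function(n_regions, sectors = default_sectors(),
                          trade_openness = 0.3, spectral_bound = 0.7,
                          seed = 1) {
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (!all(c("sector", "food", "land_using") %in% names(sectors)))
    stop("sectors must have columns sector, food, land_using")
  if (!any(sectors$food)) stop("sector spec must name at least one food-related sector")
  if (!any(sectors$land_using)) stop("sector spec must name at least one land-using sector")
  if (trade_openness < 0 || trade_openness > 1)
    stop("trade_openness must lie in [0, 1]")

  m <- nrow(sectors)
  regions <- mrio_region_names(n_regions)
  labels <- mrio_labels(regions, sectors$sector)
  N <- n_regions * m

  with_substream(seed, "mrio", {
    A <- matrix(0, N, N, dimnames = list(labels$key, labels$key))
    for (r in seq_len(n_regions)) {
      for (s in seq_len(n_regions)) {
        rows <- (r - 1L) * m + seq_len(m)
        cols <- (s - 1L) * m + seq_len(m)
        block <- matrix(runif(m * m), m, m)
        if (r != s) block <- block * trade_openness
        A[rows, cols] <- block
      }
    }
    rho <- spectral_radius(A)
    A <- A * (0.8 * spectral_bound / rho)

    Y <- matrix(0, N, n_regions, dimnames = list(labels$key, regions))
    for (r in seq_len(n_regions)) {
      dom <- (r - 1L) * m + seq_len(m)
      Y[dom, r] <- runif(m, 50, 500)
      if (trade_openness > 0 && n_regions > 1) {
        imp <- setdiff(seq_len(N), dom)
        Y[imp, r] <- runif(length(imp), 0, 100) * trade_openness
      }
    }

    x <- gross_output(A, Y)

    land_sectors <- sectors$sector[sectors$land_using]
    land_area <- tidyr::expand_grid(landuse_sector = land_sectors,
                                    region = regions)
    land_area$km2_per_meur <- rlnorm(nrow(land_area), log(10), 0.7)

    emissions <- tidyr::expand_grid(product = sectors$sector, region = regions)
    emissions <- dplyr::left_join(emissions,
                                  dplyr::rename(sectors, product = "sector"),
                                  by = "product")
    n <- nrow(emissions)
    # kg per EUR 1M output; food sectors methane-heavy, services CO2-dominated
    emissions$co2 <- rlnorm(n, log(5e5), 0.5)
    emissions$ch4 <- ifelse(emissions$food,
                            rlnorm(n, log(3e4), 0.7), rlnorm(n, log(8e2), 0.7))
    emissions$n2o <- ifelse(emissions$food,
                            rlnorm(n, log(1.2e3), 0.5), rlnorm(n, log(40), 0.5))
    emissions <- tidyr::pivot_longer(
      emissions[c("product", "region", "co2", "ch4", "n2o")],
      cols = c("co2", "ch4", "n2o"),
      names_to = "gas", values_to = "kg_per_meur")

    list(
      mrio = structure(
        list(regions = regions, sectors = sectors, A = A, Y = Y, x = x,
             labels = labels),
        class = "mrio_system"),
      extensions = structure(
        list(land_area = land_area, emissions = emissions),
        class = "extension_table"))
  })
}

#' @export
print.mrio_system <- function(x, ...) {
  cat(sprintf("<mrio_system> %d regions x %d sectors (spectral radius %.3f)\n",
              length(x$regions), nrow(x$sectors), spectral_radius(x$A)))
  invisible(x)
}
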