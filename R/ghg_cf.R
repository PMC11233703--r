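#' Global warming per EUR 1M of output, by product, region and gas
#'
#' Converts emission intensities to the global mean surface warming at the
#' 20-year horizon via the absolute GTP coefficients:
#' dT\[p,k\] = sum_g E\[g,p,k\] x C\[g\]. Per-gas terms are retained so the
#' footprint can later be decomposed by gas.
#'
#' @param extensions An `extension_table` (uses `emissions`: columns
#'   `product`, `region`, `gas`, `kg_per_meur`).
#' @param constants A [gtp_constants()] vector covering every gas present;
#'   an unknown gas label is a hard error.
#' @return Tibble of class `warming_table`: `product`, `region`, `gas`,
#'   `warming_degC` (per-gas), plus an attribute-free long format; totals
#'   are obtained by summing over `gas`.
#' @export
warming_per_output <- function(extensions, constants = gtp_constants()) {
  em <- extensions$emissions
  unknown <- setdiff(unique(em$gas), names(constants))
  if (length(unknown) > 0)
    stop("no GTP constant for gas(es): ", paste(unknown, collapse = ", "))
  out <- em
  out$warming_degC <- em$kg_per_meur * unclass(constants)[em$gas]
  out <- out[c("product", "region", "gas", "warming_degC")]
  class(out) <- c("warming_table", class(out))
  out
}

#' Spatial temperature-weighting factors from a climate-model ensemble
#'
#' Averages the per-model anomaly grids cell-wise, then normalizes by the
#' area-weighted global mean anomaly over the weighting domain:
#' F\[x\] = dT\[x\] / mean(dT). F up-weights cells warming faster than the
#' global mean. On an equal-area grid the area weighting reduces to a simple
#' mean over domain cells, and the area-weighted mean of F over the domain
#' is exactly 1.
#'
#' @param grids A [world_grids] object with anomaly layers.
#' @param domain `"land"` (unmasked cells, default) or `"all"` cells.
#' @return Object of class `climate_weighting`: list with `F` (matrix),
#'   `mean_anomaly` (scalar, degrees C), `anomaly` (ensemble-mean matrix)
#'   and `domain` (logical matrix).
#' @export
temperature_weights <- function(grids, domain = c("land", "all")) {
  domain <- match.arg(domain)
  if (is.null(grids$anomaly) || length(grids$anomaly) < 1)
    stop("grids carry no temperature-anomaly layers")
  mean_anom <- Reduce(`+`, grids$anomaly) / length(grids$anomaly)
  dom <- if (domain == "land") unmasked(grids) else
    matrix(TRUE, grids$nrow, grids$ncol)
  mbar <- mean(mean_anom[dom])
  if (!is.finite(mbar) || mbar == 0)
    stop("degenerate climate: mean anomaly over the weighting domain is zero")
  structure(list(F = mean_anom / mbar, mean_anomaly = mbar,
                 anomaly = mean_anom, domain = dom),
            class = "climate_weighting")
}

#' Climate-impact kernel: summed F x H x S x A over the analysis domain
#'
#' Because warming acts globally, the cell sum sum_x F\[x\] H\[x\] S\[x\]
#' A\[x\] is a single scalar per richness metric; every product's GHG
#' characterization factor is its warming times this kernel.
#'
#' @inheritParams temperature_weights
#' @param weighting A `climate_weighting` object.
#' @param metric `"richness"` or `"rarity"`.
#' @return Scalar kernel (species x km2 per degree C of global warming; a
#'   negative value means warming causes net loss).
#' @export
climate_kernel <- function(grids, weighting, metric = c("richness", "rarity")) {
  metric <- match.arg(metric)
  H <- climate_sensitivity_layer(grids, metric)
  S <- metric_layer(grids, metric)
  dom <- unmasked(grids)
  sum(weighting$F[dom] * H[dom] * S[dom]) * grids$cell_area
}

climate_sensitivity_layer <- function(grids, metric) {
  if (is.null(grids$sensitivity))
    stop("grids carry no climate-sensitivity layers")
  H <- grids$sensitivity[[metric]]
  if (is.null(H)) {
    if (metric == "rarity" && !is.null(grids$sensitivity$richness)) {
      warning("no rarity-specific climate sensitivity grid; reusing the ",
              "species-richness grid")
      H <- grids$sensitivity$richness
    } else {
      stop(sprintf("no climate-sensitivity grid for metric '%s'", metric))
    }
  }
  H
}

#' GHG-driven characterization factors per product, region and gas
#'
#' Chains the warming table with the spatial biodiversity response: the
#' fractional richness change in cell x from producing EUR 1M of product p
#' in region k is dS\[x,p,k\] = F\[x\] x H\[x\] x dT\[p,k\]; multiplying by
#' the undisturbed richness S\[x\] and cell area A\[x\] and summing over
#' cells gives the characterization factor, reported as a positive loss
#' (species x km2 per EUR 1M). Emissions act on global biodiversity, so two
#' regions with identical emission intensities receive identical CFs
#' regardless of their own biodiversity.
#'
#' Two equivalent implementations are provided: `"kernel"` factorizes the
#' cell sum into dT x K with K = sum_x F H S A precomputed once;
#' `"cellwise"` evaluates the per-cell grids for every (product, region,
#' gas) and sums. They must agree to floating-point accuracy.
#'
#' @param warming A `warming_table` from [warming_per_output()].
#' @param weighting A `climate_weighting` from [temperature_weights()].
#' @param grids A [world_grids] object with richness and sensitivity layers.
#' @param metric `"richness"` or `"rarity"`.
#' @param method `"kernel"` (default) or `"cellwise"`.
#' @return Tidy tibble `product`, `region`, `gas`, `metric`, `cf_value`,
#'   `units`; gas-total CFs are sums of the per-gas rows.
#' @export
ghg_characterization_factors <- function(warming, weighting, grids,
                                         metric = c("richness", "rarity"),
                                         method = c("kernel", "cellwise")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  out <- warming[c("product", "region", "gas")]
  if (method == "kernel") {
    K <- climate_kernel(grids, weighting, metric)
    out$cf_value <- -warming$warming_degC * K
  } else {
    H <- climate_sensitivity_layer(grids, metric)
    S <- metric_layer(grids, metric)
    dom <- unmasked(grids)
    Fd <- weighting$F[dom]; Hd <- H[dom]; Sd <- S[dom]
    out$cf_value <- vapply(warming$warming_degC, function(dT) {
      dS_x <- Fd * Hd * dT
      -sum(dS_x * Sd) * grids$cell_area
    }, numeric(1))
  }
  out$metric <- metric
  out$units <- if (metric == "richness") "species.km2_per_MEUR" else "range_fraction.km2_per_MEUR"
  out[c("product", "region", "gas", "metric", "cf_value", "units")]
}

#' Full GHG characterization-factor pipeline for one richness metric
#'
#' @param extensions An `extension_table`.
#' @param grids A [world_grids] object with anomaly, sensitivity and
#'   richness layers.
#' @param constants A [gtp_constants()] vector.
#' @param metric `"richness"` or `"rarity"`.
#' @param domain Weighting domain, see [temperature_weights()].
#' @return Tidy CF tibble as from [ghg_characterization_factors()].
#' @export
ghg_cf <- function(extensions, grids, constants = gtp_constants(),
                   metric = c("richness", "rarity"), domain = "land") {
  metric <- match.arg(metric)
  warming <- warming_per_output(extensions, constants)
  weighting <- temperature_weights(grids, domain)
  ghg_characterization_factors(warming, weighting, grids, metric)
}
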