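#' Spectral radius of a square matrix
#' @param A Square numeric matrix.
#' @return The largest eigenvalue modulus.
#' @export
spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Leontief inverse of a productive technical-coefficient matrix
#'
#' Returns L = (I - A)^-1, the matrix that maps final demand to the gross
#' output required through all rounds of the supply chain. The economy must
#' be productive (spectral radius of A strictly below 1) for the underlying
#' geometric series I + A + A^2 + ... to converge.
#'
#' @param A Nonnegative square technical-coefficient matrix (EUR of input
#'   per EUR of output).
#' @return The Leontief inverse, same dimension as `A`.
#' @export
leontief_inverse <- function(A) {
  check_technical_matrix(A)
  solve(diag(nrow(A)) - A)
}

check_technical_matrix <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix")
  if (any(A < 0)) stop("technical coefficient matrix must be nonnegative")
  if (spectral_radius(A) >= 1)
    stop("economy not productive: spectral radius of A is >= 1")
  invisible(A)
}

#' Gross output consistent with a technical matrix and final demand
#'
#' Solves x = A x + y (y the row sums of final demand Y) as a linear system,
#' i.e. x = (I - A)^-1 y without forming the explicit inverse.
#'
#' @param A Productive technical-coefficient matrix.
#' @param Y Final-demand matrix (one column per consuming region) or a
#'   total-final-demand vector.
#' @return Gross output vector x (EUR 1M).
#' @export
gross_output <- function(A, Y) {
  check_technical_matrix(A)
  y <- if (is.matrix(Y)) rowSums(Y) else as.numeric(Y)
  if (length(y) != nrow(A)) stop("final demand does not match A's dimension")
  as.vector(solve(diag(nrow(A)) - A, y))
}

check_alignment <- function(f, labels) {
  if (length(f) != nrow(labels))
    stop("intensity vector length does not match the (sector, region) labels")
  if (!is.null(names(f)) && !identical(names(f), labels$key))
    stop("intensity vector labels are misaligned with the MRIO ordering")
  invisible(f)
}

#' Production-based footprints: direct territorial attribution
#'
#' The footprint of (sector, region) is its direct characterization-factor
#' intensity times its gross output; region totals sum over the region's
#' sectors. This attributes impacts to where production physically occurs.
#'
#' @param f Intensity vector (impact per EUR 1M output), aligned to `labels`;
#'   if named, names must equal `labels$key`.
#' @param x Gross output vector (EUR 1M).
#' @param labels Tibble with columns `region`, `sector`, `key` in the MRIO's
#'   region-major ordering (see [mrio_labels()]).
#' @return Tibble with `producing_region`, `producing_sector`, `value`.
#' @export
production_footprints <- function(f, x, labels) {
  check_alignment(f, labels)
  if (length(x) != nrow(labels)) stop("gross output misaligned with labels")
  tibble::tibble(producing_region = labels$region,
                 producing_sector = labels$sector,
                 value = as.numeric(f) * as.numeric(x))
}

#' Consumption-based footprints through the Leontief model
#'
#' Computes the impacts embodied in each region's final demand,
#' E_r = f . (I - A)^-1 . Y_r, solved as a linear system. Two attribution
#' views are available: `"origin"` keeps the producing (sector, region) where
#' each impact physically occurs; `"final_product"` attributes the embodied
#' impact of the whole upstream chain to the final product purchased.
#'
#' @param f Intensity vector as in [production_footprints()].
#' @param A Productive technical-coefficient matrix.
#' @param Y Final-demand matrix, one column per consuming region.
#' @param labels MRIO labels tibble.
#' @param view `"origin"` (default) or `"final_product"`.
#' @return For `"origin"`: tibble `producing_region`, `producing_sector`,
#'   `consuming_region`, `value`. For `"final_product"`: tibble
#'   `final_product_region`, `final_product_sector`, `consuming_region`,
#'   `value`.
#' @export
consumption_footprints <- function(f, A, Y, labels,
                                   view = c("origin", "final_product")) {
  view <- match.arg(view)
  check_technical_matrix(A)
  check_alignment(f, labels)
  if (!is.matrix(Y) || nrow(Y) != nrow(A))
    stop("Y must be a matrix with one row per (sector, region)")
  regions <- colnames(Y) %||% unique(labels$region)
  if (view == "origin") {
    LY <- solve(diag(nrow(A)) - A, Y)        # gross output per consuming region
    M <- LY * as.numeric(f)                  # row-wise scaling by intensity
    tidy_flow_matrix(M, labels, regions)
  } else {
    fL <- as.numeric(solve(t(diag(nrow(A)) - A), as.numeric(f)))  # f' L
    M <- Y * fL                              # embodied intensity x final purchase
    out <- tidy_flow_matrix(M, labels, regions)
    names(out)[1:2] <- c("final_product_region", "final_product_sector")
    out
  }
}

tidy_flow_matrix <- function(M, labels, regions) {
  tibble::tibble(
    producing_region = rep(labels$region, times = length(regions)),
    producing_sector = rep(labels$sector, times = length(regions)),
    consuming_region = rep(regions, each = nrow(labels)),
    value = as.numeric(M))
}

#' Bilateral decomposition of embodied impacts into region-to-region flows
#'
#' Aggregates the stressor-origin consumption attribution over sectors,
#' yielding the matrix of impacts occurring in producing region s that are
#' embodied in the final demand of consuming region r. Row sums recover
#' production totals and column sums consumption totals.
#'
#' @inheritParams consumption_footprints
#' @return A regions x regions matrix `flows` with `flows[s, r]` the impact
#'   produced in s and consumed by r; dimnames are region labels.
#' @export
bilateral_flows <- function(f, A, Y, labels) {
  fp <- consumption_footprints(f, A, Y, labels, view = "origin")
  flows_matrix(fp)
}

#' Collapse a tidy origin-attribution table to a region-to-region matrix
#' @param fp Tibble from [consumption_footprints()] (origin view), possibly
#'   pre-filtered to a metric/component.
#' @return Producing x consuming region matrix.
#' @export
flows_matrix <- function(fp) {
  prod_r <- sort(unique(fp$producing_region))
  cons_r <- sort(unique(fp$consuming_region))
  out <- matrix(0, length(prod_r), length(cons_r),
                dimnames = list(producing = prod_r, consuming = cons_r))
  agg <- dplyr::summarise(
    dplyr::group_by(fp, .data$producing_region, .data$consuming_region),
    value = sum(.data$value), .groups = "drop")
  out[cbind(match(agg$producing_region, prod_r),
            match(agg$consuming_region, cons_r))] <- agg$value
  out
}
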