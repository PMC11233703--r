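#' Generate synthetic species geographic ranges on a grid
#'
#' Each species occupies a contiguous rectangular block of cells. Target
#' range sizes (in cells) are drawn from a right-skewed lognormal — the
#' typical shape of empirical range-size distributions, where most species
#' are narrow-ranged — and range centroids are biased toward the equatorial
#' rows of the grid, producing a latitudinal richness gradient once ranges
#' are stacked. Rectangles are placed fully inside the grid, so the realized
#' range area equals width x height x cell_area.
#'
#' @param n_species Number of species (>= 0).
#' @param grid A [world_grids] object (defines dimensions and cell area).
#' @param range_size List with `meanlog` and `sdlog` of the lognormal
#'   range-size distribution, in cells (default `log(25)`, `1`).
#' @param seed Master seed; draws come from the `"species"` substream.
#' @return List of `species_range` objects: `id`, `cells` (linear indices),
#'   `range_area` (km2).
#' @export
generate_species_ranges <- function(n_species, grid,
                                    range_size = list(meanlog = log(25), sdlog = 1),
                                    seed = 1) {
  if (n_species < 0) stop("n_species must be >= 0")
  if (grid$nrow < 1 || grid$ncol < 1) stop("grid is empty")
  if (n_species == 0) return(list())
  nr <- grid$nrow; nc <- grid$ncol
  with_substream(seed, "species", {
    target <- pmin(nr * nc, pmax(1, round(rlnorm(n_species, range_size$meanlog,
                                                 range_size$sdlog))))
    # equatorial bias: centroid row weighted by a gaussian about the middle row
    row_w <- stats::dnorm(seq_len(nr), mean = (nr + 1) / 2, sd = nr / 4)
    lapply(seq_len(n_species), function(i) {
      t_i <- target[i]
      w <- max(1L, min(nc, as.integer(round(sqrt(t_i * runif(1, 0.6, 1.6))))))
      h <- max(1L, min(nr, as.integer(round(t_i / w))))
      w <- max(1L, min(nc, as.integer(round(t_i / h))))  # re-fit width after clamping
      r0 <- if (nr - h > 0) {
        centre <- sample.int(nr, 1, prob = row_w)
        min(max(1L, centre - h %/% 2L), nr - h + 1L)
      } else 1L
      c0 <- if (nc - w > 0) sample.int(nc - w + 1L, 1) else 1L
      rows <- r0 + seq_len(h) - 1L
      cols <- c0 + seq_len(w) - 1L
      cells <- as.integer(outer(rows, (cols - 1L) * nr, `+`))
      structure(list(id = sprintf("sp%04d", i), cells = cells,
                     range_area = length(cells) * grid$cell_area),
                class = "species_range")
    })
  })
}

#' Stack species ranges into richness and rarity-weighted richness layers
#'
#' Species richness of a cell is the count of species whose range covers it.
#' Each species' rarity weight is the inverse of its range area; the
#' rarity-weighted richness of a cell is the sum of the weights of the
#' species present, so narrow-ranged species contribute most.
#'
#' @param ranges List of `species_range` objects rasterized on `grid`.
#' @param grid A [world_grids] object.
#' @return List with matrices `richness` (species per cell) and `rarity`
#'   (summed inverse range areas, per km2).
#' @export
stack_ranges <- function(ranges, grid) {
  richness <- matrix(0, grid$nrow, grid$ncol)
  rarity <- matrix(0, grid$nrow, grid$ncol)
  for (sp in ranges) {
    if (any(sp$cells < 1 | sp$cells > grid$nrow * grid$ncol))
      stop("species range lies off the grid")
    if (sp$range_area <= 0) stop("range_area must be positive")
    richness[sp$cells] <- richness[sp$cells] + 1
    rarity[sp$cells] <- rarity[sp$cells] + 1 / sp$range_area
  }
  list(richness = richness, rarity = rarity)
}
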