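test_that("autarkic economies have exactly zero cross-region structure", {
  res <- generate_mrio(3, trade_openness = 0, seed = 7)
  m <- nrow(res$mrio$sectors)
  for (r in 1:3) for (s in 1:3) {
    if (r == s) next
    block <- res$mrio$A[(r - 1) * m + 1:m, (s - 1) * m + 1:m]
    expect_identical(unname(as.vector(block)), rep(0, m * m))
    expect_identical(unname(res$mrio$Y[(r - 1) * m + 1:m, s]), rep(0, m))
  }
})

test_that("identical (config, seed) yields bit-identical systems", {
  a <- generate_mrio(4, trade_openness = 0.4, seed = 11)
  b <- generate_mrio(4, trade_openness = 0.4, seed = 11)
  expect_identical(a$mrio$A, b$mrio$A)
  expect_identical(a$mrio$Y, b$mrio$Y)
  expect_identical(a$extensions, b$extensions)
  w1 <- generate_world(small_world_config(), seed = 3)
  w2 <- generate_world(small_world_config(), seed = 3)
  expect_identical(w1$grids, w2$grids)
  expect_identical(w1$mrio$x, w2$mrio$x)
})

test_that("generated economies are productive within the spectral bound", {
  sectors4 <- default_sectors()[1:4, ]
  res <- generate_mrio(3, sectors4, trade_openness = 0.3,
                       spectral_bound = 0.7, seed = 1)
  # independent power-iteration estimate, not eigen()
  expect_lt(oracle_spectral_radius(res$mrio$A), 0.7)
  expect_true(all(res$mrio$A >= 0))
  expect_true(all(res$mrio$Y >= 0))
  # balance identity x = A x + rowSums(Y)
  resid <- res$mrio$x - as.vector(res$mrio$A %*% res$mrio$x) -
    rowSums(res$mrio$Y)
  expect_lt(max(abs(resid)) / max(res$mrio$x), 1e-10)
  # productive: truncated power series converges to the Leontief inverse
  L <- leontief_inverse(res$mrio$A)
  expect_true(all(L > -1e-12))
  expect_lt(max(abs(L - oracle_power_series(res$mrio$A, 300))), 1e-9)
})

test_that("degenerate sector specs and openness are rejected", {
  no_food <- tibble::tibble(sector = "services", food = FALSE,
                            land_using = TRUE)
  expect_error(generate_mrio(2, no_food, seed = 1), "food")
  no_land <- tibble::tibble(sector = "food_processing", food = TRUE,
                            land_using = FALSE)
  expect_error(generate_mrio(2, no_land, seed = 1), "land-using")
  expect_error(generate_mrio(2, trade_openness = 1.2, seed = 1), "openness")
  expect_error(generate_mrio(2, trade_openness = -0.1, seed = 1), "openness")
})

test_that("species ranges honour count, contiguity and size distribution", {
  grid <- make_grids(matrix(0, 10, 10), cell_area = 25)
  expect_identical(generate_species_ranges(0, grid, seed = 1), list())
  expect_error(generate_species_ranges(3, make_grids(matrix(0, 0, 0)),
                                       seed = 1), "empty")

  ranges <- generate_species_ranges(40, grid, seed = 5)
  for (sp in ranges) {
    expect_equal(sp$range_area, length(sp$cells) * grid$cell_area)
    expect_true(all(sp$cells >= 1 & sp$cells <= 100))
    # contiguity: the occupied cells form a full rectangle
    idx <- arrayInd(sp$cells, c(10, 10))
    expect_equal(length(sp$cells),
                 diff(range(idx[, 1]) + c(0, 1)) * diff(range(idx[, 2]) + c(0, 1)))
  }

  # realized range-size quantiles track the requested lognormal at n = 1000
  big <- make_grids(matrix(0, 50, 50), cell_area = 1)
  rs <- list(meanlog = log(25), sdlog = 1)
  areas <- vapply(generate_species_ranges(1000, big, rs, seed = 9),
                  function(sp) sp$range_area, numeric(1))
  for (q in c(0.25, 0.5, 0.75)) {
    expect_lt(abs(stats::quantile(areas, q) - qlnorm(q, rs$meanlog, rs$sdlog)) /
                qlnorm(q, rs$meanlog, rs$sdlog), 0.15)
  }
})

test_that("range stacking matches the per-cell brute force", {
  grid <- make_grids(matrix(0, 20, 20), cell_area = 4)
  expect_equal(stack_ranges(list(), grid)$richness, matrix(0, 20, 20))
  expect_equal(stack_ranges(list(), grid)$rarity, matrix(0, 20, 20))

  full <- structure(list(id = "sp1", cells = 1:400, range_area = 400 * 4),
                    class = "species_range")
  layers <- stack_ranges(list(full), grid)
  expect_true(all(layers$richness == 1))
  expect_true(all(layers$rarity == 1 / (400 * 4)))

  ranges <- generate_species_ranges(50, grid, seed = 2)
  got <- stack_ranges(ranges, grid)
  want <- oracle_stack(ranges, grid)
  expect_identical(got$richness, want$richness)
  expect_identical(got$rarity, want$rarity)
})

test_that("landscape partitions cells and supports the excluded-biome mask", {
  g1 <- generate_landscape(15, 15, 50, n_biomes = 1, n_regions = 2,
                           landuse_types = c("crops", "livestock"),
                           mask_fraction = 0, seed = 3)
  expect_true(all(g1$biome_id == 1L))
  expect_true(all(g1$region_id %in% 1:2))

  g2 <- generate_landscape(20, 20, 50, n_biomes = 4, n_regions = 3,
                           landuse_types = c("crops", "livestock"),
                           mask_fraction = 0.1, seed = 3)
  expect_equal(sum(is.na(g2$biome_id)), 40)  # 10% of 400 cells
  # masked cells are absent from all stratified statistics
  ct <- cell_table(g2)
  expect_equal(nrow(ct), 360)
  expect_false(any(is.na(ct$biome)))
  lu <- landuse_table(g2)
  expect_true(all(lu$cell %in% ct$cell))
  # per-land-use global area agrees with an independent summation
  for (type in c("crops", "livestock")) {
    expect_equal(sum(lu$landuse_area[lu$landuse == type]),
                 oracle_landuse_area(g2, type))
  }
  expect_error(generate_landscape(10, 10, 50, 0, 2, "crops", seed = 1),
               "n_biomes")
  expect_error(generate_landscape(10, 10, 50, 2, 0, "crops", seed = 1),
               "n_regions")
})

test_that("climate layers average correctly and honour constant sensitivity", {
  grid <- generate_landscape(12, 12, 100, 2, 2, "crops", 0, seed = 4)
  grid <- generate_climate(grid, n_models = 3, warming_mean = 0.6,
                           sensitivity = -0.02, seed = 4)
  expect_true(all(grid$sensitivity$richness == -0.02))
  # multi-model mean equals an independent cell-wise average
  want <- matrix(0, 12, 12)
  for (m in grid$anomaly) want <- want + m / 3
  tw <- temperature_weights(grid, domain = "all")
  expect_equal(tw$anomaly, want, tolerance = 1e-12)
  # identical models: the ensemble mean equals each member everywhere
  grid$anomaly <- rep(list(grid$anomaly[[1]]), 3)
  tw1 <- temperature_weights(grid, domain = "all")
  expect_equal(tw1$anomaly, grid$anomaly[[1]], tolerance = 1e-14)
})
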