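test_that("stratum means weight richness by land-use area", {
  # uniform richness: every populated stratum has S = 50
  g <- make_grids(matrix(50, 5, 5))
  s <- stratum_mean_richness(g)
  expect_true(all(s$S == 50))

  # two cells, richness 10 and 20, land-use areas in ratio 1:3 -> S = 17.5
  g2 <- make_grids(matrix(c(10, 20), 1, 2), cell_area = 10,
                   fractions = list(crops = matrix(c(0.1, 0.3), 1, 2)))
  expect_equal(stratum_mean_richness(g2)$S, 17.5)
  # unweighted switch: simple cell mean
  expect_equal(stratum_mean_richness(g2, weighted = FALSE)$S, 15)

  # a zero-fraction cell contributes nothing
  g3 <- make_grids(matrix(c(10, 999), 1, 2), cell_area = 10,
                   fractions = list(crops = matrix(c(0.5, 0), 1, 2)))
  expect_equal(stratum_mean_richness(g3)$S, 10)

  # sub-threshold strata are flagged, not dropped
  s3 <- stratum_mean_richness(g3, min_area = 100)
  expect_true(s3$flagged)
  expect_equal(nrow(s3), 1)
})

test_that("biome shares are area proportions that sum to one", {
  g <- make_grids(matrix(c(1, 1), 1, 2))
  expect_equal(biome_shares(g)$B, 1)

  # areas 30 km2 (biome 1) and 10 km2 (biome 2) -> shares 0.75 / 0.25
  g2 <- make_grids(matrix(c(1, 1), 1, 2), cell_area = 100,
                   biome_id = matrix(1:2, 1, 2),
                   fractions = list(crops = matrix(c(0.3, 0.1), 1, 2)),
                   biome_names = c("tropical_forest", "drylands"))
  b <- biome_shares(g2)
  expect_equal(sort(b$B), c(0.25, 0.75))

  # normalization holds on a generated landscape, excluded biomes dropped
  g3 <- generate_landscape(20, 20, 50, 4, 3, c("crops", "livestock"),
                           mask_fraction = 0.1, seed = 8)
  b3 <- biome_shares(g3)
  sums <- dplyr::summarise(dplyr::group_by(b3, landuse, region),
                           s = sum(B), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-10))
})

test_that("land-use-driven richness change follows S x P and biome weighting", {
  g <- make_grids(matrix(100, 2, 2))
  strata <- stratum_mean_richness(g)
  shares <- biome_shares(g)

  # P = 0 nullifies everything
  d0 <- land_delta_richness(strata, shares, simple_sensitivity(0))
  expect_true(all(d0$stratum$dS_stratum == 0))
  expect_true(all(d0$total$dS == 0))

  # S = 100, P = -0.3 -> stratum change -30
  d <- land_delta_richness(strata, shares, simple_sensitivity(-0.3))
  expect_equal(d$stratum$dS_stratum, -30)

  # strata changes (-30, -10) with shares (0.75, 0.25) -> -25
  g2 <- make_grids(matrix(c(100, 100), 1, 2), cell_area = 100,
                   biome_id = matrix(1:2, 1, 2),
                   fractions = list(crops = matrix(c(0.3, 0.1), 1, 2)),
                   biome_names = c("tropical_forest", "drylands"))
  sens <- sensitivity_table(
    P = tibble::tibble(biome = c("tropical_forest", "drylands"),
                       class = "cropland", P = c(-0.3, -0.1)),
    correspondence = tibble::tibble(landuse = "crops", class = "cropland"))
  d2 <- land_delta_richness(stratum_mean_richness(g2), biome_shares(g2), sens)
  expect_equal(d2$total$dS, -30 * 0.75 + -10 * 0.25)

  # a populated biome with no P entry is a hard error naming the pair
  bad <- sensitivity_table(
    P = tibble::tibble(biome = "tropical_forest", class = "cropland",
                       P = -0.3),
    correspondence = tibble::tibble(landuse = "crops", class = "cropland"))
  expect_error(
    land_delta_richness(stratum_mean_richness(g2), biome_shares(g2), bad),
    "drylands.*cropland")
})

test_that("characterization factors flip sign to positive-loss and gate on A", {
  delta <- tibble::tibble(landuse = "crops", region = "R01", dS = -25)
  ext0 <- make_extensions(tibble::tibble(landuse_sector = "crops",
                                         region = "R01", km2_per_meur = 0))
  expect_equal(land_characterization_factors(delta, ext0)$cf_value, 0)

  # dS = -25 species, A = 2 km2/MEUR -> CF = +50 species km2 per MEUR
  ext2 <- make_extensions(tibble::tibble(landuse_sector = "crops",
                                         region = "R01", km2_per_meur = 2))
  cf <- land_characterization_factors(delta, ext2)
  expect_equal(cf$cf_value, 50)
  expect_equal(cf$units, "species.km2_per_MEUR")

  extneg <- make_extensions(tibble::tibble(landuse_sector = "crops",
                                           region = "R01", km2_per_meur = -1))
  expect_error(land_characterization_factors(delta, extneg), "nonnegative")

  # pairs with no stratum on the grid come out 0 and flagged
  delta_missing <- tibble::tibble(landuse = "crops", region = "R99", dS = -25)
  cfm <- land_characterization_factors(delta_missing, ext2)
  expect_equal(cfm$cf_value, 0)
  expect_true(cfm$no_stratum)
})

test_that("stratified pipeline equals the cell-level brute force", {
  for (seed in 1:3) {
    w <- generate_world(small_world_config(), seed = seed)
    for (metric in c("richness", "rarity")) {
      cf <- land_cf(w$grids, w$sensitivity[[metric]], w$extensions, metric)
      want <- oracle_land_cf(w$grids, w$sensitivity[[metric]],
                             w$extensions, metric)
      scale <- max(abs(want))
      expect_lt(max(abs(cf$cf_value - want)) / scale, 1e-8)
    }
  }
})

test_that("land CFs are homogeneous of degree one in the richness layer", {
  w <- generate_world(small_world_config(), seed = 4)
  cf1 <- land_cf(w$grids, w$sensitivity$richness, w$extensions, "richness")
  g2 <- w$grids
  g2$richness <- g2$richness * 2
  cf2 <- land_cf(g2, w$sensitivity$richness, w$extensions, "richness")
  expect_identical(cf2$cf_value, cf1$cf_value * 2)
})

test_that("the two richness metrics share one code path", {
  # with rarity := richness and the same P, the CFs must coincide exactly
  w <- generate_world(small_world_config(), seed = 5)
  g <- w$grids
  g$rarity <- g$richness
  cf_sr <- land_cf(g, w$sensitivity$richness, w$extensions, "richness")
  cf_rwr <- land_cf(g, w$sensitivity$richness, w$extensions, "rarity")
  expect_identical(cf_sr$cf_value, cf_rwr$cf_value)
})
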