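# Independent oracles, deliberately written as plain per-cell / per-term
# loops so they share no code path with the package implementation.

# richness and rarity by looping over every cell and every species
oracle_stack <- function(ranges, grid) {
  n <- grid$nrow * grid$ncol
  richness <- numeric(n)
  rarity <- numeric(n)
  for (cell in seq_len(n)) {
    for (sp in ranges) {
      if (cell %in% sp$cells) {
        richness[cell] <- richness[cell] + 1
        rarity[cell] <- rarity[cell] + 1 / sp$range_area
      }
    }
  }
  list(richness = matrix(richness, grid$nrow, grid$ncol),
       rarity = matrix(rarity, grid$nrow, grid$ncol))
}

# truncated Neumann series I + A + A^2 + ... for the Leontief inverse
oracle_power_series <- function(A, n_terms = 500) {
  L <- diag(nrow(A))
  term <- diag(nrow(A))
  for (i in seq_len(n_terms)) {
    term <- term %*% A
    L <- L + term
  }
  L
}

# spectral radius by plain power iteration (independent of eigen())
oracle_spectral_radius <- function(A, iters = 2000) {
  v <- rep(1, nrow(A))
  lambda <- 0
  for (i in seq_len(iters)) {
    w <- A %*% v
    lambda <- sqrt(sum(w^2)) / sqrt(sum(v^2))
    v <- w / sqrt(sum(w^2))
  }
  lambda
}

# land CF by a direct cell-level sum, bypassing the stratified tables:
# dS[i,k] = sum_cells w S P(biome) / sum_cells w, CF = -dS * A[i,k]
oracle_land_cf <- function(grids, sens, extensions, metric) {
  layer <- grids[[metric]]
  land <- extensions$land_area
  cf <- numeric(nrow(land))
  for (r in seq_len(nrow(land))) {
    i <- land$landuse_sector[r]
    k <- land$region[r]
    k_id <- match(k, grids$region_names)
    cls <- sens$correspondence$class[sens$correspondence$landuse == i]
    frac <- grids$landuse_fraction[[i]]
    num <- 0; den <- 0
    for (cell in seq_len(grids$nrow * grids$ncol)) {
      if (is.na(grids$biome_id[cell])) next
      if (grids$region_id[cell] != k_id) next
      if (frac[cell] <= 0) next
      w <- frac[cell] * grids$cell_area
      biome <- grids$biome_names[grids$biome_id[cell]]
      P <- sens$P$P[sens$P$biome == biome & sens$P$class == cls]
      num <- num + w * layer[cell] * P
      den <- den + w
    }
    cf[r] <- if (den == 0) 0 else -(num / den) * land$km2_per_meur[r]
  }
  cf
}

# per-landuse global area by plain summation over all cells
oracle_landuse_area <- function(grids, type) {
  tot <- 0
  frac <- grids$landuse_fraction[[type]]
  for (cell in seq_len(grids$nrow * grids$ncol)) {
    if (is.na(grids$biome_id[cell])) next
    tot <- tot + frac[cell] * grids$cell_area
  }
  tot
}
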