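test_that("niche-model metaweb hits the target connectance and is valid", {
  cfg <- syntheticConfig(n_species = 100, metaweb_connectance = 0.1, seed = 1)
  mw <- generateMetaweb(cfg)
  expect_true(validObject(mw))
  # ~1000 directed edges at n = 100, C = 0.1 (within 20% of target)
  expect_gt(nLinks(mw), 800)
  expect_lt(nLinks(mw), 1200)
  # body mass increases with niche value in expectation
  sp <- mwSpecies(mw)
  expect_gt(cor(sp$niche_value, log(sp$body_mass_g)), 0.5)
  # determinism
  mw2 <- generateMetaweb(cfg)
  expect_identical(mwEdges(mw), mwEdges(mw2))
})

test_that("degenerate metaweb configurations stay valid and bad ones error", {
  tiny <- generateMetaweb(syntheticConfig(n_species = 2,
                                          metaweb_connectance = 1e-4,
                                          seed = 2))
  expect_true(validObject(tiny))
  expect_lte(nLinks(tiny), 2)
  expect_error(syntheticConfig(metaweb_connectance = 0), "connectance")
  expect_error(syntheticConfig(metaweb_connectance = 1.2), "connectance")
  expect_error(syntheticConfig(protection_effects =
                                 list(nonsense_metric = list(beta = 1, sd = 0))),
               "mechanism")
})

test_that("landscape has full covariates and contiguous regions", {
  cfg <- syntheticConfig(grid_dims = c(20, 20), n_regions = 2, seed = 3)
  cells <- generateLandscape(cfg)
  expect_identical(nrow(cells), 400L)
  num <- c("x", "y", "elevation", "slope", "remoteness", "human_density")
  expect_false(any(is.na(cells[, c(num, "region", "land_cover")])))
  expect_identical(sort(unique(cells$region)), c("R1", "R2"))
  # axis-aligned region blocks: each region spans a contiguous column range
  for (r in unique(cells$region)) {
    cols <- sort(unique(cells$col[cells$region == r]))
    expect_identical(cols, seq(min(cols), max(cols)))
  }
  expect_identical(cells, generateLandscape(cfg))
})

test_that("reserve placement bias pushes PA centres uphill", {
  cfg0 <- syntheticConfig(grid_dims = c(20, 20), n_pa = 12,
                          placement_bias = 0, seed = 1)
  cells <- generateLandscape(cfg0)
  grid_mean <- mean(cells$elevation)
  centre_elev <- function(pas) {
    idx <- match(paste(pas$center_x, pas$center_y),
                 paste(cells$x, cells$y))
    mean(cells$elevation[idx])
  }
  unbiased <- biased <- numeric(100)
  for (s in 1:100) {
    c0 <- syntheticConfig(grid_dims = c(20, 20), n_pa = 12,
                          placement_bias = 0, seed = s)
    c2 <- syntheticConfig(grid_dims = c(20, 20), n_pa = 12,
                          placement_bias = 2, seed = s)
    unbiased[s] <- centre_elev(generateProtectedAreas(c0, cells))
    biased[s] <- centre_elev(generateProtectedAreas(c2, cells))
  }
  expect_lt(abs(mean(unbiased) - grid_mean), 30)    # Monte-Carlo error band
  expect_gt(mean(biased), grid_mean + 100)
  one <- generateProtectedAreas(
    syntheticConfig(grid_dims = c(20, 20), n_pa = 1, seed = 4), cells)
  expect_identical(nrow(one), 1L)
})

test_that("null protection effects leave no richness contrast", {
  contrasts <- c()
  for (s in 1:12) {
    cfg <- tinyWorldConfig(s)
    cfg$protection_effects <- list()
    w <- generateWorld(cfg)
    mem <- cellMembership(w@truth$networks)
    rich <- tapply(w@occurrences$species_id, w@occurrences$cell_id,
                   function(x) length(unique(x)))
    for (nid in networkTable(w@truth$networks)$network_id) {
      m <- mem[mem$network_id == nid, ]
      ri <- rich[m$cell_id[m$status == "protected"]]
      ro <- rich[m$cell_id[m$status == "nonprotected"]]
      if (sum(!is.na(ri)) >= 3 && sum(!is.na(ro)) >= 3)
        contrasts <- c(contrasts, mean(ri, na.rm = TRUE) -
                                    mean(ro, na.rm = TRUE))
    }
  }
  expect_gte(length(contrasts), 50)
  se <- sd(contrasts) / sqrt(length(contrasts))
  expect_lt(abs(mean(contrasts)), 3 * se + 0.5)
})

test_that("a positive richness effect yields a positive detected contrast", {
  contrasts <- c()
  for (s in 1:12) {
    cfg <- tinyWorldConfig(s)
    cfg$protection_effects <- list(species_richness =
                                     list(beta = 0.5, sd = 0.1))
    w <- generateWorld(cfg)
    mem <- cellMembership(w@truth$networks)
    rich <- tapply(w@occurrences$species_id, w@occurrences$cell_id,
                   function(x) length(unique(x)))
    for (nid in networkTable(w@truth$networks)$network_id) {
      m <- mem[mem$network_id == nid, ]
      ri <- rich[m$cell_id[m$status == "protected"]]
      ro <- rich[m$cell_id[m$status == "nonprotected"]]
      if (sum(!is.na(ri)) >= 3 && sum(!is.na(ro)) >= 3)
        contrasts <- c(contrasts, mean(ri, na.rm = TRUE) -
                                    mean(ro, na.rm = TRUE))
    }
  }
  expect_gte(length(contrasts), 50)
  expect_gt(mean(contrasts), 0)
})

test_that("survey effort respects a high configured mean", {
  cfg <- syntheticConfig(grid_dims = c(12, 12), mean_events_per_cell = 400,
                         effort_dispersion = 30, seed = 6)
  cells <- generateLandscape(cfg)
  pas <- filterPAs(generateProtectedAreas(cfg, cells))
  st <- assignProtectionStatus(cells, pas, seed = 6)
  nw <- attachBuffer(groupPANetworks(pas, st), st)
  occ <- generateOccurrences(cfg, generateMetaweb(cfg), cells, nw)
  expect_gte(min(occ$truth$n_events), 50)
})

test_that("world generation is byte-identical under one seed", {
  cfg <- tinyWorldConfig(9)
  w1 <- generateWorld(cfg)
  w2 <- generateWorld(cfg)
  expect_identical(w1@occurrences, w2@occurrences)
  expect_identical(w1@cells, w2@cells)
  expect_identical(mwEdges(w1@metaweb), mwEdges(w2@metaweb))
  # record fields honour the breeding-season window
  mo <- as.integer(substr(w1@occurrences$date, 6, 7))
  expect_true(all(mo >= 4 & mo <= 8))
  expect_true(all(w1@occurrences$year >= 2000 & w1@occurrences$year <= 2022))
})

test_that("worlds round-trip through the CSV writers", {
  w <- generateWorld(tinyWorldConfig(10))
  dir <- tempfile("world")
  writeWorld(w, dir)
  w2 <- readWorld(dir)
  expect_equal(mwEdges(w2@metaweb), mwEdges(w@metaweb))
  expect_equal(nrow(w2@occurrences), nrow(w@occurrences))
  expect_equal(w2@cells$cell_id, w@cells$cell_id)
  unlink(dir, recursive = TRUE)
})
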