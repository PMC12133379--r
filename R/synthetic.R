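#' @include AllClasses.R utils.R
NULL

# Occupancy-level mechanisms available for injecting protection effects.
# Each maps a metric name to a species-weight profile on the occupancy-logit
# scale: "uniform" lifts every species equally (richness-type effects),
# "top" lifts large, high-niche species (top-body-mass effects), "mid" lifts
# mid-niche species (intermediate-guild effects), and "tilt" trades small
# species for large ones with near-zero net richness change, so
# composition-driven metrics (food-chain length, trophic level) shift
# without riding on a richness change.
.EFFECT_PROFILES <- c(
  species_richness = "uniform",
  mfcl             = "tilt",
  mean_trophic_level = "tilt",
  bm_top           = "top",
  n_intermediate   = "mid",
  bm_intermediate  = "mid"
)

.LAND_COVER_CLASSES <- c("artificial", "agricultural", "forest_seminatural",
                         "wetlands", "water")

#' Configuration of a synthetic study system
#'
#' Bundles all knobs of the synthetic-data generator: the metaweb (species
#' pool size and target connectance), the landscape grid of 10 x 10 km cells,
#' protected-area number, size and placement bias towards high elevation,
#' survey effort (mean events per cell and overdispersion), and the
#' protection effects to inject, each given as an overall effect
#' \code{beta} on the occupancy-logit scale, a between-network standard
#' deviation \code{sd}, and optionally \code{elevation_mod}, a per-standard-
#' deviation-of-network-elevation modulation of the effect.
#'
#' @param n_species number of species in the metaweb.
#' @param metaweb_connectance target connectance (links / species^2), in
#'   (0, 1).
#' @param grid_dims integer c(rows, cols) of the 10 x 10 km grid.
#' @param n_pa number of protected areas to place.
#' @param pa_mean_radius_cells mean PA radius in cell widths (10 km units).
#' @param n_regions number of contiguous biogeographical regions.
#' @param effort_dispersion negative-binomial size parameter of per-cell
#'   survey-event counts (smaller = more overdispersed).
#' @param mean_events_per_cell mean number of survey events per cell.
#' @param protection_effects named list; names must be metrics with an
#'   occupancy-level mechanism (\code{species_richness}, \code{mfcl},
#'   \code{mean_trophic_level}, \code{bm_top}, \code{n_intermediate},
#'   \code{bm_intermediate}); each element a list with \code{beta},
#'   \code{sd} and optional \code{elevation_mod}.
#' @param placement_bias strength of PA preference for high-elevation cells
#'   (log-linear in the elevation z-score; 0 = unbiased).
#' @param seed integer seed; all generators derive named substreams from it.
#' @param metaweb_seed optional separate seed for the metaweb, so one fixed
#'   interaction pool (as in a real continental metaweb) can be reused
#'   across replicate worlds; defaults to \code{seed}.
#' @return a validated list of class \code{pawebs_config}.
#' @examples
#' cfg <- syntheticConfig(n_species = 40, grid_dims = c(12, 12), seed = 7)
#' @export
syntheticConfig <- function(n_species = 70,
                            metaweb_connectance = 0.08,
                            grid_dims = c(64L, 64L),
                            n_pa = 160,
                            pa_mean_radius_cells = 2.2,
                            n_regions = 6,
                            effort_dispersion = 2,
                            mean_events_per_cell = 150,
                            protection_effects = list(
                              species_richness = list(beta = 0.25, sd = 0.10),
                              bm_top = list(beta = 0.30, sd = 0.15)
                            ),
                            placement_bias = 1,
                            seed = 1L,
                            metaweb_seed = NULL) {
  cfg <- list(
    n_species = as.integer(n_species),
    metaweb_connectance = metaweb_connectance,
    grid_dims = as.integer(grid_dims),
    n_pa = as.integer(n_pa),
    pa_mean_radius_cells = pa_mean_radius_cells,
    n_regions = as.integer(n_regions),
    effort_dispersion = effort_dispersion,
    mean_events_per_cell = mean_events_per_cell,
    protection_effects = protection_effects,
    placement_bias = placement_bias,
    seed = as.integer(seed),
    metaweb_seed = if (is.null(metaweb_seed)) NULL else
      as.integer(metaweb_seed)
  )
  stopifnot(
    cfg$n_species >= 1, cfg$n_pa >= 1, cfg$n_regions >= 1,
    length(cfg$grid_dims) == 2L, all(cfg$grid_dims >= 1L),
    cfg$pa_mean_radius_cells > 0, cfg$effort_dispersion > 0,
    cfg$mean_events_per_cell > 0
  )
  if (!(cfg$metaweb_connectance > 0 && cfg$metaweb_connectance < 1))
    stop("metaweb_connectance must lie in (0, 1)")
  if (length(cfg$protection_effects)) {
    bad <- setdiff(names(cfg$protection_effects), names(.EFFECT_PROFILES))
    if (length(bad))
      stop("no occupancy-level mechanism for protection effect(s): ",
           paste(bad, collapse = ", "))
    for (e in cfg$protection_effects)
      stopifnot(is.numeric(e$beta), is.numeric(e$sd), e$sd >= 0)
  }
  class(cfg) <- "pawebs_config"
  cfg
}

#' Generate a niche-model metaweb
#'
#' Draws a directed consumer-to-resource web from the niche model: each
#' species gets a niche value in \code{[0, 1]} and consumes every species
#' whose niche value falls in a contiguous diet interval centred below its
#' own value. Self-loops are removed. Body masses are log-normal and increase
#' in expectation with niche value, so larger species sit higher in the web.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return a \linkS4class{Metaweb}.
#' @examples
#' mw <- generateMetaweb(syntheticConfig(n_species = 50, seed = 3))
#' nLinks(mw) / nSpecies(mw)^2   # close to the configured connectance
#' @export
generateMetaweb <- function(cfg) {
  stopifnot(inherits(cfg, "pawebs_config"))
  mwseed <- if (is.null(cfg$metaweb_seed)) cfg$seed else cfg$metaweb_seed
  .withSeed(substreamSeed(mwseed, "metaweb"), {
    n <- cfg$n_species
    C <- cfg$metaweb_connectance
    eta <- sort(runif(n))
    # beta-distributed diet breadth calibrated so E[links] = C * n^2
    bshape <- 1 / (2 * C) - 1
    breadth <- eta * rbeta(n, 1, max(bshape, 1e-8))
    centre <- runif(n, breadth / 2, pmax(eta, breadth / 2))
    ids <- sprintf("sp%03d", seq_len(n))
    cons <- integer(0); res <- integer(0)
    for (i in seq_len(n)) {
      prey <- which(eta >= centre[i] - breadth[i] / 2 &
                    eta <= centre[i] + breadth[i] / 2 &
                    seq_len(n) != i)
      if (length(prey)) {
        cons <- c(cons, rep.int(i, length(prey)))
        res <- c(res, prey)
      }
    }
    body_mass <- exp(log(15) + 4 * eta + rnorm(n, 0, 0.6))
    methods::new("Metaweb",
      species = data.frame(species_id = ids, body_mass_g = body_mass,
                           niche_value = eta, stringsAsFactors = FALSE),
      edges = data.frame(consumer = ids[cons], resource = ids[res],
                         stringsAsFactors = FALSE))
  })
}

#' Generate a landscape of grid-cell attributes
#'
#' One row per 10 x 10 km cell with smooth spatial elevation, slope and
#' remoteness fields plus noise, a human-density field declining with
#' elevation, one of the five top-level CORINE land-cover classes, and a
#' region label partitioning the grid into contiguous axis-aligned blocks.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return data.frame with columns cell_id, row, col, x, y (km), region,
#'   elevation (m), slope (degrees), remoteness (minutes travel time),
#'   human_density (persons / km^2), land_cover.
#' @export
generateLandscape <- function(cfg) {
  stopifnot(inherits(cfg, "pawebs_config"))
  .withSeed(substreamSeed(cfg$seed, "landscape"), {
    nr <- cfg$grid_dims[1]; nc <- cfg$grid_dims[2]
    g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
    x <- (g$col - 0.5) * 10; y <- (g$row - 0.5) * 10
    u <- g$col / nc; v <- g$row / nr
    n <- nrow(g)
    bump <- exp(-((u - 0.72)^2 + (v - 0.66)^2) / (2 * 0.18^2))
    wave <- sin(2.2 * pi * u + 0.6) * cos(1.7 * pi * v + 0.3)
    elev_smooth <- 350 + 650 * bump + 220 * wave
    elevation <- pmax(0, elev_smooth + rnorm(n, 0, 35))
    # slope from the smooth field's finite-difference gradient (m per cell);
    # expand.grid orders rows fastest, matching matrix(elev_smooth, nr, nc)
    em <- matrix(elev_smooth, nr, nc)
    central <- function(m, dim) {
      d <- matrix(0, nrow(m), ncol(m))
      if (dim == 2L && ncol(m) >= 2) {
        d[, 1] <- m[, 2] - m[, 1]
        d[, ncol(m)] <- m[, ncol(m)] - m[, ncol(m) - 1]
        if (ncol(m) >= 3) {
          j <- 2:(ncol(m) - 1)
          d[, j] <- (m[, j + 1] - m[, j - 1]) / 2
        }
      } else if (dim == 1L && nrow(m) >= 2) {
        d[1, ] <- m[2, ] - m[1, ]
        d[nrow(m), ] <- m[nrow(m), ] - m[nrow(m) - 1, ]
        if (nrow(m) >= 3) {
          i <- 2:(nrow(m) - 1)
          d[i, ] <- (m[i + 1, ] - m[i - 1, ]) / 2
        }
      }
      d
    }
    gradmag <- as.vector(sqrt(central(em, 1L)^2 + central(em, 2L)^2))
    slope <- pmax(0, 0.02 * gradmag + rnorm(n, 0, 0.4))
    remoteness <- pmax(5, 30 + 0.15 * elevation + rnorm(n, 0, 20))
    human_density <- exp(4.2 - 0.004 * elevation -
                           0.005 * (remoteness - 30) + rnorm(n, 0, 0.5))
    lc_logits <- cbind(
      artificial         = -2.6 + 0.9 * .zscore(log1p(human_density)),
      agricultural       = 1.0 - 0.0035 * elevation + 0.3 * .zscore(log1p(human_density)),
      forest_seminatural = 0.6 + 0.0012 * elevation,
      wetlands           = -1.8 - 0.004 * elevation,
      water              = -2.4
    )
    p <- exp(lc_logits); p <- p / rowSums(p)
    land_cover <- vapply(seq_len(n), function(i)
      sample(.LAND_COVER_CLASSES, 1, prob = p[i, ]), character(1))
    region <- sprintf("R%d", 1L + floor((g$col - 1L) * cfg$n_regions / nc))
    data.frame(
      cell_id = sprintf("c%03d_%03d", g$row, g$col),
      row = g$row, col = g$col, x = x, y = y, region = region,
      elevation = elevation, slope = slope, remoteness = remoteness,
      human_density = human_density, land_cover = land_cover,
      stringsAsFactors = FALSE)
  })
}

#' Generate protected areas over a landscape
#'
#' Places \code{n_pa} disc-shaped protected areas with centre-placement
#' probability increasing log-linearly with cell elevation at rate
#' \code{placement_bias} (reproducing the documented bias of real reserves
#' towards high, remote terrain). A small fraction of PAs receives a
#' post-2015 designation year so the temporal filters are exercised.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param cells landscape from \code{\link{generateLandscape}}.
#' @return data.frame with pa_id, center_x, center_y, radius_km, area_km2,
#'   designation_year, protection_level (ordinal 1-10), bird_directive,
#'   region.
#' @export
generateProtectedAreas <- function(cfg, cells) {
  stopifnot(inherits(cfg, "pawebs_config"), is.data.frame(cells))
  .withSeed(substreamSeed(cfg$seed, "pas"), {
    w <- exp(cfg$placement_bias * .zscore(cells$elevation))
    idx <- sample.int(nrow(cells), cfg$n_pa, prob = w,
                      replace = cfg$n_pa > nrow(cells))
    radius <- rgamma(cfg$n_pa, shape = 6,
                     rate = 6 / (cfg$pa_mean_radius_cells * 10))
    late <- runif(cfg$n_pa) < 0.1
    year <- ifelse(late, sample(2016:2022, cfg$n_pa, replace = TRUE),
                   sample(1962:2012, cfg$n_pa, replace = TRUE))
    data.frame(
      pa_id = sprintf("pa%03d", seq_len(cfg$n_pa)),
      center_x = cells$x[idx], center_y = cells$y[idx],
      radius_km = radius, area_km2 = pi * radius^2,
      designation_year = as.integer(year),
      protection_level = sample(1:10, cfg$n_pa, replace = TRUE),
      bird_directive = runif(cfg$n_pa) < 0.4,
      region = cells$region[idx],
      stringsAsFactors = FALSE)
  })
}

#' Filter a protected-area table to the analysis grain
#'
#' Drops PAs smaller than the grain size of one grid cell (100 km^2) and PAs
#' designated after the temporal cutoff (too recent for protection to have
#' shaped the resident food webs).
#'
#' @param pas PA table.
#' @param min_area_km2 minimum area retained; default one 10 x 10 km cell.
#' @param max_year latest designation year retained.
#' @return the filtered PA table.
#' @export
filterPAs <- function(pas, min_area_km2 = 100, max_year = 2015) {
  pas[pas$area_km2 >= min_area_km2 & pas$designation_year <= max_year, ,
      drop = FALSE]
}

# Species-weight profile matrix (n_species x n_effects) for effect injection.
.effectWeights <- function(niche, effects) {
  vapply(names(effects), function(e) {
    switch(.EFFECT_PROFILES[[e]],
      uniform = rep(1, length(niche)),
      top = pmax(0, (niche - 0.55) / 0.45),
      mid = exp(-((niche - 0.5) / 0.18)^2),
      tilt = {
        # concentrated uplift of the top trophic tail, balanced by a diffuse
        # negative offset so net expected richness is unchanged; the diffuse
        # loss is too weak to strip whole basal levels, so chains lengthen
        # from the top rather than eroding from the bottom
        pos <- pmax(0, (niche - 0.6) / 0.4)
        pos - mean(pos)
      })
  }, numeric(length(niche)))
}

#' Generate occurrence records with injected protection effects
#'
#' Per cell, survey-event counts are drawn from an overdispersed negative
#' binomial around \code{mean_events_per_cell}. Each species has a baseline
#' occupancy and a per-event detection probability; protection shifts
#' occupancy on the logit scale, with per-network effect sizes drawn around
#' the configured overall effect (optionally modulated by network mean
#' elevation), so injected effects propagate through the same generative
#' chain the analysis assumes. Each record carries species, cell, a date in
#' April--August of 2000--2022, a time and a survey programme.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @param metaweb a \linkS4class{Metaweb}.
#' @param cells landscape table.
#' @param networks a \linkS4class{PANetworkSet} carrying each cell's
#'   protection status (cells absent from the membership receive no effect).
#' @return list with \code{occurrences} (record table) and \code{truth}
#'   (per-network injected effect sizes and species-level parameters).
#' @export
generateOccurrences <- function(cfg, metaweb, cells, networks) {
  stopifnot(inherits(cfg, "pawebs_config"), is(metaweb, "Metaweb"),
            is.data.frame(cells), is(networks, "PANetworkSet"))
  .withSeed(substreamSeed(cfg$seed, "occurrences"), {
    sp <- mwSpecies(metaweb)
    S <- nrow(sp); Z <- nrow(cells)
    n_events <- rnbinom(Z, size = cfg$effort_dispersion,
                        mu = cfg$mean_events_per_cell)
    logit0 <- rnorm(S, qlogis(0.30), 0.9)
    detect <- rbeta(S, 2, 6)

    mem <- cellMembership(networks)
    net_ids <- networkTable(networks)$network_id
    eff <- cfg$protection_effects
    delta <- NULL
    if (length(eff) && length(net_ids)) {
      pelev <- vapply(net_ids, function(nid) {
        pz <- mem$cell_id[mem$network_id == nid & mem$status == "protected"]
        mean(cells$elevation[match(pz, cells$cell_id)])
      }, numeric(1))
      zel <- .zscore(pelev)
      delta <- vapply(seq_along(eff), function(j) {
        e <- eff[[j]]
        mod <- if (is.null(e$elevation_mod)) 0 else e$elevation_mod
        e$beta + mod * zel + rnorm(length(net_ids), 0, e$sd)
      }, numeric(length(net_ids)))
      delta <- matrix(delta, nrow = length(net_ids),
                      dimnames = list(net_ids, names(eff)))
    }

    # occupancy logits: S x Z baseline, plus injected effects on protected cells
    L <- matrix(logit0, S, Z)
    if (!is.null(delta)) {
      W <- .effectWeights(sp$niche_value, eff)          # S x n_eff
      prot <- mem[mem$status == "protected", ]
      zi <- match(prot$cell_id, cells$cell_id)
      shift <- W %*% t(delta[prot$network_id, , drop = FALSE])  # S x n_prot
      L[, zi] <- L[, zi] + shift
    }
    present <- matrix(runif(S * Z) < plogis(L), S, Z)

    # detection counts per present (species, cell) pair
    k <- matrix(0L, S, Z)
    pres_idx <- which(present, arr.ind = TRUE)
    if (nrow(pres_idx)) {
      k[pres_idx] <- rbinom(nrow(pres_idx),
                            size = n_events[pres_idx[, 2]],
                            prob = detect[pres_idx[, 1]])
    }

    # survey-event attributes, one block per cell
    tot <- sum(n_events)
    years <- sample(2000:2022, tot, replace = TRUE)
    months <- sample(4:8, tot, replace = TRUE)
    days <- sample(1:28, tot, replace = TRUE)
    times <- sprintf("%02d:%02d", sample(4:20, tot, replace = TRUE),
                     sample(0:59, tot, replace = TRUE))
    programme <- sample(c("eBird", "iNaturalist", "observation.org"), tot,
                        replace = TRUE, prob = c(0.5, 0.3, 0.2))
    offset <- c(0L, cumsum(n_events))[seq_len(Z)]

    hit <- which(k > 0, arr.ind = TRUE)
    if (nrow(hit)) {
      kk <- k[hit]
      ev_local <- unlist(lapply(seq_len(nrow(hit)), function(r)
        sample.int(n_events[hit[r, 2]], kk[r])), use.names = FALSE)
      ev_global <- rep(offset[hit[, 2]], kk) + ev_local
      occ <- data.frame(
        species_id = sp$species_id[rep(hit[, 1], kk)],
        cell_id = cells$cell_id[rep(hit[, 2], kk)],
        date = sprintf("%04d-%02d-%02d", years[ev_global], months[ev_global],
                       days[ev_global]),
        year = years[ev_global],
        time = times[ev_global],
        programme = programme[ev_global],
        stringsAsFactors = FALSE)
    } else {
      occ <- data.frame(species_id = character(), cell_id = character(),
                        date = character(), year = integer(),
                        time = character(), programme = character(),
                        stringsAsFactors = FALSE)
    }
    list(occurrences = occ,
         truth = list(network_effects = delta, baseline_logit = logit0,
                      detection = detect, n_events = n_events))
  })
}

#' Generate a complete synthetic study system
#'
#' Chains metaweb, landscape and protected-area generation, assigns
#' protection status and groups PA networks (centre rule), and generates
#' occurrence records with the configured injected effects. The returned
#' world holds the raw input tables exactly as the analysis pipeline consumes
#' them; status assignment and grouping are re-derived downstream from the
#' raw tables.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return a \linkS4class{SyntheticWorld}.
#' @examples
#' w <- generateWorld(syntheticConfig(n_species = 40, grid_dims = c(10, 10),
#'                                    n_pa = 4, mean_events_per_cell = 20,
#'                                    seed = 11))
#' w
#' @export
generateWorld <- function(cfg) {
  stopifnot(inherits(cfg, "pawebs_config"))
  mw <- generateMetaweb(cfg)
  cells <- generateLandscape(cfg)
  pas_all <- generateProtectedAreas(cfg, cells)
  pas <- filterPAs(pas_all)
  if (!nrow(pas)) stop("no protected areas survive the area/year filters")
  status <- assignProtectionStatus(cells, pas, coverageRule("center"),
                                   seed = cfg$seed)
  nets <- groupPANetworks(pas, status)
  nets <- attachBuffer(nets, status)
  res <- generateOccurrences(cfg, mw, cells, nets)
  methods::new("SyntheticWorld", metaweb = mw, cells = cells, pas = pas_all,
               occurrences = res$occurrences,
               truth = c(res$truth, list(networks = nets)),
               config = unclass(cfg))
}

#' Write / read a synthetic world as plain CSV tables
#'
#' Writers for the five input tables consumed by the pipeline: metaweb edge
#' list (consumer, resource), species traits, grid cells, PA attributes with
#' disc geometry (center_x, center_y, radius_km), and occurrence records.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param dir output directory (created if missing).
#' @return \code{writeWorld}: the directory, invisibly. \code{readWorld}: a
#'   \linkS4class{SyntheticWorld} with empty truth/config.
#' @export
writeWorld <- function(world, dir) {
  stopifnot(is(world, "SyntheticWorld"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(mwEdges(world@metaweb), file.path(dir, "metaweb_edges.csv"),
            row.names = FALSE)
  write.csv(mwSpecies(world@metaweb), file.path(dir, "species_traits.csv"),
            row.names = FALSE)
  write.csv(world@cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(world@pas, file.path(dir, "pas.csv"), row.names = FALSE)
  write.csv(world@occurrences, file.path(dir, "occurrences.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' @rdname writeWorld
#' @export
readWorld <- function(dir) {
  mw <- methods::new("Metaweb",
    species = read.csv(file.path(dir, "species_traits.csv"),
                       stringsAsFactors = FALSE),
    edges = read.csv(file.path(dir, "metaweb_edges.csv"),
                     stringsAsFactors = FALSE))
  methods::new("SyntheticWorld", metaweb = mw,
    cells = read.csv(file.path(dir, "cells.csv"), stringsAsFactors = FALSE),
    pas = read.csv(file.path(dir, "pas.csv"), stringsAsFactors = FALSE),
    occurrences = read.csv(file.path(dir, "occurrences.csv"),
                           stringsAsFactors = FALSE),
    truth = list(), config = list())
}
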