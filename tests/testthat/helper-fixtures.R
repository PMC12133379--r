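# Shared fixture builders for the table-level tests.

# A 4-species metaweb used by the induced-subgraph examples.
fixtureMetaweb <- function() {
  methods::new("Metaweb",
    species = data.frame(species_id = c("A", "B", "C", "D"),
                         body_mass_g = c(10, 100, 1000, 50),
                         niche_value = c(0.1, 0.4, 0.9, 0.3),
                         stringsAsFactors = FALSE),
    edges = data.frame(consumer = c("B", "C", "C", "D"),
                       resource = c("A", "B", "A", "C"),
                       stringsAsFactors = FALSE))
}

# Occurrence rows with a full survey-event key.
occRows <- function(species, cell, date = "2016-05-01", time = "06:00",
                    programme = "eBird", year = 2016L) {
  n <- max(length(species), length(cell) * (length(species) > 0))
  data.frame(species_id = rep_len(species, n), cell_id = rep_len(cell, n),
             date = rep_len(date, n), year = rep_len(year, n),
             time = rep_len(time, n), programme = rep_len(programme, n),
             stringsAsFactors = FALSE)
}

# Event/record tables with given per-cell event counts, one species pool.
fixtureSurveys <- function(counts, n_species = 12, records_per_event = 3,
                           seed = 1) {
  set.seed(seed)
  sp <- sprintf("sp%02d", seq_len(n_species))
  occ <- do.call(rbind, lapply(names(counts), function(cz) {
    do.call(rbind, lapply(seq_len(counts[[cz]]), function(e) {
      occRows(sample(sp, records_per_event, replace = TRUE), cz,
              date = sprintf("2016-05-%02d", 1 + e %% 28),
              time = sprintf("%02d:%02d", e %% 24, e %% 60))
    }))
  }))
  buildSurveyEvents(occ)
}

# Hand-built PANetworkSet from a membership table.
fixtureNetworkSet <- function(membership, regions = NULL, youngest = NULL) {
  ids <- unique(membership$network_id)
  networks <- data.frame(
    network_id = ids,
    region = if (is.null(regions)) "R1" else regions[ids],
    youngest_designation_year =
      if (is.null(youngest)) 2000L else youngest[ids],
    member_pa_ids = "pa1",
    n_protected = 0L, n_nonprotected = 0L,
    sampled_cell_ratio = NA_real_, stringsAsFactors = FALSE)
  methods::new("PANetworkSet", membership = membership, networks = networks)
}

# A small CellMetrics object with simulated metric values.
fixtureCellMetrics <- function(n_networks = 3, cells_per_network = 30,
                               seed = 1) {
  set.seed(seed)
  n <- n_networks * cells_per_network
  net <- rep(sprintf("net%02d", seq_len(n_networks)),
             each = cells_per_network)
  prot <- rep(rep(c(TRUE, FALSE), each = cells_per_network / 2), n_networks)
  cid <- sprintf("c%03d", seq_len(n))
  rich <- rpois(n, 20) + 2
  mat <- rbind(species_richness = rich,
               mfcl = 1.5 + 0.3 * prot + rnorm(n, 0, 0.3),
               connectance = plogis(rnorm(n, -2, 0.3)))
  colnames(mat) <- cid
  cd <- S4Vectors::DataFrame(
    cell_id = cid, network_id = net, protected = prot,
    effort = exp(runif(n, log(50), log(400))),
    elevation = rnorm(n, 500, 150), remoteness = rnorm(n, 60, 15),
    land_cover = sample(c("agricultural", "forest_seminatural", "artificial"),
                        n, replace = TRUE),
    row.names = cid)
  methods::new("CellMetrics", SummarizedExperiment::SummarizedExperiment(
    assays = list(metrics = mat), colData = cd))
}

# Gaussian stage-1 simulation design (networks x cells, sinusoidal effort
# nuisance, random intercepts and protection slopes).
simStage1Design <- function(seed, beta = 0.5, slope_sd = 0.2,
                            n_networks = 40, cells = 50,
                            intercept_sd = 0.3, resid_sd = 0.5) {
  set.seed(seed)
  net <- factor(rep(sprintf("n%02d", seq_len(n_networks)), each = cells))
  prot <- rep(rep(0:1, each = cells / 2), n_networks)
  eff <- exp(runif(n_networks * cells, log(50), log(500)))
  u <- rnorm(n_networks, 0, slope_sd)
  b <- rnorm(n_networks, 0, intercept_sd)
  y <- 2 + (beta + u[as.integer(net)]) * prot + b[as.integer(net)] +
    0.5 * sin(eff / 500 * 2 * pi) + rnorm(n_networks * cells, 0, resid_sd)
  structure(
    data.frame(y = y, prot_num = prot, effort = eff, richness = NA_real_,
               network = net, elevation = 0, remoteness = 0,
               land_cover = factor("x")),
    true_beta = beta, true_slopes = beta + u)
}

# Compact synthetic-world configuration for pipeline-level tests.
tinyWorldConfig <- function(seed, ...) {
  syntheticConfig(n_species = 45, metaweb_connectance = 0.1,
                  grid_dims = c(26, 26), n_pa = 24,
                  pa_mean_radius_cells = 1.6, n_regions = 2,
                  effort_dispersion = 3, mean_events_per_cell = 45,
                  placement_bias = 1, seed = seed, ...)
}

tinyRunConfig <- function(seed, metrics = c("species_richness", "mfcl"),
                          ...) {
  runConfig(synthetic = tinyWorldConfig(seed), seed = seed,
            effort_floor = 20, min_cells = 6, min_ratio = 0.10,
            metrics = metrics, engine = "bam", ...)
}
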