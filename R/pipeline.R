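#' @include AllClasses.R synthetic.R occurrences.R protected_areas.R
#' @include foodwebs.R effects_model.R drivers.R
NULL

#' Configuration of a full pipeline run
#'
#' Exactly one of \code{synthetic} (a \code{\link{syntheticConfig}}) or
#' \code{input_dir} (a directory of CSV tables as written by
#' \code{\link{writeWorld}}) must be given. The global seed propagates to
#' every stochastic stage through named substreams.
#'
#' @param synthetic a \code{\link{syntheticConfig}}, or NULL.
#' @param input_dir directory with input CSVs, or NULL.
#' @param seed global integer seed.
#' @param outdir optional output directory for intermediate tables.
#' @param coverage a \code{\link{coverageRule}}.
#' @param grouping_distance_km PA grouping distance (boundaries closer than
#'   this are one network).
#' @param buffer_radius_km buffer of comparison cells around each network.
#' @param effort_floor minimum survey events per analyzed cell.
#' @param min_cells,min_ratio network inclusion thresholds (protected and
#'   non-protected retained cells; sampled-cell ratio).
#' @param metrics metric names to compute.
#' @param stage2_metrics metrics taken to stage 2; default same as
#'   \code{metrics}.
#' @param stage2_candidates driver columns for stage 2 (NULL = all usable).
#' @param family_overrides optional stage-1 family overrides.
#' @param env_slopes include elevation/remoteness random slopes in stage 1.
#' @param engine stage-1 fitting engine, \code{"gam"} or \code{"bam"}.
#' @return list of class \code{pawebs_run_config}.
#' @export
runConfig <- function(synthetic = syntheticConfig(), input_dir = NULL,
                      seed = 1L, outdir = NULL,
                      coverage = coverageRule("center"),
                      grouping_distance_km = 1, buffer_radius_km = 100,
                      effort_floor = 50, min_cells = 15, min_ratio = 0.10,
                      metrics = METRIC_NAMES, stage2_metrics = NULL,
                      stage2_candidates = NULL, family_overrides = NULL,
                      env_slopes = TRUE, engine = "gam") {
  if (is.null(synthetic) == is.null(input_dir))
    stop("give exactly one of 'synthetic' or 'input_dir'")
  stopifnot(inherits(coverage, "pawebs_coverage_rule"),
            all(metrics %in% METRIC_NAMES))
  structure(list(
    synthetic = synthetic, input_dir = input_dir, seed = as.integer(seed),
    outdir = outdir, coverage = coverage,
    grouping_distance_km = grouping_distance_km,
    buffer_radius_km = buffer_radius_km, effort_floor = effort_floor,
    min_cells = min_cells, min_ratio = min_ratio, metrics = metrics,
    stage2_metrics = stage2_metrics %||% metrics,
    stage2_candidates = stage2_candidates,
    family_overrides = family_overrides, env_slopes = env_slopes,
    engine = engine
  ), class = "pawebs_run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{runConfig}};
#' \code{synthetic} and \code{coverage} are nested maps passed to
#' \code{\link{syntheticConfig}} and \code{\link{coverageRule}}.
#'
#' @param path YAML file path.
#' @return a \code{\link{runConfig}}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) {
    if (!is.null(y$synthetic$grid_dims))
      y$synthetic$grid_dims <- unlist(y$synthetic$grid_dims)
    y$synthetic <- do.call(syntheticConfig, y$synthetic)
  }
  if (!is.null(y$coverage)) y$coverage <- do.call(coverageRule, y$coverage)
  do.call(runConfig, y)
}

.stage <- function(manifest, name, rows_in, rows_out, t0, seed) {
  rbind(manifest, data.frame(
    stage = name, rows_in = rows_in, rows_out = rows_out,
    seed = seed, wall_time_s = round(as.numeric(Sys.time()) - t0, 3),
    stringsAsFactors = FALSE))
}

.writeTab <- function(x, outdir, name, hash) {
  if (is.null(outdir)) return(invisible())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  attrline <- sprintf("# pawebs config_hash=%s", hash)
  path <- file.path(outdir, paste0(name, ".csv"))
  con <- file(path, "w")
  writeLines(attrline, con)
  write.csv(x, con, row.names = FALSE)
  close(con)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order: data generation or ingest, protection
#' status assignment, PA-network grouping with buffers, temporal and
#' survey-effort filters with network inclusion, within-network rarefaction,
#' local web construction, metric computation, the stage-1 protection-effect
#' models and the stage-2 driver regressions. All intermediate tables are
#' written to \code{outdir} (if given) stamped with the configuration hash,
#' and a manifest records rows in/out, the seed and wall time per stage.
#' Any stage failure aborts with a condition carrying the stage name.
#' Runs are idempotent under a fixed seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @return list with \code{manifest}, \code{config_hash}, \code{world},
#'   \code{status}, \code{networks}, \code{rarefaction}, \code{metrics}
#'   (a \linkS4class{CellMetrics}), \code{stage1}, \code{stage2}.
#' @examples
#' \donttest{
#' cfg <- runConfig(synthetic = syntheticConfig(grid_dims = c(14, 14),
#'                    n_species = 40, n_pa = 6, seed = 2),
#'                  effort_floor = 20, min_cells = 5,
#'                  metrics = c("species_richness", "n_links"))
#' run <- runPipeline(cfg)
#' run$manifest
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pawebs_run_config"))
  hash <- .configHash(unclass(config))
  manifest <- NULL
  seed <- config$seed
  fail <- function(stage, e) {
    stop(structure(class = c("pawebs_stage_error", "error", "condition"),
                   list(message = sprintf("pipeline stage '%s' failed: %s",
                                          stage, conditionMessage(e)),
                        call = NULL, stage = stage, parent = e)))
  }
  run_stage <- function(name, rows_in, expr) {
    t0 <- as.numeric(Sys.time())
    out <- tryCatch(force(expr), error = function(e) fail(name, e))
    manifest <<- .stage(manifest, name, rows_in, attr(out, "rows") %||%
                          (if (is.data.frame(out)) nrow(out) else NA_integer_),
                        t0, seed)
    out
  }

  # 1. ingest -----------------------------------------------------------
  world <- run_stage("ingest", 0L, {
    w <- if (!is.null(config$synthetic)) {
      cfg <- config$synthetic; cfg$seed <- seed
      generateWorld(cfg)
    } else readWorld(config$input_dir)
    structure(w, rows = nrow(w@occurrences))
  })
  cells <- world@cells
  pas <- filterPAs(world@pas)
  .writeTab(cells, config$outdir, "cells", hash)
  .writeTab(world@occurrences, config$outdir, "occurrences_raw", hash)

  # 2. protection status -------------------------------------------------
  status <- run_stage("status", nrow(cells),
    assignProtectionStatus(cells, pas, config$coverage, seed = seed))
  .writeTab(status, config$outdir, "status", hash)

  # 3. networks: grouping + buffers --------------------------------------
  networks <- run_stage("networks", nrow(pas), {
    nw <- groupPANetworks(pas, status, config$grouping_distance_km)
    nw <- attachBuffer(nw, status, config$buffer_radius_km)
    structure(nw, rows = nrow(cellMembership(nw)))
  })

  # 4. temporal + effort filters + network inclusion ----------------------
  filt <- run_stage("filters", nrow(world@occurrences), {
    occ <- temporalFilter(networks, world@occurrences)
    surveys <- buildSurveyEvents(occ)
    retained <- filterCellsByEffort(surveys$events, config$effort_floor)
    nets <- networkInclusionFilter(networks, retained, config$min_cells,
                                   config$min_ratio)
    mem <- cellMembership(nets)
    keep_cells <- intersect(retained, mem$cell_id)
    structure(list(surveys = surveys, networks = nets,
                   retained = keep_cells), rows = length(keep_cells))
  })
  networks <- filt$networks
  .writeTab(cellMembership(networks), config$outdir, "network_membership", hash)
  .writeTab(networkTable(networks), config$outdir, "network_summary", hash)

  # 5. rarefaction --------------------------------------------------------
  raref <- run_stage("rarefaction", nrow(filt$surveys$records), {
    mem <- cellMembership(networks)
    mem <- mem[mem$cell_id %in% filt$retained, , drop = FALSE]
    ev <- filt$surveys$events
    ev <- ev[ev$cell_id %in% filt$retained, , drop = FALSE]
    plan <- rarefactionPlan(ev, mem, seed = seed)
    rr <- rarefyNetwork(list(events = ev,
                             records = filt$surveys$records), plan)
    structure(rr, rows = nrow(rr$records))
  })
  .writeTab(raref$report, config$outdir, "rarefaction_report", hash)

  # 6. local web construction --------------------------------------------
  webs <- run_stage("webs", nrow(raref$records), {
    sp_by_cell <- lapply(split(raref$records$species_id,
                               raref$records$cell_id), unique)
    structure(sp_by_cell, rows = length(sp_by_cell))
  })

  # 7. metrics ------------------------------------------------------------
  eff_tab <- table(filt$surveys$events$cell_id)
  effort <- setNames(as.numeric(eff_tab), names(eff_tab))
  metricsSE <- run_stage("metrics", length(webs), {
    cmx <- computeCellMetrics(raref$records, world@metaweb, cells, networks,
                              effort, seed = seed, metrics = config$metrics)
    structure(cmx, rows = ncol(cmx))
  })
  .writeTab(cbind(cell_id = colnames(metricsSE),
                  as.data.frame(t(SummarizedExperiment::assay(metricsSE)))),
            config$outdir, "metrics", hash)

  # 8. stage 1 ------------------------------------------------------------
  stage1 <- run_stage("stage1", ncol(metricsSE), {
    s1m <- intersect(config$metrics, rownames(metricsSE))
    structure(fitStage1(metricsSE, s1m, config$family_overrides,
                        env_slopes = config$env_slopes,
                        engine = config$engine), rows = length(s1m))
  })
  .writeTab(stage1Summary(stage1), config$outdir, "stage1_summary", hash)
  .writeTab(stage1NetworkTable(stage1), config$outdir, "stage1_networks", hash)

  # 9. stage 2 ------------------------------------------------------------
  stage2 <- run_stage("stage2", length(stage1), {
    drivers <- computeDrivers(networks, cells, pas)
    s2 <- lapply(intersect(config$stage2_metrics, names(stage1)), function(mt) {
      stepwiseBIC(stage1[[mt]]@network_effects, drivers,
                  candidates = config$stage2_candidates, metric = mt)
    })
    names(s2) <- intersect(config$stage2_metrics, names(stage1))
    structure(list(results = s2, drivers = drivers), rows = length(s2))
  })
  if (length(stage2$results)) {
    s2s <- stage2Summary(stage2$results)
    .writeTab(s2s$coefficients, config$outdir, "stage2_coefficients", hash)
    .writeTab(s2s$models, config$outdir, "stage2_models", hash)
  }
  .writeTab(manifest, config$outdir, "manifest", hash)

  list(manifest = manifest, config_hash = hash, world = world,
       status = status, networks = networks, rarefaction = raref,
       metrics = metricsSE, stage1 = stage1, stage2 = stage2$results,
       drivers = stage2$drivers)
}

#' Pearson correlations between per-network protection effects
#'
#' Convenience report: correlates chosen pairs of metrics' per-network
#' effects across PA networks. Refuses to run with fewer than three
#' networks.
#'
#' @param stage1 named list of \linkS4class{Stage1Result}.
#' @param pairs list of length-2 character vectors of metric names; default
#'   all pairs of the fitted metrics.
#' @return data.frame (metric_a, metric_b, r, p, n).
#' @export
correlationReport <- function(stage1, pairs = NULL) {
  if (is.null(pairs))
    pairs <- utils::combn(names(stage1), 2, simplify = FALSE)
  n <- nrow(stage1[[1]]@network_effects)
  if (n < 3) stop("correlationReport needs at least 3 networks")
  do.call(rbind, lapply(pairs, function(p) {
    a <- stage1[[p[1]]]@network_effects
    b <- stage1[[p[2]]]@network_effects
    m <- merge(a[, c("network_id", "beta_i")],
               b[, c("network_id", "beta_i")], by = "network_id")
    ct <- cor.test(m$beta_i.x, m$beta_i.y)
    data.frame(metric_a = p[1], metric_b = p[2],
               r = unname(ct$estimate), p = ct$p.value, n = nrow(m),
               stringsAsFactors = FALSE)
  }))
}
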