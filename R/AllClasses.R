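#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' The canonical food-web metric names
#'
#' The sixteen per-cell metrics: thirteen structural metrics plus three
#' role-specific mean body masses (grams).
#'
#' @export
METRIC_NAMES <- c(
  "modularity", "mfcl", "mean_trophic_level", "fraction_omnivory",
  "mean_generality", "mean_vulnerability",
  "species_richness", "n_links", "connectance", "linkage_density",
  "n_basal", "n_intermediate", "n_top",
  "bm_basal", "bm_intermediate", "bm_top"
)

#' Metaweb: a continental species pool with trophic links
#'
#' Holds the species trait table (body mass in grams, a niche value in
#' \code{[0, 1]}) and the directed consumer-to-resource edge list. Local food
#' webs are induced subgraphs of this object.
#'
#' @slot species data.frame with columns \code{species_id},
#'   \code{body_mass_g}, \code{niche_value}.
#' @slot edges data.frame with columns \code{consumer}, \code{resource}.
#' @export
setClass("Metaweb", slots = c(species = "data.frame", edges = "data.frame"))

setValidity("Metaweb", function(object) {
  sp <- object@species; ed <- object@edges
  msg <- character()
  need <- c("species_id", "body_mass_g", "niche_value")
  if (!all(need %in% names(sp)))
    msg <- c(msg, paste("species table needs columns:", paste(need, collapse = ", ")))
  if (!all(c("consumer", "resource") %in% names(ed)))
    msg <- c(msg, "edge table needs columns consumer, resource")
  if (!length(msg)) {
    if (anyDuplicated(sp$species_id))
      msg <- c(msg, "duplicated species_id")
    if (any(sp$body_mass_g <= 0, na.rm = TRUE))
      msg <- c(msg, "body_mass_g must be positive")
    if (nrow(ed)) {
      if (!all(ed$consumer %in% sp$species_id) ||
          !all(ed$resource %in% sp$species_id))
        msg <- c(msg, "edge endpoints must be listed species")
      if (any(ed$consumer == ed$resource))
        msg <- c(msg, "self-loops are not allowed")
      if (anyDuplicated(paste(ed$consumer, ed$resource, sep = "\r")))
        msg <- c(msg, "duplicated edges")
    }
  }
  if (length(msg)) msg else TRUE
})

#' LocalFoodWeb: the induced food web of one grid cell
#'
#' @slot cell_id character scalar.
#' @slot species character vector of species present.
#' @slot edges data.frame (\code{consumer}, \code{resource}) restricted to
#'   \code{species}.
#' @slot roles named character vector, one of \code{"basal"},
#'   \code{"intermediate"}, \code{"top"} per species.
#' @export
setClass("LocalFoodWeb", slots = c(
  cell_id = "character", species = "character",
  edges = "data.frame", roles = "character"
))

setValidity("LocalFoodWeb", function(object) {
  msg <- character()
  if (length(object@cell_id) != 1L) msg <- c(msg, "cell_id must be scalar")
  ed <- object@edges
  if (nrow(ed) &&
      (!all(ed$consumer %in% object@species) ||
       !all(ed$resource %in% object@species)))
    msg <- c(msg, "edges must connect present species")
  if (length(object@roles)) {
    if (!setequal(names(object@roles), object@species))
      msg <- c(msg, "roles must cover exactly the present species")
    if (!all(object@roles %in% c("basal", "intermediate", "top")))
      msg <- c(msg, "invalid role label")
  }
  if (length(msg)) msg else TRUE
})

#' CellMetrics: per-cell food-web metrics with cell covariates
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"metrics"}
#' holds the metric-by-cell matrix (rows are metrics from
#' \code{\link{METRIC_NAMES}}, columns are grid cells) and whose
#' \code{colData} carries the per-cell covariates used by the stage-1 model
#' (protection status, network id, survey effort before rarefaction,
#' elevation, remoteness, land cover).
#'
#' @export
setClass("CellMetrics", contains = "SummarizedExperiment")

setValidity("CellMetrics", function(object) {
  msg <- character()
  if (!"metrics" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'metrics' is required")
  if (!all(rownames(object) %in% METRIC_NAMES))
    msg <- c(msg, "row names must be canonical metric names")
  if (length(msg)) msg else TRUE
})

#' PANetworkSet: protected-area networks and their cell membership
#'
#' @slot membership data.frame with one row per analyzed cell:
#'   \code{cell_id}, \code{network_id}, \code{status} ("protected" or
#'   "nonprotected"), \code{pa_id} (assigned PA for protected cells).
#' @slot networks data.frame with one row per network: \code{network_id},
#'   \code{region}, \code{youngest_designation_year}, \code{member_pa_ids}
#'   (semicolon-separated), \code{n_protected}, \code{n_nonprotected},
#'   \code{sampled_cell_ratio} (NA until the effort filter has run).
#' @export
setClass("PANetworkSet",
         slots = c(membership = "data.frame", networks = "data.frame"))

setValidity("PANetworkSet", function(object) {
  m <- object@membership; n <- object@networks
  msg <- character()
  if (!all(c("cell_id", "network_id", "status", "pa_id") %in% names(m)))
    msg <- c(msg, "membership needs cell_id, network_id, status, pa_id")
  if (!all(c("network_id", "region", "youngest_designation_year") %in% names(n)))
    msg <- c(msg, "networks needs network_id, region, youngest_designation_year")
  if (!length(msg)) {
    if (anyDuplicated(m$cell_id))
      msg <- c(msg, "a cell may belong to only one network")
    if (nrow(m) && !all(m$status %in% c("protected", "nonprotected")))
      msg <- c(msg, "invalid status label")
    if (nrow(m) && !all(m$network_id %in% n$network_id))
      msg <- c(msg, "membership references unknown network")
  }
  if (length(msg)) msg else TRUE
})

#' Stage1Result: protection effect on one metric
#'
#' Overall protection effect \code{beta} with its standard error and 95\% CI,
#' plus the per-network variable slopes (\code{beta + } conditional deviation)
#' with conditional 95\% CIs and a significance flag (network deviates from
#' the overall effect when \code{beta} falls outside the network CI).
#'
#' @slot metric character metric name.
#' @slot family character, one of gaussian / nb / quasibinomial_log.
#' @slot beta0,beta,se,ci_lo,ci_hi numeric scalars for the overall effect.
#' @slot network_effects data.frame (\code{network_id}, \code{beta_i},
#'   \code{se_i}, \code{ci_lo}, \code{ci_hi}, \code{significant}).
#' @slot converged logical.
#' @slot model the underlying \code{mgcv} fit (or NULL).
#' @export
setClass("Stage1Result", slots = c(
  metric = "character", family = "character",
  beta0 = "numeric", beta = "numeric", se = "numeric",
  ci_lo = "numeric", ci_hi = "numeric",
  network_effects = "data.frame", converged = "logical", model = "ANY"
))

#' Stage2Result: environmental drivers of one metric's protection effect
#'
#' @slot metric character metric name.
#' @slot coefficients data.frame (\code{term}, \code{estimate}, \code{se},
#'   \code{p}) from the final OLS refit on z-scored drivers.
#' @slot selected character vector of selected drivers (control excluded).
#' @slot adj_r2,n numeric scalars.
#' @slot model the final \code{lm} fit (or NULL).
#' @export
setClass("Stage2Result", slots = c(
  metric = "character", coefficients = "data.frame",
  selected = "character", adj_r2 = "numeric", n = "numeric", model = "ANY"
))

#' SyntheticWorld: one generated study system
#'
#' @slot metaweb \linkS4class{Metaweb}.
#' @slot cells data.frame of grid-cell attributes.
#' @slot pas data.frame of protected-area attributes and disc geometry.
#' @slot occurrences data.frame of individual occurrence records.
#' @slot truth list of injected ground-truth quantities (per-network effect
#'   sizes on the occupancy scale).
#' @slot config the \code{\link{syntheticConfig}} used.
#' @export
setClass("SyntheticWorld", slots = c(
  metaweb = "Metaweb", cells = "data.frame", pas = "data.frame",
  occurrences = "data.frame", truth = "list", config = "list"
))
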