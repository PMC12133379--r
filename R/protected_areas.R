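#' @include AllClasses.R utils.R
NULL

#' Coverage rule for labelling grid cells as protected
#'
#' Under the default \code{"center"} mode a cell is protected when its centre
#' falls inside a PA polygon (maximizes sample size). Under
#' \code{"area_threshold"}, a cell is protected only when at least
#' \code{threshold} of its area is covered by the union of PA polygons
#' (0.5 and 0.9 in the sensitivity analysis).
#'
#' @param mode "center" or "area_threshold".
#' @param threshold coverage fraction, used only in area_threshold mode.
#' @return list of class \code{pawebs_coverage_rule}.
#' @export
coverageRule <- function(mode = c("center", "area_threshold"),
                         threshold = 0.5) {
  mode <- match.arg(mode)
  if (mode == "area_threshold")
    stopifnot(threshold > 0, threshold <= 1)
  structure(list(mode = mode,
                 threshold = if (mode == "area_threshold") threshold else NA_real_),
            class = "pawebs_coverage_rule")
}

# Fraction of each cell covered by the union of PA discs, estimated on a
# regular subgrid of sample points (cells are 10 km squares).
.cellCoverage <- function(cells, pas, npts = 20L) {
  off <- (seq_len(npts) - 0.5) / npts * 10 - 5
  pts <- expand.grid(dx = off, dy = off)
  cov <- matrix(FALSE, nrow(cells), nrow(pts))
  for (j in seq_len(nrow(pas))) {
    for (p in seq_len(nrow(pts))) {
      d2 <- (cells$x + pts$dx[p] - pas$center_x[j])^2 +
            (cells$y + pts$dy[p] - pas$center_y[j])^2
      cov[, p] <- cov[, p] | d2 <= pas$radius_km[j]^2
    }
  }
  rowMeans(cov)
}

#' Resolve overlapping protected areas for one grid cell
#'
#' Deterministic tie-breaking cascade: highest protection level, then oldest
#' designation, then largest area, then a seeded uniform random choice. A
#' pure function of its arguments: the random step derives its stream from
#' the seed and the candidate ids and restores the caller's RNG state.
#'
#' @param candidates PA table rows overlapping one cell (at least one row).
#' @param seed integer seed for the final random tie-break.
#' @return the single selected PA row.
#' @export
resolveOverlaps <- function(candidates, seed = 1L) {
  if (!nrow(candidates)) stop("resolveOverlaps: empty candidate set")
  k <- candidates[candidates$protection_level ==
                    max(candidates$protection_level), , drop = FALSE]
  k <- k[k$designation_year == min(k$designation_year), , drop = FALSE]
  k <- k[k$area_km2 == max(k$area_km2), , drop = FALSE]
  if (nrow(k) > 1L) {
    pick <- .withSeed(
      substreamSeed(seed, paste(sort(k$pa_id), collapse = "|")),
      sample.int(nrow(k), 1L))
    k <- k[pick, , drop = FALSE]
  }
  k
}

#' Assign protection status to grid cells
#'
#' Labels every cell protected or non-protected under a
#' \code{\link{coverageRule}} and resolves multiple overlapping PAs with the
#' \code{\link{resolveOverlaps}} cascade, so each protected cell carries
#' exactly one assigned PA. PAs with invalid geometry (non-positive or
#' missing radius) are rejected with a warning.
#'
#' @param cells grid-cell table (needs \code{cell_id}, \code{x}, \code{y}).
#' @param pas PA table (needs \code{pa_id}, \code{center_x}, \code{center_y},
#'   \code{radius_km}, \code{protection_level}, \code{designation_year},
#'   \code{area_km2}).
#' @param rule a \code{\link{coverageRule}}.
#' @param seed integer seed for random tie-breaks.
#' @return \code{cells} with added columns \code{protected} (logical) and
#'   \code{pa_id} (assigned PA, NA when non-protected).
#' @export
assignProtectionStatus <- function(cells, pas, rule = coverageRule("center"),
                                   seed = 1L) {
  stopifnot(inherits(rule, "pawebs_coverage_rule"))
  bad <- !is.finite(pas$radius_km) | pas$radius_km <= 0
  if (any(bad)) {
    .pwLog(sum(bad), " PA(s) rejected: invalid geometry", level = "warn")
    pas <- pas[!bad, , drop = FALSE]
  }
  out <- cells
  out$protected <- FALSE
  out$pa_id <- NA_character_
  if (!nrow(pas)) return(out)

  # candidate PAs per cell: centre containment or any overlap with the cell
  d2 <- outer(cells$x, pas$center_x, "-")^2 + outer(cells$y, pas$center_y, "-")^2
  centre_in <- sweep(d2, 2, pas$radius_km^2, "<=")
  if (rule$mode == "center") {
    protected <- rowSums(centre_in) > 0
    cand <- centre_in
  } else {
    # overlap possible when the disc comes within the cell's circumradius
    near <- sweep(sqrt(d2), 2, pas$radius_km + sqrt(50), "<=")
    coverage <- rep(0, nrow(cells))
    any_near <- rowSums(near) > 0
    if (any(any_near))
      coverage[any_near] <- .cellCoverage(cells[any_near, , drop = FALSE], pas)
    protected <- coverage >= rule$threshold
    cand <- near
  }
  for (i in which(protected)) {
    sel <- resolveOverlaps(pas[cand[i, ], , drop = FALSE], seed = seed)
    out$protected[i] <- TRUE
    out$pa_id[i] <- sel$pa_id
  }
  out
}

#' Group protected areas into PA networks
#'
#' PAs less than 1 km apart (boundary-to-boundary) and in the same
#' biogeographical region are connected; the connected components of that
#' graph are the PA networks. Each network collects the protected cells
#' assigned to its member PAs.
#'
#' @param pas filtered PA table.
#' @param status cells with protection status from
#'   \code{\link{assignProtectionStatus}}.
#' @param distance_km grouping distance; boundaries closer than this (strict)
#'   are connected. Default 1 km.
#' @return a \linkS4class{PANetworkSet} (membership holds protected cells
#'   only until \code{\link{attachBuffer}} adds comparison cells).
#' @export
groupPANetworks <- function(pas, status, distance_km = 1) {
  stopifnot(nrow(pas) >= 1)
  dc <- as.matrix(dist(cbind(pas$center_x, pas$center_y)))
  bdist <- pmax(dc - outer(pas$radius_km, pas$radius_km, "+"), 0)
  same_region <- outer(pas$region, pas$region, "==")
  adj <- bdist < distance_km & same_region
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  nets <- lapply(sort(unique(comp)), function(ci) {
    m <- pas[comp == ci, , drop = FALSE]
    data.frame(network_id = sprintf("net%03d", ci),
               region = m$region[1],
               youngest_designation_year = max(m$designation_year),
               member_pa_ids = paste(m$pa_id, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  networks <- do.call(rbind, nets)
  prot <- status[status$protected, , drop = FALSE]
  net_of_pa <- setNames(sprintf("net%03d", comp), pas$pa_id)
  membership <- data.frame(
    cell_id = prot$cell_id,
    network_id = unname(net_of_pa[prot$pa_id]),
    status = rep_len("protected", nrow(prot)),
    pa_id = prot$pa_id,
    stringsAsFactors = FALSE)
  membership <- membership[!is.na(membership$network_id), , drop = FALSE]
  tab <- table(membership$network_id)
  networks$n_protected <- as.integer(tab[networks$network_id])
  networks$n_protected[is.na(networks$n_protected)] <- 0L
  networks$n_nonprotected <- 0L
  networks$sampled_cell_ratio <- NA_real_
  out <- methods::new("PANetworkSet", membership = membership,
                      networks = networks)
  attr(out, "pas") <- pas     # disc geometry, reused by attachBuffer()
  out
}

#' Attach non-protected comparison cells to PA networks
#'
#' Non-protected cells within \code{radius_km} of any member PA (boundary
#' distance) and in the same region are attached as comparison cells. A cell
#' within reach of several networks is attached to the nearest one, so every
#' analyzed cell belongs to exactly one network.
#'
#' @param networks a \linkS4class{PANetworkSet} from
#'   \code{\link{groupPANetworks}}.
#' @param status cells with protection status (needs \code{x}, \code{y},
#'   \code{region}, \code{protected}).
#' @param radius_km buffer radius, default 100 km.
#' @param pas the PA table used for grouping; defaults to the table
#'   \code{\link{groupPANetworks}} recorded on the object.
#' @return the \linkS4class{PANetworkSet} with non-protected members added.
#' @export
attachBuffer <- function(networks, status, radius_km = 100, pas = NULL) {
  nt <- networkTable(networks)
  mem <- cellMembership(networks)
  if (is.null(pas)) pas <- attr(networks, "pas")
  if (is.null(pas))
    stop("attachBuffer needs the PA table (argument 'pas')")
  nonprot <- status[!status$protected, , drop = FALSE]
  if (!nrow(nonprot) || !nrow(nt)) return(networks)
  dmin <- matrix(Inf, nrow(nonprot), nrow(nt))
  for (k in seq_len(nrow(nt))) {
    ids <- strsplit(nt$member_pa_ids[k], ";")[[1]]
    mp <- pas[pas$pa_id %in% ids, , drop = FALSE]
    d <- sqrt(outer(nonprot$x, mp$center_x, "-")^2 +
              outer(nonprot$y, mp$center_y, "-")^2)
    bd <- pmax(sweep(d, 2, mp$radius_km, "-"), 0)
    dmin[, k] <- apply(bd, 1, min)
    dmin[nonprot$region != nt$region[k], k] <- Inf
  }
  best <- max.col(-dmin, ties.method = "first")
  ok <- dmin[cbind(seq_len(nrow(nonprot)), best)] <= radius_km
  add <- data.frame(cell_id = nonprot$cell_id[ok],
                    network_id = nt$network_id[best[ok]],
                    status = "nonprotected", pa_id = NA_character_,
                    stringsAsFactors = FALSE)
  mem <- rbind(mem, add)
  tab <- table(add$network_id)
  nt$n_nonprotected <- as.integer(tab[nt$network_id])
  nt$n_nonprotected[is.na(nt$n_nonprotected)] <- 0L
  out <- methods::new("PANetworkSet", membership = mem, networks = nt)
  attr(out, "pas") <- pas
  out
}

#' Temporal filter: keep records from after network protection began
#'
#' Within each PA network (protected and comparison cells alike), only
#' occurrence records from the designation year of the network's youngest
#' member PA onwards are kept, so every analyzed community was protected
#' when surveyed. Records in cells outside any network pass through.
#'
#' @param networks a \linkS4class{PANetworkSet}.
#' @param occ occurrence table with \code{cell_id} and \code{year}.
#' @return the filtered occurrence table.
#' @export
temporalFilter <- function(networks, occ) {
  mem <- cellMembership(networks)
  nt <- networkTable(networks)
  net <- mem$network_id[match(occ$cell_id, mem$cell_id)]
  cutoff <- nt$youngest_designation_year[match(net, nt$network_id)]
  keep <- is.na(cutoff) | occ$year >= cutoff
  occ[keep, , drop = FALSE]
}

#' Inclusion filter for PA networks
#'
#' Keeps networks with at least \code{min_cells} protected and
#' \code{min_cells} non-protected cells among the effort-retained cells, and
#' with a fraction of adequately sampled cells of at least \code{min_ratio}
#' (networks whose area is barely surveyed are poorly represented by the
#' occurrence data and are dropped with a log entry).
#'
#' @param networks a \linkS4class{PANetworkSet}.
#' @param retained_cells cell ids that passed the survey-effort filter.
#' @param min_cells minimum protected and non-protected retained cells;
#'   default 15.
#' @param min_ratio minimum sampled-cell ratio; default 0.10.
#' @return the filtered \linkS4class{PANetworkSet} with updated
#'   \code{n_protected}, \code{n_nonprotected} (retained-cell counts) and
#'   \code{sampled_cell_ratio}.
#' @export
networkInclusionFilter <- function(networks, retained_cells, min_cells = 15,
                                   min_ratio = 0.10) {
  nt <- networkTable(networks)
  mem <- cellMembership(networks)
  mem$retained <- mem$cell_id %in% retained_cells
  stats <- do.call(rbind, lapply(seq_len(nrow(nt)), function(k) {
    m <- mem[mem$network_id == nt$network_id[k], , drop = FALSE]
    data.frame(
      n_protected = sum(m$retained & m$status == "protected"),
      n_nonprotected = sum(m$retained & m$status == "nonprotected"),
      sampled_cell_ratio = if (nrow(m)) mean(m$retained) else 0)
  }))
  nt$n_protected <- stats$n_protected
  nt$n_nonprotected <- stats$n_nonprotected
  nt$sampled_cell_ratio <- stats$sampled_cell_ratio
  keep <- nt$n_protected >= min_cells & nt$n_nonprotected >= min_cells &
    nt$sampled_cell_ratio >= min_ratio
  dropped <- nt$network_id[!keep]
  if (length(dropped))
    .pwLog("network(s) dropped by inclusion filter: ",
           paste(dropped, collapse = ", "))
  if (!any(keep))
    stop("no PA network satisfies the inclusion criteria")
  nt <- nt[keep, , drop = FALSE]
  mem <- mem[mem$network_id %in% nt$network_id,
             c("cell_id", "network_id", "status", "pa_id"), drop = FALSE]
  out <- methods::new("PANetworkSet", membership = mem, networks = nt)
  attr(out, "pas") <- attr(networks, "pas")
  out
}
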