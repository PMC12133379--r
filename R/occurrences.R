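#' @include utils.R
NULL

#' Build survey events from occurrence records
#'
#' A survey event is one unique survey visit: the combination of programme,
#' date, time and location (here, the grid cell). Records missing any key
#' component are rejected with a warning. Sampling effort downstream is the
#' number of events per cell.
#'
#' @param occ occurrence table with columns \code{species_id},
#'   \code{cell_id}, \code{date}, \code{time}, \code{programme} (a
#'   \code{year} column is carried through if present).
#' @return list with \code{events} (one row per event: \code{event_id},
#'   \code{cell_id}, \code{programme}, \code{date}, \code{time},
#'   \code{n_records}) and \code{records} (the input rows plus
#'   \code{event_id}).
#' @examples
#' occ <- data.frame(species_id = c("a", "b", "a"), cell_id = "c1",
#'                   date = "2016-05-01", time = "06:00",
#'                   programme = c("eBird", "eBird", "iNaturalist"))
#' buildSurveyEvents(occ)$events   # two events: programmes differ
#' @export
buildSurveyEvents <- function(occ) {
  need <- c("species_id", "cell_id", "date", "time", "programme")
  stopifnot(all(need %in% names(occ)))
  keyed <- occ[, need[-1]]
  ok <- complete.cases(keyed) &
    rowSums(keyed == "" | is.na(keyed)) == 0
  if (any(!ok)) {
    .pwLog(sum(!ok), " record(s) dropped: incomplete survey-event key",
           level = "warn")
    occ <- occ[ok, , drop = FALSE]
  }
  if (!nrow(occ)) {
    return(list(
      events = data.frame(event_id = character(), cell_id = character(),
                          programme = character(), date = character(),
                          time = character(), n_records = integer(),
                          stringsAsFactors = FALSE),
      records = cbind(occ, event_id = character(0))))
  }
  key <- paste(occ$programme, occ$date, occ$time, occ$cell_id, sep = "\r")
  uk <- unique(key)
  event_id <- sprintf("ev%06d", seq_along(uk))
  idx <- match(key, uk)
  first <- match(uk, key)
  events <- data.frame(
    event_id = event_id,
    cell_id = occ$cell_id[first],
    programme = occ$programme[first],
    date = occ$date[first],
    time = occ$time[first],
    n_records = as.integer(tabulate(idx, length(uk))),
    stringsAsFactors = FALSE)
  if ("year" %in% names(occ)) events$year <- occ$year[first]
  records <- occ
  records$event_id <- event_id[idx]
  list(events = events, records = records)
}

#' Filter grid cells by survey effort
#'
#' Cells with fewer survey events than the floor are removed from all
#' biodiversity analyses (they remain usable for environmental
#' characterization of PA networks, which is computed over all cells).
#' A cell with exactly \code{floor} events is retained.
#'
#' @param events event table from \code{\link{buildSurveyEvents}}.
#' @param floor minimum number of events; default 50.
#' @return character vector of retained cell ids.
#' @export
filterCellsByEffort <- function(events, floor = 50) {
  counts <- table(events$cell_id)
  names(counts)[counts >= floor]
}

#' Plan a within-network rarefaction
#'
#' For each PA network, effort is standardized to the smallest per-cell
#' event count among that network's retained cells.
#'
#' @param events event table.
#' @param membership data.frame (\code{cell_id}, \code{network_id}) over the
#'   retained cells.
#' @param seed integer seed for the event draws.
#' @return list of class \code{pawebs_rarefaction_plan} with per-cell counts
#'   \code{n_events}, per-network minima \code{n_min}, and \code{seed}.
#' @export
rarefactionPlan <- function(events, membership, seed = 1L) {
  stopifnot(all(c("cell_id", "network_id") %in% names(membership)))
  cnt <- table(events$cell_id)
  n_events <- as.integer(cnt[membership$cell_id])
  n_events[is.na(n_events)] <- 0L
  plan <- data.frame(cell_id = membership$cell_id,
                     network_id = membership$network_id,
                     n_events = n_events, stringsAsFactors = FALSE)
  n_min <- tapply(plan$n_events, plan$network_id, min)
  structure(list(cells = plan,
                 n_min = setNames(as.integer(n_min), names(n_min)),
                 seed = as.integer(seed)),
            class = "pawebs_rarefaction_plan")
}

#' Rarefy survey effort within PA networks
#'
#' Draws, without replacement and deterministically under the plan's seed,
#' the per-network minimum number of survey events in every cell, and
#' returns the occurrence records of the drawn events. After rarefaction all
#' cells of a network carry identical effort.
#'
#' @param surveys list from \code{\link{buildSurveyEvents}}.
#' @param plan a \code{\link{rarefactionPlan}}.
#' @return list with \code{records} (rarefied occurrence rows),
#'   \code{events} (retained events) and \code{report} (cell_id, network_id,
#'   n_raw, n_rarefied).
#' @export
rarefyNetwork <- function(surveys, plan) {
  stopifnot(inherits(plan, "pawebs_rarefaction_plan"))
  ev <- surveys$events
  keep <- character(0)
  report <- plan$cells
  report$n_rarefied <- plan$n_min[report$network_id]
  stopifnot(all(report$n_rarefied <= report$n_events))
  by_cell <- split(ev$event_id, ev$cell_id)
  keep <- .withSeed(substreamSeed(plan$seed, "rarefaction"), {
    unlist(lapply(seq_len(nrow(report)), function(i) {
      sample(by_cell[[report$cell_id[i]]], report$n_rarefied[i])
    }), use.names = FALSE)
  })
  names(report)[names(report) == "n_events"] <- "n_raw"
  list(records = surveys$records[surveys$records$event_id %in% keep, ,
                                 drop = FALSE],
       events = ev[ev$event_id %in% keep, , drop = FALSE],
       report = report)
}
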