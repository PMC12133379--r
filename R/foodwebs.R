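#' @include AllClasses.R utils.R
NULL

#' Build the local food web of one grid cell
#'
#' The local web is the subgraph of the metaweb induced by the species
#' present in the cell: a trophic interaction is realized locally whenever
#' both species co-occur and the interaction exists in the metaweb. No edge
#' is invented and no metaweb edge among present species is omitted.
#'
#' @param present character vector of species present in the cell.
#' @param metaweb a \linkS4class{Metaweb}.
#' @param cell_id cell identifier carried on the result.
#' @return a \linkS4class{LocalFoodWeb} with roles classified.
#' @examples
#' mw <- methods::new("Metaweb",
#'   species = data.frame(species_id = c("A", "B", "C", "D"),
#'                        body_mass_g = c(10, 100, 1000, 50),
#'                        niche_value = c(.1, .4, .9, .3)),
#'   edges = data.frame(consumer = c("B", "C", "C", "D"),
#'                      resource = c("A", "B", "A", "C")))
#' buildLocalWeb(c("A", "B", "C"), mw)
#' @export
buildLocalWeb <- function(present, metaweb, cell_id = "cell") {
  present <- unique(present)
  sp <- mwSpecies(metaweb)$species_id
  unknown <- setdiff(present, sp)
  if (length(unknown))
    stop("unknown species id(s): ", paste(head(unknown, 5), collapse = ", "))
  ed <- mwEdges(metaweb)
  ed <- ed[ed$consumer %in% present & ed$resource %in% present, , drop = FALSE]
  rownames(ed) <- NULL
  web <- methods::new("LocalFoodWeb", cell_id = cell_id, species = present,
                      edges = ed, roles = character(0))
  web@roles <- classifyRoles(web)
  web
}

# out-degree = number of prey; in-degree = number of predators
.degrees <- function(web) {
  s <- web@species
  list(
    out = setNames(as.integer(table(factor(web@edges$consumer, s))), s),
    `in` = setNames(as.integer(table(factor(web@edges$resource, s))), s))
}

#' Classify species roles in a local web
#'
#' In this bird-only context a basal species is a bird that feeds on no other
#' bird (out-degree 0, including isolated species), a top species feeds on
#' birds but has no bird predator (out-degree > 0, in-degree 0), and an
#' intermediate species has both prey and predators within the web.
#'
#' @param web a \linkS4class{LocalFoodWeb}.
#' @return named character vector of roles.
#' @export
classifyRoles <- function(web) {
  if (!length(web@species))
    return(setNames(character(0), character(0)))
  d <- .degrees(web)
  r <- ifelse(d$out == 0, "basal",
              ifelse(d$`in` == 0, "top", "intermediate"))
  setNames(as.character(r), web@species)
}

#' Prey-averaged trophic levels
#'
#' Basal species sit at level 1; every consumer at 1 plus the mean level of
#' its prey. With cycles, the definition is the solution of the linear
#' system; if that system is singular (a pathological cycle with no basal
#' input), the function falls back to shortest-path levels (1 + fewest links
#' to a basal species) with a warning.
#'
#' @param web a \linkS4class{LocalFoodWeb}.
#' @return named numeric vector of trophic levels (possibly NA for species
#'   with no path to a basal species under the fallback).
#' @examples
#' # chain C eats B eats A: levels 1, 2, 3
#' @export
trophicLevels <- function(web) {
  s <- web@species
  n <- length(s)
  if (!n) return(setNames(numeric(0), character(0)))
  tl <- setNames(rep(1, n), s)
  ed <- web@edges
  if (!nrow(ed)) return(tl)
  W <- matrix(0, n, n, dimnames = list(s, s))
  W[cbind(ed$consumer, ed$resource)] <- 1
  nprey <- rowSums(W)
  cons <- nprey > 0
  W[cons, ] <- W[cons, , drop = FALSE] / nprey[cons]
  A <- diag(n) - W
  sol <- tryCatch(solve(A, rep(1, n)), error = function(e) NULL)
  if (!is.null(sol) && all(is.finite(sol))) return(setNames(as.numeric(sol), s))
  .pwLog("singular trophic-level system; falling back to shortest-path levels",
         level = "warn")
  # BFS upward from the basal set on predator links
  dist <- setNames(rep(NA_real_, n), s)
  dist[nprey == 0] <- 0
  frontier <- s[nprey == 0]
  step <- 0
  while (length(frontier)) {
    step <- step + 1
    nxt <- unique(ed$consumer[ed$resource %in% frontier])
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- step
    frontier <- nxt
  }
  dist + 1
}

# Kahn topological order on consumer -> resource edges; NULL if cyclic.
.toposort <- function(species, edges) {
  indeg <- setNames(as.integer(table(factor(edges$resource, species))), species)
  out_of <- split(edges$resource, factor(edges$consumer, species))
  order <- character(0)
  queue <- species[indeg == 0]
  indeg_work <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in out_of[[v]]) {
      indeg_work[w] <- indeg_work[w] - 1L
      if (indeg_work[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) == length(species)) order else NULL
}

#' Mean food chain length
#'
#' The mean number of trophic links over all maximal food chains: directed
#' paths (following consumer-to-resource links, i.e. from a top species down
#' to a basal one) that cannot be extended into a longer simple path at
#' either end. On acyclic webs these are exactly the paths from species with
#' no predator to species with no prey, and the mean is computed exactly by
#' dynamic programming; on webs with cycles, maximal simple paths are
#' enumerated by depth-first search, guarded by \code{cap} (the mean over
#' the enumerated paths is returned with a warning when the cap is hit).
#' A web with no consumer has no chain and yields \code{NA}.
#'
#' @param web a \linkS4class{LocalFoodWeb}.
#' @param cap maximum number of paths enumerated on cyclic webs.
#' @return mean chain length in links.
#' @export
meanFoodChainLength <- function(web, cap = 1e5) {
  s <- web@species
  ed <- web@edges
  if (!nrow(ed)) return(NA_real_)
  succ <- split(ed$resource, factor(ed$consumer, s))
  pred <- split(ed$consumer, factor(ed$resource, s))
  topo <- .toposort(s, ed)
  if (!is.null(topo)) {
    cnt <- setNames(numeric(length(s)), s)   # chains from node down to basal
    len <- setNames(numeric(length(s)), s)   # total links over those chains
    for (v in rev(topo)) {
      sv <- succ[[v]]
      if (!length(sv)) { cnt[v] <- 1; len[v] <- 0 } else {
        cnt[v] <- sum(cnt[sv])
        len[v] <- sum(len[sv] + cnt[sv])
      }
    }
    tops <- s[vapply(pred[s], length, 1L) == 0 &
              vapply(succ[s], length, 1L) > 0]
    if (!length(tops)) return(NA_real_)
    return(sum(len[tops]) / sum(cnt[tops]))
  }
  # cyclic web: enumerate maximal simple paths
  n_paths <- 0; tot_len <- 0; truncated <- FALSE
  dfs <- function(path) {
    if (truncated) return()
    v <- path[length(path)]
    ext <- setdiff(succ[[v]], path)
    if (!length(ext)) {
      if (length(path) >= 2 && all(pred[[path[1]]] %in% path)) {
        if (n_paths >= cap) { truncated <<- TRUE; return() }
        n_paths <<- n_paths + 1
        tot_len <<- tot_len + (length(path) - 1)
      }
      return()
    }
    for (w in ext) dfs(c(path, w))
  }
  for (v in s) dfs(v)
  if (truncated)
    .pwLog("food-chain enumeration truncated at cap = ", cap, level = "warn")
  if (!n_paths) return(NA_real_)
  tot_len / n_paths
}

#' Fraction of omnivory
#'
#' The fraction of species (out of the whole web) that are omnivores:
#' consumers whose prey span at least two distinct integer-rounded trophic
#' levels.
#'
#' @param web a \linkS4class{LocalFoodWeb}.
#' @param tl trophic levels from \code{\link{trophicLevels}} (computed if
#'   missing).
#' @return fraction in \code{[0, 1]} (0 for an edgeless web).
#' @export
fractionOmnivory <- function(web, tl = trophicLevels(web)) {
  s <- web@species
  if (!length(s)) return(NA_real_)
  ed <- web@edges
  if (!nrow(ed)) return(0)
  prey_of <- split(ed$resource, ed$consumer)
  omn <- vapply(prey_of, function(p) {
    lv <- unique(round(tl[p]))
    length(lv[!is.na(lv)]) >= 2
  }, logical(1))
  sum(omn) / length(s)
}

#' Mean generality and vulnerability
#'
#' Generality is a consumer's number of prey items, averaged over consumers
#' only; vulnerability is a species' number of predators, averaged over
#' preyed-upon species only. Either is \code{NA} when its denominator is
#' empty (e.g. an edgeless web).
#'
#' @param web a \linkS4class{LocalFoodWeb}.
#' @return named numeric vector (mean_generality, mean_vulnerability).
#' @export
dietMetrics <- function(web) {
  d <- .degrees(web)
  g <- if (any(d$out > 0)) mean(d$out[d$out > 0]) else NA_real_
  v <- if (any(d$`in` > 0)) mean(d$`in`[d$`in` > 0]) else NA_real_
  c(mean_generality = g, mean_vulnerability = v)
}

#' Food-web complexity metrics
#'
#' Species richness S, number of links L, connectance (fraction of realized
#' links, L / S^2) and linkage density (links per species, L / S). Ratios are
#' \code{NA} on an empty web.
#'
#' @param web a \linkS4class{LocalFoodWeb}.
#' @return named numeric vector (species_richness, n_links, connectance,
#'   linkage_density).
#' @export
complexityMetrics <- function(web) {
  S <- length(web@species)
  L <- nrow(web@edges)
  c(species_richness = S, n_links = L,
    connectance = if (S > 0) L / S^2 else NA_real_,
    linkage_density = if (S > 0) L / S else NA_real_)
}

# ---- modularity -----------------------------------------------------------

# Undirected simple projection as a symmetric 0/1 matrix.
.undirectedAdj <- function(web) {
  s <- web@species
  A <- matrix(0, length(s), length(s), dimnames = list(s, s))
  if (nrow(web@edges)) {
    A[cbind(web@edges$consumer, web@edges$resource)] <- 1
    A <- pmax(A, t(A))
  }
  A
}

# Newman modularity of a partition on a symmetric weight matrix
# (convention: diagonal holds twice the self-loop weight).
.partitionQ <- function(W, comm) {
  m2 <- sum(W)
  if (m2 == 0) return(NA_real_)
  Q <- 0
  for (c in unique(comm)) {
    idx <- comm == c
    Q <- Q + sum(W[idx, idx]) / m2 - (sum(W[, idx]) / m2)^2
  }
  Q
}

# One Louvain run: local node moves to the neighbouring community with the
# largest modularity gain, then community aggregation, repeated to
# convergence. Returns the flat partition of the original nodes.
.louvainRun <- function(W0) {
  n0 <- nrow(W0)
  node_comm <- seq_len(n0)      # partition of original nodes
  W <- W0
  repeat {
    n <- nrow(W)
    comm <- seq_len(n)
    k <- rowSums(W)
    m2 <- sum(W)
    tot <- k                    # community total degree
    improved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        ci <- comm[i]
        nb <- which(W[i, ] > 0 & seq_len(n) != i)
        cand <- unique(comm[nb])
        if (!length(cand)) next
        # weight from i to each candidate community
        tot[ci] <- tot[ci] - k[i]
        w_i <- vapply(cand, function(cc) sum(W[i, comm == cc & seq_len(n) != i]),
                      numeric(1))
        gain <- w_i / m2 * 2 - 2 * k[i] * tot[cand] / m2^2
        w_stay <- sum(W[i, comm == ci & seq_len(n) != i])
        gain_stay <- w_stay / m2 * 2 - 2 * k[i] * tot[ci] / m2^2
        best <- which.max(gain)
        if (gain[best] > gain_stay + 1e-12) {
          comm[i] <- cand[best]
          moved <- TRUE
          improved_any <- TRUE
        }
        tot[comm[i]] <- tot[comm[i]] + k[i]
      }
      if (!moved) break
    }
    comm <- match(comm, unique(comm))
    node_comm <- comm[node_comm]
    if (!improved_any || max(comm) == n) break
    # aggregate communities into super-nodes
    nc <- max(comm)
    M <- matrix(0, n, nc); M[cbind(seq_len(n), comm)] <- 1
    W <- t(M) %*% W %*% M
  }
  node_comm
}

#' Food-web modularity
#'
#' Newman modularity Q of the best partition found by a seeded multi-restart
#' Louvain search on the undirected projection of the web. Q lies in
#' [-0.5, 1]; an edgeless web yields \code{NA}.
#'
#' @param web a \linkS4class{LocalFoodWeb}.
#' @param seed integer seed for the search (restarts shuffle node order).
#' @param restarts number of independent search restarts.
#' @return the best Q found.
#' @export
webModularity <- function(web, seed = 1L, restarts = 8L) {
  A <- .undirectedAdj(web)
  if (sum(A) == 0) return(NA_real_)
  .withSeed(substreamSeed(seed, paste0("modularity:", web@cell_id)), {
    best <- -Inf
    for (r in seq_len(restarts)) {
      part <- .louvainRun(A)
      q <- .partitionQ(A, part)
      if (q > best) best <- q
    }
    best
  })
}

#' Mean body mass per trophic role
#'
#' Arithmetic mean body mass (grams) of the basal, intermediate and top
#' species of a web. An empty role yields \code{NA}; species lacking a body
#' mass are excluded with a warning.
#'
#' @param web a \linkS4class{LocalFoodWeb} with roles classified.
#' @param traits data.frame with \code{species_id} and \code{body_mass_g}.
#' @return named numeric vector (bm_basal, bm_intermediate, bm_top).
#' @export
bodyMassByRole <- function(web, traits) {
  roles <- if (length(web@roles)) web@roles else classifyRoles(web)
  bm <- traits$body_mass_g[match(names(roles), traits$species_id)]
  if (anyNA(bm) && length(roles)) {
    .pwLog(sum(is.na(bm)), " species without body mass excluded",
           level = "warn")
  }
  out <- vapply(c("basal", "intermediate", "top"), function(r) {
    v <- bm[roles == r & !is.na(bm)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  setNames(out, c("bm_basal", "bm_intermediate", "bm_top"))
}

#' Compute the full metric vector of one local web
#'
#' All sixteen metrics (or a requested subset), with degenerate webs giving
#' zero counts and missing continuous metrics.
#'
#' @param web a \linkS4class{LocalFoodWeb}.
#' @param traits species trait table with body masses.
#' @param seed integer seed (used by the modularity search).
#' @param metrics metric names to compute; default all of
#'   \code{\link{METRIC_NAMES}}.
#' @return named numeric vector over \code{metrics}.
#' @export
computeAllMetrics <- function(web, traits, seed = 1L,
                              metrics = METRIC_NAMES) {
  stopifnot(all(metrics %in% METRIC_NAMES))
  out <- setNames(rep(NA_real_, length(METRIC_NAMES)), METRIC_NAMES)
  roles <- if (length(web@roles)) web@roles else classifyRoles(web)
  out[c("species_richness", "n_links", "connectance", "linkage_density")] <-
    complexityMetrics(web)
  rc <- table(factor(roles, c("basal", "intermediate", "top")))
  out[c("n_basal", "n_intermediate", "n_top")] <- as.numeric(rc)
  if (length(web@species)) {
    tl <- if (any(c("mean_trophic_level", "fraction_omnivory") %in% metrics))
      trophicLevels(web) else NULL
    if ("mean_trophic_level" %in% metrics)
      out["mean_trophic_level"] <- mean(tl, na.rm = TRUE)
    if ("fraction_omnivory" %in% metrics)
      out["fraction_omnivory"] <- fractionOmnivory(web, tl)
    if ("mfcl" %in% metrics) out["mfcl"] <- meanFoodChainLength(web)
    if (any(c("mean_generality", "mean_vulnerability") %in% metrics))
      out[c("mean_generality", "mean_vulnerability")] <- dietMetrics(web)
    if ("modularity" %in% metrics)
      out["modularity"] <- webModularity(web, seed = seed)
    if (any(c("bm_basal", "bm_intermediate", "bm_top") %in% metrics))
      out[c("bm_basal", "bm_intermediate", "bm_top")] <-
        bodyMassByRole(web, traits)
  }
  out[metrics]
}

#' Compute the metric table over all cells
#'
#' Builds each cell's local web from its rarefied species records and
#' assembles the per-cell metric matrix together with the stage-1 covariates
#' into a \linkS4class{CellMetrics} object.
#'
#' @param records rarefied occurrence records (\code{species_id},
#'   \code{cell_id}).
#' @param metaweb a \linkS4class{Metaweb}.
#' @param cells grid-cell attribute table.
#' @param networks a \linkS4class{PANetworkSet}.
#' @param effort named per-cell survey-event counts before rarefaction.
#' @param seed integer seed.
#' @param metrics metric names to compute.
#' @return a \linkS4class{CellMetrics}.
#' @export
computeCellMetrics <- function(records, metaweb, cells, networks, effort,
                               seed = 1L, metrics = METRIC_NAMES) {
  mem <- cellMembership(networks)
  use <- intersect(unique(records$cell_id), mem$cell_id)
  sp_by_cell <- split(records$species_id, records$cell_id)[use]
  traits <- mwSpecies(metaweb)
  mat <- vapply(use, function(cz) {
    web <- buildLocalWeb(unique(sp_by_cell[[cz]]), metaweb, cell_id = cz)
    computeAllMetrics(web, traits, seed = seed, metrics = metrics)
  }, numeric(length(metrics)))
  mat <- matrix(mat, nrow = length(metrics),
                dimnames = list(metrics, use))
  idx <- match(use, cells$cell_id)
  midx <- match(use, mem$cell_id)
  cd <- S4Vectors::DataFrame(
    cell_id = use,
    network_id = mem$network_id[midx],
    protected = mem$status[midx] == "protected",
    effort = as.numeric(effort[use]),
    elevation = cells$elevation[idx],
    remoteness = cells$remoteness[idx],
    land_cover = cells$land_cover[idx],
    row.names = use)
  methods::new("CellMetrics", SummarizedExperiment::SummarizedExperiment(
    assays = list(metrics = mat), colData = cd))
}
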