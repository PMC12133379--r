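#' @include AllClasses.R utils.R
NULL

#' The candidate environmental drivers
#'
#' Column names produced by \code{\link{computeDrivers}}: PA characteristics,
#' network-level environment, surrounding landscape, and inside-minus-outside
#' differences, plus the always-included control \code{prop_protected}.
#'
#' @export
DRIVER_NAMES <- c(
  "mean_designation_year", "mean_protection_level", "aggregation",
  "forest_inside", "frac_bird_directive",
  "mean_elevation", "mean_slope", "mean_remoteness", "landcover_diversity",
  "human_density_out", "urban_out", "agri_out", "forest_out",
  "diff_agri", "diff_forest", "diff_urban", "diff_human_density"
)

#' Characterize each PA network by its environmental drivers
#'
#' Computed over all cells of a network regardless of the survey-effort
#' filter. Land-cover diversity is the Shannon index of land-cover class
#' proportions; the aggregation coefficient is the largest member PA's share
#' of the network's total protected area (a monotone proxy for the inverse
#' of fragmentation); "surrounding" quantities are means over the
#' non-protected cells, differences are inside mean minus outside mean.
#' Networks without outside cells get missing difference drivers (logged).
#'
#' @param networks a \linkS4class{PANetworkSet}.
#' @param cells full grid-cell attribute table.
#' @param pas PA attribute table.
#' @return data.frame with one row per network: \code{network_id},
#'   \code{prop_protected} and the columns of \code{\link{DRIVER_NAMES}}.
#' @export
computeDrivers <- function(networks, cells, pas) {
  nt <- networkTable(networks)
  mem <- cellMembership(networks)
  frac_lc <- function(sub, class) {
    if (!nrow(sub)) return(NA_real_)
    mean(sub$land_cover == class)
  }
  rows <- lapply(seq_len(nrow(nt)), function(k) {
    nid <- nt$network_id[k]
    m <- mem[mem$network_id == nid, , drop = FALSE]
    cc <- cells[match(m$cell_id, cells$cell_id), , drop = FALSE]
    inside <- cc[m$status == "protected", , drop = FALSE]
    outside <- cc[m$status == "nonprotected", , drop = FALSE]
    ids <- strsplit(nt$member_pa_ids[k], ";")[[1]]
    mp <- pas[pas$pa_id %in% ids, , drop = FALSE]
    if (!nrow(outside))
      .pwLog("network ", nid, " has no outside cells; ",
             "difference drivers missing", level = "warn")
    out_mean <- function(x) if (nrow(outside)) mean(x) else NA_real_
    data.frame(
      network_id = nid,
      prop_protected = nrow(inside) / nrow(cc),
      mean_designation_year = mean(mp$designation_year),
      mean_protection_level = mean(mp$protection_level),
      aggregation = max(mp$area_km2) / sum(mp$area_km2),
      forest_inside = frac_lc(inside, "forest_seminatural"),
      frac_bird_directive = mean(mp$bird_directive),
      mean_elevation = mean(cc$elevation),
      mean_slope = mean(cc$slope),
      mean_remoteness = mean(cc$remoteness),
      landcover_diversity = .shannon(cc$land_cover),
      human_density_out = out_mean(outside$human_density),
      urban_out = frac_lc(outside, "artificial"),
      agri_out = frac_lc(outside, "agricultural"),
      forest_out = frac_lc(outside, "forest_seminatural"),
      diff_agri = frac_lc(inside, "agricultural") - frac_lc(outside, "agricultural"),
      diff_forest = frac_lc(inside, "forest_seminatural") - frac_lc(outside, "forest_seminatural"),
      diff_urban = frac_lc(inside, "artificial") - frac_lc(outside, "artificial"),
      diff_human_density = mean(inside$human_density) - out_mean(outside$human_density),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bayesian information criterion
#'
#' \code{ln(n) * k - 2 * ln(L)} with \code{k} parameters, log-likelihood
#' \code{loglik} and sample size \code{n}.
#'
#' @param loglik log-likelihood of the model.
#' @param k number of parameters.
#' @param n sample size (at least 1).
#' @return the BIC value.
#' @examples
#' bic(-10, 3, 45)   # 3 * log(45) + 20
#' @export
bic <- function(loglik, k, n) {
  stopifnot(k >= 0)
  if (n < 1) stop("bic: n must be >= 1")
  log(n) * k - 2 * loglik
}

#' Explain per-network protection effects with BIC-stepwise regression
#'
#' Regresses the per-network effects on z-scored environmental drivers with
#' bidirectional stepwise selection minimizing the BIC, starting from the
#' control-only model (the proportion of protected cells is always kept as a
#' candidate and never removed). The final OLS refit reports scaled
#' coefficients, standard errors, p-values and adjusted R-squared. The
#' search is deterministic; ties follow the candidate order.
#'
#' @param beta_i data.frame with \code{network_id} and \code{beta_i} (e.g.
#'   a slice of \code{\link{stage1NetworkTable}}).
#' @param drivers driver table from \code{\link{computeDrivers}}.
#' @param candidates driver columns to consider; default all of
#'   \code{\link{DRIVER_NAMES}} present and complete in \code{drivers}.
#' @param control column forced into every model.
#' @param metric metric name carried on the result.
#' @param min_resid_df smallest residual degrees of freedom a candidate
#'   model may have; additions that would cross it are not considered, so a
#'   saturated model is never fitted even with more candidates than
#'   networks.
#' @return a \linkS4class{Stage2Result}.
#' @export
stepwiseBIC <- function(beta_i, drivers, candidates = NULL,
                        control = "prop_protected", metric = "metric",
                        min_resid_df = 3) {
  d <- merge(beta_i[, c("network_id", "beta_i")],
             drivers[, setdiff(names(drivers), "beta_i"), drop = FALSE],
             by = "network_id")
  if (is.null(candidates)) {
    candidates <- intersect(DRIVER_NAMES, names(d))
    candidates <- candidates[vapply(candidates, function(cn)
      !anyNA(d[[cn]]) && sd(d[[cn]]) > 0, logical(1))]
  }
  stopifnot(control %in% names(d), all(candidates %in% names(d)))
  n <- nrow(d)
  dz <- d
  for (cn in c(control, candidates)) dz[[cn]] <- .zscore(dz[[cn]])
  fit <- function(terms) lm(as.formula(
    paste("beta_i ~", paste(c(control, terms), collapse = " + "))), data = dz)
  model_bic <- function(m) {
    ll <- logLik(m)
    bic(as.numeric(ll), attr(ll, "df"), n)
  }
  current <- character(0)
  sel <- fit(current)
  best_bic <- model_bic(sel)
  repeat {
    moves <- list()
    for (cn in setdiff(candidates, current))        # forward
      if (n - (2 + length(current) + 1) >= min_resid_df)
        moves[[length(moves) + 1]] <- c(current, cn)
    for (cn in current)                             # backward
      moves[[length(moves) + 1]] <- setdiff(current, cn)
    if (!length(moves)) break
    bics <- vapply(moves, function(tt) model_bic(fit(tt)), numeric(1))
    j <- which.min(bics)                            # ties: first move wins
    if (bics[j] < best_bic - 1e-10) {
      current <- moves[[j]]
      sel <- fit(current)
      best_bic <- bics[j]
    } else break
  }
  sm <- summary(sel)
  co <- sm$coefficients
  coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      p = co[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  selected <- setdiff(attr(terms(sel), "term.labels"), control)
  methods::new("Stage2Result", metric = metric, coefficients = coefs,
               selected = selected, adj_r2 = sm$adj.r.squared, n = n,
               model = sel)
}

#' Tabulate stage-2 results
#'
#' @param results list of \linkS4class{Stage2Result}.
#' @return list with \code{coefficients} (long table of scaled coefficients)
#'   and \code{models} (one row per metric: adjusted R-squared, n, number of
#'   selected drivers).
#' @export
stage2Summary <- function(results) {
  co <- do.call(rbind, lapply(results, function(r) {
    x <- r@coefficients
    x$metric <- r@metric
    x[, c("metric", "term", "estimate", "se", "p")]
  }))
  mo <- do.call(rbind, lapply(results, function(r) data.frame(
    metric = r@metric, adj_r2 = r@adj_r2, n = r@n,
    k_selected = length(r@selected), stringsAsFactors = FALSE)))
  list(coefficients = co, models = mo)
}
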