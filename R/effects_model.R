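#' @include AllClasses.R utils.R
NULL

#' Error-family map for the stage-1 models
#'
#' Count metrics are modelled with a negative-binomial error distribution,
#' proportion metrics with a quasi-binomial with log link, and continuous
#' metrics (including modularity, whose range includes negatives) with a
#' Gaussian.
#'
#' @param metric metric name.
#' @param overrides optional named character vector mapping metric names to
#'   one of \code{"gaussian"}, \code{"nb"}, \code{"quasibinomial_log"}.
#' @return the family label.
#' @export
familyForMetric <- function(metric, overrides = NULL) {
  if (!is.null(overrides) && metric %in% names(overrides))
    return(match.arg(overrides[[metric]],
                     c("gaussian", "nb", "quasibinomial_log")))
  counts <- c("species_richness", "n_links", "n_basal", "n_intermediate",
              "n_top")
  props <- c("connectance", "fraction_omnivory")
  if (metric %in% counts) "nb"
  else if (metric %in% props) "quasibinomial_log"
  else "gaussian"
}

#' Build the stage-1 model design for one metric
#'
#' Joins the metric values with the cell covariates: protection status
#' (fixed), survey effort before rarefaction and species richness (penalized
#' smooths; the richness smooth is omitted when the response is species
#' richness itself), and the grouping variables for the random terms
#' (PA network, land cover). Rows with a missing response are dropped with a
#' logged count. Refuses to proceed with fewer than two networks; networks
#' in which protection status is constant are flagged in
#' \code{attr(, "constant_protection")}.
#'
#' @param cm a \linkS4class{CellMetrics}.
#' @param metric metric name (a row of \code{cm}).
#' @return a data.frame with columns \code{y}, \code{prot_num},
#'   \code{effort}, \code{richness}, \code{network}, \code{elevation},
#'   \code{remoteness}, \code{land_cover}.
#' @export
buildDesign <- function(cm, metric) {
  stopifnot(is(cm, "CellMetrics"), metric %in% rownames(cm))
  a <- SummarizedExperiment::assay(cm, "metrics")
  cd <- as.data.frame(SummarizedExperiment::colData(cm))
  df <- data.frame(
    y = as.numeric(a[metric, ]),
    prot_num = as.numeric(cd$protected),
    effort = cd$effort,
    richness = if ("species_richness" %in% rownames(a))
      as.numeric(a["species_richness", ]) else NA_real_,
    network = factor(cd$network_id),
    elevation = as.numeric(scale(cd$elevation)),
    remoteness = as.numeric(scale(cd$remoteness)),
    land_cover = factor(cd$land_cover),
    row.names = colnames(a))
  drop <- is.na(df$y)
  if (any(drop)) .pwLog(sum(drop), " cell(s) dropped: missing ", metric)
  df <- df[!drop, , drop = FALSE]
  df$network <- droplevels(df$network)
  if (nlevels(df$network) < 2)
    stop("fewer than 2 PA networks: refusing to fit random slopes")
  const <- tapply(df$prot_num, df$network, function(p) length(unique(p)) == 1)
  if (any(const))
    .pwLog("protection constant within network(s): ",
           paste(names(const)[const], collapse = ", "), level = "warn")
  attr(df, "metric") <- metric
  attr(df, "constant_protection") <- names(const)[const]
  df
}

.gamFamily <- function(family) {
  switch(family,
         gaussian = stats::gaussian(),
         nb = mgcv::nb(),
         quasibinomial_log = stats::quasibinomial(link = "log"),
         stop("unknown family: ", family))
}

#' Fit the stage-1 protection-effect model for one metric
#'
#' A generalized additive mixed model: metric ~ protection status +
#' s(survey effort) + s(species richness) + random intercepts per PA network
#' and per land-cover type, random protection slopes per network (the
#' variable-slope terms of interest), and random elevation and remoteness
#' slopes per network to absorb the placement bias of reserves. Smooths are
#' penalized thin-plate splines and all variance components are estimated by
#' REML. Per-network effects are reported as the overall effect plus the
#' conditional (posterior-mean) deviation, with conditional 95\% CIs from
#' the fit's posterior covariance; a network deviates significantly when the
#' overall effect lies outside its CI.
#'
#' @param design data.frame from \code{\link{buildDesign}}.
#' @param family family label (see \code{\link{familyForMetric}}).
#' @param richness_smooth include the richness smooth (disable when the
#'   response is species richness).
#' @param env_slopes include the per-network elevation and remoteness random
#'   slopes.
#' @param k basis dimension of the penalized smooths.
#' @param metric metric name carried on the result.
#' @param engine \code{"gam"} (exact REML) or \code{"bam"} (fast fREML with
#'   discretized covariates; numerically equivalent on these designs and
#'   much faster on large simulations). Quasi-likelihood families always use
#'   \code{gam}.
#' @return a \linkS4class{Stage1Result}.
#' @export
fitMetricModel <- function(design, family = "gaussian",
                           richness_smooth = TRUE, env_slopes = TRUE,
                           k = 10, metric = attr(design, "metric") %||% "metric",
                           engine = c("gam", "bam")) {
  engine <- match.arg(engine)
  if (family == "quasibinomial_log") engine <- "gam"
  terms <- c("prot_num")
  ke <- min(k, max(3, length(unique(design$effort)) - 1))
  terms <- c(terms, sprintf("s(effort, k = %d)", ke))
  if (richness_smooth && length(unique(design$richness)) > 3 &&
      !anyNA(design$richness)) {
    kr <- min(k, max(3, length(unique(design$richness)) - 1))
    terms <- c(terms, sprintf("s(richness, k = %d)", kr))
  }
  terms <- c(terms, "s(network, bs = 're')",
             "s(prot_num, network, bs = 're')")
  if (env_slopes && sd(design$elevation) > 0)
    terms <- c(terms, "s(elevation, network, bs = 're')")
  if (env_slopes && sd(design$remoteness) > 0)
    terms <- c(terms, "s(remoteness, network, bs = 're')")
  if (nlevels(droplevels(design$land_cover)) >= 2) {
    design$land_cover <- droplevels(design$land_cover)
    terms <- c(terms, "s(land_cover, bs = 're')")
  }
  fml <- as.formula(paste("y ~", paste(terms, collapse = " + ")))
  m <- tryCatch(
    if (engine == "bam")
      mgcv::bam(fml, data = design, family = .gamFamily(family),
                method = "fREML", discrete = TRUE)
    else
      mgcv::gam(fml, data = design, family = .gamFamily(family),
                method = "REML"),
    error = function(e) e)
  if (inherits(m, "error") || !isTRUE(m$converged)) {
    diag <- if (inherits(m, "error")) conditionMessage(m) else "not converged"
    stop(structure(class = c("pawebs_convergence_error", "error", "condition"),
                   list(message = paste0("stage-1 fit failed for ", metric,
                                         ": ", diag),
                        call = sys.call(), metric = metric, diagnostics = diag)))
  }
  b <- coef(m)
  V <- m$Vp
  dimnames(V) <- list(names(b), names(b))
  beta <- unname(b["prot_num"])
  se <- sqrt(V["prot_num", "prot_num"])
  sm <- Filter(function(s) setequal(s$term, c("prot_num", "network")),
               m$smooth)[[1]]
  idx <- sm$first.para:sm$last.para
  dev <- unname(b[idx])
  var_dev <- diag(V)[idx]
  cov_dev <- V[idx, "prot_num"]
  beta_i <- beta + dev
  se_i <- sqrt(pmax(0, se^2 + var_dev + 2 * cov_dev))
  ne <- data.frame(
    network_id = levels(design$network),
    beta_i = beta_i, se_i = se_i,
    ci_lo = beta_i - 1.96 * se_i, ci_hi = beta_i + 1.96 * se_i,
    stringsAsFactors = FALSE)
  res <- methods::new("Stage1Result", metric = metric, family = family,
                      beta0 = unname(b["(Intercept)"]), beta = beta, se = se,
                      ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
                      network_effects = ne, converged = TRUE, model = m)
  res@network_effects$significant <- classifySignificance(res)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify per-network deviations from the overall protection effect
#'
#' A network's effect differs significantly from the overall effect when the
#' overall point estimate falls outside the network's conditional 95\% CI;
#' a CI touching the estimate exactly counts as overlap (not significant).
#'
#' @param result a \linkS4class{Stage1Result}.
#' @return logical vector along the networks.
#' @export
classifySignificance <- function(result) {
  ne <- result@network_effects
  result@beta < ne$ci_lo | result@beta > ne$ci_hi
}

#' Fit the stage-1 model for every metric
#'
#' @param cm a \linkS4class{CellMetrics}.
#' @param metrics metric names; default all rows of \code{cm}.
#' @param family_overrides optional named overrides for
#'   \code{\link{familyForMetric}}.
#' @param env_slopes,engine passed to \code{\link{fitMetricModel}}.
#' @return named list of \linkS4class{Stage1Result}.
#' @export
fitStage1 <- function(cm, metrics = rownames(cm), family_overrides = NULL,
                      env_slopes = TRUE, engine = "gam") {
  res <- lapply(metrics, function(mt) {
    design <- buildDesign(cm, mt)
    fitMetricModel(design, family = familyForMetric(mt, family_overrides),
                   richness_smooth = mt != "species_richness",
                   env_slopes = env_slopes, metric = mt, engine = engine)
  })
  names(res) <- metrics
  res
}

#' Tabulate stage-1 results
#'
#' \code{stage1Summary} returns one row per metric (overall effect);
#' \code{stage1NetworkTable} one row per metric and network (the
#' histogram-ready long format).
#'
#' @param results list of \linkS4class{Stage1Result} from
#'   \code{\link{fitStage1}}.
#' @return a data.frame.
#' @export
stage1Summary <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    metric = r@metric, family = r@family, beta = r@beta, se = r@se,
    ci_lo = r@ci_lo, ci_hi = r@ci_hi,
    n_networks = nrow(r@network_effects),
    n_significant = sum(r@network_effects$significant),
    stringsAsFactors = FALSE)))
}

#' @rdname stage1Summary
#' @export
stage1NetworkTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    ne <- r@network_effects
    ne$metric <- r@metric
    ne$beta <- r@beta
    ne[, c("metric", "network_id", "beta", "beta_i", "se_i", "ci_lo",
           "ci_hi", "significant")]
  }))
}
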