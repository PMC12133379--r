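#' @include AllClasses.R
NULL

#' Accessors for pawebs classes
#'
#' \code{mwSpecies} and \code{mwEdges} return the species trait table and the
#' directed consumer-to-resource edge list of a \linkS4class{Metaweb} or
#' \linkS4class{LocalFoodWeb}; \code{nSpecies} and \code{nLinks} their sizes;
#' \code{speciesRoles} the basal / intermediate / top partition of a local
#' web; \code{networkTable} and \code{cellMembership} the two tables of a
#' \linkS4class{PANetworkSet}.
#'
#' @param x an object.
#' @return the corresponding table or count.
#' @name pawebs-accessors
NULL

#' @rdname pawebs-accessors
#' @export
setGeneric("mwSpecies", function(x) standardGeneric("mwSpecies"))
#' @rdname pawebs-accessors
#' @export
setGeneric("mwEdges", function(x) standardGeneric("mwEdges"))
#' @rdname pawebs-accessors
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))
#' @rdname pawebs-accessors
#' @export
setGeneric("nLinks", function(x) standardGeneric("nLinks"))
#' @rdname pawebs-accessors
#' @export
setGeneric("speciesRoles", function(x) standardGeneric("speciesRoles"))
#' @rdname pawebs-accessors
#' @export
setGeneric("networkTable", function(x) standardGeneric("networkTable"))
#' @rdname pawebs-accessors
#' @export
setGeneric("cellMembership", function(x) standardGeneric("cellMembership"))

#' @rdname pawebs-accessors
setMethod("mwSpecies", "Metaweb", function(x) x@species)
#' @rdname pawebs-accessors
setMethod("mwEdges", "Metaweb", function(x) x@edges)
#' @rdname pawebs-accessors
setMethod("nSpecies", "Metaweb", function(x) nrow(x@species))
#' @rdname pawebs-accessors
setMethod("nLinks", "Metaweb", function(x) nrow(x@edges))
#' @rdname pawebs-accessors
setMethod("mwEdges", "LocalFoodWeb", function(x) x@edges)
#' @rdname pawebs-accessors
setMethod("nSpecies", "LocalFoodWeb", function(x) length(x@species))
#' @rdname pawebs-accessors
setMethod("nLinks", "LocalFoodWeb", function(x) nrow(x@edges))
#' @rdname pawebs-accessors
setMethod("speciesRoles", "LocalFoodWeb", function(x) x@roles)
#' @rdname pawebs-accessors
setMethod("networkTable", "PANetworkSet", function(x) x@networks)
#' @rdname pawebs-accessors
setMethod("cellMembership", "PANetworkSet", function(x) x@membership)

setMethod("show", "Metaweb", function(object) {
  cat(sprintf("Metaweb: %d species, %d trophic links (connectance %.3f)\n",
              nSpecies(object), nLinks(object),
              if (nSpecies(object)) nLinks(object) / nSpecies(object)^2 else NA))
})

setMethod("show", "LocalFoodWeb", function(object) {
  r <- table(factor(object@roles, c("basal", "intermediate", "top")))
  cat(sprintf(
    "LocalFoodWeb [%s]: %d species, %d links (basal %d / interm %d / top %d)\n",
    object@cell_id, nSpecies(object), nLinks(object), r[1], r[2], r[3]))
})

setMethod("show", "PANetworkSet", function(object) {
  m <- object@membership
  cat(sprintf("PANetworkSet: %d networks, %d cells (%d protected)\n",
              nrow(object@networks), nrow(m),
              sum(m$status == "protected")))
})

setMethod("show", "Stage1Result", function(object) {
  cat(sprintf(
    "Stage1Result [%s, %s]: beta = %.4f (95%% CI %.4f..%.4f), %d networks, %d deviating\n",
    object@metric, object@family, object@beta, object@ci_lo, object@ci_hi,
    nrow(object@network_effects), sum(object@network_effects$significant)))
})

setMethod("show", "Stage2Result", function(object) {
  cat(sprintf("Stage2Result [%s]: %d driver(s) selected, adj. R2 = %.3f (n = %d)\n",
              object@metric, length(object@selected), object@adj_r2,
              as.integer(object@n)))
  if (length(object@selected))
    cat("  drivers:", paste(object@selected, collapse = ", "), "\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld: %d species metaweb, %d cells, %d PAs, %d occurrence records\n",
    nSpecies(object@metaweb), nrow(object@cells), nrow(object@pas),
    nrow(object@occurrences)))
})
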