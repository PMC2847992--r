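#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a package object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(object, ...) standardGeneric("abundances"))

#' @rdname accessors
#' @export
setGeneric("fragmentId", function(object, ...) standardGeneric("fragmentId"))

#' @rdname accessors
#' @export
setGeneric("nCarbons", function(object, ...) standardGeneric("nCarbons"))

#' @rdname accessors
#' @export
setGeneric("fluxes", function(object, ...) standardGeneric("fluxes"))

#' @rdname accessors
#' @export
setGeneric("normalizedFluxes", function(object, ...)
  standardGeneric("normalizedFluxes"))

#' @rdname accessors
#' @export
setGeneric("reactionIds", function(object, ...) standardGeneric("reactionIds"))

#' @rdname accessors
#' @export
setGeneric("metaboliteIds", function(object, ...)
  standardGeneric("metaboliteIds"))

#' @rdname accessors
#' @export
setGeneric("stoichiometryMatrix", function(object, ...)
  standardGeneric("stoichiometryMatrix"))

#' @rdname accessors
#' @export
setGeneric("isReversible", function(object, ...)
  standardGeneric("isReversible"))

#' @rdname accessors
#' @export
setGeneric("edges", function(object, ...) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("universe", function(object, ...) standardGeneric("universe"))

#' Degree of respiration
#'
#' The uptake-normalized net flux from mitochondrial malate to mitochondrial
#' oxaloacetate, the statistic used to quantify respiratory TCA-cycle
#' activity across carbon sources.
#'
#' @param object a [FluxSolution-class] (other inputs may gain methods).
#' @param ... passed to methods.
#' @export
setGeneric("degreeOfRespiration", function(object, ...)
  standardGeneric("degreeOfRespiration"))

#' @rdname accessors
setMethod("abundances", "MassIsotopomerDistribution",
          function(object, ...) object@abundances)

#' @rdname accessors
setMethod("fragmentId", "MassIsotopomerDistribution",
          function(object, ...) object@fragmentId)

#' @rdname accessors
setMethod("nCarbons", "MassIsotopomerDistribution",
          function(object, ...) object@nCarbons)

#' @rdname accessors
setMethod("fluxes", "FluxSolution", function(object, ...) object@v)

#' @rdname accessors
setMethod("normalizedFluxes", "FluxSolution",
          function(object, ...) object@vNormalized)

#' @rdname accessors
setMethod("reactionIds", "StoichiometricModel",
          function(object, ...) colnames(object@stoichiometry))

#' @rdname accessors
setMethod("metaboliteIds", "StoichiometricModel",
          function(object, ...) rownames(object@stoichiometry))

#' @rdname accessors
setMethod("stoichiometryMatrix", "StoichiometricModel",
          function(object, ...) object@stoichiometry)

#' @rdname accessors
setMethod("isReversible", "StoichiometricModel", function(object, ...) {
  structure(object@reversible, names = colnames(object@stoichiometry))
})

#' @rdname accessors
setMethod("reactionIds", "FluxSolution",
          function(object, ...) reactionIds(object@model))

#' @rdname accessors
setMethod("edges", "RegulatoryNetwork", function(object, ...) object@edges)

#' @rdname accessors
setMethod("universe", "RegulatoryNetwork",
          function(object, ...) object@universe)

setMethod("show", "MassIsotopomerDistribution", function(object) {
  cat("MassIsotopomerDistribution '", object@fragmentId, "' (",
      object@nCarbons, " backbone C)\n", sep = "")
  a <- round(object@abundances, 4)
  names(a) <- paste0("m", seq_along(a) - 1L)
  print(a)
})

setMethod("show", "StoichiometricModel", function(object) {
  S <- object@stoichiometry
  cat("StoichiometricModel: ", nrow(S), " metabolites (",
      sum(object@balanced), " balanced), ", ncol(S), " reactions (",
      sum(object@reversible), " reversible)\n", sep = "")
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution on", ncol(object@model@stoichiometry), "reactions;",
      "weighted residual", format(object@residual, digits = 4), "\n")
  if (!is.na(object@normalizedTo))
    cat("  normalized to |", object@normalizedTo, "| x scale ",
        object@scale, "\n", sep = "")
})

setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork:", length(unique(object@edges$tf)), "TFs,",
      nrow(object@edges), "edges, universe of",
      length(object@universe), "enzymes\n")
})
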