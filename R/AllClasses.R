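#' @import methods
NULL

#' Mass-isotopomer distribution of a carbon fragment
#'
#' Fractional abundances of the mass channels m+0, m+1, ... of a molecular
#' fragment, the currency of all 13C-labeling computations.  The vector may be
#' longer than \code{nCarbons + 1} when the measured ion carries non-backbone
#' atoms that can contribute mass shifts.
#'
#' @slot fragmentId single character identifier (e.g. \code{"Asp_f302"}).
#' @slot nCarbons number of backbone carbon atoms (>= 1).
#' @slot abundances numeric vector m0..mk, non-negative, summing to 1.
#'
#' @seealso [correctMDV()], [estimateMixingFraction()]
#' @exportClass MassIsotopomerDistribution
setClass("MassIsotopomerDistribution",
  representation(
    fragmentId = "character",
    nCarbons   = "integer",
    abundances = "numeric"
  )
)

setValidity("MassIsotopomerDistribution", function(object) {
  msg <- character()
  if (length(object@fragmentId) != 1L)
    msg <- c(msg, "fragmentId must be a single string")
  if (length(object@nCarbons) != 1L || is.na(object@nCarbons) ||
      object@nCarbons < 1L)
    msg <- c(msg, "nCarbons must be a single integer >= 1")
  a <- object@abundances
  if (length(a) < object@nCarbons + 1L)
    msg <- c(msg, "abundances must cover at least m0..m(nCarbons)")
  if (any(a < -1e-12))
    msg <- c(msg, "abundances must be non-negative")
  if (abs(sum(a) - 1) > 1e-9)
    msg <- c(msg, "abundances must sum to 1 (within 1e-9)")
  if (length(msg)) msg else TRUE
})

#' Construct a MassIsotopomerDistribution
#'
#' @param fragmentId fragment identifier.
#' @param nCarbons number of backbone carbons.
#' @param abundances numeric vector of mass-channel abundances m0..mk; must be
#'   non-negative.  When \code{normalize = TRUE} (default) the vector is
#'   rescaled to sum to 1, as measured GC-MS intensities are only relative.
#' @param normalize logical; rescale to unit sum.
#' @return A [MassIsotopomerDistribution-class] object.
#' @examples
#' mdv(c(0.8, 0, 0, 0.2), nCarbons = 3, fragmentId = "pyr")
#' @export
mdv <- function(abundances, nCarbons = length(abundances) - 1L,
                fragmentId = "fragment", normalize = TRUE) {
  if (any(abundances < -1e-12))
    stop("abundances must be non-negative")
  abundances <- pmax(abundances, 0)
  s <- sum(abundances)
  if (normalize) {
    if (s <= 0) stop("abundances sum to zero; cannot normalize")
    abundances <- abundances / s
  }
  new("MassIsotopomerDistribution",
      fragmentId = as.character(fragmentId),
      nCarbons = as.integer(nCarbons),
      abundances = abundances)
}

#' Stoichiometric model of central metabolism
#'
#' Compartmented metabolites (cytosolic \code{_cyt}, mitochondrial \code{_mit},
#' external \code{_ext}) and reactions with stoichiometric coefficients.
#' Unbalanced metabolites (external pools) are not constrained by mass
#' balance; a reaction touching exactly one balanced metabolite acts as an
#' exchange/drain.
#'
#' @slot stoichiometry numeric matrix, metabolites x reactions.
#' @slot balanced logical per metabolite; FALSE marks external pools.
#' @slot compartment character per metabolite.
#' @slot reversible logical per reaction.
#'
#' @seealso [stoichiometricModel()], [solveNetFluxes()], [yeastCentralModel()]
#' @exportClass StoichiometricModel
setClass("StoichiometricModel",
  representation(
    stoichiometry = "matrix",
    balanced      = "logical",
    compartment   = "character",
    reversible    = "logical"
  )
)

setValidity("StoichiometricModel", function(object) {
  S <- object@stoichiometry
  msg <- character()
  if (is.null(rownames(S)) || is.null(colnames(S)))
    msg <- c(msg, "stoichiometry must have metabolite row names and reaction column names")
  if (length(object@balanced) != nrow(S))
    msg <- c(msg, "balanced flag must match the number of metabolites")
  if (length(object@compartment) != nrow(S))
    msg <- c(msg, "compartment must match the number of metabolites")
  if (length(object@reversible) != ncol(S))
    msg <- c(msg, "reversible flag must match the number of reactions")
  if (!length(msg)) {
    nActive <- colSums(S[object@balanced, , drop = FALSE] != 0)
    if (!any(nActive == 1L) && !any(!object@balanced))
      msg <- c(msg, "model must contain at least one exchange reaction")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StoichiometricModel from a reaction list
#'
#' @param reactions named list; each element is a list with components
#'   \code{stoich} (named numeric, negative = consumed) and optional
#'   \code{reversible} (default FALSE).
#' @param unbalanced character vector of metabolite ids exempt from mass
#'   balance (external pools); metabolites are otherwise balanced.
#' @param compartments optional named character vector metabolite -> tag; by
#'   default inferred from an id suffix (\code{_cyt}, \code{_mit},
#'   \code{_ext}).
#' @return A [StoichiometricModel-class].
#' @examples
#' m <- stoichiometricModel(list(
#'   up = list(stoich = c(A = 1)),
#'   r1 = list(stoich = c(A = -1, B = 1)),
#'   out = list(stoich = c(B = -1))))
#' @export
stoichiometricModel <- function(reactions, unbalanced = character(),
                                compartments = NULL) {
  mets <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  S <- matrix(0, nrow = length(mets), ncol = length(reactions),
              dimnames = list(mets, names(reactions)))
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoich
    if (!all(names(st) %in% mets))
      stop("reaction ", names(reactions)[j], " references undeclared metabolites")
    S[names(st), j] <- st
  }
  if (is.null(compartments)) {
    compartments <- ifelse(grepl("_mit$", mets), "mit",
                    ifelse(grepl("_ext$", mets), "ext", "cyt"))
    names(compartments) <- mets
  }
  rev <- vapply(reactions, function(r) isTRUE(r$reversible), logical(1))
  new("StoichiometricModel",
      stoichiometry = S,
      balanced = !(mets %in% unbalanced),
      compartment = unname(compartments[mets]),
      reversible = unname(rev))
}

#' Net-flux solution of a constrained stoichiometric system
#'
#' @slot model the [StoichiometricModel-class] that was solved.
#' @slot v named net fluxes, mmol/gCDW/h.
#' @slot vNormalized fluxes normalized to the uptake rate (empty until
#'   [normalizeFluxes()] is called).
#' @slot residual weighted sum of squared measurement deviations.
#' @slot normalizedTo id of the uptake reaction used for normalization, or
#'   \code{NA}.
#' @slot scale normalization scale factor.
#' @exportClass FluxSolution
setClass("FluxSolution",
  representation(
    model        = "StoichiometricModel",
    v            = "numeric",
    vNormalized  = "numeric",
    residual     = "numeric",
    normalizedTo = "character",
    scale        = "numeric"
  )
)

setValidity("FluxSolution", function(object) {
  S <- object@model@stoichiometry
  msg <- character()
  if (length(object@v) != ncol(S))
    msg <- c(msg, "flux vector length must match the number of reactions")
  else {
    imbalance <- S[object@model@balanced, , drop = FALSE] %*% object@v
    if (length(imbalance) && max(abs(imbalance)) > 1e-8)
      msg <- c(msg, "mass balance violated at a balanced metabolite")
    bad <- !object@model@reversible & object@v < -1e-9
    if (any(bad))
      msg <- c(msg, paste("negative flux through irreversible reaction(s):",
                          paste(colnames(S)[bad], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Transcription-factor regulatory network
#'
#' A literature-curated edge list (TF -> target) together with the universe of
#' investigated enzymes, mirroring a yeastract-style export.
#'
#' @slot edges data.frame with columns \code{tf}, \code{target},
#'   \code{evidence}.
#' @slot universe character vector of investigated enzyme ids.
#' @seealso [regulatoryNetwork()], [filterNetwork()], [rankTFs()]
#' @exportClass RegulatoryNetwork
setClass("RegulatoryNetwork",
  representation(edges = "data.frame", universe = "character"))

setValidity("RegulatoryNetwork", function(object) {
  msg <- character()
  if (!all(c("tf", "target", "evidence") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns tf, target, evidence")
  else if (anyDuplicated(object@edges[, c("tf", "target", "evidence")]))
    msg <- c(msg, "duplicate edges are not allowed")
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a RegulatoryNetwork
#'
#' @param tf,target character vectors of equal length (one edge per entry).
#' @param evidence edge evidence codes (recycled); the curation filter keeps
#'   \code{"literature"} edges.
#' @param universe enzyme universe the enrichment is computed over.
#' @return A [RegulatoryNetwork-class].
#' @export
regulatoryNetwork <- function(tf, target, evidence = "literature",
                              universe = sort(unique(target))) {
  edges <- unique(data.frame(tf = as.character(tf),
                             target = as.character(target),
                             evidence = as.character(evidence),
                             stringsAsFactors = FALSE))
  new("RegulatoryNetwork", edges = edges, universe = as.character(universe))
}
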