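#' Flux constraint set
#'
#' Measurements and labeling-derived constraints used to pin down the net
#' fluxes of a stoichiometric model: measured uptake/secretion/growth rates
#' with SDs enter the weighted least squares, flux-ratio constraints enter
#' as soft linear equations a.v = 0, and ratio ranges as hard linear
#' inequalities l <= a.v <= u.
#'
#' @param measured data.frame with columns \code{reaction}, \code{value},
#'   \code{sd} (sd > 0).
#' @param ratios optional list; each element a list with \code{coef}
#'   (named numeric over reactions), \code{value} (default 0) and
#'   \code{sd}.
#' @param ranges optional list; each element a list with \code{coef},
#'   \code{lower}, \code{upper}.
#' @return list of class \code{"FluxConstraintSet"}.
#' @examples
#' fluxConstraints(data.frame(reaction = "up", value = 1, sd = 0.05))
#' @export
fluxConstraints <- function(measured, ratios = list(), ranges = list()) {
  stopifnot(all(c("reaction", "value", "sd") %in% names(measured)))
  if (any(measured$sd <= 0)) stop("measurement sds must be > 0")
  for (r in ratios) {
    if (is.null(r$coef)) stop("each ratio constraint needs a coef vector")
    if (is.null(r$sd) || r$sd <= 0) stop("each ratio constraint needs sd > 0")
  }
  for (r in ranges) {
    if (is.null(r$coef)) stop("each range constraint needs a coef vector")
    if (r$lower > r$upper) stop("range bounds must be ordered")
  }
  structure(list(measured = measured, ratios = ratios, ranges = ranges),
            class = "FluxConstraintSet")
}

# orthonormal basis of the null space of a matrix (svd based)
.nullspace <- function(A, tol = 1e-10) {
  if (nrow(A) == 0L) return(diag(ncol(A)))
  sv <- svd(A, nu = 0, nv = ncol(A))
  keep <- sv$d < tol * max(sv$d, 1)
  r <- sum(sv$d >= tol * max(sv$d, 1))
  if (r == ncol(A)) return(matrix(0, ncol(A), 0))
  sv$v[, (r + 1L):ncol(A), drop = FALSE]
}

# least distance programming: min ||w|| s.t. E w >= f  (Lawson & Hanson)
.ldp <- function(E, f, tol = 1e-10) {
  p <- ncol(E)
  M <- rbind(t(E), matrix(f, nrow = 1L))
  b <- c(numeric(p), 1)
  fit <- nnls(M, b)
  r <- drop(M %*% fit$x - b)
  if (sqrt(sum(r^2)) < tol)
    return(list(w = NULL, feasible = FALSE))
  list(w = -r[seq_len(p)] / r[p + 1L], feasible = TRUE)
}

# least squares with linear inequality constraints:
# min ||C z - d|| s.t. G z >= h  (LSI -> LDP transformation)
.lsi <- function(C, d, G, h) {
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) stop("internal: LSI requires full-rank C")
  R <- qr.R(qrC)[seq_len(ncol(C)), , drop = FALSE]
  f1 <- qr.qty(qrC, d)[seq_len(ncol(C))]
  if (nrow(G) == 0L) return(backsolve(R, f1))
  Rinv <- backsolve(R, diag(ncol(C)))
  E <- G %*% Rinv
  f <- h - drop(E %*% f1)
  sol <- .ldp(E, f)
  if (!sol$feasible) return(NULL)
  drop(Rinv %*% (sol$w + f1))
}

#' Solve a constrained stoichiometric system for net fluxes
#'
#' Weighted least squares over the flux space: mass balance S v = 0 at
#' every balanced metabolite is imposed exactly (null-space
#' parametrization), measured rates and flux-ratio equations are fit by
#' minimizing the weighted sum of squares sum(((measured - predicted)/sd)^2),
#' and irreversibility bounds plus ratio ranges are enforced as hard
#' inequality constraints (solved exactly via the least-squares-with-
#' inequalities transformation to non-negative least squares).
#'
#' @param model a [StoichiometricModel-class].
#' @param constraints a [fluxConstraints()] set.
#' @param onRankDeficient what to do when the measurements do not pin down
#'   every degree of freedom: \code{"error"} (default; reports the free
#'   flux directions) or \code{"minnorm"} (returns the minimum-norm
#'   solution, appropriate for closed/zero-flux sanity cases).
#' @return a [FluxSolution-class].
#' @export
solveNetFluxes <- function(model, constraints,
                           onRankDeficient = c("error", "minnorm")) {
  onRankDeficient <- match.arg(onRankDeficient)
  stopifnot(is(model, "StoichiometricModel"),
            inherits(constraints, "FluxConstraintSet"))
  S <- model@stoichiometry
  rxns <- colnames(S)
  N <- .nullspace(S[model@balanced, , drop = FALSE])
  if (ncol(N) == 0L)
    stop("model admits no nonzero balanced flux distribution")

  # assemble measurement rows over v
  meas <- constraints$measured
  bad <- setdiff(meas$reaction, rxns)
  if (length(bad)) stop("measured reaction(s) not in model: ",
                        paste(bad, collapse = ", "))
  A <- matrix(0, nrow(meas) + length(constraints$ratios), length(rxns),
              dimnames = list(NULL, rxns))
  b <- numeric(nrow(A))
  wt <- numeric(nrow(A))
  for (i in seq_len(nrow(meas))) {
    A[i, meas$reaction[i]] <- 1
    b[i] <- meas$value[i]
    wt[i] <- 1 / meas$sd[i]
  }
  for (k in seq_along(constraints$ratios)) {
    rc <- constraints$ratios[[k]]
    i <- nrow(meas) + k
    if (!all(names(rc$coef) %in% rxns))
      stop("ratio constraint ", k, " references unknown reaction(s): ",
           paste(setdiff(names(rc$coef), rxns), collapse = ", "))
    A[i, names(rc$coef)] <- rc$coef
    b[i] <- if (is.null(rc$value)) 0 else rc$value
    wt[i] <- 1 / rc$sd
  }
  C <- (A %*% N) * wt
  d <- b * wt

  # rank decided on singular values with an absolute floor: weighting can
  # leave numerically tiny but nonzero entries in unconstrained directions
  svC <- svd(C)$d
  rankC <- sum(svC > 1e-9 * max(svC[1], 1))
  if (rankC < ncol(N)) {
    if (onRankDeficient == "error") {
      svF <- svd(C, nu = 0, nv = ncol(C))
      dpad <- c(svF$d, numeric(ncol(C) - length(svF$d)))
      free <- svF$v[, dpad <= 1e-9 * max(dpad[1], 1), drop = FALSE]
      dirs <- N %*% free
      lab <- apply(dirs, 2, function(col) {
        nz <- which(abs(col) > 1e-6)
        paste(sprintf("%+.2f %s", col[nz], rxns[nz]), collapse = " ")
      })
      stop("underdetermined system: ", ncol(N) - rankC,
           " free flux direction(s):\n  ", paste(lab, collapse = "\n  "))
    }
    z <- .pinvSolve(C, d)
    v <- drop(N %*% z)
    if (any(!model@reversible & v < -1e-9))
      stop("minimum-norm solution violates irreversibility; supply more constraints")
  } else {
    # inequality constraints: irreversibility and ratio ranges
    G <- N[!model@reversible, , drop = FALSE]
    h <- numeric(nrow(G))
    for (rg in constraints$ranges) {
      a <- numeric(length(rxns)); names(a) <- rxns
      a[names(rg$coef)] <- rg$coef
      aN <- drop(a %*% N)
      if (is.finite(rg$lower)) { G <- rbind(G, aN); h <- c(h, rg$lower) }
      if (is.finite(rg$upper)) { G <- rbind(G, -aN); h <- c(h, -rg$upper) }
    }
    z <- .lsi(C, d, G, h)
    if (is.null(z)) {
      zLS <- .pinvSolve(C, d)
      viol <- h - drop(G %*% zLS)
      worst <- which.max(viol)
      stop("infeasible constraint set; most violated inequality index ",
           worst, " (violation ", signif(viol[worst], 3), ")")
    }
    v <- drop(N %*% z)
  }
  names(v) <- rxns
  v[!model@reversible & v < 0 & v > -1e-9] <- 0   # numerical dust
  residual <- sum((drop(A %*% v) - b)^2 * wt^2)
  new("FluxSolution", model = model, v = v,
      vNormalized = numeric(0), residual = residual,
      normalizedTo = NA_character_, scale = 1)
}

.pinvSolve <- function(C, d, tol = 1e-10) {
  sv <- svd(C)
  keep <- sv$d > tol * max(sv$d, 1)
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], d)) / sv$d[keep]))
}

#' Normalize fluxes to the substrate uptake rate
#'
#' Divides every net flux by the absolute uptake flux (times a configurable
#' scale) so that flux distributions on substrates with very different
#' overall metabolic rates become directly comparable.
#'
#' @param sol a [FluxSolution-class].
#' @param uptakeReaction id of the substrate uptake reaction.
#' @param scale scale factor (default 1; use 100 for percent-of-uptake).
#' @return the solution with \code{normalizedFluxes()} populated.
#' @export
normalizeFluxes <- function(sol, uptakeReaction, scale = 1) {
  stopifnot(is(sol, "FluxSolution"))
  v <- sol@v
  if (!uptakeReaction %in% names(v))
    stop("uptake reaction not in model: ", uptakeReaction)
  up <- abs(v[[uptakeReaction]])
  if (up == 0) stop("cannot normalize: uptake flux is zero")
  sol@vNormalized <- v / up * scale
  sol@normalizedTo <- uptakeReaction
  sol@scale <- scale
  sol
}

#' @describeIn degreeOfRespiration the uptake-normalized net flux through
#'   the mitochondrial malate -> oxaloacetate reaction (floored at zero).
#'   The solution must have been normalized with [normalizeFluxes()] first.
#' @param reaction id of the mitochondrial malate dehydrogenase reaction.
#' @export
setMethod("degreeOfRespiration", "FluxSolution",
  function(object, reaction = "mdh_mit", ...) {
    if (!reaction %in% reactionIds(object))
      stop("model lacks the mitochondrial malate->oxaloacetate reaction '",
           reaction, "'")
    if (!length(object@vNormalized))
      stop("normalize the solution with normalizeFluxes() first")
    max(object@vNormalized[[reaction]], 0)
  })

#' Compact stoichiometric model of central yeast carbon metabolism
#'
#' A deliberately small (~25 reaction) model: lumped glycolysis and pentose
#' phosphate pathway, the pyruvate branch point (decarboxylation to
#' acetaldehyde -> ethanol/acetate, transport into the mitochondrion,
#' carboxylation to oxaloacetate), cytosolic and mitochondrial oxaloacetate
#' and malate pools, a lumped TCA cycle, glycerol/ethanol/acetate/CO2
#' exchange and a biomass drain with configurable precursor coefficients.
#' It is a package-authored stand-in for a full genome-scale model: carbon
#' balanced at the lumped level and sufficient to carry uptake, secretion,
#' growth and ratio constraints into a respiratory-flux estimate.
#'
#' The degree-of-respiration reaction is \code{mdh_mit}
#' (mal_mit -> oaa_mit).
#'
#' @param biomass named numeric vector of precursor drain coefficients in
#'   mmol per g CDW (defaults follow standard yeast biomass composition,
#'   rounded; they are configurable, not measured values).
#' @param substrate \code{"glucose"} (hexose uptake feeding g6p) or
#'   \code{"pyruvate"} (uptake feeding cytosolic pyruvate).
#' @return a [StoichiometricModel-class].
#' @export
yeastCentralModel <- function(biomass = c(g6p_cyt = 0.9, p5p_cyt = 0.9,
                                          t3p_cyt = 0.3, pyr_cyt = 1.9,
                                          accoa_cyt = 0.9, akg_mit = 1.1,
                                          oaa_mit = 1.3),
                              substrate = c("glucose", "pyruvate")) {
  substrate <- match.arg(substrate)
  rxn <- list()
  if (substrate == "glucose") {
    rxn$uptake <- list(stoich = c(g6p_cyt = 1))
  } else {
    rxn$uptake <- list(stoich = c(pyr_cyt = 1))
  }
  rxn$ppp        <- list(stoich = c(g6p_cyt = -1, p5p_cyt = 1, co2_cyt = 1))
  rxn$p5p_t3p    <- list(stoich = c(p5p_cyt = -3, t3p_cyt = 5),
                         reversible = TRUE)      # carbon-lumped C5 -> C3
  rxn$glycolysis <- list(stoich = c(g6p_cyt = -1, t3p_cyt = 2),
                         reversible = TRUE)
  rxn$pyk        <- list(stoich = c(t3p_cyt = -1, pyr_cyt = 1))
  rxn$pck        <- list(stoich = c(oaa_cyt = -1, t3p_cyt = 1, co2_cyt = 1))
  rxn$pdc        <- list(stoich = c(pyr_cyt = -1, acd_cyt = 1, co2_cyt = 1))
  rxn$adh        <- list(stoich = c(acd_cyt = -1, etoh_cyt = 1),
                         reversible = TRUE)
  rxn$ald        <- list(stoich = c(acd_cyt = -1, ace_cyt = 1))
  rxn$acs        <- list(stoich = c(ace_cyt = -1, accoa_cyt = 1))
  rxn$glycerol   <- list(stoich = c(t3p_cyt = -1, glyc_cyt = 1))
  rxn$pyr_mit    <- list(stoich = c(pyr_cyt = -1, pyr_mit = 1))
  rxn$pdh        <- list(stoich = c(pyr_mit = -1, accoa_mit = 1, co2_mit = 1))
  rxn$pyc        <- list(stoich = c(pyr_cyt = -1, co2_cyt = -1, oaa_cyt = 1))
  rxn$oaa_mit_tr <- list(stoich = c(oaa_cyt = -1, oaa_mit = 1),
                         reversible = TRUE)
  rxn$mdh_cyt    <- list(stoich = c(oaa_cyt = -1, mal_cyt = 1),
                         reversible = TRUE)
  rxn$mal_mit_tr <- list(stoich = c(mal_cyt = -1, mal_mit = 1),
                         reversible = TRUE)
  rxn$cs         <- list(stoich = c(oaa_mit = -1, accoa_mit = -1, cit_mit = 1))
  rxn$idh        <- list(stoich = c(cit_mit = -1, akg_mit = 1, co2_mit = 1))
  rxn$tca_lump   <- list(stoich = c(akg_mit = -1, mal_mit = 1, co2_mit = 1))
  rxn$mdh_mit    <- list(stoich = c(mal_mit = -1, oaa_mit = 1))
  rxn$mae        <- list(stoich = c(mal_mit = -1, pyr_mit = 1, co2_mit = 1))
  rxn$etoh_ex    <- list(stoich = c(etoh_cyt = -1))
  rxn$ace_ex     <- list(stoich = c(ace_cyt = -1))
  rxn$glyc_ex    <- list(stoich = c(glyc_cyt = -1))
  rxn$co2_mit_tr <- list(stoich = c(co2_mit = -1, co2_cyt = 1))
  rxn$co2_ex     <- list(stoich = c(co2_cyt = -1), reversible = TRUE)
  rxn$biomass    <- list(stoich = -biomass)
  stoichiometricModel(rxn)
}

#' Flux solution as a table
#'
#' @param sol a [FluxSolution-class].
#' @return data.frame with reaction ids, net fluxes and (if computed)
#'   uptake-normalized fluxes.
#' @export
fluxTable <- function(sol) {
  stopifnot(is(sol, "FluxSolution"))
  out <- data.frame(reaction = reactionIds(sol), v = unname(sol@v))
  if (length(sol@vNormalized)) out$v_normalized <- unname(sol@vNormalized)
  out
}
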