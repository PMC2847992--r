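#' Estimate the mixing fraction of two converging fluxes
#'
#' A metabolite pool fed by two pathways carries a labeling pattern that is
#' the flux-weighted mixture of its precursors' patterns.  The fraction R
#' contributed by precursor A is estimated by bounded least squares on
#' \code{MDV_product ~ R * MDV_A + (1 - R) * MDV_B}: the closed-form
#' projection of the product onto the segment between the two precursor
#' MDVs, clipped to [0, 1].  The standard deviation comes from first-order
#' propagation of independent per-mass-channel measurement noise.
#'
#' @param product,precursorA,precursorB
#'   [MassIsotopomerDistribution-class] objects (or bare numeric MDVs) of
#'   equal length.
#' @param sdPerMass absolute SD assumed per mass channel of the product
#'   (default 0.005, typical for GC-MS fractional abundances).
#' @param label free-text description of the converging-flux node.
#' @return object of class \code{"FluxRatio"}: list with \code{value} (R in
#'   [0,1]), \code{sd}, \code{residual} (sum of squared deviations at the
#'   optimum) and \code{label}.
#' @examples
#' a <- mdv(c(0.8, 0, 0, 0.2)); b <- mdv(c(0.2, 0.3, 0.3, 0.2))
#' p <- mdv(0.5 * abundances(a) + 0.5 * abundances(b))
#' estimateMixingFraction(p, a, b)$value   # 0.5
#' @export
estimateMixingFraction <- function(product, precursorA, precursorB,
                                   sdPerMass = 0.005, label = "") {
  p <- if (is(product, "MassIsotopomerDistribution")) abundances(product) else product
  a <- if (is(precursorA, "MassIsotopomerDistribution")) abundances(precursorA) else precursorA
  b <- if (is(precursorB, "MassIsotopomerDistribution")) abundances(precursorB) else precursorB
  if (length(p) != length(a) || length(a) != length(b))
    stop("product and precursor MDVs must have equal length")
  d <- a - b
  nd2 <- sum(d^2)
  if (sqrt(nd2) < 1e-6)
    stop("unidentifiable: precursor labeling patterns are indistinguishable")
  R <- sum((p - b) * d) / nd2
  R <- min(max(R, 0), 1)
  fit <- R * a + (1 - R) * b
  residual <- sum((p - fit)^2)
  # Var(R) = sum_i (d_i / ||d||^2)^2 * sd^2 = sd^2 / ||d||^2
  sdR <- sdPerMass / sqrt(nd2)
  structure(list(value = R, sd = sdR, residual = residual, label = label),
            class = "FluxRatio")
}

#' Respiratory TCA flux from the anaplerosis/TCA split
#'
#' At the mitochondrial oxaloacetate node, the anaplerotic fraction R of the
#' flux into the TCA cycle equals the biosynthetic drain; the remaining
#' fraction (1 - R) cycles through the respiratory TCA reactions.  Given the
#' anaplerotic flux v_ana (mmol/g/h, from the biomass requirement for
#' oxaloacetate/2-oxoglutarate precursors), the respiratory TCA flux is
#' v_tca = v_ana * (1 - R) / R.  When the substrate uptake rate is
#' supplied, the uptake-normalized flux (the degree of respiration) is also
#' reported.
#'
#' @param R anaplerotic fraction of mitochondrial oxaloacetate, a
#'   \code{"FluxRatio"} or a number in (0, 1].
#' @param vAna anaplerotic flux, mmol/g/h, >= 0.
#' @param uptake substrate uptake rate, mmol/g/h (sign ignored); optional.
#' @param scale normalization scale factor for the degree of respiration
#'   (default 1; the published AU scale is not defined, so it stays
#'   configurable).
#' @return object of class \code{"RespirationEstimate"}: list with
#'   \code{vAna}, \code{vTca}, \code{R}, \code{degreeOfRespiration} (NA if
#'   no uptake given), \code{uptake}, \code{scale}.
#' @examples
#' tcaFluxFromSplit(0.2, vAna = 0.5)$vTca  # 2.0
#' @export
tcaFluxFromSplit <- function(R, vAna, uptake = NULL, scale = 1) {
  Rsd <- NA_real_
  if (inherits(R, "FluxRatio")) { Rsd <- R$sd; R <- R$value }
  if (vAna < 0) stop("vAna must be >= 0")
  if (R <= 0) {
    if (vAna > 0)
      stop("unidentifiable: R = 0 with positive anaplerotic flux implies infinite TCA flux")
    R <- NA_real_
  }
  vTca <- if (is.na(R)) 0 else vAna * (1 - R) / R
  degree <- if (!is.null(uptake)) {
    if (abs(uptake) == 0) stop("uptake rate must be nonzero")
    scale * vTca / abs(uptake)
  } else NA_real_
  structure(list(vAna = vAna, vTca = vTca, R = R, RSd = Rsd,
                 degreeOfRespiration = degree,
                 uptake = if (is.null(uptake)) NA_real_ else uptake,
                 scale = scale),
            class = "RespirationEstimate")
}

#' Standard deviation of the respiratory TCA flux
#'
#' Two conventions: \code{"propagate"} applies first-order error
#' propagation through v_tca = v_ana (1 - R)/R, i.e.
#' |dv_tca/dR| = v_ana / R^2 times the SD of R; \code{"flat20"} applies the
#' flat 20\% relative-SD convention used for respiratory TCA flux on
#' gluconeogenic substrates where only this one split is resolvable.
#'
#' @param estimate a \code{"RespirationEstimate"}.
#' @param RSd standard deviation of the ratio R (propagate mode; defaults
#'   to the SD stored in the estimate).
#' @param mode \code{"propagate"} or \code{"flat20"}.
#' @return list with \code{sdVTca} and \code{sdDegree} (NA when the
#'   estimate carries no uptake normalization).
#' @examples
#' est <- tcaFluxFromSplit(0.5, vAna = 1, uptake = 1)
#' propagateRatioSd(est, RSd = 0.05)$sdVTca    # 0.2
#' @export
propagateRatioSd <- function(estimate, RSd = NULL,
                             mode = c("propagate", "flat20")) {
  mode <- match.arg(mode)
  stopifnot(inherits(estimate, "RespirationEstimate"))
  if (mode == "flat20") {
    sdV <- 0.2 * abs(estimate$vTca)
    sdD <- if (is.na(estimate$degreeOfRespiration)) NA_real_
           else 0.2 * abs(estimate$degreeOfRespiration)
  } else {
    if (is.null(RSd)) RSd <- estimate$RSd
    if (is.na(RSd)) stop("no SD for R available; supply RSd")
    sdV <- abs(-estimate$vAna / estimate$R^2) * RSd
    sdD <- if (is.na(estimate$degreeOfRespiration)) NA_real_
           else estimate$scale * sdV / abs(estimate$uptake)
  }
  list(sdVTca = sdV, sdDegree = sdD, mode = mode)
}

#' Steady-state mitochondrial OAA labeling under repeated TCA turns
#'
#' The bundled worked configuration of the two-precursor mixing problem:
#' mitochondrial oxaloacetate is made either by anaplerosis (pyruvate
#' carboxylation; labeling = pyruvate pattern plus one unlabeled CO2
#' carbon) or by a turn of the TCA cycle (condensation with acetyl-CoA,
#' loss of two carbons).  The TCA-derived precursor pattern is itself a
#' function of the OAA pool, so it is computed as the fixed point of the
#' mixing map, iterated until the OAA MDV changes by less than \code{tol}.
#' Carbon positions are treated as exchangeable within a fragment
#' (mass-level approximation): decarboxylation removes 2 of 6 carbons
#' hypergeometrically.
#'
#' @param pyrMDV backbone MDV of pyruvate (3 carbons, channels m0..m3).
#' @param accoaMDV backbone MDV of acetyl-CoA's two acetyl carbons
#'   (channels m0..m2).
#' @param R anaplerotic fraction of the OAA pool, in (0, 1].
#' @param tol convergence tolerance on the OAA MDV (default 1e-8).
#' @return list with \code{oaa}, \code{anaplerotic} and \code{tcaTurn}
#'   [MassIsotopomerDistribution-class] objects (4 carbons each).
#' @export
oaaSteadyState <- function(pyrMDV, accoaMDV, R, tol = 1e-8) {
  stopifnot(R > 0, R <= 1)
  pyr <- if (is(pyrMDV, "MassIsotopomerDistribution")) abundances(pyrMDV) else pyrMDV
  acc <- if (is(accoaMDV, "MassIsotopomerDistribution")) abundances(accoaMDV) else accoaMDV
  pyr <- pyr[1:4]; pyr[is.na(pyr)] <- 0            # m0..m3
  acc <- acc[1:3]; acc[is.na(acc)] <- 0            # m0..m2
  # anaplerotic OAA: pyruvate + one (unlabeled) CO2-derived carbon
  anap <- c(pyr, 0)[1:5]                           # m0..m4 on 4 carbons
  oaa <- anap
  turn <- oaa
  for (iter in 1:1000) {
    cit <- .convolve(oaa, acc)                     # 6 carbons, m0..m6
    turn <- .removeCarbons(cit, nCarbons = 6L, drop = 2L)[1:5]
    oaaNew <- R * anap + (1 - R) * turn
    if (max(abs(oaaNew - oaa)) < tol) { oaa <- oaaNew; break }
    oaa <- oaaNew
  }
  list(
    oaa = mdv(oaa, nCarbons = 4L, fragmentId = "oaa_mit"),
    anaplerotic = mdv(anap, nCarbons = 4L, fragmentId = "oaa_anaplerotic"),
    tcaTurn = mdv(turn, nCarbons = 4L, fragmentId = "oaa_tca")
  )
}

# hypergeometric carbon removal: from a fragment with nCarbons carbons and
# mass distribution a (m0..), drop `drop` carbons chosen at random
.removeCarbons <- function(a, nCarbons, drop) {
  keep <- nCarbons - drop
  out <- numeric(keep + 1L)
  for (j in seq_along(a) - 1L) {               # j labeled carbons present
    if (a[j + 1L] == 0 || j > nCarbons) next
    i <- max(0L, j - drop):min(j, keep)        # labeled carbons retained
    out[i + 1L] <- out[i + 1L] +
      a[j + 1L] * stats::dhyper(i, j, nCarbons - j, keep)
  }
  out
}

#' @export
print.FluxRatio <- function(x, ...) {
  cat(sprintf("FluxRatio%s: R = %.4f +/- %.4f (residual %.3g)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$value, x$sd, x$residual))
  invisible(x)
}

#' @export
print.RespirationEstimate <- function(x, ...) {
  cat(sprintf("RespirationEstimate: v_ana = %.4g, R = %.4g, v_tca = %.4g",
              x$vAna, x$R, x$vTca))
  if (!is.na(x$degreeOfRespiration))
    cat(sprintf(", degree of respiration = %.4g", x$degreeOfRespiration))
  cat("\n")
  invisible(x)
}
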