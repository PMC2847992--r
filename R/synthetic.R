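#' Ground-truth parameter set for the synthetic-data generators
#'
#' The stated world every generator draws from: exponential batch growth at
#' mu = 0.33/h (glucose-like) after a 2 h lag up to an OD plateau, 2\%
#' multiplicative optical noise, eight replicate cultures, a 20\%/80\%
#' uniformly-13C/natural substrate mixture at 99\% tracer purity, additive
#' MDV noise of 0.005, and a 47-enzyme universe with planted active
#' regulators whose targets overlap the differential set with probability
#' 0.9.
#'
#' @param mu specific growth rate, 1/h.
#' @param lag lag time, h.
#' @param od0 inoculation OD600.
#' @param plateau stationary-phase OD cap.
#' @param noiseCv multiplicative (log-normal) noise CV on optical signals.
#' @param nReplicates replicate cultures per condition.
#' @param expression true expression level e* (GFP slope units).
#' @param autofluorescence strain-independent autofluorescence slope a.
#' @param RStar true anaplerotic fraction of mitochondrial OAA.
#' @param vAna true anaplerotic flux, mmol/g/h.
#' @param uptake true substrate uptake rate, mmol/g/h.
#' @param mdvNoise additive SD per MDV mass channel.
#' @param tracerPurity,fractionLabeled,fractionUnlabeled labeling design.
#' @param nEnzymes universe size for the network generator.
#' @param nActiveTFs,nDecoyTFs planted and decoy regulator counts.
#' @param targetsPerTF curated targets per TF.
#' @param hitProbability probability that an active TF's target is drawn
#'   from the differential set.
#' @param nDiff size of the differential enzyme set.
#' @param foldEffect planted fold change for condition effects.
#' @param seed integer seed recorded with every simulated object.
#' @return list of class \code{"SyntheticTruth"}.
#' @export
syntheticTruth <- function(mu = 0.33, lag = 2, od0 = 0.05, plateau = 4,
                           noiseCv = 0.02, nReplicates = 8L,
                           expression = 3, autofluorescence = 1,
                           RStar = 0.35, vAna = 0.5, uptake = -2.5,
                           mdvNoise = 0.005, tracerPurity = 0.99,
                           fractionLabeled = 0.2, fractionUnlabeled = 0,
                           nEnzymes = 47L, nActiveTFs = 2L, nDecoyTFs = 8L,
                           targetsPerTF = 10L, hitProbability = 0.9,
                           nDiff = 18L, foldEffect = 3, seed = 1L) {
  stopifnot(mu > 0, lag >= 0, plateau > od0, od0 > 0, noiseCv >= 0,
            RStar > 0, RStar <= 1, nActiveTFs >= 1L)
  structure(as.list(environment()), class = "SyntheticTruth")
}

#' Simulate a batch growth curve
#'
#' Lag / exponential / plateau OD trajectory with multiplicative log-normal
#' noise; deterministic given the truth's seed.
#'
#' @param truth a [syntheticTruth()].
#' @param times sampling times in hours (default 12 readings across the
#'   culture, matching the 8-12 manual OD readings of a batch experiment).
#' @param seed overrides \code{truth$seed}.
#' @return data.frame with \code{time}, \code{od600}; attribute
#'   \code{truth}.
#' @export
simulateGrowth <- function(truth = syntheticTruth(),
                           times = seq(0, 24, length.out = 12),
                           seed = truth$seed) {
  set.seed(seed)
  mean <- .meanOd(truth, times)
  noise <- if (truth$noiseCv > 0)
    stats::rlnorm(length(times), meanlog = -truth$noiseCv^2 / 2,
                  sdlog = truth$noiseCv) else rep(1, length(times))
  out <- data.frame(time = times, od600 = mean * noise)
  attr(out, "truth") <- truth
  out
}

.meanOd <- function(truth, times) {
  od <- truth$od0 * exp(truth$mu * pmax(times - truth$lag, 0))
  pmin(od, truth$plateau)
}

#' Simulate plate-reader biomass and GFP channels
#'
#' Biomass channel proportional to OD; GFP channel
#' \code{(e + a) * biomass * (1 + noise)} where \code{e} is the strain's
#' expression level (0 for the autofluorescence reference) and \code{a} the
#' shared autofluorescence.
#'
#' @param truth a [syntheticTruth()].
#' @param expression expression level e* (default from truth); use 0 for
#'   the reference strain.
#' @param times sampling times, hours (plate readers log densely).
#' @param scatterGain biomass-signal gain, AU per OD.
#' @param seed overrides \code{truth$seed}.
#' @return data.frame with \code{time}, \code{biomass}, \code{gfp}.
#' @export
simulatePlate <- function(truth = syntheticTruth(),
                          expression = truth$expression,
                          times = seq(0, 24, by = 0.5),
                          scatterGain = 100, seed = truth$seed) {
  set.seed(seed)
  mult <- function(n) if (truth$noiseCv > 0)
    stats::rlnorm(n, meanlog = -truth$noiseCv^2 / 2,
                  sdlog = truth$noiseCv) else rep(1, n)
  biomass <- scatterGain * .meanOd(truth, times) * mult(length(times))
  gfp <- (expression + truth$autofluorescence) * biomass * mult(length(times))
  out <- data.frame(time = times, biomass = biomass, gfp = gfp)
  attr(out, "truth") <- truth
  out
}

#' Simulate measured MDVs for the two-precursor OAA mixing problem
#'
#' Builds the anaplerotic and TCA-turn precursor patterns implied by the
#' uniformly labeled substrate mixture, mixes them at the true anaplerotic
#' fraction R*, pushes the product through the forward measurement model
#' (tracer impurity, unlabeled biomass, natural-isotope convolution) and
#' adds clipped Gaussian channel noise.
#'
#' @param truth a [syntheticTruth()].
#' @param composition non-backbone element counts of the measured ion
#'   (default: the bundled aspartate [M-57] fragment, the usual reporter of
#'   oxaloacetate labeling).
#' @param noise logical; add measurement noise.
#' @param seed overrides \code{truth$seed}.
#' @return list with \code{product} (measured-scale
#'   [MassIsotopomerDistribution-class]), \code{precursorA},
#'   \code{precursorB} (backbone-scale reference patterns), and
#'   \code{truth}.
#' @export
simulateMDVs <- function(truth = syntheticTruth(),
                         composition = c(C = 14, H = 40, N = 1, O = 4, Si = 3),
                         noise = TRUE, seed = truth$seed) {
  set.seed(seed)
  fl <- truth$fractionLabeled
  pyr <- mdv(c(1 - fl, 0, 0, fl), nCarbons = 3, fragmentId = "pyr")
  acc <- mdv(c(1 - fl, 0, fl), nCarbons = 2, fragmentId = "accoa")
  ss <- oaaSteadyState(pyr, acc, R = truth$RStar)
  a <- abundances(ss$anaplerotic)
  b <- abundances(ss$tcaTurn)
  productTrue <- truth$RStar * a + (1 - truth$RStar) * b
  exp <- labelingExperiment(tracerPurity = truth$tracerPurity,
                            fractionUnlabeled = truth$fractionUnlabeled,
                            fractionLabeled = fl)
  measured <- forwardMDV(mdv(productTrue, nCarbons = 4,
                             fragmentId = "oaa_product"),
                         composition, exp)
  y <- abundances(measured)
  if (noise && truth$mdvNoise > 0) {
    y <- pmax(y + stats::rnorm(length(y), 0, truth$mdvNoise), 0)
    y <- y / sum(y)
  }
  list(product = mdv(y, nCarbons = 4, fragmentId = "oaa_product"),
       precursorA = ss$anaplerotic,
       precursorB = ss$tcaTurn,
       composition = composition,
       experiment = exp,
       truth = truth)
}

#' Simulate a regulatory network with planted active regulators
#'
#' Universe of \code{nEnzymes} enzymes, a differential set of \code{nDiff}
#' of them, \code{nActiveTFs} planted regulators whose targets fall in the
#' differential set with probability \code{hitProbability}, and
#' \code{nDecoyTFs} decoys with uniformly drawn targets.
#'
#' @param truth a [syntheticTruth()].
#' @param seed overrides \code{truth$seed}.
#' @return list with \code{network} ([RegulatoryNetwork-class]),
#'   \code{diffSet}, \code{activeTFs}, \code{truth}.
#' @export
simulateNetwork <- function(truth = syntheticTruth(), seed = truth$seed) {
  set.seed(seed)
  enzymes <- sprintf("E%02d", seq_len(truth$nEnzymes))
  diffSet <- sample(enzymes, truth$nDiff)
  nonDiff <- setdiff(enzymes, diffSet)
  activeTFs <- sprintf("TF_active%d", seq_len(truth$nActiveTFs))
  decoyTFs <- sprintf("TF_decoy%d", seq_len(truth$nDecoyTFs))
  drawTargets <- function(active) {
    if (active) {
      fromDiff <- stats::runif(truth$targetsPerTF) < truth$hitProbability
      nHit <- min(sum(fromDiff), length(diffSet))
      nMiss <- min(truth$targetsPerTF - nHit, length(nonDiff))
      c(sample(diffSet, nHit), sample(nonDiff, nMiss))
    } else {
      sample(enzymes, min(truth$targetsPerTF, length(enzymes)))
    }
  }
  edges <- do.call(rbind, c(
    lapply(activeTFs, function(tf)
      data.frame(tf = tf, target = drawTargets(TRUE))),
    lapply(decoyTFs, function(tf)
      data.frame(tf = tf, target = drawTargets(FALSE)))))
  net <- regulatoryNetwork(edges$tf, edges$target, evidence = "literature",
                           universe = enzymes)
  list(network = net, diffSet = diffSet, activeTFs = activeTFs,
       truth = truth)
}

#' Simulate replicate expression levels for a two-condition contrast
#'
#' End-to-end helper for fold-change recovery: simulates plate time series
#' for a baseline and an effect condition (expression multiplied by
#' \code{truth$foldEffect}) plus the shared autofluorescence reference,
#' computes expression levels per replicate with [expressionLevel()], and
#' returns the long-format table expected by [foldChanges()].
#'
#' @param truth a [syntheticTruth()].
#' @param enzyme enzyme id used in the output table.
#' @param seed overrides \code{truth$seed}.
#' @return data.frame with columns enzyme, condition, replicate, level,
#'   status.
#' @export
simulateExpressionContrast <- function(truth = syntheticTruth(),
                                       enzyme = "Enz1", seed = truth$seed) {
  set.seed(seed)
  rows <- list()
  for (cond in c("glucose", "pyruvate")) {
    e <- truth$expression * if (cond == "glucose") 1 else truth$foldEffect
    for (rep in seq_len(truth$nReplicates)) {
      s <- simulatePlate(truth, expression = e,
                         seed = sample.int(.Machine$integer.max / 2, 1))
      r <- simulatePlate(truth, expression = 0,
                         seed = sample.int(.Machine$integer.max / 2, 1))
      est <- expressionLevel(s, r)
      rows[[length(rows) + 1L]] <-
        data.frame(enzyme = enzyme, condition = cond, replicate = rep,
                   level = ifelse(is.na(est$level), NA, est$level),
                   status = est$status)
    }
  }
  do.call(rbind, rows)
}
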