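#' Natural isotope abundance distributions per element
#'
#' Standard IUPAC terrestrial abundances for the elements occurring in
#' TBDMS-derivatized amino-acid fragments.  Each entry is the mass-shift
#' distribution (+0, +1, +2 mass units) of a single atom.
#'
#' @return named list of numeric vectors.
#' @export
naturalAbundances <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(1 - 0.000115, 0.000115),
    N  = c(1 - 0.00364, 0.00364),
    O  = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    Si = c(1 - 0.04685 - 0.03092, 0.04685, 0.03092),
    S  = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425)
  )
}

# discrete convolution of two mass-shift distributions
.convolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# distribution of total mass shift from `count` atoms of one element
.elementDistribution <- function(element, count,
                                 tables = naturalAbundances()) {
  d <- 1
  if (count > 0) {
    base <- tables[[element]]
    if (is.null(base)) stop("no isotope table for element ", element)
    for (k in seq_len(count)) d <- .convolve(d, base)
  }
  d
}

#' Natural-isotope mass-shift distribution of a fragment's non-backbone atoms
#'
#' Convolution of the per-atom isotope distributions of every non-backbone
#' atom (derivatization carbons, H, N, O, Si, S) of the measured ion.
#'
#' @param composition named integer vector of element counts beyond the
#'   carbon backbone, e.g. \code{c(C = 8, H = 26, N = 1, O = 2, Si = 2)}.
#' @param length truncate/pad the distribution to this many mass channels
#'   (optional).
#' @return numeric vector of mass-shift probabilities starting at +0.
#' @export
fragmentShiftDistribution <- function(composition, length = NULL) {
  if (any(composition < 0)) stop("element counts must be non-negative")
  d <- 1
  for (el in names(composition))
    d <- .convolve(d, .elementDistribution(el, composition[[el]]))
  if (!is.null(length)) {
    d <- d[seq_len(min(length, base::length(d)))]
    d <- c(d, numeric(length - base::length(d)))
  }
  d
}

#' Natural-isotope correction matrix
#'
#' Lower-triangular matrix whose column j is the natural mass-shift
#' distribution of the non-backbone atoms placed onto a molecule already
#' carrying j extra mass units.  Multiplying a backbone labeling pattern by
#' this matrix produces the measured (naturally smeared) pattern; solving
#' the linear system removes the smear.  Mass shifts falling beyond the
#' measured window are truncated, so columns sum to <= 1.
#'
#' @param composition named integer vector of non-backbone element counts.
#' @param length number of mass channels (matrix dimension).
#' @return a \code{length x length} lower-triangular matrix.
#' @examples
#' isotopeCorrectionMatrix(c(C = 1), length = 2)
#' @export
isotopeCorrectionMatrix <- function(composition, length) {
  if (length < 1) stop("length must be >= 1")
  d <- fragmentShiftDistribution(composition)
  M <- matrix(0, length, length)
  for (j in seq_len(length)) {
    reach <- min(base::length(d), length - j + 1L)
    M[j:(j + reach - 1L), j] <- d[seq_len(reach)]
  }
  M
}

#' Lawson-Hanson non-negative least squares
#'
#' Solves min ||Ax - b|| subject to x >= 0.  Implemented here because no
#' NNLS/quadratic-programming package is available in the target
#' environment; the algorithm is the classical active-set method.
#'
#' @param A numeric matrix. @param b numeric vector.
#' @param tol tolerance on the dual feasibility test.
#' @return list with \code{x} and \code{residual} (Euclidean norm).
#' @keywords internal
#' @export
nnls <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  maxIter <- 30L * n
  while (any(!passive) && any(w[!passive] > tol) && iter < maxIter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- drop(qr.solve(qr(Ap), b))
      if (all(s[passive] > tol)) break
      idx <- which(passive & s <= tol)
      alpha <- min(x[idx] / (x[idx] - s[idx]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sqrt(sum((b - A %*% x)^2)))
}

#' Labeling experiment description
#'
#' Bundles the tracer purity, the fraction of unlabeled biomass carried over
#' from the naturally labeled inoculum, and the tracer design (the reference
#' design is a mixture of 20\% uniformly 13C-labeled and 80\% naturally
#' labeled substrate).
#'
#' @param tracerPurity 13C enrichment of the labeled substrate, in (0.9, 1].
#' @param fractionUnlabeled fraction of biomass formed from unlabeled
#'   (pre-culture) carbon, in [0, 1).
#' @param fractionLabeled fraction of uniformly labeled substrate in the
#'   feed mixture.
#' @return list of class \code{"LabelingExperiment"}.
#' @export
labelingExperiment <- function(tracerPurity = 0.99, fractionUnlabeled = 0,
                               fractionLabeled = 0.2) {
  if (tracerPurity <= 0.9 || tracerPurity > 1)
    stop("tracerPurity must be in (0.9, 1]")
  if (fractionUnlabeled < 0 || fractionUnlabeled >= 1)
    stop("fractionUnlabeled must be in [0, 1)")
  if (fractionLabeled < 0 || fractionLabeled > 1)
    stop("fractionLabeled must be in [0, 1]")
  structure(list(tracerPurity = tracerPurity,
                 fractionUnlabeled = fractionUnlabeled,
                 fractionLabeled = fractionLabeled),
            class = "LabelingExperiment")
}

# natural-abundance MDV of an n-carbon backbone (binomial in 13C), padded
.naturalBackboneMDV <- function(nCarbons, length) {
  p <- naturalAbundances()$C[2]
  d <- stats::dbinom(seq_len(length) - 1L, nCarbons, p)
  d / sum(d)
}

#' Correct a measured MDV for natural isotopes and unlabeled biomass
#'
#' Two-step correction of a GC-MS mass-isotopomer distribution: (1) the
#' natural-isotope smear of all non-backbone atoms is removed by solving
#' \code{M x = raw} (non-negative least squares by default, plain
#' triangular inversion optionally for exactness checks); (2) the fraction
#' \code{w} of unlabeled biomass is subtracted:
#' \code{x' = (x - w * MDVnat) / (1 - w)}, clipped at zero and
#' renormalized.  Backbone carbons keep their natural 13C content in step
#' (2)'s reference so a fully unlabeled sample corrects to (1, 0, ..., 0).
#'
#' @param raw a [MassIsotopomerDistribution-class] as measured.
#' @param composition non-backbone element counts of the measured ion.
#' @param experiment a [labelingExperiment()]; only
#'   \code{fractionUnlabeled} is used here (tracer impurity belongs to the
#'   forward model, not the correction).
#' @param method \code{"nnls"} (default) or \code{"solve"}.
#' @param correctBackbone also remove the natural 13C of the backbone
#'   carbons themselves by deconvolution (default TRUE).
#' @return corrected [MassIsotopomerDistribution-class]; attributes
#'   \code{residual} (NNLS residual norm) and \code{negClipped} (mass
#'   removed by clipping).
#' @export
correctMDV <- function(raw, composition, experiment = labelingExperiment(),
                       method = c("nnls", "solve"), correctBackbone = TRUE) {
  method <- match.arg(method)
  stopifnot(is(raw, "MassIsotopomerDistribution"))
  w <- experiment$fractionUnlabeled
  y <- abundances(raw)
  L <- length(y)
  comp <- composition
  if (correctBackbone) {
    # fold the backbone's own natural 13C into the deconvolution: after it,
    # channel i means "i tracer-derived heavy atoms"
    comp <- c(comp, C = nCarbons(raw))
    if (sum(names(comp) == "C") > 1L) {
      cc <- sum(comp[names(comp) == "C"])
      comp <- comp[names(comp) != "C"]
      comp <- c(comp, C = cc)
    }
  }
  M <- isotopeCorrectionMatrix(comp, L)
  if (method == "solve") {
    x <- drop(solve(M, y))
    residual <- 0
  } else {
    fit <- nnls(M, y)
    x <- fit$x
    residual <- fit$residual
  }
  negClipped <- -sum(pmin(x, 0))
  if (negClipped > 1e-3)
    warning(sprintf(
      "negative abundances beyond tolerance before clipping (mass %.4g); check composition/window",
      negClipped))
  x <- pmax(x, 0)
  x <- x / sum(x)

  if (w > 0) {
    # after backbone deconvolution the unlabeled-biomass reference is a
    # point mass at m0; otherwise it is the natural backbone binomial
    natural <- if (correctBackbone) c(1, numeric(L - 1L))
               else .naturalBackboneMDV(nCarbons(raw), L)
    x <- (x - w * natural) / (1 - w)
    x <- pmax(x, 0)
    x <- x / sum(x)
  }
  out <- mdv(x, nCarbons = nCarbons(raw), fragmentId = fragmentId(raw),
             normalize = TRUE)
  attr(out, "residual") <- residual
  attr(out, "negClipped") <- negClipped
  out
}

#' Forward-simulate a measured MDV from a tracer-derived labeling pattern
#'
#' The inverse of [correctMDV()]: mixes in the unlabeled-biomass fraction,
#' applies tracer impurity (each nominally 13C backbone atom is 13C with
#' probability \code{tracerPurity}), and convolves with the natural-isotope
#' distribution of all atoms.  Used by the synthetic-data generator and the
#' round-trip property tests.
#'
#' @param x backbone labeling pattern (a
#'   [MassIsotopomerDistribution-class] with channels = tracer-derived heavy
#'   atoms).
#' @param composition non-backbone element counts.
#' @param experiment a [labelingExperiment()].
#' @return a [MassIsotopomerDistribution-class] on the measurement scale.
#' @export
forwardMDV <- function(x, composition, experiment = labelingExperiment()) {
  stopifnot(is(x, "MassIsotopomerDistribution"))
  a <- abundances(x)
  L <- length(a)
  nC <- nCarbons(x)
  p <- experiment$tracerPurity
  if (p < 1) {
    # binomial thinning: j nominal tracer atoms retain i with prob B(j, p)
    thinned <- numeric(L)
    for (j in seq_len(L) - 1L) {
      if (a[j + 1L] == 0) next
      probs <- stats::dbinom(0:j, j, p)
      thinned[1:(j + 1L)] <- thinned[1:(j + 1L)] + a[j + 1L] * probs
    }
    a <- thinned
  }
  w <- experiment$fractionUnlabeled
  if (w > 0) a <- (1 - w) * a + w * c(1, numeric(L - 1L))
  comp <- c(composition, C = nC)
  if (sum(names(comp) == "C") > 1L) {
    cc <- sum(comp[names(comp) == "C"])
    comp <- comp[names(comp) != "C"]
    comp <- c(comp, C = cc)
  }
  M <- isotopeCorrectionMatrix(comp, L)
  mdv(drop(M %*% a), nCarbons = nC, fragmentId = fragmentId(x))
}

#' Bundled TBDMS fragment compositions
#'
#' Non-backbone element counts of the [M-57] ions of the TBDMS-derivatized
#' amino acids commonly used to read central-metabolite labeling (alanine,
#' glycine, serine, threonine, aspartate, glutamate, phenylalanine,
#' valine).  Shipped as JSON in \code{inst/extdata}.
#'
#' @return named list fragment -> named integer vector of element counts.
#' @export
tbdmsFragments <- function() {
  path <- system.file("extdata", "fragment_compositions.json",
                      package = "respflux")
  readFragmentCompositions(path)
}
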