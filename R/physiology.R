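#' Fit the maximum specific growth rate from an OD time course
#'
#' Specific growth rates are estimated by linear regression of log(OD600)
#' against time over the contiguous window of at least \code{minPoints}
#' points at maximum rate.  Among all contiguous windows of length >=
#' \code{minPoints}, the window with the steepest slope among those with
#' R^2 >= \code{r2Threshold} is chosen; if no window reaches that fit
#' quality, the window with the best R^2 is used instead.
#'
#' @param time numeric, hours, strictly increasing.
#' @param od numeric OD600 readings, same length as \code{time}.
#' @param minPoints minimum number of points in the regression window
#'   (default 6, the conventional minimum for batch growth-rate fits).
#' @param r2Threshold minimum R^2 for a window to compete on slope.
#' @return An object of class \code{"PhysiologyResult"}: a list with
#'   \code{mu} (1/h), \code{fitR2}, \code{nPoints}, \code{window} (first and
#'   last time of the selected window) and \code{intercept}.
#' @examples
#' t <- 0:7
#' fitGrowthRate(t, 0.05 * exp(0.30 * t))$mu   # 0.30
#' @export
fitGrowthRate <- function(time, od, minPoints = 6L, r2Threshold = 0.99) {
  if (length(time) != length(od))
    stop("time and od must have equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  keep <- which(od > 0)
  if (length(keep) < minPoints)
    stop("fewer than ", minPoints, " positive OD readings")
  t <- time[keep]
  y <- log(od[keep])
  n <- length(t)

  best <- NULL
  for (i in seq_len(n - minPoints + 1L)) {
    for (j in seq.int(i + minPoints - 1L, n)) {
      idx <- i:j
      fit <- .linfit(t[idx], y[idx])
      cand <- list(mu = fit$slope, r2 = fit$r2, i = i, j = j,
                   intercept = fit$intercept)
      if (is.null(best)) { best <- cand; next }
      bothGood <- cand$r2 >= r2Threshold && best$r2 >= r2Threshold
      if (bothGood) {
        if (cand$mu > best$mu) best <- cand
      } else if (cand$r2 >= r2Threshold && best$r2 < r2Threshold) {
        best <- cand
      } else if (cand$r2 < r2Threshold && best$r2 < r2Threshold) {
        if (cand$r2 > best$r2) best <- cand
      }
    }
  }
  structure(list(mu = best$mu, fitR2 = best$r2,
                 nPoints = best$j - best$i + 1L,
                 window = c(t[best$i], t[best$j]),
                 intercept = best$intercept),
            class = "PhysiologyResult")
}

# slope/intercept/R2 of y ~ x without lm() overhead (called in tight loops)
.linfit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate fit: zero variance in predictor")
  slope <- sum((x - mx) * (y - my)) / sxx
  res <- y - my - slope * (x - mx)
  syy <- sum((y - my)^2)
  r2 <- if (syy == 0) 1 else 1 - sum(res^2) / syy
  list(slope = slope, intercept = my - slope * mx, r2 = r2)
}

#' Uptake/secretion rate and biomass yield from concentration-vs-CDW data
#'
#' Substrate or by-product concentrations sampled during exponential growth
#' are regressed against the corresponding cell dry weight (CDW = OD600 x
#' \code{odToCdw}).  The slope s (mmol per g CDW) gives the molar biomass
#' yield as 1/|s| and, multiplied by the growth rate, the specific
#' uptake/secretion rate q = s * mu (negative for consumed substrates).
#' With replicates the rate is computed per replicate and summarized as
#' mean and sample SD.
#'
#' @param concentration mmol/L, non-negative.
#' @param od OD600 values matching \code{concentration}.
#' @param mu specific growth rate, 1/h (> 0).
#' @param mw molecular weight of the analyte in g/mmol (e.g. glucose
#'   0.18016).
#' @param odToCdw OD600 -> CDW conversion, g/L per OD unit.  The default 0.5
#'   is an arbitrary placeholder; calibrate it for your instrument.
#' @param replicate optional replicate ids; rates are fit per replicate.
#' @param role \code{"substrate"} (expects a negative slope) or
#'   \code{"product"}; a sign mismatch raises a warning, not an error.
#' @return \code{"PhysiologyResult"} list with \code{uptakeRate} (q,
#'   mmol/g/h), \code{uptakeSd}, \code{yieldMolar} (g/mmol),
#'   \code{yieldMass} (g/g), \code{yieldMassSd}, \code{slope}, \code{mu},
#'   \code{fitR2}, \code{nPoints}.
#' @examples
#' cdw <- c(0.2, 0.6)                      # via default odToCdw = 0.5
#' conc <- 10 - 2 * cdw                    # s = -2 mmol/g
#' fitUptakeYield(conc, c(0.4, 1.2), mu = 0.3, mw = 0.18016)
#' @export
fitUptakeYield <- function(concentration, od, mu, mw, odToCdw = 0.5,
                           replicate = NULL, role = c("substrate", "product")) {
  role <- match.arg(role)
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  if (mu <= 0) stop("mu must be positive")
  if (odToCdw <= 0) stop("odToCdw must be positive")
  if (is.null(replicate)) replicate <- rep(1L, length(od))
  cdw <- od * odToCdw

  perRep <- lapply(split(seq_along(cdw), replicate), function(idx) {
    if (length(unique(cdw[idx])) < 2L)
      stop("degenerate fit: zero CDW variance within a replicate")
    .linfit(cdw[idx], concentration[idx])
  })
  slopes <- vapply(perRep, `[[`, numeric(1), "slope")
  r2s <- vapply(perRep, `[[`, numeric(1), "r2")

  if (role == "substrate" && mean(slopes) > 0)
    warning("positive concentration slope for a declared substrate")
  if (role == "product" && mean(slopes) < 0)
    warning("negative concentration slope for a declared product")

  s <- mean(slopes)
  q <- slopes * mu
  yieldMolar <- 1 / abs(slopes)
  yieldMass <- yieldMolar / mw
  sdOrNA <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_

  structure(list(mu = mu,
                 slope = s,
                 uptakeRate = mean(q), uptakeSd = sdOrNA(q),
                 yieldMolar = mean(yieldMolar),
                 yieldMass = mean(yieldMass), yieldMassSd = sdOrNA(yieldMass),
                 fitR2 = mean(r2s), nPoints = length(cdw),
                 nReplicates = length(perRep)),
            class = "PhysiologyResult")
}

#' Biomass yield implied by growth and uptake rates
#'
#' The algebraic identity linking the three physiological quantities:
#' yield (g/g) = mu / (|q| * MW).  Used to check the internal consistency of
#' published rate tables.
#'
#' @param mu growth rate, 1/h.
#' @param q uptake rate, mmol/g/h (sign ignored).
#' @param mw molecular weight, g/mmol.
#' @return yield in g CDW per g substrate.
#' @examples
#' yieldFromRates(0.33, -16.3, 0.18016)  # ~0.11 g/g on glucose
#' @export
yieldFromRates <- function(mu, q, mw) mu / (abs(q) * mw)

#' Default molecular-weight table (g/mmol)
#'
#' Free-acid/free-sugar masses for the four carbon sources; configurable
#' because published tables rarely state whether salts were used.
#' @return named numeric vector.
#' @export
defaultMwTable <- function() {
  c(glucose = 0.18016, mannose = 0.18016, galactose = 0.18016,
    pyruvate = 0.08806)
}

#' @export
print.PhysiologyResult <- function(x, ...) {
  cat("PhysiologyResult\n")
  for (f in names(x)) {
    v <- x[[f]]
    if (is.numeric(v)) v <- signif(v, 5)
    cat("  ", f, ": ", paste(v, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
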