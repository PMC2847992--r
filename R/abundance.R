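#' Enzyme expression level from a GFP/biomass slope
#'
#' During exponential growth the GFP fluorescence of a reporter strain rises
#' proportionally to biomass, with a slope proportional to the enzyme's
#' expression level plus a strain-independent autofluorescence.  The level
#' is the ordinary-least-squares slope of GFP against the biomass signal
#' over the exponential window, minus the same slope of the
#' autofluorescence reference strain.
#'
#' The exponential window keeps points whose biomass signal lies between
#' \code{windowFrac[1]} and \code{windowFrac[2]} of the plateau (series
#' maximum).  A strain whose biomass signal never exceeds
#' \code{growthFold} times its initial value is flagged \code{"ng"} (no
#' growth); a negative corrected slope is flagged \code{"below_detection"}
#' with level 0.
#'
#' @param strain data.frame with columns \code{time}, \code{biomass},
#'   \code{gfp} for the GFP-fusion strain.
#' @param reference same layout for the autofluorescence control strain.
#' @param windowFrac two fractions of the biomass plateau delimiting the
#'   exponential window (default \code{c(0.1, 0.6)}).
#' @param growthFold minimum plateau/initial biomass ratio to count as
#'   growth (default 2).
#' @param minPoints minimum points in the window (default 4).
#' @return object of class \code{"AbundanceEstimate"}: list with
#'   \code{level}, \code{status} ("ok", "ng" or "below_detection"),
#'   \code{slopeStrain}, \code{slopeReference}, \code{nPoints}.
#' @examples
#' tt <- 0:20
#' bm <- 100 * exp(0.3 * pmin(tt, 12))
#' s <- data.frame(time = tt, biomass = bm, gfp = 3 * bm)
#' r <- data.frame(time = tt, biomass = bm, gfp = 1 * bm)
#' expressionLevel(s, r)$level   # 2
#' @export
expressionLevel <- function(strain, reference, windowFrac = c(0.1, 0.6),
                            growthFold = 2, minPoints = 4L) {
  for (d in list(strain, reference))
    stopifnot(all(c("time", "biomass", "gfp") %in% names(d)))
  if (max(strain$biomass) < growthFold * strain$biomass[1])
    return(structure(list(level = NA_real_, status = "ng",
                          slopeStrain = NA_real_, slopeReference = NA_real_,
                          nPoints = 0L),
                     class = "AbundanceEstimate"))
  slopeOf <- function(d) {
    plateau <- max(d$biomass)
    keep <- d$biomass >= windowFrac[1] * plateau &
            d$biomass <= windowFrac[2] * plateau
    if (sum(keep) < minPoints)
      stop("fewer than ", minPoints, " points in the exponential window")
    .linfit(d$biomass[keep], d$gfp[keep])$slope
  }
  ss <- slopeOf(strain)
  sr <- slopeOf(reference)
  level <- ss - sr
  status <- "ok"
  if (level < 0) { level <- 0; status <- "below_detection" }
  structure(list(level = level, status = status,
                 slopeStrain = ss, slopeReference = sr,
                 nPoints = sum(strain$biomass >= windowFrac[1] * max(strain$biomass) &
                               strain$biomass <= windowFrac[2] * max(strain$biomass))),
            class = "AbundanceEstimate")
}

#' Fold changes in enzyme expression relative to a baseline carbon source
#'
#' For each enzyme and non-baseline condition, the fold change is the ratio
#' of mean replicate levels, and significance is a two-sided Welch t-test
#' on the replicate levels (the published analysis states only the p <=
#' 0.12 threshold; Welch's test is this package's choice).  Codes:
#' \code{"ok"} (significant change), \code{"nsc"} (p > alpha),
#' \code{"ng"} (strain did not grow on that condition),
#' \code{"bd"} (condition level below detection; fold fixed at 0).
#' A condition detected while the baseline is below detection yields
#' \code{fold = Inf} with code \code{"ok"} ("induced from zero").
#'
#' @param levels data.frame with columns \code{enzyme}, \code{condition},
#'   \code{replicate}, \code{level}, \code{status}; optionally
#'   \code{pathway}.
#' @param baseline baseline condition id (default \code{"glucose"}).
#' @param alpha significance threshold on the Welch p-value (default 0.12).
#' @return a \code{"FoldChangeTable"}: data.frame with one row per enzyme
#'   and columns \code{<cond>_fold}, \code{<cond>_code}, \code{<cond>_p}
#'   per non-baseline condition (plus \code{pathway} if supplied).
#' @export
foldChanges <- function(levels, baseline = "glucose", alpha = 0.12) {
  req <- c("enzyme", "condition", "replicate", "level", "status")
  stopifnot(all(req %in% names(levels)))
  conds <- setdiff(unique(levels$condition), baseline)
  enzymes <- unique(levels$enzyme)
  hasPathway <- "pathway" %in% names(levels)
  out <- data.frame(enzyme = enzymes, stringsAsFactors = FALSE)
  if (hasPathway)
    out$pathway <- levels$pathway[match(enzymes, levels$enzyme)]
  for (cond in conds) {
    fold <- numeric(length(enzymes)); code <- character(length(enzymes))
    pval <- rep(NA_real_, length(enzymes))
    for (i in seq_along(enzymes)) {
      e <- enzymes[i]
      xb <- levels[levels$enzyme == e & levels$condition == baseline, ]
      xc <- levels[levels$enzyme == e & levels$condition == cond, ]
      if (all(xc$status == "ng")) { fold[i] <- NA; code[i] <- "ng"; next }
      mb <- mean(xb$level); mc <- mean(xc$level)
      if (all(xc$status == "below_detection") || mc <= 0) {
        fold[i] <- 0; code[i] <- "bd"; next
      }
      if (mb <= 0) { fold[i] <- Inf; code[i] <- "ok"; next }
      fold[i] <- mc / mb
      if (nrow(xb) >= 3 && nrow(xc) >= 3 &&
          stats::sd(xb$level) + stats::sd(xc$level) > 0) {
        pval[i] <- stats::t.test(xc$level, xb$level)$p.value
      } else {
        pval[i] <- NA_real_
      }
      code[i] <- if (!is.na(pval[i]) && pval[i] <= alpha) "ok" else "nsc"
    }
    out[[paste0(cond, "_fold")]] <- fold
    out[[paste0(cond, "_code")]] <- code
    out[[paste0(cond, "_p")]] <- pval
  }
  class(out) <- c("FoldChangeTable", "data.frame")
  out
}

.condCols <- function(table) {
  sub("_code$", "", grep("_code$", names(table), value = TRUE))
}

# helpers over a FoldChangeTable row: significant up / down per condition
.isUp <- function(table, cond, countNg = FALSE) {
  code <- table[[paste0(cond, "_code")]]
  fold <- table[[paste0(cond, "_fold")]]
  up <- code == "ok" & !is.na(fold) & fold > 1
  if (countNg) up | code == "ng" else up
}

.isDown <- function(table, cond) {
  code <- table[[paste0(cond, "_code")]]
  fold <- table[[paste0(cond, "_fold")]]
  (code == "ok" & !is.na(fold) & fold < 1) | code == "bd"
}

#' Classify carbon-source expression patterns
#'
#' Rule-based partition of enzymes into five pattern classes, applied in
#' order (first match wins): \enumerate{
#'   \item \code{positively_related}: significantly up on galactose AND
#'     pyruvate (no-growth on a respiratory substrate counts as
#'     respiration-important, i.e. as up);
#'   \item \code{pyruvate_only_up}: up on pyruvate only;
#'   \item \code{negatively_related}: significantly down (or below
#'     detection) on galactose or pyruvate;
#'   \item \code{mannose_affected}: changed on mannose only;
#'   \item \code{unchanged}: everything else.
#' }
#' The rules are exhaustive and mutually exclusive by construction.
#'
#' @param table a \code{"FoldChangeTable"} with conditions \code{man},
#'   \code{gal}, \code{pyr}.
#' @return data.frame with columns \code{enzyme}, \code{class}.
#' @export
classifyPatterns <- function(table) {
  stopifnot(all(c("man_code", "gal_code", "pyr_code") %in% names(table)))
  upGal <- .isUp(table, "gal", countNg = TRUE)
  upPyr <- .isUp(table, "pyr", countNg = TRUE)
  downGal <- .isDown(table, "gal")
  downPyr <- .isDown(table, "pyr")
  changedMan <- table$man_code %in% c("ok", "bd", "ng")
  changedGal <- table$gal_code %in% c("ok", "bd", "ng")
  changedPyr <- table$pyr_code %in% c("ok", "bd", "ng")
  cls <- ifelse(upGal & upPyr, "positively_related",
         ifelse(upPyr, "pyruvate_only_up",
         ifelse(downGal | downPyr, "negatively_related",
         ifelse(changedMan & !changedGal & !changedPyr, "mannose_affected",
                "unchanged"))))
  data.frame(enzyme = table$enzyme, class = cls, stringsAsFactors = FALSE)
}

#' Correlate enzyme fold changes with the degree of respiration
#'
#' Pearson correlation, per enzyme, between expression across the four
#' carbon sources and the corresponding degrees of respiration.  Because
#' only fold changes (not absolute levels) are available, the baseline
#' (glucose) is fixed at 1 and non-significant changes are taken as 1 -- an
#' approximation to correlating measured levels.  Enzymes with a no-growth
#' condition are excluded (NA), as are zero-variance profiles (with a
#' warning).
#'
#' @param table a \code{"FoldChangeTable"} with conditions man/gal/pyr.
#' @param degrees named numeric degrees of respiration for
#'   \code{c(glucose, man, gal, pyr)} in that condition order.
#' @param threshold absolute correlation for selection (default 0.90).
#' @return data.frame with \code{enzyme}, \code{r}, \code{selected},
#'   \code{sign}.
#' @export
correlateWithRespiration <- function(table,
                                     degrees = c(glucose = 0, man = 0.06,
                                                 gal = 6.9, pyr = 13.3),
                                     threshold = 0.90) {
  conds <- c("man", "gal", "pyr")
  stopifnot(all(paste0(conds, "_code") %in% names(table)),
            length(degrees) == 4L)
  r <- rep(NA_real_, nrow(table))
  zeroVar <- character()
  for (i in seq_len(nrow(table))) {
    folds <- c(1, vapply(conds, function(cc) {
      code <- table[[paste0(cc, "_code")]][i]
      fold <- table[[paste0(cc, "_fold")]][i]
      if (code == "ng") return(NA_real_)
      if (code == "nsc") return(1)
      if (code == "bd") return(0)
      fold
    }, numeric(1)))
    if (anyNA(folds) || any(!is.finite(folds))) next
    if (stats::sd(folds) == 0 || stats::sd(degrees) == 0) {
      zeroVar <- c(zeroVar, table$enzyme[i])
      next
    }
    r[i] <- stats::cor(folds, as.numeric(degrees))
  }
  if (length(zeroVar))
    warning("correlation undefined (zero variance), excluded: ",
            paste(zeroVar, collapse = ", "))
  data.frame(enzyme = table$enzyme, r = r,
             selected = !is.na(r) & abs(r) >= threshold,
             sign = ifelse(is.na(r), NA, ifelse(r >= 0, "positive", "negative")),
             stringsAsFactors = FALSE)
}

#' Differential-expression summary counts
#'
#' The headline counting statistics of the screen: \describe{
#'   \item{up_gal, up_pyr}{enzymes up-regulated on galactose / pyruvate vs
#'     glucose.  Strains that fail to grow on the respiratory substrate are
#'     counted as up-regulated/respiration-important here.}
#'   \item{up_tca_resp_union}{TCA-cycle + respiratory-chain enzymes with a
#'     significant fold-change increase on galactose and/or pyruvate
#'     (no-growth strains excluded: this count is fold-change based).}
#'   \item{down_tca_resp_union}{same union, significantly down or below
#'     detection.}
#'   \item{pct_changed}{percent of all enzymes with any significant change
#'     (including below-detection and no-growth) on at least one carbon
#'     source.}
#' }
#'
#' @param table a \code{"FoldChangeTable"} with a \code{pathway} column
#'   (\code{"tca"}, \code{"respiratory_chain"}, \code{"ethanol"}).
#' @return named list of the five statistics.
#' @export
summarizeDifferential <- function(table) {
  if (is.null(table$pathway) || anyNA(table$pathway))
    stop("pathway annotation missing for enzyme(s): ",
         paste(table$enzyme[is.na(table$pathway)], collapse = ", "))
  if (nrow(table) == 0L)
    return(list(up_gal = 0L, up_pyr = 0L, up_tca_resp_union = 0L,
                down_tca_resp_union = 0L, pct_changed = 0))
  tcaResp <- table$pathway %in% c("tca", "respiratory_chain")
  upGalFC <- .isUp(table, "gal"); upPyrFC <- .isUp(table, "pyr")
  list(
    up_gal = sum(.isUp(table, "gal", countNg = TRUE)),
    up_pyr = sum(.isUp(table, "pyr", countNg = TRUE)),
    up_tca_resp_union = sum(tcaResp & (upGalFC | upPyrFC)),
    down_tca_resp_union = sum(tcaResp &
                                (.isDown(table, "gal") | .isDown(table, "pyr"))),
    pct_changed = 100 * mean(
      table$man_code %in% c("ok", "bd", "ng") |
      table$gal_code %in% c("ok", "bd", "ng") |
      table$pyr_code %in% c("ok", "bd", "ng"))
  )
}
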