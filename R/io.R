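#' Read growth curves from delimited text
#'
#' Expects a tab-separated file with header columns \code{strain_id},
#' \code{time_h}, \code{od600}.
#'
#' @param path file path.
#' @return data.frame split-ready by strain.
#' @export
readGrowthCurves <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("strain_id", "time_h", "od600")
  if (!all(req %in% names(d)))
    stop("growth-curve file must have columns ", paste(req, collapse = ", "))
  if (any(d$od600 < 0)) stop("od600 must be >= 0")
  d
}

#' Read concentration-vs-OD rate samples
#'
#' Tab-separated with header columns \code{analyte}, \code{replicate_id},
#' \code{od600}, \code{conc_mM}.
#' @param path file path.
#' @return data.frame.
#' @export
readRateSamples <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("analyte", "replicate_id", "od600", "conc_mM")
  if (!all(req %in% names(d)))
    stop("rate-sample file must have columns ", paste(req, collapse = ", "))
  if (any(d$conc_mM < 0)) stop("concentrations must be >= 0")
  d
}

#' Read a mass-isotopomer table
#'
#' Tab-separated with columns \code{fragment_id}, \code{n_carbons},
#' \code{m0}, \code{m1}, ...; rows are normalized to unit sum.
#' @param path file path.
#' @return named list of [MassIsotopomerDistribution-class] objects.
#' @export
readMDVTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  mcols <- grep("^m[0-9]+$", names(d), value = TRUE)
  if (!all(c("fragment_id", "n_carbons") %in% names(d)) || !length(mcols))
    stop("MDV file must have fragment_id, n_carbons and m0.. columns")
  mcols <- mcols[order(as.integer(sub("^m", "", mcols)))]
  out <- lapply(seq_len(nrow(d)), function(i) {
    a <- as.numeric(d[i, mcols])
    a <- a[!is.na(a)]
    mdv(a, nCarbons = d$n_carbons[i], fragmentId = d$fragment_id[i])
  })
  names(out) <- d$fragment_id
  out
}

#' Read fragment compositions from JSON
#'
#' JSON object mapping fragment id to an object of element counts, e.g.
#' \code{{"Asp_M57": {"C": 14, "H": 40, "N": 1, "O": 4, "Si": 3}}}.
#' @param path file path.
#' @return named list of named integer vectors.
#' @export
readFragmentCompositions <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(x, function(el) {
    v <- unlist(el)
    if (any(v < 0)) stop("element counts must be non-negative")
    storage.mode(v) <- "integer"
    v
  })
}

#' Read a TF-target network from delimited text
#'
#' Two or three tab-separated columns: \code{tf}, \code{target} and
#' optionally \code{evidence} (default \code{"literature"}).
#' @param path file path.
#' @param universe enzyme universe for the network.
#' @return a [RegulatoryNetwork-class].
#' @export
readRegulatoryNetwork <- function(path, universe) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tf", "target") %in% names(d)))
    stop("network file must have columns tf, target[, evidence]")
  if (is.null(d$evidence)) d$evidence <- "literature"
  regulatoryNetwork(d$tf, d$target, d$evidence, universe = universe)
}

#' Bundled physiology fixture (growth, uptake, yield, respiration)
#'
#' The per-carbon-source physiological reference values shipped with the
#' package: uptake rate (mmol/g/h, negative = consumption), biomass yield
#' (g/g), growth rate (1/h) and degree of respiration (AU), with SDs and
#' the molecular weight used for yield arithmetic.
#'
#' @return data.frame with one row per carbon source.
#' @export
loadTable1Fixture <- function() {
  path <- system.file("extdata", "table1_physiology.tsv",
                      package = "respflux")
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) != 4L ||
      !identical(d$c_source, c("glucose", "mannose", "galactose", "pyruvate")))
    stop("corrupted fixture: table1_physiology.tsv")
  d
}

#' Bundled enzyme fold-change fixture
#'
#' Fold changes in metabolic enzyme expression on mannose, galactose and
#' pyruvate relative to glucose for the 47 investigated GFP-fusion strains
#' (21 TCA cycle, 19 respiratory chain, 7 ethanol production).  Codes:
#' \code{ok} significant fold change, \code{nsc} not significantly
#' changed, \code{ng} no growth, \code{bd} below detection (fold 0).
#' \code{*_pbin} preserves the published p-value bin markers
#' (\code{*} = 0.06-0.10, \code{**} = 0.11-0.12).
#'
#' @return a \code{"FoldChangeTable"} data.frame (47 rows).
#' @export
loadTable2Fixture <- function() {
  path <- system.file("extdata", "table2_foldchanges.tsv",
                      package = "respflux")
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = "NA")
  counts <- table(d$pathway)
  if (nrow(d) != 47L || anyDuplicated(d$enzyme) ||
      counts[["tca"]] != 21L || counts[["respiratory_chain"]] != 19L ||
      counts[["ethanol"]] != 7L)
    stop("corrupted fixture: table2_foldchanges.tsv")
  class(d) <- c("FoldChangeTable", "data.frame")
  d
}

#' End-to-end summary report
#'
#' Runs the downstream analysis chain on the bundled (or user-supplied)
#' tables: differential-expression counts, pattern classification,
#' correlation of fold changes with the degree of respiration, yield
#' arithmetic consistency, and -- when a regulatory network is supplied --
#' the hypergeometric TF ranking for the galactose and pyruvate contrasts.
#'
#' @param foldTable a \code{"FoldChangeTable"} (default: bundled fixture).
#' @param physiology physiology table (default: bundled fixture).
#' @param network optional [RegulatoryNetwork-class] over the table's
#'   enzymes.
#' @param corrThreshold correlation-screen threshold.
#' @param top TFs reported per contrast.
#' @return list of class \code{"respirationReport"} with components
#'   \code{counts}, \code{patterns}, \code{correlation}, \code{yields},
#'   \code{tfRanking} (NULL without a network).
#' @export
respirationReport <- function(foldTable = loadTable2Fixture(),
                              physiology = loadTable1Fixture(),
                              network = NULL, corrThreshold = 0.90,
                              top = 5L) {
  counts <- summarizeDifferential(foldTable)
  patterns <- classifyPatterns(foldTable)
  degrees <- stats::setNames(physiology$degree_respiration,
                             physiology$c_source)
  corr <- correlateWithRespiration(
    foldTable,
    degrees = c(degrees[["glucose"]], degrees[["mannose"]],
                degrees[["galactose"]], degrees[["pyruvate"]]),
    threshold = corrThreshold)
  yields <- data.frame(
    c_source = physiology$c_source,
    printed = physiology$yield_mass,
    recomputed = yieldFromRates(physiology$growth_rate,
                                physiology$uptake_rate, physiology$mw))
  tfRanking <- NULL
  if (!is.null(network)) {
    net <- filterNetwork(network, universe = foldTable$enzyme)
    tfRanking <- list(
      galactose = rankTFs(net, foldTable$enzyme[.isUp(foldTable, "gal",
                                                      countNg = TRUE)],
                          top = top),
      pyruvate = rankTFs(net, foldTable$enzyme[.isUp(foldTable, "pyr",
                                                     countNg = TRUE)],
                         top = top))
  }
  structure(list(counts = counts, patterns = patterns, correlation = corr,
                 yields = yields, tfRanking = tfRanking),
            class = "respirationReport")
}

#' @export
print.respirationReport <- function(x, ...) {
  cat("== Differential expression counts ==\n")
  for (f in names(x$counts))
    cat(sprintf("  %-22s %.4g\n", f, x$counts[[f]]))
  cat("== Pattern classes ==\n")
  print(table(x$patterns$class))
  sel <- x$correlation[which(x$correlation$selected), ]
  cat("== Enzymes correlated with degree of respiration (|r| >= 0.9) ==\n")
  if (nrow(sel))
    cat(sprintf("  %s (r = %.3f, %s)\n", sel$enzyme, sel$r, sel$sign),
        sep = "")
  cat("== Yield arithmetic (printed vs recomputed, g/g) ==\n")
  print(transform(x$yields, recomputed = round(recomputed, 2)),
        row.names = FALSE)
  if (!is.null(x$tfRanking)) {
    for (cond in names(x$tfRanking)) {
      cat("== TF ranking (", cond, ") ==\n", sep = "")
      print(head(x$tfRanking[[cond]], 8), row.names = FALSE)
    }
  }
  invisible(x)
}
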