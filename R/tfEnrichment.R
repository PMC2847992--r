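#' Filter a regulatory network to curated edges within the enzyme universe
#'
#' Keeps literature-curated edges whose target belongs to the investigated
#' enzyme universe, collapses duplicate curation entries, and drops
#' transcription factors left without targets.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param universe enzyme universe (defaults to the network's own).
#' @param evidence evidence class to keep (default \code{"literature"}).
#' @return a filtered [RegulatoryNetwork-class].
#' @export
filterNetwork <- function(net, universe = NULL, evidence = "literature") {
  stopifnot(is(net, "RegulatoryNetwork"))
  if (is.null(universe)) universe <- net@universe
  e <- net@edges
  e <- e[e$evidence %in% evidence & e$target %in% universe, , drop = FALSE]
  e <- unique(e[, c("tf", "target")])
  e$evidence <- rep(evidence[1], nrow(e))
  rownames(e) <- NULL
  if (nrow(e) == 0L)
    warning("no edges survive the curation/universe filter")
  new("RegulatoryNetwork", edges = e[, c("tf", "target", "evidence")],
      universe = as.character(universe))
}

#' Upper-tail hypergeometric probability value f
#'
#' The probability that a transcription factor with \code{m} curated
#' targets among the \code{N} investigated enzymes hits at least \code{k}
#' of the \code{n} differentially expressed enzymes by chance:
#' \deqn{f = \sum_{i=k}^{\min(m,n)} \frac{{m \choose i}{N-m \choose n-i}}
#'   {{N \choose n}}.}
#' Computed by summing hypergeometric log-probabilities (log-sum-exp) for
#' numerical stability at extreme tails.
#'
#' @param k observed number of targets among the differential enzymes.
#' @param m total targets among all investigated enzymes (>= 1).
#' @param n number of differential enzymes.
#' @param N total number of investigated enzymes.
#' @return probability in (0, 1]; \code{f = 1} whenever \code{k = 0}.
#' @examples
#' fValue(2, m = 2, n = 2, N = 5)   # 0.1
#' fValue(1, m = 2, n = 2, N = 5)   # 0.7
#' @export
fValue <- function(k, m, n, N) {
  if (m < 1 || m > N) stop("m must be in 1..N")
  if (n < 0 || n > N) stop("n must be in 0..N")
  if (k < 0 || k > min(m, n))
    stop("k must be in 0..min(m, n)")
  if (k == 0) return(1)
  i <- k:min(m, n)
  lp <- stats::dhyper(i, m, N - m, n, log = TRUE)
  mx <- max(lp)
  min(exp(mx + log(sum(exp(lp - mx)))), 1)
}

#' Rank transcription factors by hypergeometric f value
#'
#' For every TF in the filtered network, counts its distinct targets among
#' the differential enzymes (k) and among the whole universe (m), computes
#' the f value against the universe size N, and returns the TFs with the
#' \code{top} lowest f values.  Ties in f are broken by larger k, then
#' alphabetically; all TFs tied with the last selected f value are
#' included, so more than \code{top} rows may be returned.
#'
#' @param net a filtered [RegulatoryNetwork-class].
#' @param diffSet character vector of differentially expressed enzyme ids.
#' @param N universe size for the hypergeometric (default: size of the
#'   network universe).
#' @param top number of lowest-f TFs to report (default 5).
#' @return data.frame with columns \code{tf}, \code{k}, \code{m},
#'   \code{f}, \code{rank}, \code{selected}; attribute \code{degenerate}
#'   flags the n = N case where every f is 1.
#' @export
rankTFs <- function(net, diffSet, N = length(universe(net)), top = 5L) {
  stopifnot(is(net, "RegulatoryNetwork"), length(diffSet) >= 1L)
  diffSet <- unique(diffSet)
  extra <- setdiff(diffSet, net@universe)
  if (length(extra))
    stop("differential enzymes outside the universe: ",
         paste(extra, collapse = ", "))
  n <- length(diffSet)
  e <- unique(net@edges[, c("tf", "target")])
  tfs <- sort(unique(e$tf))
  m <- vapply(tfs, function(tf)
    length(unique(e$target[e$tf == tf])), integer(1))
  k <- vapply(tfs, function(tf)
    length(unique(intersect(e$target[e$tf == tf], diffSet))), integer(1))
  f <- mapply(fValue, k, m, MoreArgs = list(n = n, N = N))
  ord <- order(f, -k, tfs)
  out <- data.frame(tf = tfs[ord], k = k[ord], m = m[ord], f = f[ord],
                    stringsAsFactors = FALSE)
  out$rank <- rank(out$f, ties.method = "min")
  cut <- if (nrow(out) <= top) max(out$f) else sort(out$f)[top]
  out$selected <- out$f <= cut
  degenerate <- n == N
  if (degenerate)
    warning("every investigated enzyme is differential (n = N); all f values are 1")
  attr(out, "degenerate") <- degenerate
  out
}

#' Bundled toy regulatory network
#'
#' A small five-TF network over a ten-enzyme universe used in the examples
#' and tests; hand-countable by design.
#'
#' @return a [RegulatoryNetwork-class].
#' @export
toyNetwork <- function() {
  path <- system.file("extdata", "toy_network.tsv", package = "respflux")
  readRegulatoryNetwork(path, universe = paste0("E", sprintf("%02d", 1:10)))
}
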