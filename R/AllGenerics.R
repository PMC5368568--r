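#' Accessors for linkEntropy result objects
#'
#' Slot access for the S4 result classes. `nodeMemberships()` returns the
#' n x K membership matrix (rownames are node labels); `nmfLoss()` the squared
#' reconstruction error; `edgeScores()` the per-edge score data.frame;
#' `scoringMethod()` and `scoreParams()` the method name and parameter list of
#' a score table or trace; `percolationThreshold()` and `peakSusceptibility()`
#' the detected threshold and susceptibility peak of a trace.
#'
#' @param x a linkEntropy S4 object of the matching class.
#' @return The slot contents; see Details for each accessor.
#' @name accessors
#' @aliases nodeMemberships nmfLoss edgeScores scoringMethod scoreParams
#'   percolationThreshold peakSusceptibility
#' @examples
#' g <- fixtureFig2()
#' tab <- degreeProduct(g)
#' head(edgeScores(tab))
#' scoringMethod(tab)
NULL

#' @rdname accessors
#' @export
setGeneric("nodeMemberships", function(x) standardGeneric("nodeMemberships"))

#' @rdname accessors
#' @export
setGeneric("nmfLoss", function(x) standardGeneric("nmfLoss"))

#' @rdname accessors
#' @export
setGeneric("edgeScores", function(x) standardGeneric("edgeScores"))

#' @rdname accessors
#' @export
setGeneric("scoringMethod", function(x) standardGeneric("scoringMethod"))

#' @rdname accessors
#' @export
setGeneric("scoreParams", function(x) standardGeneric("scoreParams"))

#' @rdname accessors
#' @export
setGeneric("percolationThreshold",
           function(x) standardGeneric("percolationThreshold"))

#' @rdname accessors
#' @export
setGeneric("peakSusceptibility",
           function(x) standardGeneric("peakSusceptibility"))

#' @rdname accessors
#' @export
setMethod("nodeMemberships", "MembershipMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("nodeMemberships", "FactorizationResult",
          function(x) x@membership@values)

#' @rdname accessors
#' @export
setMethod("nmfLoss", "FactorizationResult", function(x) x@loss)

#' @rdname accessors
#' @export
setMethod("edgeScores", "EdgeScoreTable", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("scoringMethod", "EdgeScoreTable", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("scoringMethod", "PercolationTrace", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("scoreParams", "EdgeScoreTable", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("percolationThreshold", "PercolationTrace", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("peakSusceptibility", "PercolationTrace", function(x) x@peak)

#' @describeIn accessors trace as a data.frame with columns f, rgc,
#'   susceptibility.
#' @param row.names,optional,... passed on as in [base::as.data.frame()].
#' @export
as.data.frame.PercolationTrace <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  x@trace
}

#' @describeIn accessors score table as a data.frame (from, to, score).
#' @export
as.data.frame.EdgeScoreTable <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  x@scores
}

#' @describeIn accessors one-row data.frame with the descriptor columns.
#' @export
as.data.frame.NetworkStats <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(N = x@nNodes, E = x@nEdges, mean_k = x@meanDegree,
             k_max = x@maxDegree, H_k = x@heterogeneity,
             r = x@assortativity, C = x@clustering)
}
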