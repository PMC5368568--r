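#' @import methods
#' @importFrom stats runif setNames
#' @importFrom utils head write.csv write.table read.delim
NULL

.CLAMP <- 1e-7

#' MembershipMatrix: node-community probability distributions
#'
#' An n x K nonnegative matrix whose row i is the probability distribution of
#' node i over K communities, as produced by symmetric NMF of the self-looped
#' adjacency matrix. Rows sum to one; after [clampZeros()] every entry is at
#' least 1e-7 so that logarithms are always defined.
#'
#' @slot values numeric matrix, n x K, rownames are node labels.
#' @slot nCommunities integer, the number of communities K.
#'
#' @seealso [factorizeAdjacency()], [clampZeros()], [nodeMemberships()]
#' @export
setClass("MembershipMatrix",
  slots = c(values = "matrix", nCommunities = "integer"))

setValidity("MembershipMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (is.null(rownames(v))) return("'values' must have node labels as rownames")
  if (ncol(v) != object@nCommunities) return("ncol(values) != nCommunities")
  if (any(v < 0)) return("membership probabilities must be nonnegative")
  if (any(abs(rowSums(v) - 1) > 1e-8)) return("rows must sum to 1")
  TRUE
})

#' FactorizationResult: one symmetric-NMF fit
#'
#' Bundles the fitted [MembershipMatrix-class] with the squared-error loss
#' \eqn{\|A - XX^T\|_F^2} evaluated at the returned membership, the number of
#' multiplicative-update iterations performed, a convergence flag and the RNG
#' seed used for initialization.
#'
#' @slot membership a [MembershipMatrix-class].
#' @slot loss numeric, squared Frobenius reconstruction error at the solution.
#' @slot nIterations integer, iterations run.
#' @slot converged logical, whether the relative loss change fell below tol.
#' @slot seed integer, initialization seed.
#'
#' @seealso [factorizeAdjacency()], [bestOfRestarts()], [nmfLoss()]
#' @export
setClass("FactorizationResult",
  slots = c(membership = "MembershipMatrix", loss = "numeric",
            nIterations = "integer", converged = "logical", seed = "integer"))

setValidity("FactorizationResult", function(object) {
  if (length(object@loss) != 1 || object@loss < 0)
    return("'loss' must be a single nonnegative number")
  TRUE
})

#' EdgeScoreTable: per-edge significance scores for one method
#'
#' Maps every edge of a graph to a nonnegative score under one named
#' edge-significance index, along with the parameters of the run (K, seeds,
#' theta, ...). The table is the ranking input to [percolate()].
#'
#' @slot method character, the index name (e.g. "le", "betweenness").
#' @slot scores data.frame with columns `from`, `to` (character node labels,
#'   `from` < `to` in graph node order) and `score` (numeric, finite, >= 0).
#' @slot params named list of run parameters.
#'
#' @seealso [scoreMethod()], [scoreLE()], [edgeScores()]
#' @export
setClass("EdgeScoreTable",
  slots = c(method = "character", scores = "data.frame", params = "list"))

setValidity("EdgeScoreTable", function(object) {
  sc <- object@scores
  if (!all(c("from", "to", "score") %in% names(sc)))
    return("scores must have columns from, to, score")
  if (!is.numeric(sc$score)) return("'score' must be numeric")
  if (any(!is.finite(sc$score))) return("scores must be finite")
  if (any(sc$score < -1e-12)) return("scores must be nonnegative")
  if (length(object@method) != 1) return("'method' must be a single name")
  TRUE
})

#' PercolationTrace: a targeted edge-attack trajectory
#'
#' Records, after each batch of removals in descending-score order, the
#' fraction of edges removed f, the giant-component fraction R_GC (relative to
#' the original node count) and the normalized susceptibility
#' \eqn{\tilde S = \sum_s n_s s^2 / N} over all components but one largest.
#' The percolation threshold is the smallest f attaining the susceptibility
#' peak.
#'
#' @slot trace data.frame with columns `f`, `rgc`, `susceptibility`; the first
#'   row is the intact graph at f = 0.
#' @slot threshold numeric, detected percolation threshold.
#' @slot peak numeric, maximum susceptibility along the trace.
#' @slot tieSeed integer, seed used to shuffle equal-score ties.
#' @slot method character, name of the scoring method attacked with.
#'
#' @seealso [percolate()], [detectThreshold()], [susceptibility()]
#' @export
setClass("PercolationTrace",
  slots = c(trace = "data.frame", threshold = "numeric", peak = "numeric",
            tieSeed = "integer", method = "character"))

setValidity("PercolationTrace", function(object) {
  tr <- object@trace
  if (!all(c("f", "rgc", "susceptibility") %in% names(tr)))
    return("trace must have columns f, rgc, susceptibility")
  if (is.unsorted(tr$f)) return("'f' must be non-decreasing")
  if (any(diff(tr$rgc) > 1e-12)) return("R_GC must be non-increasing in f")
  TRUE
})

#' NetworkStats: basic structural descriptors of a network
#'
#' The standard descriptor tuple for an undirected, unweighted network: node
#' and edge counts, mean and maximum degree, degree heterogeneity
#' \eqn{H_k = \langle k^2\rangle/\langle k\rangle^2}, degree assortativity r
#' (Pearson correlation of endpoint degrees over edges) and the mean local
#' clustering coefficient C.
#'
#' @slot nNodes,nEdges integer counts.
#' @slot meanDegree,heterogeneity,assortativity,clustering numeric descriptors.
#' @slot maxDegree integer, maximum degree.
#'
#' @seealso [networkStats()]
#' @export
setClass("NetworkStats",
  slots = c(nNodes = "integer", nEdges = "integer", meanDegree = "numeric",
            maxDegree = "integer", heterogeneity = "numeric",
            assortativity = "numeric", clustering = "numeric"))

setValidity("NetworkStats", function(object) {
  if (object@nNodes < 0 || object@nEdges < 0) return("negative counts")
  if (is.finite(object@heterogeneity) && object@heterogeneity < 1 - 1e-12)
    return("heterogeneity must be >= 1")
  TRUE
})

setMethod("show", "MembershipMatrix", function(object) {
  cat(sprintf("MembershipMatrix: %d nodes x %d communities\n",
              nrow(object@values), object@nCommunities))
  cat("head of rows:\n")
  print(utils::head(round(object@values, 4), 4L))
  invisible(object)
})

setMethod("show", "FactorizationResult", function(object) {
  cat(sprintf(
    "FactorizationResult: K = %d, loss = %.6g, %d iteration(s), %s (seed %d)\n",
    object@membership@nCommunities, object@loss, object@nIterations,
    if (object@converged) "converged" else "not converged", object@seed))
  invisible(object)
})

setMethod("show", "EdgeScoreTable", function(object) {
  cat(sprintf("EdgeScoreTable: method '%s', %d edge(s)\n",
              object@method, nrow(object@scores)))
  if (length(object@params))
    cat("params:", paste(names(object@params),
        vapply(object@params, function(p) paste(format(p), collapse = ","),
               character(1)), sep = "=", collapse = ", "), "\n")
  print(utils::head(object@scores, 5L))
  invisible(object)
})

setMethod("show", "PercolationTrace", function(object) {
  cat(sprintf(
    "PercolationTrace: method '%s', %d point(s), threshold f* = %.4g, peak susceptibility = %.4g\n",
    object@method, nrow(object@trace), object@threshold, object@peak))
  invisible(object)
})

setMethod("show", "NetworkStats", function(object) {
  cat("NetworkStats:\n")
  print(as.data.frame(object), row.names = FALSE)
  invisible(object)
})
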