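## Link Entropy scoring: entropy + Jensen-Shannon divergence of endpoint
## membership distributions.

.checkDist <- function(p, what = "p") {
  if (any(p <= 0)) stop(what, " must be strictly positive (clamp first)",
                        call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6)
    stop(what, " must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
  invisible(p)
}

#' Shannon entropy of a membership distribution
#'
#' \eqn{H(p) = -\sum_k p_k \log_b p_k} with logarithm base `logBase`. With
#' base K (the number of communities) the entropy of any K-component
#' distribution lies in [0, 1]: 0 for a node purely in one community, 1 for a
#' node spread evenly across all of them. High-entropy nodes are the
#' overlapping nodes straddling community boundaries.
#'
#' @param p probability vector, strictly positive, summing to 1.
#' @param logBase logarithm base; by convention the number of communities K
#'   (2 when K = 2).
#' @return Entropy in [0, 1] (up to clamping slack).
#' @examples
#' communityEntropy(c(0.5, 0.5), 2)   # 1: maximally overlapping
#' @export
communityEntropy <- function(p, logBase = length(p)) {
  .checkDist(p)
  -sum(p * log(p)) / log(logBase)
}

#' Jensen-Shannon divergence between two membership distributions
#'
#' \eqn{JSD(p, q) = \tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)} with the common
#' baseline \eqn{m = (p+q)/2} and logarithms in base `logBase`. Symmetric in
#' its arguments and bounded in [0, 1] for base >= 2; maximal when p and q
#' put all their mass on different communities — the signature of an edge
#' joining two cleanly separated communities.
#'
#' @param p,q probability vectors of equal length, strictly positive,
#'   summing to 1.
#' @inheritParams communityEntropy
#' @return Divergence in [0, 1].
#' @examples
#' jsDivergence(c(0.9, 0.1), c(0.9, 0.1), 2)   # 0
#' @export
jsDivergence <- function(p, q, logBase = length(p)) {
  if (length(p) != length(q))
    stop("p and q must have the same length", call. = FALSE)
  .checkDist(p, "p"); .checkDist(q, "q")
  m <- (p + q) / 2
  (0.5 * sum(p * log(p / m)) + 0.5 * sum(q * log(q / m))) / log(logBase)
}

#' Link Entropy of one edge
#'
#' Combines the two complementary signals of an inter-community edge: (i) the
#' mean entropy of the endpoint membership distributions, which is high when
#' an endpoint is an overlapping node, and (ii) the Jensen-Shannon divergence
#' between them, which is high when the endpoints belong cleanly to different
#' communities (where the entropies are near zero and signal nothing). The
#' two aspects are averaged:
#' \deqn{LE = \frac12\left[\frac{H(x_i) + H(x_j)}{2} + JSD(x_i, x_j)\right]}
#' giving a score in [0, 1] with base-K logarithms.
#'
#' @param xi,xj the two endpoints' membership distributions (clamped,
#'   normalized).
#' @inheritParams communityEntropy
#' @return The LE score in [0, 1].
#' @examples
#' linkEntropy(c(0.5, 0.5), c(0.5, 0.5), 2)   # 0.5: overlapping endpoints
#' @export
linkEntropy <- function(xi, xj, logBase = length(xi)) {
  0.5 * ((communityEntropy(xi, logBase) + communityEntropy(xj, logBase)) / 2 +
           jsDivergence(xi, xj, logBase))
}

#' Link Entropy scores for every edge of a graph
#'
#' The full pipeline: build the self-looped adjacency matrix, fit the
#' symmetric NMF keeping the best of `nRestarts` random restarts, clamp zero
#' memberships, then score every edge with [linkEntropy()] using base-K
#' logarithms. The returned table records K, the seeds, the restart count and
#' the NMF loss in its `params`.
#'
#' The defaults (K = 2, 20 restarts) suit targeted-attack ranking: splitting
#' a network into two large parts by removing few edges is exactly the K = 2
#' objective, and restarts stabilize the stochastic fit. Use `nRestarts = 1`
#' to study single-initialization variability.
#'
#' @param g an igraph.
#' @param k number of communities (>= 2; K = 1 carries no information).
#' @param nRestarts NMF restarts, best loss kept.
#' @param seed base seed for the restarts.
#' @param maxIter,tol passed to [factorizeAdjacency()].
#' @return An [EdgeScoreTable-class] with method `"le"`.
#' @examples
#' tab <- scoreLE(fixtureFig2(), k = 2, nRestarts = 5, seed = 1)
#' head(edgeScores(tab)[order(-edgeScores(tab)$score), ])
#' @export
scoreLE <- function(g, k = 2, nRestarts = 20, seed = 1, maxIter = 2000,
                    tol = 1e-9) {
  g <- .canonGraph(g)
  if (k < 2) stop("k must be >= 2 for edge scoring", call. = FALSE)
  a <- buildAdjacency(g)
  fit <- bestOfRestarts(a, k, nRestarts = nRestarts, baseSeed = seed,
                        maxIter = maxIter, tol = tol)
  x <- clampZeros(fit@membership)@values
  el <- .edgeMatrix(g)
  score <- vapply(seq_len(nrow(el)), function(i)
    linkEntropy(x[el[i, 1], ], x[el[i, 2], ], logBase = k), numeric(1))
  new("EdgeScoreTable", method = "le",
      scores = data.frame(from = el[, 1], to = el[, 2], score = score),
      params = list(k = k, nRestarts = nRestarts, seed = seed,
                    loss = fit@loss, nmfSeed = fit@seed, logBase = k))
}
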