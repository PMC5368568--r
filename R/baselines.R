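## The six benchmark edge-significance indices.
##
## All operate on undirected, unweighted graphs and return an EdgeScoreTable
## over exactly the graph's edge set. Endpoint-symmetric and nonnegative by
## construction.

.scoreTable <- function(g, method, score, params = list()) {
  el <- .edgeMatrix(g)
  new("EdgeScoreTable", method = method,
      scores = data.frame(from = el[, 1], to = el[, 2], score = score),
      params = params)
}

#' Edge betweenness centrality
#'
#' For each edge E, the sum over unordered node pairs \{s, t\} of
#' \eqn{\sigma_{st}(E)/\sigma_{st}}, the fraction of shortest s-t paths that
#' pass through E. Pairs in different components contribute 0. A global
#' index: expensive on large networks, but sensitive to edges that carry
#' shortest-path traffic between regions.
#'
#' @param g an igraph.
#' @return An [EdgeScoreTable-class] with method `"betweenness"`.
#' @examples
#' edgeScores(edgeBetweenness(generateBarbell(3)))
#' @export
edgeBetweenness <- function(g) {
  g <- .canonGraph(g)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  b <- igraph::edge_betweenness(g, directed = FALSE)
  .scoreTable(g, "betweenness", b)
}

#' Degree product
#'
#' \eqn{(k_x k_y)^\theta} for an edge between nodes of degree k_x and k_y;
#' the default exponent is \eqn{\theta = 1} since only the ranking matters.
#' Cheap, but ranks hub-hub edges highest, which is misleading in
#' disassortative networks where the connectivity-critical edges sit between
#' communities, not between hubs.
#'
#' @param g an igraph.
#' @param theta exponent (default 1; 0 makes all scores 1).
#' @return An [EdgeScoreTable-class] with method `"degree_product"`.
#' @export
degreeProduct <- function(g, theta = 1) {
  g <- .canonGraph(g)
  k <- igraph::degree(g)
  names(k) <- .nodeLabels(g)
  el <- .edgeMatrix(g)
  .scoreTable(g, "degree_product", (k[el[, 1]] * k[el[, 2]])^theta,
              params = list(theta = theta))
}

## Exact maximal-clique enumeration (Bron-Kerbosch with pivoting), run at the
## R level so a wall-clock deadline can actually interrupt the search.
## adj: list of integer neighbor vectors. Returns list of integer vectors.
.maximalCliques <- function(adj, deadline) {
  out <- vector("list", 64L)
  nOut <- 0L
  calls <- 0L
  bk <- function(r, p, x) {
    calls <<- calls + 1L
    if (calls %% 64L == 0L && Sys.time() > deadline)
      stop(structure(class = c("linkEntropyTimeout", "error", "condition"),
                     list(message = "clique search timed out", call = NULL)))
    if (!length(p) && !length(x)) {
      nOut <<- nOut + 1L
      if (nOut > length(out)) length(out) <<- 2L * nOut
      out[[nOut]] <<- r
      return(invisible())
    }
    cand <- c(p, x)
    pivot <- cand[which.max(vapply(cand, function(u)
      sum(p %in% adj[[u]]), integer(1)))]
    for (v in setdiff(p, adj[[pivot]])) {
      bk(c(r, v), intersect(p, adj[[v]]), intersect(x, adj[[v]]))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
    invisible()
  }
  bk(integer(0), seq_along(adj), integer(0))
  out[seq_len(nOut)]
}

#' Bridgeness
#'
#' \eqn{\sqrt{S_x S_y}/S_e}, where \eqn{S_x} (resp. \eqn{S_e}) is the size of
#' the largest clique containing node x (resp. edge e). Edges joining two
#' cliques get scores above 1; edges inside a clique score 1. The index is
#' computed from an exact maximal-clique enumeration (Bron-Kerbosch with
#' pivoting), which is exponential in the worst case, so a wall-clock
#' `timeout` guards the search; on timeout an error advises skipping the
#' index (no heuristic fallback, which would silently change the index).
#'
#' @param g an igraph.
#' @param timeout seconds allowed for clique enumeration (default 60).
#' @return An [EdgeScoreTable-class] with method `"bridgeness"`.
#' @examples
#' edgeScores(bridgeness(generateBarbell(3)))   # bridge scores 1.5
#' @export
bridgeness <- function(g, timeout = 60) {
  g <- .canonGraph(g)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  labels <- .nodeLabels(g)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  cliques <- tryCatch(
    .maximalCliques(adj, deadline = Sys.time() + timeout),
    linkEntropyTimeout = function(e) {
      stop("maximal-clique enumeration exceeded ", timeout,
           " s; skip the bridgeness index for this network", call. = FALSE)
    })
  sNode <- stats::setNames(rep(1, length(labels)), labels)
  el <- .edgeMatrix(g)
  keys <- .edgeKeys(el)
  sEdge <- stats::setNames(rep(2, nrow(el)), keys)
  for (cl in cliques) {
    members <- labels[cl]
    sz <- length(members)
    sNode[members] <- pmax(sNode[members], sz)
    if (sz >= 2) {
      prs <- t(utils::combn(members, 2))
      k <- .edgeKeys(prs)
      k <- k[k %in% keys]
      sEdge[k] <- pmax(sEdge[k], sz)
    }
  }
  .scoreTable(g, "bridgeness",
              unname(sqrt(sNode[el[, 1]] * sNode[el[, 2]]) / sEdge[keys]),
              params = list(timeout = timeout))
}

#' Diffusion importance
#'
#' Motivated by epidemic spread along an edge e_xy: once the infection
#' crosses to y, it can only reach new territory through y's links that leave
#' x's closed neighborhood. The score is \eqn{(n_{x\to y} + n_{y\to x})/2}
#' with \eqn{n_{x\to y} = |N(y) \setminus (N(x) \cup \{x\})|}.
#'
#' @param g an igraph.
#' @return An [EdgeScoreTable-class] with method `"diffusion"`.
#' @export
diffusionImportance <- function(g) {
  g <- .canonGraph(g)
  labels <- .nodeLabels(g)
  nbrs <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                 function(v) labels[as.integer(v)])
  names(nbrs) <- labels
  el <- .edgeMatrix(g)
  outw <- function(x, y)   # y's links leaving x's closed neighborhood
    length(setdiff(nbrs[[y]], c(nbrs[[x]], x)))
  score <- vapply(seq_len(nrow(el)), function(i) {
    (outw(el[i, 1], el[i, 2]) + outw(el[i, 2], el[i, 1])) / 2
  }, numeric(1))
  .scoreTable(g, "diffusion", score)
}

#' Topological overlap
#'
#' The fraction of shared neighbors of an edge's endpoints,
#' \eqn{O_{ij} = n_{ij} / ((k_i - 1) + (k_j - 1) - n_{ij})} with n_ij the
#' number of common neighbors. A tie-strength proxy: 1 inside a clique, 0
#' for an edge with no common friends. When the denominator is 0 (both
#' endpoints have no other neighbors) the score is defined as 0.
#'
#' @param g an igraph.
#' @return An [EdgeScoreTable-class] with method `"overlap"`.
#' @export
topologicalOverlap <- function(g) {
  g <- .canonGraph(g)
  labels <- .nodeLabels(g)
  k <- stats::setNames(igraph::degree(g), labels)
  nbrs <- lapply(igraph::adjacent_vertices(g, igraph::V(g)),
                 function(v) labels[as.integer(v)])
  names(nbrs) <- labels
  el <- .edgeMatrix(g)
  score <- vapply(seq_len(nrow(el)), function(i) {
    u <- el[i, 1]; v <- el[i, 2]
    nij <- length(intersect(nbrs[[u]], nbrs[[v]]))
    den <- (k[[u]] - 1) + (k[[v]] - 1) - nij
    if (den <= 0) 0 else nij / den
  }, numeric(1))
  .scoreTable(g, "overlap", score)
}

#' ERW-Kpath edge centrality
#'
#' Monte-Carlo estimate of k-path edge centrality: `rho` self-avoiding (in
#' edges) random walks of at most `k` steps are simulated; each walk starts
#' at a uniformly random source and at every step picks uniformly among the
#' incident edges it has not yet traversed, stopping early when none remain.
#' An edge's score is the fraction of walks that traversed it. Longer walks
#' (the default k = 20) spread the scores and separate central from
#' peripheral edges.
#'
#' @param g an igraph.
#' @param k maximum walk length in edges (default 20).
#' @param rho number of simulated walks (default `50 * ecount(g)`).
#' @param seed integer RNG seed; same seed, same table.
#' @return An [EdgeScoreTable-class] with method `"kpath"`.
#' @export
erwKpath <- function(g, k = 20, rho = 50 * igraph::ecount(g), seed = 1) {
  g <- .canonGraph(g)
  stopifnot(k >= 1, rho >= 1)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  inc <- lapply(igraph::incident_edges(g, igraph::V(g)), as.integer)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  counts <- numeric(m)
  withr::with_seed(seed, {
    for (w in seq_len(rho)) {
      node <- sample.int(n, 1)
      used <- integer(0)
      for (step in seq_len(k)) {
        cand <- setdiff(inc[[node]], used)
        if (!length(cand)) break
        e <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
        counts[e] <- counts[e] + 1
        used <- c(used, e)
        ep <- ends[e, ]
        node <- if (ep[1] == node) ep[2] else ep[1]
      }
    }
  })
  ## counts follow igraph edge order; .edgeMatrix preserves that order
  .scoreTable(g, "kpath", counts / rho,
              params = list(k = k, rho = rho, seed = seed))
}

#' Score a graph's edges with any of the seven indices
#'
#' Uniform dispatcher over the Link Entropy score and the six benchmark
#' indices. Method-specific parameters are passed through `...` and recorded
#' in the returned table.
#'
#' @param g an igraph.
#' @param method one of `"le"`, `"betweenness"`, `"degree_product"`,
#'   `"bridgeness"`, `"diffusion"`, `"overlap"`, `"kpath"`.
#' @param ... parameters for the chosen method (e.g. `k`, `nRestarts`,
#'   `seed` for `"le"`; `theta`; `timeout`; `k`, `rho`, `seed` for
#'   `"kpath"`).
#' @return An [EdgeScoreTable-class].
#' @examples
#' scoreMethod(fixtureFig2(), "degree_product")
#' @export
scoreMethod <- function(g, method, ...) {
  methods <- c("le", "betweenness", "degree_product", "bridgeness",
               "diffusion", "overlap", "kpath")
  if (!is.character(method) || length(method) != 1 || !method %in% methods)
    stop("unknown method '", paste(method, collapse = ","),
         "'; valid methods: ", paste(methods, collapse = ", "),
         call. = FALSE)
  switch(method,
         le = scoreLE(g, ...),
         betweenness = edgeBetweenness(g),
         degree_product = degreeProduct(g, ...),
         bridgeness = bridgeness(g, ...),
         diffusion = diffusionImportance(g),
         overlap = topologicalOverlap(g),
         kpath = erwKpath(g, ...))
}
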