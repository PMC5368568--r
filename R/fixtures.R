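## Built-in example graphs and seeded synthetic generators.

#' Nine-node three-triangle example graph
#'
#' The small worked example used throughout the documentation: three
#' triangles \{1,2,3\}, \{4,5,6\} and \{7,8,9\} joined by the edges 1-4, 5-7
#' and 5-8 (12 edges in total). The triangle edges are redundant for
#' connectivity; the joining edges are the weak ties whose removal splits the
#' graph, so a good edge-significance index must rank them highest.
#'
#' @return An igraph with 9 nodes labelled "1".."9" and 12 edges.
#' @examples
#' igraph::ecount(fixtureFig2())
#' @export
fixtureFig2 <- function() {
  el <- matrix(c("1","2", "1","3", "2","3",
                 "4","5", "4","6", "5","6",
                 "7","8", "7","9", "8","9",
                 "1","4", "5","7", "5","8"),
               ncol = 2, byrow = TRUE)
  .canonGraph(igraph::graph_from_edgelist(el, directed = FALSE))
}

#' Zachary karate-club network
#'
#' The classic 34-node, 78-edge friendship network of a university karate
#' club (Zachary 1977), bundled as a stable reference for descriptive
#' statistics: mean degree 4.5882, degree heterogeneity 1.6933, assortativity
#' -0.4756, mean local clustering 0.5706.
#'
#' @return An igraph with 34 nodes labelled "1".."34".
#' @export
fixtureKarate <- function() {
  el <- matrix(c(
    1,2, 1,3, 1,4, 1,5, 1,6, 1,7, 1,8, 1,9, 1,11, 1,12, 1,13, 1,14, 1,18,
    1,20, 1,22, 1,32, 2,3, 2,4, 2,8, 2,14, 2,18, 2,20, 2,22, 2,31, 3,4, 3,8,
    3,9, 3,10, 3,14, 3,28, 3,29, 3,33, 4,8, 4,13, 4,14, 5,7, 5,11, 6,7, 6,11,
    6,17, 7,17, 9,31, 9,33, 9,34, 10,34, 14,34, 15,33, 15,34, 16,33, 16,34,
    19,33, 19,34, 20,34, 21,33, 21,34, 23,33, 23,34, 24,26, 24,28, 24,30,
    24,33, 24,34, 25,26, 25,28, 25,32, 26,32, 27,30, 27,34, 28,34, 29,32,
    29,34, 30,33, 30,34, 31,33, 31,34, 32,33, 32,34, 33,34), ncol = 2,
    byrow = TRUE)
  .canonGraph(igraph::graph_from_edgelist(apply(el, 2, as.character),
                                          directed = FALSE))
}

#' Two-block planted-partition random graph
#'
#' Draws a graph with two blocks of `nPerBlock` nodes each: every within-block
#' pair is connected independently with probability `pIn`, every cross-block
#' pair with probability `pOut < pIn`. The planted inter-block edges — the
#' ground-truth significant edges — are recoverable with
#' [plantedInterEdges()]; each vertex carries its block in the `block`
#' attribute. The same seed always yields the same graph.
#'
#' @param nPerBlock nodes per block (>= 2).
#' @param pIn,pOut within- and between-block edge probabilities,
#'   0 <= pOut < pIn <= 1.
#' @param seed integer RNG seed.
#' @return An igraph with nodes "1".."2*nPerBlock"; block 1 is nodes
#'   1..nPerBlock. Disconnected output is allowed (a message is emitted).
#' @examples
#' g <- generatePlantedPartition(10, 0.8, 0.05, seed = 1)
#' nrow(plantedInterEdges(g))
#' @export
generatePlantedPartition <- function(nPerBlock, pIn, pOut, seed) {
  stopifnot(nPerBlock >= 2, pOut >= 0, pIn <= 1)
  if (!(pOut < pIn)) stop("need pOut < pIn", call. = FALSE)
  n <- 2L * nPerBlock
  block <- rep(1:2, each = nPerBlock)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sameBlock <- block[pairs[, 1]] == block[pairs[, 2]]
  p <- ifelse(sameBlock, pIn, pOut)
  keep <- withr::with_seed(seed, stats::runif(nrow(pairs)) < p)
  el <- pairs[keep, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    matrix(as.character(el), ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g),
                            name = setdiff(as.character(1:n),
                                           igraph::V(g)$name))
  g <- .canonGraph(g)
  igraph::V(g)$block <- block[as.integer(igraph::V(g)$name)]
  ends <- .edgeMatrix(g)
  igraph::E(g)$inter <- block[as.integer(ends[, 1])] !=
    block[as.integer(ends[, 2])]
  if (igraph::components(g)$no > 1)
    message("planted-partition draw is disconnected (",
            igraph::components(g)$no, " components)")
  g
}

#' Ground-truth inter-block edges of a planted-partition graph
#'
#' @param g a graph from [generatePlantedPartition()].
#' @return data.frame with columns `from`, `to`, one row per planted
#'   inter-block edge.
#' @export
plantedInterEdges <- function(g) {
  if (is.null(igraph::E(g)$inter))
    stop("graph has no 'inter' edge attribute; not a planted partition",
         call. = FALSE)
  el <- .edgeMatrix(g)
  data.frame(from = el[igraph::E(g)$inter, 1],
             to = el[igraph::E(g)$inter, 2])
}

#' Barbell graph: two cliques joined by one bridge
#'
#' Two complete graphs of `cliqueSize` nodes connected by a single bridge
#' edge — the canonical test case for bridge-detecting indices: removing the
#' one bridge halves the giant component.
#'
#' @param cliqueSize nodes per clique (>= 3).
#' @return An igraph with `2 * cliqueSize` nodes; the bridge joins node
#'   `cliqueSize` to node `cliqueSize + 1`.
#' @examples
#' g <- generateBarbell(3)
#' igraph::ecount(g)   # 7 = 3 + 3 + bridge
#' @export
generateBarbell <- function(cliqueSize) {
  stopifnot(cliqueSize >= 3)
  cl <- utils::combn(cliqueSize, 2)
  el <- cbind(rbind(t(cl), t(cl) + cliqueSize),
              deparse.level = 0)
  el <- rbind(el, c(cliqueSize, cliqueSize + 1L))
  .canonGraph(igraph::graph_from_edgelist(
    matrix(as.character(el), ncol = 2), directed = FALSE))
}
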