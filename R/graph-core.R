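## Graph representation, I/O and descriptive statistics.
##
## Graphs are igraph objects with character vertex names, undirected and
## simple. Vertices are kept in sorted label order (numeric order when every
## label is an integer string) so that adjacency-matrix row indices are
## reproducible across runs and platforms.

.sortLabels <- function(labels) {
  if (all(grepl("^[0-9]+$", labels))) {
    labels[order(as.integer(labels))]
  } else {
    sort(labels, method = "radix")
  }
}

## Canonicalize: named vertices, sorted order. Errors on directed input.
.canonGraph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g))
    stop("directed graphs are not supported; symmetrize explicitly first",
         call. = FALSE)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  ord <- .sortLabels(igraph::V(g)$name)
  igraph::permute(g, match(igraph::V(g)$name, ord))
}

.nodeLabels <- function(g) igraph::V(g)$name

## Edge list as a character matrix with from < to in node order.
.edgeMatrix <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(matrix(character(0), 0, 2))
  ord <- .sortLabels(.nodeLabels(g))
  swap <- match(el[, 1], ord) > match(el[, 2], ord)
  el[swap, ] <- el[swap, 2:1]
  el
}

## Orientation-independent edge keys (lexicographic within the pair).
.edgeKeys <- function(el) {
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
}

#' Read an undirected network from an edge-list or GML file
#'
#' Edge-list files contain one edge per line as two whitespace-separated node
#' labels; everything after a `#` is a comment. Duplicate edges are collapsed
#' and self-loops dropped (a message reports how many of each). GML files are
#' read with igraph; directed GML input is rejected unless
#' `symmetrize = TRUE`, and any edge weights are discarded — every graph here
#' is treated as undirected and unweighted.
#'
#' @param path path to the input file.
#' @param format `"edgelist"` (default) or `"gml"`.
#' @param symmetrize if `TRUE`, a directed input graph is converted to its
#'   undirected skeleton instead of raising an error.
#' @return An undirected simple igraph with character vertex names in sorted
#'   label order.
#' @examples
#' f <- tempfile()
#' writeLines(c("1 2", "2 3  # a comment", "1 3"), f)
#' g <- readEdgelist(f)
#' igraph::ecount(g)
#' @seealso [writeEdgelist()], [networkStats()]
#' @export
readEdgelist <- function(path, format = c("edgelist", "gml"),
                         symmetrize = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "gml") {
    g <- igraph::read_graph(path, format = "gml")
    if (igraph::is_directed(g)) {
      if (!symmetrize)
        stop("GML graph is directed; pass symmetrize = TRUE to use its ",
             "undirected skeleton", call. = FALSE)
      g <- igraph::as_undirected(g, mode = "collapse")
    }
    if (is.null(igraph::V(g)$name)) {
      lab <- igraph::vertex_attr(g, "label")
      if (is.null(lab)) lab <- igraph::vertex_attr(g, "id")
      if (is.null(lab)) lab <- seq_len(igraph::vcount(g))
      igraph::V(g)$name <- as.character(lab)
    }
    for (attr in igraph::edge_attr_names(g))
      g <- igraph::delete_edge_attr(g, attr)
    if (igraph::vcount(g) == 0) stop("empty graph in ", path, call. = FALSE)
    return(.canonGraph(g))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  keep <- nzchar(lines)
  if (!any(keep)) stop("empty edge list: ", path, call. = FALSE)
  tokens <- strsplit(lines[keep], "[[:space:]]+")
  bad <- which(lengths(tokens) != 2)
  if (length(bad)) {
    lineno <- which(keep)[bad[1]]
    stop(sprintf("malformed edge-list line %d in %s: expected 2 fields, got %d",
                 lineno, path, lengths(tokens)[bad[1]]), call. = FALSE)
  }
  el <- do.call(rbind, tokens)
  loops <- el[, 1] == el[, 2]
  if (any(loops)) {
    message(sum(loops), " self-loop(s) dropped from ", path)
    el <- el[!loops, , drop = FALSE]
  }
  if (nrow(el) == 0) stop("no edges left after dropping self-loops in ",
                          path, call. = FALSE)
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) collapsed from ", path)
    el <- el[!dup, , drop = FALSE]
  }
  .canonGraph(igraph::graph_from_edgelist(el, directed = FALSE))
}

#' Write a graph as a plain edge list
#'
#' One edge per line, two whitespace-separated node labels. Round trips with
#' [readEdgelist()]: the edge set read back is identical.
#'
#' @param g an igraph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgelist <- function(g, path) {
  g <- .canonGraph(g)
  el <- .edgeMatrix(g)
  writeLines(paste(el[, 1], el[, 2]), path)
  invisible(path)
}

#' Self-looped binary adjacency matrix
#'
#' Builds the n x n symmetric 0/1 adjacency matrix with a unit diagonal
#' (every node is considered connected to itself), the input to the symmetric
#' NMF in [factorizeAdjacency()]. Rows and columns are labelled with node
#' names in sorted order.
#'
#' @param g an igraph.
#' @return A base numeric matrix with dimnames.
#' @examples
#' buildAdjacency(fixtureFig2())[1:4, 1:4]
#' @export
buildAdjacency <- function(g) {
  g <- .canonGraph(g)
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  a <- as.matrix(igraph::as_adjacency_matrix(g, type = "both", sparse = TRUE))
  storage.mode(a) <- "double"
  diag(a) <- 1
  a
}

#' Structural statistics of a network
#'
#' Computes the standard descriptor tuple of an undirected, unweighted
#' network: node count N, edge count E, mean degree \eqn{\langle k\rangle =
#' 2E/N}, maximum degree, degree heterogeneity \eqn{H_k = \langle k^2\rangle
#' /\langle k\rangle^2} (1 for regular graphs, large for hub-dominated ones),
#' degree assortativity r (Pearson correlation of endpoint degrees over
#' edges; undefined for regular graphs, returned as `NaN` with a warning) and
#' the clustering coefficient C, taken as the mean of the local clustering
#' coefficients with nodes of degree < 2 contributing 0.
#'
#' @param g an igraph with at least 2 nodes and 1 edge.
#' @return A [NetworkStats-class]; coerce with `as.data.frame()` for a
#'   Table-style row.
#' @examples
#' networkStats(fixtureKarate())
#' @export
networkStats <- function(g) {
  g <- .canonGraph(g)
  if (igraph::vcount(g) < 2 || igraph::ecount(g) < 1)
    stop("need at least 2 nodes and 1 edge", call. = FALSE)
  k <- igraph::degree(g)
  if (stats::sd(k) == 0) {
    warning("all degrees equal: assortativity is undefined (NaN)")
    r <- NaN
  } else {
    r <- igraph::assortativity_degree(g, directed = FALSE)
  }
  localC <- igraph::transitivity(g, type = "local", isolates = "zero")
  localC[is.na(localC)] <- 0   # degree-1 nodes contribute 0
  new("NetworkStats",
      nNodes = as.integer(igraph::vcount(g)),
      nEdges = as.integer(igraph::ecount(g)),
      meanDegree = mean(k), maxDegree = as.integer(max(k)),
      heterogeneity = mean(k^2) / mean(k)^2,
      assortativity = r, clustering = mean(localC))
}
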