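## Brute-force oracles, deliberately independent of the package's (and
## igraph's) algorithms: plain R over edge lists and adjacency lists.

## Adjacency list (character labels) from an igraph.
oracleAdjList <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  labels <- igraph::V(g)$name
  adj <- stats::setNames(vector("list", length(labels)), labels)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1]]] <- c(adj[[el[i, 1]]], el[i, 2])
    adj[[el[i, 2]]] <- c(adj[[el[i, 2]]], el[i, 1])
  }
  adj
}

## All shortest s-t paths by exhaustive DFS over simple paths.
oracleAllShortestPaths <- function(adj, s, t) {
  best <- Inf
  found <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      len <- length(path) - 1
      if (len < best) {
        best <<- len
        found <<- list(path)
      } else if (len == best) {
        found[[length(found) + 1]] <<- path
      }
      return()
    }
    if (length(path) - 1 >= best) return()
    for (w in adj[[v]]) if (!w %in% path) recurse(c(path, w))
  }
  recurse(s)
  found
}

## Edge betweenness: sum over unordered pairs of the fraction of shortest
## paths through each edge.
oracleEdgeBetweenness <- function(g) {
  adj <- oracleAdjList(g)
  labels <- names(adj)
  el <- igraph::as_edgelist(g, names = TRUE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  score <- stats::setNames(numeric(nrow(el)), key(el[, 1], el[, 2]))
  for (i in seq_along(labels)) for (j in seq_along(labels)) {
    if (i >= j) next
    paths <- oracleAllShortestPaths(adj, labels[i], labels[j])
    if (!length(paths)) next
    for (p in paths) {
      if (length(p) < 2) next
      ks <- key(p[-length(p)], p[-1])
      score[ks] <- score[ks] + 1 / length(paths)
    }
  }
  score
}

## Maximum-clique sizes per node and per edge by exhaustive subset
## enumeration (graphs up to ~12 nodes).
oracleCliqueSizes <- function(g) {
  labels <- igraph::V(g)$name
  n <- length(labels)
  adj <- oracleAdjList(g)
  isClique <- function(members) {
    if (length(members) < 2) return(TRUE)
    prs <- utils::combn(members, 2)
    all(vapply(seq_len(ncol(prs)), function(i)
      prs[2, i] %in% adj[[prs[1, i]]], logical(1)))
  }
  sNode <- stats::setNames(rep(1, n), labels)
  el <- igraph::as_edgelist(g, names = TRUE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  sEdge <- stats::setNames(rep(2, nrow(el)), key(el[, 1], el[, 2]))
  for (mask in seq_len(2^n - 1)) {
    members <- labels[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (!isClique(members)) next
    sz <- length(members)
    sNode[members] <- pmax(sNode[members], sz)
    if (sz >= 2) {
      prs <- utils::combn(members, 2)
      ks <- key(prs[1, ], prs[2, ])
      ks <- ks[ks %in% names(sEdge)]
      if (length(ks)) sEdge[ks] <- pmax(sEdge[ks], sz)
    }
  }
  list(node = sNode, edge = sEdge)
}

## Component sizes by hand-rolled BFS over an edge data.frame.
oracleComponentSizes <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    adj[[edges[i, 1]]] <- c(adj[[edges[i, 1]]], edges[i, 2])
    adj[[edges[i, 2]]] <- c(adj[[edges[i, 2]]], edges[i, 1])
  }
  seen <- character(0)
  sizes <- integer(0)
  for (v in nodes) {
    if (v %in% seen) next
    queue <- v
    comp <- character(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    seen <- c(seen, comp)
    sizes <- c(sizes, length(comp))
  }
  sizes
}

## Susceptibility straight from the definition, computed independently.
oracleSusceptibility <- function(sizes, n) {
  sizes <- sort(sizes, decreasing = TRUE)
  sum(sizes[-1]^2) / n
}

## Seeded connected G(n, p) graph for sweeps.
randomConnectedGraph <- function(n, p, seed) {
  for (try in 0:100) {
    g <- withr::with_seed(seed + 1000 * try,
                          igraph::sample_gnp(n, p, directed = FALSE))
    igraph::V(g)$name <- as.character(seq_len(n))
    if (igraph::is_connected(g)) return(g)
  }
  stop("could not draw a connected graph")
}

edgeKey <- function(df) paste(pmin(df$from, df$to), pmax(df$from, df$to))
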