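## Targeted edge attack: descending-score removal, giant component and
## normalized susceptibility, threshold detection, replication studies.

#' Normalized susceptibility of a component-size census
#'
#' \eqn{\tilde S = \sum_s n_s s^2 / N} where n_s is the number of components
#' of size s and the sum runs over all components except one largest (with
#' co-largest ties, exactly one copy of the maximal size is excluded and the
#' rest are included). Zero while the graph is connected; peaks at the point
#' where the network disintegrates into large fragments.
#'
#' @param componentSizes integer vector of component sizes.
#' @param nTotal total number of nodes N; must equal `sum(componentSizes)`.
#' @return The susceptibility, a nonnegative scalar.
#' @examples
#' susceptibility(c(5, 3, 2), 10)   # (9 + 4) / 10 = 1.3
#' @export
susceptibility <- function(componentSizes, nTotal) {
  if (length(componentSizes) == 0)
    stop("empty component-size census", call. = FALSE)
  if (sum(componentSizes) != nTotal)
    stop("component sizes sum to ", sum(componentSizes), ", not nTotal = ",
         nTotal, call. = FALSE)
  drop1 <- componentSizes[-which.max(componentSizes)]
  sum(drop1^2) / nTotal
}

.censusStats <- function(sizes, nTotal) {
  c(rgc = max(sizes) / nTotal, sus = susceptibility(sizes, nTotal))
}

#' Percolate a graph by removing edges in descending score order
#'
#' Simulates a targeted edge attack: edges are sorted by their score in the
#' supplied table in descending order (equal scores shuffled with `tieSeed`,
#' since several indices assign large groups of identical values) and removed
#' one at a time. Scores are computed once on the intact graph and never
#' recomputed during removal — the static attack protocol. After each
#' removal the trace records the removed fraction f, the giant-component
#' fraction R_GC (denominator: the original node count, isolated nodes
#' included) and the normalized susceptibility.
#'
#' For graphs with more than 5000 edges the trace is thinned to a ~200-point
#' f grid; every removal is recorded otherwise.
#'
#' @param g an igraph.
#' @param scores an [EdgeScoreTable-class] covering every edge of `g`.
#' @param tieSeed integer seed for shuffling equal-score ties.
#' @return A [PercolationTrace-class]; its first row is the intact graph at
#'   f = 0.
#' @examples
#' g <- generateBarbell(3)
#' percolate(g, edgeBetweenness(g), tieSeed = 1)
#' @seealso [detectThreshold()], [compareMethods()]
#' @export
percolate <- function(g, scores, tieSeed = 1) {
  g <- .canonGraph(g)
  stopifnot(is(scores, "EdgeScoreTable"))
  el <- .edgeMatrix(g)
  m <- nrow(el)
  n <- igraph::vcount(g)
  keys <- .edgeKeys(el)
  sc <- scores@scores
  tabKeys <- .edgeKeys(cbind(sc$from, sc$to))
  pos <- match(keys, tabKeys)
  if (anyNA(pos))
    stop("score table is missing ", sum(is.na(pos)), " edge(s) of the graph",
         call. = FALSE)
  s <- sc$score[pos]
  perm <- withr::with_seed(tieSeed, sample.int(m))
  removalOrder <- perm[order(-s[perm])]   # descending, ties shuffled
  record <- if (m <= 5000) seq_len(m) else
    unique(round(seq(1, m, length.out = 200)))
  sizes <- igraph::components(g)$csize
  rows <- vector("list", length(record) + 1)
  rows[[1]] <- c(f = 0, .censusStats(sizes, n))
  work <- g
  ri <- 1L
  for (i in seq_len(m)) {
    eid <- igraph::get_edge_ids(work,
                                c(el[removalOrder[i], 1],
                                  el[removalOrder[i], 2]))
    work <- igraph::delete_edges(work, eid)
    if (i %in% record) {
      ri <- ri + 1L
      sizes <- igraph::components(work)$csize
      rows[[ri]] <- c(f = i / m, .censusStats(sizes, n))
    }
  }
  tr <- as.data.frame(do.call(rbind, rows[seq_len(ri)]))
  names(tr) <- c("f", "rgc", "susceptibility")
  peak <- max(tr$susceptibility)
  thr <- .thresholdFromTrace(tr, warn = FALSE)
  new("PercolationTrace", trace = tr, threshold = thr, peak = peak,
      tieSeed = as.integer(tieSeed), method = scores@method)
}

.thresholdFromTrace <- function(tr, warn = TRUE) {
  peak <- max(tr$susceptibility)
  if (peak <= 0) {
    if (warn) warning("susceptibility is identically zero: ",
                      "no disintegration observed; returning f = 1")
    return(1)
  }
  tr$f[which.max(tr$susceptibility)]
}

#' Percolation threshold of a trace
#'
#' The smallest removed fraction f at which the normalized susceptibility
#' attains its maximum — the point where the network disintegrates. If the
#' susceptibility never leaves zero, no disintegration was observed and 1 is
#' returned with a warning.
#'
#' @param trace a [PercolationTrace-class].
#' @return The threshold f* in [0, 1].
#' @export
detectThreshold <- function(trace) {
  stopifnot(is(trace, "PercolationTrace"))
  if (nrow(trace@trace) == 0) stop("empty trace", call. = FALSE)
  .thresholdFromTrace(trace@trace)
}

#' Distribution of LE percolation thresholds over random initializations
#'
#' The NMF in the LE pipeline finds a local optimum that depends on its
#' random initialization. This replicates the full single-initialization
#' pipeline (one NMF fit, no restarts; percolation; threshold) `nReplicates`
#' times with seeds `baseSeed .. baseSeed + nReplicates - 1` and returns all
#' thresholds, plus a histogram with bins of width 0.1 centered on
#' 0, 0.1, ..., 1 (the bar at 0.2 counts thresholds in [0.15, 0.25)).
#'
#' @param g an igraph.
#' @param k number of communities for the LE (default 2).
#' @param nReplicates number of single-initialization replicates.
#' @param baseSeed first seed; the i-th replicate uses both NMF seed and tie
#'   seed `baseSeed + i - 1`, so the whole study is reproducible from
#'   `baseSeed`.
#' @return A list with `thresholds` (numeric vector, length `nReplicates`)
#'   and `histogram` (data.frame with columns `center`, `count`,
#'   `fraction`).
#' @export
thresholdDistribution <- function(g, k = 2, nReplicates = 100, baseSeed = 1) {
  stopifnot(nReplicates >= 1)
  g <- .canonGraph(g)
  thresholds <- vapply(seq_len(nReplicates), function(i) {
    s <- baseSeed + i - 1
    tab <- scoreLE(g, k = k, nRestarts = 1, seed = s)
    percolate(g, tab, tieSeed = s)@threshold
  }, numeric(1))
  centers <- seq(0, 1, by = 0.1)
  bin <- pmin(pmax(round(thresholds / 0.1), 0), 10)
  counts <- tabulate(bin + 1L, nbins = 11L)
  list(thresholds = thresholds,
       histogram = data.frame(center = centers, count = counts,
                              fraction = counts / nReplicates))
}

#' Compare edge-significance methods by targeted attack
#'
#' Runs the static percolation protocol once per method on the same graph
#' and summarizes each run by its threshold and susceptibility peak: a
#' method is better at finding connectivity-critical edges when its peak
#' comes earlier (smaller threshold) and is higher.
#'
#' @param g an igraph.
#' @param methods character vector of method names (see [scoreMethod()]).
#' @param tieSeed tie-shuffle seed shared by all methods.
#' @param ... parameters forwarded to [scoreMethod()] (e.g. `seed`,
#'   `nRestarts` for `"le"`); method-irrelevant ones are ignored per method.
#' @return A list with `summary` (data.frame: method, threshold, peak) and
#'   `traces` (named list of [PercolationTrace-class] objects).
#' @examples
#' cmp <- compareMethods(generateBarbell(4),
#'                       c("betweenness", "degree_product"))
#' cmp$summary
#' @export
compareMethods <- function(g, methods, tieSeed = 1, ...) {
  stopifnot(length(methods) >= 1)
  g <- .canonGraph(g)
  dots <- list(...)
  traces <- lapply(methods, function(mth) {
    keep <- switch(mth,
      le = c("k", "nRestarts", "seed", "maxIter", "tol"),
      degree_product = "theta",
      bridgeness = "timeout",
      kpath = c("k", "rho", "seed"),
      character(0))
    tab <- do.call(scoreMethod, c(list(g, mth), dots[intersect(names(dots),
                                                               keep)]))
    percolate(g, tab, tieSeed = tieSeed)
  })
  names(traces) <- methods
  list(summary = data.frame(
         method = methods,
         threshold = vapply(traces, function(t) t@threshold, numeric(1)),
         peak = vapply(traces, function(t) t@peak, numeric(1))),
       traces = traces)
}
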