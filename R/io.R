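## Tabular export/import of score tables and percolation traces.

#' Write / read an edge score table
#'
#' Score tables are written as TSV with columns `node_u`, `node_v`, `score`,
#' `method`; the run parameters (K, seeds, NMF loss, ...) go to a JSON
#' sidecar at `<path>.json`. `readScoreTable()` restores the
#' [EdgeScoreTable-class] from the pair.
#'
#' @param x an [EdgeScoreTable-class].
#' @param path output TSV path.
#' @return `writeScoreTable()`: `path`, invisibly. `readScoreTable()`: an
#'   [EdgeScoreTable-class].
#' @export
writeScoreTable <- function(x, path) {
  stopifnot(is(x, "EdgeScoreTable"))
  out <- data.frame(node_u = x@scores$from, node_v = x@scores$to,
                    score = x@scores$score, method = x@method)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(x@params, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(node_u = "character",
                                                node_v = "character"))
  sidecar <- paste0(path, ".json")
  params <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  new("EdgeScoreTable", method = unique(tab$method),
      scores = data.frame(from = tab$node_u, to = tab$node_v,
                          score = tab$score),
      params = as.list(params))
}

#' Write a percolation trace as CSV
#'
#' One row per trace point with columns `f`, `R_GC`, `S_tilde` and a
#' `method` column.
#'
#' @param x a [PercolationTrace-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(x, path) {
  stopifnot(is(x, "PercolationTrace"))
  out <- data.frame(f = x@trace$f, R_GC = x@trace$rgc,
                    S_tilde = x@trace$susceptibility, method = x@method)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a percolation trace
#'
#' Two stacked panels in the conventional layout: the giant-component
#' fraction R_GC against the removed fraction f on top, the normalized
#' susceptibility with the detected threshold marked below.
#'
#' @param x a [PercolationTrace-class].
#' @param y ignored.
#' @param ... passed to the underlying line plots.
#' @return `x`, invisibly.
#' @importFrom graphics abline par plot
#' @export
plot.PercolationTrace <- function(x, y, ...) {
  tr <- x@trace
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(tr$f, tr$rgc, type = "l", xlab = "f (edges removed)",
       ylab = expression(R[GC]), ylim = c(0, 1), ...)
  plot(tr$f, tr$susceptibility, type = "l", xlab = "f (edges removed)",
       ylab = expression(tilde(S)), ...)
  abline(v = x@threshold, lty = 2)
  invisible(x)
}
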