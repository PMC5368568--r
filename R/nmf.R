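## Symmetric NMF of the self-looped adjacency matrix.
##
## Model: A ~ X X^T with X an n x K nonnegative matrix whose row i is node
## i's probability of belonging to each of K communities. The fit minimizes
## the squared loss ||A - X X^T||_F^2 by the canonical symmetric-NMF
## multiplicative update
##     x_ik <- x_ik * (A X)_ik / (X X^T X)_ik
## with each row renormalized to sum to one after every update, so X stays a
## stochastic matrix throughout. Row normalization is a projection, not a
## descent step, so the loss is only monitored (not guaranteed) to decrease;
## in practice it plateaus quickly on small graphs.

.rowNormalize <- function(x, eps = 1e-12) x / pmax(rowSums(x), eps)

.sqLoss <- function(a, x) sum((a - tcrossprod(x))^2)

.checkAdjacency <- function(a) {
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (max(abs(a - t(a))) > 1e-12)
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(a) != 1))
    stop("adjacency must have a unit diagonal (see buildAdjacency)",
         call. = FALSE)
  invisible(a)
}

#' Symmetric NMF with multiplicative updates
#'
#' Factorizes a self-looped adjacency matrix A (from [buildAdjacency()]) into
#' a row-stochastic membership matrix X minimizing \eqn{\|A - XX^T\|_F^2}.
#' X is initialized entrywise i.i.d. uniform on (0.01, 1) from `seed` and
#' row-normalized; each iteration applies the multiplicative update
#' \eqn{x_{ik} \gets x_{ik} (AX)_{ik} / (XX^TX)_{ik}} (denominator guarded by
#' a 1e-12 epsilon) followed by row normalization, and stops when the
#' relative loss change drops below `tol` or `maxIter` is reached. The global
#' RNG state is left untouched.
#'
#' With `k = 1` every row collapses to 1 by normalization; `k > n` is an
#' error. Identical arguments give bit-identical results.
#'
#' @param a numeric symmetric matrix with unit diagonal.
#' @param k number of communities K (>= 1; use 2 for edge scoring).
#' @param seed integer seed for the random initialization.
#' @param maxIter iteration cap (default 2000).
#' @param tol relative-loss-change convergence tolerance (default 1e-9).
#' @return A [FactorizationResult-class].
#' @examples
#' a <- buildAdjacency(fixtureFig2())
#' fit <- factorizeAdjacency(a, k = 2, seed = 1)
#' nmfLoss(fit)
#' @seealso [bestOfRestarts()], [clampZeros()], [scoreLE()]
#' @export
factorizeAdjacency <- function(a, k, seed, maxIter = 2000, tol = 1e-9) {
  .checkAdjacency(a)
  n <- nrow(a)
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k = ", k, " exceeds the number of nodes (", n, ")",
                  call. = FALSE)
  labels <- rownames(a)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  eps <- 1e-12
  x <- withr::with_seed(seed, matrix(stats::runif(n * k, 0.01, 1), n, k))
  x <- .rowNormalize(x, eps)
  loss <- .sqLoss(a, x)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    x <- x * (a %*% x) / (x %*% crossprod(x) + eps)
    x <- .rowNormalize(x, eps)
    newLoss <- .sqLoss(a, x)
    if (abs(loss - newLoss) / max(loss, eps) < tol) {
      loss <- newLoss
      converged <- TRUE
      break
    }
    loss <- newLoss
  }
  rownames(x) <- labels
  new("FactorizationResult",
      membership = new("MembershipMatrix", values = x, nCommunities = k),
      loss = loss, nIterations = iter, converged = converged,
      seed = as.integer(seed))
}

#' Clamp zero memberships away from zero
#'
#' Entropy and Jensen-Shannon divergence need strictly positive
#' probabilities. Every membership entry below 1e-7 is raised to 1e-7 and the
#' added mass is subtracted from the row's largest entry, so each row still
#' sums to exactly one.
#'
#' @param x a [MembershipMatrix-class] or a plain row-stochastic matrix.
#' @return An object of the same type with all entries >= 1e-7.
#' @examples
#' clampZeros(matrix(c(1, 0), 1, 2, dimnames = list("a", NULL)))
#' @export
clampZeros <- function(x) {
  isS4in <- is(x, "MembershipMatrix")
  v <- if (isS4in) x@values else x
  if (any(abs(rowSums(v) - 1) > 1e-8))
    stop("rows must sum to 1 before clamping", call. = FALSE)
  low <- v < .CLAMP
  if (any(rowSums(!low) == 0))
    stop("a row has every entry below the clamping threshold", call. = FALSE)
  if (any(low)) {
    deficit <- rowSums((.CLAMP - v) * low)
    v[low] <- .CLAMP
    top <- max.col(v, ties.method = "first")
    idx <- cbind(seq_len(nrow(v)), top)
    v[idx] <- v[idx] - deficit
  }
  if (isS4in) new("MembershipMatrix", values = v,
                  nCommunities = x@nCommunities) else v
}

#' Keep the best of several random NMF restarts
#'
#' The multiplicative update only finds a local optimum, and the optimum
#' reached depends on the random initialization. This runs
#' [factorizeAdjacency()] with seeds `baseSeed .. baseSeed + nRestarts - 1`
#' and returns the fit with the smallest loss (ties broken by the lowest
#' seed).
#'
#' @inheritParams factorizeAdjacency
#' @param nRestarts number of restarts (>= 1).
#' @param baseSeed first seed.
#' @return The best [FactorizationResult-class].
#' @export
bestOfRestarts <- function(a, k, nRestarts, baseSeed, maxIter = 2000,
                           tol = 1e-9) {
  stopifnot(nRestarts >= 1)
  best <- NULL
  for (s in seq.int(baseSeed, length.out = nRestarts)) {
    fit <- factorizeAdjacency(a, k, seed = s, maxIter = maxIter, tol = tol)
    if (is.null(best) || fit@loss < best@loss) best <- fit
  }
  best
}
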