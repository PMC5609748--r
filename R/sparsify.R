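# Sparsification of the MAP precision matrix: partial correlations,
# percentile hard-thresholding, EBIC model scoring and threshold search.

#' Partial correlations from a precision matrix
#'
#' rho_ij = -theta_ij / sqrt(theta_ii theta_jj) off-diagonal, 1 on the
#' diagonal. A zero partial correlation means the two genes are
#' conditionally independent given all others.
#'
#' @param theta symmetric matrix with strictly positive diagonal.
#' @return symmetric p x p matrix with unit diagonal.
#' @examples
#' partialCorrelations(matrix(c(2, -1, -1, 2), 2))  # rho12 = 0.5
#' @export
partialCorrelations <- function(theta) {
  theta <- as.matrix(theta)
  d <- diag(theta)
  if (any(d <= 0)) stop("precision matrix diagonal must be strictly positive")
  r <- -theta / sqrt(outer(d, d))
  diag(r) <- 1
  (r + t(r)) / 2
}

.upperVals <- function(m) m[upper.tri(m)]

#' Hard-threshold a precision matrix at a partial-correlation percentile
#'
#' The threshold t is the given percentile (linear interpolation on the
#' sorted values) of the absolute off-diagonal partial correlations;
#' off-diagonal entries with |rho| < t are set exactly to zero and
#' entries with |rho| >= t are kept. The diagonal is never thresholded.
#'
#' @param thetaMap p x p MAP precision matrix.
#' @param pcor its partial-correlation matrix
#'   (see [partialCorrelations()]); computed when NULL.
#' @param percentile value in (0, 100).
#' @param geneIds identifiers; default from dimnames.
#' @return a [SparseNetwork-class] with `ebicValue` unset (NA).
#' @export
hardThreshold <- function(thetaMap, pcor = NULL, percentile,
                          geneIds = rownames(thetaMap)) {
  thetaMap <- as.matrix(thetaMap)
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  if (is.null(pcor)) pcor <- partialCorrelations(thetaMap)
  p <- nrow(thetaMap)
  t0 <- stats::quantile(abs(.upperVals(pcor)), percentile / 100,
                        names = FALSE, type = 7)
  drop <- abs(pcor) < t0
  diag(drop) <- FALSE
  thetaSparse <- thetaMap
  thetaSparse[drop] <- 0
  adj <- (thetaSparse != 0) * 1
  diag(adj) <- 0
  if (is.null(geneIds)) geneIds <- paste0("g", seq_len(p))
  new("SparseNetwork", thetaSparse = thetaSparse, pcor = pcor,
      percentileUsed = as.numeric(percentile), ebicValue = NA_real_,
      adjacency = adj, geneIds = as.character(geneIds))
}

#' Extended Bayesian information criterion of a sparsified precision matrix
#'
#' EBIC = -n (log|Theta| - tr(Theta S)) + df log(n) + 4 df gamma log(p),
#' where df is the number of nonzero off-diagonal entries in the upper
#' triangle (the edge count). A candidate that is not positive definite
#' has an undefined log-determinant and scores +Inf.
#'
#' @param thetaSparse symmetric (possibly thresholded) precision matrix,
#'   or a [SparseNetwork-class].
#' @param S sample covariance (divisor n, same as the likelihood).
#' @param n number of samples.
#' @param gamma non-negative penalty weight; default 0.5.
#' @return numeric EBIC value (+Inf for invalid candidates).
#' @export
ebicScore <- function(thetaSparse, S, n, gamma = 0.5) {
  if (is(thetaSparse, "SparseNetwork")) thetaSparse <- thetaSparse@thetaSparse
  stopifnot(gamma >= 0, n >= 1)
  thetaSparse <- as.matrix(thetaSparse)
  S <- as.matrix(S)
  p <- nrow(thetaSparse)
  if (any(!is.finite(thetaSparse))) return(Inf)
  ch <- tryCatch(chol(thetaSparse), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet <- 2 * sum(log(diag(ch)))
  df <- sum(thetaSparse[upper.tri(thetaSparse)] != 0)
  -n * (logdet - sum(thetaSparse * S)) + df * log(n) +
    4 * df * gamma * log(p)
}

#' Select the hard threshold by EBIC over a percentile grid
#'
#' Thresholds the MAP estimate at every percentile in the grid, scores
#' each candidate with [ebicScore()] and returns the network with the
#' smallest EBIC; ties break toward the larger percentile (the sparser
#' network).
#'
#' @param thetaMap MAP precision matrix.
#' @param S sample covariance (divisor n).
#' @param n number of samples.
#' @param percentileGrid candidate percentiles; the default spans the
#'   sparse regime around the commonly used 95th percentile.
#' @param gamma EBIC penalty weight.
#' @param geneIds identifiers.
#' @return a [SparseNetwork-class] with `percentileUsed` and `ebicValue`
#'   recorded.
#' @export
selectThreshold <- function(thetaMap, S, n,
                            percentileGrid = c(80, 85, 90, 92.5, 95, 97.5, 99),
                            gamma = 0.5, geneIds = rownames(thetaMap)) {
  if (!length(percentileGrid)) stop("percentile grid must be non-empty")
  grid <- sort(unique(percentileGrid))
  pcor <- partialCorrelations(thetaMap)
  best <- NULL
  bestEbic <- Inf
  for (pct in grid) {
    cand <- hardThreshold(thetaMap, pcor, pct, geneIds = geneIds)
    e <- ebicScore(cand, S, n, gamma)
    # grid is ascending, so <= sends ties to the larger percentile
    if (is.finite(e) && e <= bestEbic) {
      cand@ebicValue <- e
      best <- cand
      bestEbic <- e
    }
  }
  if (is.null(best))
    stop("no positive-definite candidate at any percentile in the grid")
  best
}

#' @describeIn asEdgeList edges of a sparse network, weighted by the
#'   absolute partial correlation.
#' @export
setMethod("asEdgeList", "SparseNetwork", function(object, ...) {
  adj <- object@adjacency
  idx <- which(adj != 0 & upper.tri(adj), arr.ind = TRUE)
  EdgeList(from = object@geneIds[idx[, 1L]],
           to = object@geneIds[idx[, 2L]],
           weight = abs(object@pcor[idx]),
           nodeIds = object@geneIds)
})
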