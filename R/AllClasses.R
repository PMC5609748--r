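#' @import methods
NULL

#' ExpressionMatrix: a genes-by-samples expression matrix
#'
#' Container for a numeric expression matrix (typically log2 intensities)
#' with unique gene identifiers as row names and sample identifiers as
#' column names. Internally all model fitting treats columns as i.i.d.
#' multivariate-normal samples of the p genes.
#'
#' @slot values numeric p x n matrix; rownames are gene ids, colnames
#'   sample ids.
#'
#' @seealso [readExpression()], [preprocessExpression()],
#'   [sampleCovariance()]
#' @export
setClass("ExpressionMatrix", representation(values = "matrix"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry gene ids (rownames) and sample ids (colnames)")
  if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate gene ids are not allowed")
  if (anyNA(v)) msg <- c(msg, "missing values are not allowed")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 genes")
  if (ncol(v) < 2L) msg <- c(msg, "need at least 2 samples")
  if (length(msg)) msg else TRUE
})

#' EdgeList: an undirected network as a set of gene pairs
#'
#' Edges are stored canonically with `from < to` (lexicographic), so the
#' pair (a, b) equals (b, a) and self-loops are excluded. The optional
#' `tfIds` slot records which node ids appeared in the first (regulator)
#' column of the source file; it defines the TF-target pair universe used
#' by [confusionMetrics()].
#'
#' @slot edges data.frame with character columns `from`, `to` and numeric
#'   column `weight` (NA when unweighted).
#' @slot nodeIds character vector of node identifiers.
#' @slot tfIds character vector, possibly empty; regulator ids.
#'
#' @seealso [readEdgeList()], [writeEdgeList()], [asEdgeList()]
#' @export
setClass("EdgeList",
  representation(edges = "data.frame", nodeIds = "character",
                 tfIds = "character"))

setValidity("EdgeList", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "weight") %in% names(e)))
    msg <- c(msg, "edges must have columns from, to, weight")
  else {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be canonical (from < to)")
    key <- paste(e$from, e$to, sep = "\r")
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
    if (!all(c(e$from, e$to) %in% object@nodeIds))
      msg <- c(msg, "every edge endpoint must be a known node id")
  }
  if (length(msg)) msg else TRUE
})

#' FactorModelFit: maximum-likelihood Gaussian factor analysis fit
#'
#' Result of fitting y = Lambda f + eps with f ~ N(0, I_k) and
#' eps ~ N(0, Psi), Psi diagonal, by EM. After the identification
#' rotation, t(Lambda) Psi^{-1} Lambda is diagonal with decreasing
#' entries and each column's largest-magnitude loading is positive.
#'
#' @slot loadings p x k loading matrix Lambda.
#' @slot noiseVariances length-p positive vector, the diagonal of Psi.
#' @slot k number of factors.
#' @slot loglikTrace per-iteration quasi-log-likelihood
#'   -(1/2p) log|Sigma| - (1/2p) tr(S Sigma^{-1}).
#' @slot converged logical; TRUE when the trace improvement fell below
#'   the tolerance before the iteration cap.
#' @slot nIter iterations performed.
#' @slot psiBounds the clipping interval applied to the noise variances.
#'
#' @seealso [fitFactorModel()], [buildPriorScale()]
#' @export
setClass("FactorModelFit",
  representation(loadings = "matrix", noiseVariances = "numeric",
                 k = "integer", loglikTrace = "numeric",
                 converged = "logical", nIter = "integer",
                 psiBounds = "numeric"))

setValidity("FactorModelFit", function(object) {
  msg <- character()
  if (any(object@noiseVariances <= 0))
    msg <- c(msg, "noise variances must be strictly positive")
  if (ncol(object@loadings) != object@k)
    msg <- c(msg, "loadings must have k columns")
  if (nrow(object@loadings) != length(object@noiseVariances))
    msg <- c(msg, "loadings rows must match length of noiseVariances")
  if (length(msg)) msg else TRUE
})

#' PriorScale: positive-definite Wishart prior scale structure
#'
#' The factor-analytic prior scale Omega = Lambda Lambda' is rank
#' deficient (k < p), so a positive jitter is added to the diagonal to
#' make it positive definite before it enters the Wishart prior.
#'
#' @slot omega p x p symmetric positive-definite matrix.
#' @slot jitter the value added to the diagonal.
#' @slot sourceK number of factors behind the scale (0 for an identity
#'   scale).
#'
#' @seealso [buildPriorScale()], [wishartPrior()]
#' @export
setClass("PriorScale",
  representation(omega = "matrix", jitter = "numeric", sourceK = "integer"))

setValidity("PriorScale", function(object) {
  msg <- character()
  if (object@jitter < 0) msg <- c(msg, "jitter must be non-negative")
  om <- object@omega
  if (nrow(om) != ncol(om)) msg <- c(msg, "omega must be square")
  else {
    if (max(abs(om - t(om))) > 1e-8 * max(1, max(abs(om))))
      msg <- c(msg, "omega must be symmetric")
    ch <- tryCatch(chol(om), error = function(e) NULL)
    if (is.null(ch)) msg <- c(msg, "omega must be positive definite")
  }
  if (length(msg)) msg else TRUE
})

#' WishartPrior: conjugate prior for a Gaussian precision matrix
#'
#' Parameterized as W(dof, (dof * Omega)^{-1}), so that the prior mean of
#' the precision matrix is Omega^{-1} and Omega carries the structural
#' belief about the covariance. The degrees of freedom must exceed p - 1.
#'
#' @slot dof real degrees of freedom, > p - 1.
#' @slot omega p x p symmetric positive-definite scale-structure matrix.
#'
#' @seealso [wishartPrior()], [posteriorUpdate()], [wishartLogDensity()]
#' @export
setClass("WishartPrior", representation(dof = "numeric", omega = "matrix"))

setValidity("WishartPrior", function(object) {
  p <- nrow(object@omega)
  msg <- character()
  if (ncol(object@omega) != p) msg <- c(msg, "omega must be square")
  if (length(object@dof) != 1L || !is.finite(object@dof))
    msg <- c(msg, "dof must be a single finite number")
  else if (object@dof <= p - 1)
    msg <- c(msg, sprintf(
      "dof must exceed p - 1 = %d for the Wishart prior to be proper", p - 1L))
  ch <- tryCatch(chol(object@omega), error = function(e) NULL)
  if (is.null(ch)) msg <- c(msg, "omega must be positive definite")
  if (length(msg)) msg else TRUE
})

#' WishartPosterior: conjugate posterior for the precision matrix
#'
#' Closed-form update of [WishartPrior-class] by n centered samples with
#' sample covariance S: dof* = dof + n and Omega* is the weighted average
#' (n S + dof Omega) / (n + dof).
#'
#' @slot dof posterior degrees of freedom.
#' @slot omega posterior scale-structure matrix Omega*.
#'
#' @seealso [posteriorUpdate()], [mapPrecision()]
#' @export
setClass("WishartPosterior", representation(dof = "numeric", omega = "matrix"))

#' SparseNetwork: hard-thresholded precision matrix and its network
#'
#' @slot thetaSparse p x p symmetric matrix; off-diagonal entries whose
#'   absolute partial correlation fell below the threshold are exactly 0;
#'   the diagonal is never thresholded.
#' @slot pcor p x p partial-correlation matrix with unit diagonal.
#' @slot percentileUsed the percentile (of the absolute off-diagonal
#'   partial correlations) that defined the threshold.
#' @slot ebicValue extended BIC of the thresholded model (NA until scored).
#' @slot adjacency binary symmetric matrix, zero diagonal; 1 exactly where
#'   thetaSparse is nonzero off-diagonal.
#' @slot geneIds gene identifiers in matrix order.
#'
#' @seealso [hardThreshold()], [selectThreshold()], [asEdgeList()]
#' @export
setClass("SparseNetwork",
  representation(thetaSparse = "matrix", pcor = "matrix",
                 percentileUsed = "numeric", ebicValue = "numeric",
                 adjacency = "matrix", geneIds = "character"))

setValidity("SparseNetwork", function(object) {
  msg <- character()
  th <- object@thetaSparse
  ad <- object@adjacency
  off <- row(th) != col(th)
  if (!identical(dim(th), dim(ad)))
    msg <- c(msg, "thetaSparse and adjacency must have identical dimensions")
  else {
    if (any(diag(ad) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (any((ad[off] != 0) != (th[off] != 0)))
      msg <- c(msg, "adjacency must be 1 exactly where thetaSparse is nonzero off-diagonal")
  }
  pc <- object@pcor[row(object@pcor) != col(object@pcor)]
  if (length(pc) && (min(pc) < -1 - 1e-8 || max(pc) > 1 + 1e-8))
    msg <- c(msg, "partial correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' ConfusionMetrics: network-vs-gold-standard confusion counts and rates
#'
#' @slot tp,fp,tn,fn non-negative integer counts over the evaluation
#'   pair universe.
#' @slot precision,recall,accuracy,specificity the derived rates;
#'   NA when the defining denominator is zero (undefined, not 0).
#' @slot universeSize number of unordered pairs evaluated.
#'
#' @seealso [confusionMetrics()]
#' @export
setClass("ConfusionMetrics",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", precision = "numeric", recall = "numeric",
                 accuracy = "numeric", specificity = "numeric",
                 universeSize = "integer"))

setValidity("ConfusionMetrics", function(object) {
  counts <- c(object@tp, object@fp, object@tn, object@fn)
  msg <- character()
  if (any(counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (sum(counts) != object@universeSize)
    msg <- c(msg, "tp + fp + tn + fn must equal the universe size")
  if (length(msg)) msg else TRUE
})

#' SimulationScenario: parameters of the two-species simulator
#'
#' Describes a pair of related species whose expression data share a
#' latent-factor covariance structure Sigma = Lambda Lambda' + Psi. The
#' relatedness parameter is the element-wise correlation between the two
#' species' loading matrices (1 = identical regulatory programs,
#' 0 = unrelated).
#'
#' @slot p number of genes.
#' @slot nTarget,nRelated samples per species.
#' @slot k number of latent factors.
#' @slot rhoLambda relatedness in [0, 1].
#' @slot noiseRange length-2 positive vector; per-gene noise variances are
#'   drawn log-uniformly from this interval.
#' @slot edgeDensity fraction of gene pairs declared true edges.
#' @slot seed RNG seed making the draw reproducible.
#'
#' @seealso [simulationScenario()], [simulatePair()]
#' @export
setClass("SimulationScenario",
  representation(p = "integer", nTarget = "integer", nRelated = "integer",
                 k = "integer", rhoLambda = "numeric", noiseRange = "numeric",
                 edgeDensity = "numeric", seed = "integer"))

setValidity("SimulationScenario", function(object) {
  msg <- character()
  if (object@k < 1L || object@k >= min(object@nTarget, object@p))
    msg <- c(msg, "k must satisfy 1 <= k < min(nTarget, p)")
  if (object@rhoLambda < 0 || object@rhoLambda > 1)
    msg <- c(msg, "rhoLambda must lie in [0, 1]")
  if (object@edgeDensity <= 0 || object@edgeDensity >= 1)
    msg <- c(msg, "edgeDensity must lie in (0, 1)")
  if (length(object@noiseRange) != 2L || any(object@noiseRange <= 0) ||
      object@noiseRange[1] > object@noiseRange[2])
    msg <- c(msg, "noiseRange must be an increasing pair of positive values")
  if (length(msg)) msg else TRUE
})
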