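#' @describeIn ExpressionMatrix-class gene identifiers (row order).
#' @export
setMethod("geneIds", "ExpressionMatrix", function(object) rownames(object@values))

#' @describeIn ExpressionMatrix-class sample identifiers (column order).
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(object) colnames(object@values))

#' @describeIn ExpressionMatrix-class the underlying p x n numeric matrix.
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object) object@values)

#' @describeIn ExpressionMatrix-class number of genes.
#' @param x an ExpressionMatrix.
#' @export
setMethod("nrow", "ExpressionMatrix", function(x) nrow(x@values))

#' @describeIn ExpressionMatrix-class number of samples.
#' @export
setMethod("ncol", "ExpressionMatrix", function(x) ncol(x@values))

setMethod("show", "ExpressionMatrix", function(object) {
  v <- object@values
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(v), ncol(v)))
  cat("  genes:  ", paste(utils::head(rownames(v), 4), collapse = ", "),
      if (nrow(v) > 4) ", ..." else "", "\n", sep = "")
  cat("  samples:", paste(utils::head(colnames(v), 4), collapse = ", "),
      if (ncol(v) > 4) ", ..." else "", "\n", sep = "")
})

#' @describeIn EdgeList-class the edge table (from, to, weight).
#' @export
setMethod("edges", "EdgeList", function(object) object@edges)

#' @describeIn EdgeList-class node identifiers.
#' @export
setMethod("nodeIds", "EdgeList", function(object) object@nodeIds)

#' @describeIn EdgeList-class regulator (first-column) identifiers.
#' @export
setMethod("tfIds", "EdgeList", function(object) object@tfIds)

#' @describeIn EdgeList-class number of edges.
#' @export
setMethod("edgeCount", "EdgeList", function(object) nrow(object@edges))

setMethod("show", "EdgeList", function(object) {
  cat(sprintf("EdgeList: %d edges over %d nodes", nrow(object@edges),
              length(object@nodeIds)))
  if (length(object@tfIds))
    cat(sprintf(" (%d regulator ids)", length(object@tfIds)))
  cat("\n")
})

#' @describeIn FactorModelFit-class the p x k loading matrix.
#' @export
setMethod("factorLoadings", "FactorModelFit", function(object) object@loadings)

#' @describeIn FactorModelFit-class diagonal of the noise covariance Psi.
#' @export
setMethod("noiseVariances", "FactorModelFit",
          function(object) object@noiseVariances)

#' @describeIn FactorModelFit-class number of factors.
#' @export
setMethod("numFactors", "FactorModelFit", function(object) object@k)

#' @describeIn FactorModelFit-class quasi-log-likelihood per EM iteration.
#' @export
setMethod("loglikTrace", "FactorModelFit", function(object) object@loglikTrace)

setMethod("show", "FactorModelFit", function(object) {
  cat(sprintf(
    "FactorModelFit: p = %d genes, k = %d factors, %d EM iterations (%s)\n",
    nrow(object@loadings), object@k, object@nIter,
    if (object@converged) "converged" else "iteration cap reached"))
  cat(sprintf("  final quasi-log-likelihood: %.6f\n",
              utils::tail(object@loglikTrace, 1)))
})

#' @describeIn PriorScale-class the positive-definite scale matrix Omega.
#' @export
setMethod("scaleMatrix", "PriorScale", function(object) object@omega)

#' @describeIn PriorScale-class the diagonal jitter applied.
#' @export
setMethod("jitterValue", "PriorScale", function(object) object@jitter)

setMethod("show", "PriorScale", function(object) {
  cat(sprintf("PriorScale: %d x %d, jitter %.4g, built from k = %d factors\n",
              nrow(object@omega), ncol(object@omega), object@jitter,
              object@sourceK))
})

#' @describeIn dof prior degrees of freedom.
#' @export
setMethod("dof", "WishartPrior", function(object) object@dof)

#' @describeIn dof posterior degrees of freedom.
#' @export
setMethod("dof", "WishartPosterior", function(object) object@dof)

#' @describeIn PriorScale-class prior scale structure.
#' @export
setMethod("scaleMatrix", "WishartPrior", function(object) object@omega)

#' @describeIn PriorScale-class posterior scale structure.
#' @export
setMethod("scaleMatrix", "WishartPosterior", function(object) object@omega)

setMethod("show", "WishartPrior", function(object) {
  cat(sprintf("WishartPrior: p = %d, dof = %g\n", nrow(object@omega),
              object@dof))
})

setMethod("show", "WishartPosterior", function(object) {
  cat(sprintf("WishartPosterior: p = %d, dof = %g\n", nrow(object@omega),
              object@dof))
})

#' @describeIn SparseNetwork-class binary adjacency matrix.
#' @export
setMethod("adjacencyMatrix", "SparseNetwork", function(object) object@adjacency)

setMethod("show", "SparseNetwork", function(object) {
  p <- nrow(object@thetaSparse)
  ne <- sum(object@adjacency[upper.tri(object@adjacency)])
  cat(sprintf("SparseNetwork: %d genes, %d edges", p, ne))
  if (is.finite(object@percentileUsed))
    cat(sprintf(", threshold percentile %.1f", object@percentileUsed))
  if (is.finite(object@ebicValue))
    cat(sprintf(", EBIC %.3f", object@ebicValue))
  cat("\n")
})

setMethod("show", "ConfusionMetrics", function(object) {
  cat(sprintf("ConfusionMetrics over %d pairs\n", object@universeSize))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", object@tp, object@fp,
              object@tn, object@fn))
  fmt <- function(x) if (is.na(x)) "undefined" else sprintf("%.4f", x)
  cat(sprintf("  precision %s  recall %s  accuracy %s  specificity %s\n",
              fmt(object@precision), fmt(object@recall), fmt(object@accuracy),
              fmt(object@specificity)))
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf(
    "SimulationScenario: p = %d, n = %d/%d (target/related), k = %d, rho = %.2f, edge density %.3f, seed %d\n",
    object@p, object@nTarget, object@nRelated, object@k, object@rhoLambda,
    object@edgeDensity, object@seed))
})

#' Rates of a ConfusionMetrics object as a one-row data frame
#'
#' @param object a [ConfusionMetrics-class].
#' @return data.frame with counts and the four rates.
#' @export
metricsTable <- function(object) {
  stopifnot(is(object, "ConfusionMetrics"))
  data.frame(edges = object@tp + object@fp, tp = object@tp, fp = object@fp,
             tn = object@tn, fn = object@fn, precision = object@precision,
             recall = object@recall, accuracy = object@accuracy,
             specificity = object@specificity)
}
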