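# End-to-end network reconstruction: preprocessing, factor-analytic
# prior from the related species, conjugate posterior, MAP estimate,
# EBIC-thresholded sparsification and optional gold-standard scoring.

.loadExpr <- function(x, what) {
  if (is(x, "ExpressionMatrix")) return(x)
  if (is.character(x) && length(x) == 1L) {
    delim <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    return(readExpression(x, delimiter = delim))
  }
  if (is.matrix(x)) return(ExpressionMatrix(x))
  stop(what, " must be an ExpressionMatrix, a matrix or a file path")
}

.loadEdges <- function(x) {
  if (is.null(x) || is(x, "EdgeList")) return(x)
  if (is.character(x) && length(x) == 1L) return(readEdgeList(x))
  stop("gold standard must be an EdgeList or a file path")
}

#' Reconstruct a gene regulatory network with a related-species prior
#'
#' Runs the full pipeline: center both matrices (averaging replicates /
#' log2 first if requested via [preprocessExpression()] beforehand),
#' intersect gene sets, fit the factor model to the related species
#' (choosing the number of factors by bi-cross-validation when `k` is
#' NULL), build the Wishart prior scale Lambda Lambda' + jitter, update
#' to the conjugate posterior, take the MAP precision estimate, compute
#' partial correlations, sparsify by percentile hard-thresholding
#' (EBIC-selected over `percentileGrid` unless a fixed `percentile` is
#' given) and extract the network. When a gold standard is supplied the
#' confusion metrics are computed as well.
#'
#' @param target,related expression inputs: [ExpressionMatrix-class],
#'   plain genes x samples matrix, or TSV/CSV file path.
#' @param gold optional gold-standard network ([EdgeList-class] or file
#'   path).
#' @param dofPrior prior degrees of freedom; default p + 1.
#' @param k number of factors; NULL (default) selects it by
#'   bi-cross-validation on the related species.
#' @param percentile fixed threshold percentile; when NULL the
#'   threshold is chosen by EBIC over `percentileGrid`.
#' @param percentileGrid candidate percentiles for EBIC selection.
#' @param gamma EBIC penalty weight.
#' @param epsPD positive-definiteness floor for the prior scale; NULL
#'   (default) uses the mean fitted noise variance (see
#'   [buildPriorScale()]).
#' @param priorType `"factor"` (default) or `"identity"` for the
#'   structureless diagonal-prior baseline.
#' @param universe pair universe for the evaluation (see
#'   [confusionMetrics()]).
#' @param seed RNG seed (used by the bi-cross-validation folds).
#' @param outputDir optional directory; when given, the edge list,
#'   adjacency matrix, metrics and a key-value run report are written
#'   there.
#' @return a list of class `"fmapRun"` with elements `network`
#'   ([SparseNetwork-class]), `edges` ([EdgeList-class]), `prior`,
#'   `posterior`, `factorFit` (NULL for the identity prior), `thetaMap`,
#'   `metrics` (NULL without a gold standard) and `report` (named list
#'   of every parameter and selected value).
#' @examples
#' sim <- simulatePair(simulationScenario(p = 25, seed = 3))
#' res <- runFMAP(sim$target, sim$related, gold = sim$truth, k = 3,
#'                percentile = 95, universe = "all-pairs")
#' res$report$edgeCount
#' @export
runFMAP <- function(target, related, gold = NULL, dofPrior = NULL, k = NULL,
                    percentile = NULL,
                    percentileGrid = c(80, 85, 90, 92.5, 95, 97.5, 99),
                    gamma = 0.5, epsPD = NULL,
                    priorType = c("factor", "identity"),
                    universe = c("tf-target", "all-pairs"),
                    seed = 1L, outputDir = NULL) {
  priorType <- match.arg(priorType)
  universe <- match.arg(universe)
  if (!is.null(percentile) && !missing(percentileGrid) &&
      !is.null(percentileGrid))
    stop("give either a fixed percentile or a percentile grid, not both")
  t0 <- proc.time()[["elapsed"]]
  stage <- function(msg, ...) message(sprintf(msg, ...))

  target <- .loadExpr(target, "target")
  related <- .loadExpr(related, "related")
  gold <- .loadEdges(gold)

  both <- intersectGenes(preprocessExpression(target),
                         preprocessExpression(related))
  p <- nrow(both$target)
  n <- ncol(both$target)
  stage("stage 1 (preprocess): %d shared genes, %d target samples", p, n)

  S <- sampleCovariance(both$target)

  factorFit <- NULL
  kUsed <- NA_integer_
  jitter <- NA_real_
  if (priorType == "factor") {
    if (is.null(k)) {
      k <- selectNumFactors(both$related, seed = seed)
      stage("stage 2 (factor prior): bi-cross-validation selected k = %d", k)
    }
    if (k >= 1L) {
      factorFit <- fitFactorModel(both$related, k = k)
      scale <- buildPriorScale(factorFit, epsPD = epsPD)
    } else {
      scale <- identityPriorScale(p, geneIds(both$target))
    }
    kUsed <- as.integer(k)
    jitter <- jitterValue(scale)
  } else {
    scale <- identityPriorScale(p, geneIds(both$target))
  }
  prior <- wishartPrior(scale, dof = dofPrior)
  stage("stage 2 (prior): type %s, dof = %g, jitter = %g", priorType,
        dof(prior), jitterValue(scale))

  posterior <- posteriorUpdate(prior, S, n)
  thetaMap <- mapPrecision(posterior)
  stage("stage 3 (posterior/MAP): posterior dof = %g", dof(posterior))

  if (!is.null(percentile)) {
    network <- hardThreshold(thetaMap, percentile = percentile,
                             geneIds = geneIds(both$target))
    network@ebicValue <- ebicScore(network, S, n, gamma)
  } else {
    network <- selectThreshold(thetaMap, S, n,
                               percentileGrid = percentileGrid,
                               gamma = gamma, geneIds = geneIds(both$target))
  }
  edgeList <- asEdgeList(network)
  stage("stage 4 (sparsify): percentile %.1f, %d edges, EBIC %.3f",
        network@percentileUsed, edgeCount(edgeList), network@ebicValue)

  metrics <- NULL
  if (!is.null(gold)) {
    metrics <- confusionMetrics(edgeList, gold, universe = universe)
    stage("stage 5 (evaluate): TP %d / %d predicted edges", metrics@tp,
          metrics@tp + metrics@fp)
  }

  report <- list(
    nGenes = p, nTargetSamples = n, nRelatedSamples = ncol(both$related),
    priorType = priorType, dofPrior = dof(prior),
    dofPosterior = dof(posterior), k = kUsed, jitter = jitter,
    epsPD = if (is.null(epsPD)) NA_real_ else epsPD, gamma = gamma,
    fixedPercentile = if (is.null(percentile)) NA_real_ else percentile,
    percentileGrid = if (is.null(percentile)) percentileGrid else NA_real_,
    percentileUsed = network@percentileUsed, ebic = network@ebicValue,
    edgeCount = edgeCount(edgeList), seed = seed, universe = universe,
    elapsedSeconds = round(proc.time()[["elapsed"]] - t0, 3))
  if (!is.null(metrics)) {
    report$tp <- metrics@tp; report$fp <- metrics@fp
    report$tn <- metrics@tn; report$fn <- metrics@fn
    report$precision <- metrics@precision
    report$recall <- metrics@recall
    report$accuracy <- metrics@accuracy
    report$specificity <- metrics@specificity
  }

  result <- structure(
    list(network = network, edges = edgeList, prior = prior,
         posterior = posterior, factorFit = factorFit, thetaMap = thetaMap,
         metrics = metrics, report = report),
    class = "fmapRun")
  if (!is.null(outputDir)) .writeRunOutputs(result, outputDir)
  result
}

.writeRunOutputs <- function(result, outputDir) {
  ok <- FALSE
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(outputDir,
                     c("edges.tsv", "adjacency.tsv", "report.txt",
                       "metrics.tsv"))
  on.exit(if (!ok) unlink(files))
  writeEdgeList(result$edges, files[1L])
  adj <- adjacencyMatrix(result$network)
  utils::write.table(
    data.frame(gene = result$network@geneIds, adj, check.names = FALSE),
    files[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- result$report
  fmt <- vapply(rep, function(v)
    paste(format(v, digits = 12, scientific = FALSE, trim = TRUE),
          collapse = ","), character(1))
  writeLines(paste(names(rep), fmt, sep = "\t"), files[3L])
  if (!is.null(result$metrics))
    utils::write.table(metricsTable(result$metrics), files[4L], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  ok <- TRUE
  invisible(files)
}

#' @export
print.fmapRun <- function(x, ...) {
  r <- x$report
  cat("Network reconstruction run\n")
  cat(sprintf("  genes: %d, target samples: %d, prior: %s (dof %g)\n",
              r$nGenes, r$nTargetSamples, r$priorType, r$dofPrior))
  if (!is.na(r$k)) cat(sprintf("  factors: %d (jitter %.4g)\n", r$k, r$jitter))
  cat(sprintf("  threshold percentile: %.1f, edges: %d, EBIC: %.3f\n",
              r$percentileUsed, r$edgeCount, r$ebic))
  if (!is.null(r$precision))
    cat(sprintf(
      "  precision %.3f, recall %.3f, accuracy %.3f, specificity %.3f\n",
      r$precision, r$recall, r$accuracy, r$specificity))
  invisible(x)
}
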