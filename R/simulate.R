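# Two-species latent-factor expression simulator.
#
# Both species draw their samples from y = Lambda f + eps with shared
# factor structure: the related species' loading matrix is correlated
# element-wise with the target's at a configurable relatedness rho, so
# rho = 1 emulates a closely related species whose co-expression program
# is conserved and rho = 0 an uninformative outlier lineage. Defaults
# imitate the small time-course regime of multi-species embryonic
# development microarrays: around ten samples against tens of genes, so
# the sample covariance is singular and the prior matters.

#' Define a two-species simulation scenario
#'
#' @param p number of genes.
#' @param nTarget,nRelated samples per species (default 10 each, the
#'   developmental time-course scale where n << p).
#' @param k number of shared latent factors.
#' @param rhoLambda element-wise correlation between the species'
#'   loading matrices, in [0, 1].
#' @param noiseRange interval for the log-uniform per-gene noise
#'   variances (heteroscedastic, default [0.5, 2]).
#' @param edgeDensity fraction of gene pairs declared true edges
#'   (default 0.05, the regime matched by a 95th-percentile threshold).
#' @param seed RNG seed.
#' @return a [SimulationScenario-class].
#' @export
simulationScenario <- function(p = 40L, nTarget = 10L, nRelated = 10L,
                               k = 3L, rhoLambda = 0.9,
                               noiseRange = c(0.5, 2),
                               edgeDensity = 0.05, seed = 1L) {
  new("SimulationScenario", p = as.integer(p), nTarget = as.integer(nTarget),
      nRelated = as.integer(nRelated), k = as.integer(k),
      rhoLambda = as.numeric(rhoLambda), noiseRange = as.numeric(noiseRange),
      edgeDensity = as.numeric(edgeDensity), seed = as.integer(seed))
}

.simSpecies <- function(lambda, psi, n, genes, prefix) {
  p <- nrow(lambda); k <- ncol(lambda)
  f <- matrix(stats::rnorm(k * n), k, n)
  eps <- matrix(stats::rnorm(p * n, sd = rep(sqrt(psi), n)), p, n)
  y <- lambda %*% f + eps
  y <- y - rowMeans(y)
  dimnames(y) <- list(genes, paste0(prefix, seq_len(n)))
  ExpressionMatrix(y)
}

#' Simulate a pair of related species and the true network
#'
#' Draws a target-species loading matrix with standard-normal entries,
#' mixes in an independent copy to produce the related species' loadings
#' at the requested element-wise correlation, draws heteroscedastic
#' noise variances log-uniformly per species, and samples centered
#' expression matrices. The ground-truth edge set is the top
#' `edgeDensity` fraction of gene pairs by absolute partial correlation
#' of the target's true covariance Lambda Lambda' + Psi — the edges a
#' Gaussian graphical model can in principle recover.
#'
#' @param scenario a [SimulationScenario-class].
#' @return list with elements `target`, `related`
#'   ([ExpressionMatrix-class]), `truth` ([EdgeList-class]),
#'   `lambdaTarget`, `lambdaRelated`, `psiTarget`, `psiRelated`, and
#'   `scenario`.
#' @examples
#' sim <- simulatePair(simulationScenario(p = 20, seed = 7))
#' edgeCount(sim$truth)  # round(0.05 * 20 * 19 / 2) = 10
#' @export
simulatePair <- function(scenario = simulationScenario()) {
  stopifnot(is(scenario, "SimulationScenario"))
  validObject(scenario)
  p <- scenario@p; k <- scenario@k; rho <- scenario@rhoLambda
  old <- .pushSeed(scenario@seed)
  on.exit(.popSeed(old))
  genes <- sprintf("g%04d", seq_len(p))

  lambdaT <- matrix(stats::rnorm(p * k), p, k, dimnames = list(genes, NULL))
  lambdaI <- matrix(stats::rnorm(p * k), p, k)
  lambdaR <- rho * lambdaT + sqrt(1 - rho^2) * lambdaI
  dimnames(lambdaR) <- dimnames(lambdaT)

  lo <- log(scenario@noiseRange[1]); hi <- log(scenario@noiseRange[2])
  psiT <- exp(stats::runif(p, lo, hi))
  psiR <- exp(stats::runif(p, lo, hi))
  names(psiT) <- names(psiR) <- genes

  target <- .simSpecies(lambdaT, psiT, scenario@nTarget, genes, "t")
  related <- .simSpecies(lambdaR, psiR, scenario@nRelated, genes, "r")

  sigma <- tcrossprod(lambdaT) + diag(psiT)
  pcorTrue <- partialCorrelations(chol2inv(chol(sigma)))
  m <- round(scenario@edgeDensity * p * (p - 1) / 2)
  idx <- which(upper.tri(pcorTrue), arr.ind = TRUE)
  ord <- order(abs(pcorTrue[upper.tri(pcorTrue)]), decreasing = TRUE)
  top <- idx[ord[seq_len(m)], , drop = FALSE]
  truth <- EdgeList(from = genes[top[, 1L]], to = genes[top[, 2L]],
                    weight = abs(pcorTrue[top]), nodeIds = genes)

  list(target = target, related = related, truth = truth,
       lambdaTarget = lambdaT, lambdaRelated = lambdaR,
       psiTarget = psiT, psiRelated = psiR, scenario = scenario)
}

#' Distance between the sample covariance and the generating covariance
#'
#' Relative Frobenius distance ||S - (Lambda Lambda' + Psi)||_F /
#' ||Lambda Lambda' + Psi||_F; shrinks as the number of samples grows.
#'
#' @param expr a centered [ExpressionMatrix-class] simulated from the
#'   factor model.
#' @param lambda,psi the generating loadings and noise variances.
#' @return numeric scalar.
#' @export
empiricalCovarianceCheck <- function(expr, lambda, psi) {
  v <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  if (nrow(v) != nrow(lambda) || nrow(v) != length(psi))
    stop("dimension mismatch between expression matrix and (lambda, psi)")
  S <- tcrossprod(v) / ncol(v)
  sigma <- tcrossprod(lambda) + diag(as.numeric(psi), nrow(lambda))
  norm(S - sigma, "F") / norm(sigma, "F")
}

#' Write a simulated pair to disk in pipeline-ready form
#'
#' @param sim result of [simulatePair()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(target = file.path(dir, "target_expression.tsv"),
             related = file.path(dir, "related_expression.tsv"),
             truth = file.path(dir, "truth_edges.tsv"))
  writeExpression(sim$target, paths[["target"]])
  writeExpression(sim$related, paths[["related"]])
  writeEdgeList(sim$truth, paths[["truth"]])
  invisible(paths)
}
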