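# Maximum-likelihood factor analysis for p >= n expression data.
#
# Model: y_j = Lambda f_j + eps_j with f_j ~ N(0, I_k) (the factor
# covariance is fixed to the identity for identifiability) and
# eps_j ~ N(0, Psi), Psi diagonal and heteroscedastic. The implied
# covariance is Sigma = Lambda Lambda' + Psi and the fit maximizes the
# 1/p-scaled Gaussian quasi-log-likelihood
#   -(1/2p) log|Sigma| - (1/2p) tr(S Sigma^{-1}).

#' Quasi-log-likelihood of a Gaussian factor model
#'
#' Evaluates -(1/2p) log|Sigma| - (1/2p) tr(S Sigma^{-1}) with
#' Sigma = Lambda Lambda' + Psi. The 1/p scaling only rescales the
#' objective; the maximizer is unchanged.
#'
#' @param S p x p sample covariance (divisor n).
#' @param loadings p x k loading matrix.
#' @param psi length-p vector of noise variances.
#' @return a single numeric value.
#' @export
faQuasiLogLik <- function(S, loadings, psi) {
  p <- nrow(S)
  sigma <- tcrossprod(loadings) + diag(psi, p)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  -(logdet + tr) / (2 * p)
}

# One E-step: posterior moments of the factors given current parameters.
# Returns the k x n matrix of posterior means and the shared k x k
# posterior covariance M = (I + Lambda' Psi^{-1} Lambda)^{-1}.
.faEStep <- function(Y, loadings, psi) {
  k <- ncol(loadings)
  W <- t(loadings / psi)                       # k x p, Lambda' Psi^{-1}
  M <- solve(diag(1, k) + W %*% loadings)
  M <- (M + t(M)) / 2
  list(mean = M %*% (W %*% Y), cov = M)
}

#' Fit a factor model by EM
#'
#' EM for the heteroscedastic Gaussian factor model with identity factor
#' covariance. Initialization is deterministic: the top-k eigenvectors of
#' the sample covariance scaled by root eigenvalues, with
#' Psi0 = diag(S) - diag(Lambda0 Lambda0') clipped into `psiBounds`.
#' After convergence the loadings are rotated (eigendecomposition of
#' Lambda' Psi^{-1} Lambda) so that Lambda' Psi^{-1} Lambda is diagonal
#' with decreasing entries, and column signs are fixed so each column's
#' largest-magnitude loading is positive.
#'
#' @param expr a centered [ExpressionMatrix-class] (or plain centered
#'   genes x samples matrix).
#' @param k number of factors, 1 <= k <= min(n - 1, p - 1).
#' @param maxIter iteration cap.
#' @param tol convergence tolerance on the quasi-log-likelihood
#'   improvement per iteration.
#' @param psiBounds optional clipping interval for the noise variances;
#'   default `c(1e-4, 1e4) * mean(diag(S))`, keeping the variances in a
#'   wide bounded interval as the high-dimensional theory assumes.
#' @return a [FactorModelFit-class].
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(50 * 2), 5) %*% matrix(rnorm(2 * 40), 2) +
#'      matrix(rnorm(5 * 40, sd = 0.3), 5)
#' dimnames(Y) <- list(paste0("g", 1:5), paste0("s", 1:40))
#' fit <- fitFactorModel(ExpressionMatrix(Y - rowMeans(Y)), k = 2)
#' numFactors(fit)
#' @export
fitFactorModel <- function(expr, k, maxIter = 500L, tol = 1e-8,
                           psiBounds = NULL) {
  Y <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  if (any(abs(rowMeans(Y)) > 1e-8))
    stop("factor model requires centered data (row means zero)")
  p <- nrow(Y); n <- ncol(Y)
  if (k < 1L || k > min(n - 1L, p - 1L))
    stop("k must satisfy 1 <= k <= min(n - 1, p - 1) = ",
         min(n - 1L, p - 1L))
  S <- tcrossprod(Y) / n
  if (is.null(psiBounds)) psiBounds <- c(1e-4, 1e4) * mean(diag(S))
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
  psi <- pmin(pmax(diag(S) - rowSums(lam^2), psiBounds[1]), psiBounds[2])
  if (any(!is.finite(psi)) || any(psi <= 0))
    stop("degenerate gene variances: cannot initialize noise variances")

  trace <- numeric(maxIter)
  sdiag <- diag(S)
  prev <- -Inf
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    es <- .faEStep(Y, lam, psi)
    EZ <- es$mean                              # k x n
    sumEzz <- n * es$cov + tcrossprod(EZ)      # sum_j E[z z']
    B <- Y %*% t(EZ)                           # p x k, sum_j y E[z]'
    lam <- B %*% solve(sumEzz)
    psi <- sdiag - rowSums(lam * B) / n
    psi <- pmin(pmax(psi, psiBounds[1]), psiBounds[2])
    ll <- faQuasiLogLik(S, lam, psi)
    trace[iter] <- ll
    if (is.finite(prev) && abs(ll - prev) < tol) { converged <- TRUE; break }
    if (iter >= maxIter) break
    prev <- ll
  }

  # identification rotation: diagonalize Lambda' Psi^{-1} Lambda
  A <- crossprod(lam / sqrt(psi))
  ea <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- lam %*% ea$vectors
  flip <- apply(lam, 2L, function(col) sign(col[which.max(abs(col))]))
  lam <- sweep(lam, 2L, ifelse(flip == 0, 1, flip), `*`)
  rownames(lam) <- rownames(Y)

  new("FactorModelFit", loadings = lam, noiseVariances = as.numeric(psi),
      k = as.integer(k), loglikTrace = trace[seq_len(iter)],
      converged = converged, nIter = iter, psiBounds = psiBounds)
}

#' Choose the number of factors by bi-cross-validation
#'
#' Repeatedly partitions the genes and the samples into folds; for every
#' held-out gene-by-sample block the retained blocks predict it through a
#' rank-k reconstruction (held-out block approximated by
#' Y12 pinv_k(Y22) Y21, with pinv_k the rank-k pseudo-inverse of the
#' fully retained block), and the squared prediction error is
#' accumulated. Returns the candidate k in 0..kMax with the smallest mean
#' error; ties break toward smaller k. The rank-0 candidate predicts the
#' zero matrix, so pure-noise data selects k = 0.
#'
#' @param expr a centered [ExpressionMatrix-class] or matrix.
#' @param kMax largest candidate, at most min(n - 2, p - 2).
#' @param nRepeats random fold partitions to average over.
#' @param rowFolds,colFolds number of sample and gene folds (>= 2).
#' @param seed RNG seed for the fold partitions.
#' @return the selected number of factors (integer, possibly 0).
#' @export
selectNumFactors <- function(expr, kMax = NULL, nRepeats = 10L,
                             rowFolds = 2L, colFolds = 2L, seed = 1L) {
  Y <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else as.matrix(expr)
  p <- nrow(Y); n <- ncol(Y)
  if (is.null(kMax)) kMax <- min(n - 2L, p - 2L, 20L)
  if (kMax < 0L) stop("kMax must be non-negative")
  if (kMax > min(n - 2L, p - 2L))
    stop("kMax must be at most min(n - 2, p - 2) = ", min(n - 2L, p - 2L))
  if (rowFolds < 2L || colFolds < 2L) stop("need at least 2 folds each way")
  if (n < rowFolds || p < colFolds) stop("insufficient data for the folds")
  if (kMax == 0L) return(0L)

  err <- numeric(kMax + 1L)
  old <- .pushSeed(seed)
  on.exit(.popSeed(old))
  for (r in seq_len(nRepeats)) {
    sfold <- sample(rep_len(seq_len(rowFolds), n))
    gfold <- sample(rep_len(seq_len(colFolds), p))
    for (sf in seq_len(rowFolds)) for (gf in seq_len(colFolds)) {
      hg <- gfold == gf; hs <- sfold == sf
      Y11 <- Y[hg, hs, drop = FALSE]
      Y12 <- Y[hg, !hs, drop = FALSE]
      Y21 <- Y[!hg, hs, drop = FALSE]
      Y22 <- Y[!hg, !hs, drop = FALSE]
      sv <- svd(Y22)
      kcap <- sum(sv$d > max(dim(Y22)) * .Machine$double.eps * sv$d[1])
      for (k in 0:kMax) {
        pred <- if (k == 0L) 0 else {
          kk <- min(k, kcap)
          uk <- sv$u[, seq_len(kk), drop = FALSE]
          vk <- sv$v[, seq_len(kk), drop = FALSE]
          (Y12 %*% vk) %*% (t(uk) / sv$d[seq_len(kk)]) %*% Y21
        }
        err[k + 1L] <- err[k + 1L] + sum((Y11 - pred)^2)
      }
    }
  }
  which.min(err) - 1L
}

#' Build the Wishart prior scale from a factor-model fit
#'
#' The factor-driven covariance Lambda Lambda' has rank k < p; a jitter
#' delta = max(epsPD - lambda_min, epsPD) is added to the diagonal so the
#' scale is positive definite (and at least epsPD away from singularity).
#' By default epsPD is the mean fitted noise variance, so the repaired
#' scale Lambda Lambda' + mean(Psi) I approximates the full factor-model
#' covariance with homogenized idiosyncratic noise — the prior then
#' encodes a genuine covariance structure rather than a nearly singular
#' one.
#'
#' @param fit a [FactorModelFit-class].
#' @param epsPD positive-definiteness floor for the smallest eigenvalue;
#'   NULL (default) uses `mean(noiseVariances(fit))`.
#' @return a [PriorScale-class] recording the jitter applied.
#' @examples
#' om <- buildPriorScale(
#'   new("FactorModelFit", loadings = matrix(c(1, 1), 2, 1),
#'       noiseVariances = c(1, 1), k = 1L, loglikTrace = 0,
#'       converged = TRUE, nIter = 1L, psiBounds = c(1e-4, 1e4)),
#'   epsPD = 0.01)
#' scaleMatrix(om)  # [[1.01, 1], [1, 1.01]]
#' @export
buildPriorScale <- function(fit, epsPD = NULL) {
  stopifnot(is(fit, "FactorModelFit"))
  if (is.null(epsPD)) epsPD <- mean(noiseVariances(fit))
  stopifnot(epsPD > 0)
  lam <- factorLoadings(fit)
  if (any(!is.finite(lam))) stop("non-finite loadings")
  omega0 <- tcrossprod(lam)
  omega0 <- (omega0 + t(omega0)) / 2
  lmin <- min(eigen(omega0, symmetric = TRUE, only.values = TRUE)$values)
  delta <- max(epsPD - lmin, epsPD)
  omega <- omega0 + diag(delta, nrow(omega0))
  dimnames(omega) <- list(rownames(lam), rownames(lam))
  new("PriorScale", omega = omega, jitter = delta, sourceK = fit@k)
}

#' Identity prior scale (diagonal-prior baseline)
#'
#' The structureless alternative to the factor-analytic scale: all prior
#' variances equal, all prior covariances zero.
#'
#' @param p dimension.
#' @param geneIds optional dimnames.
#' @return a [PriorScale-class] with omega = I.
#' @export
identityPriorScale <- function(p, geneIds = NULL) {
  omega <- diag(1, p)
  if (!is.null(geneIds)) dimnames(omega) <- list(geneIds, geneIds)
  new("PriorScale", omega = omega, jitter = 0, sourceK = 0L)
}

# Seed push/pop so exported functions are reproducible without
# clobbering the caller's RNG stream.
.pushSeed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

.popSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
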