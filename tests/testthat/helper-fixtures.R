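# Shared fixture builders: everything is generated in code, no files.

makeExpr <- function(values, genes = NULL, samples = NULL) {
  values <- as.matrix(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  ExpressionMatrix(values, geneIds = genes, sampleIds = samples)
}

centeredExpr <- function(values, ...) {
  v <- as.matrix(values)
  makeExpr(v - rowMeans(v), ...)
}

randomSPD <- function(p, seed = 1, jitter = 0.5) {
  set.seed(seed)
  a <- matrix(rnorm(p * p), p)
  crossprod(a) / p + diag(jitter, p)
}

# Data drawn from a known sparse precision matrix (banded, diagonally
# dominant), for threshold-selection and recovery checks.
sparseGGMData <- function(p, n, seed = 1, off = 0.3, bandEvery = 3L) {
  set.seed(seed)
  theta <- diag(1, p)
  for (i in seq_len(p - 1L)) {
    if (i %% bandEvery == 0L) {
      theta[i, i + 1L] <- off
      theta[i + 1L, i] <- off
    }
  }
  sigma <- solve(theta)
  y <- t(chol(sigma)) %*% matrix(rnorm(p * n), p, n)
  y <- y - rowMeans(y)
  dimnames(y) <- list(paste0("g", seq_len(p)), paste0("s", seq_len(n)))
  list(theta = theta, expr = ExpressionMatrix(y))
}

# Gaussian log likelihood of centered data in precision form, up to the
# Theta-independent constant: (n/2) log|Theta| - (n/2) tr(S Theta).
gaussLogLik <- function(theta, S, n) {
  ch <- chol(theta)
  n / 2 * (2 * sum(log(diag(ch)))) - n / 2 * sum(S * theta)
}
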