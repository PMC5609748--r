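# Conjugate Wishart machinery for the Gaussian precision matrix.
#
# Prior: Theta ~ W(v, G) with G = (v Omega)^{-1}, so E[Theta] = Omega^{-1}
# and Omega carries the structural prior belief about the covariance.
# With n centered samples and divisor-n sample covariance S the posterior
# is W(v + n, ((v + n) Omega*)^{-1}) where Omega* is the weighted average
# (n S + v Omega) / (n + v); its mode gives the MAP precision estimate.

.asScaleMatrix <- function(omega) {
  if (is(omega, "PriorScale")) scaleMatrix(omega) else as.matrix(omega)
}

#' Construct a Wishart prior for the precision matrix
#'
#' @param omega a [PriorScale-class] or p x p symmetric positive-definite
#'   matrix (the scale structure; the Wishart scale is `(dof * omega)^-1`).
#' @param dof degrees of freedom; must exceed p - 1 (real values
#'   allowed). Default p + 1, the smallest integer choice for which the
#'   posterior mode exists even at n = 0 and which weights all prior
#'   structures equally.
#' @return a [WishartPrior-class].
#' @examples
#' wishartPrior(diag(3))          # dof defaults to 4
#' wishartPrior(diag(3), dof = 3.5)
#' @export
wishartPrior <- function(omega, dof = NULL) {
  om <- .asScaleMatrix(omega)
  p <- nrow(om)
  if (is.null(dof)) dof <- p + 1
  if (dof <= p - 1)
    stop("dof must exceed p - 1 = ", p - 1,
         " (Wishart positive-definiteness requirement)")
  new("WishartPrior", dof = as.numeric(dof), omega = om)
}

#' Prior mean of the precision matrix
#'
#' Under W(v, (v Omega)^{-1}) the prior expectation of the precision
#' matrix is Omega^{-1}.
#'
#' @param prior a [WishartPrior-class].
#' @return p x p matrix.
#' @export
priorMeanPrecision <- function(prior) {
  stopifnot(is(prior, "WishartPrior"))
  chol2inv(chol(prior@omega))
}

#' Prior mean of the covariance matrix
#'
#' Equals Omega / (dof - p - 1), which exists only when dof > p + 1.
#' At the package default dof = p + 1 this mean is undefined and NULL is
#' returned with a warning.
#'
#' @param prior a [WishartPrior-class].
#' @return p x p matrix, or NULL when undefined.
#' @export
priorMeanCovariance <- function(prior) {
  stopifnot(is(prior, "WishartPrior"))
  p <- nrow(prior@omega)
  if (prior@dof <= p + 1) {
    warning("prior mean covariance undefined: requires dof > p + 1")
    return(NULL)
  }
  prior@omega / (prior@dof - p - 1)
}

#' Conjugate posterior update of the Wishart prior
#'
#' dof* = dof + n and Omega* = n/(n + dof) S + dof/(n + dof) Omega. The
#' result is positive definite whenever Omega is (S need only be
#' positive semi-definite), which is what makes the approach usable at
#' n << p where S is singular.
#'
#' @param prior a [WishartPrior-class].
#' @param S p x p sample covariance with divisor n (see
#'   [sampleCovariance()]).
#' @param n number of samples behind S.
#' @return a [WishartPosterior-class].
#' @export
posteriorUpdate <- function(prior, S, n) {
  stopifnot(is(prior, "WishartPrior"), n >= 1)
  S <- as.matrix(S)
  if (!identical(dim(S), dim(prior@omega)))
    stop("dimension mismatch between S and the prior scale")
  w <- n / (n + prior@dof)
  omegaStar <- w * S + (1 - w) * prior@omega
  omegaStar <- (omegaStar + t(omegaStar)) / 2
  new("WishartPosterior", dof = prior@dof + n, omega = omegaStar)
}

#' MAP estimate of the precision matrix
#'
#' The mode of the posterior W(v*, (v* Omega*)^{-1}):
#' Theta = (v* - p - 1) (v* Omega*)^{-1}. Computed by Cholesky solve and
#' symmetrized to absorb inversion round-off.
#'
#' @param posterior a [WishartPosterior-class].
#' @return p x p symmetric positive-definite precision matrix.
#' @export
mapPrecision <- function(posterior) {
  stopifnot(is(posterior, "WishartPosterior"))
  p <- nrow(posterior@omega)
  if (posterior@dof < p + 1)
    stop("posterior mode requires dof >= p + 1 (got ", posterior@dof, ")")
  ch <- tryCatch(chol(posterior@omega), error = function(e)
    stop("internal error: posterior scale is not positive definite"))
  theta <- ((posterior@dof - p - 1) / posterior@dof) * chol2inv(ch)
  (theta + t(theta)) / 2
}

#' Log density of the Wishart distribution W(dof, (dof * omega)^{-1})
#'
#' Full log density including the normalizing constant; used for the
#' conjugacy and mode diagnostics.
#'
#' @param theta symmetric positive-definite matrix at which to evaluate.
#' @param dof degrees of freedom.
#' @param omega scale-structure matrix (so the Wishart scale is
#'   `(dof * omega)^-1`).
#' @return log density (numeric scalar; -Inf when theta is not PD).
#' @export
wishartLogDensity <- function(theta, dof, omega) {
  omega <- .asScaleMatrix(omega)
  p <- nrow(omega)
  chTheta <- tryCatch(chol(theta), error = function(e) NULL)
  if (is.null(chTheta)) return(-Inf)
  logdetTheta <- 2 * sum(log(diag(chTheta)))
  chOm <- chol(omega)
  logdetG <- -(p * log(dof) + 2 * sum(log(diag(chOm))))  # log|(dof*omega)^-1|
  lmvg <- p * (p - 1) / 4 * log(pi) +
    sum(lgamma(dof / 2 + (1 - seq_len(p)) / 2))
  (dof - p - 1) / 2 * logdetTheta -
    dof / 2 * sum(omega * theta) -               # tr(G^{-1} Theta) / 2
    dof * p / 2 * log(2) - dof / 2 * logdetG - lmvg
}
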