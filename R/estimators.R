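## estimators: IVW, debiased IVW, the bias-corrected estimating-equation
## (MRBEE) estimator, the sandwich covariance, and the analytic IVW bias
## diagnostic.

condLimit <- function() 1e10

## Build a CausalFit, deriving se/z/p from theta and its covariance.
makeCausalFit <- function(theta, covTheta, method, ivMask, exposureNames,
                          nIter = 1L, converged = TRUE,
                          trace = data.frame()) {
  covTheta <- (covTheta + t(covTheta)) / 2
  se <- sqrt(pmax(diag(covTheta), 0))
  z <- ifelse(se > 0, theta / se, NA_real_)
  p <- pmax(2 * pnorm(abs(z), lower.tail = FALSE), .Machine$double.xmin)
  dimnames(covTheta) <- list(exposureNames, exposureNames)
  new("CausalFit",
      theta = setNames(as.numeric(theta), exposureNames),
      covTheta = covTheta,
      se = setNames(se, exposureNames),
      zStat = setNames(as.numeric(z), exposureNames),
      pValue = setNames(as.numeric(p), exposureNames),
      method = method,
      ivMask = ivMask,
      nIter = as.integer(nIter),
      converged = converged,
      trace = trace)
}

checkCollinearity <- function(B, exposureNames) {
  C <- crossprod(B)
  if (ncol(B) == 1L) {
    if (C[1, 1] <= 0) stop("numerical error: degenerate exposure column")
    return(C)
  }
  kap <- kappa(C, exact = TRUE)
  if (!is.finite(kap) || kap > condLimit()) {
    R <- suppressWarnings(cor(B))
    diag(R) <- 0
    worst <- which(abs(R) == max(abs(R)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "numerical error: collinear exposures (condition number %.3g); worst pair '%s' / '%s' (r = %.3f)",
      kap, exposureNames[worst[1]], exposureNames[worst[2]],
      R[worst[1], worst[2]]))
  }
  C
}

#' Multivariable IVW (ordinary least squares on z-scale statistics)
#'
#' On standardized summary statistics, multivariable inverse-variance
#' weighting is ordinary least squares of the SNP-outcome estimates on the
#' SNP-exposure estimates: \eqn{\hat\theta = (\hat B^\top \hat B)^{-1}
#' \hat B^\top \hat\alpha}. The covariance is a heteroskedasticity-robust
#' sandwich (the same sandwich as the bias-corrected estimator with zero
#' bias terms), so that IVW and the corrected estimator differ only in the
#' bias correction.
#'
#' @param panel a [SummaryPanel-class].
#' @param ivMask optional logical mask of instruments to use.
#' @return a [CausalFit-class] with `method = "ivw"`.
#' @export
fitIVW <- function(panel, ivMask = NULL) {
  stopifnot(is(panel, "SummaryPanel"))
  mask <- if (is.null(ivMask)) rep(TRUE, nIV(panel)) else ivMask
  B <- panel@Bhat[mask, , drop = FALSE]
  a <- panel@alphaHat[mask]
  C <- checkCollinearity(B, exposureNames(panel))
  th <- solve(C, crossprod(B, a))
  covTh <- sandwichCovariance(panel, zeroBiasTerms(nExposures(panel)),
                              as.numeric(th), ivMask = mask)
  makeCausalFit(th, covTh, "ivw", mask, exposureNames(panel))
}

beeCorrectedMatrix <- function(B, bias) {
  m <- nrow(B)
  C <- crossprod(B) - m * sigmaBB(bias)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  floorVal <- 1e-8 * sum(diag(crossprod(B))) / ncol(B)
  if (min(ev) < floorVal)
    stop("numerical error: corrected matrix B'B - m*Sigma_bb is not positive ",
         "definite (weak-instrument regime); use stronger instruments or ",
         "fewer exposures")
  C
}

#' Bias-corrected estimating-equation (MRBEE) estimate
#'
#' Solves the bias-corrected estimating equation
#' \eqn{S(\theta) = -\hat B^\top(\hat\alpha - \hat B\theta) -
#' m(\Sigma_{bb}\theta - \sigma_{ba}) = 0} in closed form:
#' \eqn{\hat\theta = (\hat B^\top\hat B - m\Sigma_{bb})^{-1}
#' (\hat B^\top\hat\alpha - m\sigma_{ba})}. Subtracting the error-covariance
#' terms removes both the weak-instrument (measurement-error) attenuation
#' and the sample-overlap bias of IVW. With zero bias terms the result
#' equals [fitIVW()] to machine precision.
#'
#' @param panel a [SummaryPanel-class].
#' @param bias a [BiasTerms-class] (from [estimateErrorCovariance()] or
#'   [overlapInformedTerms()]).
#' @param ivMask optional logical mask of instruments to use.
#' @return a [CausalFit-class] with `method = "bee"`.
#' @export
fitBEE <- function(panel, bias, ivMask = NULL) {
  stopifnot(is(panel, "SummaryPanel"), is(bias, "BiasTerms"))
  p <- nExposures(panel)
  if (ncol(sigmaFull(bias)) != p + 1L)
    stop("validation error: bias terms are for ", ncol(sigmaFull(bias)) - 1L,
         " exposures but the panel has ", p)
  mask <- if (is.null(ivMask)) rep(TRUE, nIV(panel)) else ivMask
  B <- panel@Bhat[mask, , drop = FALSE]
  a <- panel@alphaHat[mask]
  m <- nrow(B)
  checkCollinearity(B, exposureNames(panel))
  C <- beeCorrectedMatrix(B, bias)
  th <- solve(C, crossprod(B, a) - m * sigmaBA(bias))
  covTh <- sandwichCovariance(panel, bias, as.numeric(th), ivMask = mask)
  makeCausalFit(th, covTh, "bee", mask, exposureNames(panel))
}

#' Debiased IVW
#'
#' The bias-corrected estimator with the exposure-outcome error covariance
#' forced to zero: corrects weak-instrument attenuation only, so it is
#' identical to [fitBEE()] when the exposure and outcome GWAS share no
#' samples, and remains biased toward the confounder direction under
#' overlap.
#'
#' @inheritParams fitBEE
#' @return a [CausalFit-class] with `method = "divw"`.
#' @export
fitDIVW <- function(panel, bias, ivMask = NULL) {
  S <- sigmaFull(bias)
  p <- nrow(S) - 1L
  S[seq_len(p), p + 1L] <- 0
  S[p + 1L, seq_len(p)] <- 0
  fit <- fitBEE(panel, new("BiasTerms", SigmaFull = S, M = bias@M), ivMask)
  fit@method <- "divw"
  fit
}

#' Sandwich covariance of the bias-corrected estimate
#'
#' Computes \eqn{\hat F^{-1}\hat V\hat F^{-1}/m} with
#' \eqn{\hat F = \hat B^\top\hat B/m - \Sigma_{bb}},
#' \eqn{\hat V = m^{-1}\sum_j \hat S_j\hat S_j^\top} and per-instrument
#' score \eqn{\hat S_j = -(\hat\alpha_j - \theta^\top\hat\beta_j)\hat\beta_j
#' - \Sigma_{bb}\theta + \sigma_{ba}}. The 1/m scaling makes the sandwich
#' the covariance of \eqn{\hat\theta} itself (validated against Monte-Carlo
#' replication in the test suite).
#'
#' @param panel a [SummaryPanel-class].
#' @param bias a [BiasTerms-class].
#' @param theta causal-effect vector at which to evaluate the scores.
#' @param ivMask optional logical mask of instruments.
#' @return p x p covariance matrix.
#' @export
sandwichCovariance <- function(panel, bias, theta, ivMask = NULL) {
  mask <- if (is.null(ivMask)) rep(TRUE, nIV(panel)) else ivMask
  B <- panel@Bhat[mask, , drop = FALSE]
  a <- panel@alphaHat[mask]
  m <- nrow(B)
  Sbb <- sigmaBB(bias)
  sba <- sigmaBA(bias)
  F <- crossprod(B) / m - Sbb
  if (!is.finite(rcond(F)) || rcond(F) < 1e-14)
    stop("numerical error: singular bread matrix in the sandwich")
  r <- as.numeric(a - B %*% theta)
  ## scores: m x p matrix with rows S_j'
  Smat <- -r * B
  shift <- as.numeric(Sbb %*% theta) - sba
  Smat <- sweep(Smat, 2L, shift, `-`)
  V <- crossprod(Smat) / m
  Finv <- solve(F)
  cov <- Finv %*% V %*% Finv / m
  (cov + t(cov)) / 2
}

#' Evaluate the bias-corrected estimating equation
#'
#' Returns \eqn{S(\theta) = -\hat B^\top(\hat\alpha - \hat B\theta) -
#' m(\Sigma_{bb}\theta - \sigma_{ba})}; zero (to numerical tolerance) at the
#' fitted estimate. Exposed as a diagnostic.
#'
#' @inheritParams sandwichCovariance
#' @return length-p score vector.
#' @export
beeScore <- function(panel, bias, theta, ivMask = NULL) {
  mask <- if (is.null(ivMask)) rep(TRUE, nIV(panel)) else ivMask
  B <- panel@Bhat[mask, , drop = FALSE]
  a <- panel@alphaHat[mask]
  m <- nrow(B)
  as.numeric(-crossprod(B, a - B %*% theta) -
             m * (sigmaBB(bias) %*% theta - sigmaBA(bias)))
}

#' Predicted bias of the IVW estimator
#'
#' Analytic expectation of \eqn{\hat\theta_{IVW} - \theta}: the
#' weak-instrument-inflated measurement-error bias
#' \eqn{-(\mathrm{cov}(\beta) + \Sigma_{bb})^{-1}(\Sigma_{bb}\theta -
#' \sigma_{ba})} plus, when a SNP-effect/pleiotropy covariance is supplied,
#' the pleiotropy bias \eqn{(\mathrm{cov}(\beta) + \Sigma_{bb})^{-1}
#' \mathrm{cov}(\beta, \gamma)}. The per-instrument effect covariance
#' \eqn{\mathrm{cov}(\beta)} is estimated as
#' \eqn{\hat B^\top\hat B/m - \Sigma_{bb}}. Plug in the bias-corrected
#' estimate for `thetaRef`; the default `betaGammaCov = 0` assumes
#' instrument strength independent of direct effects after pleiotropy
#' removal.
#'
#' @param panel a [SummaryPanel-class].
#' @param bias a [BiasTerms-class].
#' @param thetaRef reference causal-effect vector (typically the
#'   bias-corrected estimate).
#' @param betaGammaCov per-instrument covariance between SNP-exposure
#'   effects and pleiotropy, length p or a single 0.
#' @param ivMask optional logical mask of instruments.
#' @return length-p predicted bias vector.
#' @export
predictIVWBias <- function(panel, bias, thetaRef, betaGammaCov = 0,
                           ivMask = NULL) {
  stopifnot(all(is.finite(thetaRef)))
  mask <- if (is.null(ivMask)) rep(TRUE, nIV(panel)) else ivMask
  B <- panel@Bhat[mask, , drop = FALSE]
  m <- nrow(B)
  p <- ncol(B)
  lead <- crossprod(B) / m  # cov(beta) + cov(w_beta)
  if (!is.finite(rcond(lead)) || rcond(lead) < 1e-14)
    stop("numerical error: singular leading matrix")
  if (length(betaGammaCov) == 1L) betaGammaCov <- rep(betaGammaCov, p)
  as.numeric(solve(lead, -(sigmaBB(bias) %*% thetaRef - sigmaBA(bias)) +
                     betaGammaCov))
}
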