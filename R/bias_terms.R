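## bias_terms: estimation-error covariance of summary statistics from
## insignificant null SNPs, and its analytic counterpart under known
## sample overlap.

#' Estimate the estimation-error covariance from null SNPs
#'
#' Computes the uncentered second-moment matrix \eqn{\Sigma =
#' Z^\top Z / M} of the null-SNP z-scores (exposure columns first, outcome
#' last). Because the selected variants carry no signal, this matrix is a
#' consistent estimate of the covariance of the z-scale estimation errors of
#' the summary statistics; the moment is deliberately uncentered, matching
#' the defining formula of the estimator. If the smallest eigenvalue falls
#' below `eigFloor`, eigenvalues are clipped up to the floor and the repair
#' is reported with a warning. Diagonal entries outside `diagBand` (the
#' plausible range for z-score error variances) are reported with a warning
#' but retained.
#'
#' @param nullPanel a [NullPanel-class].
#' @param eigFloor eigenvalue floor for the PSD repair (default 1e-10).
#' @param diagBand length-2 plausibility band for the diagonal (default
#'   `c(0.5, 2)`).
#' @param minFactor required floor `M >= minFactor * (p + 1)`.
#' @return a [BiasTerms-class].
#' @export
estimateErrorCovariance <- function(nullPanel, eigFloor = 1e-10,
                                    diagBand = c(0.5, 2), minFactor = 30) {
  stopifnot(is(nullPanel, "NullPanel"))
  Z <- nullZ(nullPanel)
  M <- nrow(Z)
  if (!all(is.finite(Z))) stop("validation error: non-finite entries in the null panel")
  if (M < minFactor * ncol(Z))
    stop(sprintf("validation error: M = %d null SNPs below the floor %d",
                 M, ceiling(minFactor * ncol(Z))))
  Sigma <- crossprod(Z) / M
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE)
  if (min(ev$values) < eigFloor) {
    warning(sprintf("PSD repair: clipping %d eigenvalue(s) below %g",
                    sum(ev$values < eigFloor), eigFloor))
    vals <- pmax(ev$values, eigFloor)
    Sigma <- ev$vectors %*% (vals * t(ev$vectors))
    Sigma <- (Sigma + t(Sigma)) / 2
  }
  d <- diag(Sigma)
  if (any(d < diagBand[1] | d > diagBand[2]))
    warning(sprintf("%d diagonal entr(ies) outside the plausibility band [%g, %g]",
                    sum(d < diagBand[1] | d > diagBand[2]), diagBand[1], diagBand[2]))
  new("BiasTerms", SigmaFull = Sigma, M = as.integer(M))
}

#' Analytic error covariance under known sample overlap
#'
#' Closed-form covariance of z-scale estimation errors when the GWAS
#' cohorts share a known fraction of individuals: the (k, l) off-diagonal
#' entry is the phenotypic (residual) correlation scaled by
#' \eqn{n_{overlap} / \sqrt{n_k n_l}}, with
#' \eqn{n_{overlap} = f \cdot \min(n_k, n_l)}; diagonal entries are 1.
#' Intended for simulations where truth is known, and as a cross-check of
#' [estimateErrorCovariance()].
#'
#' @param overlapFraction shared-sample fraction f in `[0, 1]`.
#' @param nExposures per-exposure GWAS sample sizes (length p).
#' @param nOutcome outcome GWAS sample size.
#' @param phenoCorr (p+1) x (p+1) phenotype correlation matrix (outcome
#'   last).
#' @return a [BiasTerms-class] with `M = NA`.
#' @export
overlapInformedTerms <- function(overlapFraction, nExposures, nOutcome,
                                 phenoCorr) {
  if (overlapFraction < 0 || overlapFraction > 1)
    stop("overlapFraction must be in [0, 1]")
  phenoCorr <- as.matrix(phenoCorr)
  p1 <- length(nExposures) + 1L
  if (nrow(phenoCorr) != p1 || ncol(phenoCorr) != p1)
    stop("phenoCorr must be (p + 1) x (p + 1)")
  if (max(abs(phenoCorr - t(phenoCorr))) > 1e-8 ||
      any(abs(diag(phenoCorr) - 1) > 1e-8))
    stop("validation error: phenoCorr is not a correlation matrix")
  ev <- eigen((phenoCorr + t(phenoCorr)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("validation error: phenoCorr is not positive semi-definite")
  n <- c(nExposures, nOutcome)
  Sigma <- matrix(0, p1, p1)
  for (k in seq_len(p1)) for (l in seq_len(p1)) {
    if (k == l) Sigma[k, l] <- 1
    else {
      nOv <- overlapFraction * min(n[k], n[l])
      Sigma[k, l] <- nOv / sqrt(n[k] * n[l]) * phenoCorr[k, l]
    }
  }
  new("BiasTerms", SigmaFull = (Sigma + t(Sigma)) / 2, M = NA_integer_)
}

#' Zero bias terms
#'
#' Convenience constructor of an all-zero error covariance (under which the
#' bias-corrected estimator reduces exactly to IVW).
#'
#' @param p number of exposures.
#' @return a [BiasTerms-class] with a zero matrix.
#' @export
zeroBiasTerms <- function(p) {
  new("BiasTerms", SigmaFull = matrix(0, p + 1L, p + 1L), M = NA_integer_)
}

#' Serialize bias terms to / from JSON
#'
#' Writes the full matrix, its partitions and M to a small JSON file so a
#' fit can be reproduced without the null panel.
#'
#' @param bias a [BiasTerms-class].
#' @param path JSON file path.
#' @return `writeBiasTerms()` the path invisibly; `readBiasTerms()` a
#'   `BiasTerms`.
#' @export
writeBiasTerms <- function(bias, path) {
  stopifnot(is(bias, "BiasTerms"))
  obj <- list(
    SigmaFull = sigmaFull(bias),
    SigmaBB = sigmaBB(bias),
    sigmaBA = sigmaBA(bias),
    sigmaAA = sigmaAA(bias),
    M = if (is.na(bias@M)) NULL else bias@M
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname writeBiasTerms
#' @export
readBiasTerms <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- as.matrix(obj$SigmaFull)
  new("BiasTerms", SigmaFull = (S + t(S)) / 2,
      M = if (is.null(obj$M)) NA_integer_ else as.integer(obj$M))
}
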