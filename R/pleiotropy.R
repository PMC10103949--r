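## pleiotropy: the per-SNP horizontal-pleiotropy chi-square test, iterative
## outlier removal, genome-wide scanning and locus classification.

CHISQ1_MEDIAN <- stats::qchisq(0.5, 1)  # 0.45494, median of chi-square(1)

#' Per-SNP horizontal-pleiotropy test
#'
#' For each SNP, tests the null of no horizontal pleiotropy
#' (\eqn{\gamma_j = 0}) given fitted causal effects. The statistic is the
#' squared causal-pathway residual over its delta-method variance,
#' \deqn{S_j = \frac{(\hat\alpha_j - \hat\beta_j^\top\hat\theta)^2}
#' {\sigma^2_{aa} + \hat\theta^\top\Sigma_{bb}\hat\theta +
#'  \hat\beta_j^\top \mathrm{cov}(\hat\theta)\hat\beta_j -
#'  2\hat\theta^\top\sigma_{ba}},}
#' distributed chi-square(1) under the null.
#'
#' @param panel a [SummaryPanel-class] (any set of SNPs harmonized to the
#'   same exposures, not only the instruments).
#' @param fit a [CausalFit-class] supplying \eqn{\hat\theta} and its
#'   covariance.
#' @param bias the [BiasTerms-class] used in the fit.
#' @param tau flagging significance level; defaults to the Bonferroni level
#'   `0.05 / nrow(panel)`.
#' @return data.frame with columns `snp, sPleio, pPleio, flagged`.
#' @export
pleioTest <- function(panel, fit, bias, tau = NULL) {
  stopifnot(is(panel, "SummaryPanel"), is(fit, "CausalFit"),
            is(bias, "BiasTerms"))
  if (is.null(tau)) tau <- 0.05 / nIV(panel)
  th <- as.numeric(theta(fit))
  B <- panel@Bhat
  r <- panel@alphaHat - as.numeric(B %*% th)
  Sbb <- sigmaBB(bias)
  denom <- sigmaAA(bias) + as.numeric(crossprod(th, Sbb %*% th)) +
    rowSums((B %*% covTheta(fit)) * B) -
    2 * sum(th * sigmaBA(bias))
  if (any(denom <= 0))
    stop("numerical error: nonpositive S_pleio variance; bias terms are ",
         "inconsistent with the panel")
  s <- r^2 / denom
  p <- pmax(pchisq(s, df = 1, lower.tail = FALSE), .Machine$double.xmin)
  data.frame(snp = snpId(panel), sPleio = s, pPleio = p, flagged = p < tau)
}

#' Iterative bias-corrected fit with pleiotropy removal
#'
#' Alternates between fitting the bias-corrected estimator on the currently
#' retained instruments and testing every candidate instrument for
#' horizontal pleiotropy with [pleioTest()] (at level `tau`, Bonferroni
#' 0.05/m by default). Instruments with test p-values below `tau` are
#' removed; removal is never permanent — the full candidate set is re-tested
#' at every iteration against the refreshed estimate and its refreshed
#' covariance, so the procedure is idempotent at convergence. Stops when the
#' retained set is unchanged or after `maxIter` iterations (then
#' `converged = FALSE`, with a warning).
#'
#' @param panel a [SummaryPanel-class].
#' @param bias a [BiasTerms-class].
#' @param tau removal significance level (default `0.05 / nIV(panel)`).
#' @param maxIter iteration cap (default 30).
#' @return a [CausalFit-class] with `method = "bee_iterative"`, the final
#'   retained-instrument mask, iteration count and trace.
#' @export
fitBEEIterative <- function(panel, bias, tau = NULL, maxIter = 30L) {
  stopifnot(is(panel, "SummaryPanel"), is(bias, "BiasTerms"))
  m <- nIV(panel)
  p <- nExposures(panel)
  if (is.null(tau)) tau <- 0.05 / m
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  mask <- rep(TRUE, m)
  trace <- data.frame(iteration = integer(), retained = integer(),
                      theta1 = numeric())
  fit <- NULL
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    fit <- fitBEE(panel, bias, ivMask = mask)
    pl <- pleioTest(panel, fit, bias, tau = tau)
    newMask <- pl$pPleio >= tau
    trace <- rbind(trace, data.frame(iteration = it, retained = sum(mask),
                                     theta1 = unname(theta(fit)[1])))
    if (sum(newMask) < p + 1)
      stop(sprintf(
        "algorithm error: only %d instruments retained at iteration %d (need %d); removal trace: %s",
        sum(newMask), it, p + 1,
        paste(trace$retained, collapse = " -> ")))
    if (identical(newMask, mask)) { converged <- TRUE; break }
    mask <- newMask
  }
  if (!converged)
    warning(sprintf("retained set still changing after %d iterations; returning last fit", maxIter))
  makeCausalFit(theta(fit), covTheta(fit), "bee_iterative", mask,
                exposureNames(panel), nIter = it, converged = converged,
                trace = trace)
}

#' IVW on the pleiotropy-cleaned instrument set
#'
#' Runs the iterative bias-corrected loop of [fitBEEIterative()] to identify
#' pleiotropic instruments at level `tau` (Bonferroni 0.05/m by default),
#' then returns plain [fitIVW()] on the retained set. This comparator
#' isolates what pleiotropy removal alone buys IVW: it remains subject to
#' the weak-instrument and overlap biases that the correction removes, by
#' approximately [predictIVWBias()].
#'
#' @inheritParams fitBEEIterative
#' @return a [CausalFit-class] with `method = "ivw_star"`.
#' @export
fitIVWStar <- function(panel, bias, tau = NULL, maxIter = 30L) {
  it <- fitBEEIterative(panel, bias, tau = tau, maxIter = maxIter)
  fit <- fitIVW(panel, ivMask = ivMask(it))
  makeCausalFit(theta(fit), covTheta(fit), "ivw_star", ivMask(it),
                exposureNames(panel), nIter = it@nIter,
                converged = it@converged, trace = it@trace)
}

#' Genome-wide pleiotropy scan
#'
#' Computes the pleiotropy statistic for every SNP in a genome-wide panel
#' given converged causal estimates, the genomic-control inflation factor
#' (median statistic over the chi-square(1) median), and — when chromosome
#' and position are available — a locus table built greedily: the most
#' significant remaining SNP below `threshold` seeds a window of
#' `windowKb` kb centred on it, all SNPs inside are absorbed, and the lead
#' SNP's GWAS / pleiotropy evidence classifies the locus via
#' [classifyAssociation()]. LD-based pruning is out of scope; windows are
#' distance-only.
#'
#' @param fullStats a genome-wide [SummaryPanel-class] harmonized to the
#'   same exposures as the fit.
#' @param fit a converged [CausalFit-class].
#' @param bias the [BiasTerms-class] used in the fit.
#' @param threshold genome-wide significance threshold for flagging and
#'   locus seeding (default 5e-8).
#' @param windowKb locus window size in kb (default 1000, i.e. 1 Mb).
#' @return a [ScanReport-class].
#' @export
genomeScan <- function(fullStats, fit, bias, threshold = 5e-8,
                       windowKb = 1000) {
  stopifnot(is(fullStats, "SummaryPanel"), is(fit, "CausalFit"))
  if (!fit@converged)
    stop("fit did not converge; refusing to scan")
  pl <- pleioTest(fullStats, fit, bias, tau = threshold)
  lam <- median(pl$sPleio) / CHISQ1_MEDIAN
  res <- data.frame(
    snp = pl$snp,
    chr = if (length(fullStats@chr)) fullStats@chr else NA_character_,
    pos = if (length(fullStats@pos)) fullStats@pos else NA_real_,
    sPleio = pl$sPleio, pPleio = pl$pPleio, flagged = pl$flagged)
  if (!length(fullStats@chr) || !length(fullStats@pos)) {
    warning("chromosome/position unavailable; locus table omitted")
    loci <- data.frame(chr = character(), start = numeric(), end = numeric(),
                       leadSnp = character(), leadP = numeric(),
                       class = character())
  } else {
    loci <- greedyLoci(fullStats, res, threshold, windowKb * 1000)
  }
  new("ScanReport", results = res, lambdaGC = lam, locusTable = loci)
}

greedyLoci <- function(fullStats, res, threshold, windowBp) {
  pOut <- pmax(2 * pnorm(abs(fullStats@alphaHat), lower.tail = FALSE),
               .Machine$double.xmin)
  pExpMin <- pmax(2 * pnorm(apply(abs(fullStats@Bhat), 1L, max),
                            lower.tail = FALSE), .Machine$double.xmin)
  cand <- which(res$pPleio < threshold)
  cand <- cand[order(res$pPleio[cand])]
  rows <- list()
  taken <- logical(nrow(res))
  for (i in cand) {
    if (taken[i]) next
    inWin <- res$chr == res$chr[i] & abs(res$pos - res$pos[i]) <= windowBp / 2
    taken[inWin] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      chr = res$chr[i],
      start = max(0, res$pos[i] - windowBp / 2),
      end = res$pos[i] + windowBp / 2,
      leadSnp = res$snp[i],
      leadP = res$pPleio[i],
      class = classifyAssociation(pOut[i], pExpMin[i], res$pPleio[i],
                                  threshold))
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(chr = character(), start = numeric(), end = numeric(),
                  leadSnp = character(), leadP = numeric(),
                  class = character())
}

#' Classify a locus by its association pathway
#'
#' Deterministic truth table over three significance indicators at a common
#' `threshold`: the original outcome GWAS p-value, the smallest exposure
#' GWAS p-value, and the pleiotropy-test p-value. Outcome-significant loci
#' split into `direct` (no exposure signal, pleiotropy significant —
#' association bypasses the exposures), `exposure_mediated` (exposure
#' signal, no residual pleiotropy) and `pleiotropic_shared` (both);
#' outcome-nonsignificant loci with pleiotropy evidence are
#' `novel_pleiotropic` (detectable only conditional on the causal model,
#' e.g. when exposure-mediated and direct effects cancel); anything else is
#' `null`.
#'
#' @param pOutcome outcome GWAS p-value(s).
#' @param pExposureMin minimum exposure GWAS p-value(s).
#' @param pPleio pleiotropy-test p-value(s).
#' @param threshold significance threshold (default 5e-8).
#' @return character vector of class labels.
#' @export
classifyAssociation <- function(pOutcome, pExposureMin, pPleio,
                                threshold = 5e-8) {
  stopifnot(all(pOutcome > 0 & pOutcome <= 1),
            all(pExposureMin > 0 & pExposureMin <= 1),
            all(pPleio > 0 & pPleio <= 1))
  outSig <- pOutcome < threshold
  expSig <- pExposureMin < threshold
  pleSig <- pPleio < threshold
  out <- rep("null", length(outSig))
  out[outSig & !expSig & pleSig] <- "direct"
  out[outSig & expSig & !pleSig] <- "exposure_mediated"
  out[outSig & expSig & pleSig] <- "pleiotropic_shared"
  out[!outSig & pleSig] <- "novel_pleiotropic"
  out
}
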