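#' @import methods
#' @importFrom stats pchisq pnorm qchisq qnorm median cor var sd rnorm runif
#'   setNames complete.cases ks.test
#' @importFrom utils packageVersion head
#' @importFrom data.table data.table fread fwrite setattr
#' @useDynLib mrbce, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## SummaryPanel: harmonized z-scale summary statistics for p exposures + 1
## outcome over m independent instruments.
## ---------------------------------------------------------------------------

#' Harmonized GWAS summary-statistic panel
#'
#' Container for standardized (z-scale) per-SNP association estimates for
#' \eqn{p} exposures and one outcome over \eqn{m} harmonized, LD-independent
#' variants. All estimators in the package consume this class. Estimates are
#' on the z scale (estimate divided by its standard error), the convention
#' under which multivariable inverse-variance weighting reduces to ordinary
#' least squares.
#'
#' @slot snpId character, variant identifiers (unique, length m).
#' @slot exposureNames character, exposure labels (length p).
#' @slot Bhat numeric m x p matrix of standardized SNP-exposure estimates.
#' @slot alphaHat numeric length-m vector of standardized SNP-outcome
#'   estimates.
#' @slot seB optional m x p matrix of original per-allele standard errors
#'   (zero rows when unavailable); retained only for round-tripping.
#' @slot seAlpha optional numeric vector of outcome standard errors.
#' @slot ea,oa optional effect/other allele columns (post-harmonization).
#' @slot chr,pos optional chromosome and base-pair position, used by
#'   [genomeScan()] to form loci.
#' @slot nExposure,nOutcome optional per-phenotype GWAS sample sizes
#'   (metadata only).
#'
#' @seealso [SummaryPanel()], [mergePanels()], [fitBEE()]
#' @export
setClass("SummaryPanel",
  representation(
    snpId = "character",
    exposureNames = "character",
    Bhat = "matrix",
    alphaHat = "numeric",
    seB = "matrix",
    seAlpha = "numeric",
    ea = "character",
    oa = "character",
    chr = "character",
    pos = "numeric",
    nExposure = "numeric",
    nOutcome = "numeric"
  )
)

setValidity("SummaryPanel", function(object) {
  m <- length(object@snpId)
  p <- length(object@exposureNames)
  msg <- character()
  if (nrow(object@Bhat) != m || ncol(object@Bhat) != p)
    msg <- c(msg, sprintf("Bhat must be %d x %d", m, p))
  if (length(object@alphaHat) != m)
    msg <- c(msg, "alphaHat must have one entry per SNP")
  if (anyDuplicated(object@snpId))
    msg <- c(msg, sprintf("duplicate snpId: '%s'",
                          object@snpId[duplicated(object@snpId)][1L]))
  if (m > 0 && (!all(is.finite(object@Bhat)) || !all(is.finite(object@alphaHat))))
    msg <- c(msg, "non-finite entries in Bhat/alphaHat")
  if (m < p + 1)
    msg <- c(msg, sprintf("need at least p + 1 = %d SNPs, got %d", p + 1, m))
  if (nrow(object@seB) > 0 &&
      (nrow(object@seB) != m || any(object@seB <= 0, na.rm = TRUE)))
    msg <- c(msg, "seB, when present, must be m x p with strictly positive entries")
  if (length(object@seAlpha) > 0 &&
      (length(object@seAlpha) != m || any(object@seAlpha <= 0, na.rm = TRUE)))
    msg <- c(msg, "seAlpha, when present, must be length m and strictly positive")
  for (sl in c("ea", "oa", "chr", "pos"))
    if (length(slot(object, sl)) > 0 && length(slot(object, sl)) != m)
      msg <- c(msg, sprintf("%s, when present, must have length m", sl))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## NullPanel: z-scores of insignificant, LD-independent SNPs used to
## estimate the estimation-error covariance.
## ---------------------------------------------------------------------------

#' Null-SNP z-score panel
#'
#' Standardized z-scores of genome-wide insignificant, LD-independent SNPs
#' for the p exposures (first columns) and the outcome (last column). Because
#' these variants carry (essentially) no signal, their z-scores are draws
#' from the estimation-error distribution of the summary statistics, and
#' their uncentered second moment estimates the error covariance needed by
#' the bias-corrected estimating equation.
#'
#' @slot Znull numeric M x (p+1) matrix of z-scores, outcome column last.
#' @slot pThreshold the insignificance p-value bound used at selection, or
#'   `NA` when the panel is built from variants null by construction (the
#'   simulation engine).
#'
#' @seealso [selectNullSnps()], [estimateErrorCovariance()]
#' @export
setClass("NullPanel",
  representation(Znull = "matrix", pThreshold = "numeric"),
  prototype(pThreshold = NA_real_)
)

setValidity("NullPanel", function(object) {
  msg <- character()
  if (!is.numeric(object@Znull) || ncol(object@Znull) < 2)
    msg <- c(msg, "Znull must be a numeric matrix with >= 2 columns")
  if (!all(is.finite(object@Znull)))
    msg <- c(msg, "non-finite entries in Znull")
  if (length(object@pThreshold) != 1)
    msg <- c(msg, "pThreshold must be a single value")
  else if (is.finite(object@pThreshold)) {
    bound <- qnorm(object@pThreshold / 2, lower.tail = FALSE)
    if (nrow(object@Znull) > 0 && max(abs(object@Znull)) > bound + 1e-8)
      msg <- c(msg, sprintf("|z| exceeds the bound %.3f implied by pThreshold", bound))
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## BiasTerms: (p+1) x (p+1) estimation-error covariance and its partitions.
## ---------------------------------------------------------------------------

#' Estimation-error covariance of summary statistics
#'
#' Symmetric positive semi-definite (p+1) x (p+1) covariance of the z-scale
#' estimation errors, exposures first and outcome last. The partitions drive
#' the bias correction: the p x p exposure block (see [sigmaBB()]), the
#' exposure-outcome cross-covariance vector ([sigmaBA()]), and the outcome
#' error variance ([sigmaAA()]). Partitions are computed from `SigmaFull` on
#' access, so they are exact sub-blocks by construction.
#'
#' @slot SigmaFull numeric (p+1) x (p+1) symmetric PSD matrix.
#' @slot M integer, number of null SNPs the estimate is based on (`NA_integer_`
#'   for analytic constructions).
#'
#' @seealso [estimateErrorCovariance()], [overlapInformedTerms()]
#' @export
setClass("BiasTerms",
  representation(SigmaFull = "matrix", M = "integer"),
  prototype(M = NA_integer_)
)

setValidity("BiasTerms", function(object) {
  S <- object@SigmaFull
  msg <- character()
  if (!is.numeric(S) || nrow(S) != ncol(S) || nrow(S) < 2)
    msg <- c(msg, "SigmaFull must be a square matrix of dimension >= 2")
  else {
    if (!all(is.finite(S)))
      msg <- c(msg, "non-finite entries in SigmaFull")
    else {
      if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
        msg <- c(msg, "SigmaFull is not symmetric")
      ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev), 1))
        msg <- c(msg, "SigmaFull is not positive semi-definite")
    }
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CausalFit: estimator output.
## ---------------------------------------------------------------------------

#' Fitted causal-effect estimates
#'
#' Result of one of the estimators: the causal-effect vector (z scale; for a
#' binary outcome, exponentiate to obtain odds ratios), its sandwich
#' covariance, Wald tests, the retained-instrument mask, and, for the
#' iterative fit, the removal trace.
#'
#' @slot theta named numeric length-p causal effect estimates.
#' @slot covTheta p x p covariance matrix of `theta`.
#' @slot se,zStat,pValue per-exposure standard errors, Wald z statistics,
#'   and two-sided p-values.
#' @slot method one of `"ivw"`, `"divw"`, `"bee"`, `"bee_iterative"`,
#'   `"ivw_star"`.
#' @slot ivMask logical length-m; TRUE where the instrument was retained.
#' @slot nIter number of iterations used (1 for non-iterative fits).
#' @slot converged logical.
#' @slot trace data.frame with one row per iteration (iteration, retained,
#'   theta of the first exposure) for the iterative fits.
#'
#' @seealso [fitBEE()], [fitIVW()], [fitBEEIterative()]
#' @export
setClass("CausalFit",
  representation(
    theta = "numeric",
    covTheta = "matrix",
    se = "numeric",
    zStat = "numeric",
    pValue = "numeric",
    method = "character",
    ivMask = "logical",
    nIter = "integer",
    converged = "logical",
    trace = "data.frame"
  )
)

setValidity("CausalFit", function(object) {
  p <- length(object@theta)
  msg <- character()
  if (nrow(object@covTheta) != p || ncol(object@covTheta) != p)
    msg <- c(msg, "covTheta must be p x p")
  else if (max(abs(object@covTheta - t(object@covTheta))) >
           1e-8 * max(1, max(abs(object@covTheta))))
    msg <- c(msg, "covTheta is not symmetric")
  if (length(object@se) != p || length(object@zStat) != p ||
      length(object@pValue) != p)
    msg <- c(msg, "se/zStat/pValue must have length p")
  if (any(object@pValue <= 0 | object@pValue > 1, na.rm = TRUE))
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (sum(object@ivMask) < p + 1)
    msg <- c(msg, "fewer than p + 1 retained instruments")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ScanReport: genome-wide pleiotropy scan.
## ---------------------------------------------------------------------------

#' Genome-wide pleiotropy scan report
#'
#' Per-SNP horizontal-pleiotropy statistics over the genome given fitted
#' causal effects, the genomic-control inflation factor, and (when positions
#' are available) a greedy 1-Mb locus table with pathway classifications.
#'
#' @slot results data.frame with columns snp, chr, pos, sPleio, pPleio,
#'   flagged.
#' @slot lambdaGC median pleiotropy statistic divided by the chi-square(1)
#'   median.
#' @slot locusTable data.frame with one row per locus: chr, start, end,
#'   leadSnp, leadP, class.
#'
#' @seealso [genomeScan()], [classifyAssociation()]
#' @export
setClass("ScanReport",
  representation(results = "data.frame", lambdaGC = "numeric",
                 locusTable = "data.frame")
)

setValidity("ScanReport", function(object) {
  msg <- character()
  if (length(object@lambdaGC) != 1 || !is.finite(object@lambdaGC) ||
      object@lambdaGC <= 0)
    msg <- c(msg, "lambdaGC must be a single positive number")
  need <- c("snp", "sPleio", "pPleio", "flagged")
  if (!all(need %in% names(object@results)))
    msg <- c(msg, "results must contain snp, sPleio, pPleio, flagged")
  if (length(msg)) msg else TRUE
})
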