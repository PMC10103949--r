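## Accessor generics and show methods. Slots are never accessed with @ by
## user code; these accessors are the supported surface.

#' @rdname SummaryPanel-class
#' @param object,x a `SummaryPanel` (or, where documented, another class).
#' @export
setGeneric("nIV", function(x) standardGeneric("nIV"))

#' @rdname SummaryPanel-class
#' @export
setGeneric("nExposures", function(x) standardGeneric("nExposures"))

#' @rdname SummaryPanel-class
#' @export
setGeneric("exposureNames", function(x) standardGeneric("exposureNames"))

#' @rdname SummaryPanel-class
#' @export
setGeneric("snpId", function(x) standardGeneric("snpId"))

#' @rdname SummaryPanel-class
#' @export
setGeneric("Bhat", function(x) standardGeneric("Bhat"))

#' @rdname SummaryPanel-class
#' @export
setGeneric("alphaHat", function(x) standardGeneric("alphaHat"))

#' @rdname BiasTerms-class
#' @param x a `BiasTerms` object.
#' @export
setGeneric("sigmaFull", function(x) standardGeneric("sigmaFull"))

#' @rdname BiasTerms-class
#' @export
setGeneric("sigmaBB", function(x) standardGeneric("sigmaBB"))

#' @rdname BiasTerms-class
#' @export
setGeneric("sigmaBA", function(x) standardGeneric("sigmaBA"))

#' @rdname BiasTerms-class
#' @export
setGeneric("sigmaAA", function(x) standardGeneric("sigmaAA"))

#' @rdname NullPanel-class
#' @param x a `NullPanel` object.
#' @export
setGeneric("nullZ", function(x) standardGeneric("nullZ"))

#' @rdname NullPanel-class
#' @export
setGeneric("nNullSnps", function(x) standardGeneric("nNullSnps"))

#' @rdname CausalFit-class
#' @param x a `CausalFit` object.
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @rdname CausalFit-class
#' @export
setGeneric("covTheta", function(x) standardGeneric("covTheta"))

#' @rdname CausalFit-class
#' @export
setGeneric("ivMask", function(x) standardGeneric("ivMask"))

#' @rdname ScanReport-class
#' @param x a `ScanReport` object.
#' @export
setGeneric("lambdaGC", function(x) standardGeneric("lambdaGC"))

#' @rdname ScanReport-class
#' @export
setGeneric("locusTable", function(x) standardGeneric("locusTable"))

## SummaryPanel ---------------------------------------------------------------

#' @rdname SummaryPanel-class
#' @export
setMethod("nIV", "SummaryPanel", function(x) length(x@snpId))

#' @rdname SummaryPanel-class
#' @export
setMethod("nExposures", "SummaryPanel", function(x) length(x@exposureNames))

#' @rdname SummaryPanel-class
#' @export
setMethod("exposureNames", "SummaryPanel", function(x) x@exposureNames)

#' @rdname SummaryPanel-class
#' @export
setMethod("snpId", "SummaryPanel", function(x) x@snpId)

#' @rdname SummaryPanel-class
#' @export
setMethod("Bhat", "SummaryPanel", function(x) {
  out <- x@Bhat
  dimnames(out) <- list(x@snpId, x@exposureNames)
  out
})

#' @rdname SummaryPanel-class
#' @export
setMethod("alphaHat", "SummaryPanel", function(x) setNames(x@alphaHat, x@snpId))

#' Subset a summary panel by SNP
#'
#' @param x a `SummaryPanel`.
#' @param i logical or integer index over SNP rows.
#' @param j,...,drop ignored.
#' @return a `SummaryPanel` restricted to the selected rows.
#' @export
setMethod("[", "SummaryPanel", function(x, i, j, ..., drop = FALSE) {
  sub <- function(v) if (length(v)) v[i] else v
  new("SummaryPanel",
      snpId = x@snpId[i],
      exposureNames = x@exposureNames,
      Bhat = x@Bhat[i, , drop = FALSE],
      alphaHat = x@alphaHat[i],
      seB = if (nrow(x@seB)) x@seB[i, , drop = FALSE] else x@seB,
      seAlpha = sub(x@seAlpha),
      ea = sub(x@ea), oa = sub(x@oa),
      chr = sub(x@chr), pos = sub(x@pos),
      nExposure = x@nExposure, nOutcome = x@nOutcome)
})

setMethod("show", "SummaryPanel", function(object) {
  cat(sprintf("SummaryPanel: %d instruments, %d exposure(s) + 1 outcome\n",
              nIV(object), nExposures(object)))
  cat("  exposures:", paste(object@exposureNames, collapse = ", "), "\n")
  if (length(object@chr)) cat("  genomic positions: present\n")
  invisible(object)
})

## NullPanel ------------------------------------------------------------------

#' @rdname NullPanel-class
#' @export
setMethod("nullZ", "NullPanel", function(x) x@Znull)

#' @rdname NullPanel-class
#' @export
setMethod("nNullSnps", "NullPanel", function(x) nrow(x@Znull))

setMethod("show", "NullPanel", function(object) {
  cat(sprintf("NullPanel: %d null SNPs x %d phenotypes", nrow(object@Znull),
              ncol(object@Znull)))
  if (is.finite(object@pThreshold))
    cat(sprintf(" (selected at p > %g)", object@pThreshold))
  cat("\n")
  invisible(object)
})

## BiasTerms ------------------------------------------------------------------

#' @rdname BiasTerms-class
#' @export
setMethod("sigmaFull", "BiasTerms", function(x) x@SigmaFull)

#' @rdname BiasTerms-class
#' @export
setMethod("sigmaBB", "BiasTerms", function(x) {
  p <- ncol(x@SigmaFull) - 1L
  x@SigmaFull[seq_len(p), seq_len(p), drop = FALSE]
})

#' @rdname BiasTerms-class
#' @export
setMethod("sigmaBA", "BiasTerms", function(x) {
  p <- ncol(x@SigmaFull) - 1L
  x@SigmaFull[seq_len(p), p + 1L]
})

#' @rdname BiasTerms-class
#' @export
setMethod("sigmaAA", "BiasTerms", function(x) {
  p <- ncol(x@SigmaFull) - 1L
  x@SigmaFull[p + 1L, p + 1L]
})

setMethod("show", "BiasTerms", function(object) {
  p <- ncol(object@SigmaFull) - 1L
  cat(sprintf("BiasTerms: %d exposure(s) + outcome", p))
  if (!is.na(object@M)) cat(sprintf(", estimated from M = %d null SNPs", object@M))
  cat("\n  outcome error variance:", signif(sigmaAA(object), 4), "\n")
  cat("  exposure-outcome error covariance:",
      paste(signif(sigmaBA(object), 4), collapse = ", "), "\n")
  invisible(object)
})

## CausalFit ------------------------------------------------------------------

#' @rdname CausalFit-class
#' @export
setMethod("theta", "CausalFit", function(x) x@theta)

#' @rdname CausalFit-class
#' @export
setMethod("covTheta", "CausalFit", function(x) x@covTheta)

#' @rdname CausalFit-class
#' @export
setMethod("ivMask", "CausalFit", function(x) x@ivMask)

setMethod("show", "CausalFit", function(object) {
  cat(sprintf("CausalFit (%s): %d of %d instruments retained", object@method,
              sum(object@ivMask), length(object@ivMask)))
  if (object@nIter > 1L)
    cat(sprintf(", %d iterations%s", object@nIter,
                if (object@converged) "" else " (not converged)"))
  cat("\n")
  print(summary(object))
  invisible(object)
})

#' Summarize a causal fit
#'
#' @param object a `CausalFit`.
#' @param ... unused.
#' @return data.frame with exposure, theta, se, z, p and the odds ratio with
#'   its 95\% interval (meaningful for binary outcomes).
#' @export
setMethod("summary", "CausalFit", function(object, ...) {
  ci <- qnorm(0.975)
  data.frame(
    exposure = names(object@theta),
    theta = unname(object@theta),
    se = unname(object@se),
    z = unname(object@zStat),
    p = unname(object@pValue),
    or = exp(unname(object@theta)),
    orLower = exp(unname(object@theta) - ci * unname(object@se)),
    orUpper = exp(unname(object@theta) + ci * unname(object@se)),
    row.names = NULL
  )
})

## ScanReport -----------------------------------------------------------------

#' @rdname ScanReport-class
#' @export
setMethod("lambdaGC", "ScanReport", function(x) x@lambdaGC)

#' @rdname ScanReport-class
#' @export
setMethod("locusTable", "ScanReport", function(x) x@locusTable)

setMethod("show", "ScanReport", function(object) {
  cat(sprintf("ScanReport: %d SNPs, lambda_GC = %.3f, %d flagged, %d loci\n",
              nrow(object@results), object@lambdaGC,
              sum(object@results$flagged), nrow(object@locusTable)))
  invisible(object)
})
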