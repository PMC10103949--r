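## Serialization of fit results: TSV for the per-exposure summary, JSON for
## the full object (covariance, mask, trace).

#' Write / read a causal fit
#'
#' `writeFit()` writes two files: `<prefix>.tsv` with the per-exposure
#' summary (theta, se, z, p, odds ratio and 95% interval) and
#' `<prefix>.json` with the complete fit (covariance matrix, retained-IV
#' mask, iteration trace). `readFit()` restores the [CausalFit-class] from
#' the JSON file.
#'
#' @param fit a [CausalFit-class].
#' @param prefix output path prefix.
#' @return `writeFit()` the two paths invisibly; `readFit()` a `CausalFit`.
#' @export
writeFit <- function(fit, prefix) {
  stopifnot(is(fit, "CausalFit"))
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  data.table::fwrite(summary(fit), tsv, sep = "\t")
  obj <- list(
    method = fit@method,
    exposures = names(fit@theta),
    theta = unname(fit@theta),
    se = unname(fit@se),
    z = unname(fit@zStat),
    p = unname(fit@pValue),
    covTheta = unname(fit@covTheta),
    ivMask = fit@ivMask,
    nIter = fit@nIter,
    converged = fit@converged,
    trace = fit@trace)
  jsonlite::write_json(obj, js, digits = NA, auto_unbox = TRUE)
  invisible(c(tsv, js))
}

#' @rdname writeFit
#' @param path path to a `<prefix>.json` written by `writeFit()`.
#' @export
readFit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("method", "exposures", "theta", "covTheta", "ivMask")
  if (!all(need %in% names(obj)))
    stop("fit JSON schema mismatch: missing ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  cov <- as.matrix(obj$covTheta)
  makeCausalFit(obj$theta, (cov + t(cov)) / 2, obj$method,
                as.logical(obj$ivMask), obj$exposures,
                nIter = if (is.null(obj$nIter)) 1L else obj$nIter,
                converged = isTRUE(obj$converged),
                trace = if (is.null(obj$trace)) data.frame()
                        else as.data.frame(obj$trace))
}
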