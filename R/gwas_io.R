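## gwas_io: reading, harmonization, standardization and validation of GWAS
## summary statistics.

PALINDROMIC <- c("A/T", "T/A", "C/G", "G/C")

#' Construct a summary panel
#'
#' Low-level constructor for [SummaryPanel-class]; most users will obtain a
#' panel from [mergePanels()] or the simulation engine instead.
#'
#' @param snpId character vector of unique variant ids.
#' @param Bhat m x p matrix of standardized SNP-exposure estimates (z scale).
#' @param alphaHat length-m vector of standardized SNP-outcome estimates.
#' @param exposureNames exposure labels; defaults to `colnames(Bhat)` or
#'   `x1..xp`.
#' @param seB,seAlpha optional original standard errors (per-allele units).
#' @param ea,oa optional harmonized effect/other alleles.
#' @param chr,pos optional genomic coordinates.
#' @param nExposure,nOutcome optional per-phenotype sample sizes.
#' @return a validated `SummaryPanel`.
#' @export
SummaryPanel <- function(snpId, Bhat, alphaHat, exposureNames = NULL,
                         seB = NULL, seAlpha = NULL, ea = NULL, oa = NULL,
                         chr = NULL, pos = NULL,
                         nExposure = NULL, nOutcome = NULL) {
  Bhat <- as.matrix(Bhat)
  if (is.null(exposureNames))
    exposureNames <- colnames(Bhat)
  if (is.null(exposureNames))
    exposureNames <- paste0("x", seq_len(ncol(Bhat)))
  new("SummaryPanel",
      snpId = as.character(snpId),
      exposureNames = as.character(exposureNames),
      Bhat = unname(Bhat),
      alphaHat = as.numeric(alphaHat),
      seB = if (is.null(seB)) matrix(numeric(), 0, ncol(Bhat)) else unname(as.matrix(seB)),
      seAlpha = if (is.null(seAlpha)) numeric() else as.numeric(seAlpha),
      ea = if (is.null(ea)) character() else toupper(as.character(ea)),
      oa = if (is.null(oa)) character() else toupper(as.character(oa)),
      chr = if (is.null(chr)) character() else as.character(chr),
      pos = if (is.null(pos)) numeric() else as.numeric(pos),
      nExposure = if (is.null(nExposure)) numeric() else as.numeric(nExposure),
      nOutcome = if (is.null(nOutcome)) numeric() else as.numeric(nOutcome))
}

#' Default GWAS column mapping
#'
#' The role-to-column-name mapping assumed by [readSummaryTable()] when no
#' override is supplied.
#'
#' @return named character vector over the roles
#'   `snp, ea, oa, beta, se, p, n`.
#' @export
defaultColumnMap <- function() {
  c(snp = "SNP", ea = "EA", oa = "OA", beta = "BETA", se = "SE",
    p = "P", n = "N")
}

#' Read one GWAS summary-statistics table
#'
#' Reads a delimited (TSV/CSV, transparently gzipped) per-phenotype GWAS
#' summary file, resolves columns through `columnMap`, drops rows with
#' missing required cells (logging the count), validates standard errors,
#' and standardizes estimates to the z scale (`beta / se`) unless the input
#' is already standardized. Two-sided p-values are computed from z when the
#' p column is absent.
#'
#' @param path file path.
#' @param columnMap named character vector mapping the roles
#'   `snp, ea, oa, beta, se, p, n` to column names in the file. Roles `snp`
#'   and `beta` are required; `se` is required unless `standardized = TRUE`.
#' @param standardized set TRUE when the `beta` column already holds
#'   z-scores; values are then loaded unchanged.
#' @return a `GwasTable`: a [data.table::data.table] with columns
#'   `snp, ea, oa, z, se, p, n` (allele/se/n columns NA when absent from the
#'   file), consumed by [mergePanels()] and [selectNullSnps()].
#' @export
readSummaryTable <- function(path, columnMap = defaultColumnMap(),
                             standardized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- defaultColumnMap()
  map[names(columnMap)] <- columnMap
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("snp", "beta", if (!standardized) "se")
  for (role in need) {
    if (!map[[role]] %in% names(dt))
      stop(sprintf("configuration error: required column '%s' (role '%s') not found in %s",
                   map[[role]], role, path))
  }
  pick <- function(role, default = NA) {
    cn <- map[[role]]
    if (cn %in% names(dt)) dt[[cn]] else rep(default, nrow(dt))
  }
  out <- data.table::data.table(
    snp = as.character(pick("snp")),
    ea = toupper(as.character(pick("ea", NA_character_))),
    oa = toupper(as.character(pick("oa", NA_character_))),
    beta = as.numeric(pick("beta")),
    se = if (standardized) rep(NA_real_, nrow(dt)) else as.numeric(pick("se")),
    p = as.numeric(pick("p")),
    n = as.numeric(pick("n"))
  )
  required <- c("snp", "beta", if (!standardized) "se")
  keep <- Reduce(`&`, lapply(required, function(cn) !is.na(out[[cn]])))
  nDropped <- sum(!keep)
  if (nDropped > 0) {
    warning(sprintf("%s: dropped %d row(s) with missing required cells", path, nDropped))
    out <- out[keep, ]
  }
  if (anyDuplicated(out$snp))
    stop(sprintf("validation error: duplicate snp id '%s' in %s",
                 out$snp[duplicated(out$snp)][1L], path))
  if (!standardized) {
    if (any(out$se <= 0))
      stop(sprintf("validation error: zero or negative standard error in %s", path))
    out$z <- out$beta / out$se
  } else {
    out$z <- out$beta
  }
  out$p <- ifelse(is.na(out$p), 2 * pnorm(abs(out$z), lower.tail = FALSE), out$p)
  out <- out[, c("snp", "ea", "oa", "z", "se", "p", "n")]
  data.table::setattr(out, "class", c("GwasTable", class(out)))
  out
}

allelePair <- function(a, b) paste(a, b, sep = "/")

#' Merge per-phenotype tables into a harmonized panel
#'
#' Inner-joins per-phenotype [readSummaryTable()] outputs on SNP id and
#' harmonizes alleles to the outcome table's effect allele: estimates whose
#' effect/other alleles are swapped relative to the outcome are sign-flipped;
#' rows whose allele pairs can be neither matched nor swapped are dropped and
#' counted; strand-ambiguous palindromic SNPs (A/T, C/G) are dropped unless
#' `keepPalindromic`. Join, flip and drop counts are reported via `message()`.
#'
#' @param exposureTables named list of `GwasTable`s, one per exposure.
#' @param outcomeTable `GwasTable` for the outcome; its effect allele is the
#'   reference.
#' @param keepPalindromic keep strand-ambiguous palindromic SNPs (default
#'   drop).
#' @return a [SummaryPanel-class].
#' @export
mergePanels <- function(exposureTables, outcomeTable, keepPalindromic = FALSE) {
  if (is.null(names(exposureTables)) || any(!nzchar(names(exposureTables))))
    names(exposureTables) <- paste0("x", seq_along(exposureTables))
  p <- length(exposureTables)
  ids <- Reduce(intersect, c(lapply(exposureTables, `[[`, "snp"),
                             list(outcomeTable$snp)))
  if (length(ids) == 0)
    stop("validation error: no shared SNPs across the supplied tables")
  oc <- outcomeTable[match(ids, outcomeTable$snp), ]
  hasAlleles <- !all(is.na(oc$ea))
  keep <- rep(TRUE, length(ids))
  nFlip <- 0L
  Z <- matrix(NA_real_, length(ids), p)
  SE <- matrix(NA_real_, length(ids), p)
  for (k in seq_len(p)) {
    tb <- exposureTables[[k]][match(ids, exposureTables[[k]]$snp), ]
    z <- tb$z
    if (hasAlleles && !all(is.na(tb$ea))) {
      same <- tb$ea == oc$ea & tb$oa == oc$oa
      swap <- tb$ea == oc$oa & tb$oa == oc$ea
      z[swap] <- -z[swap]
      nFlip <- nFlip + sum(swap, na.rm = TRUE)
      bad <- !(same | swap) | is.na(same)
      keep <- keep & !bad
    }
    Z[, k] <- z
    SE[, k] <- tb$se
  }
  nIrrec <- sum(!keep)
  if (hasAlleles && !keepPalindromic) {
    pal <- allelePair(oc$ea, oc$oa) %in% PALINDROMIC
    nPal <- sum(pal & keep)
    keep <- keep & !pal
  } else nPal <- 0L
  message(sprintf(
    "mergePanels: %d shared SNPs; kept %d, flipped %d estimate(s), dropped %d irreconcilable and %d palindromic",
    length(ids), sum(keep), nFlip, nIrrec, nPal))
  if (sum(keep) < p + 1)
    stop("validation error: fewer than p + 1 SNPs survive harmonization")
  anySE <- !all(is.na(SE[keep, , drop = FALSE]))
  SummaryPanel(
    snpId = ids[keep],
    Bhat = Z[keep, , drop = FALSE],
    alphaHat = oc$z[keep],
    exposureNames = names(exposureTables),
    seB = if (anySE) SE[keep, , drop = FALSE] else NULL,
    seAlpha = if (!all(is.na(oc$se[keep]))) oc$se[keep] else NULL,
    ea = if (hasAlleles) oc$ea[keep] else NULL,
    oa = if (hasAlleles) oc$oa[keep] else NULL,
    nExposure = vapply(exposureTables, function(tb) {
      n <- suppressWarnings(stats::median(tb$n, na.rm = TRUE)); if (is.finite(n)) n else NA_real_
    }, numeric(1)),
    nOutcome = {
      n <- suppressWarnings(stats::median(outcomeTable$n, na.rm = TRUE))
      if (is.finite(n)) n else NA_real_
    })
}

#' Select insignificant null SNPs for error-covariance estimation
#'
#' Retains SNPs whose association p-value exceeds `pThreshold`
#' simultaneously for every phenotype (p exposures and the outcome) and
#' returns their z-score matrix. LD independence is the caller's contract:
#' no LD is computed here. When `prethinned = FALSE` a uniform down-sampling
#' is applied as a crude proxy and a message notes that LD independence
#' remains the caller's responsibility.
#'
#' @param tables named list of genome-wide `GwasTable`s, exposures first and
#'   the outcome last.
#' @param pThreshold insignificance threshold (default 0.05): a SNP is kept
#'   only if p > `pThreshold` for all phenotypes.
#' @param prethinned assert that the input is already LD-thinned.
#' @param downsampleTo when `prethinned = FALSE`, target number of survivors
#'   to uniformly sample (default: keep every 10th).
#' @param minFactor floor on the panel size, `M >= minFactor * (p + 1)`.
#' @return a [NullPanel-class].
#' @export
selectNullSnps <- function(tables, pThreshold = 0.05, prethinned = TRUE,
                           downsampleTo = NULL, minFactor = 30) {
  k <- length(tables)
  if (k < 2) stop("need at least one exposure table and the outcome table")
  ids <- Reduce(intersect, lapply(tables, `[[`, "snp"))
  Z <- vapply(tables, function(tb) tb$z[match(ids, tb$snp)], numeric(length(ids)))
  P <- vapply(tables, function(tb) tb$p[match(ids, tb$snp)], numeric(length(ids)))
  keep <- rowSums(P > pThreshold) == k & complete.cases(Z)
  Z <- Z[keep, , drop = FALSE]
  if (!prethinned) {
    message("selectNullSnps: input not LD-thinned; down-sampling uniformly. ",
            "LD independence remains the caller's responsibility.")
    want <- if (is.null(downsampleTo)) max(1L, nrow(Z) %/% 10L) else downsampleTo
    if (want < nrow(Z))
      Z <- Z[sort(sample.int(nrow(Z), want)), , drop = FALSE]
  }
  floorM <- ceiling(minFactor * k)
  if (nrow(Z) < floorM)
    stop(sprintf("validation error: only M = %d null SNPs survive; floor is %d",
                 nrow(Z), floorM))
  new("NullPanel", Znull = unname(Z), pThreshold = pThreshold)
}

#' Write / read a harmonized panel as TSV
#'
#' Round-trips a [SummaryPanel-class] through a plain TSV with columns
#' `snp, ea, oa, z_<exposure...>, z_outcome` (plus `chr, pos` when present).
#' `readPanel()` restores the panel to full floating precision.
#'
#' @param panel a `SummaryPanel`.
#' @param path output TSV path.
#' @return `writePanel()` the path, invisibly; `readPanel()` a
#'   `SummaryPanel`.
#' @export
writePanel <- function(panel, path) {
  stopifnot(is(panel, "SummaryPanel"))
  dt <- data.table::data.table(snp = panel@snpId)
  if (length(panel@ea)) { dt$ea <- panel@ea; dt$oa <- panel@oa }
  if (length(panel@chr)) { dt$chr <- panel@chr; dt$pos <- panel@pos }
  B <- panel@Bhat
  # %.17g round-trips doubles exactly through the text representation
  for (k in seq_len(ncol(B)))
    dt[[paste0("z_", panel@exposureNames[k])]] <- sprintf("%.17g", B[, k])
  dt$z_outcome <- sprintf("%.17g", panel@alphaHat)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  dt <- data.table::fread(path, showProgress = FALSE)
  zCols <- grep("^z_", names(dt), value = TRUE)
  zCols <- setdiff(zCols, "z_outcome")
  SummaryPanel(
    snpId = dt$snp,
    Bhat = as.matrix(dt[, zCols, with = FALSE]),
    alphaHat = dt$z_outcome,
    exposureNames = sub("^z_", "", zCols),
    ea = if ("ea" %in% names(dt)) dt$ea else NULL,
    oa = if ("oa" %in% names(dt)) dt$oa else NULL,
    chr = if ("chr" %in% names(dt)) dt$chr else NULL,
    pos = if ("pos" %in% names(dt)) dt$pos else NULL)
}
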