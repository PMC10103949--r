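## simulate: individual-level data generator and per-SNP GWAS regression
## engine reproducing the univariable and multivariable validation designs,
## including configurable sample overlap and UHP/CHP contamination.

#' Simulation configuration
#'
#' Bundles and validates the generating parameters of the individual-level
#' simulation designs. Defaults are the study conditions of the validation
#' experiments: n = 30,000 individuals, instruments jointly explaining 5%
#' of each exposure's variance, minor allele frequencies Uniform(0.05,
#' 0.50), causal effects of 0.5, a shared confounder with variance
#' `(1 - h2) * 0.15` (univariable) or `(1 - h2) * (0.15/2)^2`
#' (multivariable), exposure phenotypic correlation 0.5 and genetic-effect
#' correlation 0.45 in the two-exposure design.
#'
#' Contaminated instruments (UHP: direct outcome effects independent of the
#' instrument strengths; CHP: effects negatively correlated with them)
#' carry per-SNP direct effects with standard deviation
#' `pleioRatio * sqrt(h2 / m)`, i.e. `pleioRatio` times the typical per-IV
#' exposure-effect scale; CHP effects correlate `chpCorr` with the
#' SNP-exposure effects (univariable) or are built on the mediated effect
#' \eqn{\beta_1\theta_1 + \beta_2\theta_2} (multivariable).
#'
#' @param m number of instruments (the experiments use 50, 100, 250).
#' @param n GWAS sample size per phenotype (default 30,000).
#' @param p number of exposures, 1 or 2.
#' @param h2 per-exposure heritability explained by the m instruments.
#' @param thetaTrue length-p true causal effects (default 0.5 each).
#' @param overlapFraction fraction of individuals shared between exposure
#'   and outcome GWAS samples, in `[0, 1]`.
#' @param uhpFraction,chpFraction fractions of instruments carrying UHP /
#'   CHP effects (the experiments use 0 or 0.10).
#' @param mafRange minor-allele-frequency range, default `c(0.05, 0.5)`.
#' @param phenoCorr exposure phenotypic correlation (two-exposure design).
#' @param betaCorr genetic-effect correlation (two-exposure design).
#' @param pleioRatio pleiotropy scale relative to the per-IV effect scale.
#' @param chpCorr correlation of CHP effects with instrument strength
#'   (negative).
#' @param nullM number of matched null SNPs simulated for error-covariance
#'   estimation (default 10,000; replicated experiments typically use a
#'   smaller panel, see the methods vignette).
#' @param seed optional RNG seed applied by the generators.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(m = 100L, n = 30000L, p = 1L, h2 = 0.05,
                      thetaTrue = rep(0.5, p), overlapFraction = 1,
                      uhpFraction = 0, chpFraction = 0,
                      mafRange = c(0.05, 0.5), phenoCorr = 0.5,
                      betaCorr = 0.45, pleioRatio = 2.5, chpCorr = -0.5,
                      nullM = 10000L, seed = NULL) {
  stopifnot(p %in% c(1L, 2L), m >= p + 1, n > 10,
            length(thetaTrue) == p,
            h2 > 0, h2 < 1,
            overlapFraction >= 0, overlapFraction <= 1,
            uhpFraction >= 0, uhpFraction <= 1,
            chpFraction >= 0, chpFraction <= 1,
            uhpFraction + chpFraction <= 1,
            length(mafRange) == 2, mafRange[1] > 0, mafRange[2] <= 0.5,
            abs(phenoCorr) < 1, abs(betaCorr) < 1,
            pleioRatio >= 0, chpCorr >= -1, chpCorr <= 1, nullM >= 0)
  confounderVar <- if (p == 1L) (1 - h2) * 0.15 else (1 - h2) * (0.15 / 2)^2
  if (h2 + confounderVar >= 1)
    stop("configuration error: infeasible variance budget (h2 + var(U) >= 1)")
  structure(list(
    m = as.integer(m), n = as.integer(n), p = as.integer(p), h2 = h2,
    thetaTrue = as.numeric(thetaTrue), overlapFraction = overlapFraction,
    uhpFraction = uhpFraction, chpFraction = chpFraction,
    mafRange = as.numeric(mafRange), phenoCorr = phenoCorr,
    betaCorr = betaCorr, pleioRatio = pleioRatio, chpCorr = chpCorr,
    confounderVar = confounderVar, nullM = as.integer(nullM),
    seed = seed), class = "SimConfig")
}

#' Draw a genotype matrix
#'
#' Draws an n x m matrix of additive genotype counts, column j binomial(2,
#' maf_j) with its own minor allele frequency from Uniform(`mafRange`),
#' columns independent (no LD). The MAFs are attached as attribute `"maf"`.
#'
#' @param m number of SNPs.
#' @param n number of individuals.
#' @param mafRange MAF range.
#' @param maf optional explicit MAF vector (overrides `mafRange`).
#' @return n x m numeric matrix of 0/1/2 counts with attribute `maf`.
#' @export
drawGenotypes <- function(m, n, mafRange = c(0.05, 0.5), maf = NULL) {
  stopifnot(m >= 1, n >= 1)
  if (is.null(maf)) maf <- runif(m, mafRange[1], mafRange[2])
  G <- .drawGenotypesCpp(as.integer(n), as.integer(m), as.numeric(maf))
  attr(G, "maf") <- maf
  G
}

## Standardize genotype columns to mean 0, variance 1 (sample moments).
standardizeColumns <- function(G) {
  n <- nrow(G)
  cm <- colMeans(G)
  cv <- (colSums(G * G) - n * cm^2) / (n - 1)
  if (any(cv <= 0)) stop("monomorphic genotype column")
  t((t(G) - cm) / sqrt(cv))
}

sampleVar <- function(v) sum((v - mean(v))^2) / (length(v) - 1)

## Pleiotropy effect vectors on randomly chosen disjoint UHP/CHP subsets.
## `direction` is the per-SNP quantity CHP effects anti-correlate with.
drawPleiotropy <- function(config, direction) {
  m <- config$m
  gammaU <- gammaC <- numeric(m)
  nU <- round(config$uhpFraction * m)
  nC <- round(config$chpFraction * m)
  idx <- sample.int(m, nU + nC)
  sdGamma <- config$pleioRatio * sqrt(config$h2 / m)
  if (nU > 0)
    gammaU[idx[seq_len(nU)]] <- rnorm(nU, 0, sdGamma)
  if (nC > 0) {
    iC <- idx[nU + seq_len(nC)]
    dirSd <- sqrt(mean(direction^2))
    d <- if (dirSd > 0) direction[iC] / dirSd else rnorm(nC)
    rho <- config$chpCorr
    gammaC[iC] <- sdGamma * (rho * d + sqrt(1 - rho^2) * rnorm(nC))
  }
  list(gammaU = gammaU, gammaC = gammaC,
       uhpIdx = if (nU) sort(idx[seq_len(nU)]) else integer(),
       chpIdx = if (nC) sort(idx[nU + seq_len(nC)]) else integer())
}

## Shared scaffolding: genotype pool sized for the configured overlap,
## standardized columns, and exact per-exposure heritability scaling.
initCohort <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  nOv <- round(config$overlapFraction * n)
  nTotal <- 2L * n - nOv
  G <- drawGenotypes(config$m, nTotal, config$mafRange)
  list(G = G, Gs = standardizeColumns(G), n = n, nTotal = nTotal)
}

## Rescale an effect vector so the realized genetic variance is exactly h2.
scaleToH2 <- function(beta, Gs, h2) {
  s <- as.numeric(Gs %*% beta)
  beta * sqrt(h2 / sampleVar(s))
}

#' Simulate the one-exposure cohort
#'
#' Individual-level generator for the univariable design: standardized
#' genotypes with per-SNP effects Uniform(-1, 1) rescaled so the
#' instruments explain exactly `h2` of the exposure variance, a shared
#' confounder U with variance `(1 - h2) * 0.15` entering both exposure and
#' outcome, optional UHP/CHP contamination, and outcome noise with variance
#' `1 - var(x * theta + G %*% gamma + U)` so the outcome variance budget
#' closes at exactly 1 and the standardized (z-scale) causal effect equals
#' `thetaTrue`.
#'
#' @param config a [simConfig()] with `p = 1`.
#' @return a `Cohort` list: genotype pool `G` (with `maf`), exposure matrix
#'   `x`, outcome `y`, genetic component `genetic`, sizes `n`/`nTotal`, the
#'   `config`, and `truth` (a `SimTruth` list with `beta`, `gammaU`,
#'   `gammaC`, `alphaTrue`, `confounderVar`, variance components and
#'   contamination indices).
#' @export
simulateUnivariable <- function(config) {
  stopifnot(inherits(config, "SimConfig"), config$p == 1L)
  env <- initCohort(config)
  beta <- scaleToH2(runif(config$m, -1, 1), env$Gs, config$h2)
  s <- as.numeric(env$Gs %*% beta)
  varU <- config$confounderVar
  varEx <- 1 - config$h2 - varU
  U <- rnorm(env$nTotal, 0, sqrt(varU))
  x <- s + U + rnorm(env$nTotal, 0, sqrt(varEx))
  pl <- drawPleiotropy(config, direction = beta)
  gamma <- pl$gammaU + pl$gammaC
  th <- config$thetaTrue
  sys <- x * th + as.numeric(env$Gs %*% gamma) + U
  varEy <- 1 - sampleVar(sys)
  if (varEy <= 0)
    stop("configuration error: infeasible variance budget (var(eps_y) <= 0)")
  y <- sys + rnorm(env$nTotal, 0, sqrt(varEy))
  truth <- list(beta = matrix(beta, ncol = 1), gammaU = pl$gammaU,
                gammaC = pl$gammaC,
                alphaTrue = beta * th + gamma,
                confounderVar = varU, varEx = varEx, varEy = varEy,
                sysVar = sampleVar(sys),
                uhpIdx = pl$uhpIdx, chpIdx = pl$chpIdx)
  structure(list(G = env$G, x = matrix(x, ncol = 1), y = y,
                 genetic = matrix(s, ncol = 1), n = env$n,
                 nTotal = env$nTotal, config = config, truth = truth),
            class = "Cohort")
}

#' Simulate the two-exposure cohort
#'
#' Individual-level generator for the multivariable design: per-SNP effect
#' pairs bivariate normal with correlation `betaCorr` (0.45), each column
#' rescaled so the instruments explain exactly `h2` per exposure; a shared
#' confounder with variance `(1 - h2) * (0.15/2)^2`; exposure noise terms
#' drawn jointly so the realized phenotypic correlation is exactly
#' `phenoCorr` (0.5); CHP effects built on the per-SNP mediated effect
#' \eqn{\beta_1\theta_1 + \beta_2\theta_2}; outcome noise variance
#' completing a unit outcome variance.
#'
#' @param config a [simConfig()] with `p = 2`.
#' @return a `Cohort` list; see [simulateUnivariable()].
#' @export
simulateMultivariable <- function(config) {
  stopifnot(inherits(config, "SimConfig"), config$p == 2L)
  env <- initCohort(config)
  m <- config$m
  z1 <- rnorm(m); z2 <- rnorm(m)
  b2raw <- config$betaCorr * z1 + sqrt(1 - config$betaCorr^2) * z2
  beta <- cbind(scaleToH2(z1, env$Gs, config$h2),
                scaleToH2(b2raw, env$Gs, config$h2))
  s <- env$Gs %*% beta
  varU <- config$confounderVar
  varEx <- 1 - config$h2 - varU
  covG <- sum((s[, 1] - mean(s[, 1])) * (s[, 2] - mean(s[, 2]))) / (env$nTotal - 1)
  covEps <- config$phenoCorr - covG - varU
  if (abs(covEps) >= varEx)
    stop("configuration error: requested phenotypic correlation infeasible")
  U <- rnorm(env$nTotal, 0, sqrt(varU))
  e1 <- rnorm(env$nTotal, 0, sqrt(varEx))
  rhoE <- covEps / varEx
  e2 <- rhoE * e1 + sqrt(varEx * (1 - rhoE^2)) * rnorm(env$nTotal)
  x <- cbind(s[, 1] + U + e1, s[, 2] + U + e2)
  pl <- drawPleiotropy(config, direction = as.numeric(beta %*% config$thetaTrue))
  gamma <- pl$gammaU + pl$gammaC
  sys <- as.numeric(x %*% config$thetaTrue) +
    as.numeric(env$Gs %*% gamma) + U
  varEy <- 1 - sampleVar(sys)
  if (varEy <= 0)
    stop("configuration error: infeasible variance budget (var(eps_y) <= 0)")
  y <- sys + rnorm(env$nTotal, 0, sqrt(varEy))
  truth <- list(beta = beta, gammaU = pl$gammaU, gammaC = pl$gammaC,
                alphaTrue = as.numeric(beta %*% config$thetaTrue) + gamma,
                confounderVar = varU, varEx = varEx, varEy = varEy,
                sysVar = sampleVar(sys),
                uhpIdx = pl$uhpIdx, chpIdx = pl$chpIdx)
  structure(list(G = env$G, x = x, y = y, genetic = s, n = env$n,
                 nTotal = env$nTotal, config = config, truth = truth),
            class = "Cohort")
}

#' @rdname simulateUnivariable
#' @export
simulateCohort <- function(config) {
  if (config$p == 1L) simulateUnivariable(config) else simulateMultivariable(config)
}

#' Realized generator calibration
#'
#' Sample diagnostics of a simulated cohort on the exposure-GWAS
#' individuals: per-exposure realized heritability (variance of the genetic
#' component over the exposure variance) and, for two exposures, their
#' phenotypic correlation.
#'
#' @param cohort a `Cohort` from [simulateCohort()].
#' @return list with `h2` (length p) and `phenoCorr` (NA when p = 1).
#' @export
cohortCalibration <- function(cohort) {
  rows <- seq_len(cohort$n)
  h2 <- vapply(seq_len(ncol(cohort$x)), function(k)
    sampleVar(cohort$genetic[rows, k]) / sampleVar(cohort$x[rows, k]),
    numeric(1))
  rho <- if (ncol(cohort$x) == 2L) cor(cohort$x[rows, 1], cohort$x[rows, 2])
         else NA_real_
  list(h2 = h2, phenoCorr = rho)
}

#' Per-SNP GWAS regressions on a simulated cohort
#'
#' Runs simple linear regressions of each exposure and the outcome on every
#' instrument separately, mimicking the GWAS step: exposures on individuals
#' `1..n`, the outcome on a sample of size n sharing
#' `round(overlapFraction * n)` individuals with the exposure sample and
#' completed with fresh individuals from the same generative law. Estimates
#' are standardized to the z scale. Additionally simulates `nullM` matched
#' null SNPs (zero effects, same cohorts) and regresses them identically to
#' produce the [NullPanel-class] for [estimateErrorCovariance()]; those
#' variants are null by construction, so no insignificance filter is
#' applied.
#'
#' @param cohort a `Cohort`.
#' @param overlapFraction overlap fraction; defaults to the cohort
#'   configuration's value (a smaller value than configured cannot be
#'   honoured, since the pool holds too few fresh individuals).
#' @param nullM number of null SNPs (default from the configuration).
#' @return list with `panel` (a [SummaryPanel-class]) and `nullPanel` (a
#'   [NullPanel-class], NULL when `nullM = 0`).
#' @export
gwasFromCohort <- function(cohort, overlapFraction = NULL, nullM = NULL) {
  stopifnot(inherits(cohort, "Cohort"))
  config <- cohort$config
  f <- if (is.null(overlapFraction)) config$overlapFraction else overlapFraction
  if (f < 0 || f > 1) stop("validation error: overlapFraction must be in [0, 1]")
  if (is.null(nullM)) nullM <- config$nullM
  n <- cohort$n
  nOv <- round(f * n)
  rowsExp <- seq_len(n)
  nFreshNeeded <- n - nOv
  if (n + nFreshNeeded > cohort$nTotal)
    stop(sprintf(
      "cohort pool holds %d individuals; overlap %.2f needs %d (regenerate with a smaller configured overlap)",
      cohort$nTotal, f, n + nFreshNeeded))
  rowsOut <- c(seq_len(nOv), n + seq_len(nFreshNeeded))
  p <- config$p
  regress <- function(G, rows, yvec) .snpRegressionCpp(G, as.integer(rows), yvec)
  zMat <- function(G, rowsByPheno) {
    Z <- matrix(NA_real_, ncol(G), p + 1L)
    SE <- matrix(NA_real_, ncol(G), p + 1L)
    for (k in seq_len(p)) {
      r <- regress(G, rowsExp, cohort$x[, k])
      Z[, k] <- r$beta / r$se; SE[, k] <- r$se
    }
    r <- regress(G, rowsOut, cohort$y)
    Z[, p + 1L] <- r$beta / r$se; SE[, p + 1L] <- r$se
    list(Z = Z, SE = SE)
  }
  iv <- zMat(cohort$G)
  panel <- SummaryPanel(
    snpId = sprintf("iv%d", seq_len(config$m)),
    Bhat = iv$Z[, seq_len(p), drop = FALSE],
    alphaHat = iv$Z[, p + 1L],
    exposureNames = paste0("x", seq_len(p)),
    seB = iv$SE[, seq_len(p), drop = FALSE],
    seAlpha = iv$SE[, p + 1L],
    nExposure = rep(n, p), nOutcome = n)
  nullPanel <- NULL
  if (nullM > 0) {
    Y <- cbind(cohort$x, cohort$y)
    rowsList <- c(rep(list(as.integer(rowsExp)), p), list(as.integer(rowsOut)))
    Z <- .nullGwasCpp(Y, rowsList, as.integer(nullM),
                      config$mafRange[1], config$mafRange[2])
    nullPanel <- new("NullPanel", Znull = Z, pThreshold = NA_real_)
  }
  list(panel = panel, nullPanel = nullPanel)
}
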