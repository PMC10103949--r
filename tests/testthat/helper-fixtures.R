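# Shared fixtures, built in code at test time.

# Write a small GWAS summary TSV with default column names.
writeGwasTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t")
  path
}

# A random well-conditioned panel with known structure.
randomPanel <- function(m = 30, p = 2, seed = 1) {
  set.seed(seed)
  B <- matrix(rnorm(m * p, sd = 3), m, p)
  theta <- seq_len(p) / 2
  a <- as.numeric(B %*% theta) + rnorm(m, sd = 0.5)
  SummaryPanel(snpId = sprintf("s%d", seq_len(m)), Bhat = B, alphaHat = a,
               exposureNames = paste0("x", seq_len(p)))
}

# Bias terms with specified blocks (p exposures).
biasFrom <- function(Sbb, sba, saa) {
  Sbb <- as.matrix(Sbb)
  p <- nrow(Sbb)
  S <- matrix(0, p + 1, p + 1)
  S[seq_len(p), seq_len(p)] <- Sbb
  S[seq_len(p), p + 1] <- sba
  S[p + 1, seq_len(p)] <- sba
  S[p + 1, p + 1] <- saa
  new("BiasTerms", SigmaFull = S, M = NA_integer_)
}

# Small simulated cohort + GWAS, cheap enough for unit tests.
quickSim <- function(m = 50, n = 3000, p = 1, theta = rep(0.5, p),
                     overlap = 1, uhp = 0, chp = 0, nullM = 2000,
                     seed = 1) {
  cfg <- simConfig(m = m, n = n, p = p, thetaTrue = theta,
                   overlapFraction = overlap, uhpFraction = uhp,
                   chpFraction = chp, nullM = nullM, seed = seed)
  cohort <- simulateCohort(cfg)
  gw <- gwasFromCohort(cohort)
  list(cfg = cfg, cohort = cohort, panel = gw$panel,
       nullPanel = gw$nullPanel)
}

# Independent evaluation of the bias-corrected estimating equation,
# written from the definition (not via the package's beeScore).
directScore <- function(panel, bias, theta, mask = NULL) {
  B <- Bhat(panel)
  a <- unname(alphaHat(panel))
  if (!is.null(mask)) { B <- B[mask, , drop = FALSE]; a <- a[mask] }
  m <- nrow(B)
  p <- ncol(B)
  S <- sigmaFull(bias)
  Sbb <- S[seq_len(p), seq_len(p), drop = FALSE]
  sba <- S[seq_len(p), p + 1]
  as.numeric(-t(B) %*% (a - B %*% theta) - m * (Sbb %*% theta - sba))
}

# A genome-wide null panel (true effects all zero) regressed on a cohort,
# with synthetic positions spaced so every SNP is its own 1-Mb window.
nullGenomePanel <- function(cohort, nSnps, spacingBp = 2e6) {
  p <- ncol(cohort$x)
  rows <- list()
  for (k in seq_len(p)) rows[[k]] <- seq_len(cohort$n)
  rows[[p + 1]] <- seq_len(cohort$n)  # full overlap with exposure sample
  Z <- mrbce:::.nullGwasCpp(cbind(cohort$x, cohort$y),
                            lapply(rows, as.integer), as.integer(nSnps),
                            0.05, 0.5)
  SummaryPanel(snpId = sprintf("g%d", seq_len(nSnps)),
               Bhat = Z[, seq_len(p), drop = FALSE],
               alphaHat = Z[, p + 1],
               exposureNames = paste0("x", seq_len(p)),
               chr = rep("1", nSnps), pos = seq_len(nSnps) * spacingBp)
}
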