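mkFit <- function(theta, covTheta, p = length(theta)) {
  mrbce:::makeCausalFit(theta, as.matrix(covTheta), "bee",
                        rep(TRUE, p + 1), paste0("x", seq_len(p)))
}

test_that("the pleiotropy statistic matches scalar arithmetic", {
  # residual zero: statistic 0, p-value 1
  panel0 <- SummaryPanel(snpId = c("a", "b"), Bhat = matrix(c(1, 2)),
                         alphaHat = c(0.5, 1))
  fit0 <- mkFit(0.5, matrix(0.04))
  bias0 <- biasFrom(matrix(0.25), 0.1, 1)
  pl0 <- pleioTest(panel0, fit0, bias0)
  expect_equal(pl0$sPleio[1], (0.5 - 0.5)^2 / (1 + 0.0625 + 0.04 - 0.1))
  expect_equal(pl0$pPleio[1], 1)

  # hand-computed value: alpha = 2, beta = 1, theta = 0.5
  panel <- SummaryPanel(snpId = c("a", "b"), Bhat = matrix(c(1, 1)),
                        alphaHat = c(2, 2))
  pl <- pleioTest(panel, fit0, bias0)
  expect_equal(pl$sPleio[1], 2.25 / 1.0025, tolerance = 1e-12)
  expect_equal(pl$pPleio[1], pchisq(2.25 / 1.0025, 1, lower.tail = FALSE))
})

test_that("a nonpositive pleiotropy variance is a loud error", {
  panel <- SummaryPanel(snpId = c("a", "b"), Bhat = matrix(c(1, 2)),
                        alphaHat = c(1, 1))
  fit <- mkFit(1, matrix(0))
  # boundary-degenerate error covariance: denominator 1 + 1 - 2 = 0
  bias <- biasFrom(matrix(1), 1, 1)
  expect_error(pleioTest(panel, fit, bias), "nonpositive")
})

test_that("a planted outlier is removed in one iteration and truth recovered", {
  set.seed(21)
  qs <- quickSim(m = 60, n = 4000, nullM = 3000, seed = 22)
  bt <- estimateErrorCovariance(qs$nullPanel)
  panel <- qs$panel
  a <- unname(alphaHat(panel))
  a[13] <- a[13] + 10 * max(abs(a[-13]))  # gamma far above the alpha scale
  spiked <- SummaryPanel(snpId = snpId(panel), Bhat = unname(Bhat(panel)),
                         alphaHat = a)
  fit <- fitBEEIterative(spiked, bt)
  expect_false(ivMask(fit)[13])
  expect_true(fit@converged)
  expect_lte(fit@nIter, 2L)  # removed at the first pass
  expect_false(fit@trace$theta1[1] == unname(theta(fit)[1]))
  expect_lt(abs(unname(theta(fit)[1]) - 0.5), 4 * fit@se[1])
})

test_that("iterative removal is idempotent at convergence", {
  set.seed(23)
  qs <- quickSim(m = 60, n = 4000, uhp = 0.1, chp = 0.1, nullM = 3000,
                 seed = 24)
  bt <- estimateErrorCovariance(qs$nullPanel)
  fit <- fitBEEIterative(qs$panel, bt)
  expect_true(fit@converged)
  # one more sweep by hand: the implied mask must equal the converged mask
  refit <- fitBEE(qs$panel, bt, ivMask = ivMask(fit))
  pl <- pleioTest(qs$panel, refit, bt, tau = 0.05 / nIV(qs$panel))
  expect_identical(pl$pPleio >= 0.05 / nIV(qs$panel), ivMask(fit))
})

test_that("under the clean design essentially no instruments are flagged", {
  set.seed(25)
  flagged <- vapply(1:5, function(i) {
    qs <- quickSim(m = 50, n = 3000, nullM = 3000, seed = NULL)
    bt <- estimateErrorCovariance(qs$nullPanel)
    sum(!ivMask(fitBEEIterative(qs$panel, bt)))
  }, numeric(1))
  expect_lte(mean(flagged), 1)  # Bonferroni null expectation << 1 per run
})

test_that("the statistic grows monotonically with planted pleiotropy", {
  qs <- quickSim(m = 40, n = 3000, nullM = 3000, seed = 26)
  bt <- estimateErrorCovariance(qs$nullPanel)
  fit <- fitBEE(qs$panel, bt)
  a <- unname(alphaHat(qs$panel))
  s <- vapply(c(0, 1, 2, 4, 8), function(g) {
    a2 <- a; a2[5] <- a[5] + g
    p2 <- SummaryPanel(snpId = snpId(qs$panel), Bhat = unname(Bhat(qs$panel)),
                       alphaHat = a2)
    pleioTest(p2, fit, bt)$sPleio[5]
  }, numeric(1))
  expect_true(all(diff(s) > 0))
})

test_that("retained sets never shrink below identifiability", {
  panel <- randomPanel(m = 8, p = 2, seed = 31)
  a <- unname(alphaHat(panel)) + rnorm(8, sd = 60)  # everything pleiotropic
  wild <- SummaryPanel(snpId = snpId(panel), Bhat = unname(Bhat(panel)),
                       alphaHat = a)
  expect_error(fitBEEIterative(wild, zeroBiasTerms(2), tau = 0.9),
               "algorithm error")
})

test_that("locus classification covers every threshold octant", {
  thr <- 5e-8
  lo <- 1e-10; hi <- 0.5
  expect_identical(classifyAssociation(lo, hi, lo), "direct")
  expect_identical(classifyAssociation(lo, lo, hi), "exposure_mediated")
  expect_identical(classifyAssociation(lo, lo, lo), "pleiotropic_shared")
  expect_identical(classifyAssociation(hi, lo, lo), "novel_pleiotropic")
  expect_identical(classifyAssociation(hi, hi, lo), "novel_pleiotropic")
  expect_identical(classifyAssociation(lo, hi, hi), "null")
  expect_identical(classifyAssociation(hi, lo, hi), "null")
  expect_identical(classifyAssociation(hi, hi, hi), "null")
  # labels partition the space
  grid <- expand.grid(po = c(lo, hi), pe = c(lo, hi), pp = c(lo, hi))
  labs <- classifyAssociation(grid$po, grid$pe, grid$pp)
  expect_true(all(labs %in% c("direct", "exposure_mediated",
                              "pleiotropic_shared", "novel_pleiotropic",
                              "null")))
  expect_error(classifyAssociation(0, 0.5, 0.5), "pOutcome")
})

test_that("genome scan recovers planted pleiotropic loci exactly", {
  set.seed(33)
  qs <- quickSim(m = 80, n = 4000, nullM = 10000, seed = 34)
  bt <- estimateErrorCovariance(qs$nullPanel)
  fit <- fitBEEIterative(qs$panel, bt)
  genome <- nullGenomePanel(qs$cohort, 3000)
  a <- unname(alphaHat(genome))
  planted <- c(100, 700, 1300, 1900, 2500)
  a[planted] <- a[planted] + 12  # far beyond genome-wide significance
  spiked <- SummaryPanel(snpId = snpId(genome), Bhat = unname(Bhat(genome)),
                         alphaHat = a, chr = rep("1", 3000),
                         pos = seq_len(3000) * 2e6)
  scan <- genomeScan(spiked, fit, bt)
  expect_equal(nrow(locusTable(scan)), 5L)
  expect_setequal(locusTable(scan)$leadSnp, sprintf("g%d", planted))
  # with no exposure signal and no outcome-GWAS strength requirement these
  # planted signals are novel or direct depending on the outcome z alone
  expect_true(all(locusTable(scan)$class %in% c("direct", "novel_pleiotropic")))

  # nearby significant SNPs collapse into one window
  a2 <- unname(alphaHat(genome))
  a2[100] <- a2[100] + 12
  pos2 <- seq_len(3000) * 2e6
  pos2[101] <- pos2[100] + 2e5  # within 1 Mb of the lead
  a2[101] <- a2[101] + 8
  spiked2 <- SummaryPanel(snpId = snpId(genome), Bhat = unname(Bhat(genome)),
                          alphaHat = a2, chr = rep("1", 3000), pos = pos2)
  expect_equal(nrow(locusTable(genomeScan(spiked2, fit, bt))), 1L)

  # no positions: per-SNP results survive, loci are dropped with a warning
  noPos <- SummaryPanel(snpId = snpId(genome), Bhat = unname(Bhat(genome)),
                        alphaHat = a)
  expect_warning(scan2 <- genomeScan(noPos, fit, bt), "locus table omitted")
  expect_equal(nrow(scan2@results), 3000L)
  expect_equal(nrow(locusTable(scan2)), 0L)
})

test_that("the genomic-control factor is the median over the chi-square median", {
  set.seed(35)
  qs <- quickSim(m = 50, n = 3000, nullM = 5000, seed = 36)
  bt <- estimateErrorCovariance(qs$nullPanel)
  fit <- fitBEE(qs$panel, bt)
  genome <- nullGenomePanel(qs$cohort, 2000)
  scan <- genomeScan(genome, fit, bt)
  expect_equal(lambdaGC(scan), median(scan@results$sPleio) / qchisq(0.5, 1),
               tolerance = 1e-10)
  # scale equivariance of the median ratio
  expect_equal(median(2 * scan@results$sPleio) / qchisq(0.5, 1),
               2 * lambdaGC(scan), tolerance = 1e-10)
})

test_that("with theta fixed at zero the scan reduces to the outcome GWAS", {
  set.seed(37)
  qs <- quickSim(m = 50, n = 3000, theta = 0, nullM = 5000, seed = 38)
  bt <- estimateErrorCovariance(qs$nullPanel)
  genome <- nullGenomePanel(qs$cohort, 500)
  fit0 <- mkFit(0, matrix(0))
  pl <- pleioTest(genome, fit0, bt)
  expect_equal(pl$sPleio, unname(alphaHat(genome))^2 / sigmaAA(bt),
               tolerance = 1e-12)
})
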