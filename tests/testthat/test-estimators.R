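test_that("IVW reproduces exact proportionality and a least-squares oracle", {
  p1 <- SummaryPanel(snpId = c("a", "b", "c"), Bhat = matrix(c(1, 2, 3)),
                     alphaHat = c(2, 4, 6))
  expect_equal(unname(theta(fitIVW(p1))), 2, tolerance = 1e-12)

  panel <- randomPanel(m = 10, p = 2, seed = 7)
  fit <- fitIVW(panel)
  oracle <- qr.solve(unname(Bhat(panel)), unname(alphaHat(panel)))
  expect_equal(unname(theta(fit)), unname(oracle), tolerance = 1e-10)
  expect_true(all(ivMask(fit)))
})

test_that("exact noise-free panels return the generating effects", {
  set.seed(11)
  B <- matrix(rnorm(40), 20, 2)
  th <- c(0.3, -0.7)
  panel <- SummaryPanel(snpId = sprintf("s%d", 1:20), Bhat = B,
                        alphaHat = as.numeric(B %*% th))
  expect_equal(unname(theta(fitIVW(panel))), th, tolerance = 1e-10)
  # degenerate perfect fit with zero bias terms: zero covariance
  expect_equal(max(abs(covTheta(fitIVW(panel)))), 0, tolerance = 1e-20)
})

test_that("the closed-form corrected estimate matches hand arithmetic", {
  # 50 IVs with B'B = 100, B'alpha = 25; Sigma_bb = 1, sigma_ba = 0
  m <- 50
  b <- rep(sqrt(2), m)
  a <- rep(25 / (m * sqrt(2)), m)
  panel <- SummaryPanel(snpId = sprintf("s%d", 1:m), Bhat = matrix(b),
                        alphaHat = a)
  bias <- biasFrom(matrix(1), 0, 1)
  expect_equal(unname(theta(fitBEE(panel, bias))), 25 / (100 - 50),
               tolerance = 1e-12)
})

test_that("with zero bias terms the corrected estimator collapses to IVW", {
  for (seed in 1:5) {
    panel <- randomPanel(m = 40, p = 2, seed = seed)
    z <- zeroBiasTerms(2)
    expect_equal(unname(theta(fitBEE(panel, z))),
                 unname(theta(fitIVW(panel))), tolerance = 1e-12)
    expect_equal(unname(covTheta(fitBEE(panel, z))),
                 unname(covTheta(fitIVW(panel))), tolerance = 1e-12)
  }
})

test_that("the fitted estimate is a root of the estimating equation", {
  for (seed in 1:6) {
    panel <- randomPanel(m = 60, p = 2, seed = seed)
    bias <- biasFrom(matrix(c(1, 0.3, 0.3, 1), 2), c(0.2, -0.1), 1)
    fit <- fitBEE(panel, bias)
    expect_lt(max(abs(directScore(panel, bias, unname(theta(fit))))), 1e-8)
  }
})

test_that("estimates are equivariant to outcome negation and exposure order", {
  panel <- randomPanel(m = 50, p = 2, seed = 3)
  bias <- biasFrom(matrix(c(1, 0.2, 0.2, 1), 2), c(0.1, 0.3), 1)
  fit <- fitBEE(panel, bias)
  neg <- SummaryPanel(snpId = snpId(panel), Bhat = unname(Bhat(panel)),
                      alphaHat = -unname(alphaHat(panel)),
                      exposureNames = exposureNames(panel))
  negBias <- biasFrom(sigmaBB(bias), -sigmaBA(bias), sigmaAA(bias))
  expect_equal(unname(theta(fitBEE(neg, negBias))), -unname(theta(fit)),
               tolerance = 1e-10)
  perm <- SummaryPanel(snpId = snpId(panel),
                       Bhat = unname(Bhat(panel))[, 2:1],
                       alphaHat = unname(alphaHat(panel)),
                       exposureNames = exposureNames(panel)[2:1])
  permBias <- biasFrom(sigmaBB(bias)[2:1, 2:1], sigmaBA(bias)[2:1],
                       sigmaAA(bias))
  expect_equal(unname(theta(fitBEE(perm, permBias))),
               unname(theta(fit))[2:1], tolerance = 1e-10)
})

test_that("sandwich covariance matches a by-hand evaluation on two IVs", {
  B <- matrix(c(2, 1))
  a <- c(1.5, 0.4)
  panel <- SummaryPanel(snpId = c("a", "b"), Bhat = B, alphaHat = a)
  bias <- biasFrom(matrix(0.5), 0.2, 1)
  th <- 0.6
  m <- 2
  Fhat <- sum(B^2) / m - 0.5
  Sj <- -(a - B[, 1] * th) * B[, 1] - 0.5 * th + 0.2
  Vhat <- sum(Sj^2) / m
  byHand <- Vhat / Fhat^2 / m
  expect_equal(unname(sandwichCovariance(panel, bias, th))[1, 1], byHand,
               tolerance = 1e-12)
})

test_that("debiased IVW equals the full correction only without overlap", {
  panel <- randomPanel(m = 60, p = 2, seed = 9)
  noOverlap <- biasFrom(matrix(c(1, 0.3, 0.3, 1), 2), c(0, 0), 1)
  expect_equal(unname(theta(fitDIVW(panel, noOverlap))),
               unname(theta(fitBEE(panel, noOverlap))), tolerance = 1e-12)
  withOverlap <- biasFrom(matrix(c(1, 0.3, 0.3, 1), 2), c(0.4, 0.2), 1)
  expect_gt(max(abs(theta(fitDIVW(panel, withOverlap)) -
                    theta(fitBEE(panel, withOverlap)))), 1e-4)
  expect_identical(fitDIVW(panel, withOverlap)@method, "divw")
})

test_that("overlap pulls the uncorrected estimators toward the confounding", {
  # full overlap, positive confounding, no pleiotropy: dIVW stays biased
  # upward-from-attenuation balance while the full correction is unbiased
  reps <- 40
  ths <- matrix(NA_real_, reps, 2)
  set.seed(77)
  for (r in seq_len(reps)) {
    qs <- quickSim(m = 50, n = 3000, overlap = 1, nullM = 3000, seed = NULL)
    bt <- estimateErrorCovariance(qs$nullPanel)
    ths[r, ] <- c(unname(theta(fitDIVW(qs$panel, bt))[1]),
                  unname(theta(fitBEE(qs$panel, bt))[1]))
  }
  seMean <- apply(ths, 2, sd) / sqrt(reps)
  # confounder and causal effect are positive, so cov(u, v) > 0 pulls the
  # overlap-blind correction upward
  expect_gt(mean(ths[, 1]) - 0.5, 3 * seMean[1])
  expect_lt(abs(mean(ths[, 2]) - 0.5), 3 * seMean[2])
})

test_that("predicted IVW bias reproduces the scalar hand calculation", {
  # cov(beta) = 1, Sigma_bb = 1 => B'B/m = 2; theta = 0.5, sigma_ba = 0
  m <- 50
  panel <- SummaryPanel(snpId = sprintf("s%d", 1:m),
                        Bhat = matrix(rep(sqrt(2), m)),
                        alphaHat = rnorm(m))
  bias <- biasFrom(matrix(1), 0, 1)
  expect_equal(predictIVWBias(panel, bias, 0.5), -0.25, tolerance = 1e-12)
  expect_equal(predictIVWBias(panel, zeroBiasTerms(1), 0.5, betaGammaCov = 0),
               0, tolerance = 1e-12)
})

test_that("collinear exposures and weak-instrument regimes fail loudly", {
  set.seed(5)
  b <- rnorm(30, sd = 3)
  panel <- SummaryPanel(snpId = sprintf("s%d", 1:30),
                        Bhat = cbind(b, b * (1 + 1e-13)),
                        alphaHat = rnorm(30),
                        exposureNames = c("sbp", "dbp"))
  expect_error(fitIVW(panel), "collinear.*(sbp.*dbp|dbp.*sbp)")
  weak <- SummaryPanel(snpId = sprintf("s%d", 1:30),
                       Bhat = matrix(rnorm(30, sd = 0.2)),
                       alphaHat = rnorm(30))
  expect_error(fitBEE(weak, biasFrom(matrix(5), 0, 1)), "weak-instrument")
  expect_error(fitBEE(randomPanel(30, 1), biasFrom(diag(2), c(0, 0), 1)),
               "bias terms are for 2 exposures")
})

test_that("fit summaries expose odds ratios and serialization round-trips", {
  panel <- randomPanel(m = 40, p = 2, seed = 13)
  fit <- fitBEE(panel, zeroBiasTerms(2))
  sm <- summary(fit)
  expect_equal(sm$or, exp(sm$theta))
  prefix <- tempfile()
  writeFit(fit, prefix)
  back <- readFit(paste0(prefix, ".json"))
  expect_equal(theta(back), theta(fit), tolerance = 1e-12)
  expect_equal(covTheta(back), covTheta(fit), tolerance = 1e-12)
  expect_identical(ivMask(back), ivMask(fit))
  broken <- tempfile(fileext = ".json")
  jsonlite::write_json(list(theta = 1), broken, auto_unbox = TRUE)
  expect_error(readFit(broken), "schema mismatch")
})
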