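test_that("mixture construction validates and centers", {
  m <- buildMixture(1, list(c(0, 0)), diag(2))
  expect_s4_class(m, "GaussianMixture")

  # symmetric two-component means are centered for any separation
  m <- buildMixture(c(0.5, 0.5), list(c(3, 0), c(-3, 0)), diag(2),
                    enforceCentering = FALSE)
  expect_s4_class(m, "GaussianMixture")

  # enforceCentering translates an off-center configuration
  m <- buildMixture(c(0.3, 0.7), list(c(1, 0), c(0, 0)), diag(2))
  wmean <- 0.3 * m@mu[[1]] + 0.7 * m@mu[[2]]
  expect_equal(wmean, c(0, 0))
  expect_equal(m@mu[[1]] - m@mu[[2]], c(1, 0))  # relative geometry kept

  expect_error(buildMixture(c(0.5, 0.4), list(0, 0), matrix(1)), "sum to one")
  expect_error(buildMixture(1, list(c(0, 0)), matrix(c(1, 2, 2, 1), 2)),
               "not PD")
})

test_that("mixture sampling matches its generative law", {
  m <- buildMixture(c(1, 0), list(c(0, 0), c(-5, -5)), diag(2),
                    enforceCentering = FALSE)
  Y <- sampleMixture(m, 50, seed = 1)
  expect_true(all(attr(Y, "component") == 1))

  m <- buildMixture(c(0.3, 0.7), list(c(4, 0), c(0, 0)), diag(2))
  Y <- sampleMixture(m, 10000, seed = 2)
  z <- attr(Y, "component")
  expect_lt(abs(mean(z == 1) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
  # population mean is zero under the centering convention
  seMean <- sqrt(diag(stats::cov(Y)) / 10000)
  expect_true(all(abs(colMeans(Y)) < 3 * seMean + 3 * 0.3 * 4 / sqrt(10000)))

  expect_identical(sampleMixture(m, 20, seed = 3), sampleMixture(m, 20, seed = 3))
})

test_that("Monte-Carlo mixture entropy recovers known limits", {
  Sigma <- randomPD(3, seed = 90)
  closed <- gaussianEntropy(Sigma, "differential")

  # single component: closed form
  m1 <- buildMixture(1, list(rep(0, 3)), Sigma)
  mc <- mixtureEntropyMC(m1, M = 20000, seed = 91)
  expect_lt(abs(mc$H - closed), 3 * mc$se)

  # two identical components: same density, same entropy
  m2 <- buildMixture(c(0.5, 0.5), list(rep(0, 3), rep(0, 3)), Sigma)
  mc2 <- mixtureEntropyMC(m2, M = 20000, seed = 92)
  expect_lt(abs(mc2$H - closed), 3 * mc2$se)

  # well-separated 1-D components: H -> 1/2 log(2 pi e) + log 2
  msep <- buildMixture(c(0.5, 0.5), list(-20, 20), matrix(1))
  mcs <- mixtureEntropyMC(msep, M = 20000, seed = 93)
  expect_lt(abs(mcs$H - (0.5 * log(2 * pi * exp(1)) + log(2))), 3 * mcs$se)

  expect_error(mixtureEntropyMC(m1, M = 10), "at least 1000")
})

test_that("log-sum-exp density agrees with the naive density when safe", {
  m <- buildMixture(c(0.4, 0.6), list(c(1, 0), c(0, 0)), diag(2))
  Y <- sampleMixture(m, 50, seed = 94)
  naive <- log(
    0.4 * exp(netEntropy:::logDmvnorm(Y, m@mu[[1]], m@Sigma[[1]])) +
    0.6 * exp(netEntropy:::logDmvnorm(Y, m@mu[[2]], m@Sigma[[2]])))
  expect_equal(netEntropy:::mixtureLogDensity(m, Y), naive, tolerance = 1e-12)
})

test_that("component-entropy mean is the closed-form weighted average", {
  m <- buildMixture(1, list(c(0, 0)), diag(2))
  expect_equal(componentEntropyMean(m), log(2 * pi * exp(1)))

  # equal covariances: value independent of the means
  S <- randomPD(4, seed = 95)
  mA <- buildMixture(c(0.5, 0.5), list(rep(0, 4), rep(0, 4)), S)
  mB <- buildMixture(c(0.5, 0.5), list(rep(2, 4), rep(-2, 4)), S)
  expect_equal(componentEntropyMean(mA), componentEntropyMean(mB))

  # zero-weight components are ignored
  mC <- buildMixture(c(1, 0), list(rep(0, 2), rep(9, 2)),
                     list(diag(2), 100 * diag(2)), enforceCentering = FALSE)
  expect_equal(componentEntropyMean(mC), log(2 * pi * exp(1)))
})

test_that("mixing never loses entropy relative to the component mean", {
  # equality at a single component
  m1 <- buildMixture(1, list(rep(0, 2)), randomPD(2, seed = 96))
  r1 <- checkProposition1(m1, M = 20000, seed = 97)
  expect_true(r1$pass)
  expect_lt(abs(r1$gap), 3 * r1$se)

  # shared covariance, separated means: strict surplus
  s1 <- scenarioMixture(1, K = 2, p = 2, effect = 4, seed = 98)
  r <- checkProposition1(s1, M = 20000, seed = 99)
  expect_gt(r$gap, 3 * r$se)

  # inflated components: mixture entropy above the reference Gaussian
  s2 <- scenarioMixture(2, K = 3, p = 3, effect = 1, seed = 100)
  expect_true(all(sapply(s2$model@Sigma, det) >= det(s2$refSigma) - 1e-12))
  mc <- mixtureEntropyMC(s2$model, M = 20000, seed = 101)
  expect_gt(mc$H, gaussianEntropy(s2$refSigma, "differential") - 3 * mc$se)

  # random mixtures: inequality within Monte-Carlo error
  for (s in 1:10) {
    r <- checkProposition1(randomMixture(110 + s), M = 10000, seed = 200 + s)
    expect_true(r$pass)
  }

  # scenario 1 with zero effect collapses to identical components
  s0 <- scenarioMixture(1, K = 2, p = 2, effect = 0, seed = 102)
  expect_equal(s0@mu[[1]], s0@mu[[2]])
})
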