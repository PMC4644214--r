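test_that("block scaling reduces to the base and block-diagonal limits", {
  Om <- randomOmega(6, seed = 1)
  blocks <- list(1:2, 3:4, 5:6)
  bp1 <- buildBlockOmega(Om, blocks, rep(1, 3))
  expect_equal(bp1@OmegaGamma, Om)

  bp0 <- buildBlockOmega(Om, blocks, rep(0, 3))
  expect_true(all(bp0@OmegaGamma[1:2, 3:6] == 0))
  expect_equal(bp0@OmegaGamma[3:4, 3:4], Om[3:4, 3:4])

  # two blocks: any gamma in [0, 1] keeps positive definiteness
  for (s in 1:20) {
    Om2 <- randomOmega(5, seed = 100 + s)
    g <- netEntropy:::withSeed(200 + s, runif(1))
    expect_s4_class(buildBlockOmega(Om2, list(1:2, 3:5), g),
                    "BlockPartialCorrelation")
  }
})

test_that("entropy under weakening: closed forms and monotonicity", {
  # 2 x 2 closed form log(1 - gamma^2 rho^2), unit variances
  rho <- 0.6
  Om <- matrix(c(1, rho, rho, 1), 2)
  for (g in seq(0, 1, by = 0.25)) {
    expect_equal(entropyUnderWeakening(Om, list(1, 2), g),
                 log(1 - g^2 * rho^2), tolerance = 1e-12)
  }

  # gamma = 0: independence, entropy is the sum of log marginal variances
  Om3 <- randomOmega(4, seed = 10)
  mv <- c(1, 2, 0.5, 3)
  expect_equal(entropyUnderWeakening(Om3, as.list(1:4), rep(0, 6), mv),
               sum(log(mv)), tolerance = 1e-12)

  # entropy is non-decreasing as gamma decreases along a grid
  H <- sapply(seq(1, 0, by = -0.1), function(g)
    entropyUnderWeakening(Om3, list(1:2, 3:4), g))
  expect_true(all(diff(H) >= -1e-10))

  # the built covariance carries exactly the prescribed partial correlations
  bp <- buildBlockOmega(Om3, list(1:2, 3:4), 0.6)
  C <- stats::cov2cor(solve(bp@OmegaGamma))
  Sigma <- diag(sqrt(mv[1:4])) %*% C %*% diag(sqrt(mv[1:4]))
  expect_equal(standardizeConcentration(solve(Sigma)), bp@OmegaGamma,
               tolerance = 1e-8)
  expect_equal(gaussianEntropy(Sigma),
               entropyUnderWeakening(Om3, list(1:2, 3:4), 0.6, mv),
               tolerance = 1e-10)
})

test_that("knockout entropy: hand inversion, monotone bound, literal variant", {
  # isolated node: knockout changes nothing, either way
  Sigma <- diag(c(1, 2, 3))
  expect_equal(knockoutEntropy(Sigma, 2), gaussianEntropy(Sigma))
  expect_equal(knockoutEntropy(Sigma, 2, "none"), gaussianEntropy(Sigma))

  # 2 x 2, literal variant: entropy after knockout is -log(K11 K22)
  rho <- 0.7
  S2 <- matrix(c(1, rho, rho, 1), 2)
  K <- solve(S2)
  expect_equal(knockoutEntropy(S2, 1, "none"), -log(K[1, 1] * K[2, 2]),
               tolerance = 1e-12)
  # margin-preserving variant at p = 2: full disconnection of a unit-
  # variance pair gives independent unit variances, entropy 0
  expect_equal(knockoutEntropy(S2, 1), 0, tolerance = 1e-12)

  for (s in 1:20) {
    S <- randomPD(6, seed = 300 + s)
    H0 <- gaussianEntropy(S)
    K <- solve(S)
    for (j in c(1, 4)) {
      # margin-preserving removal never lowers entropy
      expect_gte(knockoutEntropy(S, j), H0 - 1e-10)
      # the literal construction never raises it, and matches the
      # Schur-complement closed form
      q <- drop(K[j, -j] %*% solve(K[-j, -j], K[-j, j]))
      expect_equal(knockoutEntropy(S, j, "none"), H0 + log(1 - q / K[j, j]),
                   tolerance = 1e-10)
      expect_lte(knockoutEntropy(S, j, "none"), H0 + 1e-10)
    }
  }

  # margin-preserving variant really restores the marginal variances
  S <- randomPD(5, seed = 321)
  K <- solve(S); K[2, -2] <- 0; K[-2, 2] <- 0
  St <- solve(K)
  d <- sqrt(diag(S) / diag(St))
  expect_equal(knockoutEntropy(S, 2, preserve = "margins"),
               gaussianEntropy(St * tcrossprod(d)), tolerance = 1e-10)
})

test_that("knockout-degree experiment flags degenerate degrees and reproduces", {
  ko <- knockoutDegreeExperiment(p = 12, kind = "smallworld", replicates = 3,
                                 seed = 5, rewire = 0)
  expect_true(all(ko$correlations$degenerate))
  expect_true(all(is.na(ko$correlations$spearman)))

  ko1 <- knockoutDegreeExperiment(p = 15, kind = "scalefree", replicates = 4,
                                  seed = 6, m = 1)
  ko2 <- knockoutDegreeExperiment(p = 15, kind = "scalefree", replicates = 4,
                                  seed = 6, m = 1)
  expect_identical(ko1, ko2)
  expect_identical(nrow(ko1$results), 60L)
  # knockout entropy never below the intact-network baseline
  base <- ko1$correlations$baseline[ko1$results$replicate]
  expect_true(all(ko1$results$entropy >= base - 1e-10))
})

test_that("weakening marginal dependence can decrease entropy", {
  w <- marginalWeakeningCounterexample(p = 3, attempts = 10000, seed = 7)
  expect_false(is.null(w))
  expect_true(verifyMarginalWitness(w))
  expect_true(all(w$gammaLow <= w$gammaHigh))
  expect_lt(w$entropyLow, w$entropyHigh)

  # the shipped synthetic witness re-verifies after a JSON round trip
  fixture <- system.file("extdata", "marginal_counterexample_synthetic.json",
                         package = "netEntropy")
  expect_true(nzchar(fixture))
  stored <- jsonlite::read_json(fixture, simplifyVector = TRUE)
  stored$corBase <- as.matrix(stored$corBase)
  expect_true(verifyMarginalWitness(stored))
})
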