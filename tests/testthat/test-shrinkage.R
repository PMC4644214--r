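test_that("sample covariance is the unbiased centered cross-product", {
  S <- sampleCovariance(rbind(c(0, 0), c(2, 2)))
  expect_equal(unclass(S), matrix(2, 2, 2), ignore_attr = TRUE)
  expect_error(sampleCovariance(matrix(1, 1, 3)), "two samples")

  # constant columns are allowed but flagged
  S <- sampleCovariance(cbind(rnorm(10), rep(1, 10)))
  expect_identical(as.integer(attr(S, "zeroVariance")), 2L)

  # Monte-Carlo oracle: elementwise error within 5 standard errors
  Sigma <- randomPD(5, seed = 41)
  X <- netEntropy:::withSeed(42, MASS::mvrnorm(200, rep(0, 5), Sigma))
  S <- sampleCovariance(X)
  se <- sqrt((outer(diag(Sigma), diag(Sigma)) + Sigma^2) / 200)
  expect_true(all(abs(S - Sigma) < 5 * se))
})

test_that("the MSE-optimal shrinkage weight behaves at its limits", {
  # perfectly correlated columns: lambda decreases toward 0 with n
  lam <- sapply(c(10, 100, 1000), function(n) {
    x <- netEntropy:::withSeed(50 + n, rnorm(n))
    optimalShrinkageLambda(cbind(x, x, x))
  })
  expect_true(all(diff(lam) < 0))
  expect_lt(lam[3], 0.01)

  # independent columns at small n: strong shrinkage in >= 90/100 seeds
  high <- sum(sapply(1:100, function(s) {
    X <- netEntropy:::withSeed(s, matrix(rnorm(10 * 20), 10, 20))
    optimalShrinkageLambda(X) > 0.5
  }))
  expect_gte(high, 90)

  # orthogonal-design columns: all off-diagonal s_ij are 0 -> lambda = 1
  X <- stats::contr.poly(6)[, 1:3]
  expect_identical(optimalShrinkageLambda(X), 1)
  # the weight is clipped into [0, 1] whatever the data
  for (s in 1:25) {
    X <- netEntropy:::withSeed(s, matrix(rt(4 * 10, df = 2), 4, 10))
    lam <- optimalShrinkageLambda(X)
    expect_gte(lam, 0); expect_lte(lam, 1)
  }
  expect_error(optimalShrinkageLambda(matrix(rnorm(4), 2, 2)), "three samples")
})

test_that("shrunken covariance interpolates S and its diagonal target", {
  X <- netEntropy:::withSeed(60, matrix(rnorm(20 * 4), 20, 4))
  S <- sampleCovariance(X)
  expect_equal(covarianceMatrix(shrunkenCovariance(X, 1)),
               diag(diag(S)), ignore_attr = TRUE)
  expect_equal(covarianceMatrix(shrunkenCovariance(X, 0)),
               unclass(S), ignore_attr = TRUE, tolerance = 1e-12)

  X2 <- cbind(X[, 1], X[, 1] + 0.5 * X[, 2])
  S2 <- sampleCovariance(X2)
  half <- covarianceMatrix(shrunkenCovariance(X2, 0.5))
  expect_equal(half[1, 2], S2[1, 2] / 2)
  expect_equal(diag(half), diag(S2))
  expect_error(shrunkenCovariance(X, 1.5), "lambda")

  # eigenvalues of the convex combination stay inside the union of bounds
  for (lam in c(0.25, 0.5, 0.75)) {
    est <- shrunkenCovariance(X, lam)
    evS <- eigen(S, only.values = TRUE)$values
    evT <- diag(S)
    ev <- eigen(covarianceMatrix(est), only.values = TRUE)$values
    expect_gte(min(ev), min(c(evS, evT)) - 1e-10)
    expect_lte(max(ev), max(c(evS, evT)) + 1e-10)
  }

  # zero-variance gene dropped with a warning
  expect_warning(est <- shrunkenCovariance(cbind(X, 0)), "zero-variance")
  expect_identical(est@droppedGenes, 5L)
})

test_that("gaussian entropy conventions and scaling law", {
  expect_equal(gaussianEntropy(diag(2)), 0)
  expect_equal(gaussianEntropy(0.3 * diag(50)), 50 * log(0.3))
  expect_equal(gaussianEntropy(matrix(1), "differential"),
               0.5 * log(2 * pi * exp(1)))
  expect_error(gaussianEntropy(matrix(c(1, 2, 2, 1), 2)), "eigenvalue")

  for (s in 1:10) {
    p <- 2 + s %% 6
    Sigma <- randomPD(p, seed = 70 + s)
    c0 <- 0.2 + s / 5
    expect_equal(gaussianEntropy(c0 * Sigma),
                 gaussianEntropy(Sigma) + p * log(c0), tolerance = 1e-10)
    # stable factorization agrees with the brute-force determinant
    expect_equal(gaussianEntropy(Sigma), log(det(Sigma)), tolerance = 1e-10)
  }
})

test_that("subsampled group comparison is deterministic and detects scale", {
  Sigma <- randomPD(6, seed = 80)
  X1 <- netEntropy:::withSeed(81, MASS::mvrnorm(40, rep(0, 6), Sigma))
  X2 <- netEntropy:::withSeed(82, MASS::mvrnorm(30, rep(0, 6), 2.5 * Sigma))
  data <- rbind(X1, X2)
  labels <- rep(c("g1", "g2"), c(40, 30))

  cmp <- compareGroupEntropy(data, labels, B = 25, seed = 9)
  cmp2 <- compareGroupEntropy(data, labels, B = 25, seed = 9)
  expect_identical(entropyDraws(cmp), entropyDraws(cmp2))
  expect_identical(cmp@nSub, 27L)  # floor(0.9 * 30)

  # inflated-covariance group has the larger entropy (truth: p log 2.5)
  s <- entropySummary(cmp)
  expect_gt(s$medianDifference, 0)
  expect_gt(s$fracFirstLower, 0.95)

  # frac = 1 with identical groups: identical entropies draw by draw
  dup <- rbind(X1, X1)
  cmpId <- compareGroupEntropy(dup, rep(c("a", "b"), each = 40),
                               B = 10, frac = 1, seed = 10)
  d <- entropyDraws(cmpId)
  expect_equal(d$entropy[d$group == "a"], d$entropy[d$group == "b"])

  expect_error(compareGroupEntropy(data, rep("g1", 70)), "two levels")
  expect_warning(compareGroupEntropy(cbind(data, 1), labels, B = 2, seed = 1),
                 "zero-variance")
})
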