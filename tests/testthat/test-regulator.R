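test_that("regulator model construction and conditional law", {
  # empty network: Y | X ~ N(beta o x, SigmaEps) exactly
  m <- buildRegulatorModel(diag(3), beta = c(2, 1, 0.5))
  cl <- conditionalLaw(m, c(3, 0, 0))
  expect_equal(cl$mean, c(6, 0, 0))
  expect_equal(cl$cov, 0.3 * diag(3))

  # defaults: beta = 1, SigmaEps = 0.3 I
  g <- sampleTopology("smallworld", 20, seed = 1)
  m <- buildRegulatorModel(g, seed = 2)
  expect_equal(m@beta, rep(1, 20))
  expect_equal(m@SigmaEps, 0.3 * diag(20))
  W <- diag(20) - m@Theta
  expect_lte(max(abs(eigen(W, only.values = TRUE)$values)), 0.5 + 1e-10)

  # scalar sanity: Theta = 1, beta = 2, x = 3 -> N(6, 0.3)
  ms <- buildRegulatorModel(matrix(1), beta = 2, sigmaEps = matrix(0.3))
  cls <- conditionalLaw(ms, 3)
  expect_equal(cls$mean, 6)
  expect_equal(cls$cov, matrix(0.3))
})

test_that("unconditional variance matches simulation and degenerate limits", {
  m <- randomRegulatorModel(5, seed = 10)
  Thinv <- solve(m@Theta)
  base <- Thinv %*% m@SigmaEps %*% t(Thinv)

  noX <- new("RegulatorModel", Theta = m@Theta, beta = m@beta,
             SigmaEps = m@SigmaEps, VarX = matrix(0, 5, 5))
  expect_equal(unconditionalVariance(noX), netEntropy:::symmetrize(base),
               tolerance = 1e-12)
  noBeta <- new("RegulatorModel", Theta = m@Theta, beta = rep(0, 5),
                SigmaEps = m@SigmaEps, VarX = m@VarX)
  expect_equal(unconditionalVariance(noBeta), netEntropy:::symmetrize(base),
               tolerance = 1e-12)

  # forward sampler as the oracle
  V <- unconditionalVariance(m)
  se <- simulatePaired(m, 50000, seed = 11)
  Shat <- stats::cov(expressionMatrix(se))
  seV <- sqrt((outer(diag(V), diag(V)) + V^2) / 50000)
  expect_true(all(abs(Shat - V) < 5 * seV))

  # conditional covariance against simulation at fixed x
  x0 <- c(1, -1, 0, 2, 0.5)
  cl <- conditionalLaw(m, x0)
  Ysim <- netEntropy:::withSeed(12, {
    E <- MASS::mvrnorm(20000, rep(0, 5), m@SigmaEps)
    t(solve(m@Theta, t(sweep(E, 2, -m@beta * x0) )))
  })
  seC <- sqrt((outer(diag(cl$cov), diag(cl$cov)) + cl$cov^2) / 20000)
  expect_true(all(abs(stats::cov(Ysim) - cl$cov) < 5 * seC))
  expect_true(all(abs(colMeans(Ysim) - cl$mean) < 5 * sqrt(diag(cl$cov) / 20000)))
})

test_that("paired simulation is reproducible and respects VarX = 0", {
  m <- buildRegulatorModel(diag(4))
  se <- simulatePaired(m, 10, seed = 13)
  expect_true(all(copyNumberMatrix(se) == 0))
  m2 <- randomRegulatorModel(4, seed = 14)
  a <- simulatePaired(m2, 15, seed = 15)
  b <- simulatePaired(m2, 15, seed = 15)
  expect_identical(expressionMatrix(a), expressionMatrix(b))
  expect_identical(copyNumberMatrix(a), copyNumberMatrix(b))
})

test_that("genomic-variance sweep: rank-one increments via determinant lemma", {
  m <- randomRegulatorModel(8, seed = 20)
  # v = 0 leaves the baseline untouched
  sw0 <- genomicVarianceSweep(m, v = 0)
  expect_true(all(sw0$sweep$deltaH == 0))

  # diagonal SigmaEps: closed-form increments log(1 + v beta_j^2 / sigma_jj)
  for (s in 1:20) {
    p <- 6 + s %% 5
    g <- sampleTopology(if (s %% 2) "scalefree" else "smallworld", p,
                        m = 1, seed = 300 + s)
    p <- igraph::vcount(g)
    sig <- netEntropy:::withSeed(400 + s, runif(p, 0.2, 1))
    beta <- netEntropy:::withSeed(500 + s, runif(p, 0.5, 2))
    mm <- buildRegulatorModel(g, beta = beta, sigmaEps = diag(sig),
                              seed = 600 + s)
    v <- 0.5 + s / 10
    sw <- genomicVarianceSweep(mm, v = v)
    expect_equal(sw$sweep$deltaH, log(1 + v * beta^2 / sig), tolerance = 1e-8)
  }
})

test_that("copy-number variation can only increase the determinant", {
  # equality when VarX = 0 or beta = 0
  m0 <- buildRegulatorModel(diag(3))
  chk <- detInequalityCheck(m0)
  expect_true(chk$holds && chk$equalityExpected && chk$equalityObserved)

  m <- randomRegulatorModel(5, seed = 30)
  mb0 <- new("RegulatorModel", Theta = m@Theta, beta = rep(0, 5),
             SigmaEps = m@SigmaEps, VarX = m@VarX)
  chk <- detInequalityCheck(mb0)
  expect_true(chk$holds && chk$equalityExpected && chk$equalityObserved)

  # strict inequality for PD VarX and nonzero beta
  for (s in 1:20) {
    chk <- detInequalityCheck(randomRegulatorModel(5, seed = 700 + s))
    expect_true(chk$holds)
    expect_false(chk$equalityExpected)
    expect_gt(chk$logDetVarY, chk$logDetBase)
  }
})

test_that("equation-wise lasso honours penalty limits and the lasso oracle", {
  m <- randomRegulatorModel(6, seed = 40, varXScale = 1)
  se <- simulatePaired(m, 300, seed = 41)
  X <- copyNumberMatrix(se); Y <- expressionMatrix(se)

  # overwhelming penalty: empty support, beta_j from simple regression
  f <- fitRegulator(X, Y, lambda1 = 1e4)
  expect_equal(f$edges, 0)
  for (j in 1:6) {
    slope <- unname(coef(lm(Y[, j] ~ X[, j]))[2])
    expect_equal(f$beta[j], slope, tolerance = 1e-6)
  }

  # edge count non-increasing along the penalty path
  grid <- exp(seq(log(0.5), log(0.01), length.out = 10))
  counts <- sapply(grid, function(l) fitRegulator(X, Y, l)$edges)
  expect_true(all(diff(counts) >= 0))  # grid is decreasing in lambda

  # glmnet solution agrees with an independent coordinate-descent oracle
  Zs <- popStandardize(cbind(Y[, -1], X[, 1]))
  for (lam in c(0.05, 0.15)) {
    cf <- netEntropy:::fitOneEquation(Zs, Y[, 1], c(rep(1, 5), 0), lam)[, 1]
    oracle <- lassoCD(Zs, Y[, 1], lam, pf = c(rep(1, 5), 0))
    expect_equal(unname(cf), oracle$b, tolerance = 1e-6)
  }
})

test_that("support recovery and refit on strong signal", {
  g <- sampleTopology("scalefree", 10, m = 1, seed = 50)
  m <- buildRegulatorModel(g, varX = 0.5 * diag(10), targetRadius = 0.8,
                           seed = 51)
  se <- simulatePaired(m, 1000, seed = 52)
  X <- copyNumberMatrix(se); Y <- expressionMatrix(se)
  trueSupp <- netEntropy:::supportFromTheta(m@Theta)
  nTrue <- sum(trueSupp) / 2

  grid <- exp(seq(log(0.5), log(0.005), length.out = 12))
  stats <- sapply(grid, function(l) {
    f <- fitRegulator(X, Y, l)
    tp <- sum(f$support & trueSupp) / 2
    fp <- sum(f$support & !trueSupp) / 2
    c(sens = tp / nTrue, fdr = fp / max(1, tp + fp))
  })
  expect_true(any(stats["sens", ] >= 0.9 & stats["fdr", ] <= 0.1))

  # refit with the true support on near-noiseless data recovers Theta, beta
  mq <- buildRegulatorModel(m@Theta, beta = m@beta,
                            sigmaEps = 1e-8 * diag(10),
                            varX = 0.5 * diag(10))
  seq_ <- simulatePaired(mq, 400, seed = 53)
  rf <- refitSupport(copyNumberMatrix(seq_), expressionMatrix(seq_), trueSupp)
  expect_equal(rf$Theta, m@Theta, tolerance = 1e-3)
  expect_equal(rf$beta, m@beta, tolerance = 1e-3)

  # empty support: univariate regression slope
  rf0 <- refitSupport(X, Y, matrix(FALSE, 10, 10))
  slope <- unname(coef(lm(Y[, 1] ~ X[, 1]))[2])
  expect_equal(rf0$beta[1], slope, tolerance = 1e-10)
  expect_true(all(rf0$Theta[upper.tri(rf0$Theta)] == 0))
})

test_that("edge-count curves are deterministic and vanish under heavy penalty", {
  cfg <- cohortConfig(p = 12, n1 = 30, n2 = 25,
                      topology = list(kind = "scalefree", m = 1))
  se <- generateCohort(cfg, seed = 60)
  X <- copyNumberMatrix(se); Y <- expressionMatrix(se)
  grp <- SummarizedExperiment::colData(se)$group

  grid <- c(100, 0.3, 0.1)
  c1 <- edgeCountCurve(X, Y, grp, lambdaGrid = grid, B = 4, seed = 61)
  c2 <- edgeCountCurve(X, Y, grp, lambdaGrid = grid, B = 4, seed = 61)
  expect_identical(c1, c2)
  expect_true(all(c1$meanEdges[c1$lambda == 100] == 0))
  expect_true(all(c1$meanEdges >= 0))
  cap <- attr(c1, "capacity")
  expect_identical(cap, 12 * 11 / 2)
  expect_identical(c1$inWindow,
                   c1$meanEdges / cap >= 0.01 & c1$meanEdges / cap <= 0.10)
})
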