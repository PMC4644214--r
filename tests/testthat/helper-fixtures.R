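# Fixture builders and independent oracles used across the suite.

# well-conditioned random PD matrix
randomPD <- function(p, seed = NULL) {
  netEntropy:::withSeed(seed, {
    A <- matrix(rnorm(p * p), p, p)
    crossprod(A) / p + 0.5 * diag(p)
  })
}

# random unit-diagonal PD matrix (standardized concentration form)
randomOmega <- function(p, seed = NULL) {
  standardizeConcentration(randomPD(p, seed))
}

# random GaussianMixture with K <= maxK components in dimension <= maxP
randomMixture <- function(seed, maxK = 4, maxP = 10) {
  netEntropy:::withSeed(seed, {
    K <- sample(1:maxK, 1)
    p <- sample(2:maxP, 1)
    tau <- runif(K, 0.2, 1)
    tau <- tau / sum(tau)
    mu <- lapply(seq_len(K), function(k) rnorm(p, sd = 2))
    Sigma <- lapply(seq_len(K), function(k) randomPD(p))
    buildMixture(tau, mu, Sigma, enforceCentering = TRUE)
  })
}

# Independent lasso oracle: plain cyclic coordinate descent on
# (1/2n)||y - b0 - Z b||^2 + lambda * sum(pf * |b|), no standardization.
# pf is rescaled to sum to the number of covariates, the convention the
# implementation's solver also applies.
lassoCD <- function(Z, y, lambda, pf = rep(1, ncol(Z)), iters = 5000,
                    tol = 1e-12) {
  pf <- pf * length(pf) / sum(pf)
  n <- nrow(Z)
  b0 <- mean(y)
  b <- rep(0, ncol(Z))
  zc <- scale(Z, center = TRUE, scale = FALSE)
  yc <- y - b0
  z2 <- colSums(zc^2) / n
  r <- yc
  for (it in seq_len(iters)) {
    delta <- 0
    for (k in seq_along(b)) {
      rho <- sum(zc[, k] * r) / n + z2[k] * b[k]
      bnew <- sign(rho) * max(0, abs(rho) - lambda * pf[k]) / z2[k]
      if (bnew != b[k]) {
        r <- r - zc[, k] * (bnew - b[k])
        delta <- max(delta, abs(bnew - b[k]))
        b[k] <- bnew
      }
    }
    if (delta < tol) break
  }
  list(b0 = b0 - sum(colMeans(Z) * b), b = b)
}

# standardize columns to population (1/n) unit variance, so glmnet's
# internal standardization is a no-op and objectives coincide
popStandardize <- function(Z) {
  n <- nrow(Z)
  sds <- apply(Z, 2, function(z) sqrt(mean((z - mean(z))^2)))
  sweep(Z, 2, sds, "/")
}

randomRegulatorModel <- function(p, seed, varXScale = 0.5) {
  netEntropy:::withSeed(seed, {
    g <- sampleTopology("scalefree", p, m = 1,
                        seed = sample.int(1e6, 1))
    buildRegulatorModel(g, beta = runif(p, 0.5, 1.5),
                        sigmaEps = randomPD(p) * 0.3,
                        varX = varXScale * randomPD(p),
                        seed = sample.int(1e6, 1))
  })
}
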