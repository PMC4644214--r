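# Finite Gaussian mixtures modelling regulatory switches, Monte-Carlo
# mixture entropy, and numerical checks of the mixture-entropy inequality.

#' Build a finite Gaussian mixture
#'
#' Validates weights and component covariances and, by default, translates
#' all component means by the weighted mean so the population mean is
#' exactly zero (the normalization convention for expression data).
#'
#' @param tau nonnegative weights summing to one (tolerance 1e-10).
#' @param mu list of p-vectors (or a K x p matrix) of component means.
#' @param Sigma list of p x p PD component covariances (or a single matrix
#'   recycled to all components).
#' @param enforceCentering translate means so sum_k tau_k mu_k = 0
#'   (default \code{TRUE}).
#' @return a \code{\linkS4class{GaussianMixture}}.
#' @export
buildMixture <- function(tau, mu, Sigma, enforceCentering = TRUE) {
  if (is.matrix(mu)) mu <- lapply(seq_len(nrow(mu)), function(k) mu[k, ])
  mu <- lapply(mu, as.numeric)
  if (is.matrix(Sigma)) Sigma <- rep(list(Sigma), length(tau))
  if (abs(sum(tau) - 1) > 1e-10)
    stop("mixing proportions must sum to one", call. = FALSE)
  if (enforceCentering) {
    m <- Reduce(`+`, Map(`*`, mu, as.list(tau)))
    mu <- lapply(mu, function(v) v - m)
  }
  new("GaussianMixture", tau = as.numeric(tau), mu = mu, Sigma = Sigma)
}

#' Sample from a Gaussian mixture
#'
#' @param model a \code{\linkS4class{GaussianMixture}}.
#' @param n number of draws.
#' @param seed integer seed.
#' @return n x p matrix with integer attribute \code{"component"} holding
#'   the latent component index of each row.
#' @export
sampleMixture <- function(model, n, seed = NULL) {
  stopIfNot(n >= 1, "n must be at least 1")
  K <- length(model@tau)
  p <- length(model@mu[[1]])
  withSeed(seed, {
    z <- sample.int(K, n, replace = TRUE, prob = model@tau)
    out <- matrix(0, n, p)
    for (k in seq_len(K)) {
      idx <- which(z == k)
      if (length(idx))
        out[idx, ] <- rmvn(length(idx), model@mu[[k]], model@Sigma[[k]])
    }
    attr(out, "component") <- z
    out
  })
}

# log-density of the mixture at the rows of X, via log-sum-exp over
# components (stable for well-separated components).
mixtureLogDensity <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  K <- length(model@tau)
  keep <- which(model@tau > 0)
  L <- vapply(keep, function(k) {
    log(model@tau[k]) + logDmvnorm(X, model@mu[[k]], model@Sigma[[k]])
  }, numeric(nrow(X)))
  if (!is.matrix(L)) L <- matrix(L, nrow = nrow(X))
  mx <- apply(L, 1L, max)
  mx + log(rowSums(exp(L - mx)))
}

#' Monte-Carlo differential entropy of a Gaussian mixture
#'
#' Mixture entropy has no closed form; it is estimated as
#' -(1/M) sum_m log f(y_m) with y_m drawn from the mixture and the
#' log-density evaluated through a log-sum-exp over components.
#'
#' @param model a \code{\linkS4class{GaussianMixture}}.
#' @param M Monte-Carlo sample size (>= 1000; default 1e5).
#' @param seed integer seed.
#' @return list with \code{H} (differential entropy estimate), \code{se}
#'   (Monte-Carlo standard error), and \code{M}.
#' @export
mixtureEntropyMC <- function(model, M = 1e5, seed = NULL) {
  stopIfNot(M >= 1000, "M must be at least 1000")
  Y <- sampleMixture(model, M, seed)
  lf <- mixtureLogDensity(model, Y)
  list(H = -mean(lf), se = sd(lf) / sqrt(M), M = as.integer(M))
}

#' Weighted mean of component differential entropies
#'
#' The closed-form quantity sum_k tau_k [p/2 log(2 pi e) + 1/2 log|Sigma_k|],
#' the lower bound that the mixture's entropy cannot fall below.
#'
#' @param model a \code{\linkS4class{GaussianMixture}}.
#' @return the weighted component-entropy mean.
#' @export
componentEntropyMean <- function(model) {
  sum(model@tau * vapply(model@Sigma, gaussianEntropy,
                         numeric(1), convention = "differential"))
}

#' Check the mixture-entropy lower bound numerically
#'
#' Verifies that the Monte-Carlo mixture entropy is at least the weighted
#' mean of component entropies (within Monte-Carlo error): mixing can only
#' add heterogeneity. For a single component the gap is zero.
#'
#' @param model a \code{\linkS4class{GaussianMixture}}.
#' @param M Monte-Carlo sample size.
#' @param seed integer seed.
#' @return list with the mixture entropy estimate and its standard error,
#'   the component mean, the gap, a \code{pass} flag (gap >= -3 se), and
#'   both entropies also on the log-determinant scale
#'   (2 x differential - p log(2 pi e)).
#' @export
checkProposition1 <- function(model, M = 1e5, seed = NULL) {
  mc <- mixtureEntropyMC(model, M, seed)
  compMean <- componentEntropyMean(model)
  p <- length(model@mu[[1]])
  offset <- p * log(2 * pi * exp(1))
  list(mixtureEntropy = mc$H, se = mc$se,
       componentMean = compMean,
       gap = mc$H - compMean,
       pass = (mc$H - compMean) >= -3 * mc$se,
       mixtureEntropyLogdet = 2 * mc$H - offset,
       componentMeanLogdet = 2 * compMean - offset)
}

#' Generate switch scenarios with a known entropy ordering
#'
#' Scenario 1: all components share one covariance but differ in mean
#' (differential expression between regulatory modules); the population
#' entropy exceeds that of any single module once means separate.
#' Scenario 2: component covariances with determinant at least that of a
#' reference covariance (a heterogeneity increase inside a module),
#' implemented by inflating the reference by per-component factors >= 1.
#'
#' @param which scenario, 1 or 2.
#' @param K number of components (default 2).
#' @param p dimension (default 2).
#' @param effect positive effect size: mean separation scale (scenario 1)
#'   or maximal covariance inflation (scenario 2).
#' @param seed integer seed.
#' @return for scenario 1, a \code{\linkS4class{GaussianMixture}}; for
#'   scenario 2, a list with the mixture and the reference covariance
#'   \code{refSigma}.
#' @export
scenarioMixture <- function(which, K = 2, p = 2, effect = 1, seed = NULL) {
  stopIfNot(which %in% c(1, 2), "which must be 1 or 2")
  stopIfNot(effect >= 0, "effect must be nonnegative")
  withSeed(seed, {
    A <- matrix(rnorm(p * p), p, p)
    Sigma <- crossprod(A) / p + diag(p) * 0.5
    tau <- rep(1 / K, K)
    if (which == 1) {
      mu <- lapply(seq_len(K), function(k) {
        u <- rnorm(p)
        effect * u / sqrt(sum(u^2))
      })
      buildMixture(tau, mu, Sigma, enforceCentering = TRUE)
    } else {
      infl <- runif(K, 1, 1 + effect)
      SigmaK <- lapply(infl, function(c) c * Sigma)
      model <- buildMixture(tau, rep(list(rep(0, p)), K), SigmaK,
                            enforceCentering = FALSE)
      list(model = model, refSigma = Sigma)
    }
  })
}
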