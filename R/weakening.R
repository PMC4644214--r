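# Entropy under block-wise weakening of partial correlations, in silico
# gene knockouts, and the marginal-dependence counterexample search.

# index of block pair (a, b), a < b, in the row-major gamma ordering
# (1,2), (1,3), ..., (1,r), (2,3), ..., (r-1, r)
blockPairIndex <- function(a, b, r) {
  (a - 1) * r - a * (a - 1) / 2 + (b - a)
}

scaleBlocks <- function(base, blocks, gamma) {
  r <- length(blocks)
  out <- base
  for (a in seq_len(r - 1)) for (b in (a + 1):r) {
    g <- gamma[blockPairIndex(a, b, r)]
    out[blocks[[a]], blocks[[b]]] <- g * base[blocks[[a]], blocks[[b]]]
    out[blocks[[b]], blocks[[a]]] <- g * base[blocks[[b]], blocks[[a]]]
  }
  out
}

#' Block-scale a standardized concentration matrix
#'
#' Scales each off-diagonal block (a, b) of a unit-diagonal PD
#' concentration matrix by gamma_ab in [0, 1], weakening the conditional
#' dependencies between node blocks while leaving within-block structure
#' intact. Positive definiteness of the result is verified by
#' factorization and violations are reported as errors (for two blocks the
#' scaled matrix is always PD; for more blocks it need not be).
#'
#' @param omegaBase unit-diagonal PD matrix (standardized concentration).
#' @param blocks list of integer vectors partitioning 1..p.
#' @param gamma numeric vector, one scale per unordered block pair in
#'   row-major order.
#' @return a \code{\linkS4class{BlockPartialCorrelation}}.
#' @export
buildBlockOmega <- function(omegaBase, blocks, gamma) {
  omegaBase <- as.matrix(omegaBase)
  blocks <- lapply(blocks, as.integer)
  new("BlockPartialCorrelation", OmegaBase = omegaBase, blocks = blocks,
      gamma = as.numeric(gamma),
      OmegaGamma = scaleBlocks(omegaBase, blocks, gamma))
}

#' Entropy of a model with weakened conditional dependencies
#'
#' Builds the covariance with the prescribed block-scaled
#' partial-correlation structure and prescribed marginal variances:
#' Sigma = D^{1/2} C D^{1/2} with C the inverse of the scaled
#' concentration matrix rescaled to unit diagonal (partial correlations
#' are invariant under per-variable rescaling, so the construction attains
#' both constraints exactly). Returns log|Sigma| =
#' sum_j log sigma_j^2 + log|C|. Element-wise smaller gamma (weaker
#' conditional dependencies) never decreases this entropy.
#'
#' @param omegaBase,blocks,gamma as in \code{\link{buildBlockOmega}}.
#' @param marginalVariances positive marginal variances (recycled;
#'   default 1).
#' @return log-determinant entropy of the weakened model.
#' @export
entropyUnderWeakening <- function(omegaBase, blocks, gamma,
                                  marginalVariances = 1) {
  obj <- buildBlockOmega(omegaBase, blocks, gamma)
  p <- nrow(obj@OmegaGamma)
  mv <- rep_len(marginalVariances, p)
  stopIfNot(all(mv > 0), "marginal variances must be positive")
  C <- stats::cov2cor(pdInverse(obj@OmegaGamma))
  sum(log(mv)) + logDet(C)
}

#' Entropy after an in silico gene knockout
#'
#' Removes all conditional dependencies of node j: the off-diagonal row
#' and column j of the concentration matrix K = Sigma^{-1} are set to
#' zero and the entropy log|Sigma-tilde| of the modified inverse is
#' returned.
#'
#' With the default \code{preserve = "margins"}, the modified covariance
#' is rescaled back to the original marginal variances, so the comparison
#' isolates the loss of conditional dependence; this is the construction
#' under which dependency removal can only increase entropy (it is the
#' single-block-disconnection case of the block-weakening monotonicity,
#' which is stated for equal marginal variances) and under which hub
#' knockouts yield the larger increase.
#'
#' \code{preserve = "none"} keeps the precision diagonal instead. That
#' variant also shrinks the knocked-out gene's own variance (from
#' Sigma_jj down to 1/K_jj), and by the Schur-complement identity
#' det(K-tilde) = K_jj det(K_{-j,-j}) >= det(K) it always yields an
#' entropy at or below the baseline -- a knockout is not fully equivalent
#' to dependency removal.
#'
#' @param Sigma PD covariance matrix.
#' @param j node to knock out.
#' @param preserve \code{"margins"} (default) or \code{"none"}.
#' @return entropy log|Sigma-tilde| after knockout.
#' @export
knockoutEntropy <- function(Sigma, j, preserve = c("margins", "none")) {
  preserve <- match.arg(preserve)
  Sigma <- as.matrix(Sigma)
  K <- pdInverse(Sigma)
  K[j, -j] <- 0
  K[-j, j] <- 0
  SigmaT <- pdInverse(K)
  if (preserve == "margins") {
    d <- sqrt(diag(Sigma) / diag(SigmaT))
    SigmaT <- SigmaT * tcrossprod(d)
  }
  logDet(SigmaT)
}

#' Knockout entropy versus node degree
#'
#' For each replicate: draw a topology, attach a PD concentration matrix,
#' knock out every node in turn, and relate the entropy increase to the
#' node's degree by Spearman rank correlation (the claim being
#' monotonicity, not linearity). Hub knockouts remove more conditional
#' dependencies and free more of the network to vary, so the correlation
#' is expected positive.
#'
#' @param p network size (default 50).
#' @param kind topology family (default \code{"scalefree"}).
#' @param replicates independent draws (default 100).
#' @param seed integer seed.
#' @param ... passed to \code{\link{sampleTopology}} (e.g. \code{m},
#'   \code{k}, \code{rewire}).
#' @return list with \code{results} (replicate, node, degree, entropy)
#'   and \code{correlations} (replicate, baseline, spearman;
#'   \code{spearman} is \code{NA}, flagged by \code{degenerate}, when all
#'   degrees are equal).
#' @export
knockoutDegreeExperiment <- function(p = 50, kind = "scalefree",
                                     replicates = 100, seed = NULL, ...) {
  stopIfNot(p >= 10, "p must be at least 10")
  stopIfNot(replicates >= 1, "replicates must be at least 1")
  seeds <- spawnSeeds(seed, 2L * replicates)
  res <- vector("list", replicates)
  cors <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    g <- sampleTopology(kind, p, seed = seeds[2 * r - 1], ...)
    cm <- precisionFromTopology(g, seed = seeds[2 * r])
    Sigma <- covarianceMatrix(cm)
    d <- igraph::degree(g)
    H <- vapply(seq_len(p), function(j) knockoutEntropy(Sigma, j), numeric(1))
    res[[r]] <- data.frame(replicate = r, node = seq_len(p), degree = d,
                           entropy = H)
    degenerate <- sd(d) == 0
    cors[[r]] <- data.frame(
      replicate = r, baseline = logDet(Sigma),
      spearman = if (degenerate) NA_real_ else
        cor(d, H, method = "spearman"),
      degenerate = degenerate)
  }
  list(results = do.call(rbind, res), correlations = do.call(rbind, cors))
}

#' Search for a marginal-dependence counterexample
#'
#' Weakening conditional dependencies never decreases entropy, but the
#' analogous statement for marginal dependencies is false. This random
#' search looks for a witness: a correlation matrix whose off-diagonal
#' blocks, scaled by element-wise ordered factors gammaLow <= gammaHigh,
#' yield H(gammaLow) < H(gammaHigh) -- weakening the marginal dependence
#' decreases the entropy.
#'
#' @param p dimension (>= 3; blocks are singletons).
#' @param attempts maximum random attempts (default 10000).
#' @param seed integer seed.
#' @return a witness list (\code{corBase}, \code{gammaLow},
#'   \code{gammaHigh}, \code{entropyLow}, \code{entropyHigh},
#'   \code{attempt}) or \code{NULL} when none is found in the budget.
#' @export
marginalWeakeningCounterexample <- function(p = 3, attempts = 10000,
                                            seed = NULL) {
  stopIfNot(p >= 3, "p must be at least 3")
  blocks <- as.list(seq_len(p))
  nPairs <- p * (p - 1) / 2
  withSeed(seed, {
    for (a in seq_len(attempts)) {
      A <- matrix(rnorm(p * p), p, p)
      C <- stats::cov2cor(crossprod(A) + diag(p) * 0.1)
      if (a %% 2 == 0) {
        # fully random ordered pair
        gHigh <- runif(nPairs)
        gLow <- gHigh * runif(nPairs)
      } else {
        # weaken a single randomly chosen marginal dependence: the loss of
        # an interaction term can then outweigh the gained quadratic slack
        gHigh <- rep(1, nPairs)
        gLow <- gHigh
        gLow[sample.int(nPairs, 1)] <- runif(1)
      }
      CH <- scaleBlocks(C, blocks, gHigh)
      CL <- scaleBlocks(C, blocks, gLow)
      if (!isPD(CH) || !isPD(CL)) next
      hH <- logDet(CH)
      hL <- logDet(CL)
      if (hL < hH - 1e-10) {
        return(list(corBase = C, gammaLow = gLow, gammaHigh = gHigh,
                    entropyLow = hL, entropyHigh = hH, attempt = a))
      }
    }
    NULL
  })
}

#' Re-verify a marginal counterexample witness
#'
#' @param witness a list as returned by
#'   \code{\link{marginalWeakeningCounterexample}} (possibly re-read from
#'   JSON).
#' @return \code{TRUE} when both scaled matrices are PD and the claimed
#'   entropy ordering holds; otherwise \code{FALSE}.
#' @export
verifyMarginalWitness <- function(witness) {
  C <- as.matrix(witness$corBase)
  p <- nrow(C)
  blocks <- as.list(seq_len(p))
  CH <- scaleBlocks(C, blocks, as.numeric(witness$gammaHigh))
  CL <- scaleBlocks(C, blocks, as.numeric(witness$gammaLow))
  isPD(CH) && isPD(CL) &&
    all(witness$gammaLow <= witness$gammaHigh + 1e-12) &&
    logDet(CL) < logDet(CH) - 1e-10
}
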