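#' @import methods
NULL

#' ConcentrationModel: a Gaussian graphical model on a known topology
#'
#' Couples an undirected regulatory topology (an \pkg{igraph} graph) with a
#' positive-definite concentration (inverse covariance) matrix whose
#' off-diagonal support equals the graph's edge set, together with its
#' covariance inverse.
#'
#' @slot graph an \code{igraph} object; the regulatory topology.
#' @slot K numeric matrix; the concentration (precision) matrix.
#' @slot Sigma numeric matrix; the covariance, \code{solve(K)}.
#'
#' @seealso \code{\link{precisionFromTopology}}, \code{\link{sampleTopology}}
#' @export
setClass("ConcentrationModel",
  representation(graph = "ANY", K = "matrix", Sigma = "matrix"),
  validity = function(object) {
    K <- object@K
    msg <- character()
    if (!isSymmetric2(K)) msg <- c(msg, "K must be symmetric")
    if (!isPD(K)) msg <- c(msg, "K must be positive definite")
    if (!all(dim(object@Sigma) == dim(K)))
      msg <- c(msg, "Sigma and K dimensions differ")
    if (max(abs(object@Sigma %*% K - diag(nrow(K)))) > 1e-6)
      msg <- c(msg, "Sigma is not the inverse of K")
    if (inherits(object@graph, "igraph")) {
      A <- igraph::as_adjacency_matrix(object@graph, sparse = FALSE) > 0
      supp <- abs(K) > 1e-12
      diag(supp) <- FALSE
      if (!identical(unname(supp), unname(A)))
        msg <- c(msg, "off-diagonal support of K must equal the graph's edges")
    }
    if (length(msg)) msg else TRUE
  }
)

#' GaussianMixture: a finite mixture of multivariate normals
#'
#' A K-component Gaussian mixture with nonnegative weights summing to one and
#' component means constrained to a weighted mean of zero (the normalization
#' convention for expression data), modelling a population in which a
#' regulatory switch selects among regulatory modules.
#'
#' @slot tau numeric; mixing proportions.
#' @slot mu list of numeric vectors; component means.
#' @slot Sigma list of PD matrices; component covariances.
#'
#' @seealso \code{\link{buildMixture}}, \code{\link{mixtureEntropyMC}}
#' @export
setClass("GaussianMixture",
  representation(tau = "numeric", mu = "list", Sigma = "list"),
  validity = function(object) {
    msg <- character()
    K <- length(object@tau)
    if (any(object@tau < 0)) msg <- c(msg, "mixing proportions must be nonnegative")
    if (abs(sum(object@tau) - 1) > 1e-10)
      msg <- c(msg, "mixing proportions must sum to one")
    if (length(object@mu) != K || length(object@Sigma) != K)
      msg <- c(msg, "tau, mu and Sigma must have one entry per component")
    p <- length(object@mu[[1]])
    if (!all(vapply(object@mu, length, 1L) == p))
      msg <- c(msg, "component means differ in dimension")
    for (k in seq_len(K)) {
      S <- object@Sigma[[k]]
      if (!all(dim(S) == p)) { msg <- c(msg, "covariance dimension mismatch"); break }
      if (!isPD(S)) { msg <- c(msg, sprintf("component %d covariance is not PD", k)); break }
    }
    m <- Reduce(`+`, Map(`*`, object@mu, as.list(object@tau)))
    if (max(abs(m)) > 1e-8)
      msg <- c(msg, "weighted component means must sum to zero (centering convention)")
    if (length(msg)) msg else TRUE
  }
)

#' RegulatorModel: steady-state copy-number to expression network model
#'
#' The structural model Theta Y = beta o X + eps, with Theta the (unit
#' diagonal, invertible) gene-gene effect matrix, beta the per-gene
#' cis-effect of DNA copy number on expression, eps ~ N(0, SigmaEps), and
#' VarX the covariance of the copy-number vector X.
#'
#' @slot Theta numeric matrix; gene-gene effects, unit diagonal.
#' @slot beta numeric; cis-effect vector.
#' @slot SigmaEps numeric matrix; PD error covariance.
#' @slot VarX numeric matrix; PSD covariance of copy number.
#'
#' @seealso \code{\link{buildRegulatorModel}}, \code{\link{unconditionalVariance}}
#' @export
setClass("RegulatorModel",
  representation(Theta = "matrix", beta = "numeric", SigmaEps = "matrix",
                 VarX = "matrix"),
  validity = function(object) {
    msg <- character()
    p <- nrow(object@Theta)
    if (max(abs(diag(object@Theta) - 1)) > 1e-10)
      msg <- c(msg, "Theta must have a unit diagonal")
    if (length(object@beta) != p) msg <- c(msg, "beta length must match Theta")
    if (!all(dim(object@SigmaEps) == p) || !isPD(object@SigmaEps))
      msg <- c(msg, "SigmaEps must be PD of matching dimension")
    if (!all(dim(object@VarX) == p) || !isSymmetric2(object@VarX))
      msg <- c(msg, "VarX must be symmetric of matching dimension")
    evx <- eigen(symmetrize(object@VarX), symmetric = TRUE, only.values = TRUE)$values
    if (min(evx) < -1e-8) msg <- c(msg, "VarX must be positive semi-definite")
    d <- determinant(object@Theta, logarithm = TRUE)
    if (!is.finite(d$modulus)) msg <- c(msg, "Theta must be invertible")
    if (length(msg)) msg else TRUE
  }
)

#' VARProcess: first-order vector autoregression with an optional disturbance
#'
#' Expression dynamics Y_t = nu + A Y_{t-1} + eps_t with eps_t ~ N(0,
#' SigmaEps), independent across time, Y_0 = 0, and an optional one-time
#' Gaussian disturbance delta ~ N(0, SigmaDelta) injected at time tau.
#'
#' @slot nu numeric; intercept.
#' @slot A numeric matrix; lag-one coefficients.
#' @slot SigmaEps numeric matrix; PD innovation covariance.
#' @slot SigmaDelta numeric matrix; PD disturbance covariance.
#' @slot tau numeric; disturbance time, or \code{NA} for none.
#'
#' @seealso \code{\link{varProcess}}, \code{\link{varCovariance}}
#' @export
setClass("VARProcess",
  representation(nu = "numeric", A = "matrix", SigmaEps = "matrix",
                 SigmaDelta = "matrix", tau = "numeric"),
  validity = function(object) {
    msg <- character()
    p <- nrow(object@A)
    if (ncol(object@A) != p) msg <- c(msg, "A must be square")
    if (length(object@nu) != p) msg <- c(msg, "nu length must match A")
    if (!all(dim(object@SigmaEps) == p) || !isPD(object@SigmaEps))
      msg <- c(msg, "SigmaEps must be PD of matching dimension")
    if (!all(dim(object@SigmaDelta) == p) || !isPD(object@SigmaDelta))
      msg <- c(msg, "SigmaDelta must be PD of matching dimension")
    if (!is.na(object@tau) && (object@tau < 1 || object@tau != round(object@tau)))
      msg <- c(msg, "tau must be a positive integer time point or NA")
    if (length(msg)) msg else TRUE
  }
)

#' BlockPartialCorrelation: block-scaled standardized concentration matrix
#'
#' A unit-diagonal PD concentration matrix partitioned into r node blocks,
#' with each off-diagonal block (a, b) scaled by a factor gamma_ab in [0, 1].
#' Scaling gamma below one weakens the conditional dependencies between the
#' blocks; gamma = 1 recovers the base matrix, gamma = 0 disconnects blocks.
#'
#' @slot OmegaBase numeric matrix; unit-diagonal PD base.
#' @slot blocks list of integer vectors partitioning 1..p.
#' @slot gamma numeric; one scale per unordered block pair, row-major order
#'   (1,2), (1,3), ..., (r-1, r).
#' @slot OmegaGamma numeric matrix; the scaled (and PD-validated) result.
#'
#' @seealso \code{\link{buildBlockOmega}}, \code{\link{entropyUnderWeakening}}
#' @export
setClass("BlockPartialCorrelation",
  representation(OmegaBase = "matrix", blocks = "list", gamma = "numeric",
                 OmegaGamma = "matrix"),
  validity = function(object) {
    msg <- character()
    p <- nrow(object@OmegaBase)
    if (max(abs(diag(object@OmegaBase) - 1)) > 1e-10)
      msg <- c(msg, "OmegaBase must have a unit diagonal")
    idx <- sort(unlist(object@blocks))
    if (!identical(as.integer(idx), seq_len(p)))
      msg <- c(msg, "blocks must partition 1..p")
    r <- length(object@blocks)
    if (length(object@gamma) != r * (r - 1) / 2)
      msg <- c(msg, "gamma must have one entry per block pair")
    if (any(object@gamma < 0 | object@gamma > 1))
      msg <- c(msg, "gamma entries must lie in [0, 1]")
    if (!isPD(object@OmegaGamma))
      msg <- c(msg, "scaled matrix OmegaGamma is not positive definite")
    if (length(msg)) msg else TRUE
  }
)

#' ShrinkageEstimate: Ledoit-Wolf type shrunken covariance
#'
#' The convex combination (1 - lambda) S + lambda T of the sample covariance
#' S and the diagonal target T = diag(S); the diagonal is preserved for
#' every lambda.
#'
#' @slot S numeric matrix; sample covariance.
#' @slot lambda numeric; shrinkage weight in [0, 1].
#' @slot SigmaHat numeric matrix; the shrunken estimate.
#' @slot droppedGenes integer; indices of zero-variance genes removed
#'   before estimation (empty when none).
#'
#' @seealso \code{\link{shrunkenCovariance}}, \code{\link{optimalShrinkageLambda}}
#' @export
setClass("ShrinkageEstimate",
  representation(S = "matrix", lambda = "numeric", SigmaHat = "matrix",
                 droppedGenes = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@lambda < 0 || object@lambda > 1)
      msg <- c(msg, "lambda must lie in [0, 1]")
    if (!all(dim(object@S) == dim(object@SigmaHat)))
      msg <- c(msg, "S and SigmaHat dimensions differ")
    if (max(abs(diag(object@SigmaHat) - diag(object@S))) > 1e-10)
      msg <- c(msg, "shrinkage must preserve the diagonal of S")
    if (length(msg)) msg else TRUE
  }
)

#' EntropyComparison: subsampled two-group entropy comparison
#'
#' Result of the equal-size subsampling protocol: B draws, each subsampling
#' the same number of samples from both groups, estimating a shrinkage
#' weight, and recording each group's log-determinant entropy.
#'
#' @slot draws data.frame with columns draw, group, entropy, lambda.
#' @slot groupLevels character; the two group labels, in factor order.
#' @slot nSub integer; per-group subsample size.
#' @slot B integer; number of subsample draws.
#' @slot frac numeric; subsampling fraction of the smaller group.
#' @slot convention character; entropy convention used.
#'
#' @seealso \code{\link{compareGroupEntropy}}
#' @export
setClass("EntropyComparison",
  representation(draws = "data.frame", groupLevels = "character",
                 nSub = "integer", B = "integer", frac = "numeric",
                 convention = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@groupLevels) != 2)
      msg <- c(msg, "exactly two group levels expected")
    if (nrow(object@draws) != 2L * object@B)
      msg <- c(msg, "draws must contain exactly B entropy values per group")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "ConcentrationModel", function(object) {
  p <- nrow(object@K)
  ne <- sum(abs(object@K[upper.tri(object@K)]) > 1e-12)
  kind <- if (inherits(object@graph, "igraph"))
    igraph::graph_attr(object@graph, "kind") else "custom"
  cat(sprintf("ConcentrationModel: %d nodes, %d edges (%s topology)\n",
              p, ne, if (is.null(kind)) "custom" else kind))
  cat(sprintf("  entropy log|Sigma| = %.4f\n", logDet(object@Sigma)))
})

setMethod("show", "GaussianMixture", function(object) {
  cat(sprintf("GaussianMixture: %d components in %d dimensions\n",
              length(object@tau), length(object@mu[[1]])))
  cat("  weights:", paste(signif(object@tau, 4), collapse = ", "), "\n")
})

setMethod("show", "RegulatorModel", function(object) {
  p <- nrow(object@Theta)
  offdiag <- object@Theta; diag(offdiag) <- 0
  cat(sprintf("RegulatorModel: %d genes, %d directed gene-gene effects\n",
              p, sum(abs(offdiag) > 1e-12)))
  cat(sprintf("  mean |beta| = %.3f, copy-number variance present: %s\n",
              mean(abs(object@beta)), any(object@VarX != 0)))
})

setMethod("show", "VARProcess", function(object) {
  cat(sprintf("VARProcess: %d genes%s\n", nrow(object@A),
              if (is.na(object@tau)) "" else sprintf(", disturbance at t = %d", object@tau)))
})

setMethod("show", "BlockPartialCorrelation", function(object) {
  cat(sprintf("BlockPartialCorrelation: %d nodes in %d blocks, gamma = [%s]\n",
              nrow(object@OmegaBase), length(object@blocks),
              paste(signif(object@gamma, 3), collapse = ", ")))
})

setMethod("show", "ShrinkageEstimate", function(object) {
  cat(sprintf("ShrinkageEstimate: p = %d, lambda = %.4f\n",
              nrow(object@SigmaHat), object@lambda))
  if (length(object@droppedGenes))
    cat("  dropped zero-variance genes:",
        paste(object@droppedGenes, collapse = ", "), "\n")
})

setMethod("show", "EntropyComparison", function(object) {
  s <- entropySummary(object)
  cat(sprintf("EntropyComparison: %d draws, n_sub = %d per group\n",
              object@B, object@nSub))
  cat(sprintf("  median entropy  %s: %.4f   %s: %.4f\n",
              object@groupLevels[1], s$medians[1],
              object@groupLevels[2], s$medians[2]))
  cat(sprintf("  fraction of draws with %s < %s: %.3f\n",
              object@groupLevels[1], object@groupLevels[2], s$fracFirstLower))
})
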