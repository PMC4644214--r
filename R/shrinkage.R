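# Shrinkage covariance estimation, log-determinant entropy, and the
# equal-size subsampled two-group entropy comparison protocol.

#' Unbiased sample covariance
#'
#' Column-centers the data and returns the (n - 1)-denominator covariance.
#' Constant columns are allowed; their indices are attached as attribute
#' \code{"zeroVariance"}.
#'
#' @param data numeric matrix, samples in rows, genes in columns; n >= 2.
#' @return symmetric covariance matrix with attribute \code{zeroVariance}.
#' @export
sampleCovariance <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 2) stop("at least two samples are required", call. = FALSE)
  if (anyNA(data)) stop("missing values are not supported", call. = FALSE)
  X <- scale(data, center = TRUE, scale = FALSE)
  S <- symmetrize(crossprod(X) / (n - 1))
  attr(S, "zeroVariance") <- which(diag(S) < .Machine$double.eps * n)
  S
}

#' MSE-optimal shrinkage weight for a diagonal target
#'
#' Estimates the weight lambda of the convex-combination covariance
#' estimator (1 - lambda) S + lambda diag(S) that minimizes the estimated
#' sum of element-wise mean squared errors. With the target matching the
#' diagonal of S exactly, the diagonal terms cancel and
#' lambda = sum_{i != j} Varhat(s_ij) / sum_{i != j} s_ij^2, clipped to
#' [0, 1], with Varhat the standard unbiased estimate of the sampling
#' variance of a covariance entry. Returns 1 when all off-diagonal entries
#' of S are zero.
#'
#' @param data numeric matrix, samples in rows; n >= 3.
#' @return shrinkage weight in [0, 1].
#' @export
optimalShrinkageLambda <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (n < 3) stop("at least three samples are required to estimate lambda",
                  call. = FALSE)
  X <- scale(data, center = TRUE, scale = FALSE)
  S <- crossprod(X) / (n - 1)
  # Var-hat of s_ij: n / (n-1)^3 * sum_t (w_tij - wbar_ij)^2 with
  # w_tij = x_ti x_tj; sum_t w^2 = (X^2)'(X^2), wbar = (n-1)/n * S.
  M2 <- crossprod(X^2)
  wbar <- S * (n - 1) / n
  varS <- n / (n - 1)^3 * (M2 - n * wbar^2)
  off <- !diag(nrow(S))
  denom <- sum(S[off]^2)
  if (denom <= 0) return(1)
  min(1, max(0, sum(varS[off]) / denom))
}

#' Shrunken covariance estimate
#'
#' Computes Sigma-hat(lambda) = (1 - lambda) S + lambda T with diagonal
#' target T = diag(S); the diagonal of S is preserved for every lambda.
#' When \code{lambda} is omitted it is estimated by
#' \code{\link{optimalShrinkageLambda}}.
#'
#' @param data numeric matrix, samples in rows.
#' @param lambda shrinkage weight in [0, 1], or \code{NULL} to estimate.
#' @param dropZeroVariance drop constant genes (with a warning) before
#'   estimation; they would make the target singular. Default \code{TRUE}.
#' @return a \code{\linkS4class{ShrinkageEstimate}}.
#' @export
shrunkenCovariance <- function(data, lambda = NULL, dropZeroVariance = TRUE) {
  data <- as.matrix(data)
  S <- sampleCovariance(data)
  dropped <- attr(S, "zeroVariance")
  if (length(dropped) && dropZeroVariance) {
    warning(sprintf("dropping %d zero-variance gene(s) before shrinkage",
                    length(dropped)))
    data <- data[, -dropped, drop = FALSE]
    S <- sampleCovariance(data)
  } else {
    dropped <- integer()
  }
  if (is.null(lambda)) lambda <- optimalShrinkageLambda(data)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  Tmat <- diag(diag(S), nrow = nrow(S))
  new("ShrinkageEstimate", S = unclassMatrix(S), lambda = lambda,
      SigmaHat = symmetrize((1 - lambda) * S + lambda * Tmat),
      droppedGenes = as.integer(dropped))
}

# strip helper attributes so slots hold plain matrices
unclassMatrix <- function(S) {
  attr(S, "zeroVariance") <- NULL
  S
}

#' Gaussian log-determinant entropy
#'
#' Entropy of a p-variate normal with covariance Sigma, in either of two
#' conventions: \code{"logdet"} returns log|Sigma| (natural log), the
#' heterogeneity measure used throughout this package; \code{"differential"}
#' returns the true differential entropy p/2 log(2 pi e) + 1/2 log|Sigma|,
#' needed when comparing against mixture entropies. Computed via Cholesky
#' factorization, never a raw determinant.
#'
#' @param Sigma symmetric PD covariance matrix.
#' @param convention \code{"logdet"} (default) or \code{"differential"}.
#' @return entropy value (natural log units).
#' @examples
#' gaussianEntropy(diag(2))                    # 0
#' gaussianEntropy(diag(2), "differential")    # log(2*pi*e)
#' @export
gaussianEntropy <- function(Sigma, convention = c("logdet", "differential")) {
  convention <- match.arg(convention)
  Sigma <- as.matrix(Sigma)
  stopIfNot(isSymmetric2(Sigma), "Sigma must be symmetric")
  ld <- logDet(Sigma)
  if (convention == "logdet") ld
  else 0.5 * nrow(Sigma) * log(2 * pi * exp(1)) + 0.5 * ld
}

#' Two-group entropy comparison by equal-size subsampling
#'
#' Compares the transcriptomic entropy of two groups while neutralizing
#' their sample-size difference: both groups are repeatedly subsampled
#' without replacement to the same size (a fraction \code{frac} of the
#' smaller group), a shrinkage weight is estimated from the subsampled
#' data, and each group's entropy is computed as log|Sigma-hat(lambda)| of
#' its shrunken covariance.
#'
#' @param data numeric matrix, samples in rows, genes in columns.
#' @param labels two-level factor (or coercible) of length nrow(data).
#' @param B number of subsample draws (default 500).
#' @param frac subsample size as a fraction of the smaller group
#'   (default 0.9); the per-group size is \code{floor(frac * min(n1, n2))}.
#' @param seed integer seed; each draw uses an independent substream.
#' @param convention entropy convention, see \code{\link{gaussianEntropy}}.
#' @param lambdaMode \code{"pooled"} (default): one lambda per draw,
#'   estimated from the per-group-centered pooled subsample and shared by
#'   both groups; \code{"pergroup"}: a separate lambda per group.
#'
#' @return an \code{\linkS4class{EntropyComparison}}; see
#'   \code{\link{entropySummary}} and \code{\link{entropyDraws}}.
#'
#' @details Genes with zero within-group variance are dropped (with a
#' warning) before subsampling since they make the shrinkage target
#' singular.
#' @export
compareGroupEntropy <- function(data, labels, B = 500, frac = 0.9,
                                seed = NULL,
                                convention = c("logdet", "differential"),
                                lambdaMode = c("pooled", "pergroup")) {
  convention <- match.arg(convention)
  lambdaMode <- match.arg(lambdaMode)
  data <- as.matrix(data)
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must have exactly two levels", call. = FALSE)
  stopIfNot(length(labels) == nrow(data), "labels must match rows of data")
  lev <- levels(labels)
  idxList <- split(seq_len(nrow(data)), labels)
  nMin <- min(lengths(idxList))
  nSub <- floor(frac * nMin)
  if (nSub < 3)
    stop("groups too small for the requested subsampling fraction", call. = FALSE)

  # drop genes constant within either group: singular shrinkage target
  zv <- unique(unlist(lapply(idxList, function(ii) {
    v <- apply(data[ii, , drop = FALSE], 2, var)
    which(v < .Machine$double.eps * length(ii))
  })))
  if (length(zv)) {
    warning(sprintf("dropping %d zero-variance gene(s)", length(zv)))
    data <- data[, -zv, drop = FALSE]
  }

  subSeeds <- spawnSeeds(seed, B)
  draws <- vector("list", B)
  for (b in seq_len(B)) {
    draws[[b]] <- withSeed(subSeeds[b], {
      sub <- lapply(idxList, function(ii) {
        data[sample(ii, nSub), , drop = FALSE]
      })
      centered <- lapply(sub, scale, center = TRUE, scale = FALSE)
      if (lambdaMode == "pooled") {
        lam <- optimalShrinkageLambda(do.call(rbind, centered))
        lam <- c(lam, lam)
      } else {
        lam <- vapply(sub, optimalShrinkageLambda, numeric(1))
      }
      ent <- vapply(seq_along(sub), function(g) {
        est <- shrunkenCovariance(sub[[g]], lambda = lam[g])
        gaussianEntropy(est@SigmaHat, convention)
      }, numeric(1))
      data.frame(draw = b, group = lev, entropy = ent, lambda = lam,
                 row.names = NULL)
    })
  }
  new("EntropyComparison",
      draws = do.call(rbind, draws), groupLevels = lev,
      nSub = as.integer(nSub), B = as.integer(B), frac = frac,
      convention = convention)
}
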