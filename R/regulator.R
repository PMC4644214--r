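# The steady-state structural model Theta Y = beta o X + eps: forward
# laws, the genomic-variance sweep, the determinant inequality, sparse
# fitting with an unpenalized cis-effect, and edge-count curves.

#' Build a regulator model
#'
#' Constructs the structural model Theta Y = beta o X + eps either from an
#' explicit unit-diagonal Theta or from an undirected topology: each edge
#' receives a signed uniform weight (placed symmetrically), and the weight
#' matrix W = I - Theta is rescaled so its spectral radius stays below
#' \code{targetRadius}, which guarantees Theta is invertible.
#'
#' @param graphOrTheta an \pkg{igraph} graph or a unit-diagonal matrix.
#' @param beta cis-effect vector (default all ones).
#' @param sigmaEps error covariance (default 0.3 * I, the simulation
#'   default used throughout).
#' @param varX copy-number covariance (default the zero matrix: no genomic
#'   variation).
#' @param weightLow,weightHigh edge-weight magnitude range for graph input.
#' @param targetRadius cap on the spectral radius of I - Theta
#'   (default 0.5).
#' @param seed integer seed for the weight draw.
#' @return a \code{\linkS4class{RegulatorModel}}.
#' @export
buildRegulatorModel <- function(graphOrTheta, beta = NULL, sigmaEps = NULL,
                                varX = NULL, weightLow = 0.3,
                                weightHigh = 0.7, targetRadius = 0.5,
                                seed = NULL) {
  if (inherits(graphOrTheta, "igraph")) {
    p <- igraph::vcount(graphOrTheta)
    el <- igraph::as_edgelist(graphOrTheta, names = FALSE)
    W <- matrix(0, p, p)
    if (nrow(el) > 0) {
      w <- withSeed(seed, {
        runif(nrow(el), weightLow, weightHigh) *
          sample(c(-1, 1), nrow(el), replace = TRUE)
      })
      W[el] <- w
      W[el[, c(2, 1), drop = FALSE]] <- w
    }
    rho <- max(abs(eigen(W, only.values = TRUE)$values))
    if (rho > targetRadius) W <- W * (targetRadius / rho)
    Theta <- diag(p) - W
  } else {
    Theta <- as.matrix(graphOrTheta)
    p <- nrow(Theta)
  }
  if (is.null(beta)) beta <- rep(1, p)
  if (is.null(sigmaEps)) sigmaEps <- 0.3 * diag(p)
  if (is.null(varX)) varX <- matrix(0, p, p)
  new("RegulatorModel", Theta = Theta, beta = as.numeric(beta),
      SigmaEps = as.matrix(sigmaEps), VarX = as.matrix(varX))
}

#' Conditional law of expression given copy number
#'
#' Y | X = x is normal with mean Theta^{-1} (beta o x) and covariance
#' Theta^{-1} SigmaEps Theta^{-T}.
#'
#' @param model a \code{\linkS4class{RegulatorModel}}.
#' @param x copy-number vector of length p.
#' @return list with \code{mean} and \code{cov}.
#' @export
conditionalLaw <- function(model, x) {
  p <- nrow(model@Theta)
  stopIfNot(length(x) == p, "x must have length p")
  Thinv <- solve(model@Theta)
  list(mean = as.numeric(Thinv %*% (model@beta * x)),
       cov = symmetrize(Thinv %*% model@SigmaEps %*% t(Thinv)))
}

#' Unconditional variance of expression
#'
#' Var(Y) = [Theta^{-1} o (1 beta^T)] Var(X) [Theta^{-1} o (1 beta^T)]^T
#' + Theta^{-1} SigmaEps Theta^{-T}; the Hadamard factor scales column k
#' of Theta^{-1} by beta_k.
#'
#' @param model a \code{\linkS4class{RegulatorModel}}.
#' @return symmetric PD covariance of Y.
#' @export
unconditionalVariance <- function(model) {
  Thinv <- solve(model@Theta)
  M <- Thinv %*% diag(model@beta, nrow = length(model@beta))
  symmetrize(M %*% model@VarX %*% t(M) +
             Thinv %*% model@SigmaEps %*% t(Thinv))
}

#' Per-node genomic-variance sweep
#'
#' Starting from a model with no genomic variation, the copy-number
#' variance of one node at a time is raised to \code{v} (all others kept
#' at zero) and the resulting transcriptomic entropy H_j = log|Var(Y)| is
#' recorded, together with the baseline H0 (Var(X) = 0) and the increments
#' delta H_j. With beta = 1 and SigmaEps = sigma^2 I the increment is
#' log(1 + v beta_j^2 / sigma^2), identical for every node regardless of
#' its connectivity: the system is closed and at equilibrium, so injected
#' variation stays in it wherever it enters.
#'
#' @param model a \code{\linkS4class{RegulatorModel}} (its VarX is ignored;
#'   the sweep uses v e_j e_j^T).
#' @param v variance injected at the swept node (default 1).
#' @param nodes nodes to sweep (default all).
#' @return list with \code{H0} and a data.frame (node, H, deltaH).
#' @export
genomicVarianceSweep <- function(model, v = 1, nodes = NULL) {
  stopIfNot(v >= 0, "v must be nonnegative")
  p <- nrow(model@Theta)
  if (is.null(nodes)) nodes <- seq_len(p)
  Thinv <- solve(model@Theta)
  base <- symmetrize(Thinv %*% model@SigmaEps %*% t(Thinv))
  H0 <- logDet(base)
  M <- Thinv %*% diag(model@beta, nrow = p)
  H <- vapply(nodes, function(j) {
    logDet(base + v * tcrossprod(M[, j]))
  }, numeric(1))
  list(H0 = H0, sweep = data.frame(node = nodes, H = H, deltaH = H - H0))
}

#' Determinant inequality for the unconditional variance
#'
#' Numerically verifies det[Var(Y)] >= det(Theta^{-1} SigmaEps Theta^{-T})
#' (adding the PSD copy-number term cannot shrink the determinant), with
#' equality exactly when Var(beta o X) vanishes.
#'
#' @param model a \code{\linkS4class{RegulatorModel}}.
#' @param tol tolerance for the equality flag.
#' @return list with both log-determinants, \code{holds}, and
#'   \code{equalityExpected}.
#' @export
detInequalityCheck <- function(model, tol = 1e-8) {
  Thinv <- solve(model@Theta)
  base <- symmetrize(Thinv %*% model@SigmaEps %*% t(Thinv))
  ldBase <- logDet(base)
  ldFull <- logDet(unconditionalVariance(model))
  D <- diag(model@beta, nrow = length(model@beta))
  varBX <- D %*% model@VarX %*% D
  list(logDetVarY = ldFull, logDetBase = ldBase,
       holds = ldFull >= ldBase - tol,
       equalityExpected = max(abs(varBX)) < tol,
       equalityObserved = abs(ldFull - ldBase) < tol)
}

#' Simulate paired copy-number and expression data
#'
#' Draws X ~ N(0, VarX) and eps ~ N(0, SigmaEps) and solves the structural
#' equations for Y = Theta^{-1}(beta o X + eps).
#'
#' @param model a \code{\linkS4class{RegulatorModel}}.
#' @param n number of samples.
#' @param seed integer seed.
#' @return a \code{SummarizedExperiment} with gene-by-sample assays
#'   \code{copyNumber} and \code{expression}; the generating model is kept
#'   in \code{metadata()$model}.
#' @export
simulatePaired <- function(model, n, seed = NULL) {
  stopIfNot(n >= 1, "n must be at least 1")
  p <- nrow(model@Theta)
  withSeed(seed, {
    X <- rmvn(n, rep(0, p), model@VarX)
    E <- rmvn(n, rep(0, p), model@SigmaEps)
    Y <- t(solve(model@Theta, t(X %*% diag(model@beta, nrow = p) + E)))
    genes <- sprintf("g%03d", seq_len(p))
    samples <- sprintf("s%04d", seq_len(n))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(copyNumber = t(`dimnames<-`(X, list(samples, genes))),
                    expression = t(`dimnames<-`(Y, list(samples, genes)))),
      metadata = list(model = model))
  })
}

#' Extract sample-by-gene matrices from a paired experiment
#'
#' @param x a \code{SummarizedExperiment} produced by
#'   \code{\link{simulatePaired}} or \code{\link{generateCohort}}.
#' @return numeric matrix, samples in rows.
#' @export
expressionMatrix <- function(x) t(SummarizedExperiment::assay(x, "expression"))

#' @rdname expressionMatrix
#' @export
copyNumberMatrix <- function(x) t(SummarizedExperiment::assay(x, "copyNumber"))

# Fit one structural equation: lasso of y on Z with penalty factors pf
# evaluated at lambdaGrid (decreasing); returns coefficient matrix
# ncol(Z) x length(lambdaGrid).
fitOneEquation <- function(Z, y, pf, lambdaGrid) {
  ord <- order(lambdaGrid, decreasing = TRUE)
  grid <- lambdaGrid[ord]
  # pad the path upward for glmnet's warm starts
  path <- sort(unique(c(grid, max(grid) * c(8, 4, 2))), decreasing = TRUE)
  fit <- glmnet::glmnet(Z, y, family = "gaussian", alpha = 1,
                        lambda = path, penalty.factor = pf,
                        standardize = TRUE, intercept = TRUE,
                        thresh = 1e-12)
  cf <- as.matrix(coef(fit, s = grid, exact = FALSE))[-1L, , drop = FALSE]
  # back to the caller's lambda order
  cf[, order(ord), drop = FALSE]
}

#' Fit the structural model by equation-wise penalized least squares
#'
#' For each gene j, fits a lasso regression of Y_j on the other genes with
#' penalty \code{lambda1} on their coefficients, while the gene's own
#' copy number X_j enters as an unpenalized covariate (the cis-effect).
#' Rows of the estimated Theta carry the sign convention
#' Y_j = -sum_{k != j} Theta_jk Y_k + beta_j X_j + eps_j with unit
#' diagonal. With \code{expressionOnly = TRUE} the copy-number term is
#' dropped, giving a neighborhood-selection fit of the partial-correlation
#' graph from expression alone.
#'
#' @param X n x p copy-number matrix (ignored when
#'   \code{expressionOnly = TRUE}).
#' @param Y n x p expression matrix.
#' @param lambda1 nonnegative penalty (on the scale of
#'   \code{glmnet}, i.e. the 1/(2n) residual-sum-of-squares objective).
#' @param expressionOnly drop the copy-number covariate.
#' @param rule edge symmetrization for the support: \code{"or"} (default)
#'   marks an edge when either directed coefficient is nonzero,
#'   \code{"and"} when both are.
#' @return list with \code{Theta} (p x p, unit diagonal), \code{beta}
#'   (zeros when \code{expressionOnly}), \code{support} (symmetric logical
#'   p x p), \code{edges} (edge count), \code{lambda1}, \code{rule}.
#' @export
fitRegulator <- function(X, Y, lambda1, expressionOnly = FALSE,
                         rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopIfNot(lambda1 >= 0, "lambda1 must be nonnegative")
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  stopIfNot(n >= 3, "at least three samples are required")
  if (!expressionOnly) {
    X <- as.matrix(X)
    stopIfNot(all(dim(X) == dim(Y)), "X and Y must have identical shape")
  }
  Theta <- diag(p)
  beta <- numeric(p)
  for (j in seq_len(p)) {
    if (expressionOnly) {
      Z <- Y[, -j, drop = FALSE]
      pf <- rep(1, p - 1)
    } else {
      Z <- cbind(Y[, -j, drop = FALSE], X[, j])
      pf <- c(rep(1, p - 1), 0)
    }
    cf <- fitOneEquation(Z, Y[, j], pf, lambda1)[, 1L]
    Theta[j, -j] <- -cf[seq_len(p - 1)]
    if (!expressionOnly) beta[j] <- cf[p]
  }
  support <- supportFromTheta(Theta, rule)
  list(Theta = Theta, beta = beta, support = support,
       edges = sum(support[upper.tri(support)]), lambda1 = lambda1,
       rule = rule)
}

supportFromTheta <- function(Theta, rule = "or", tol = 1e-12) {
  nz <- abs(Theta) > tol
  diag(nz) <- FALSE
  s <- if (rule == "or") nz | t(nz) else nz & t(nz)
  diag(s) <- FALSE
  s
}

#' Refit the structural model on a fixed support
#'
#' Ordinary least squares per equation, restricted to the selected edges,
#' with the copy-number covariate always included and unpenalized; entries
#' outside the support are exactly zero. This removes the shrinkage bias
#' the penalty puts on the selected coefficients.
#'
#' @param X n x p copy-number matrix (or \code{NULL} with
#'   \code{expressionOnly = TRUE}).
#' @param Y n x p expression matrix.
#' @param support symmetric logical p x p edge indicator, e.g. from
#'   \code{\link{fitRegulator}}.
#' @param expressionOnly drop the copy-number covariate.
#' @return list with \code{Theta} and \code{beta}.
#' @export
refitSupport <- function(X, Y, support, expressionOnly = FALSE) {
  Y <- as.matrix(Y)
  n <- nrow(Y); p <- ncol(Y)
  Theta <- diag(p)
  beta <- numeric(p)
  for (j in seq_len(p)) {
    sel <- which(support[j, ])
    Z <- Y[, sel, drop = FALSE]
    if (!expressionOnly) Z <- cbind(Z, X[, j])
    if (ncol(Z) >= n)
      stop("selected covariates must be fewer than samples", call. = FALSE)
    Z1 <- cbind(1, Z)
    qrz <- qr(Z1)
    if (qrz$rank < ncol(Z1)) {
      warning("rank-deficient refit equation; using pseudo-inverse")
      cf <- as.numeric(MASS::ginv(Z1) %*% Y[, j])
    } else {
      cf <- qr.coef(qrz, Y[, j])
    }
    cf <- cf[-1L]
    if (length(sel)) Theta[j, sel] <- -cf[seq_along(sel)]
    if (!expressionOnly) beta[j] <- cf[length(cf)]
  }
  list(Theta = Theta, beta = beta)
}

# Count symmetrized edges per lambda for one data set.
edgeCountsAtGrid <- function(X, Y, lambdaGrid, expressionOnly, rule = "or") {
  p <- ncol(Y)
  nl <- length(lambdaGrid)
  nz <- array(FALSE, c(p, p, nl))
  for (j in seq_len(p)) {
    if (expressionOnly) {
      Z <- Y[, -j, drop = FALSE]; pf <- rep(1, p - 1)
    } else {
      Z <- cbind(Y[, -j, drop = FALSE], X[, j]); pf <- c(rep(1, p - 1), 0)
    }
    cf <- fitOneEquation(Z, Y[, j], pf, lambdaGrid)
    for (l in seq_len(nl)) nz[j, -j, l] <- abs(cf[seq_len(p - 1), l]) > 1e-12
  }
  vapply(seq_len(nl), function(l) {
    s <- if (rule == "or") nz[, , l] | t(nz[, , l]) else nz[, , l] & t(nz[, , l])
    sum(s[upper.tri(s)])
  }, numeric(1))
}

#' Choose a penalty grid spanning the sparse-network window
#'
#' Scans a wide log-spaced candidate path on the full data set and returns
#' grid values whose fitted edge density falls in the
#' \code{window} band (default 1-10 percent of the p(p-1)/2 possible
#' edges), the range held to be biologically plausible for gene-gene
#' interaction networks. The grid is global for a data set, not per
#' subsample draw.
#'
#' @param X,Y data matrices as in \code{\link{fitRegulator}}.
#' @param nGrid number of grid points returned (default 8).
#' @param window density band (default \code{c(0.01, 0.10)}).
#' @param expressionOnly drop the copy-number covariate.
#' @return numeric vector of penalties, decreasing.
#' @export
autoLambdaGrid <- function(X, Y, nGrid = 8, window = c(0.01, 0.10),
                           expressionOnly = FALSE) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  capacity <- p * (p - 1) / 2
  # candidate path from the data scale downward
  lmax <- maxAbsInnerProduct(X, Y, expressionOnly)
  cand <- exp(seq(log(lmax), log(lmax / 500), length.out = 40))
  counts <- edgeCountsAtGrid(X, Y, cand, expressionOnly)
  dens <- counts / capacity
  inWin <- which(dens >= window[1] & dens <= window[2])
  if (!length(inWin)) {
    # fall back to the closest grid region
    inWin <- order(abs(dens - mean(window)))[seq_len(min(4, length(cand)))]
  }
  lo <- min(cand[inWin]); hi <- max(cand[inWin])
  if (lo == hi) { lo <- lo / 1.5; hi <- hi * 1.5 }
  sort(exp(seq(log(hi), log(lo), length.out = nGrid)), decreasing = TRUE)
}

maxAbsInnerProduct <- function(X, Y, expressionOnly) {
  Yc <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  n <- nrow(Yc)
  mx <- 0
  for (j in seq_len(ncol(Yc))) {
    v <- abs(crossprod(Yc[, -j, drop = FALSE], Yc[, j])) / n
    mx <- max(mx, v)
  }
  mx
}

#' Edge counts along the penalty path for two groups
#'
#' The subsampled counterpart of the sparse fit: for each of B draws both
#' groups are subsampled to the same size, the structural model (or the
#' expression-only neighborhood-selection fit) is fitted along the penalty
#' grid, and the symmetrized edge count is recorded. Counts are averaged
#' over draws per group and penalty, and flagged when their density lies
#' in the sparse-network window.
#'
#' @param X n x p copy-number matrix (or \code{NULL}).
#' @param Y n x p expression matrix.
#' @param labels two-level factor of length n.
#' @param lambdaGrid penalties; \code{NULL} (default) selects a global
#'   grid with \code{\link{autoLambdaGrid}} on the pooled data.
#' @param B subsample draws per group (default 50).
#' @param frac subsample fraction of the smaller group (default 0.9).
#' @param seed integer seed.
#' @param expressionOnly drop the copy-number covariate.
#' @param window sparse-network density band (default 1-10 percent).
#' @return data.frame (lambda, group, meanEdges, inWindow) with attribute
#'   \code{"capacity"} = p(p-1)/2.
#' @export
edgeCountCurve <- function(X = NULL, Y, labels, lambdaGrid = NULL, B = 50,
                           frac = 0.9, seed = NULL, expressionOnly = is.null(X),
                           window = c(0.01, 0.10)) {
  Y <- as.matrix(Y)
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must have exactly two levels", call. = FALSE)
  p <- ncol(Y)
  capacity <- p * (p - 1) / 2
  idxList <- split(seq_len(nrow(Y)), labels)
  nSub <- floor(frac * min(lengths(idxList)))
  stopIfNot(nSub >= 4, "groups too small for the requested fraction")
  if (is.null(lambdaGrid))
    lambdaGrid <- autoLambdaGrid(X, Y, expressionOnly = expressionOnly,
                                 window = window)
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
  subSeeds <- spawnSeeds(seed, B)
  acc <- matrix(0, length(lambdaGrid), 2)
  for (b in seq_len(B)) {
    counts <- withSeed(subSeeds[b], {
      vapply(seq_along(idxList), function(g) {
        ii <- sample(idxList[[g]], nSub)
        edgeCountsAtGrid(if (is.null(X)) NULL else X[ii, , drop = FALSE],
                         Y[ii, , drop = FALSE], lambdaGrid, expressionOnly)
      }, numeric(length(lambdaGrid)))
    })
    acc <- acc + counts
  }
  acc <- acc / B
  out <- data.frame(
    lambda = rep(lambdaGrid, 2),
    group = rep(levels(labels), each = length(lambdaGrid)),
    meanEdges = c(acc[, 1], acc[, 2]))
  out$inWindow <- out$meanEdges / capacity >= window[1] &
    out$meanEdges / capacity <= window[2]
  attr(out, "capacity") <- capacity
  out
}

#' Compare the two groups' edge-count curves in the sparse window
#'
#' Restricts an \code{\link{edgeCountCurve}} result to the penalties at
#' which at least one group's fitted density lies in the sparse window
#' (the same penalty set for both groups, so the comparison is not
#' confounded by per-group window membership) and averages each group's
#' counts over it.
#'
#' @param curve result of \code{\link{edgeCountCurve}}.
#' @return list with \code{means} (named per group over the shared window
#'   penalties), \code{lambdaWindow}, and \code{secondLower} (whether the
#'   second group's mean count is the lower one).
#' @export
edgeCurveComparison <- function(curve) {
  lamW <- unique(curve$lambda[curve$inWindow])
  if (!length(lamW)) lamW <- unique(curve$lambda)
  w <- curve[curve$lambda %in% lamW, ]
  means <- tapply(w$meanEdges, w$group, mean)
  groups <- unique(curve$group)
  means <- means[groups]
  list(means = means, lambdaWindow = lamW,
       secondLower = unname(means[2] < means[1]))
}
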