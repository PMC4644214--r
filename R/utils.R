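# Internal helpers shared across modules.

#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif cor median sd var quantile coef lm filter
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. seed = NULL leaves the RNG untouched.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has.old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has.old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has.old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Spawn `n` child seeds from a parent seed (kept < 2^31).
spawnSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

symmetrize <- function(M) (M + t(M)) / 2

isSymmetric2 <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol * max(1, max(abs(M)))
}

# Stable log-determinant of a symmetric positive-definite matrix via Cholesky.
# Errors (naming the offending eigenvalue) when the matrix is not PD.
logDet <- function(Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(symmetrize(Sigma), symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf("matrix is not positive definite (smallest eigenvalue %.4e)",
                 min(ev)), call. = FALSE)
  }
  2 * sum(log(diag(ch)))
}

isPD <- function(M, tol = 1e-10) {
  isSymmetric2(M) && !inherits(tryCatch(chol(M), error = function(e) e), "error")
}

# Inverse of a symmetric PD matrix via Cholesky.
pdInverse <- function(M) {
  S <- chol2inv(chol(M))
  dimnames(S) <- dimnames(M)
  symmetrize(S)
}

# Multivariate normal draws; returns an n x p matrix even for n = 1 or p = 1.
rmvn <- function(n, mu, Sigma) {
  p <- length(mu)
  if (all(Sigma == 0)) {
    return(matrix(rep(mu, each = n), nrow = n))
  }
  out <- MASS::mvrnorm(n = n, mu = mu, Sigma = Sigma)
  if (n == 1L) out <- matrix(out, nrow = 1L)
  out
}

# Row-wise log-density of N(mu, Sigma) evaluated at the rows of X, computed
# through the Cholesky factor (no explicit inverse or determinant).
logDmvnorm <- function(X, mu, Sigma) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  p <- ncol(X)
  ch <- chol(Sigma)
  centered <- sweep(X, 2L, mu, "-")
  z <- backsolve(ch, t(centered), transpose = TRUE)
  -0.5 * p * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

matrixPower <- function(A, k) {
  p <- nrow(A)
  out <- diag(p)
  if (k == 0L) return(out)
  base <- A
  while (k > 0L) {
    if (k %% 2L == 1L) out <- out %*% base
    k <- k %/% 2L
    if (k > 0L) base <- base %*% base
  }
  out
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
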