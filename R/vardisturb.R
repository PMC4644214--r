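# VAR(1) expression dynamics, the one-time disturbance model, entropy
# trajectories and the disturbance-ordering checks.

#' Construct a VAR(1) process
#'
#' Y_t = nu + A Y_{t-1} + eps_t with eps_t ~ N(0, SigmaEps) independent
#' across time and Y_0 = 0. A disturbance delta ~ N(0, SigmaDelta) can be
#' injected once, at time \code{tau}; the disturbed process recurses on
#' its own past, so the shock propagates through A (the only reading under
#' which a disturbance increases entropy at later times; see the package
#' vignette).
#'
#' Stability of A is deliberately not enforced: with Y_0 = 0 and finite
#' horizons, non-stationary dynamics are well defined.
#'
#' @param A p x p coefficient matrix.
#' @param sigmaEps innovation covariance (default I).
#' @param sigmaDelta disturbance covariance (default I).
#' @param nu intercept (default 0; affects means only, never entropies).
#' @param tau disturbance time point, or \code{NA} for none.
#' @return a \code{\linkS4class{VARProcess}}.
#' @export
varProcess <- function(A, sigmaEps = NULL, sigmaDelta = NULL, nu = NULL,
                       tau = NA) {
  A <- as.matrix(A)
  p <- nrow(A)
  if (is.null(sigmaEps)) sigmaEps <- diag(p)
  if (is.null(sigmaDelta)) sigmaDelta <- diag(p)
  if (is.null(nu)) nu <- rep(0, p)
  new("VARProcess", nu = as.numeric(nu), A = A,
      SigmaEps = as.matrix(sigmaEps), SigmaDelta = as.matrix(sigmaDelta),
      tau = as.numeric(tau))
}

#' Marginal covariance of a VAR(1) at time t
#'
#' Undisturbed: the recursion V_t = A V_{t-1} A^T + SigmaEps from V_0 = 0.
#' Disturbed at tau <= t: V_t + A^{t - tau} SigmaDelta (A^{t - tau})^T,
#' the shock covariance propagated forward by the dynamics.
#'
#' @param process a \code{\linkS4class{VARProcess}}.
#' @param t time point, >= 1.
#' @param tau disturbance time (defaults to the process slot; \code{NA}
#'   for none).
#' @return p x p covariance matrix.
#' @export
varCovariance <- function(process, t, tau = process@tau) {
  stopIfNot(t >= 1 && t == round(t), "t must be a positive integer")
  if (!is.na(tau) && tau > t)
    stop("tau must not exceed t", call. = FALSE)
  A <- process@A
  V <- matrix(0, nrow(A), ncol(A))
  for (s in seq_len(t)) V <- A %*% V %*% t(A) + process@SigmaEps
  if (!is.na(tau)) {
    Ak <- matrixPower(A, as.integer(t - tau))
    V <- V + Ak %*% process@SigmaDelta %*% t(Ak)
  }
  symmetrize(V)
}

#' Simulate a VAR(1) path
#'
#' Iterates the recursion from Y_0 = 0. When \code{sharedInnovationsWith}
#' is a previous run, its innovation draws are reused so a disturbed /
#' undisturbed pair differs only by the one-time shock (the paired design
#' used for perturbation illustrations).
#'
#' @param process a \code{\linkS4class{VARProcess}}.
#' @param horizon number of time points.
#' @param seed integer seed.
#' @param disturb inject the disturbance at \code{process@tau}
#'   (default: whenever tau is set).
#' @param sharedInnovationsWith a previous \code{simulateVAR} result whose
#'   innovations to reuse.
#' @param delta optional fixed disturbance vector (otherwise drawn from
#'   N(0, SigmaDelta); when innovations are shared, the shared run's delta
#'   draw is NOT reused -- the disturbance is this run's own).
#' @return horizon x p matrix of class \code{"varPath"} with attributes
#'   \code{innovations} (horizon x p) and \code{delta}.
#' @export
simulateVAR <- function(process, horizon, seed = NULL,
                        disturb = !is.na(process@tau),
                        sharedInnovationsWith = NULL, delta = NULL) {
  stopIfNot(horizon >= 1, "horizon must be at least 1")
  p <- nrow(process@A)
  tau <- process@tau
  if (disturb && (is.na(tau) || tau > horizon))
    stop("disturbance requested but tau is unset or beyond the horizon",
         call. = FALSE)
  withSeed(seed, {
    # draw innovations unconditionally so the RNG stream position (and
    # hence the delta draw below) is the same with or without sharing
    E <- rmvn(horizon, rep(0, p), process@SigmaEps)
    if (!is.null(sharedInnovationsWith))
      E <- attr(sharedInnovationsWith, "innovations")
    if (disturb && is.null(delta))
      delta <- as.numeric(rmvn(1, rep(0, p), process@SigmaDelta))
    Y <- matrix(0, horizon, p)
    prev <- rep(0, p)
    for (t in seq_len(horizon)) {
      yt <- process@nu + as.numeric(process@A %*% prev) + E[t, ]
      if (disturb && t == tau) yt <- yt + delta
      Y[t, ] <- yt
      prev <- yt
    }
    attr(Y, "innovations") <- E
    attr(Y, "delta") <- if (disturb) delta else NULL
    class(Y) <- c("varPath", class(Y))
    Y
  })
}

#' Draws of Y_t across many independent paths
#'
#' Vectorized forward sampler used to check the analytic covariance
#' recursion by simulation: returns \code{nPaths} independent draws of the
#' state at time t (disturbed at \code{tau} when given).
#'
#' @param process a \code{\linkS4class{VARProcess}}.
#' @param t time point.
#' @param nPaths number of independent paths.
#' @param seed integer seed.
#' @param tau disturbance time or \code{NA}.
#' @return nPaths x p matrix of Y_t draws.
#' @export
simulateVarEnsemble <- function(process, t, nPaths, seed = NULL,
                                tau = process@tau) {
  p <- nrow(process@A)
  withSeed(seed, {
    Y <- matrix(0, nPaths, p)
    for (s in seq_len(t)) {
      E <- rmvn(nPaths, rep(0, p), process@SigmaEps)
      Y <- Y %*% t(process@A) + E
      Y <- sweep(Y, 2L, process@nu, "+")
      if (!is.na(tau) && s == tau)
        Y <- Y + rmvn(nPaths, rep(0, p), process@SigmaDelta)
    }
    Y
  })
}

# Stacked covariance of (Y_1, ..., Y_t): block (s, u) is
# sum_{i<=min(s,u)} A^{s-i} SigmaEps (A^{u-i})^T, plus the propagated
# disturbance block for s, u >= tau.
stackedCovariance <- function(process, t, tau = NA) {
  A <- process@A
  p <- nrow(A)
  pow <- vector("list", t)
  pow[[1]] <- diag(p)
  if (t > 1) for (k in 2:t) pow[[k]] <- pow[[k - 1]] %*% A
  V <- matrix(0, t * p, t * p)
  for (s in seq_len(t)) for (u in s:t) {
    blk <- matrix(0, p, p)
    for (i in seq_len(s))
      blk <- blk + pow[[s - i + 1]] %*% process@SigmaEps %*% t(pow[[u - i + 1]])
    if (!is.na(tau) && s >= tau)
      blk <- blk + pow[[s - tau + 1]] %*% process@SigmaDelta %*% t(pow[[u - tau + 1]])
    ri <- (s - 1) * p + seq_len(p)
    ci <- (u - 1) * p + seq_len(p)
    V[ri, ci] <- blk
    V[ci, ri] <- t(blk)
  }
  symmetrize(V)
}

#' Entropy trajectory of a (possibly disturbed) VAR(1)
#'
#' Log-determinant entropy at each requested time point, either of the
#' marginal law of Y_t or of the joint law of the whole path
#' (Y_1, ..., Y_t) built blockwise from the recursion.
#'
#' @param process a \code{\linkS4class{VARProcess}}.
#' @param tGrid integer time points, each >= max(1, tau).
#' @param tau disturbance time or \code{NA}.
#' @param mode \code{"marginal"} or \code{"path"}.
#' @return numeric vector of entropies, one per grid point.
#' @export
entropyTrajectory <- function(process, tGrid, tau = process@tau,
                              mode = c("marginal", "path")) {
  mode <- match.arg(mode)
  if (!is.na(tau)) stopIfNot(all(tGrid >= tau), "all t must be >= tau")
  vapply(tGrid, function(t) {
    if (mode == "marginal") logDet(varCovariance(process, t, tau))
    else logDet(stackedCovariance(process, t, tau))
  }, numeric(1))
}

#' Compare disturbance timings
#'
#' Reports the entropy of the undisturbed process and of two disturbed
#' versions at the same observation time: part (a), a disturbance strictly
#' increases entropy (guaranteed for nonsingular A, since the propagated
#' shock covariance is then PD); part (b), whether the earlier disturbance
#' yields the larger entropy. Part (b) is reported, not asserted: its
#' direction depends on the dynamics (under contractive A in marginal mode
#' it can reverse).
#'
#' @param process a \code{\linkS4class{VARProcess}}.
#' @param t observation time.
#' @param tau1,tau2 disturbance times with tau1 < tau2 <= t.
#' @param mode \code{"marginal"} or \code{"path"}.
#' @return list with the three entropies and flags \code{partA},
#'   \code{partB}.
#' @export
checkProposition2 <- function(process, t, tau1, tau2,
                              mode = c("marginal", "path")) {
  mode <- match.arg(mode)
  stopIfNot(tau1 <= tau2 && tau2 <= t, "need tau1 <= tau2 <= t")
  H0 <- entropyTrajectory(process, t, tau = NA, mode = mode)
  H1 <- entropyTrajectory(process, t, tau = tau1, mode = mode)
  H2 <- entropyTrajectory(process, t, tau = tau2, mode = mode)
  list(H = H0, Htau1 = H1, Htau2 = H2,
       partA = H1 > H0 && H2 > H0,
       partB = H1 > H2)
}

#' Paired disturbed/undisturbed demonstration series
#'
#' Generates an artificial three-gene pathway time course twice with the
#' same innovations, once with a disturbance at \code{tau}, and returns
#' gene 1's two trajectories together with a moving-average smooth --
#' the standard visualization of a one-time perturbation propagating
#' through the dynamics.
#'
#' @param seed integer seed.
#' @param p number of genes (default 3).
#' @param tau disturbance time (default 25).
#' @param horizon series length (default 50).
#' @param window moving-average window (odd, default 5).
#' @param A coefficient matrix; by default a stable chain with
#'   autoregression 0.5 and feed-forward 0.3.
#' @param sigmaEps,sigmaDelta innovation / disturbance covariances
#'   (defaults 0.25 I and 4 I).
#' @return data.frame (t, arm, value, smooth) for gene 1, arms
#'   \code{"unperturbed"} and \code{"perturbed"}.
#' @export
disturbanceDemo <- function(seed = NULL, p = 3, tau = 25, horizon = 50,
                            window = 5, A = NULL, sigmaEps = NULL,
                            sigmaDelta = NULL) {
  if (is.null(A)) {
    A <- diag(p) * 0.5
    if (p > 1) A[cbind(2:p, 1:(p - 1))] <- 0.3
  }
  if (is.null(sigmaEps)) sigmaEps <- 0.25 * diag(p)
  if (is.null(sigmaDelta)) sigmaDelta <- 4 * diag(p)
  proc <- varProcess(A, sigmaEps, sigmaDelta, tau = tau)
  base <- simulateVAR(proc, horizon, seed = seed, disturb = FALSE)
  pert <- simulateVAR(proc, horizon, seed = seed, disturb = TRUE,
                      sharedInnovationsWith = base)
  smooth <- function(x) as.numeric(stats::filter(x, rep(1 / window, window),
                                                 sides = 2))
  rbind(
    data.frame(t = seq_len(horizon), arm = "unperturbed",
               value = base[, 1], smooth = smooth(base[, 1])),
    data.frame(t = seq_len(horizon), arm = "perturbed",
               value = pert[, 1], smooth = smooth(pert[, 1])))
}
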