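# Synthetic two-group cohort generator emulating the structure of a
# paired copy-number / expression study with an ER-status-like contrast.

#' Configure a synthetic two-group cohort
#'
#' Declarative configuration for \code{\link{generateCohort}}. The two
#' groups share one base regulator model; the second group's model is
#' modified by independent, multiplicative mechanisms so each can be
#' switched on alone: its copy-number variance is scaled by
#' \code{varXScale}, its cis-effect by \code{betaScale}, and a random
#' fraction \code{1 - retention} of its gene-gene edges is removed.
#' All three mechanisms at their defaults leave the groups identically
#' distributed.
#'
#' @param p number of genes (default 30).
#' @param n1,n2 group sizes (defaults 60 and 40, the order of magnitude
#'   of typical two-group expression studies; both >= 10).
#' @param topology list with \code{kind} plus generator parameters for
#'   \code{\link{sampleTopology}}.
#' @param varXBase base per-gene copy-number variance (default 0.3).
#' @param varXScale group-2 copy-number variance multiplier (default 1).
#' @param betaScale group-2 cis-effect multiplier (default 1).
#' @param retention fraction of group-1 edges kept in group 2, in (0, 1]
#'   (default 1).
#' @param weightLow,weightHigh,targetRadius edge-weight parameters for
#'   \code{\link{buildRegulatorModel}}.
#' @param groupLabels two labels (default \code{c("ERpos", "ERneg")}).
#' @return validated configuration list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(p = 30, n1 = 60, n2 = 40,
                         topology = list(kind = "scalefree", m = 2),
                         varXBase = 0.3, varXScale = 1, betaScale = 1,
                         retention = 1, weightLow = 0.3, weightHigh = 0.7,
                         targetRadius = 0.8,
                         groupLabels = c("ERpos", "ERneg")) {
  stopIfNot(n1 >= 10 && n2 >= 10, "group sizes must be at least 10")
  stopIfNot(retention > 0 && retention <= 1, "retention must lie in (0, 1]")
  stopIfNot(varXScale > 0 && betaScale > 0 && varXBase >= 0,
            "scales must be positive")
  stopIfNot(length(groupLabels) == 2, "exactly two group labels expected")
  structure(list(p = p, n1 = n1, n2 = n2, topology = topology,
                 varXBase = varXBase, varXScale = varXScale,
                 betaScale = betaScale, retention = retention,
                 weightLow = weightLow, weightHigh = weightHigh,
                 targetRadius = targetRadius, groupLabels = groupLabels),
            class = "CohortConfig")
}

#' Generate a synthetic two-group paired cohort
#'
#' Draws a shared topology and base regulator model, derives the group-2
#' model per the configuration (scaled copy-number variance, scaled
#' cis-effect, thinned edge set), and simulates paired copy-number /
#' expression data for both groups. The generating truth -- both models,
#' their implied entropies log|Var(Y)|, and true edge counts -- is
#' attached so estimators can be scored against it.
#'
#' The error covariance of each group's structural model is coupled to
#' its network as SigmaEps = 0.3 Theta, so that
#' Var(Y | X) = 0.3 Theta^{-1} and the conditional-independence graph of
#' expression given copy number coincides exactly with the generating
#' topology (edges = nonzero partial correlations). Under this
#' parameterization each structural equation is the true conditional
#' mean of its gene given the others, which is what makes the fitted
#' edge sets and refitted cis-effects interpretable against the truth.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param seed integer seed.
#' @return a \code{SummarizedExperiment} (genes x samples, assays
#'   \code{copyNumber} and \code{expression}, \code{colData()$group}) with
#'   \code{metadata()$truth} holding \code{model1}, \code{model2},
#'   \code{entropy1}, \code{entropy2}, \code{edges1}, \code{edges2} and
#'   the topology.
#' @export
generateCohort <- function(config, seed = NULL) {
  stopIfNot(inherits(config, "CohortConfig"), "config must be a cohortConfig()")
  seeds <- spawnSeeds(seed, 5L)
  top <- config$topology
  g <- do.call(sampleTopology, c(list(kind = top$kind, p = config$p,
                                      seed = seeds[1]),
                                 top[setdiff(names(top), "kind")]))
  varX <- config$varXBase * diag(config$p)
  m1 <- buildRegulatorModel(g, beta = rep(1, config$p),
                            varX = varX,
                            weightLow = config$weightLow,
                            weightHigh = config$weightHigh,
                            targetRadius = config$targetRadius,
                            seed = seeds[2])
  # network-coupled errors: Var(Y | X) = 0.3 Theta^{-1}, a Gaussian
  # graphical model whose edge set is exactly the drawn topology
  m1 <- new("RegulatorModel", Theta = m1@Theta, beta = m1@beta,
            SigmaEps = 0.3 * m1@Theta, VarX = varX)
  Theta2 <- m1@Theta
  if (config$retention < 1) {
    el <- igraph::as_edgelist(g, names = FALSE)
    keep <- withSeed(seeds[3], runif(nrow(el)) <= config$retention)
    drop <- el[!keep, , drop = FALSE]
    Theta2[drop] <- 0
    Theta2[drop[, c(2, 1), drop = FALSE]] <- 0
    ev2 <- eigen(Theta2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev2) <= 1e-8)
      stop("edge thinning left a non-PD Theta; choose another seed",
           call. = FALSE)
  }
  m2 <- new("RegulatorModel", Theta = Theta2,
            beta = rep(config$betaScale, config$p),
            SigmaEps = 0.3 * Theta2,
            VarX = config$varXScale * varX)
  se1 <- simulatePaired(m1, config$n1, seed = seeds[4])
  se2 <- simulatePaired(m2, config$n2, seed = seeds[5])
  cn <- cbind(SummarizedExperiment::assay(se1, "copyNumber"),
              SummarizedExperiment::assay(se2, "copyNumber"))
  ex <- cbind(SummarizedExperiment::assay(se1, "expression"),
              SummarizedExperiment::assay(se2, "expression"))
  colnames(cn) <- colnames(ex) <- sprintf("s%04d", seq_len(config$n1 + config$n2))
  group <- factor(rep(config$groupLabels, c(config$n1, config$n2)),
                  levels = config$groupLabels)
  countEdges <- function(Theta) {
    s <- supportFromTheta(Theta)
    sum(s[upper.tri(s)])
  }
  truth <- list(model1 = m1, model2 = m2,
                entropy1 = logDet(unconditionalVariance(m1)),
                entropy2 = logDet(unconditionalVariance(m2)),
                edges1 = countEdges(m1@Theta),
                edges2 = countEdges(m2@Theta),
                topology = g, config = config)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(copyNumber = cn, expression = ex),
    colData = S4Vectors::DataFrame(group = group),
    metadata = list(truth = truth))
}

#' Sample an expression population governed by a regulatory switch
#'
#' Draws a cohort from a finite Gaussian mixture: each sample's regulatory
#' module (mixture component) is latent, and returned as hidden truth for
#' evaluation.
#'
#' @param model a \code{\linkS4class{GaussianMixture}}.
#' @param n number of samples.
#' @param seed integer seed.
#' @return n x p expression matrix with attribute \code{"component"}.
#' @export
generateSwitchPopulation <- function(model, n, seed = NULL) {
  sampleMixture(model, n, seed)
}
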