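# Hypothetical regulatory-network topologies and PD concentration matrices.

#' Sample a hypothetical regulatory-network topology
#'
#' Draws a connected undirected graph of one of the two random-graph
#' families commonly used as stand-ins for regulatory topologies:
#' small-world (Watts-Strogatz ring lattice with rewiring) or scale-free
#' (Barabasi-Albert preferential attachment).
#'
#' @param kind \code{"smallworld"} or \code{"scalefree"}.
#' @param p number of nodes (genes), at least 3.
#' @param k small-world only: even number of ring-lattice neighbours
#'   (default 4).
#' @param rewire small-world only: rewiring probability in [0, 1]
#'   (default 0.05).
#' @param m scale-free only: edges attached per new node (default 2).
#' @param seed integer seed; the draw is deterministic given the seed and
#'   the caller's RNG state is left untouched.
#'
#' @return an \pkg{igraph} graph with graph attribute \code{kind}.
#'
#' @details Small-world draws that come out disconnected (possible after
#' rewiring) are redrawn, up to 100 times. Preferential-attachment graphs
#' are connected by construction; with \code{m = 1} they are trees with
#' \code{p - 1} edges.
#'
#' @examples
#' g <- sampleTopology("scalefree", p = 50, m = 1, seed = 1)
#' igraph::ecount(g)  # 49: a tree
#' @export
sampleTopology <- function(kind = c("smallworld", "scalefree"), p,
                           k = 4, rewire = 0.05, m = 2, seed = NULL) {
  kind <- match.arg(kind)
  stopIfNot(is.numeric(p) && length(p) == 1 && p >= 3, "p must be at least 3")
  p <- as.integer(p)
  if (kind == "smallworld") {
    stopIfNot(k %% 2 == 0 && k >= 2, "neighbour count k must be a positive even number")
    stopIfNot(k < p, "neighbour count k must be smaller than p")
    stopIfNot(rewire >= 0 && rewire <= 1, "rewiring probability must lie in [0, 1]")
  } else {
    stopIfNot(m >= 1 && m == round(m), "attachment count m must be a positive integer")
    stopIfNot(m < p, "attachment count m must be smaller than p")
  }
  g <- withSeed(seed, {
    if (kind == "scalefree") {
      igraph::simplify(igraph::sample_pa(p, m = m, directed = FALSE))
    } else {
      for (attempt in seq_len(100)) {
        cand <- igraph::simplify(
          igraph::sample_smallworld(1, p, k %/% 2, rewire))
        if (igraph::is_connected(cand)) break
        cand <- NULL
      }
      if (is.null(cand)) stop("failed to draw a connected small-world graph",
                              call. = FALSE)
      cand
    }
  })
  igraph::graph_attr(g, "kind") <- kind
  g
}

#' Build a PD concentration matrix supported on a topology
#'
#' Assigns each graph edge a uniformly drawn weight in
#' \code{[weightLow, weightHigh]} with a random sign, then sets each
#' diagonal entry to 1 plus the row-wise sum of absolute off-diagonal
#' weights plus \code{dominanceMargin}. Strict diagonal dominance
#' guarantees (Gershgorin) that every eigenvalue is at least
#' \code{1 + dominanceMargin}, so the result is always positive definite
#' with off-diagonal support exactly the edge set, and an isolated node
#' gets unit-scale precision.
#'
#' @param graph an undirected \pkg{igraph} graph.
#' @param weightLow,weightHigh edge-weight magnitude range, 0 < low <= high.
#' @param dominanceMargin additive diagonal margin (> 0, default 0.1);
#'   doubles as a lower bound on the smallest eigenvalue.
#' @param seed integer seed for the weight draw.
#'
#' @return a \code{\linkS4class{ConcentrationModel}}.
#' @export
precisionFromTopology <- function(graph, weightLow = 0.5, weightHigh = 1,
                                  dominanceMargin = 0.1, seed = NULL) {
  stopIfNot(inherits(graph, "igraph"), "graph must be an igraph object")
  stopIfNot(weightLow > 0 && weightLow <= weightHigh,
            "need 0 < weightLow <= weightHigh")
  stopIfNot(dominanceMargin > 0, "dominanceMargin must be positive")
  p <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  K <- matrix(0, p, p)
  if (nrow(el) > 0) {
    w <- withSeed(seed, {
      runif(nrow(el), weightLow, weightHigh) *
        sample(c(-1, 1), nrow(el), replace = TRUE)
    })
    K[el] <- w
    K[el[, c(2, 1), drop = FALSE]] <- w
  }
  diag(K) <- 1 + rowSums(abs(K)) + dominanceMargin
  # diagonal dominance makes failure impossible; guard anyway
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) stop("internal error: dominance construction not PD")
  new("ConcentrationModel", graph = graph, K = K, Sigma = symmetrize(chol2inv(ch)))
}

#' Covariance implied by a concentration matrix
#'
#' @param model a \code{\linkS4class{ConcentrationModel}} or a PD
#'   concentration matrix.
#' @return the covariance matrix (inverse of the concentration matrix).
#' @export
covarianceFromPrecision <- function(model) {
  if (is(model, "ConcentrationModel")) return(model@Sigma)
  stopIfNot(is.matrix(model), "expected a ConcentrationModel or a matrix")
  if (!isPD(model)) stop("concentration matrix is singular or not PD", call. = FALSE)
  pdInverse(model)
}

#' Standardize a concentration matrix to unit diagonal
#'
#' Rescales K to D^{-1/2} K D^{-1/2} with D = diag(K). The off-diagonal
#' entries of the result equal the partial correlations up to a sign flip;
#' determinant-based entropies are unaffected by the convention.
#'
#' @param K a symmetric concentration matrix with positive diagonal.
#' @return the unit-diagonal standardized matrix.
#' @export
standardizeConcentration <- function(K) {
  stopIfNot(all(diag(K) > 0), "concentration diagonal must be positive")
  d <- 1 / sqrt(diag(K))
  symmetrize(K * tcrossprod(d))
}
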