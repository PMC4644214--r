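#' Accessors for model objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{precisionMatrix} and \code{covarianceMatrix} return the
#' concentration matrix K and its inverse; \code{topology} the underlying
#' \pkg{igraph} graph; \code{partialCorrelations} the standardized
#' (unit-diagonal) concentration matrix, whose off-diagonal entries equal
#' the partial correlations up to a sign flip; \code{entropySummary}
#' summarises an \code{\linkS4class{EntropyComparison}}.
#'
#' @param object a model object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("precisionMatrix", function(object) standardGeneric("precisionMatrix"))

#' @rdname accessors
#' @export
setGeneric("covarianceMatrix", function(object) standardGeneric("covarianceMatrix"))

#' @rdname accessors
#' @export
setGeneric("topology", function(object) standardGeneric("topology"))

#' @rdname accessors
#' @export
setGeneric("partialCorrelations", function(object) standardGeneric("partialCorrelations"))

#' @rdname accessors
#' @export
setGeneric("entropySummary", function(object) standardGeneric("entropySummary"))

#' @rdname accessors
#' @export
setMethod("precisionMatrix", "ConcentrationModel", function(object) object@K)

#' @rdname accessors
#' @export
setMethod("covarianceMatrix", "ConcentrationModel", function(object) object@Sigma)

#' @rdname accessors
#' @export
setMethod("covarianceMatrix", "ShrinkageEstimate", function(object) object@SigmaHat)

#' @rdname accessors
#' @export
setMethod("topology", "ConcentrationModel", function(object) object@graph)

#' @rdname accessors
#' @export
setMethod("partialCorrelations", "ConcentrationModel", function(object) {
  standardizeConcentration(object@K)
})

#' @rdname accessors
#' @export
setMethod("entropySummary", "EntropyComparison", function(object) {
  d <- object@draws
  lev <- object@groupLevels
  e1 <- d$entropy[d$group == lev[1]]
  e2 <- d$entropy[d$group == lev[2]]
  list(medians = stats::setNames(c(median(e1), median(e2)), lev),
       medianDifference = median(e2) - median(e1),
       fracFirstLower = mean(e1 < e2),
       lambdaMedian = median(d$lambda))
})

#' Draw-level results of an entropy comparison
#'
#' @param object an \code{EntropyComparison}.
#' @return data.frame with columns draw, group, entropy, lambda.
#' @export
setGeneric("entropyDraws", function(object) standardGeneric("entropyDraws"))

#' @rdname entropyDraws
#' @export
setMethod("entropyDraws", "EntropyComparison", function(object) object@draws)
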