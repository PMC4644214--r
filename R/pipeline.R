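# Single programmatic entry point wiring the modules into reproducible,
# seeded, manifest-writing runs.

#' Run a named pipeline command
#'
#' Dispatches one of the package's analysis commands with a parameter
#' list, a mandatory seed (for the stochastic commands) and an output
#' directory. Every run writes its tabular outputs as TSV plus a
#' \code{manifest.json} recording the command, parameters, seed and
#' package version, from which the run can be reproduced exactly.
#'
#' Commands and their main parameters:
#' \describe{
#'   \item{simulate-network}{\code{kind}, \code{p}, generator params;
#'     writes \code{edges.tsv}, \code{precision.tsv}.}
#'   \item{cohort}{fields of \code{\link{cohortConfig}}; writes
#'     \code{X.tsv}, \code{Y.tsv}, \code{labels.tsv}, \code{truth.json}.}
#'   \item{entropy-compare}{\code{exprFile}, \code{labelsFile}, \code{B},
#'     \code{frac}, \code{convention}; writes \code{draws.tsv},
#'     \code{summary.json}.}
#'   \item{mixture-entropy}{\code{specFile} (JSON with tau, mu, Sigma),
#'     \code{M}; writes \code{report.json}.}
#'   \item{regulator-sweep}{\code{p}, \code{kind}, \code{v}; writes
#'     \code{sweep.tsv}.}
#'   \item{disturbance}{\code{p}, \code{tau}, \code{horizon},
#'     \code{window}; writes \code{series.tsv}.}
#'   \item{knockout}{\code{p}, \code{kind}, \code{replicates}; writes
#'     \code{knockout.tsv}, \code{correlations.tsv}.}
#'   \item{weaken}{\code{specFile} (JSON with omega, blocks),
#'     \code{gammaGrid}; writes \code{entropies.tsv}.}
#'   \item{fit}{\code{exprFile}, optional \code{cnFile}, \code{lambda1};
#'     writes \code{theta.tsv}, \code{beta.tsv}, \code{edges.tsv}.}
#'   \item{edge-curve}{\code{exprFile}, optional \code{cnFile},
#'     \code{labelsFile}, \code{B}, \code{frac}; writes \code{curve.tsv}.}
#' }
#'
#' @param command command name (see Details).
#' @param params named list of command parameters.
#' @param seed integer seed (mandatory for stochastic commands).
#' @param outDir output directory; created if absent.
#' @param overwrite allow writing into a non-empty directory
#'   (default \code{FALSE}).
#' @return invisibly, a character vector of the files written.
#' @export
runPipeline <- function(command, params = list(), seed = NULL,
                        outDir, overwrite = FALSE) {
  known <- c("simulate-network", "cohort", "entropy-compare",
             "mixture-entropy", "regulator-sweep", "disturbance",
             "knockout", "weaken", "fit", "edge-curve")
  if (!command %in% known)
    stop(sprintf("unknown command '%s'; known: %s", command,
                 paste(known, collapse = ", ")), call. = FALSE)
  stochastic <- setdiff(known, c("weaken", "fit", "mixture-entropy"))
  if (command %in% stochastic && is.null(seed))
    stop("a seed is mandatory for stochastic commands", call. = FALSE)
  if (!dir.exists(outDir)) {
    dir.create(outDir, recursive = TRUE)
  } else if (!overwrite && length(list.files(outDir))) {
    stop(sprintf("output directory '%s' is not empty (use overwrite = TRUE)",
                 outDir), call. = FALSE)
  }
  pth <- function(f) file.path(outDir, f)
  getp <- function(name, default) params[[name]] %||% default
  needFile <- function(name) {
    f <- params[[name]]
    if (is.null(f)) stop(sprintf("parameter '%s' is required", name),
                         call. = FALSE)
    if (!file.exists(f)) stop(sprintf("input file not found: %s", f),
                              call. = FALSE)
    f
  }
  written <- character()
  emit <- function(obj, f) {
    if (is.matrix(obj)) writeMatrixTSV(obj, pth(f))
    else utils::write.table(obj, pth(f), sep = "\t", quote = FALSE,
                            row.names = FALSE)
    written <<- c(written, pth(f))
  }
  emitJSON <- function(obj, f) {
    jsonlite::write_json(obj, pth(f), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, pth(f))
  }

  switch(command,
    "simulate-network" = {
      g <- sampleTopology(getp("kind", "scalefree"), getp("p", 50),
                          k = getp("k", 4), rewire = getp("rewire", 0.05),
                          m = getp("m", 2), seed = seed)
      cm <- precisionFromTopology(g, seed = seed + 1L)
      writeEdgeListTSV(g, pth("edges.tsv")); written <- c(written, pth("edges.tsv"))
      emit(precisionMatrix(cm), "precision.tsv")
    },
    "cohort" = {
      cfgArgs <- params[intersect(names(params), names(formals(cohortConfig)))]
      cfg <- do.call(cohortConfig, cfgArgs)
      se <- generateCohort(cfg, seed = seed)
      emit(copyNumberMatrix(se), "X.tsv")
      emit(expressionMatrix(se), "Y.tsv")
      grp <- SummarizedExperiment::colData(se)$group
      names(grp) <- colnames(se)
      writeLabelsTSV(grp, pth("labels.tsv")); written <- c(written, pth("labels.tsv"))
      tr <- S4Vectors::metadata(se)$truth
      emitJSON(list(entropy1 = tr$entropy1, entropy2 = tr$entropy2,
                    edges1 = tr$edges1, edges2 = tr$edges2), "truth.json")
    },
    "entropy-compare" = {
      expr <- readExpressionTSV(needFile("exprFile"))
      labels <- readLabelsTSV(needFile("labelsFile"))
      cmp <- compareGroupEntropy(expr, labels[rownames(expr)],
                                 B = getp("B", 500), frac = getp("frac", 0.9),
                                 seed = seed,
                                 convention = getp("convention", "logdet"))
      emit(entropyDraws(cmp), "draws.tsv")
      s <- entropySummary(cmp)
      emitJSON(list(medians = as.list(s$medians),
                    medianDifference = s$medianDifference,
                    fracFirstLower = s$fracFirstLower), "summary.json")
    },
    "mixture-entropy" = {
      spec <- jsonlite::read_json(needFile("specFile"), simplifyVector = TRUE)
      Sig <- spec$Sigma
      if (is.array(Sig) && length(dim(Sig)) == 3)
        Sig <- lapply(seq_len(dim(Sig)[1]), function(k) Sig[k, , ])
      model <- buildMixture(spec$tau, spec$mu, Sig)
      rep1 <- checkProposition1(model, M = getp("M", 1e5), seed = seed %||% 1L)
      emitJSON(rep1, "report.json")
    },
    "regulator-sweep" = {
      g <- sampleTopology(getp("kind", "smallworld"), getp("p", 50),
                          seed = seed)
      model <- buildRegulatorModel(g, seed = seed + 1L)
      sw <- genomicVarianceSweep(model, v = getp("v", 1))
      emit(cbind(sw$sweep, H0 = sw$H0, degree = igraph::degree(g)), "sweep.tsv")
    },
    "disturbance" = {
      df <- disturbanceDemo(seed = seed, p = getp("p", 3),
                            tau = getp("tau", 25),
                            horizon = getp("horizon", 50),
                            window = getp("window", 5))
      emit(df, "series.tsv")
    },
    "knockout" = {
      ko <- knockoutDegreeExperiment(p = getp("p", 50),
                                     kind = getp("kind", "scalefree"),
                                     replicates = getp("replicates", 100),
                                     seed = seed)
      emit(ko$results, "knockout.tsv")
      emit(ko$correlations, "correlations.tsv")
    },
    "weaken" = {
      spec <- jsonlite::read_json(needFile("specFile"), simplifyVector = TRUE)
      omega <- as.matrix(spec$omega)
      blocks <- lapply(spec$blocks, as.integer)
      grid <- getp("gammaGrid", seq(1, 0, by = -0.1))
      nPairs <- length(blocks) * (length(blocks) - 1) / 2
      H <- vapply(grid, function(g)
        entropyUnderWeakening(omega, blocks, rep(g, nPairs)), numeric(1))
      emit(data.frame(gamma = grid, entropy = H), "entropies.tsv")
    },
    "fit" = {
      Y <- readExpressionTSV(needFile("exprFile"))
      exprOnly <- is.null(params$cnFile)
      X <- if (exprOnly) NULL else readExpressionTSV(needFile("cnFile"))
      fit <- fitRegulator(X, Y, lambda1 = getp("lambda1", 0.1),
                          expressionOnly = exprOnly)
      emit(fit$Theta, "theta.tsv")
      emit(data.frame(gene = colnames(Y), beta = fit$beta), "beta.tsv")
      edges <- which(fit$support & upper.tri(fit$support), arr.ind = TRUE)
      emit(data.frame(from = edges[, 1], to = edges[, 2]), "edges.tsv")
    },
    "edge-curve" = {
      Y <- readExpressionTSV(needFile("exprFile"))
      exprOnly <- is.null(params$cnFile)
      X <- if (exprOnly) NULL else readExpressionTSV(needFile("cnFile"))
      labels <- readLabelsTSV(needFile("labelsFile"))
      curve <- edgeCountCurve(X, Y, labels[rownames(Y)],
                              B = getp("B", 50), frac = getp("frac", 0.9),
                              seed = seed, expressionOnly = exprOnly)
      emit(curve, "curve.tsv")
    })

  manifest <- list(command = command, params = params, seed = seed,
                   package = "netEntropy",
                   version = as.character(utils::packageVersion("netEntropy")))
  emitJSON(manifest, "manifest.json")
  invisible(written)
}
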