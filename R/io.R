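# Plain-text readers and writers for the package's tabular interfaces.

#' Write / read a numeric matrix as TSV with row and column ids
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return \code{readMatrixTSV} returns the matrix; writers return the
#'   path invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  df <- data.frame(id = rownames(m) %||% seq_len(nrow(m)), m,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMatrixTSV
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expression matrix I/O (samples in rows, first column sample id)
#'
#' @param data samples x genes matrix with row names as sample ids.
#' @param path file path.
#' @export
writeExpressionTSV <- function(data, path) writeMatrixTSV(data, path)

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) readMatrixTSV(path)

#' Group-label table I/O (sample id, group)
#'
#' @param labels factor or character vector named by sample id (or a
#'   data.frame with columns id, group).
#' @param path file path.
#' @export
writeLabelsTSV <- function(labels, path) {
  df <- data.frame(id = names(labels) %||% seq_along(labels),
                   group = as.character(labels))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLabelsTSV
#' @export
readLabelsTSV <- function(path) {
  df <- utils::read.delim(path)
  stats::setNames(factor(df$group), df$id)
}

#' Graph edge-list I/O (two integer columns, 0-based node ids)
#'
#' @param graph an \pkg{igraph} graph.
#' @param path file path.
#' @param p node count (needed on read so isolated nodes survive).
#' @export
writeEdgeListTSV <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  utils::write.table(data.frame(from = el[, 1], to = el[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdgeListTSV
#' @export
readEdgeListTSV <- function(path, p) {
  df <- utils::read.delim(path)
  igraph::graph_from_edgelist(as.matrix(df) + 1L, directed = FALSE) |>
    igraph::add_vertices(max(0, p - max(df) - 1))
}

#' Write a graph as GraphML
#'
#' @param graph an \pkg{igraph} graph.
#' @param path file path.
#' @export
writeGraphML <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
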