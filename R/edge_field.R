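#' Edge field: a real-valued map over a graph's undirected edge set
#'
#' Edge fields carry one value per undirected edge, stored once against the
#' canonical edge index (`i < j`) of a [matched_network()]. They hold the
#' mass-action weights `x_i x_j`, the flow distances `d_t(i, j)`, edge-wise
#' Forman-Ricci curvatures and the flow normaliser.
#'
#' @param net a `matched_network` providing the edge index.
#' @param values numeric vector, one entry per edge in canonical order.
#' @return An object of class `edge_field` with elements `i`, `j` (integer
#'   node indices, `i < j`), `values` and `node_ids`.
#' @export
#' @examples
#' net <- make_star(3, eps = 2)
#' weighted_adjacency(net)
edge_field <- function(net, values) {
  stopifnot(inherits(net, "matched_network"))
  values <- as.numeric(values)
  if (length(values) != length(net$edge_i))
    stop("values must have one entry per edge (", length(net$edge_i), ")")
  structure(
    list(i = net$edge_i, j = net$edge_j, values = values,
         node_ids = net$node_ids),
    class = "edge_field")
}

#' @export
print.edge_field <- function(x, ...) {
  cat(sprintf("edge_field over %d edges (%d nodes)\n",
              length(x$values), length(x$node_ids)))
  print(utils::head(as.data.frame(x), 6))
  if (length(x$values) > 6) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.edge_field <- function(x, ...) {
  data.frame(node_i = x$node_ids[x$i], node_j = x$node_ids[x$j],
             value = x$values, stringsAsFactors = FALSE)
}

#' Look up edge-field values by node pair
#'
#' Access is symmetric: `edge_value(f, a, b)` equals `edge_value(f, b, a)`.
#'
#' @param field an `edge_field`
#' @param a,b node identifiers (character) or 1-based node indices.
#' @return numeric vector of values; `NA` where no such edge exists.
#' @export
edge_value <- function(field, a, b) {
  stopifnot(inherits(field, "edge_field"))
  if (is.character(a)) a <- match(a, field$node_ids)
  if (is.character(b)) b <- match(b, field$node_ids)
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- paste(field$i, field$j)
  field$values[match(paste(lo, hi), key)]
}

# shared-edge-index contract used throughout the flow and evaluation code
check_same_edges <- function(a, b) {
  if (!identical(a$node_ids, b$node_ids) ||
      !identical(a$i, b$i) || !identical(a$j, b$j))
    stop("edge fields are defined on different edge sets")
  invisible(TRUE)
}

# symmetric sparse matrix carrying an edge field's values
edge_field_matrix <- function(field) {
  n <- length(field$node_ids)
  Matrix::sparseMatrix(i = c(field$i, field$j), j = c(field$j, field$i),
                       x = rep(field$values, 2), dims = c(n, n),
                       dimnames = list(field$node_ids, field$node_ids))
}
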