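#' Matched network: an interaction graph aligned with an expression profile
#'
#' A `matched_network` couples an undirected, connected, simple graph (the
#' protein-interaction network, PIN) with a strictly positive expression
#' vector `x` indexed by its nodes. It is the `(A, x)` pair from which the
#' mass-action weighted network `W(x) = (a_ij x_i x_j)`, the random-walk
#' transition matrix `P(x)` and its stationary distribution are derived.
#'
#' @param adjacency square symmetric 0/1 matrix (dense or sparse) with zero
#'   diagonal describing a single connected component.
#' @param expression numeric vector of strictly positive values, one per node,
#'   index-aligned with `node_ids` (normalised transcript abundance, unitless).
#' @param node_ids character vector of unique node identifiers; defaults to
#'   the adjacency row names.
#'
#' @return An object of class `matched_network` with elements `node_ids`,
#'   `adjacency` (a pattern-free `dgCMatrix` of 0/1), `expression`, `degree`,
#'   and the canonical edge index (`edge_i`, `edge_j`, with `edge_i < edge_j`).
#' @export
#' @examples
#' net <- make_star(3, eps = 2)
#' net$degree
matched_network <- function(adjacency, expression,
                            node_ids = rownames(adjacency)) {
  A <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  n <- nrow(A)
  if (ncol(A) != n) stop("adjacency must be square")
  if (is.null(node_ids)) node_ids <- as.character(seq_len(n))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("node_ids length must match adjacency")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  A@x[] <- 1
  A <- Matrix::drop0(A)
  if (!Matrix::isSymmetric(A)) stop("adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0)) stop("adjacency must have zero diagonal")
  expression <- as.numeric(expression)
  if (length(expression) != n)
    stop("expression length must match the number of nodes")
  if (any(!is.finite(expression)) || any(expression <= 0))
    stop("all expression values must be strictly positive and finite; ",
         "offending nodes: ",
         paste(node_ids[!is.finite(expression) | expression <= 0],
               collapse = ", "))
  deg <- as.numeric(Matrix::rowSums(A))
  if (n >= 2 && any(deg == 0)) stop("graph contains isolated nodes")
  if (!is_connected_adjacency(A))
    stop("graph must be a single connected component")
  tri <- Matrix::which(Matrix::triu(A, 1) != 0, arr.ind = TRUE)
  ord <- order(tri[, 1], tri[, 2])
  structure(
    list(node_ids = node_ids,
         adjacency = A,
         expression = expression,
         degree = deg,
         edge_i = as.integer(tri[ord, 1]),
         edge_j = as.integer(tri[ord, 2])),
    class = "matched_network")
}

# connectivity by breadth-first search on the sparse pattern
is_connected_adjacency <- function(A) {
  n <- nrow(A)
  if (n <= 1) return(TRUE)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nb <- unique(methods::slot(A[, frontier, drop = FALSE], "i")) + 1L
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  all(seen)
}

#' @export
print.matched_network <- function(x, ...) {
  cat(sprintf("matched_network: %d nodes, %d edges\n",
              length(x$node_ids), length(x$edge_i)))
  cat(sprintf("  expression range: [%.4g, %.4g]\n",
              min(x$expression), max(x$expression)))
  invisible(x)
}

#' Number of nodes and edges of a matched network
#' @param net a `matched_network`
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$node_ids)

#' @rdname n_nodes
#' @export
n_edges <- function(net) length(net$edge_i)

#' Convert a matched network to an igraph object
#'
#' Node names are preserved and the expression vector is attached as the
#' vertex attribute `expression`.
#'
#' @param net a `matched_network`
#' @return an undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(net$adjacency,
                                           mode = "undirected")
  igraph::V(g)$name <- net$node_ids
  igraph::V(g)$expression <- net$expression
  g
}
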