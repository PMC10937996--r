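#' Match an expression profile onto a protein-interaction network
#'
#' Genes are matched to proteins in the network (identity mapping on shared
#' identifiers unless a gene-to-protein table is supplied). When multiple
#' genes map to a single protein their expression levels are averaged. Nodes
#' without matched expression are removed and only the largest connected
#' component of the matched subgraph is kept.
#'
#' @param graph an undirected `igraph` graph with named vertices (see
#'   [load_network()]) or a `matched_network` (whose expression is replaced).
#' @param expression named numeric vector of nonnegative values, or a one- or
#'   multi-column matrix with gene row names (the column selected by `sample`
#'   is used).
#' @param mapping optional data.frame with columns `gene_id`, `protein_id`
#'   (see [read_mapping()]).
#' @param pseudocount nonnegative constant added to every matched value before
#'   the positivity check. The default of 0 makes zero expression a hard
#'   error: the weighting scheme requires `x > 0` and the tool does not
#'   silently fabricate signal.
#' @param sample column to use when `expression` is a matrix.
#' @return a [matched_network()].
#' @export
#' @examples
#' net0 <- make_star(3, eps = 2)
#' g <- as_igraph(net0)
#' x <- stats::setNames(net0$expression, net0$node_ids)
#' net <- match_expression(g, x)
match_expression <- function(graph, expression, mapping = NULL,
                             pseudocount = 0, sample = 1) {
  if (inherits(graph, "matched_network")) graph <- as_igraph(graph)
  stopifnot(igraph::is_igraph(graph))
  if (is.matrix(expression) || is.data.frame(expression)) {
    expr <- as.matrix(expression)[, sample]
    names(expr) <- rownames(expression)
  } else {
    expr <- expression
  }
  if (is.null(names(expr))) stop("expression must carry gene identifiers")
  expr <- expr[!is.na(expr)]
  if (any(expr < 0)) stop("expression values must be nonnegative")

  # gene -> protein; many genes mapping to one protein are averaged
  if (!is.null(mapping)) {
    keep <- mapping$gene_id %in% names(expr)
    mapping <- mapping[keep, , drop = FALSE]
    vals <- expr[mapping$gene_id]
    prot <- tapply(vals, mapping$protein_id, mean)
  } else {
    prot <- tapply(expr, names(expr), mean)
  }
  prot_ids <- names(prot)

  node_names <- igraph::V(graph)$name
  matched <- intersect(node_names, prot_ids)
  if (length(matched) < 3)
    stop("fewer than 3 genes match network nodes (", length(matched), ")")

  x <- as.numeric(prot[matched]) + pseudocount
  bad <- matched[x <= 0]
  if (length(bad))
    stop("matched expression is nonpositive for nodes: ",
         paste(bad, collapse = ", "),
         "; supply a pseudocount or filter these genes")

  sub <- igraph::induced_subgraph(graph, matched)
  comp <- igraph::components(sub)
  lcc <- which(comp$membership == which.max(comp$csize))
  if (length(lcc) < 3)
    stop("largest connected component after matching has fewer than 3 nodes")
  sub <- igraph::induced_subgraph(sub, lcc)

  ids <- igraph::V(sub)$name
  A <- igraph::as_adjacency_matrix(sub, sparse = TRUE)
  matched_network(A, stats::setNames(x, matched)[ids], node_ids = ids)
}
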