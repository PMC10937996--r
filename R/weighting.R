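#' Mass-action weighted adjacency
#'
#' Edge weights `x_i * x_j`: the product of endpoint expression levels, the
#' mass-action propensity of the interaction.
#'
#' @param net a [matched_network()]
#' @return an [edge_field()] of weights.
#' @export
weighted_adjacency <- function(net) {
  x <- net$expression
  edge_field(net, x[net$edge_i] * x[net$edge_j])
}

#' Random-walk transition matrix of the weighted network
#'
#' Row-stochastic matrix `p_ij = a_ij x_j / sum_k a_ik x_k`.
#'
#' @param net a [matched_network()]
#' @return a sparse row-stochastic `dgCMatrix` with node-id dimnames.
#' @export
transition_matrix <- function(net) {
  strength <- as.numeric(net$adjacency %*% net$expression)
  stopifnot(all(strength > 0))  # guaranteed: connected, x > 0
  P <- Matrix::Diagonal(x = 1 / strength) %*% net$adjacency %*%
    Matrix::Diagonal(x = net$expression)
  dimnames(P) <- list(net$node_ids, net$node_ids)
  methods::as(P, "CsparseMatrix")
}

#' Stationary distribution of the random walk
#'
#' For an undirected connected graph the stationary distribution of `P(x)`
#' has the closed form `pi_i = x_i sum_j a_ij x_j / sum_kj a_kj x_k x_j`
#' (node strength over total strength of the weighted network `W(x)`).
#'
#' @param net a [matched_network()]
#' @return numeric probability vector named by node id, satisfying
#'   `pi %*% P == pi`.
#' @export
stationary_distribution <- function(net) {
  w <- net$expression * as.numeric(net$adjacency %*% net$expression)
  stats::setNames(w / sum(w), net$node_ids)
}
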