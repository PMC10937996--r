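#' Edge-wise Forman-Ricci curvature of an expression-weighted network
#'
#' Computes the degree-normalised Forman-Ricci curvature on every edge, using
#' node weights `W_i = 1/deg(i)` and edge weights `omega_ij = 1/(x_i x_j)`
#' (the reciprocal mass-action weight, so highly co-expressed neighbours are
#' "close"). With these choices the curvature simplifies to
#'
#' \deqn{R_F(i,j) = \frac{1}{\deg i}\Big[1 - \sum_{k \in N(i)\setminus j}
#'   \sqrt{x_k/x_j}\Big] + \frac{1}{\deg j}\Big[1 -
#'   \sum_{k \in N(j)\setminus i}\sqrt{x_k/x_i}\Big]}
#'
#' Only existing edges contribute to the neighbourhood sums. The `1/deg`
#' node weights bound each bracket independently of degree, so nodal averages
#' carry no spurious degree dependence.
#'
#' @param net a [matched_network()]
#' @return an [edge_field()] of curvatures (symmetric by construction).
#' @export
#' @examples
#' edge_curvature(make_star(4, eps = 2))
edge_curvature <- function(net) {
  x <- net$expression
  sqx <- sqrt(x)
  s <- as.numeric(net$adjacency %*% sqx)  # s_i = sum_{k in N(i)} sqrt(x_k)
  i <- net$edge_i
  j <- net$edge_j
  inv_deg <- 1 / net$degree
  r_ij <- inv_deg[i] * (1 - (s[i] - sqx[j]) / sqx[j])
  r_ji <- inv_deg[j] * (1 - (s[j] - sqx[i]) / sqx[i])
  edge_field(net, r_ij + r_ji)
}

#' Forman-Ricci curvature from an arbitrary positive distance field
#'
#' Evaluates the general weighted Forman form
#' \deqn{R_F(i,j) = W_i + W_j - \sqrt{\omega_{ij}}\Big[W_i
#'   \sum_{k \in N(i)\setminus j} \omega_{ik}^{-1/2} + W_j
#'   \sum_{k \in N(j)\setminus i} \omega_{kj}^{-1/2}\Big]}
#' with edge weights `omega = d` and fixed node weights `W_i = 1/deg(i)`.
#' Needed inside the Ricci flow, where after one step the distances are no
#' longer of product form `1/(x_i x_j)`. For a product-form `d` this agrees
#' with [edge_curvature()] to machine precision.
#'
#' @param d an [edge_field()] of strictly positive distances.
#' @param net the [matched_network()] fixing topology and degrees.
#' @return an [edge_field()] of curvatures.
#' @export
edge_curvature_from_distances <- function(d, net) {
  stopifnot(inherits(d, "edge_field"))
  if (any(d$values <= 0)) stop("all distances must be strictly positive")
  n <- length(net$node_ids)
  if (!identical(d$i, net$edge_i) || !identical(d$j, net$edge_j))
    stop("distance field does not match the network's edge set")
  inv_sq <- 1 / sqrt(d$values)
  t_sum <- as.numeric(rowsum(
    c(inv_sq, inv_sq), c(d$i, d$j),
    reorder = TRUE))  # t_i = sum over incident edges of d^{-1/2}
  # rowsum drops absent groups, but every node has degree >= 1 here
  i <- d$i
  j <- d$j
  W <- 1 / net$degree
  vals <- W[i] + W[j] - sqrt(d$values) *
    (W[i] * (t_sum[i] - inv_sq) + W[j] * (t_sum[j] - inv_sq))
  edge_field(net, vals)
}

#' Nodal Forman-Ricci curvature
#'
#' Mean of the incident edge curvatures:
#' `Ric_i = (1/deg i) sum_j a_ij R_F(i, j)`.
#'
#' @param edge an [edge_field()] of edge curvatures.
#' @param net the underlying [matched_network()].
#' @return numeric vector named by node id.
#' @export
nodal_curvature <- function(edge, net) {
  stopifnot(inherits(edge, "edge_field"))
  s <- as.numeric(rowsum(c(edge$values, edge$values), c(edge$i, edge$j),
                         reorder = TRUE))
  stats::setNames(s / net$degree, net$node_ids)
}

#' Total (network-average) Forman-Ricci curvature
#'
#' Stationary-weighted mean of nodal curvatures:
#' `Ric(x) = sum_i pi_i Ric_i`.
#'
#' @param nodal numeric vector of nodal curvatures.
#' @param pi stationary probability vector (sums to 1).
#' @return scalar.
#' @export
total_curvature <- function(nodal, pi) {
  stopifnot(length(nodal) == length(pi))
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  sum(pi * nodal)
}

#' Full curvature summary for one sample
#'
#' @param net a [matched_network()]
#' @return list with `edge` (edge curvature field), `nodal` (vector) and
#'   `total` (scalar).
#' @export
#' @examples
#' network_curvature(make_star(5, eps = 2))$total
network_curvature <- function(net) {
  edge <- edge_curvature(net)
  nodal <- nodal_curvature(edge, net)
  list(edge = edge, nodal = nodal,
       total = total_curvature(nodal, stationary_distribution(net)))
}
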