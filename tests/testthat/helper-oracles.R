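# Independent dense, loop-based reference implementations used as oracles.
# Deliberately naive: O(n^2) matrices and explicit sums, no shared code with
# the package internals.

dense_net <- function(net) {
  list(A = as.matrix(net$adjacency), x = net$expression)
}

ref_transition <- function(A, x) {
  P <- sweep(A, 2, x, `*`)
  P / rowSums(P)
}

# stationary distribution by left power iteration on the lazy walk
# (P + I)/2, which shares pi but is aperiodic even on bipartite graphs
ref_stationary <- function(A, x, tol = 1e-14, maxit = 1e6) {
  P <- ref_transition(A, x)
  Q <- (P + diag(nrow(P))) / 2
  v <- rep(1 / nrow(P), nrow(P))
  for (it in seq_len(maxit)) {
    v2 <- as.numeric(v %*% Q)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) break
    v <- v2
  }
  v2
}

ref_local_entropy <- function(A, x) {
  P <- ref_transition(A, x)
  apply(P, 1, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

ref_entropy_rate <- function(A, x) {
  sum(ref_stationary(A, x) * ref_local_entropy(A, x))
}

# curvature in the expression form: explicit neighbourhood sums
ref_edge_curvature <- function(A, x) {
  n <- nrow(A)
  deg <- rowSums(A)
  R <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (A[i, j] > 0) {
    Ni <- setdiff(which(A[i, ] > 0), j)
    Nj <- setdiff(which(A[j, ] > 0), i)
    R[i, j] <- (1 / deg[i]) * (1 - sum(sqrt(x[Ni] / x[j]))) +
      (1 / deg[j]) * (1 - sum(sqrt(x[Nj] / x[i])))
  }
  R
}

# curvature in the general weighted Forman form on a distance matrix
ref_curvature_from_distances <- function(A, D) {
  n <- nrow(A)
  deg <- rowSums(A)
  W <- 1 / deg
  R <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (A[i, j] > 0) {
    Ni <- setdiff(which(A[i, ] > 0), j)
    Nj <- setdiff(which(A[j, ] > 0), i)
    R[i, j] <- W[i] + W[j] - sqrt(D[i, j]) *
      (W[i] * sum(1 / sqrt(D[i, Ni])) + W[j] * sum(1 / sqrt(D[Nj, j])))
  }
  R
}

ref_total_curvature <- function(A, x) {
  deg <- rowSums(A)
  R <- ref_edge_curvature(A, x)
  nodal <- sapply(seq_len(nrow(A)), function(i)
    sum(R[i, A[i, ] > 0]) / deg[i])
  sum(ref_stationary(A, x) * nodal)
}

# small matched_network from an explicit edge list and named expression
net_from_edges <- function(edges, x) {
  ids <- names(x)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]
    b <- edges[r, 2]
    A[a, b] <- 1
    A[b, a] <- 1
  }
  matched_network(A, as.numeric(x), node_ids = ids)
}

# end state sharing topology, expression perturbed by log-normal fold changes
perturbed_state <- function(net, seed, sd = 1) {
  x <- withr::with_seed(seed,
    net$expression * exp(stats::rnorm(length(net$expression), 0, sd)))
  matched_network(net$adjacency, x, net$node_ids)
}

dense_from_field <- function(field) {
  n <- length(field$node_ids)
  D <- matrix(0, n, n)
  D[cbind(c(field$i, field$j), c(field$j, field$i))] <- rep(field$values, 2)
  D
}

random_distance_field <- function(net, seed, sdlog = 0.7) {
  edge_field(net, withr::with_seed(seed,
    stats::rlnorm(n_edges(net), 0, sdlog)))
}
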