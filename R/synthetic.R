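#' Construct the k-star toy network
#'
#' Hub plus `k` leaves; expression 1 everywhere except the distinguished leaf
#' `j`, which carries `eps`. Node identifiers are `l1..l(k-1)` (plain
#' leaves), `i` (hub) and `j` (distinguished leaf), in that order.
#'
#' @param k integer >= 2, number of leaves.
#' @param eps positive weight of leaf `j`.
#' @return a [matched_network()].
#' @export
#' @examples
#' make_star(3, eps = 2)$expression  # 1 1 1 2
make_star <- function(k, eps = 1) {
  check_star_params(k, eps)
  stopifnot(length(eps) == 1)
  ids <- c(paste0("l", seq_len(k - 1)), "i", "j")
  n <- k + 1
  hub <- k  # position of "i"
  leaves <- setdiff(seq_len(n), hub)
  A <- Matrix::sparseMatrix(i = c(rep(hub, k), leaves),
                            j = c(leaves, rep(hub, k)),
                            x = 1, dims = c(n, n),
                            dimnames = list(ids, ids))
  x <- rep(1, n)
  x[n] <- eps
  matched_network(A, x, node_ids = ids)
}

#' Generate a random sparse connected weighted network
#'
#' Largest connected component of an Erdos-Renyi G(n, m) graph with
#' `m = round(mean_degree * n / 2)` edges, carrying log-normal positive
#' expression (meanlog 0; `sdlog` defaults to 0.5, a realistic spread for
#' normalised transcript abundance). Deterministic under `seed`.
#'
#' @param n number of nodes before restriction to the largest component.
#' @param mean_degree target mean degree.
#' @param seed integer seed.
#' @param sdlog log-scale standard deviation of the expression values.
#' @return a [matched_network()] (node count may be below `n` if the random
#'   graph is disconnected).
#' @export
#' @examples
#' net <- make_random_pin(30, mean_degree = 4, seed = 1)
make_random_pin <- function(n, mean_degree = 4, seed = 1, sdlog = 0.5) {
  stopifnot(n >= 3, mean_degree > 0)
  withr::with_seed(seed, {
    m <- max(n - 1, round(mean_degree * n / 2))
    g <- igraph::sample_gnm(n, m)
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
    nn <- igraph::vcount(g)
    ids <- paste0("g", seq_len(nn))
    igraph::V(g)$name <- ids
    x <- stats::rlnorm(nn, meanlog = 0, sdlog = sdlog)
    matched_network(igraph::as_adjacency_matrix(g, sparse = TRUE), x,
                    node_ids = ids)
  })
}

#' Generate a time-ordered series of true weighted networks
#'
#' Emulates a differentiation time course: intermediate "truth" weighted
#' networks between a start and an end state, with known ground-truth
#' ordering. Two generators are provided: `"flow"` samples the normalised
#' Ricci flow trajectory itself at the requested iteration fractions (for
#' self-consistency tests), while `"geometric"` takes the elementwise
#' log-linear path `W_s = W0^(1-s) WT^s` — a curved path independent of the
#' flow, for non-circular ordering tests. Optional multiplicative log-normal
#' noise perturbs each edge weight.
#'
#' @param net_start,net_end [matched_network()]s sharing topology.
#' @param sample_times fractions strictly inside (0, 1) locating the truths
#'   along the path.
#' @param noise_sigma log-scale sd of the multiplicative noise (0.01 = 1%).
#' @param seed integer seed for the noise.
#' @param method `"flow"` or `"geometric"`.
#' @param config [flow_config()] used when `method = "flow"`.
#' @return list with `truths` (list of weight [edge_field()]s), `times`
#'   (= `sample_times`), `iterations` (flow iterations sampled; `NA` for the
#'   geometric path) and `method`.
#' @export
make_timecourse <- function(net_start, net_end, sample_times,
                            noise_sigma = 0, seed = 1,
                            method = c("flow", "geometric"),
                            config = flow_config()) {
  method <- match.arg(method)
  if (any(sample_times <= 0 | sample_times >= 1))
    stop("sample_times must lie strictly inside (0, 1)")
  if (is.unsorted(sample_times)) stop("sample_times must be increasing")

  if (method == "flow") {
    traj <- run_flow(net_start, net_end, config)
    iters <- pmax(1L, pmin(traj$n_iter,
                           as.integer(round(sample_times * traj$n_iter))))
    truths <- lapply(iters, function(r) predicted_weights(traj, r))
  } else {
    W0 <- weighted_adjacency(net_start)
    WT <- weighted_adjacency(net_end)
    check_same_edges(W0, WT)
    iters <- rep(NA_integer_, length(sample_times))
    truths <- lapply(sample_times, function(s) {
      out <- W0
      out$values <- exp((1 - s) * log(W0$values) + s * log(WT$values))
      out
    })
  }
  if (noise_sigma > 0) {
    truths <- withr::with_seed(seed, lapply(truths, function(w) {
      w$values <- w$values * exp(stats::rnorm(length(w$values), 0,
                                              noise_sigma))
      w
    }))
  }
  list(truths = truths, times = sample_times, iterations = iters,
       method = method)
}
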