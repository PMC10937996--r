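#' Initial edge distances of the Ricci flow
#'
#' The flow starts from `d_0(i,j) = omega_ij = 1/(x_i x_j)` on the start
#' state: reciprocal mass-action weight, so strongly co-expressed neighbours
#' begin close together.
#'
#' @param net_start the [matched_network()] of the start state.
#' @return an [edge_field()] of strictly positive distances.
#' @export
initial_distances <- function(net_start) {
  x <- net_start$expression
  edge_field(net_start, 1 / (x[net_start$edge_i] * x[net_start$edge_j]))
}

#' Normaliser field from the end state
#'
#' The edge-wise target of the normalised flow is the Forman-Ricci curvature
#' field of the fully differentiated (end) state.
#'
#' @param net_end the end-state [matched_network()].
#' @param net_start optional start-state network; when given, the two edge
#'   sets are checked to be identical (the flow requires shared topology).
#' @return an [edge_field()] of target curvatures.
#' @export
normaliser_from_state <- function(net_end, net_start = NULL) {
  if (!is.null(net_start)) {
    if (!identical(net_start$node_ids, net_end$node_ids) ||
        !identical(net_start$edge_i, net_end$edge_i) ||
        !identical(net_start$edge_j, net_end$edge_j))
      stop("start and end networks must share node set and edge set")
  }
  edge_curvature(net_end)
}

#' One step of the normalised discrete Ricci flow
#'
#' `d' = d * (1 + dt * (ric - norm))` elementwise. An edge whose current
#' curvature exceeds its target is stretched, which lowers its curvature on
#' the next iteration, driving convergence to the normaliser.
#'
#' @param d current distance [edge_field()], strictly positive.
#' @param ric current curvature [edge_field()].
#' @param norm normaliser [edge_field()].
#' @param dt positive step size.
#' @return the updated distance [edge_field()].
#' @export
flow_step <- function(d, ric, norm, dt) {
  check_same_edges(d, ric)
  check_same_edges(d, norm)
  stopifnot(dt > 0)
  new_vals <- d$values * (1 + dt * (ric$values - norm$values))
  if (any(new_vals <= 0)) {
    bad <- which.min(new_vals)
    stop(sprintf(
      paste0("flow step produced a nonpositive distance on edge %s--%s; ",
             "dt = %g exceeds the stability bound dt* = %g"),
      d$node_ids[d$i[bad]], d$node_ids[d$j[bad]], dt,
      max_stable_dt(ric, norm)))
  }
  out <- d
  out$values <- new_vals
  out
}

#' Largest stable step size of the flow
#'
#' `dt* = min over E* of 1 / (norm - ric0)` where `E*` is the set of edges on
#' which the normaliser exceeds the initial curvature. Any `dt < dt*` keeps
#' the first flow step strictly positive. `+Inf` when `E*` is empty.
#'
#' @param ric0 initial curvature [edge_field()].
#' @param norm normaliser [edge_field()].
#' @return scalar, possibly `Inf`.
#' @export
max_stable_dt <- function(ric0, norm) {
  check_same_edges(ric0, norm)
  gap <- norm$values - ric0$values
  pos <- gap > 0
  if (!any(pos)) return(Inf)
  min(1 / gap[pos])
}

#' Empirical step-size selection
#'
#' Runs one flow step from the start state for each candidate and returns the
#' largest step size whose first-step distances are all strictly positive.
#'
#' @param net_start start-state [matched_network()].
#' @param norm normaliser [edge_field()] (see [normaliser_from_state()]).
#' @param grid positive candidate step sizes; default a linear grid 0.001 to
#'   0.1 in steps of 0.001.
#' @return list with `dt` (selected value) and `dt_star` (theoretical bound).
#' @export
select_dt <- function(net_start, norm, grid = seq(0.001, 0.1, by = 0.001)) {
  if (!length(grid)) stop("step-size grid is empty")
  if (any(grid <= 0)) stop("step-size candidates must be positive")
  d0 <- initial_distances(net_start)
  ric0 <- edge_curvature(net_start)
  dt_star <- max_stable_dt(ric0, norm)
  delta <- ric0$values - norm$values
  for (cand in sort(grid, decreasing = TRUE)) {
    if (all(d0$values * (1 + cand * delta) > 0))
      return(list(dt = cand, dt_star = dt_star))
  }
  stop("no candidate step size admits positive first-step distances; ",
       "dt* = ", dt_star)
}

#' Flow configuration
#'
#' @param dt step size; `NULL` (default) selects it empirically via
#'   [select_dt()].
#' @param n_iter number of iterations (default 150, sufficient for
#'   convergence close to the normaliser on the networks considered).
#' @param dt_grid candidate step sizes when `dt` is `NULL`.
#' @param record_every store the distance field every this many iterations
#'   (iteration 0 and the final iteration are always stored).
#' @return list of class `flow_config`.
#' @export
flow_config <- function(dt = NULL, n_iter = 150L,
                        dt_grid = seq(0.001, 0.1, by = 0.001),
                        record_every = 1L) {
  if (!is.null(dt) && dt <= 0) stop("dt must be positive")
  n_iter <- as.integer(n_iter)
  if (n_iter < 1) stop("n_iter must be at least 1")
  record_every <- as.integer(record_every)
  if (record_every < 1) stop("record_every must be at least 1")
  structure(list(dt = dt, n_iter = n_iter, dt_grid = dt_grid,
                 record_every = record_every),
            class = "flow_config")
}

#' Run the normalised discrete Ricci flow between two states
#'
#' Starting from `d_0 = 1/(x^start_i x^start_j)`, iterates [flow_step()]
#' toward the curvature field of the end state. The curvature entering each
#' step is recomputed from the current distances via the general weighted
#' Forman form ([edge_curvature_from_distances()]), since after one step the
#' distances are no longer of product form; node weights `1/deg` stay fixed
#' throughout. The per-iteration residual `max |R_F^t - norm|` is recorded.
#'
#' @param net_start,net_end [matched_network()]s sharing node and edge sets.
#' @param config a [flow_config()].
#' @return object of class `flow_trajectory`: `distances` (list of
#'   [edge_field()]s named by iteration), `iterations` (recorded iteration
#'   numbers), `residuals` (length `n_iter + 1`, indexed 0..n_iter),
#'   `dt_used`, `dt_star`, `n_iter`, `net` (the start network, fixing the
#'   topology).
#' @export
#' @examples
#' a <- make_star(4, eps = 1)
#' b <- make_star(4, eps = 3)
#' traj <- run_flow(a, b, flow_config(n_iter = 50))
#' traj$residuals[c(1, 51)]
run_flow <- function(net_start, net_end, config = flow_config()) {
  stopifnot(inherits(config, "flow_config"))
  norm <- normaliser_from_state(net_end, net_start)
  d <- initial_distances(net_start)
  sel <- NULL
  if (is.null(config$dt)) {
    sel <- select_dt(net_start, norm, config$dt_grid)
    dt <- sel$dt
  } else {
    dt <- config$dt
  }
  dt_star <- if (!is.null(sel)) sel$dt_star else
    max_stable_dt(edge_curvature(net_start), norm)

  n_iter <- config$n_iter
  residuals <- numeric(n_iter + 1)
  keep <- unique(c(0L, seq(0L, n_iter, by = config$record_every), n_iter))
  distances <- vector("list", length(keep))
  names(distances) <- as.character(sort(keep))
  distances[["0"]] <- d
  for (t in seq_len(n_iter)) {
    ric <- edge_curvature_from_distances(d, net_start)
    residuals[t] <- max(abs(ric$values - norm$values))
    d <- tryCatch(
      flow_step(d, ric, norm, dt),
      error = function(e) stop("at iteration ", t, ": ",
                               conditionMessage(e)))
    key <- as.character(t)
    if (key %in% names(distances)) distances[[key]] <- d
  }
  ric <- edge_curvature_from_distances(d, net_start)
  residuals[n_iter + 1] <- max(abs(ric$values - norm$values))
  names(residuals) <- as.character(0:n_iter)

  structure(
    list(distances = distances, iterations = sort(keep),
         residuals = residuals, dt_used = dt, dt_star = dt_star,
         n_iter = n_iter, net = net_start),
    class = "flow_trajectory")
}

#' @export
print.flow_trajectory <- function(x, ...) {
  cat(sprintf(paste0("flow_trajectory: %d iterations, dt = %g (dt* = %g)\n",
                     "  residual max|R_F - norm|: %.4g (t=0) -> %.4g ",
                     "(t=%d)\n"),
              x$n_iter, x$dt_used, x$dt_star,
              x$residuals[1], x$residuals[x$n_iter + 1], x$n_iter))
  invisible(x)
}

#' Predicted weighted network along the flow
#'
#' The flow's predicted weighted network at iteration `r` is the elementwise
#' reciprocal of the distance field, `W_p = 1/d_r`.
#'
#' @param traj a `flow_trajectory`.
#' @param iteration recorded iteration number.
#' @return an [edge_field()] of predicted weights.
#' @export
predicted_weights <- function(traj, iteration) {
  key <- as.character(iteration)
  if (!key %in% names(traj$distances))
    stop("iteration ", iteration, " was not recorded")
  d <- traj$distances[[key]]
  d$values <- 1 / d$values
  d
}

#' All recorded predicted weight fields of a flow trajectory
#'
#' @param traj a `flow_trajectory`.
#' @param drop_initial drop iteration 0 (the start state itself), so the
#'   result aligns with trajectory points `r = 1..n_iter`.
#' @return named list of [edge_field()]s.
#' @export
trajectory_weights <- function(traj, drop_initial = TRUE) {
  its <- traj$iterations
  if (drop_initial) its <- its[its != 0L]
  stats::setNames(lapply(its, function(r) predicted_weights(traj, r)),
                  as.character(its))
}
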