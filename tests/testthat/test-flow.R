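test_that("initial distances are reciprocal mass-action weights", {
  unit <- make_star(3, eps = 1)
  expect_true(all(initial_distances(unit)$values == 1))
  two <- net_from_edges(cbind("a", "b"), c(a = 2, b = 5))
  expect_equal(initial_distances(two)$values, 0.1)
  # monotone in the co-expression product
  net <- make_random_pin(20, 4, seed = 1)
  d <- initial_distances(net)
  W <- weighted_adjacency(net)
  expect_equal(order(d$values), order(-W$values))
})

test_that("the normaliser is the end state's curvature and needs shared topology", {
  net <- make_star(4, eps = 2)
  expect_equal(normaliser_from_state(net, net)$values,
               edge_curvature(net)$values)
  other <- make_star(5, eps = 2)
  expect_error(normaliser_from_state(other, net), "share")
})

test_that("flow steps follow the update rule and guard positivity", {
  two <- net_from_edges(cbind("a", "b"), c(a = 1, b = 1))
  d <- edge_field(two, 1)
  ric <- edge_field(two, -2)
  norm <- edge_field(two, 0)
  expect_equal(flow_step(d, ric, norm, 0.1)$values, 0.8)
  # fixed point when curvature already equals the target
  expect_equal(flow_step(d, norm, norm, 0.1)$values, d$values)
  # dt above the stability bound: distance would hit zero or below
  expect_error(flow_step(d, ric, norm, 0.6), "dt\\*")
})

test_that("the stability bound is the minimal reciprocal curvature gap", {
  net <- make_star(3, eps = 1)  # 3 edges
  ric0 <- edge_field(net, c(0, 0, 0))
  norm <- edge_field(net, c(2, 5, -1))
  expect_equal(max_stable_dt(ric0, norm), 0.2)
  all_neg <- edge_field(net, c(-1, 0, -3))
  expect_equal(max_stable_dt(ric0, all_neg), Inf)
})

test_that("any dt below the bound keeps the first step positive", {
  for (seed in 1:20) {
    net <- make_random_pin(25, 4, seed = seed)
    end <- perturbed_state(net, seed + 100)
    d0 <- initial_distances(net)
    ric0 <- edge_curvature(net)
    norm <- edge_curvature(end)
    dt_star <- max_stable_dt(ric0, norm)
    dt <- if (is.finite(dt_star)) 0.99 * dt_star else 1
    expect_true(all(flow_step(d0, ric0, norm, dt)$values > 0))
  }
})

test_that("select_dt returns the largest candidate with a positive first step", {
  net <- make_star(4, eps = 2)
  ric0 <- edge_curvature(net)
  # craft a normaliser with a known stability bound of 1/(1/0.07)
  norm <- ric0
  norm$values <- ric0$values + c(1 / 0.07, rep(-1, n_edges(net) - 1))
  sel <- select_dt(net, norm, grid = c(0.05, 0.1))
  expect_equal(sel$dt, 0.05)
  expect_equal(sel$dt_star, 0.07)
  # no positive gaps: bound infinite, max of the grid is returned
  below <- ric0
  below$values <- ric0$values - 1
  expect_equal(select_dt(net, below, grid = c(0.01, 0.2))$dt, 0.2)
  expect_equal(select_dt(net, below, grid = c(0.01, 0.2))$dt_star, Inf)
  expect_error(select_dt(net, norm, grid = numeric(0)), "empty")
})

test_that("identical start and end states are a fixed point of the flow", {
  for (net in list(make_star(5, eps = 2), make_random_pin(30, 4, seed = 2))) {
    traj <- run_flow(net, net, flow_config(n_iter = 150))
    d0 <- traj$distances[["0"]]$values
    dT <- traj$distances[["150"]]$values
    expect_lt(max(abs(dT - d0) / d0), 1e-12)
    expect_lt(max(traj$residuals), 1e-12)
  }
})

test_that("the flow converges toward the normaliser on star and random fixtures", {
  a <- make_star(5, eps = 1)
  b <- make_star(5, eps = 4)
  traj <- run_flow(a, b, flow_config(n_iter = 150))
  expect_lt(traj$residuals["150"], traj$residuals["10"])
  expect_lt(traj$residuals["150"], traj$residuals["0"])
  expect_true(all(vapply(traj$distances, function(d) all(d$values > 0),
                         logical(1))))

  net <- make_random_pin(40, 5, seed = 11)
  end <- perturbed_state(net, 42)
  traj2 <- run_flow(net, end, flow_config(n_iter = 150))
  expect_lt(traj2$residuals["150"], traj2$residuals["0"])
})

test_that("an edge above its target curvature stretches, then flattens", {
  # craft a two-edge path with one edge's curvature above its target: that
  # edge's distance must grow at the first step (update rule sign) and its
  # curvature must then decrease (monotonicity), driving it toward the target
  net <- net_from_edges(rbind(c("a", "b"), c("b", "c")),
                        c(a = 1, b = 1, c = 1))
  d <- initial_distances(net)
  ric <- edge_curvature_from_distances(d, net)
  norm <- ric
  norm$values <- ric$values - c(0.5, 0)  # target below current on edge 1
  d1 <- flow_step(d, ric, norm, 0.1)
  expect_gt(d1$values[1], d$values[1])
  expect_equal(d1$values[2], d$values[2])
  ric1 <- edge_curvature_from_distances(d1, net)
  expect_lt(ric1$values[1], ric$values[1])
})

test_that("step-size failures inside the flow report the iteration", {
  net <- make_star(3, eps = 1)
  end <- make_star(3, eps = 30)
  dt_star <- max_stable_dt(edge_curvature(net), edge_curvature(end))
  expect_error(run_flow(net, end, flow_config(dt = 2 * dt_star)),
               "at iteration 1")
})

test_that("trajectories record thinned distances and predicted weights", {
  a <- make_star(4, eps = 1)
  b <- make_star(4, eps = 3)
  traj <- run_flow(a, b, flow_config(n_iter = 20, record_every = 5))
  expect_equal(traj$iterations, c(0, 5, 10, 15, 20))
  expect_length(traj$residuals, 21)
  W10 <- predicted_weights(traj, 10)
  expect_equal(W10$values, 1 / traj$distances[["10"]]$values)
  expect_error(predicted_weights(traj, 7), "not recorded")
  expect_length(trajectory_weights(traj), 4)  # iteration 0 dropped
})
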