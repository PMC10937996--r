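test_that("edge lists are read as simple undirected graphs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "A\tB"), f)
  g <- load_network(f)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "X\tX"), f2)
  expect_message(g2 <- load_network(f2), "self-loop")
  expect_equal(igraph::ecount(g2), 1)
  expect_false(igraph::any_loop(g2))
})

test_that("GraphML and SIF yield the same edge set as the edge list", {
  el <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "C\tD"), el)
  g_el <- load_network(el)

  gml <- withr::local_tempfile(fileext = ".graphml")
  igraph::write_graph(g_el, gml, format = "graphml")
  g_ml <- load_network(gml)

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A pp B C", "B pp C", "C pp D"), sif)  # A-C extra edge
  g_sif <- load_network(sif)

  canon <- function(g) {
    e <- igraph::as_edgelist(g)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(canon(g_ml), canon(g_el))
  expect_identical(canon(g_sif), sort(c("A B", "B C", "C D", "A C")))
})

test_that("parse and validation failures are reported", {
  expect_error(load_network(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("loneley_column", f)
  expect_error(load_network(f), "two columns")
})

test_that("genes mapping to one protein are averaged", {
  g <- igraph::make_graph(~ P - Q - R)
  mapping <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                        protein_id = c("P", "P", "Q", "R"))
  x <- c(g1 = 2, g2 = 4, g3 = 1, g4 = 1)
  net <- match_expression(g, x, mapping = mapping)
  expect_equal(net$expression[net$node_ids == "P"], 3)
})

test_that("matching keeps only the largest connected component", {
  g <- igraph::make_graph(~ A - B - C, D - E)
  x <- c(A = 1, B = 2, C = 3, D = 4)  # D matched but cut off from the LCC
  net <- match_expression(g, x)
  expect_setequal(net$node_ids, c("A", "B", "C"))
  expect_equal(n_nodes(net), 3)
})

test_that("the star fixture survives a full write/load/match round trip", {
  net0 <- make_star(3, eps = 2)
  stem <- withr::local_tempfile()
  write_matched_network(net0, stem)
  g <- load_network(paste0(stem, ".edges.tsv"))
  expr <- read_expression(paste0(stem, ".expr.tsv"))
  net <- match_expression(g, expr)
  expect_setequal(net$node_ids, c("l1", "l2", "i", "j"))
  key <- c("l1", "l2", "i", "j")
  expect_equal(unname(net$expression[match(key, net$node_ids)]),
               c(1, 1, 1, 2))
})

test_that("nonpositive matched expression errors unless a pseudocount is given", {
  g <- igraph::make_graph(~ A - B - C)
  x <- c(A = 0, B = 2, C = 3)
  expect_error(match_expression(g, x), "A")
  net <- match_expression(g, x, pseudocount = 0.5)
  expect_equal(unname(net$expression[net$node_ids == "A"]), 0.5)
  expect_error(match_expression(g, c(A = -1, B = 2, C = 3)), "nonnegative")
  expect_error(match_expression(g, c(A = 1, B = 2)), "fewer than 3")
})

test_that("match_expression is idempotent", {
  net <- make_random_pin(25, 4, seed = 7)
  again <- match_expression(as_igraph(net),
                            stats::setNames(net$expression, net$node_ids))
  expect_identical(again$node_ids, net$node_ids)
  expect_equal(again$expression, net$expression)
  expect_equal(as.matrix(again$adjacency), as.matrix(net$adjacency))
})

test_that("mass-action weights are endpoint products", {
  net <- make_star(3, eps = 2)
  W <- weighted_adjacency(net)
  expect_equal(edge_value(W, "i", "j"), 2)
  expect_equal(edge_value(W, "i", "l1"), 1)
  expect_equal(edge_value(W, "j", "i"), edge_value(W, "i", "j"))

  unit <- matched_network(net$adjacency, rep(1, 4), net$node_ids)
  expect_true(all(weighted_adjacency(unit)$values == 1))

  scaled <- matched_network(net$adjacency, 3 * net$expression, net$node_ids)
  expect_equal(weighted_adjacency(scaled)$values, 9 * W$values)
})

test_that("transition matrix is row-stochastic with the k-star closed form", {
  net <- make_star(3, eps = 2)
  P <- transition_matrix(net)
  expect_equal(unname(Matrix::rowSums(P)), rep(1, 4))
  # hub row over (j, l1, l2): eps/(k+eps-1), then 1/(k+eps-1) each
  expect_equal(P["i", "j"], 0.5)
  expect_equal(P["i", "l1"], 0.25)
  expect_equal(P["i", "l2"], 0.25)
  expect_equal(P["l1", "i"], 1)
  expect_equal(P["j", "i"], 1)

  for (seed in 1:5) {
    netr <- make_random_pin(30, 4, seed = seed)
    expect_equal(unname(Matrix::rowSums(transition_matrix(netr))),
                 rep(1, n_nodes(netr)))
  }
})

test_that("closed-form stationary distribution is the random walk's", {
  for (seed in 1:50) {
    net <- make_random_pin(sample(10:50, 1), 4, seed = seed)
    pi <- stationary_distribution(net)
    expect_equal(sum(pi), 1)
    d <- dense_net(net)
    expect_lt(max(abs(pi - ref_stationary(d$A, d$x))), 1e-10)
    # fixed-point property pi P = pi
    P <- transition_matrix(net)
    expect_lt(max(abs(as.numeric(pi %*% P) - pi)), 1e-12)
  }
})

test_that("hub stationary probability is 1/2 and regular graphs are uniform", {
  for (k in c(2, 5, 12)) for (eps in c(0.3, 1, 4)) {
    pi <- stationary_distribution(make_star(k, eps))
    expect_equal(unname(pi["i"]), 0.5)
  }
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  net <- match_expression(ring, stats::setNames(rep(2, 6), letters[1:6]))
  expect_equal(unname(stationary_distribution(net)), rep(1 / 6, 6))
})

test_that("matched_network rejects invalid inputs", {
  A <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(matched_network(A, c(1, -1)), "positive")
  expect_error(matched_network(A, c(1, 1, 1)), "length")
  A3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A3[1, 2] <- A3[2, 1] <- 1  # c isolated
  expect_error(matched_network(A3, rep(1, 3)), "isolated|connected")
})
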