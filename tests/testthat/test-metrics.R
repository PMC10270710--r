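test_that("weight-to-length remap is the reciprocal with Inf for non-edges", {
  w <- matrix(c(0, 1, 4, 1, 0, 0, 4, 0, 0), 3, 3)
  l <- weights_to_lengths(w)
  expect_equal(l[1, 2], 1)
  expect_equal(l[1, 3], 0.25)
  expect_identical(l[2, 3], Inf)
  expect_identical(unname(diag(l)), rep(0, 3))
})

test_that("shortest paths handle direct-vs-multihop trade-offs", {
  # path graph A-B-C, unit weights
  d <- shortest_path_lengths(path_graph(3))
  expect_equal(d, matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3))

  # triangle with weights 1,1,10: lengths 1,1,0.1; direct A-B (1) beats
  # A-C-B (1.1)
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 10
  d <- shortest_path_lengths(w)
  expect_equal(d[1, 2], 1)
  expect_equal(d[1, 3], 0.1)

  # two disconnected dyads
  w2 <- matrix(0, 4, 4)
  w2[1, 2] <- w2[2, 1] <- 1
  w2[3, 4] <- w2[4, 3] <- 1
  d2 <- shortest_path_lengths(w2)
  expect_identical(d2[1, 3], Inf)
  expect_identical(d2[2, 4], Inf)
})

test_that("characteristic path length and global efficiency closed forms", {
  d3 <- shortest_path_lengths(path_graph(3))
  expect_equal(characteristic_path_length(d3)$value, 4 / 3)
  expect_equal(global_efficiency(d3), 5 / 6)

  dK <- shortest_path_lengths(complete_graph(4))
  expect_equal(characteristic_path_length(dK)$value, 1)
  expect_equal(global_efficiency(dK), 1)

  # isolated 4th node: mean over the 3 reachable pairs only
  w <- path_graph(4)
  w[3, 4] <- w[4, 3] <- 0
  cpl <- suppressWarnings(characteristic_path_length(shortest_path_lengths(w)))
  expect_equal(cpl$value, (1 + 1 + 2) / 3)
  expect_equal(cpl$n_unreachable_pairs, 3)

  # fully disconnected graph: efficiency 0, path length undefined
  z <- matrix(0, 3, 3)
  expect_equal(global_efficiency(shortest_path_lengths(z)), 0)
  expect_error(characteristic_path_length(shortest_path_lengths(z)),
               class = "graphme_metric_undefined_error")
})

test_that("node strength sums incident weights and scales linearly", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1   # AB
  w[2, 3] <- w[3, 2] <- 2   # BC
  w[1, 3] <- w[3, 1] <- 3   # AC
  expect_equal(node_strength(w), c(4, 3, 5))
  expect_equal(node_strength(2 * w), 2 * c(4, 3, 5))
  w0 <- matrix(0, 3, 3)
  w0[1, 2] <- w0[2, 1] <- 1
  expect_equal(node_strength(w0)[3], 0)
})

test_that("clustering coefficient matches the geometric-mean formula", {
  expect_equal(clustering_coef(complete_graph(3)), rep(1, 3))
  expect_equal(clustering_coef(path_graph(3)), rep(0, 3))

  # triangle with weights 1,1,8: normalized (0.125, 0.125, 1);
  # each C_i = (0.125 * 0.125 * 1)^(1/3) = 0.25
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 8
  expect_equal(clustering_coef(w), rep(0.25, 3))
})

test_that("local efficiency is the neighbor-subgraph global efficiency", {
  expect_equal(local_efficiency(complete_graph(3)), rep(1, 3))
  expect_equal(local_efficiency(complete_graph(4)), rep(1, 4))
  # star graph: no edges between any node's neighbors
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(local_efficiency(star), rep(0, 5))
})

test_that("betweenness matches closed forms including fractional ties", {
  expect_equal(betweenness_nodes(path_graph(3)), c(0, 1, 0))
  expect_equal(betweenness_nodes(complete_graph(5)), rep(0, 5))
  # 4-cycle: two equal shortest paths between opposite corners
  ring <- ring_lattice(4, 1)
  expect_equal(betweenness_nodes(ring), rep(0.5, 4))
})

test_that("navigation efficiency enumerates greedy walks correctly", {
  # 3 collinear nodes, edges only 1-2 and 2-3, unit weights
  w <- path_graph(3)
  nt <- tiny_node_table(cbind(c(0, 1, 2), 0, 0))
  nav <- navigation_efficiency(w, nt)
  expect_equal(nav$value, 5 / 6)
  expect_true(all(nav$success[upper.tri(nav$success)]))

  # complete graph: greedy hops straight to the target
  wc <- complete_graph(4) * 2
  ntc <- tiny_node_table(cbind(c(0, 3, 9, 20), 0, 0))
  navc <- navigation_efficiency(wc, ntc)
  expect_equal(navc$value, 2)  # every direct edge has length 1/2

  # dead end: from node 4 toward node 1, the geometrically closest
  # neighbor is the dead-end node 2
  wd <- matrix(0, 4, 4)
  wd[4, 2] <- wd[2, 4] <- 1   # s - deadend
  wd[4, 3] <- wd[3, 4] <- 1   # s - m
  wd[3, 1] <- wd[1, 3] <- 1   # m - t
  ntd <- tiny_node_table(cbind(c(0, 1, 3, 10), 0, 0))
  navd <- navigation_efficiency(wd, ntd)
  expect_false(navd$success[4, 1])
  expect_equal(navd$efficiency[4, 1], 0)
  expect_true(navd$success[3, 1])

  # missing coordinates
  expect_error(navigation_efficiency(w, cbind(c(0, NA, 2), 0, 0)),
               class = "graphme_value_error")
})

test_that("navigation is never more efficient than shortest paths", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- 12
    coords <- cbind(runif(n, -50, 50), runif(n, -50, 50), runif(n, -50, 50))
    w <- random_weighted_graph(n, p = 0.4, seed = seed + 100)
    nav <- navigation_efficiency(w, tiny_node_table(coords))
    d <- shortest_path_lengths(w)
    sp_eff <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
    expect_true(all(nav$efficiency <= sp_eff + 1e-12))
  }
})

test_that("rewired surrogates preserve degrees and the weight multiset", {
  for (seed in 1:20) {
    w <- random_weighted_graph(15, p = 0.3, seed = seed)
    set.seed(seed)
    r <- rewire_degseq_weighted(w, rewires_per_edge = 10)
    expect_identical(r, t(r))
    expect_identical(unname(diag(r)), rep(0, 15))
    expect_equal(rowSums(r > 0), rowSums(w > 0))
    expect_equal(sort(r[upper.tri(r) & r > 0]),
                 sort(w[upper.tri(w) & w > 0]))
  }
  # rewiring does move edges
  w <- random_weighted_graph(20, p = 0.3, seed = 7)
  set.seed(1)
  r <- rewire_degseq_weighted(w, 10)
  expect_gt(sum((r > 0) != (w > 0)), 0)
})

test_that("normalized clustering behaves on lattices, nulls and K_n", {
  # complete graph: no legal swap exists, nulls are identical copies
  cn <- normalized_clustering(complete_graph(6), n_nulls = 5, seed = 1)
  expect_equal(cn$value, 1)

  # ring lattice has far more clustering than its rewired surrogates
  cnl <- normalized_clustering(ring_lattice(30, 3), n_nulls = 30, seed = 2)
  expect_gt(cnl$value, 1.5)

  # the null ensemble mean is stable across independent ensembles:
  # two ensembles of the same random graph agree within 3 combined SEM
  w <- random_weighted_graph(40, p = 0.25, seed = 11)
  a <- normalized_clustering(w, n_nulls = 60, seed = 3)
  b <- normalized_clustering(w, n_nulls = 60, seed = 4)
  sem <- sqrt(a$null_sd^2 / 60 + b$null_sd^2 / 60)
  expect_lt(abs(a$null_mean - b$null_mean), 3 * sem + 1e-12)
})

test_that("metric profile matches closed forms on K_5 and is deterministic", {
  nt <- tiny_node_table(cbind(seq(0, 4) * 10, 0, 0))
  p <- suppressWarnings(connectome_metrics(complete_graph(5), nt,
                                           n_nulls = 10, seed = 42))
  g <- p$globals
  expect_equal(unname(g["strength"]), 4)
  expect_equal(unname(g["char_path_length"]), 1)
  expect_equal(unname(g["global_efficiency"]), 1)
  expect_equal(unname(g["betweenness"]), 0)
  expect_equal(unname(g["clustering"]), 1)
  expect_equal(unname(g["local_efficiency"]), 1)
  expect_equal(unname(g["normalized_clustering"]), 1)

  p2 <- suppressWarnings(connectome_metrics(complete_graph(5), nt,
                                            n_nulls = 10, seed = 42))
  expect_identical(p$globals, p2$globals)

  # tidy/glance interfaces
  td <- tidy(p)
  expect_equal(nrow(td), 8)
  expect_true(all(c("metric", "value") %in% names(td)))
  expect_equal(nrow(glance(p)), 1)
})

test_that("uniform weight scaling transforms metrics as expected", {
  nt <- tiny_node_table(cbind(runif(10, -40, 40), runif(10, -40, 40), 0))
  w <- random_weighted_graph(10, p = 0.6, seed = 31)
  c_scale <- 3.7
  p1 <- suppressWarnings(connectome_metrics(w, nt, n_nulls = 15, seed = 9))
  p2 <- suppressWarnings(connectome_metrics(c_scale * w, nt, n_nulls = 15,
                                            seed = 9))
  g1 <- p1$globals
  g2 <- p2$globals
  expect_equal(unname(g2["strength"]), unname(c_scale * g1["strength"]))
  expect_equal(unname(g2["char_path_length"]),
               unname(g1["char_path_length"] / c_scale))
  expect_equal(unname(g2["global_efficiency"]),
               unname(c_scale * g1["global_efficiency"]))
  expect_equal(unname(g2["clustering"]), unname(g1["clustering"]))
  expect_equal(unname(g2["normalized_clustering"]),
               unname(g1["normalized_clustering"]))
  expect_equal(unname(g2["betweenness"]), unname(g1["betweenness"]))
})

test_that("profile equals brute-force oracle on a small synthetic connectome", {
  w <- random_weighted_graph(8, p = 0.7, seed = 123)
  d <- shortest_path_lengths(w)
  d_oracle <- oracle_shortest_paths(w)
  expect_equal(d, d_oracle, tolerance = 1e-9)
  expect_equal(betweenness_nodes(w), oracle_betweenness(w), tolerance = 1e-9)
  expect_equal(clustering_coef(w), oracle_clustering(w), tolerance = 1e-12)
  expect_equal(local_efficiency(w), oracle_local_efficiency(w),
               tolerance = 1e-9)
  expect_equal(global_efficiency(d), oracle_global_efficiency(d_oracle),
               tolerance = 1e-9)
})
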