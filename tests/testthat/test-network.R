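test_that("density thresholding keeps the strongest pairs with deterministic ties", {
  # complete graph at density 1 on 64 nodes
  set.seed(1)
  v <- matrix(0, 64, 64)
  v[upper.tri(v)] <- runif(choose(64, 2))
  v <- v + t(v)
  net1 <- threshold_by_density(fake_mi(v), 1.0)
  expect_equal(count_edges(net1), 2016)

  net01 <- threshold_by_density(fake_mi(v), 0.1)
  expect_equal(count_edges(net01), 202)      # round(0.1 * 2016)

  # 4-node brute-force ranking oracle
  m4 <- matrix(0, 4, 4)
  m4[upper.tri(m4)] <- c(0.9, 0.1, 0.8, 0.4, 0.2, 0.7)
  m4 <- m4 + t(m4)
  net <- threshold_by_density(fake_mi(m4), 0.5)
  ut <- which(upper.tri(m4))
  top3 <- ut[order(-m4[ut])][1:3]
  expect_equal(sort(which(upper.tri(m4) & net$adjacency == 1)), sort(top3))
  expect_equal(net$threshold_value, sort(m4[ut], decreasing = TRUE)[3])

  # ties at the cut: ascending (row, column) wins
  tied <- matrix(0, 3, 3)
  tied[upper.tri(tied)] <- c(0.5, 0.5, 0.5)
  tied <- tied + t(tied)
  nt <- threshold_by_density(fake_mi(tied), 1 / 3)
  expect_equal(nt$adjacency[1, 2], 1)
  expect_equal(sum(nt$adjacency), 2)

  expect_error(threshold_by_density(fake_mi(m4), 0),
               class = "afcn_invalid_argument")
  expect_warning(threshold_by_density(fake_mi(m4), 0.01), "zero edges")
})

test_that("edge count, degree, giant component and clustering match hand oracles", {
  full <- adj_to_net(matrix(1, 64, 64) - diag(64))
  expect_equal(count_edges(full), 2016)
  expect_equal(average_degree(full), 63)
  expect_equal(giant_component_size(full), 64)
  expect_equal(average_clustering(full), 1)
  expect_equal(characteristic_path_length(full), 1)

  empty <- adj_to_net(matrix(0, 5, 5))
  expect_equal(count_edges(empty), 0)
  expect_equal(average_degree(empty), 0)
  expect_equal(giant_component_size(empty), 1)
  expect_error(characteristic_path_length(empty),
               class = "afcn_undefined_metric")

  ring10 <- generate_planted_network(10, "lattice", k = 2)
  rnet <- adj_to_net(ring10$adjacency)
  expect_equal(count_edges(rnet), 10)
  expect_equal(average_degree(rnet), 2)
  expect_equal(average_clustering(rnet), 0)

  # cycle on 6 nodes: L = 1.8 by full enumeration
  ring6 <- adj_to_net(generate_planted_network(6, "lattice", k = 2)$adjacency)
  expect_equal(characteristic_path_length(ring6), 1.8)

  # disjoint cliques of 5 and 3
  adj <- matrix(0, 8, 8)
  adj[1:5, 1:5] <- 1; adj[6:8, 6:8] <- 1; diag(adj) <- 0
  expect_equal(giant_component_size(adj_to_net(adj)), 5)

  # triangle plus pendant: local coefficients (1, 1, 1/3, 0) -> mean 7/12
  tp <- matrix(0, 4, 4)
  tp[1, 2] <- tp[2, 3] <- tp[1, 3] <- tp[3, 4] <- 1
  tp <- tp + t(tp); tp[tp > 1] <- 1
  expect_equal(average_clustering(adj_to_net(tp)), 7 / 12)
  expect_equal(average_clustering(adj_to_net(tp)), brute_clustering(tp))

  # two disjoint edges: reachable-pairs L is 1; penalized counts the rest at n
  de <- matrix(0, 4, 4)
  de[1, 2] <- de[2, 1] <- de[3, 4] <- de[4, 3] <- 1
  expect_equal(characteristic_path_length(adj_to_net(de)), 1)
  expect_equal(characteristic_path_length(adj_to_net(de), mode = "penalized"),
               (2 * 1 + 4 * 4) / 6)
})

test_that("metrics agree with brute force on 500 random graphs", {
  set.seed(99)
  for (i in 1:500) {
    n <- sample(3:7, 1)
    adj <- random_adj(n, runif(1, 0.2, 0.9))
    net <- adj_to_net(adj)
    expect_equal(average_clustering(net), brute_clustering(adj))
    expect_equal(giant_component_size(net), brute_giant(adj))
    if (sum(adj) > 0) {
      expect_equal(characteristic_path_length(net), brute_path_length(adj))
      expect_equal(characteristic_path_length(net, mode = "penalized"),
                   brute_path_length(adj, mode = "penalized"))
    }
  }
})

test_that("null ensemble matches counts and the Erdos-Renyi expectation", {
  null <- build_null_ensemble(64, 605, ensemble_size = 100, seed = 5)
  expect_equal(null$n_edges, 605)
  # ER clustering expectation ~ density
  expect_lt(abs(null$mean_C_rand - 0.3), 3 * null$sd_C_rand)
  # determinism
  null2 <- build_null_ensemble(64, 605, ensemble_size = 100, seed = 5)
  expect_identical(null$mean_C_rand, null2$mean_C_rand)
  expect_identical(null$sigma_rand_values, null2$sigma_rand_values)

  # forced completeness: degenerate ensemble
  nc <- build_null_ensemble(5, 10, ensemble_size = 20, seed = 1)
  expect_equal(nc$mean_C_rand, 1)
  expect_equal(nc$mean_L_rand, 1)
  expect_equal(nc$sd_C_rand, 0)

  expect_error(build_null_ensemble(5, 11), class = "afcn_invalid_argument")
})

test_that("normalization is exact for complete graphs and calibrated for null draws", {
  full <- adj_to_net(matrix(1, 6, 6) - diag(6))
  null <- build_null_ensemble(6, 15, ensemble_size = 10, seed = 2)
  nm <- normalized_metrics(full, null)
  expect_equal(nm$C_norm, 1)
  expect_equal(nm$L_norm, 1)
  sw <- suppressWarnings(small_world_index(full, null))
  expect_equal(sw$sigma, 1)
  expect_true(is.na(sw$z))    # degenerate null sigma distribution

  # draws from the null sit near 1 (self-consistency, 20 draws)
  null64 <- build_null_ensemble(64, 400, ensemble_size = 100, seed = 3)
  set.seed(30)
  ok <- vapply(1:20, function(i) {
    g <- igraph::sample_gnm(64, 400)
    net <- adj_to_net(as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)))
    nm <- normalized_metrics(net, null64)
    abs(nm$C_norm - 1) <= 3 * null64$sd_C_rand / null64$mean_C_rand &&
      abs(nm$L_norm - 1) <= 3 * null64$sd_L_rand / null64$mean_L_rand
  }, TRUE)
  expect_gte(mean(ok), 0.9)

  # mismatched null is rejected
  expect_error(normalized_metrics(full, null64),
               class = "afcn_invalid_argument")
})

test_that("Watts-Strogatz graphs register as small-world", {
  null <- build_null_ensemble(64, 192, ensemble_size = 100, seed = 11)
  res <- vapply(1:20, function(s) {
    ws <- generate_planted_network(64, "smallworld", k = 6, p = 0.05, seed = s)
    sw <- small_world_index(adj_to_net(ws$adjacency), null)
    c(sw$sigma, sw$z)
  }, c(0, 0))
  expect_gte(mean(res[1, ] > 1), 0.95)
  expect_gte(mean(res[2, ] > 2), 0.9)
})

test_that("density sweep is nested, monotone, and complete", {
  set.seed(12)
  v <- matrix(0, 16, 16)
  v[upper.tri(v)] <- runif(120)
  v <- v + t(v)
  mi <- fake_mi(v)

  sweep <- density_sweep(mi, ensemble_size = 20, null_seed = 4)
  expect_equal(nrow(sweep), 21)                        # default grid
  expect_true(all(diff(sweep$n_edges) > 0))            # strictly increasing
  expect_true(all(diff(sweep$giant_component) >= 0))   # non-decreasing

  # threshold nesting: edges at lower density are a subset
  e1 <- threshold_by_density(mi, 0.1)$adjacency
  e2 <- threshold_by_density(mi, 0.3)$adjacency
  expect_true(all(e2[e1 == 1] == 1))

  expect_error(density_sweep(mi, densities = c(0.1, 1.5)),
               class = "afcn_invalid_argument")
})
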