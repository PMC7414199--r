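path_graph <- function(nodes) {
  igraph::make_graph(rep(nodes, each = 2)[-c(1, 2 * length(nodes))], directed = FALSE)
}

test_that("three-node path has the textbook centrality values", {
  g <- path_graph(c("A", "B", "C"))
  cent <- compute_centralities(g, epc_reps = 10, epc_retain_p = 1, rng_seed = 1)
  b <- cent[cent$node == "B", ]
  expect_equal(b$degree, 2)
  expect_equal(b$betweenness, 1)
  expect_equal(b$stress, 1)
  expect_equal(b$closeness, 1)
  expect_equal(cent$closeness[cent$node == "A"], 2 / 3)
})

test_that("betweenness, stress, closeness match brute force on all labeled connected graphs up to 5 nodes", {
  for (n in 2:5) {
    pairs <- utils::combn(n, 2)
    n_pairs <- ncol(pairs)
    for (mask in 0:(2^n_pairs - 1)) {
      on <- which(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)) > 0)
      g <- igraph::make_empty_graph(n, directed = FALSE)
      if (length(on) > 0) g <- igraph::add_edges(g, as.vector(pairs[, on]))
      if (!igraph::is_connected(g)) next
      g <- igraph::set_vertex_attr(g, "name", value = paste0("v", 1:n))
      sp <- mirffl:::sp_dist_sigma(g)
      bs <- mirffl:::betweenness_stress(sp$D, sp$S)
      oracle <- bf_centralities(g)
      expect_equal(bs$betweenness, oracle$betweenness, tolerance = 1e-12)
      expect_equal(bs$stress, oracle$stress)
      expect_equal(mirffl:::closeness_from_dist(sp$D), oracle$closeness,
                   tolerance = 1e-12)
    }
  }
})

test_that("centralities match brute force and igraph on random 6-7 node graphs", {
  withr::local_seed(6)
  for (i in 1:12) {
    g <- random_connected_graph(sample(6:7, 1), p = 0.45)
    sp <- mirffl:::sp_dist_sigma(g)
    bs <- mirffl:::betweenness_stress(sp$D, sp$S)
    oracle <- bf_centralities(g)
    expect_equal(bs$betweenness, oracle$betweenness, tolerance = 1e-12)
    expect_equal(bs$stress, oracle$stress)
    # independent library cross-check for betweenness
    expect_equal(bs$betweenness, unname(igraph::betweenness(g)), tolerance = 1e-9)
  }
})

test_that("centralities are equivariant under node relabeling", {
  withr::local_seed(8)
  g <- random_connected_graph(7, 0.4)
  perm <- sample(7)
  g2 <- igraph::permute(g, perm)
  c1 <- compute_centralities(g, epc_reps = 1, epc_retain_p = 1, rng_seed = 1)
  c2 <- compute_centralities(g2, epc_reps = 1, epc_retain_p = 1, rng_seed = 1)
  for (m in c("degree", "betweenness", "stress", "closeness")) {
    expect_equal(c2[[m]][match(c1$node, c2$node)], c1[[m]])
  }
})

test_that("stress and betweenness vanish together", {
  withr::local_seed(9)
  for (i in 1:10) {
    g <- random_connected_graph(sample(4:7, 1), 0.5)
    sp <- mirffl:::sp_dist_sigma(g)
    bs <- mirffl:::betweenness_stress(sp$D, sp$S)
    expect_equal(bs$stress == 0, bs$betweenness == 0)
    expect_true(all(bs$stress >= bs$betweenness - 1e-12))
  }
})

test_that("EPC limits: full retention gives n-1, zero retention gives 0", {
  withr::local_seed(10)
  g <- random_connected_graph(12, 0.3)
  expect_equal(epc_centrality(g, reps = 3, retain_p = 1, rng_seed = 1),
               rep(11, 12))
  expect_equal(epc_centrality(g, reps = 3, retain_p = 0, rng_seed = 1),
               rep(0, 12))
})

test_that("EPC replicate standard error is small at 1000 realizations", {
  withr::local_seed(11)
  g <- random_connected_graph(20, 0.2)
  reps <- vapply(1:6, function(s) {
    epc_centrality(g, reps = 1000, retain_p = 0.5, rng_seed = 100 + s)
  }, numeric(20))
  per_node_sd <- apply(reps, 1, stats::sd)
  expect_lt(max(per_node_sd), 0.5)
})

test_that("top-n selection keeps boundary ties and clamps large n", {
  nodes <- letters[1:5]
  vals <- c(5, 4, 4, 3, 1)
  expect_setequal(mirffl:::top_n_dense(nodes, vals, 2), c("a", "b", "c"))
  expect_setequal(mirffl:::top_n_dense(nodes, vals, 1), "a")
  expect_warning(out <- mirffl:::top_n_dense(nodes, vals, 10), "clamped")
  expect_setequal(out, nodes)
})

test_that("star center is the unique hub at n = 1", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  star <- igraph::set_vertex_attr(star, "name", value = c("HUB", paste0("leaf", 1:5)))
  cent <- compute_centralities(star, epc_reps = 200, epc_retain_p = 0.5, rng_seed = 2)
  expect_equal(identify_hubs(cent, 1, seeds = c("HUB", "leaf1")), "HUB")
  # a node missing from one measure's top set is not a hub
  expect_false("leaf1" %in% identify_hubs(cent, 1))
})

test_that("monotone rescaling of betweenness leaves ranks unchanged", {
  withr::local_seed(12)
  g <- random_connected_graph(8, 0.4)
  cent <- compute_centralities(g, epc_reps = 1, epc_retain_p = 1, rng_seed = 1)
  n <- igraph::vcount(g)
  normalized <- cent$betweenness / ((n - 1) * (n - 2) / 2)
  expect_equal(mirffl:::dense_rank_desc(normalized),
               mirffl:::dense_rank_desc(cent$betweenness))
})
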