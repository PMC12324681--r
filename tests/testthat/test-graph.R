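# Similarity graphs, singletons, components, Leiden clustering and the
# three null models.

random_sim <- function(n, p_edge = 0.1, seed = 1, max_score = 100) {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  similarity_matrix(ids, pairs[, 1], pairs[, 2],
                    runif(nrow(pairs), 0, max_score), species = "SPX")
}

test_that("edges require the normalized score to strictly exceed the cut", {
  sim <- similarity_matrix(c("a", "b"), "a", "b", 10)
  g <- build_graph(sim)
  expect_equal(g$normalization_max, 10)
  expect_equal(igraph::ecount(g$unweighted), 1)

  # normalized exactly 0.1: excluded
  sim2 <- similarity_matrix(c("a", "b", "c"), c("a", "a"), c("b", "c"),
                            c(100, 10))
  g2 <- build_graph(sim2)
  expect_equal(igraph::ecount(g2$unweighted), 1)
  expect_equal(igraph::ends(g2$unweighted, 1), cbind("a", "b"))
  # the weighted graph keeps every scored pair
  expect_equal(igraph::ecount(g2$weighted), 2)

  # thresholded edge set equals brute force on random matrices
  for (seed in 1:5) {
    sim3 <- random_sim(40, 0.15, seed)
    g3 <- build_graph(sim3, edge_threshold = 0.3)
    m <- as.matrix(sim3$scores) / max(sim3$scores)
    want <- which(m > 0.3 & upper.tri(m), arr.ind = TRUE)
    expect_equal(igraph::ecount(g3$unweighted), nrow(want))
  }
})

test_that("singletons are defined on raw alignment scores", {
  sim <- similarity_matrix(c("a", "b", "c", "d"), "a", "b", 5)
  expect_setequal(find_singletons(sim), c("c", "d"))
  empty <- similarity_matrix(c("x", "y"))
  expect_setequal(find_singletons(empty), c("x", "y"))
  expect_equal(igraph::ecount(build_graph(empty)$unweighted), 0)
  full <- similarity_matrix(c("a", "b", "c"), c("a", "a", "b"),
                            c("b", "c", "c"), c(1, 2, 3))
  expect_length(find_singletons(full), 0)
})

test_that("threshold components equal a union-find oracle", {
  sim <- similarity_matrix(c("a", "b", "c"), c("a", "b"), c("b", "c"),
                           c(4, 8))
  # threshold above the maximum: all singletons
  above <- components_at_threshold(sim, 9)
  expect_equal(above$n_communities, 0)
  expect_equal(above$n_singletons, 3)
  # threshold 0 on a connected graph: one component
  expect_equal(components_at_threshold(sim, 0)$n_communities, 1)
  # raw threshold is inclusive
  expect_equal(components_at_threshold(sim, 8)$n_communities, 1)
  expect_equal(components_at_threshold(sim, 8)$n_singletons, 1)

  for (seed in 1:30) {
    n <- 25
    sim_r <- random_sim(n, 0.08, seed + 100)
    thr <- 40
    got <- components_at_threshold(sim_r, thr)
    m <- as.matrix(sim_r$scores)
    edges <- which(m >= thr & m > 0 & upper.tri(m), arr.ind = TRUE)
    oracle <- uf_components(n, edges)
    sizes <- tabulate(oracle)
    expect_equal(got$n_communities, sum(sizes >= 2))
    expect_equal(got$n_singletons, sum(sizes == 1))
    expect_equal(got$n_unique, got$n_communities + got$n_singletons)
  }
})

test_that("Leiden clustering respects separable structure", {
  # two disconnected cliques
  ids <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:4))
  pairs <- rbind(t(combn(1:5, 2)), t(combn(6:9, 2)))
  sim <- similarity_matrix(ids, pairs[, 1], pairs[, 2],
                           runif(nrow(pairs), 5, 10))
  cl <- leiden_communities(build_graph(sim))
  expect_equal(cl$n_communities, 2)
  expect_equal(cl$largest_community, 5)
  expect_equal(cl$n_singletons, 0)

  # complete graph: one community at the default low resolution
  pairs2 <- t(combn(1:8, 2))
  sim2 <- similarity_matrix(sprintf("c%d", 1:8), pairs2[, 1], pairs2[, 2],
                            rep(7, nrow(pairs2)))
  cl2 <- leiden_communities(build_graph(sim2))
  expect_equal(cl2$n_communities, 1)

  # clustering results are reproducible under a fixed seed
  planted <- plant_similarity("SPX", c(20, 15, 30), 10, seed = 3)
  g <- build_graph(planted$sim)
  r1 <- leiden_communities(g, seed = 5, singletons = find_singletons(planted$sim))
  r2 <- leiden_communities(g, seed = 5, singletons = find_singletons(planted$sim))
  expect_identical(r1$communities, r2$communities)
  expect_equal(r1$n_communities, 3)
})

test_that("clustering results enforce the partition contract", {
  expect_error(clustering_result("S", list(c("a", "b")), c("b")), "partition")
  expect_error(clustering_result("S", list("a"), character()), ">= 2")
  ok <- clustering_result("S", list(c("a", "b"), c("c", "d", "e")), "f")
  expect_equal(ok$n_unique, 3)
  expect_equal(ok$largest_community, 3)
})

test_that("degree-preserving rewiring keeps the exact degree multiset", {
  planted <- plant_similarity("SPX", c(15, 25, 10), 5, seed = 9)
  g <- build_graph(planted$sim)
  rw <- rewire_degree_preserving(g, seed = 2)
  d0 <- igraph::degree(g$unweighted)
  d1 <- igraph::degree(rw$unweighted)
  expect_equal(d1[names(d0)], d0)
  expect_false(any(igraph::which_loop(rw$unweighted)))
  expect_false(any(igraph::which_multiple(rw$unweighted)))

  # a two-edge path admits no swap and is returned unchanged
  path_sim <- similarity_matrix(c("a", "b", "c"), c("a", "b"), c("b", "c"),
                                c(5, 5))
  pg <- build_graph(path_sim)
  rw2 <- rewire_degree_preserving(pg, seed = 1)
  e0 <- apply(igraph::as_edgelist(pg$unweighted), 1,
              function(x) paste(sort(x), collapse = "-"))
  e1 <- apply(igraph::as_edgelist(rw2$unweighted), 1,
              function(x) paste(sort(x), collapse = "-"))
  expect_setequal(e1, e0)

  # rewiring genuinely randomizes: triangle counts move while degrees stay
  set.seed(4)
  base <- random_sim(50, 0.12, seed = 44)
  bg <- build_graph(base, edge_threshold = 0)
  t0 <- igraph::count_triangles(bg$unweighted)
  tri <- vapply(1:100, function(s) {
    sum(igraph::count_triangles(
      rewire_degree_preserving(bg, seed = s)$unweighted))
  }, 0)
  expect_gt(length(unique(tri)), 1)
  expect_false(all(tri == sum(t0)))
})

test_that("density-matched and score-permutation nulls preserve invariants", {
  base <- random_sim(60, 0.1, seed = 7)
  g <- build_graph(base, edge_threshold = 0)
  rg <- random_graph_same_density(g, seed = 1)
  expect_equal(igraph::vcount(rg$unweighted), igraph::vcount(g$unweighted))
  expect_equal(igraph::ecount(rg$unweighted), igraph::ecount(g$unweighted))

  perm <- randomize_score_matrix(base, seed = 1)
  expect_equal(sort(perm$scores@x), sort(base$scores@x))
  expect_true(Matrix::isSymmetric(perm$scores))
  expect_equal(Matrix::diag(perm$scores), rep(0, 60), ignore_attr = TRUE)

  # different seeds give different edge sets on 100-node graphs
  big <- random_sim(100, 0.05, seed = 8)
  gb <- build_graph(big, edge_threshold = 0)
  e1 <- igraph::as_edgelist(random_graph_same_density(gb, seed = 1)$unweighted)
  e2 <- igraph::as_edgelist(random_graph_same_density(gb, seed = 2)$unweighted)
  key <- function(e) sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  expect_false(identical(key(e1), key(e2)))
})

test_that("community-size histograms conserve mass and recover the tail", {
  res <- clustering_result("S", list(c("a", "b"), c("c", "d"), c("e", "f")),
                           character())
  h <- cluster_size_histogram(res)
  expect_equal(h$histogram, data.frame(size = 2L, frequency = 3L))

  # planted power-law sizes: log-log slope recovered
  set.seed(10)
  sizes <- sample(2:60, 1000, replace = TRUE, prob = (2:60)^-2)
  ids <- sprintf("p%05d", seq_len(sum(sizes)))
  comm <- split(ids, rep(seq_along(sizes), sizes))
  res2 <- clustering_result("S", unname(comm), character())
  h2 <- cluster_size_histogram(res2)
  expect_equal(sum(h2$histogram$size * h2$histogram$frequency), sum(sizes))
  expect_lt(abs(h2$loglog_slope - (-2)), 0.3)
})
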