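# 2D projections of embedding vectors and the binned label-entropy map.

test_that("PCA recovers exact low-rank geometry and handles duplicates", {
  # points lying in a 2D plane embedded in 128-d: pairwise distances are
  # reproduced exactly by the first two components
  set.seed(3)
  basis <- qr.Q(qr(matrix(rnorm(128 * 2), 128)))  # orthonormal 128 x 2
  plane <- matrix(rnorm(40 * 2, sd = 4), 40)
  emb <- embedding_set(sprintf("p%02d", 1:40), plane %*% t(basis))
  proj <- project_embeddings(emb, "pca")
  expect_equal(unname(as.matrix(dist(proj$coords))),
               unname(as.matrix(dist(plane))), tolerance = 1e-8)

  v <- matrix(rnorm(2 * 128), 2)
  dup <- embedding_set(c("a", "b", "c", "d"),
                       rbind(v[1, ], v[1, ], v[2, ], v[1, ] + v[2, ]))
  pd <- project_embeddings(dup, "pca")
  expect_equal(pd$coords["a", ], pd$coords["b", ], ignore_attr = TRUE)
  pi2 <- project_embeddings(dup, "ica")
  expect_equal(pi2$coords["a", ], pi2$coords["b", ], ignore_attr = TRUE)

  expect_error(project_embeddings(embedding_set("a", matrix(0, 1, 128))),
               "2 pockets")
})

test_that("the neighbor embedding separates well-separated mixtures", {
  cfg <- synthetic_config(seed = 9, n_components = 3,
                          component_separation = 15, n_species = 11)
  emb <- generate_embeddings(cfg, n_per_species = 30)
  proj <- project_embeddings(emb, "tsne", seed = 3, perplexity = 50,
                             n_iter = 400)
  # nearest-centroid purity against the true mixture components,
  # recovered by 128-d distances to the three true centers
  d128 <- as.matrix(dist(emb$vectors))
  truth <- cutree(hclust(as.dist(d128), method = "single"), k = 3)
  centroids <- rowsum(proj$coords, truth) / as.vector(table(truth))
  assigned <- apply(proj$coords, 1, function(p) {
    which.min(colSums((t(centroids) - p)^2))
  })
  purity <- mean(assigned == truth)
  expect_gt(purity, 0.95)
  expect_error(project_embeddings(emb, "tsne", perplexity = 1000),
               "perplexity")
})

test_that("bin entropies match the closed-form values", {
  # a projection laid out so bins are fully controlled: one bin per
  # quadrant, labels assigned per construction
  set.seed(1)
  coords <- rbind(
    cbind(runif(40, 0, 1), runif(40, 0, 1)),      # bin 1: one kingdom
    cbind(runif(40, 9, 10), runif(40, 0, 1)),     # bin 2: 4 kingdoms even
    cbind(runif(40, 0, 1), runif(40, 9, 10)),     # bin 3: (.5, .25, .25)
    cbind(runif(8, 9, 10), runif(8, 9, 10))       # bin 4: below min_count
  )
  labels <- c(rep("A", 40),
              rep(c("A", "B", "C", "D"), 10),
              rep(c("A", "A", "B", "C"), 10),
              rep("D", 8))
  proj <- structure(list(coords = coords, method = "pca"),
                    class = "projection2d")
  gr <- binned_entropy(proj, labels, 2, 2, min_count = 20)
  expect_equal(gr$count, matrix(c(40, 40, 40, 8), 2))
  expect_equal(gr$entropy[1, 1], 0)
  expect_equal(gr$entropy[2, 1], log(4), tolerance = 1e-12)
  expect_equal(gr$entropy[1, 2], 1.5 * log(2), tolerance = 1e-12)
  expect_true(is.na(gr$entropy[2, 2]))
  # bounds and conservation
  expect_true(all(gr$entropy >= 0 & gr$entropy <= log(4), na.rm = TRUE))
  expect_equal(sum(gr$count), length(labels))

  # entropy is invariant under label permutation
  remap <- c(A = "D", B = "C", C = "B", D = "A")
  gr2 <- binned_entropy(proj, unname(remap[labels]), 2, 2, min_count = 20)
  expect_equal(gr2$entropy, gr$entropy)

  # masked-bin count is monotone in the threshold
  masked <- function(min_count) {
    g <- binned_entropy(proj, labels, 2, 2, min_count = min_count)
    sum(is.na(g$entropy) & g$count > 0)
  }
  expect_true(all(diff(vapply(c(1, 10, 41, 100), masked, 0)) >= 0))

  expect_error(binned_entropy(proj, labels, 0, 2), "at least one bin")
  expect_error(binned_entropy(proj, labels[-1], 2, 2), "label")
})

test_that("kingdom mixing in the generator drives the entropy map", {
  # shared components: occupied bins are close to maximal diversity
  cfg <- synthetic_config(seed = 5, n_species = 4, n_components = 1)
  emb <- generate_embeddings(cfg, n_per_species = 100)
  proj <- project_embeddings(emb, "pca")
  gr <- binned_entropy(proj, emb$labels$kingdom, 5, 5, min_count = 20)
  occ <- gr$entropy[!is.na(gr$entropy)]
  expect_gt(length(occ), 0)
  expect_true(all(occ > 0.8 * log(4)))

  # perfectly segregated kingdoms: entropy 0 in every robust bin
  cfg2 <- synthetic_config(seed = 5, n_species = 2,
                           kingdoms = c("Bacteria", "Fungi"),
                           kingdom_association = "strong",
                           component_separation = 40)
  emb2 <- generate_embeddings(cfg2, n_per_species = 120)
  proj2 <- project_embeddings(emb2, "pca")
  gr2 <- binned_entropy(proj2, emb2$labels$kingdom, 6, 6, min_count = 20)
  occ2 <- gr2$entropy[!is.na(gr2$entropy)]
  expect_true(all(occ2 == 0))
})
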